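# ---------------------------------------------------------------------------
# Cohort containers and tabular I/O.
#
# A mood_stream is one participant's weekly four-channel score sequence
# (ASRM, QIDS, EQ-5D, GAD-7) with the sentinel -1 marking missing responses
# and an optional diagnosis in {BD, HC, BPD}.  A mood_cohort is a list of
# streams.
# ---------------------------------------------------------------------------

MOODSIG_CHANNELS <- c("ASRM", "QIDS", "EQ5D", "GAD7")
MOODSIG_CLASSES <- c("BD", "HC", "BPD")
MOODSIG_SENTINEL <- -1

# display names used in reports and plots
.channel_display <- c(ASRM = "ASRM", QIDS = "QIDS", EQ5D = "EQ-5D",
                      GAD7 = "GAD-7", MISS = "the missing signal")

#' Instrument score ranges
#'
#' Maximum attainable total score per instrument: QIDS 0-27, GAD-7 0-21,
#' EQ-5D 0-100.  The ASRM maximum defaults to the instrument's published
#' maximum of 20 and is configurable.
#'
#' @param asrm_max maximum ASRM score.
#' @return Named numeric vector of per-channel maxima.
#' @export
instrument_ranges <- function(asrm_max = 20) {
  c(ASRM = asrm_max, QIDS = 27, EQ5D = 100, GAD7 = 21)
}

#' Construct a single participant's mood stream
#'
#' @param participant_id identifier (coerced to character).
#' @param scores W x 4 numeric matrix of weekly scores, columns ASRM, QIDS,
#'   EQ5D, GAD7; the value `sentinel` marks a missing response.
#' @param diagnosis one of `"BD"`, `"HC"`, `"BPD"`, or `NA` for unlabeled
#'   streams.
#' @param weeks integer week indices (consecutive, step 1); defaults to
#'   `1:nrow(scores)`.
#' @param ranges per-channel maxima used for validation.
#' @param sentinel missing-value code (default -1).
#' @return An object of class `mood_stream`.
#' @export
mood_stream <- function(participant_id, scores, diagnosis = NA_character_,
                        weeks = NULL, ranges = instrument_ranges(),
                        sentinel = MOODSIG_SENTINEL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != length(MOODSIG_CHANNELS))
    stop("'scores' must have ", length(MOODSIG_CHANNELS), " columns")
  colnames(scores) <- MOODSIG_CHANNELS
  if (is.null(weeks)) weeks <- seq_len(nrow(scores))
  if (length(weeks) != nrow(scores) || any(diff(weeks) != 1L))
    stop("'weeks' must be consecutive integers matching nrow(scores)")
  if (!is.na(diagnosis) && !diagnosis %in% MOODSIG_CLASSES)
    stop("unknown diagnosis label: ", diagnosis)
  for (ch in MOODSIG_CHANNELS) {
    v <- scores[, ch]
    bad <- !is.na(v) & v != sentinel & (v < 0 | v > ranges[[ch]])
    if (any(bad))
      stop(sprintf("participant %s: %s score out of range [0, %g] in week(s) %s",
                   participant_id, ch, ranges[[ch]],
                   paste(weeks[bad], collapse = ", ")))
  }
  structure(list(participant_id = as.character(participant_id),
                 diagnosis = diagnosis,
                 weeks = as.integer(weeks),
                 scores = scores,
                 sentinel = sentinel),
            class = "mood_stream")
}

#' @export
print.mood_stream <- function(x, ...) {
  n_miss <- sum(x$scores == x$sentinel)
  cat(sprintf("Mood stream %s (%s): %d weeks, %d missing entries (%.1f%%)\n",
              x$participant_id,
              ifelse(is.na(x$diagnosis), "unlabeled", x$diagnosis),
              nrow(x$scores), n_miss,
              100 * n_miss / length(x$scores)))
  invisible(x)
}

#' Construct a cohort from a list of mood streams
#'
#' @param streams list of `mood_stream` objects with unique participant ids.
#' @return An object of class `mood_cohort` (a list of streams).
#' @export
mood_cohort <- function(streams) {
  stopifnot(all(vapply(streams, inherits, logical(1), "mood_stream")))
  ids <- vapply(streams, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids)) stop("duplicate participant ids in cohort")
  names(streams) <- ids
  structure(streams, class = "mood_cohort")
}

#' @export
print.mood_cohort <- function(x, ...) {
  dx <- vapply(x, `[[`, character(1), "diagnosis")
  cat(sprintf("Mood cohort: %d participants (%s)\n", length(x),
              paste(sprintf("%s %d", MOODSIG_CLASSES,
                            vapply(MOODSIG_CLASSES,
                                   function(g) sum(dx == g, na.rm = TRUE),
                                   numeric(1))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.mood_cohort <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(s) {
    data.frame(participant_id = s$participant_id,
               week = s$weeks,
               asrm = s$scores[, "ASRM"],
               qids = s$scores[, "QIDS"],
               eq5d = s$scores[, "EQ5D"],
               gad7 = s$scores[, "GAD7"],
               diagnosis = s$diagnosis,
               row.names = NULL)
  }))
}

#' Read a cohort from CSV
#'
#' Two schemas are supported.  `"wide"`: one row per participant-week with
#' columns `participant_id, week, asrm, qids, eq5d, gad7[, diagnosis]`.
#' `"long"`: one row per response with columns
#' `participant_id, date, instrument, score[, diagnosis]`, which is aligned to
#' calendar weeks via [align_weekly()].
#'
#' @param path CSV file path (UTF-8, header row).
#' @param schema `"wide"` or `"long"`.
#' @param ranges per-channel maxima for validation.
#' @param sentinel missing-value code.
#' @return A `mood_cohort`.
#' @export
read_cohort <- function(path, schema = c("wide", "long"),
                        ranges = instrument_ranges(),
                        sentinel = MOODSIG_SENTINEL) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty cohort file: ", path)
    return(mood_cohort(list()))
  }
  if (schema == "long") return(align_weekly(df, ranges = ranges,
                                            sentinel = sentinel))
  need <- c("participant_id", "week", "asrm", "qids", "eq5d", "gad7")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("wide cohort CSV lacks column(s): ", paste(miss, collapse = ", "))
  has_dx <- "diagnosis" %in% names(df)
  streams <- lapply(split(df, df$participant_id), function(g) {
    g <- g[order(g$week), ]
    dx <- if (has_dx) unique(g$diagnosis) else NA_character_
    if (length(dx) > 1L)
      stop("participant ", g$participant_id[1L],
           " carries multiple diagnosis labels")
    mood_stream(g$participant_id[1L],
                cbind(g$asrm, g$qids, g$eq5d, g$gad7),
                diagnosis = dx, weeks = g$week,
                ranges = ranges, sentinel = sentinel)
  })
  mood_cohort(unname(streams))
}

#' Write a cohort to wide-format CSV
#'
#' @param cohort a `mood_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Align a long-format response table to calendar weeks
#'
#' Builds one stream per participant covering every calendar (ISO, Monday-
#' based) week from their first to their last response.  Exact duplicate rows
#' are dropped; when several responses to the same instrument fall in one
#' week, only the earliest is kept; weeks with no response to an instrument
#' receive the sentinel.
#'
#' @param raw_rows data.frame with columns `participant_id, date, instrument,
#'   score` and optionally `diagnosis`; `instrument` in
#'   `asrm/qids/eq5d/gad7` (case-insensitive).
#' @param ranges,sentinel see [mood_stream()].
#' @return A `mood_cohort`.
#' @export
align_weekly <- function(raw_rows, ranges = instrument_ranges(),
                         sentinel = MOODSIG_SENTINEL) {
  need <- c("participant_id", "date", "instrument", "score")
  miss <- setdiff(need, names(raw_rows))
  if (length(miss))
    stop("long cohort table lacks column(s): ", paste(miss, collapse = ", "))
  raw_rows <- unique(raw_rows)
  inst <- toupper(gsub("[^[:alnum:]]", "", raw_rows$instrument))
  inst[inst == "EQ5D"] <- "EQ5D"
  unknown <- setdiff(unique(inst), MOODSIG_CHANNELS)
  if (length(unknown))
    stop("unknown instrument name(s): ", paste(unknown, collapse = ", "))
  dates <- as.Date(raw_rows$date)
  if (anyNA(dates)) stop("unparseable date(s) in rows ",
                         paste(which(is.na(dates)), collapse = ", "))
  # Monday-based calendar-week bin (1970-01-05 was a Monday)
  wk <- as.integer(floor((as.numeric(dates) - 4) / 7))
  has_dx <- "diagnosis" %in% names(raw_rows)
  streams <- lapply(split(seq_len(nrow(raw_rows)), raw_rows$participant_id),
                    function(ii) {
    pid <- raw_rows$participant_id[ii[1L]]
    ord <- ii[order(dates[ii])]
    wks <- wk[ord]
    rng <- wks[1L]:wks[length(wks)]
    sc <- matrix(sentinel, nrow = length(rng),
                 ncol = length(MOODSIG_CHANNELS),
                 dimnames = list(NULL, MOODSIG_CHANNELS))
    for (j in ord) {
      r <- match(wk[j], rng)
      ch <- inst[j]
      if (sc[r, ch] == sentinel)  # first response of the week wins
        sc[r, ch] <- raw_rows$score[j]
    }
    dx <- if (has_dx) unique(raw_rows$diagnosis[ii]) else NA_character_
    mood_stream(pid, sc, diagnosis = dx[1L], weeks = seq_along(rng),
                ranges = ranges, sentinel = sentinel)
  })
  mood_cohort(unname(streams))
}

#' Drop participants with too little data
#'
#' Removes streams whose task-active duration is below `min_weeks` (default
#' ten, the minimum needed for one analysis window).
#'
#' @param cohort a `mood_cohort`.
#' @param min_weeks minimum number of weeks to retain a participant.
#' @return The filtered `mood_cohort`; the number removed is messaged.
#' @export
apply_exclusions <- function(cohort, min_weeks = 10L) {
  stopifnot(min_weeks >= 1L)
  if (!length(cohort)) {
    warning("empty cohort")
    return(cohort)
  }
  keep <- vapply(cohort, function(s) nrow(s$scores) >= min_weeks, logical(1))
  if (any(!keep))
    message(sum(!keep), " participant(s) excluded (< ", min_weeks,
            " weeks of data); ", sum(keep), " retained")
  mood_cohort(unname(cohort[keep]))
}

#' Per-group cohort summaries
#'
#' For each diagnostic group: the median and interquartile range of
#' per-participant missing-response proportions; the Pearson correlation
#' matrix of per-participant mean scores (over valid responses); and
#' per-instrument proportions of participant-weeks that are missing, at or
#' below, or above the clinical cutoff (ASRM > 5 manic, QIDS > 10 moderate
#' depression, GAD-7 > 10 moderate anxiety; EQ-5D has no cutoff and reports
#' missing vs observed only).
#'
#' @param cohort a labeled `mood_cohort`.
#' @return A list with one entry per group: `n`, `missing_median`,
#'   `missing_iqr`, `cor` (4 x 4 or `NULL` when the group has fewer than two
#'   participants), and `state_proportions` (instrument x
#'   \{missing, below_cutoff, above_cutoff\}).
#' @export
cohort_summary <- function(cohort) {
  dx <- vapply(cohort, `[[`, character(1), "diagnosis")
  cutoffs <- c(ASRM = 5, QIDS = 10, EQ5D = NA, GAD7 = 10)
  out <- lapply(MOODSIG_CLASSES, function(g) {
    streams <- cohort[dx == g]
    if (!length(streams)) return(NULL)
    miss_prop <- vapply(streams, function(s)
      mean(s$scores == s$sentinel), numeric(1))
    means <- t(vapply(streams, function(s) {
      vapply(MOODSIG_CHANNELS, function(ch) {
        v <- s$scores[, ch]
        mean(v[v != s$sentinel])
      }, numeric(1))
    }, numeric(length(MOODSIG_CHANNELS))))
    cormat <- if (length(streams) >= 2L) stats::cor(means) else NULL
    allsc <- do.call(rbind, lapply(streams, `[[`, "scores"))
    states <- t(vapply(MOODSIG_CHANNELS, function(ch) {
      v <- allsc[, ch]
      n <- length(v)
      mis <- mean(v == MOODSIG_SENTINEL)
      if (is.na(cutoffs[[ch]])) {
        c(missing = mis, below_cutoff = 1 - mis, above_cutoff = NA)
      } else {
        c(missing = mis,
          below_cutoff = mean(v != MOODSIG_SENTINEL & v <= cutoffs[[ch]]),
          above_cutoff = mean(v != MOODSIG_SENTINEL & v > cutoffs[[ch]]))
      }
    }, numeric(3)))
    list(n = length(streams),
         missing_median = stats::median(miss_prop),
         missing_iqr = stats::IQR(miss_prop),
         cor = cormat,
         state_proportions = states)
  })
  names(out) <- MOODSIG_CLASSES
  out
}
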