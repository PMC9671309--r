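# ---------------------------------------------------------------------------
# Scale-free normalise-and-accumulate transform and ten-week sliding windows.
# ---------------------------------------------------------------------------

#' Sliding-window specification
#'
#' @param width window width in weeks (default 10).
#' @param stride step between window starts in weeks (default 1, overlapping
#'   windows).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 10L, stride = 1L) {
  stopifnot(width >= 2L, stride >= 1L)
  structure(list(width = as.integer(width), stride = as.integer(stride)),
            class = "window_spec")
}

#' Normalise weekly values and accumulate them into a basepointed path
#'
#' Score channels are divided by their instrument maxima so weekly values lie
#' in \[0, 1\]; the missing-count channel's weekly increments are divided by
#' the maximum possible window total (4 channels x window width).  The
#' normalised weekly values are then cumulatively summed and an origin point
#' is prepended, yielding the scale-free path the log-signature is taken of.
#'
#' @param encoded an [encode_missing()] result (aggregated counts).
#' @param ranges per-channel maxima, see [instrument_ranges()].
#' @param width window width used to scale the missing-count channel.
#' @return List with `weekly` (W x 5 normalised weekly increments) and `path`
#'   ((W+1) x 5 cumulative path starting at the origin); the fifth channel is
#'   the missing signal (`MISS`).
#' @export
normalize_accumulate <- function(encoded, ranges = instrument_ranges(),
                                 width = 10L) {
  stopifnot(inherits(encoded, "encoded_stream"))
  if (is.matrix(encoded$miss_count))
    stop("normalize_accumulate expects the aggregated (single-channel) count")
  sc <- encoded$filled
  for (ch in colnames(sc)) {
    if (any(sc[, ch] > ranges[[ch]] | sc[, ch] < 0))
      stop(sprintf("participant %s: %s value outside [0, %g] in week(s) %s",
                   encoded$participant_id, ch, ranges[[ch]],
                   paste(encoded$weeks[sc[, ch] > ranges[[ch]] | sc[, ch] < 0],
                         collapse = ", ")))
    sc[, ch] <- sc[, ch] / ranges[[ch]]
  }
  miss_inc <- diff(c(0, encoded$miss_count)) / (ncol(encoded$filled) * width)
  weekly <- cbind(sc, MISS = miss_inc)
  path <- apply(weekly, 2L, cumsum)
  path <- rbind(0, path)
  list(weekly = weekly, path = path)
}

#' Cut a stream into overlapping analysis windows
#'
#' Missing-response encoding is applied to the full stream first (so the
#' cumulative count keeps its cross-window context), then windows of
#' `spec$width` weeks are cut every `spec$stride` weeks and each window is
#' re-based: normalise-and-accumulate is applied to the window's weekly
#' values so that every window path starts at the origin and windows are
#' translation-comparable.
#'
#' @param encoded an [encode_missing()] result.
#' @param spec a [window_spec()].
#' @param ranges per-channel maxima.
#' @return List of `prepared_window` objects, each with `path`
#'   ((width+1) x 5 matrix), `participant_id`, `diagnosis`, `start_week`;
#'   empty (with a warning) when the stream is shorter than the window.
#' @export
cut_windows <- function(encoded, spec = window_spec(),
                        ranges = instrument_ranges()) {
  stopifnot(inherits(encoded, "encoded_stream"),
            inherits(spec, "window_spec"))
  W <- nrow(encoded$filled)
  if (W < spec$width) {
    warning(sprintf("participant %s: %d week(s) < window width %d; no windows",
                    encoded$participant_id, W, spec$width))
    return(list())
  }
  na <- normalize_accumulate(encoded, ranges = ranges, width = spec$width)
  starts <- seq.int(1L, W - spec$width + 1L, by = spec$stride)
  lapply(starts, function(s) {
    wk <- na$weekly[s:(s + spec$width - 1L), , drop = FALSE]
    path <- rbind(0, apply(wk, 2L, cumsum))
    structure(list(path = path,
                   participant_id = encoded$participant_id,
                   diagnosis = encoded$diagnosis,
                   start_week = encoded$weeks[s]),
              class = "prepared_window")
  })
}

# Windows for a whole cohort: encode + cut per stream, kept in cohort order.
.cohort_windows <- function(cohort, spec = window_spec(),
                            ranges = instrument_ranges()) {
  unlist(lapply(cohort, function(s) cut_windows(encode_missing(s), spec,
                                                ranges)),
         recursive = FALSE, use.names = FALSE)
}
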