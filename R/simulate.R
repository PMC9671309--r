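# ---------------------------------------------------------------------------
# Synthetic three-group mood cohort generator.
#
# Latent per-instrument trajectories are mean-reverting first-order
# autoregressive processes around group baselines; bipolar participants
# additionally carry a two-state episode process shifting ASRM upward (manic
# episodes) or QIDS/GAD-7 upward and EQ-5D downward (depressive episodes);
# borderline participants have larger week-to-week innovations than healthy
# controls.  Missingness is injected per week with a group base rate and an
# optional mood-dependent (MNAR) component tied to latent distress.
# ---------------------------------------------------------------------------

.group_dynamics_defaults <- function() {
  list(
    BD = list(baseline = c(ASRM = 2, QIDS = 8, EQ5D = 70, GAD7 = 6),
              innovation_sd = c(ASRM = 1.0, QIDS = 2.0, EQ5D = 5, GAD7 = 1.5),
              reversion = 0.5,
              episodes = list(hazard = 0.08, mean_duration = 4,
                              p_manic = 0.5,
                              manic_shift = c(ASRM = 8, QIDS = 0,
                                              EQ5D = -5, GAD7 = 0),
                              depressive_shift = c(ASRM = 0, QIDS = 10,
                                                   EQ5D = -25, GAD7 = 6))),
    HC = list(baseline = c(ASRM = 1, QIDS = 3, EQ5D = 85, GAD7 = 2),
              innovation_sd = c(ASRM = 0.5, QIDS = 1.0, EQ5D = 3, GAD7 = 0.8),
              reversion = 0.5,
              episodes = NULL),
    BPD = list(baseline = c(ASRM = 3, QIDS = 12, EQ5D = 60, GAD7 = 10),
               innovation_sd = c(ASRM = 2.5, QIDS = 4.0, EQ5D = 10,
                                 GAD7 = 3.5),
               reversion = 0.3,
               episodes = NULL))
}

#' Configuration for the synthetic cohort generator
#'
#' The `"amoss-like"` preset uses 52 weeks per participant, group sizes
#' (BD 53, HC 52, BPD 34) and weekly missingness base rates ordered
#' HC < BD < BPD (0.05, 0.25, 0.40).  The `"missingness-only"` preset gives
#' all three groups identical (healthy-control) score dynamics so the ONLY
#' group signal is the missingness rate — useful for isolating what the
#' missing-response channel contributes.
#'
#' @param preset `"amoss-like"` (default) or `"missingness-only"`.
#' @param n_per_group named counts for BD, HC, BPD.
#' @param weeks weeks per participant.
#' @param dynamics per-group dynamics (baseline, innovation_sd, reversion,
#'   episodes); defaults depend on the preset.
#' @param missing_base named per-group weekly missingness probabilities.
#' @param mnar_coef log-odds increase in missingness per standard deviation
#'   of latent distress (0 = missing completely at random given group).
#' @param whole_week if `TRUE` (default) a missing week blanks all four
#'   instruments together; otherwise instruments are blanked independently.
#' @param ranges instrument maxima for clipping.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(preset = c("amoss-like", "missingness-only"),
                          n_per_group = NULL,
                          weeks = 52L,
                          dynamics = NULL,
                          missing_base = c(BD = 0.25, HC = 0.05, BPD = 0.40),
                          mnar_coef = 0,
                          whole_week = TRUE,
                          ranges = instrument_ranges()) {
  preset <- match.arg(preset)
  if (is.null(n_per_group))
    n_per_group <- if (preset == "amoss-like") c(BD = 53, HC = 52, BPD = 34)
                   else c(BD = 30, HC = 30, BPD = 30)
  if (is.null(dynamics)) {
    dynamics <- .group_dynamics_defaults()
    if (preset == "missingness-only")
      dynamics <- list(BD = dynamics$HC, HC = dynamics$HC, BPD = dynamics$HC)
  }
  stopifnot(all(missing_base >= 0 & missing_base <= 1),
            all(MOODSIG_CLASSES %in% names(n_per_group)),
            all(MOODSIG_CLASSES %in% names(missing_base)),
            weeks >= 2L)
  structure(list(preset = preset, n_per_group = n_per_group,
                 weeks = as.integer(weeks), dynamics = dynamics,
                 missing_base = missing_base, mnar_coef = mnar_coef,
                 whole_week = whole_week, ranges = ranges),
            class = "cohort_config")
}

#' Generate a complete (no-missing) labeled cohort
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return A `mood_cohort` of complete streams.  Each stream carries a
#'   `"distress"` attribute (the standardised latent QIDS + GAD-7 level) used
#'   by [inject_missing()] for the MNAR component.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  .with_seed(seed, {
    streams <- list()
    pid <- 0L
    for (g in MOODSIG_CLASSES) {
      dyn <- config$dynamics[[g]]
      for (i in seq_len(config$n_per_group[[g]])) {
        pid <- pid + 1L
        streams[[pid]] <- .simulate_stream(sprintf("P%03d", pid), g, dyn,
                                           config$weeks, config$ranges)
      }
    }
    mood_cohort(streams)
  })
}

.simulate_stream <- function(id, group, dyn, W, ranges) {
  C <- length(MOODSIG_CHANNELS)
  lat <- matrix(0, W, C, dimnames = list(NULL, MOODSIG_CHANNELS))
  lat[1L, ] <- dyn$baseline + stats::rnorm(C, 0, dyn$innovation_sd)
  if (W >= 2L) for (t in 2:W) {
    lat[t, ] <- lat[t - 1L, ] +
      dyn$reversion * (dyn$baseline - lat[t - 1L, ]) +
      stats::rnorm(C, 0, dyn$innovation_sd)
  }
  shift <- matrix(0, W, C)
  if (!is.null(dyn$episodes)) {
    ep <- dyn$episodes
    t <- 1L
    while (t <= W) {
      if (stats::runif(1) < ep$hazard) {
        dur <- 1L + stats::rgeom(1L, 1 / ep$mean_duration)
        kind <- if (stats::runif(1) < ep$p_manic) ep$manic_shift
                else ep$depressive_shift
        span <- t:min(W, t + dur - 1L)
        shift[span, ] <- matrix(kind, length(span), C, byrow = TRUE)
        t <- t + dur + 1L
      } else t <- t + 1L
    }
  }
  lat <- lat + shift
  scores <- lat
  for (ch in seq_len(C)) {
    scores[, ch] <- round(pmin(pmax(lat[, ch], 0), ranges[[ch]]))
  }
  distress <- lat[, "QIDS"] / ranges[["QIDS"]] + lat[, "GAD7"] / ranges[["GAD7"]]
  s <- mood_stream(id, scores, diagnosis = group, ranges = ranges)
  attr(s, "distress") <- as.numeric(scale(distress))
  s
}

#' Inject group-dependent missingness into a cohort
#'
#' Each week is independently missing with probability
#' `plogis(qlogis(base) + mnar_coef * distress)`, where `distress` is the
#' standardised latent distress stored by [generate_cohort()] (or recomputed
#' from the observed scores when absent).  In whole-week mode a missing week
#' blanks all four instruments; otherwise each instrument is blanked
#' independently with the same probability.
#'
#' @param cohort a complete `mood_cohort`.
#' @param config a [cohort_config()] providing `missing_base`, `mnar_coef`
#'   and `whole_week`.
#' @param seed integer seed.
#' @return A `mood_cohort` with sentinel entries.
#' @export
inject_missing <- function(cohort, config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  .with_seed(seed, {
    streams <- lapply(cohort, function(s) {
      base <- config$missing_base[[s$diagnosis]]
      W <- nrow(s$scores)
      distress <- attr(s, "distress")
      if (is.null(distress)) {
        z <- rowSums(scale(s$scores[, c("QIDS", "GAD7")]))
        distress <- as.numeric(scale(z))
      }
      p <- if (base <= 0) rep(0, W)
           else if (base >= 1) rep(1, W)
           else stats::plogis(stats::qlogis(base) +
                              config$mnar_coef * distress)
      sc <- s$scores
      if (config$whole_week) {
        hit <- stats::runif(W) < p
        sc[hit, ] <- s$sentinel
      } else {
        hit <- matrix(stats::runif(W * ncol(sc)), W) < p
        sc[hit] <- s$sentinel
      }
      s$scores <- sc
      s
    })
    mood_cohort(unname(streams))
  })
}

#' Simulate a labeled cohort with missingness in one call
#'
#' Convenience wrapper: [generate_cohort()] then [inject_missing()], with the
#' two stages seeded from `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return A `mood_cohort`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  inject_missing(generate_cohort(config, seed = seed), config,
                 seed = seed + 100003L)
}

#' Empirical missingness rate per group
#'
#' @param cohort a `mood_cohort`.
#' @return Named numeric vector: mean fraction of missing entries per group.
#' @export
missing_rate <- function(cohort) {
  dx <- vapply(cohort, `[[`, character(1), "diagnosis")
  vapply(MOODSIG_CLASSES, function(g) {
    sc <- do.call(rbind, lapply(cohort[dx == g], `[[`, "scores"))
    if (is.null(sc)) return(NA_real_)
    mean(sc == MOODSIG_SENTINEL)
  }, numeric(1))
}
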