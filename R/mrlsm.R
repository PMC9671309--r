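# ---------------------------------------------------------------------------
# mrlsm(): the missing-response-incorporated log-signature model, and the
# comparison baselines, under one participant-level cross-validation harness.
# ---------------------------------------------------------------------------

#' Fit the missing-response-incorporated log-signature model (MRLSM)
#'
#' Runs the full pipeline on a labeled cohort: missing-response encoding,
#' ten-week sliding windows of the normalised accumulated five-channel path,
#' level-`level` log-signature features, and a random-forest classifier under
#' `k`-fold participant-level cross-validation; window predictions are
#' aggregated to participant diagnoses by hard (majority) and soft (summed
#' probability) voting.  The comparison baselines run under the identical
#' harness: `"naive"` uses per-window mean scores over valid responses;
#' `"knn"` and `"ppca"` impute the weekly observation matrix (within each
#' training fold by default) and classify flattened window vectors;
#' `"external"` accepts a cohort already completed by an outside imputer.
#'
#' @param cohort a labeled [mood_cohort()].
#' @param method feature pipeline: `"mrlsf"` (default), `"naive"`, `"knn"`,
#'   `"ppca"` or `"external"`.
#' @param level log-signature truncation level (default 3).
#' @param window a [window_spec()] (default ten-week windows, stride 1).
#' @param k number of cross-validation folds (default 3).
#' @param seed integer seed controlling fold assignment, forests and the
#'   AUC bootstrap.
#' @param folds optional [make_folds()] assignment, for paired comparisons
#'   across methods.
#' @param ranges instrument maxima, see [instrument_ranges()].
#' @param rf an [rf_control()].
#' @param knn_k neighbours for `"knn"` (default 5).
#' @param ppca_components,ppca_tol,ppca_max_iter PPCA-EM settings.
#' @param transductive if `TRUE`, imputation baselines impute once on the
#'   full cohort instead of within training folds (the literal reading of
#'   impute-first protocols; the default is the stricter leakage-free one).
#' @param boot_B bootstrap replicates for AUC confidence intervals.
#' @param keep_models keep the per-fold forests on the returned object.
#' @return An object of class `mrlsm` with components `eval` (accuracy, F1,
#'   confusion, AUC), `predictions`, `importance_table`, `folds` and the
#'   refit full-data model used by [predict.mrlsm()].
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(n_per_group = c(BD = 8, HC = 8, BPD = 8),
#'                                      weeks = 16), seed = 1)
#' fit <- mrlsm(coh, rf = rf_control(ntree = 100), boot_B = 100, seed = 1)
#' summary(fit)
#' }
#' @export
mrlsm <- function(cohort,
                  method = c("mrlsf", "naive", "knn", "ppca", "external"),
                  level = 3L,
                  window = window_spec(),
                  k = 3L,
                  seed = 1L,
                  folds = NULL,
                  ranges = instrument_ranges(),
                  rf = rf_control(),
                  knn_k = 5L,
                  ppca_components = 2L,
                  ppca_tol = 1e-6,
                  ppca_max_iter = 200L,
                  transductive = FALSE,
                  boot_B = 1000L,
                  keep_models = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "mood_cohort"))
  cohort <- apply_exclusions(cohort, min_weeks = window$width)
  if (!length(cohort))
    stop("no participant provides at least ", window$width,
         " weeks of data")
  dx <- vapply(cohort, `[[`, character(1), "diagnosis")
  if (anyNA(dx)) stop("all participants must carry a diagnosis label")
  if (is.null(folds)) folds <- make_folds(names(cohort), dx, k = k,
                                          seed = seed)
  built <- .build_features(cohort, method, level, window, ranges, knn_k,
                           ppca_components, ppca_tol, ppca_max_iter,
                           transductive, folds)
  cvres <- fit_predict_cv(built$windowset, folds, rf = rf, seed = seed,
                          fold_features = built$fold_features,
                          keep_models = keep_models)
  eval <- evaluate_predictions(cvres$predictions, dx, boot_B = boot_B,
                               boot_seed = seed)
  imp_tab <- if (method == "mrlsf") {
    importance_report(cvres$importance, built$windowset$words)
  } else {
    avg <- rowMeans(cvres$importance)
    if (sum(avg) > 0) avg <- avg / sum(avg)
    ord <- utils::head(order(avg, decreasing = TRUE), 10L)
    data.frame(rank = seq_along(ord),
               feature = rownames(cvres$importance)[ord],
               importance = avg[ord],
               interpretation = rownames(cvres$importance)[ord],
               row.names = NULL)
  }
  final <- .with_seed(seed, .fit_rf(built$final_features,
                                    factor(built$windowset$labels,
                                           levels = MOODSIG_CLASSES), rf))
  structure(list(call = match.call(),
                 method = method,
                 level = as.integer(level),
                 window = window,
                 k = folds$k,
                 seed = as.integer(seed),
                 classes = MOODSIG_CLASSES,
                 folds = folds,
                 n_participants = length(cohort),
                 n_windows = nrow(built$windowset$features),
                 truth = dx,
                 windowset = built$windowset,
                 predictions = cvres$predictions,
                 importance = cvres$importance,
                 importance_table = imp_tab,
                 eval = eval,
                 fold_models = cvres$fold_models,
                 final_model = final,
                 transformer = built$transformer,
                 ranges = ranges),
            class = "mrlsm")
}

# Build the window-level feature set for a method, plus the per-fold feature
# builder for leakage-free imputation and the transformer state needed to
# featurise new cohorts at predict() time.
.build_features <- function(cohort, method, level, window, ranges, knn_k,
                            ppca_components, ppca_tol, ppca_max_iter,
                            transductive, folds) {
  if (method == "mrlsf") {
    ws <- extract_mrlsf(.cohort_windows(cohort, window, ranges), p = level)
    return(list(windowset = ws, fold_features = NULL,
                final_features = ws$features,
                transformer = list(kind = "mrlsf", level = level,
                                   window = window, ranges = ranges)))
  }
  wi <- .window_index(cohort, window)
  idx <- wi$index
  X <- wi$weekly$X
  width <- window$width
  flat_names <- paste0("wk", rep(seq_len(width), each = ncol(X)), "_",
                       rep(tolower(MOODSIG_CHANNELS), width))
  flatten_rows <- function(Ximp, starts) {
    out <- t(vapply(starts, function(r)
      flatten_features(Ximp[r:(r + width - 1L), , drop = FALSE]),
      numeric(width * ncol(X))))
    colnames(out) <- flat_names
    out
  }
  if (method == "naive") {
    feats <- t(vapply(seq_len(nrow(idx)), function(i) {
      r <- idx$global_start[i]
      pid <- idx$participant_id[i]
      srows <- which(wi$weekly$row_participant == pid)
      naive_features(X[r:(r + width - 1L), , drop = FALSE],
                     X[srows, , drop = FALSE],
                     participant_id = pid, sentinel = NA)
    }, numeric(ncol(X))))
    colnames(feats) <- paste0("mean_", tolower(MOODSIG_CHANNELS))
    ws <- structure(list(features = feats,
                         window_participant = idx$participant_id,
                         labels = idx$diagnosis, words = NULL, p = NA),
                    class = "window_set")
    return(list(windowset = ws, fold_features = NULL, final_features = feats,
                transformer = list(kind = "naive", window = window)))
  }
  if (method == "external") {
    if (anyNA(X))
      stop("method 'external' expects a sentinel-free (pre-imputed) cohort")
    feats <- flatten_rows(X, idx$global_start)
    ws <- structure(list(features = feats,
                         window_participant = idx$participant_id,
                         labels = idx$diagnosis, words = NULL, p = NA),
                    class = "window_set")
    return(list(windowset = ws, fold_features = NULL, final_features = feats,
                transformer = list(kind = "external", window = window)))
  }
  # knn / ppca
  impute_with_pool <- function(pool_rows) {
    if (method == "knn") {
      list(full = knn_impute(X, K = knn_k,
                             pool = X[pool_rows, , drop = FALSE]),
           fit = NULL)
    } else {
      fit <- ppca_impute(X[pool_rows, , drop = FALSE],
                         n_components = ppca_components,
                         tol = ppca_tol, max_iter = ppca_max_iter)
      full <- X
      full[pool_rows, ] <- fit$completed
      other <- setdiff(seq_len(nrow(X)), pool_rows)
      if (length(other))
        full[other, ] <- .ppca_fill(fit, X[other, , drop = FALSE])
      list(full = full, fit = fit)
    }
  }
  full_imp <- impute_with_pool(seq_len(nrow(X)))
  feats_full <- flatten_rows(full_imp$full, idx$global_start)
  ws <- structure(list(features = feats_full,
                       window_participant = idx$participant_id,
                       labels = idx$diagnosis, words = NULL, p = NA),
                  class = "window_set")
  fold_features <- NULL
  if (!transductive) {
    fold_features <- function(train_w, test_w) {
      train_pids <- unique(idx$participant_id[train_w])
      pool_rows <- which(wi$weekly$row_participant %in% train_pids)
      imp <- impute_with_pool(pool_rows)
      list(train = flatten_rows(imp$full, idx$global_start[train_w]),
           test = flatten_rows(imp$full, idx$global_start[test_w]))
    }
  }
  list(windowset = ws, fold_features = fold_features,
       final_features = feats_full,
       transformer = list(kind = method, window = window,
                          knn_k = knn_k, knn_pool = if (method == "knn") X,
                          ppca_fit = full_imp$fit))
}

#' @export
print.mrlsm <- function(x, ...) {
  cat(sprintf("%s: %s features, level %s, %d-fold participant-level CV\n",
              "Mood-stream diagnostic classifier",
              switch(x$method,
                     mrlsf = "missing-response-incorporated log-signature",
                     naive = "naive mean-score",
                     knn = "KNN-imputed flattened",
                     ppca = "PPCA-imputed flattened",
                     external = "externally imputed flattened"),
              ifelse(x$method == "mrlsf", x$level, "-"), x$k))
  cat(sprintf("  %d participants, %d windows of %d weeks\n",
              x$n_participants, x$n_windows, x$window$width))
  cat(sprintf("  accuracy: hard voting %.1f%%, soft voting %.1f%%\n",
              100 * x$eval$accuracy[["hard"]],
              100 * x$eval$accuracy[["soft"]]))
  invisible(x)
}

#' @export
summary.mrlsm <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$eval)
  cat("\nConfusion matrix (hard voting):\n")
  print(object$eval$confusion$hard)
  cat("\nTop features:\n")
  print(object$importance_table, digits = 3)
  invisible(object)
}

#' Predict diagnoses for a new cohort
#'
#' Featurises the new streams with the transformer state stored at fit time
#' (for the imputation baselines, the full training pool / fitted PPCA model)
#' and applies the full-data forest; window probabilities are aggregated per
#' participant by both votings.
#'
#' @param object a fitted [mrlsm()] object.
#' @param newdata a `mood_cohort` (labels not required).
#' @param ... unused.
#' @return data.frame with `participant_id`, `hard`, `soft` labels and the
#'   three soft-vote class probabilities.
#' @export
predict.mrlsm <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "mood_cohort"))
  tr <- object$transformer
  width <- object$window$width
  if (tr$kind == "mrlsf") {
    ws <- extract_mrlsf(.cohort_windows(newdata, object$window,
                                        object$ranges), p = object$level)
    feats <- ws$features
    wp <- ws$window_participant
  } else {
    wi <- .window_index(newdata, object$window)
    X <- wi$weekly$X
    wp <- wi$index$participant_id
    if (tr$kind == "naive") {
      feats <- t(vapply(seq_len(nrow(wi$index)), function(i) {
        r <- wi$index$global_start[i]
        pid <- wi$index$participant_id[i]
        srows <- which(wi$weekly$row_participant == pid)
        naive_features(X[r:(r + width - 1L), , drop = FALSE],
                       X[srows, , drop = FALSE], pid, sentinel = NA)
      }, numeric(ncol(X))))
    } else {
      Ximp <- switch(tr$kind,
        knn = knn_impute(X, K = tr$knn_k, pool = tr$knn_pool),
        ppca = if (anyNA(X)) .ppca_fill(tr$ppca_fit, X) else X,
        external = { if (anyNA(X)) stop("new cohort has missing entries"); X })
      feats <- t(vapply(wi$index$global_start, function(r)
        flatten_features(Ximp[r:(r + width - 1L), , drop = FALSE]),
        numeric(width * ncol(X))))
    }
    colnames(feats) <- colnames(object$windowset$features)
  }
  probs <- stats::predict(object$final_model, feats,
                          type = "prob")[, MOODSIG_CLASSES, drop = FALSE]
  res <- lapply(unique(wp), function(pid) {
    rows <- probs[wp == pid, , drop = FALSE]
    sv <- vote_soft(rows)
    c(list(participant_id = pid, hard = vote_hard(rows), soft = sv$label),
      as.list(stats::setNames(sv$soft_prob,
                              paste0("prob_", MOODSIG_CLASSES))))
  })
  do.call(rbind, lapply(res, as.data.frame))
}

#' Plot the probability-simplex spectrum of a fitted model
#'
#' Projects each participant's soft-vote probability vector onto the
#' equilateral triangle (vertices BD lower-left, HC lower-right, BPD apex)
#' and overlays highest-density contours enclosing 25/50/75% of each group's
#' participants.
#'
#' @param x a fitted [mrlsm()] object.
#' @param groups which true groups to draw (default all three).
#' @param ... passed to [plot_spectrum()].
#' @export
plot.mrlsm <- function(x, groups = MOODSIG_CLASSES, ...) {
  probs <- t(vapply(x$predictions, `[[`, numeric(3), "soft_prob"))
  plot_spectrum(probs, x$truth[rownames(probs)], groups = groups, ...)
}
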