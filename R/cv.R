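# ---------------------------------------------------------------------------
# Participant-level cross-validation, window-to-participant voting, and
# evaluation metrics.
# ---------------------------------------------------------------------------

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified participant-level fold assignment
#'
#' Partitions participants into `k` folds, stratified by diagnosis, so that
#' every participant is held out exactly once and no participant's windows
#' ever appear on both sides of a split.
#'
#' @param participants character vector of participant ids (unique).
#' @param labels diagnoses, parallel to `participants`.
#' @param k number of folds (default 3).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return An object of class `fold_assignment`: list with
#'   `fold_of_participant` (named integer vector, folds `1..k`), `k`, `seed`.
#' @export
make_folds <- function(participants, labels, k = 3L, seed = 1L) {
  stopifnot(k >= 2L, !anyDuplicated(participants),
            length(participants) == length(labels))
  tab <- table(labels)
  if (any(tab < k))
    stop("class(es) with fewer than k participants: ",
         paste(names(tab)[tab < k], collapse = ", "))
  fold <- integer(length(participants))
  names(fold) <- participants
  .with_seed(seed, {
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(fold_of_participant = fold, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Random-forest configuration
#'
#' Hyperparameters for the window-level classifier: 500 trees, unlimited
#' depth, square-root feature subsampling (the `randomForest` classification
#' default when `mtry = NULL`).
#'
#' @param ntree number of trees.
#' @param mtry variables tried at each split; `NULL` for `floor(sqrt(F))`.
#' @param nodesize minimum terminal node size.
#' @return A list of class `rf_control`.
#' @export
rf_control <- function(ntree = 500L, mtry = NULL, nodesize = 1L) {
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 nodesize = as.integer(nodesize)),
            class = "rf_control")
}

.fit_rf <- function(x, y, rf) {
  mtry <- if (is.null(rf$mtry)) max(1L, floor(sqrt(ncol(x)))) else rf$mtry
  randomForest::randomForest(x = x, y = y, ntree = rf$ntree, mtry = mtry,
                             nodesize = rf$nodesize, importance = FALSE)
}

#' Cross-validated window probabilities aggregated per participant
#'
#' For each fold, trains a random forest on all windows of the training-fold
#' participants and predicts class probabilities for every hold-out window;
#' each participant is predicted exactly once.  A feature builder may be
#' supplied for methods whose features depend on the training fold (the
#' imputation baselines); by default the fixed `windowset$features` matrix is
#' used for both sides.
#'
#' @param windowset a `window_set` (or any list with `features`,
#'   `window_participant`, `labels`).
#' @param folds a [make_folds()] assignment.
#' @param rf an [rf_control()].
#' @param seed integer seed for the per-fold forests.
#' @param fold_features optional `function(train_idx, test_idx)` returning
#'   `list(train = <matrix>, test = <matrix>)` of fold-specific features.
#' @return List with `predictions` (per participant: class
#'   `participant_prediction` with `window_probs`, hard/soft labels and
#'   `soft_prob`), `importance` (feature x fold matrix of mean-decrease-Gini
#'   importances), `fold_models` (NULL unless `keep_models`).
#' @param keep_models keep the fitted per-fold forests (memory-heavy).
#' @export
fit_predict_cv <- function(windowset, folds, rf = rf_control(), seed = 1L,
                           fold_features = NULL, keep_models = FALSE) {
  wp <- windowset$window_participant
  labs <- windowset$labels
  fmap <- folds$fold_of_participant
  if (!all(unique(wp) %in% names(fmap)))
    stop("fold assignment does not cover all window participants")
  classes <- MOODSIG_CLASSES
  probs <- matrix(NA_real_, nrow = length(wp), ncol = length(classes),
                  dimnames = list(NULL, classes))
  nfeat <- ncol(windowset$features)
  imp <- matrix(0, nrow = nfeat, ncol = folds$k,
                dimnames = list(colnames(windowset$features), NULL))
  models <- if (keep_models) vector("list", folds$k) else NULL
  for (f in seq_len(folds$k)) {
    test_w <- which(fmap[wp] == f)
    train_w <- which(fmap[wp] != f)
    # leakage guard: asserted, not assumed
    stopifnot(length(intersect(wp[train_w], wp[test_w])) == 0L)
    y <- factor(labs[train_w], levels = classes)
    if (length(unique(labs[train_w])) < 2L)
      stop("degenerate training fold: a single class")
    if (is.null(fold_features)) {
      xtr <- windowset$features[train_w, , drop = FALSE]
      xte <- windowset$features[test_w, , drop = FALSE]
    } else {
      ff <- fold_features(train_w, test_w)
      xtr <- ff$train
      xte <- ff$test
    }
    fit <- .with_seed(seed + f, .fit_rf(xtr, y, rf))
    probs[test_w, ] <- stats::predict(fit, xte, type = "prob")[, classes]
    gi <- fit$importance[, "MeanDecreaseGini"]
    if (length(gi) == nfeat) imp[, f] <- gi
    if (keep_models) models[[f]] <- fit
  }
  preds <- lapply(unique(wp), function(pid) {
    rows <- probs[wp == pid, , drop = FALSE]
    hv <- vote_hard(rows)
    sv <- vote_soft(rows)
    structure(list(participant_id = pid,
                   window_probs = rows,
                   hard_label = hv,
                   soft_label = sv$label,
                   soft_prob = sv$soft_prob),
              class = "participant_prediction")
  })
  names(preds) <- unique(wp)
  list(predictions = preds, importance = imp, fold_models = models)
}

#' Hard (majority) vote over a participant's windows
#'
#' Each window votes for its most probable class; the modal class wins.  A
#' tie between modal classes falls back to the soft vote (the summed
#' probabilities), which uses the available probability information instead
#' of an arbitrary choice.
#'
#' @param window_probs M x 3 matrix of window class probabilities (columns
#'   BD, HC, BPD).
#' @return The winning class label.
#' @export
vote_hard <- function(window_probs) {
  window_probs <- rbind(window_probs)
  stopifnot(nrow(window_probs) >= 1L)
  wl <- apply(window_probs, 1L, which.max)  # within-window tie: lowest index
  counts <- tabulate(wl, nbins = ncol(window_probs))
  top <- which(counts == max(counts))
  if (length(top) == 1L) return(MOODSIG_CLASSES[top])
  vote_soft(window_probs)$label
}

#' Soft vote over a participant's windows
#'
#' The participant label is the argmax of the summed window probabilities;
#' exact ties resolve to the lowest class index in the fixed order
#' BD < HC < BPD.
#'
#' @param window_probs M x 3 matrix of window class probabilities.
#' @return List with `label` and `soft_prob` (the column means, a probability
#'   vector).
#' @export
vote_soft <- function(window_probs) {
  window_probs <- rbind(window_probs)
  stopifnot(nrow(window_probs) >= 1L)
  s <- colSums(window_probs)
  list(label = MOODSIG_CLASSES[which.max(s)],
       soft_prob = stats::setNames(s / nrow(window_probs), MOODSIG_CLASSES))
}

#' Evaluate participant-level predictions
#'
#' Computes accuracy under hard and soft voting, per-class F1 scores
#' (harmonic mean of precision and recall), 3 x 3 confusion matrices (rows:
#' truth, columns: prediction), and per-class one-vs-rest ROC AUC from the
#' soft probability vectors with a percentile-bootstrap 95% confidence
#' interval over participants.
#'
#' @param predictions list of `participant_prediction` objects named by
#'   participant id.
#' @param true_labels named character vector of diagnoses (one per predicted
#'   participant).
#' @param boot_B bootstrap replicates for the AUC interval.
#' @param boot_seed seed for the bootstrap resampling.
#' @return An object of class `mrlsm_eval`.
#' @export
evaluate_predictions <- function(predictions, true_labels, boot_B = 1000L,
                                 boot_seed = 1L) {
  ids <- names(predictions)
  if (!all(ids %in% names(true_labels)))
    stop("missing true labels for: ",
         paste(setdiff(ids, names(true_labels)), collapse = ", "))
  truth <- factor(true_labels[ids], levels = MOODSIG_CLASSES)
  hard <- factor(vapply(predictions, `[[`, character(1), "hard_label"),
                 levels = MOODSIG_CLASSES)
  soft <- factor(vapply(predictions, `[[`, character(1), "soft_label"),
                 levels = MOODSIG_CLASSES)
  probs <- t(vapply(predictions, `[[`, numeric(3), "soft_prob"))
  conf <- function(pred) table(truth = truth, prediction = pred)
  f1_of <- function(cm) {
    prec <- diag(cm) / pmax(colSums(cm), 1)
    rec <- diag(cm) / pmax(rowSums(cm), 1)
    f1 <- 2 * prec * rec / (prec + rec)
    f1[is.nan(f1)] <- 0
    f1
  }
  cm_h <- conf(hard)
  cm_s <- conf(soft)
  auc_of <- function(idx) {
    vapply(seq_along(MOODSIG_CLASSES), function(ci) {
      resp <- as.integer(truth[idx] == MOODSIG_CLASSES[ci])
      if (length(unique(resp)) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, probs[idx, ci], quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    }, numeric(1))
  }
  auc <- auc_of(seq_along(truth))
  ci <- .with_seed(boot_seed, {
    reps <- replicate(boot_B,
                      auc_of(sample.int(length(truth), replace = TRUE)))
    apply(rbind(reps), 1L, stats::quantile,
          probs = c(0.025, 0.975), na.rm = TRUE)
  })
  structure(list(
    n = length(truth),
    accuracy = c(hard = mean(hard == truth), soft = mean(soft == truth)),
    f1 = rbind(hard = f1_of(cm_h), soft = f1_of(cm_s)),
    confusion = list(hard = cm_h, soft = cm_s),
    auc = data.frame(class = MOODSIG_CLASSES, auc = auc,
                     ci_lo = ci[1L, ], ci_hi = ci[2L, ],
                     row.names = NULL)),
    class = "mrlsm_eval")
}

#' @export
print.mrlsm_eval <- function(x, ...) {
  cat(sprintf("Participant-level evaluation (n = %d)\n", x$n))
  cat(sprintf("  accuracy: hard %.1f%%, soft %.1f%%\n",
              100 * x$accuracy[["hard"]], 100 * x$accuracy[["soft"]]))
  f1 <- x$f1
  colnames(f1) <- MOODSIG_CLASSES
  cat("  F1 by class:\n")
  print(round(f1, 3))
  cat("  one-vs-rest AUC (95% CI):\n")
  with(x$auc, cat(sprintf("    %s: %.3f (%.3f-%.3f)\n",
                          class, auc, ci_lo, ci_hi), sep = ""))
  invisible(x)
}

#' Ranked feature-importance report
#'
#' Averages per-fold random-forest importances, normalises them to sum to
#' one, and renders human-readable interpretations: single-letter words as
#' "Incremental effects of <channel>", two-letter words as "Interaction
#' between <a> and <b>", three-letter words as "Interaction among <a>, <b>
#' and <c>"; the fifth channel is "the missing signal".
#'
#' @param importance feature x fold matrix (from [fit_predict_cv()]).
#' @param words list of integer word vectors, parallel to the rows.
#' @param top_n rows to keep (default 10).
#' @return data.frame with `rank`, `feature`, `importance`,
#'   `interpretation`.
#' @export
importance_report <- function(importance, words, top_n = 10L) {
  avg <- rowMeans(importance)
  tot <- sum(avg)
  if (tot > 0) avg <- avg / tot
  ord <- order(avg, decreasing = TRUE)
  ord <- utils::head(ord, top_n)
  chn <- unname(.channel_display[c(MOODSIG_CHANNELS, "MISS")])
  interp <- vapply(words[ord], function(w) {
    nm <- chn[w]
    switch(length(w),
           paste0("Incremental effects of ",
                  if (nm[1] == "the missing signal") nm[1] else nm[1]),
           paste0("Interaction between ", nm[1], " and ", nm[2]),
           paste0("Interaction among ", nm[1], ", ", nm[2], " and ", nm[3]),
           paste0("Interaction among ", paste(nm, collapse = ", ")))
  }, character(1))
  data.frame(rank = seq_along(ord),
             feature = rownames(importance)[ord],
             importance = avg[ord],
             interpretation = interp,
             row.names = NULL)
}
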