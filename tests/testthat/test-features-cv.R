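test_that("MRLSF extraction yields 55 deterministic features per five-channel window", {
  set.seed(21)
  ms <- masked_stream(W = 14, miss_prob = 0.2)
  wins <- cut_windows(encode_missing(ms$stream))
  ws <- extract_mrlsf(wins, p = 3)
  expect_equal(ncol(ws$features), 55)
  expect_equal(nrow(ws$features), length(wins))
  expect_equal(ws$features, extract_mrlsf(wins, p = 3)$features)
  # all-zero scores, nothing missed: the feature row vanishes
  z <- constant_stream("z", c(0, 0, 0, 0), W = 10, diagnosis = "HC")
  wz <- extract_mrlsf(cut_windows(encode_missing(z)))
  expect_equal(max(abs(wz$features)), 0)
  expect_error(extract_mrlsf(list()), "no windows")
})

test_that("folds are stratified, deterministic and participant-disjoint", {
  ids <- sprintf("p%03d", 1:45)
  labs <- rep(c("BD", "HC", "BPD"), each = 15)
  f1 <- make_folds(ids, labs, k = 3, seed = 9)
  f2 <- make_folds(ids, labs, k = 3, seed = 9)
  expect_identical(f1, f2)
  expect_setequal(names(f1$fold_of_participant), ids)
  for (g in unique(labs)) {
    per_fold <- table(f1$fold_of_participant[labs == g])
    expect_true(max(per_fold) - min(per_fold) <= 1)
  }
  for (k in 1:3) {
    test_ids <- names(f1$fold_of_participant)[f1$fold_of_participant == k]
    train_ids <- setdiff(ids, test_ids)
    expect_length(intersect(test_ids, train_ids), 0)
  }
  expect_error(make_folds(c("a", "b", "c"), c("BD", "BD", "HC"), k = 3),
               "fewer than k")
})

test_that("hard and soft voting follow the documented rules", {
  bd <- c(0.8, 0.1, 0.1); hc <- c(0.1, 0.8, 0.1)
  expect_equal(vote_hard(rbind(bd, bd, hc)), "BD")
  expect_equal(vote_hard(rbind(bd)), "BD")
  # hard tie falls back to the soft vote
  expect_equal(vote_hard(rbind(c(0.6, 0.3, 0.1), c(0.05, 0.9, 0.05))), "HC")
  sv <- vote_soft(rbind(c(0.6, 0.2, 0.2), c(0.1, 0.8, 0.1)))
  expect_equal(sv$label, "HC")
  expect_equal(sv$soft_prob, c(BD = 0.35, HC = 0.5, BPD = 0.15))
  # exact soft tie resolves to the lowest class index (BD < HC < BPD)
  expect_equal(vote_soft(rbind(c(0.4, 0.4, 0.2)))$label, "BD")
  # agreement between votings when all windows agree
  expect_equal(vote_hard(rbind(hc, hc, hc)),
               vote_soft(rbind(hc, hc, hc))$label)
})

make_pred <- function(id, prob) {
  structure(list(participant_id = id, window_probs = rbind(prob),
                 hard_label = c("BD", "HC", "BPD")[which.max(prob)],
                 soft_label = c("BD", "HC", "BPD")[which.max(prob)],
                 soft_prob = prob), class = "participant_prediction")
}

test_that("evaluation metrics: perfect case, hand-computed F1, constant-classifier AUC", {
  probs <- list(BD = c(0.9, 0.05, 0.05), HC = c(0.05, 0.9, 0.05),
                BPD = c(0.05, 0.05, 0.9))
  ids <- sprintf("q%02d", 1:9)
  truth <- setNames(rep(c("BD", "HC", "BPD"), 3), ids)
  perfect <- setNames(lapply(ids, function(i) make_pred(i, probs[[truth[i]]])),
                      ids)
  ev <- evaluate_predictions(perfect, truth, boot_B = 50)
  expect_equal(unname(ev$accuracy), c(1, 1))
  expect_equal(unname(ev$f1["hard", ]), rep(1, 3))
  expect_equal(sum(diag(ev$confusion$hard)), 9)
  expect_equal(ev$auc$auc, rep(1, 3))
  # confusion [[2,1],[1,2]] on BD/HC gives F1 = 2/3 for both
  ids6 <- sprintf("r%02d", 1:6)
  truth6 <- setNames(rep(c("BD", "HC"), each = 3), ids6)
  predlab <- c("BD", "BD", "HC", "HC", "HC", "BD")
  preds6 <- setNames(lapply(1:6, function(i)
    make_pred(ids6[i], probs[[predlab[i]]])), ids6)
  ev6 <- evaluate_predictions(preds6, truth6, boot_B = 50)
  expect_equal(unname(ev6$f1["hard", 1:2]), c(2 / 3, 2 / 3))
  expect_equal(unname(ev6$accuracy[["hard"]]), 4 / 6)
  # a constant classifier is uninformative: AUC 0.5 inside its bootstrap CI
  const <- setNames(lapply(ids, function(i) make_pred(i, c(1, 1, 1) / 3)), ids)
  evc <- evaluate_predictions(const, truth, boot_B = 200)
  expect_true(all(evc$auc$ci_lo <= 0.5 & evc$auc$ci_hi >= 0.5))
  expect_error(evaluate_predictions(perfect[1:3], truth[4:6]), "missing true")
})

test_that("importance interpretations name channels the way clinicians read them", {
  words <- list(2L, c(3L, 5L), c(1L, 2L, 5L), 5L)
  imp <- matrix(c(4, 3, 2, 1), ncol = 1,
                dimnames = list(c("L2", "L35", "L125", "L5"), NULL))
  rep1 <- importance_report(imp, words, top_n = 4)
  expect_equal(rep1$interpretation[1], "Incremental effects of QIDS")
  expect_equal(rep1$interpretation[2],
               "Interaction between EQ-5D and the missing signal")
  expect_equal(rep1$interpretation[3],
               "Interaction among ASRM, QIDS and the missing signal")
  expect_equal(rep1$interpretation[4],
               "Incremental effects of the missing signal")
  expect_equal(sum(rep1$importance), 1)
})

test_that("cross-validated forests separate a separable cohort and are seed-stable", {
  coh <- separable_cohort(n_per_group = 5, W = 14)
  dx <- vapply(coh, `[[`, character(1), "diagnosis")
  ws <- extract_mrlsf(moodsig:::.cohort_windows(coh))
  folds <- make_folds(names(coh), dx, k = 3, seed = 2)
  cv1 <- fit_predict_cv(ws, folds, rf = rf_control(ntree = 100), seed = 4)
  hard <- vapply(cv1$predictions, `[[`, character(1), "hard_label")
  expect_equal(mean(hard == dx[names(hard)]), 1)
  # window probability rows are proper distributions
  pr <- cv1$predictions[[1]]
  expect_equal(rowSums(pr$window_probs), rep(1, nrow(pr$window_probs)),
               tolerance = 1e-9)
  expect_equal(sum(pr$soft_prob), 1, tolerance = 1e-9)
  cv2 <- fit_predict_cv(ws, folds, rf = rf_control(ntree = 100), seed = 4)
  expect_identical(lapply(cv1$predictions, `[[`, "window_probs"),
                   lapply(cv2$predictions, `[[`, "window_probs"))
})

test_that("cohort summaries report missingness and mean-score correlations per group", {
  set.seed(31)
  cfg <- cohort_config(n_per_group = c(BD = 30, HC = 30, BPD = 30),
                       weeks = 52,
                       missing_base = c(BD = 0.25, HC = 0.05, BPD = 0.40))
  coh <- simulate_cohort(cfg, seed = 31)
  cs <- cohort_summary(coh)
  expect_equal(cs$HC$n, 30)
  expect_lt(abs(cs$HC$missing_median - 0.05), 0.05)
  expect_lt(abs(cs$BD$missing_median - 0.25), 0.05)
  expect_lt(abs(cs$BPD$missing_median - 0.40), 0.05)
  expect_equal(dim(cs$BD$cor), c(4, 4))
  expect_equal(diag(cs$BD$cor), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rownames(cs$HC$state_proportions), c("ASRM", "QIDS", "EQ5D",
                                                    "GAD7"))
  # a group where nobody misses reports a zero median
  complete <- mood_cohort(lapply(1:3, function(i)
    constant_stream(paste0("h", i), c(i, 2 + i, 80 - i, i), W = 12,
                    diagnosis = "HC")))
  expect_equal(cohort_summary(complete)$HC$missing_median, 0)
  # perfectly correlated mean scores
  two <- mood_cohort(lapply(1:4, function(i)
    constant_stream(paste0("c", i), c(i, 2 * i, 50 + i, 1 + i), W = 12,
                    diagnosis = "BD")))
  expect_equal(cohort_summary(two)$BD$cor["ASRM", "QIDS"], 1)
})
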