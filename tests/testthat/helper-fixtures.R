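# Shared generators for tests: random piecewise-linear paths and small
# labeled cohorts built in code.

random_path <- function(d, n_segments, lim = 1) {
  matrix(stats::runif((n_segments + 1) * d, -lim, lim), ncol = d)
}

# a complete (no-missing) stream with prescribed constant scores
constant_stream <- function(id, scores4, W = 12, diagnosis = "HC") {
  mood_stream(id, matrix(rep(scores4, each = W), nrow = W),
              diagnosis = diagnosis)
}

# small cohort whose three classes are linearly separable in mean level
separable_cohort <- function(n_per_group = 5, W = 14, seed = 7) {
  set.seed(seed)
  lv <- list(BD = c(2, 20, 40, 16), HC = c(1, 2, 90, 1),
             BPD = c(8, 12, 60, 10))
  streams <- list()
  i <- 0
  for (g in names(lv)) {
    for (j in seq_len(n_per_group)) {
      i <- i + 1
      sc <- matrix(rep(lv[[g]], each = W), nrow = W) +
        matrix(sample(0:1, W * 4, replace = TRUE), nrow = W)
      streams[[i]] <- mood_stream(sprintf("S%02d", i), sc, diagnosis = g)
    }
  }
  mood_cohort(streams)
}

# random stream with a random missingness mask (always keeps at least one
# valid value per channel)
masked_stream <- function(id = "m1", W = 20, miss_prob = 0.3,
                          diagnosis = "BD") {
  sc <- cbind(sample(0:20, W, TRUE), sample(0:27, W, TRUE),
              sample(0:100, W, TRUE), sample(0:21, W, TRUE))
  mask <- matrix(stats::runif(W * 4) < miss_prob, W)
  for (ch in 1:4) if (all(mask[, ch])) mask[sample(W, 1), ch] <- FALSE
  masked <- sc
  masked[mask] <- -1
  list(stream = mood_stream(id, masked, diagnosis = diagnosis),
       complete = sc, mask = mask)
}
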