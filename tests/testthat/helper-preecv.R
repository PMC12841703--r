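# Shared oracles and builders. Each oracle is an independent route to the
# quantity it checks — deliberately naive (enumeration, brute force, grid
# search), never calling the implementation under test.

# Exhaustive pair-counting AUC: ties count one-half.
brute_auc <- function(predictions, outcomes) {
  pos <- predictions[outcomes == 1]
  neg <- predictions[outcomes == 0]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(pos) * length(neg))
}

# Coarse-to-fine 2-D grid search of the logistic log-likelihood.
grid_logistic_mle <- function(scores, outcomes, n_grid = 121, stages = 5) {
  ll <- function(a, b) {
    eta <- a + b * scores
    sum(outcomes * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
  }
  a0 <- 0; b0 <- 0; wa <- 20; wb <- 10
  for (s in seq_len(stages)) {
    as <- seq(a0 - wa / 2, a0 + wa / 2, length.out = n_grid)
    bs <- seq(b0 - wb / 2, b0 + wb / 2, length.out = n_grid)
    vals <- outer(as, bs, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    a0 <- as[best[1]]; b0 <- bs[best[2]]
    wa <- 4 * wa / n_grid; wb <- 4 * wb / n_grid
  }
  c(intercept = a0, slope = b0)
}

# Closed-form Wilson interval, written out independently.
wilson_oracle <- function(s, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- s / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n))
}

# Brute-force Youden scan over every integer cutoff (rule: score >= c),
# ties toward the largest cutoff.
brute_youden <- function(scores, outcomes) {
  best_j <- -Inf; best_c <- NA
  for (c in seq(min(scores), max(scores) + 1)) {
    sens <- sum(scores >= c & outcomes == 1) / sum(outcomes == 1)
    spec <- sum(scores < c & outcomes == 0) / sum(outcomes == 0)
    j <- sens + spec - 1
    if (j >= best_j) { best_j <- j; best_c <- c }
  }
  list(cutoff = best_c, j = best_j)
}

# A tiny hand-built cohort of `n` valid records.
toy_cohort <- function(n = 3) {
  grid <- ecv_profile_grid()
  out <- grid[seq_len(n), ]
  out$id <- paste0("t", seq_len(n))
  out$success <- rep(c(TRUE, FALSE), length.out = n)
  out
}

# The two extreme profiles: everything score-positive / everything zero.
max_profile <- function() {
  tibble::tibble(parity = "multiparous", presentation = "transverse",
                 engaged = FALSE, palpable_head = TRUE, efw_ge_10th = TRUE,
                 mvp_ge_4cm = TRUE, placenta_posterior = TRUE,
                 tocolysis = TRUE)
}
min_profile <- function() {
  tibble::tibble(parity = "nulliparous", presentation = "frank_breech",
                 engaged = TRUE, palpable_head = FALSE, efw_ge_10th = FALSE,
                 mvp_ge_4cm = FALSE, placenta_posterior = FALSE,
                 tocolysis = FALSE)
}
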