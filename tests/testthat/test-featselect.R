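test_that("redundancy filter applies the stated greedy rule", {
  n <- 60
  set.seed(2)
  # A and C weakly related; B strongly rank-correlated with both
  A <- rnorm(n)
  C <- 0.55 * A + rnorm(n, sd = 0.9)
  B <- 0.8 * scale(A)[, 1] + 0.8 * scale(C)[, 1] + rnorm(n, sd = 0.12)
  X <- cbind(A = A, B = B, C = C)
  rho <- abs(cor(X, method = "spearman"))
  expect_gt(rho["A", "B"], 0.6)
  expect_gt(rho["B", "C"], 0.6)
  expect_lt(rho["A", "C"], 0.6)
  kept <- spearman_redundancy_filter(X, 0.6)
  expect_equal(sort(names(kept)), c("A", "C"))

  # uncorrelated columns all kept
  set.seed(4)
  Xu <- matrix(rnorm(50 * 6), 50)
  expect_length(spearman_redundancy_filter(Xu, 0.6), 6)

  # exact duplicate: exactly one of the pair dropped
  Xd <- cbind(Xu, dup = Xu[, 1])
  keptd <- spearman_redundancy_filter(Xd, 0.6)
  expect_length(keptd, 6)
  expect_equal(sum(keptd %in% c(1, 7)), 1)

  # constant column dropped with a warning
  expect_warning(kc <- spearman_redundancy_filter(cbind(Xu, k = 1), 0.6), "constant")
  expect_false(7 %in% kc)

  # no surviving pair at or above the threshold
  set.seed(6)
  Z <- matrix(rnorm(40 * 12), 40)
  Z[, 2] <- Z[, 1] + rnorm(40, sd = 0.1)
  Z[, 5] <- -Z[, 4] + rnorm(40, sd = 0.2)
  kz <- spearman_redundancy_filter(Z, 0.6)
  rr <- abs(cor(Z[, kz], method = "spearman")); diag(rr) <- 0
  expect_lt(max(rr), 0.6)
})

test_that("compiled greedy filter matches the naive reference", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(30 * 10), 30)
    X[, 3] <- X[, 1] + rnorm(30, sd = 0.15)
    X[, 7] <- X[, 3] + rnorm(30, sd = 0.15)
    expect_equal(unname(spearman_redundancy_filter(X, 0.5)),
                 oracle_redundancy_filter(X, 0.5))
  }
})

test_that("mRMR ranks relevance first and penalizes redundancy", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    y <- rep(0:1, each = 50)
    X <- cbind(signal = y + rnorm(100, sd = 0.05),
               matrix(rnorm(100 * 10), 100))
    mrmr_rank(X, y, 3)[1] == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # an exact duplicate of the informative feature is not ranked second
  set.seed(12)
  y <- rep(0:1, each = 40)
  f <- y + rnorm(80, sd = 0.3)
  X <- cbind(f1 = f, f2 = f, matrix(rnorm(80 * 6), 80))
  r <- mrmr_rank(X, y, 4)
  expect_equal(unname(r[1]), 1L)
  expect_false(r[2] == 2L)

  expect_error(mrmr_rank(X, rep(1, 80), 2), "single-class")
})

test_that("greedy mRMR agrees with exhaustive search over the same objective", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 50
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * 5), n)
    X[, 2] <- y + rnorm(n, sd = 0.5)
    got <- mrmr_rank(X, y, 2)

    n_bins <- min(10, max(2, ceiling(sqrt(n))))
    B <- apply(X, 2, oracle_bin, n_bins = n_bins)
    yb <- y + 1L
    rel <- apply(B, 2, oracle_mi, b = yb)
    first <- which.max(rel)
    score2 <- vapply(seq_len(ncol(X)), function(j) {
      if (j == first) return(-Inf)
      rel[j] - oracle_mi(B[, j], B[, first])
    }, numeric(1))
    expect_equal(unname(got), c(first, which.max(score2)))
  }
})

test_that("stability selection is seeded, monotone, and recovers planted signal", {
  set.seed(50)
  n <- 200
  y <- rep(0:1, each = n / 2)
  X <- cbind(
    s1 = y + rnorm(n, sd = 0.4),
    s2 = -1.5 * y + rnorm(n, sd = 0.5),
    s3 = y + rnorm(n, sd = 0.45),
    matrix(rnorm(n * 20), n)
  )
  colnames(X)[4:23] <- paste0("noise", 1:20)
  cfg <- selection_config(n_iterations = 10, n_candidates = 5, seed = 3)
  out <- stability_select(X, y, cfg)
  expect_true(all(c("s1", "s2", "s3") %in% names(out$selected)))
  out2 <- stability_select(X, y, cfg)
  expect_identical(out$frequency, out2$frequency)

  # threshold 0 returns everything ever recorded; raising it never enlarges
  all_rec <- stability_select(X, y, selection_config(n_iterations = 10,
                                                     n_candidates = 5,
                                                     stability_threshold = 0,
                                                     seed = 3))
  expect_true(all(names(out$selected) %in% names(all_rec$selected)))
  freq <- out$frequency
  for (thr in c(0.2, 0.5, 0.9)) {
    sel_thr <- freq$feature[freq$frequency >= thr]
    expect_lte(length(sel_thr), sum(freq$frequency >= 0.1))
  }
  strict <- stability_select(X, y, selection_config(n_iterations = 10,
                                                    n_candidates = 5,
                                                    stability_threshold = 0.9,
                                                    seed = 3))
  expect_true(all(names(strict$selected) %in% names(all_rec$selected)))
  expect_lte(length(strict$selected), length(all_rec$selected))

  # empty selection falls back to the top-frequency set with a warning
  set.seed(51)
  Xn <- matrix(rnorm(60 * 30), 60)
  yn <- rep(0:1, each = 30)
  expect_warning(
    fb <- stability_select(Xn, yn, selection_config(n_iterations = 4,
                                                    n_candidates = 2,
                                                    stability_threshold = 1,
                                                    seed = 1)),
    "top-frequency"
  )
  expect_gt(length(fb$selected), 0)
})

test_that("auto candidate-size mode runs and returns a valid selection", {
  set.seed(60)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(sig = y + rnorm(n, sd = 0.3), matrix(rnorm(n * 12), n))
  cfg <- selection_config(n_iterations = 2, n_candidates = "auto",
                          auto_grid = c(3, 6), stability_threshold = 0.5, seed = 2)
  out <- stability_select(X, y, cfg)
  expect_gt(length(out$selected), 0)
  expect_true(all(out$frequency$frequency >= 0 & out$frequency$frequency <= 1))
})
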