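mk_mask <- function(d, fill_idx = NULL, spacing = c(1, 1, 1)) {
  m <- array(0L, d)
  if (!is.null(fill_idx)) m[fill_idx] <- 1L
  mask_volume(m, spacing)
}

test_that("dice coefficient handles overlap and empty-mask conventions", {
  d <- c(6, 6, 6)
  A <- mk_mask(d); A$data[2:4, 2:4, 2:4] <- 1L
  expect_equal(dice_coefficient(A, A), 1)

  B <- mk_mask(d); B$data[5:6, 5:6, 5:6] <- 1L
  expect_equal(dice_coefficient(A, B), 0)

  # |A| = 4, |B| = 4, |A ∩ B| = 2
  A2 <- mk_mask(d); A2$data[1:4, 1, 1] <- 1L
  B2 <- mk_mask(d); B2$data[3:6, 1, 1] <- 1L
  expect_equal(dice_coefficient(A2, B2), 0.5)

  expect_message(e2 <- dice_coefficient(mk_mask(d), mk_mask(d)), "both masks empty")
  expect_equal(e2, 1)
  expect_message(e1 <- dice_coefficient(A, mk_mask(d)), "one mask empty")
  expect_equal(e1, 0)
  expect_error(dice_coefficient(A, mk_mask(c(5, 5, 5))), "different grids")
})

test_that("HD95 matches hand cases and the brute-force oracle", {
  d <- c(12, 12, 12)
  A <- mk_mask(d); A$data[3:6, 3:6, 3:6] <- 1L
  expect_equal(hausdorff95(A, A), 0)

  # two single voxels 5 apart along x at 1 mm
  P <- mk_mask(d); P$data[2, 2, 2] <- 1L
  Q <- mk_mask(d); Q$data[7, 2, 2] <- 1L
  expect_equal(hausdorff95(P, Q), 5)

  # anisotropic spacing scales physical distance
  Pz <- mk_mask(d, spacing = c(1, 1, 4)); Pz$data[2, 2, 2] <- 1L
  Qz <- mk_mask(d, spacing = c(1, 1, 4)); Qz$data[2, 2, 5] <- 1L
  expect_equal(hausdorff95(Pz, Qz), 12)

  # seeded blob pairs against the all-pairs oracle, exact
  co <- tiny_cohort(n = 2, seed = 13)
  m1 <- co$cyst_masks[[1]]
  for (s in 1:3) {
    m2 <- perturb_mask(m1, 0.5, seed = s)
    expect_equal(hausdorff95(m1, m2),
                 brute_hd95(m1$data, m2$data, m1$spacing), tolerance = 1e-9)
    expect_equal(hausdorff95(m1, m2), hausdorff95(m2, m1))
    # the 95th percentile is bounded by the exact (maximal) Hausdorff
    hmax <- brute_hd95(m1$data, m2$data, m1$spacing, probs = 1)
    expect_lte(hausdorff95(m1, m2), hmax + 1e-12)
  }

  expect_error(hausdorff95(A, mk_mask(d)), "empty mask")
})

test_that("weighted kappa matches the direct formula and null behaviour", {
  s <- factor(c("no", "low", "high", "low", "no", "high"),
              levels = c("no", "low", "high"), ordered = TRUE)
  expect_equal(weighted_kappa(s, s), 1)

  # worked 3x3 contingency vs the independent formula, both weightings
  set.seed(10)
  a <- sample(1:3, 300, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  b <- ifelse(runif(300) < 0.6, a, sample(1:3, 300, replace = TRUE))
  lv <- c("no", "low", "high")
  expect_equal(weighted_kappa(lv[a], lv[b], "linear"),
               oracle_weighted_kappa(a, b, 3, quadratic = FALSE), tolerance = 1e-12)
  expect_equal(weighted_kappa(lv[a], lv[b], "quadratic"),
               oracle_weighted_kappa(a, b, 3, quadratic = TRUE), tolerance = 1e-12)

  # independent raters: kappa near zero at n = 2000
  set.seed(11)
  r1 <- lv[sample(1:3, 2000, replace = TRUE)]
  r2 <- lv[sample(1:3, 2000, replace = TRUE)]
  expect_lt(abs(weighted_kappa(r1, r2)), 0.05)

  expect_error(weighted_kappa(rep("no", 10), lv[sample(1:3, 10, replace = TRUE)]),
               "degenerate")
})

test_that("rater metrics binarize correctly and handle majority exclusion", {
  labels <- c(1, 1, 0, 0, 1, 0)
  lv <- c("no", "low", "high")
  tbl <- tibble::tibble(
    subject_id = paste0("S", 1:6), label = labels,
    rater_1 = ifelse(labels == 1, "high", "low"),       # perfect
    rater_2 = ifelse(labels == 1, "no", "high"),        # inverted
    rater_3 = c("high", "high", "no", "low", "high", "no")
  )
  rm <- rater_metrics(tbl)
  expect_equal(rm$metrics$sens[rm$metrics$rater == "rater_1"], 1)
  expect_equal(rm$metrics$spec[rm$metrics$rater == "rater_1"], 1)
  expect_equal(rm$metrics$sens[rm$metrics$rater == "rater_2"], 0)
  expect_equal(rm$metrics$spec[rm$metrics$rater == "rater_2"], 0)

  # three-way disagreements drop out of the majority row
  tbl2 <- tibble::tibble(
    subject_id = paste0("S", 1:4), label = c(1, 0, 1, 0),
    rater_1 = c("high", "no", "high", "no"),
    rater_2 = c("low", "low", "high", "no"),
    rater_3 = c("no", "high", "high", "no")
  )
  rm2 <- rater_metrics(tbl2)
  expect_equal(rm2$n_excluded, 2)
  expect_equal(rm2$n_majority, 2)
  expect_equal(rm2$metrics$n[rm2$metrics$rater == "majority"], 2)

  expect_error(rater_metrics(tbl2[, 1:4]), "at least 3 raters")

  # configured operating points recovered within binomial error at n = 2000
  set.seed(20)
  y <- rbinom(2000, 1, 0.4)
  ratings <- simulate_ratings(y, 3, per_rater_sens = c(0.7, 0.45, 0.72),
                              per_rater_spec = c(0.65, 0.35, 0.42), seed = 8)
  rm3 <- rater_metrics(ratings)
  got <- rm3$metrics[rm3$metrics$rater != "majority", ]
  expect_equal(got$sens, c(0.7, 0.45, 0.72), tolerance = 0.05)
  expect_equal(got$spec, c(0.65, 0.35, 0.42), tolerance = 0.05)
})

test_that("Cochran's Q matches the textbook formula", {
  same <- matrix(rep(c(1, 0, 1, 1, 0), 3), ncol = 3)
  out <- cochran_q(same)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  set.seed(15)
  calls <- cbind(rbinom(40, 1, 0.7), rbinom(40, 1, 0.4), rbinom(40, 1, 0.55))
  got <- cochran_q(calls)
  expect_equal(got$statistic, oracle_cochran_q(calls), tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p_value,
               pchisq(oracle_cochran_q(calls), 2, lower.tail = FALSE))

  expect_error(cochran_q(matrix(1, 5, 1)), "at least 2 raters")
  expect_error(cochran_q(matrix(1, 1, 3)), "at least 2 subjects")
})
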