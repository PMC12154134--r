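# manifest with the reference per-center subject counts
reference_manifest <- function() {
  counts <- c(AHN = 14, MCA = 15, EMC = 36, IU = 35, MCF = 94, NMH = 94, NYU = 71)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(sum(counts))),
    center_id = rep(names(counts), counts)
  )
}

test_that("leave-center-out trials fill counts from the subject table", {
  man <- reference_manifest()
  trials <- make_center_trials(man, default_trial_design())
  expect_equal(trials$trial_id, c("T1", "T2", "T3", "T4"))
  expect_equal(trials$test_n, c(29L, 36L, 35L, 71L))
  expect_equal(trials$cv_n, c(330L, 323L, 324L, 288L))
  expect_equal(trials$cv_n + trials$test_n, rep(359L, 4))
  for (i in 1:4) {
    expect_length(intersect(trials$cv_centers[[i]], trials$test_centers[[i]]), 0)
    expect_setequal(c(trials$cv_centers[[i]], trials$test_centers[[i]]),
                    unique(man$center_id))
  }

  # singleton designs: one trial per center, complementary counts
  singles <- make_center_trials(man, as.list(setNames(unique(man$center_id),
                                                      unique(man$center_id))))
  expect_equal(nrow(singles), 7)
  expect_true(all(singles$cv_n + singles$test_n == nrow(man)))

  expect_error(make_center_trials(man, list(T1 = "XX")), "unknown center")
  expect_error(make_center_trials(man, list(T1 = character(0))), "empty test set")
})

test_that("random-forest scorer is seeded and separates separable data", {
  set.seed(1)
  n <- 40
  y <- rep(0:1, each = n / 2)
  X <- cbind(a = y * 3 + rnorm(n, sd = 0.1), b = -2 * y + rnorm(n, sd = 0.1))
  sc <- train_rf(X, y, seed = 7)
  p <- predict(sc, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(compute_metrics(p, y)$auc, 1)

  sc2 <- train_rf(X, y, seed = 7)
  expect_identical(predict(sc2, X), p)

  expect_error(train_rf(X, rep(1, n)), "single-class")
})

test_that("label-permuted forests score at chance on held-out folds", {
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    X <- matrix(rnorm(n * 5), n)
    y <- sample(rep(0:1, each = n / 2))
    tr <- c(1:20, 31:50); te <- setdiff(1:n, tr)
    sc <- train_rf(X[tr, ], y[tr], rf_config = list(ntree = 200), seed = s)
    compute_metrics(predict(sc, X[te, ]), y[te])$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("metrics follow the concordance and threshold definitions", {
  m <- compute_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(unname(unlist(m)), rep(1, 6))

  expect_equal(compute_metrics(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(compute_metrics(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  # AUC invariant under strictly monotone transforms of the scores
  set.seed(3)
  p <- runif(30); y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(compute_metrics(p, y)$auc, compute_metrics(p^3, y)$auc)
  expect_equal(compute_metrics(p, y)$auc,
               compute_metrics(plogis(5 * p - 2), y)$auc)

  # f1 consistency with ppv and sens
  mm <- compute_metrics(p, y, threshold = 0.4)
  expect_equal(mm$f1, 2 * mm$ppv * mm$sens / (mm$ppv + mm$sens))

  expect_error(compute_metrics(p, rep(1, 30)), "single-class")
})

test_that("aggregation reproduces simple and weighted means", {
  per_trial <- tibble::tibble(acc = c(53.1, 63.7, 76.3, 70.6))
  expect_equal(aggregate_metrics(per_trial)$acc, 65.925)
  expect_equal(aggregate_metrics(per_trial, weights = rep(2, 4))$acc, 65.925)

  wt <- tibble::tibble(acc = c(48.3, 54.9, 68.0, 67.3))
  expect_equal(round(aggregate_metrics(wt, weights = c(29, 36, 35, 71))$acc, 1), 61.6)

  single <- tibble::tibble(auc = 0.7, acc = 0.6)
  expect_equal(aggregate_metrics(single), single)
  expect_error(aggregate_metrics(per_trial, weights = c(1, 2)), "weights length")
})

test_that("the experiment pipeline keeps test centers out of training", {
  co <- generate_cohort(synth_config(n_subjects = 40, n_centers = 4,
                                     class_balance = 0.5, effect_size = 2,
                                     seed = 17))
  feats <- extract_cohort_features(
    co, mode = "2D",
    config = feature_config(windows = 3, gray_levels = c(4, 8),
                            collage_windows = 3, collage_bins = 16)
  )
  trials <- make_center_trials(co$manifest,
                               list(TA = unique(co$manifest$center_id)[1]))
  scfg <- selection_config(n_iterations = 5, n_candidates = 10, seed = 2)
  ex1 <- run_radiomics_experiment(co, trials = trials, mode = "2D",
                                  select_cfg = scfg, seed = 5, features = feats)

  # inject a label-leak into an existing feature, test-center rows only:
  # training artifacts must be bit-identical
  te_rows <- which(co$manifest$center_id %in% trials$test_centers[[1]])
  leaked <- feats
  leaked[[5]][te_rows] <- as.numeric(co$manifest$label[te_rows])
  ex2 <- run_radiomics_experiment(co, trials = trials, mode = "2D",
                                  select_cfg = scfg, seed = 5, features = leaked)
  expect_identical(ex1$details[[1]]$selected, ex2$details[[1]]$selected)
  expect_identical(ex1$per_trial$n_features, ex2$per_trial$n_features)

  # end-to-end determinism
  ex3 <- run_radiomics_experiment(co, trials = trials, mode = "2D",
                                  select_cfg = scfg, seed = 5, features = feats)
  expect_identical(ex1$per_trial, ex3$per_trial)
  expect_identical(ex1$details[[1]]$probs, ex3$details[[1]]$probs)

  # tidiers and plot methods
  td <- tidy(ex1)
  expect_true(all(c("trial_id", "metric", "value") %in% names(td)))
  gl <- glance(ex1)
  expect_equal(gl$n_trials, 1)
  expect_s3_class(autoplot(ex1), "ggplot")
})
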