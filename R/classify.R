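# Random-forest risk classification over leave-center(s)-out trials,
# classification metrics, and the simple / count-weighted metric
# aggregation used for multi-trial summaries.

#' Build leave-center-out trial splits
#'
#' One split per design entry: the named centers form the held-out test set
#' and all remaining centers the cross-validation (training) set, with
#' subject counts filled from the table. This mirrors a multi-center design
#' where every trial tests on the complete data of one or two centers.
#'
#' @param subjects Tibble with at least `subject_id` and `center_id`.
#' @param design Named list of character vectors of test centers; default
#'   [default_trial_design()].
#' @return Tibble of class columns: `trial_id`, list-columns `cv_centers`
#'   and `test_centers`, and counts `cv_n`, `test_n`.
#' @export
make_center_trials <- function(subjects, design = default_trial_design()) {
  stopifnot(all(c("subject_id", "center_id") %in% names(subjects)))
  centers <- unique(subjects$center_id)
  purrr::imap_dfr(design, function(test_centers, trial_id) {
    if (!length(test_centers)) stop("empty test set in trial design", call. = FALSE)
    unknown <- setdiff(test_centers, centers)
    if (length(unknown)) {
      stop(sprintf("unknown center(s) in design: %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    cv_centers <- setdiff(centers, test_centers)
    if (!length(cv_centers)) stop("design leaves no cross-validation centers", call. = FALSE)
    n_cv <- sum(subjects$center_id %in% cv_centers)
    n_te <- sum(subjects$center_id %in% test_centers)
    tibble::tibble(
      trial_id = trial_id,
      cv_centers = list(sort(cv_centers)),
      test_centers = list(sort(test_centers)),
      cv_n = n_cv,
      test_n = n_te
    )
  })
}

#' The four-trial leave-center-out design of the modeled cohort
#'
#' T1 holds out AHN and MCA together; T2, T3 and T4 hold out EMC, IU and NYU
#' respectively.
#'
#' @return Named list of test-center sets.
#' @export
default_trial_design <- function() {
  list(T1 = c("AHN", "MCA"), T2 = "EMC", T3 = "IU", T4 = "NYU")
}

#' Train a seeded random-forest probability scorer
#'
#' Defaults: 500 trees, `sqrt(p)` variables per split. The returned scorer
#' maps feature rows to the predicted probability of the high-risk class.
#'
#' @param X_train Feature matrix / tibble.
#' @param y_train Binary labels (0/1), both classes present.
#' @param rf_config List with optional `ntree`, `mtry`, `nodesize`.
#' @param seed Integer seed (same seed, same forest).
#' @return Object of class `rf_scorer` with a [predict()] method.
#' @export
train_rf <- function(X_train, y_train, rf_config = list(), seed = 1L) {
  X_train <- as_feature_matrix(X_train)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L) {
    stop("single-class training data: cannot fit a classifier", call. = FALSE)
  }
  ntree <- rf_config$ntree %||% 500L
  mtry <- rf_config$mtry %||% max(1L, floor(sqrt(ncol(X_train))))
  nodesize <- rf_config$nodesize %||% 1L
  fit <- with_seed_local(seed, {
    randomForest::randomForest(
      x = as.data.frame(X_train), y = factor(y_train, levels = c(0L, 1L)),
      ntree = ntree, mtry = min(mtry, ncol(X_train)), nodesize = nodesize
    )
  })
  structure(list(fit = fit, features = colnames(X_train), seed = seed),
            class = "rf_scorer")
}

#' @export
predict.rf_scorer <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  newdata <- newdata[, object$features, drop = FALSE]
  unname(stats::predict(object$fit, as.data.frame(newdata), type = "prob")[, "1"])
}

# AUC by pairwise concordance with ties counting 1/2 (midrank formula).
auc_concordance <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined for single-class labels", call. = FALSE)
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a probability threshold
#'
#' AUC is computed by pairwise concordance (ties count 1/2); accuracy,
#' sensitivity, specificity, PPV and F1 are computed after thresholding the
#' probabilities (prediction positive when `prob >= threshold`). F1 is
#' `2 * ppv * sens / (ppv + sens)`, 0 when both are 0; PPV is 0 when nothing
#' is predicted positive.
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param labels Binary labels (0/1), both classes present.
#' @param threshold Operating threshold (default 0.5).
#' @return One-row tibble: `auc`, `acc`, `sens`, `spec`, `ppv`, `f1`.
#' @export
compute_metrics <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels))
  auc <- auc_concordance(probs, labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  tibble::tibble(auc = auc, acc = (tp + tn) / length(labels),
                 sens = sens, spec = spec, ppv = ppv, f1 = f1)
}

#' Aggregate per-trial metrics
#'
#' Unweighted arithmetic mean across trials, or a count-weighted mean
#' (weights typically the per-trial test-set sizes, reflecting differing
#' subject counts per center).
#'
#' @param per_trial Tibble of per-trial metrics (numeric columns averaged).
#' @param weights `NULL` for the unweighted mean, or a numeric vector with
#'   one weight per trial.
#' @return One-row tibble of aggregated metrics.
#' @export
aggregate_metrics <- function(per_trial, weights = NULL) {
  stopifnot(nrow(per_trial) >= 1L)
  num <- dplyr::select(per_trial, dplyr::where(is.numeric))
  if (is.null(weights)) {
    dplyr::summarise(num, dplyr::across(dplyr::everything(), mean))
  } else {
    if (length(weights) != nrow(per_trial)) {
      stop("weights length must match the number of trials", call. = FALSE)
    }
    dplyr::summarise(num, dplyr::across(dplyr::everything(),
                                        ~ stats::weighted.mean(.x, w = weights)))
  }
}

#' Run the radiomics-only leave-center-out experiment
#'
#' Per trial: per-subject preprocessing and feature extraction, Spearman
#' redundancy filtering and stability mRMR selection on the training
#' (cross-validation) centers only, random-forest training on the training
#' centers, and scoring of the held-out center(s). No test-subject
#' information enters selection or training.
#'
#' @param cohort A [generate_cohort()] result with volumes.
#' @param trials Trial table from [make_center_trials()]; default derived
#'   from [default_trial_design()] restricted to centers present.
#' @param mode `"3D"` or `"2D"` radiomics.
#' @param feature_cfg A [feature_config()].
#' @param select_cfg A [selection_config()].
#' @param rf_config Random-forest settings (see [train_rf()]).
#' @param threshold Operating probability threshold.
#' @param seed Seed for selection and forest training.
#' @param features Optional precomputed [extract_cohort_features()] table
#'   (must align with the cohort manifest); skips extraction.
#' @return Object of class `cyst_experiment`: per-trial metrics, unweighted
#'   and test-size-weighted aggregates, selected features and test-set
#'   probabilities per trial.
#' @export
run_radiomics_experiment <- function(cohort, trials = NULL,
                                     mode = c("3D", "2D"),
                                     feature_cfg = feature_config(),
                                     select_cfg = selection_config(),
                                     rf_config = list(), threshold = 0.5,
                                     seed = 1L, features = NULL) {
  mode <- match.arg(mode)
  manifest <- cohort$manifest
  if (is.null(trials)) {
    design <- purrr::keep(default_trial_design(),
                          ~ all(.x %in% manifest$center_id))
    trials <- make_center_trials(manifest, design)
  }
  if (is.null(features)) {
    features <- extract_cohort_features(cohort, mode = mode, config = feature_cfg)
  }
  stopifnot(identical(features$subject_id, manifest$subject_id))
  fmat <- as_feature_matrix(features)

  per_trial <- list()
  details <- list()
  for (i in seq_len(nrow(trials))) {
    tr_centers <- trials$cv_centers[[i]]
    te_centers <- trials$test_centers[[i]]
    tr <- which(manifest$center_id %in% tr_centers)
    te <- which(manifest$center_id %in% te_centers)
    y_tr <- manifest$label[tr]; y_te <- manifest$label[te]

    kept <- spearman_redundancy_filter(fmat[tr, , drop = FALSE],
                                       select_cfg$spearman_threshold)
    sel <- stability_select(fmat[tr, kept, drop = FALSE], y_tr, select_cfg)
    feat_idx <- kept[sel$selected]
    scorer <- train_rf(fmat[tr, feat_idx, drop = FALSE], y_tr,
                       rf_config = rf_config, seed = seed)
    probs <- predict(scorer, fmat[te, feat_idx, drop = FALSE])
    metrics <- if (length(unique(y_te)) < 2L) {
      # a held-out center can contain a single class in small cohorts;
      # discrimination is undefined there, so the trial scores NA and is
      # dropped from the aggregates
      message(sprintf("trial %s: single-class held-out set, metrics NA",
                      trials$trial_id[i]))
      tibble::tibble(auc = NA_real_, acc = NA_real_, sens = NA_real_,
                     spec = NA_real_, ppv = NA_real_, f1 = NA_real_)
    } else {
      compute_metrics(probs, y_te, threshold = threshold)
    }
    per_trial[[i]] <- dplyr::bind_cols(
      tibble::tibble(trial_id = trials$trial_id[i], cv_n = length(tr),
                     test_n = length(te), n_features = length(feat_idx)),
      metrics
    )
    details[[trials$trial_id[i]]] <- list(
      selected = names(feat_idx), feat_idx = feat_idx, scorer = scorer,
      frequency = sel$frequency, probs = probs, labels = y_te,
      test_subjects = manifest$subject_id[te]
    )
  }
  per_trial <- dplyr::bind_rows(per_trial)
  metric_cols <- c("auc", "acc", "sens", "spec", "ppv", "f1")
  scored <- !is.na(per_trial$auc)
  if (!any(scored)) stop("no trial had a two-class held-out set", call. = FALSE)
  structure(
    list(
      per_trial = per_trial,
      aggregate = aggregate_metrics(per_trial[scored, metric_cols]),
      aggregate_weighted = aggregate_metrics(per_trial[scored, metric_cols],
                                             weights = per_trial$test_n[scored]),
      details = details, mode = mode, seed = seed
    ),
    class = "cyst_experiment"
  )
}

#' @export
print.cyst_experiment <- function(x, ...) {
  cat(sprintf("<cyst_experiment> %s radiomics, %d trials\n", x$mode, nrow(x$per_trial)))
  print(x$per_trial)
  cat("mean test AUC:", round(x$aggregate$auc, 3),
      "| weighted:", round(x$aggregate_weighted$auc, 3), "\n")
  invisible(x)
}
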