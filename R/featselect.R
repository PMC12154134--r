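# Stability feature selection: Spearman redundancy filter, mRMR ranking
# (MID difference form with binned mutual information), and repeated
# cross-validated selection with a retention threshold.

#' Selection configuration
#'
#' Defaults follow the modeled study procedure: |rho| >= 0.6 Spearman
#' redundancy cutoff, 5 folds, 50 iterations, 70% stability retention, 30
#' candidates ranked per run.
#'
#' @param spearman_threshold Absolute Spearman correlation cutoff in (0, 1\].
#' @param n_folds Folds per iteration (>= 2).
#' @param n_iterations Re-shuffled iterations.
#' @param stability_threshold Retention fraction in (0, 1\].
#' @param n_candidates Features ranked per run, or `"auto"` to pick the best
#'   candidate-set size by a random-forest fold evaluation.
#' @param auto_grid Candidate sizes tried when `n_candidates = "auto"`.
#' @param seed Base seed; iteration r uses `seed + r`.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(spearman_threshold = 0.6, n_folds = 5L,
                             n_iterations = 50L, stability_threshold = 0.7,
                             n_candidates = 30L, auto_grid = c(10L, 20L, 30L),
                             seed = 1L) {
  stopifnot(spearman_threshold > 0, spearman_threshold <= 1,
            stability_threshold >= 0, stability_threshold <= 1, n_folds >= 2)
  structure(
    list(spearman_threshold = spearman_threshold, n_folds = as.integer(n_folds),
         n_iterations = as.integer(n_iterations),
         stability_threshold = stability_threshold, n_candidates = n_candidates,
         auto_grid = as.integer(auto_grid), seed = as.integer(seed)),
    class = "selection_config"
  )
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) {
    X <- X[, setdiff(names(X), "subject_id"), drop = FALSE]
    X <- as.matrix(X)
  }
  storage.mode(X) <- "double"
  cn <- colnames(X)
  if (is.null(cn)) cn <- rep("", ncol(X))
  blank <- !nzchar(cn)
  cn[blank] <- paste0("f", which(blank))
  colnames(X) <- cn
  X
}

#' Greedy Spearman redundancy filter
#'
#' Repeatedly finds the most-correlated remaining pair with
#' `|rho| >= threshold` and drops the member with the larger mean absolute
#' correlation to all remaining features, until no pair exceeds the
#' threshold. Ties break deterministically by column order (earlier pair
#' first; the later column is dropped on an exact mean tie). Constant
#' columns, whose rank correlation is undefined, are dropped with a warning.
#'
#' @param X Feature matrix / tibble (a `subject_id` column is ignored).
#' @param threshold Absolute Spearman cutoff (default 0.6).
#' @return Integer indices of kept columns (relative to the feature columns),
#'   named by feature.
#' @export
spearman_redundancy_filter <- function(X, threshold = 0.6) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 subjects", call. = FALSE)
  p <- ncol(X)
  const <- which(apply(X, 2, function(v) max(v) - min(v) == 0))
  keep <- setdiff(seq_len(p), const)
  if (length(const)) {
    warning(sprintf("dropping %d constant column(s): rank correlation undefined",
                    length(const)))
  }
  if (length(keep) < 2L) return(stats::setNames(keep, colnames(X)[keep]))

  rho <- abs(stats::cor(X[, keep, drop = FALSE], method = "spearman"))
  diag(rho) <- 0
  alive <- cpp_redundancy_greedy(rho, threshold)
  kept <- keep[alive]
  stats::setNames(kept, colnames(X)[kept])
}

# Equal-frequency binning for mutual information: ceiling(sqrt(n)) bins,
# capped at 10; deterministic rank-based assignment.
mi_bins <- function(X, n_bins = NULL) {
  n <- nrow(X)
  if (is.null(n_bins)) n_bins <- min(10L, max(2L, ceiling(sqrt(n))))
  B <- apply(X, 2, function(v) {
    r <- rank(v, ties.method = "first")
    as.integer(floor((r - 1) / n * n_bins)) + 1L
  })
  storage.mode(B) <- "integer"
  list(bins = B, n_bins = as.integer(n_bins))
}

#' mRMR feature ranking
#'
#' Greedy forward selection maximizing `relevance(f, y) - mean redundancy(f,
#' selected)` (the MID difference form), with relevance and redundancy
#' measured by mutual information on equal-frequency-binned features
#' (`ceiling(sqrt(n))` bins, capped at 10).
#'
#' @param X Feature matrix / tibble.
#' @param y Binary labels (0/1).
#' @param n_select Number of features to rank (<= number of features).
#' @return Integer vector of column indices in selection order, named.
#' @export
mrmr_rank <- function(X, y, n_select) {
  X <- as_feature_matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class y: relevance undefined", call. = FALSE)
  stopifnot(length(y) == nrow(X), n_select <= ncol(X))
  bn <- mi_bins(X)
  sel <- cpp_mrmr_rank(bn$bins, y + 1L, seq_len(nrow(X)), as.integer(n_select),
                       bn$n_bins, 2L)
  stats::setNames(as.integer(sel), colnames(X)[sel])
}

make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Stability selection by repeated cross-validated mRMR
#'
#' For each of `n_iterations` iterations the fold assignment is re-shuffled
#' (stratified by label, iteration r seeded with `seed + r`); within each
#' iteration, every fold's training portion is ranked by mRMR and the top
#' `n_candidates` features recorded. A feature's selection frequency is the
#' fraction of all iteration-by-fold runs in which it was recorded; features
#' with frequency at or above `stability_threshold` are returned. With
#' `n_candidates = "auto"`, each iteration first picks the candidate-set
#' size from `auto_grid` by the mean held-out-fold AUC of a random forest
#' trained on the top-ranked features.
#'
#' @param X Redundancy-filtered feature matrix / tibble.
#' @param y Binary labels (0/1).
#' @param config A [selection_config()].
#' @return List with `selected` (named indices), `frequency` (tibble:
#'   feature, frequency), and `config`.
#' @export
stability_select <- function(X, y, config = selection_config()) {
  X <- as_feature_matrix(X)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2L) stop("single-class y", call. = FALSE)
  p <- ncol(X)
  bn <- mi_bins(X)
  auto <- identical(config$n_candidates, "auto")
  counts <- numeric(p)
  n_runs <- 0L

  for (r in seq_len(config$n_iterations)) {
    fold <- with_seed_local(config$seed + r, make_stratified_folds(y, config$n_folds))
    n_cand <- if (auto) {
      pick_candidate_size(X, y, bn, fold, config, iter_seed = config$seed + r)
    } else {
      min(as.integer(config$n_candidates), p)
    }
    for (f in seq_len(config$n_folds)) {
      rows <- which(fold != f)
      if (length(unique(y[rows])) < 2L) next
      sel <- cpp_mrmr_rank(bn$bins, y + 1L, rows, n_cand, bn$n_bins, 2L)
      counts[sel] <- counts[sel] + 1
      n_runs <- n_runs + 1L
    }
  }
  freq <- counts / n_runs
  selected <- which(freq >= config$stability_threshold)
  if (!length(selected)) {
    warning("no feature reached the stability threshold; returning the top-frequency set")
    selected <- which(freq == max(freq))
  }
  list(
    selected = stats::setNames(selected, colnames(X)[selected]),
    frequency = tibble::tibble(feature = colnames(X), frequency = freq) |>
      dplyr::arrange(dplyr::desc(.data$frequency)),
    config = config
  )
}

# RF-evaluated candidate-set size for "auto" mode: mean held-out-fold AUC
# over the iteration's folds for each size in the grid.
pick_candidate_size <- function(X, y, bn, fold, config, iter_seed) {
  grid <- config$auto_grid[config$auto_grid <= ncol(X)]
  if (!length(grid)) grid <- ncol(X)
  aucs <- vapply(grid, function(k) {
    fold_auc <- vapply(seq_len(config$n_folds), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) return(NA_real_)
      sel <- cpp_mrmr_rank(bn$bins, y + 1L, tr, as.integer(k), bn$n_bins, 2L)
      scorer <- train_rf(X[tr, sel, drop = FALSE], y[tr],
                         rf_config = list(ntree = 100L), seed = iter_seed)
      auc_concordance(predict(scorer, X[te, sel, drop = FALSE]), y[te])
    }, numeric(1))
    mean(fold_auc, na.rm = TRUE)
  }, numeric(1))
  as.integer(grid[which.max(aucs)])
}
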