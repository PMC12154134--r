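# Decision-level radiomics–DL probability fusion with threshold t and
# weight k, and its grid search on stratified five-fold cross-validation.

#' Fusion rule parameters
#'
#' @param t Threshold on the radiomics probability, in \[0, 1\].
#' @param k Weight of the deep-learning probability in the blend branch, in
#'   \[0, 1\].
#' @return List of class `fusion_params`.
#' @export
fusion_params <- function(t, k) {
  stopifnot(t >= 0, t <= 1, k >= 0, k <= 1)
  structure(list(t = t, k = k), class = "fusion_params")
}

#' Fuse radiomics and deep-learning probabilities
#'
#' If the radiomics probability exceeds the threshold `t`, the fused output
#' is the radiomics probability alone (the DL prediction is discarded);
#' otherwise the output is the weighted blend `(1 - k) * p_rad + k * p_dl`.
#' On the blend branch the output never leaves
#' `[min(p_rad, p_dl), max(p_rad, p_dl)]`.
#'
#' @param p_rad,p_dl Probability vectors in \[0, 1\] (recycled).
#' @param params A [fusion_params()].
#' @return Fused probability vector in \[0, 1\].
#' @export
fuse_probabilities <- function(p_rad, p_dl, params) {
  stopifnot(inherits(params, "fusion_params"))
  if (any(!is.finite(p_rad)) || any(p_rad < 0 | p_rad > 1) ||
      any(!is.finite(p_dl)) || any(p_dl < 0 | p_dl > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p_rad > params$t, p_rad, (1 - params$k) * p_rad + params$k * p_dl)
}

#' Grid search for the fusion hyperparameters
#'
#' Exhaustively evaluates every `(t, k)` pair on stratified `n_folds`
#' cross-validation: the objective is the mean held-out-fold AUC of the
#' fused probabilities. Ties break deterministically towards the smaller
#' `k`, then the smaller `t`.
#'
#' @param p_rad_cv,p_dl_cv Cross-validation probability vectors.
#' @param labels Binary labels (0/1), both classes present.
#' @param t_grid,k_grid Candidate grids (defaults 0, 0.05, ..., 1).
#' @param n_folds Folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `params` ([fusion_params()]), `cv_auc`, and `grid`
#'   (tibble of every evaluated combination).
#' @export
grid_search_fusion <- function(p_rad_cv, p_dl_cv, labels,
                               t_grid = seq(0, 1, by = 0.05),
                               k_grid = seq(0, 1, by = 0.05),
                               n_folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("single-class labels", call. = FALSE)
  if (!length(t_grid) || !length(k_grid)) stop("empty grid", call. = FALSE)
  stopifnot(length(p_rad_cv) == length(labels), length(p_dl_cv) == length(labels))

  fold <- with_seed_local(seed, make_stratified_folds(labels, n_folds))
  fold_sets <- lapply(seq_len(n_folds), function(f) which(fold == f))
  fold_sets <- purrr::keep(fold_sets, ~ length(unique(labels[.x])) == 2L)
  if (!length(fold_sets)) stop("no fold contains both classes", call. = FALSE)

  combos <- expand.grid(t = t_grid, k = k_grid)      # t varies fastest
  combos <- combos[order(combos$k, combos$t), ]
  cv_auc <- vapply(seq_len(nrow(combos)), function(i) {
    pars <- fusion_params(combos$t[i], combos$k[i])
    mean(vapply(fold_sets, function(te) {
      auc_concordance(fuse_probabilities(p_rad_cv[te], p_dl_cv[te], pars), labels[te])
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cv_auc)                          # first max: smallest k then t
  list(
    params = fusion_params(combos$t[best], combos$k[best]),
    cv_auc = cv_auc[best],
    grid = tibble::tibble(t = combos$t, k = combos$k, cv_auc = cv_auc)
  )
}
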