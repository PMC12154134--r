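# Segmentation-agreement metrics (Dice, 95th-percentile Hausdorff surface
# distance) and rater statistics (per-rater and majority sens/spec/acc,
# pairwise weighted kappa, Cochran's Q).

#' Dice similarity coefficient of two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`. Two empty masks are defined as perfectly
#' agreeing (1.0); one empty mask gives 0.0; both conventions are messaged.
#'
#' @param A,B [mask_volume()]s on the same grid.
#' @return Value in \[0, 1\].
#' @export
dice_coefficient <- function(A, B) {
  stopifnot(is_mask_volume(A), is_mask_volume(B))
  stopifnot_same_grid(A, B)
  na <- sum(A$data); nb <- sum(B$data)
  if (na + nb == 0L) {
    message("both masks empty: Dice defined as 1")
    return(1)
  }
  if (na == 0L || nb == 0L) {
    message("one mask empty: Dice defined as 0")
    return(0)
  }
  2 * sum(A$data & B$data) / (na + nb)
}

# Boundary voxels: mask voxels with at least one face-adjacent background
# neighbour; voxels at the array edge count as boundary.
boundary_voxels <- function(mask) {
  m <- mask$data
  d <- dim(m)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    for (off in c(-1L, 1L)) {
      idx <- seq_len(d[ax]) + off
      pad_bg <- idx < 1L | idx > d[ax]
      idx <- pmin(pmax(idx, 1L), d[ax])
      nb <- switch(ax, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
                   m[, , idx, drop = FALSE])
      if (any(pad_bg)) {
        switch(ax,
               nb[pad_bg, , ] <- 0L,
               nb[, pad_bg, ] <- 0L,
               nb[, , pad_bg] <- 0L)
      }
      interior <- interior & (nb > 0L)
    }
  }
  which(m > 0L & !interior, arr.ind = TRUE)
}

# Directed nearest surface distances from points P to points Q (physical mm),
# chunked so large boundaries stay memory-bounded.
nearest_dists <- function(P, Q, spacing) {
  Pp <- sweep(P, 2, spacing, `*`); Qp <- sweep(Q, 2, spacing, `*`)
  out <- numeric(nrow(Pp))
  q2 <- rowSums(Qp^2)
  for (s in seq(1, nrow(Pp), by = 512L)) {
    e <- min(s + 511L, nrow(Pp))
    blk <- Pp[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), q2, `+`) - 2 * blk %*% t(Qp)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95th-percentile symmetric Hausdorff surface distance
#'
#' Boundary voxels are mask voxels with a face-adjacent background
#' neighbour; distances are between boundary voxel centres in physical mm.
#' The statistic is the 95th percentile of the pooled set of directed
#' nearest surface distances in both directions, so it is symmetric in its
#' arguments and bounded above by the exact Hausdorff distance.
#'
#' @param A,B Non-empty [mask_volume()]s on the same grid.
#' @param spacing Voxel spacing in mm (defaults to the masks' spacing).
#' @param probs Percentile (default 0.95).
#' @return Distance in mm.
#' @export
hausdorff95 <- function(A, B, spacing = NULL, probs = 0.95) {
  stopifnot(is_mask_volume(A), is_mask_volume(B))
  stopifnot_same_grid(A, B)
  if (sum(A$data) == 0L || sum(B$data) == 0L) {
    stop("hausdorff95 undefined for an empty mask", call. = FALSE)
  }
  spacing <- spacing %||% A$spacing
  pa <- boundary_voxels(A); pb <- boundary_voxels(B)
  d <- c(nearest_dists(pa, pb, spacing), nearest_dists(pb, pa, spacing))
  unname(stats::quantile(d, probs = probs, type = 7))
}

#' Weighted Cohen's kappa for two ordinal raters
#'
#' `1 - sum(w * O) / sum(w * E)` with disagreement weights over the ordered
#' categories: `|i - j|` (linear, default) or `(i - j)^2` (quadratic).
#' Errors when either rater is constant (degenerate marginals leave chance
#' agreement undefined).
#'
#' @param scores_r1,scores_r2 Equal-length score vectors (factors or values
#'   matching `levels`).
#' @param weights `"linear"` or `"quadratic"`.
#' @param levels Ordered category levels.
#' @return Kappa (<= 1).
#' @export
weighted_kappa <- function(scores_r1, scores_r2, weights = c("linear", "quadratic"),
                           levels = c("no", "low", "high")) {
  weights <- match.arg(weights)
  i1 <- as.integer(factor(as.character(scores_r1), levels = levels))
  i2 <- as.integer(factor(as.character(scores_r2), levels = levels))
  stopifnot(length(i1) == length(i2))
  if (anyNA(i1) || anyNA(i2)) stop("scores outside the stated levels", call. = FALSE)
  if (length(unique(i1)) < 2L || length(unique(i2)) < 2L) {
    stop("degenerate marginals: a rater used a single category, kappa undefined",
         call. = FALSE)
  }
  L <- length(levels)
  O <- table(factor(i1, levels = 1:L), factor(i2, levels = 1:L)) / length(i1)
  E <- outer(rowSums(O), colSums(O))
  W <- outer(1:L, 1:L, function(i, j) if (weights == "linear") abs(i - j) else (i - j)^2)
  1 - sum(W * O) / sum(W * E)
}

#' Per-rater and majority-vote diagnostic accuracy
#'
#' Binarizes each rater's ordinal score (positive = `"high"` by default,
#' both `"no"` and `"low"` negative) against the binary reference label and
#' reports sensitivity, specificity and accuracy per rater plus a majority
#' row: the score assigned by more than half of the raters, with subjects
#' lacking any majority score (three-way disagreement) excluded and counted.
#'
#' @param ratings Rating table from [simulate_ratings()] (columns
#'   `subject_id`, `label`, `rater_*`).
#' @param positive_levels Score level(s) counted as a positive call.
#' @return List with `metrics` (tibble: rater, n, sens, spec, acc),
#'   `n_majority` and `n_excluded`.
#' @export
rater_metrics <- function(ratings, positive_levels = "high") {
  rater_cols <- grep("^rater_", names(ratings), value = TRUE)
  if (length(rater_cols) < 3L) {
    stop("majority voting needs at least 3 raters", call. = FALSE)
  }
  label <- as.integer(ratings$label)
  stopifnot(all(label %in% 0:1))
  binarize <- function(sc) as.integer(as.character(sc) %in% positive_levels)
  one_row <- function(name, calls, truth) {
    tibble::tibble(
      rater = name, n = length(truth),
      sens = mean(calls[truth == 1L] == 1L),
      spec = mean(calls[truth == 0L] == 0L),
      acc = mean(calls == truth)
    )
  }
  rows <- purrr::map(rater_cols, function(rc) {
    one_row(rc, binarize(ratings[[rc]]), label)
  })

  score_mat <- vapply(rater_cols, function(rc) as.character(ratings[[rc]]),
                      character(nrow(ratings)))
  maj <- apply(score_mat, 1, function(s) {
    tb <- table(s)
    w <- names(tb)[tb > length(s) / 2]
    if (length(w)) w else NA_character_
  })
  has_major <- !is.na(maj)
  maj_row <- one_row("majority",
                     as.integer(maj[has_major] %in% positive_levels),
                     label[has_major])
  list(
    metrics = dplyr::bind_rows(rows, maj_row),
    n_majority = sum(has_major),
    n_excluded = sum(!has_major)
  )
}

#' Cochran's Q test for heterogeneity of matched binary calls
#'
#' Tests whether the raters' positive-call rates differ across matched
#' subjects; the statistic is referred to a chi-square distribution with
#' `raters - 1` degrees of freedom. Subjects on which all raters agree
#' contribute nothing; if every subject is concordant, Q = 0 and p = 1.
#'
#' @param calls n x k binary matrix (subjects x raters).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
cochran_q <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  k <- ncol(calls); n <- nrow(calls)
  if (k < 2L) stop("Cochran's Q needs at least 2 raters", call. = FALSE)
  if (n < 2L) stop("Cochran's Q needs at least 2 subjects", call. = FALSE)
  stopifnot(all(calls %in% 0:1))
  Cj <- colSums(calls); Ri <- rowSums(calls)
  denom <- k * sum(Ri) - sum(Ri^2)
  if (denom == 0) {
    return(list(statistic = 0, df = k - 1L, p_value = 1))
  }
  Q <- (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / denom
  list(statistic = Q, df = k - 1L,
       p_value = stats::pchisq(Q, df = k - 1L, lower.tail = FALSE))
}
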