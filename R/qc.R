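# Image-quality profiling: a 21-indicator vector per scan, dataset-level
# normalization, and a deterministic 2D embedding for visualizing center
# structure.

qc_indicator_names <- c(
  "fg_mean", "fg_range", "fg_variance", "fg_cv", "fg_median", "fg_iqr",
  "fg_skewness", "fg_kurtosis", "bg_mean", "bg_sd", "cpp",
  "snr1", "snr2", "snr3", "snr4", "cnr", "cvp", "cjv", "efc", "fber",
  "fg_fraction"
)

#' Compute the image-quality indicator vector for one scan
#'
#' 21 named indicators: foreground intensity statistics (mean, range,
#' variance, coefficient of variation, median, IQR, skewness, kurtosis),
#' background mean and sd, contrast per pixel (mean absolute deviation of
#' foreground voxels from their 3x3x3 neighbourhood mean), four
#' signal-to-noise variants (`fg_mean/fg_sd`, `fg_median/fg_sd`,
#' `fg_mean/bg_sd`, `fg_median/bg_sd`), contrast-to-noise ratio, coefficient
#' of variation of foreground patch means, coefficient of joint variation,
#' entropy focus criterion (Shannon entropy of energy-normalized
#' magnitudes; scale-invariant), foreground-background energy ratio
#' (median foreground energy over median background energy), and the
#' foreground volume fraction. The foreground/background partition is an
#' Otsu threshold on the intensities unless a mask is supplied.
#' Background-dependent indicators on an empty background are flagged `NaN`
#' with a reason attribute.
#'
#' @param vol A [volume_grid()].
#' @param fg_mask Optional [mask_volume()] overriding the Otsu partition.
#' @return Named numeric vector of length 21 (attribute `nan_reason` lists
#'   any flagged indicators).
#' @export
compute_quality_indicators <- function(vol, fg_mask = NULL) {
  stopifnot(is_volume_grid(vol))
  v <- vol$data
  fg <- if (!is.null(fg_mask)) {
    stopifnot_same_grid(vol, fg_mask)
    fg_mask$data > 0L
  } else {
    v > otsu_threshold(v)
  }
  if (!any(fg)) stop("foreground is empty", call. = FALSE)
  f <- v[fg]; b <- v[!fg]
  fsd <- stats::sd(f)
  nan_reason <- character(0)

  # contrast per pixel over foreground voxels whose full 3^3 neighbourhood
  # is foreground, so a constant foreground scores exactly 0
  nb_mean <- sep_conv3(v, rep(1 / 3, 3), rep(1 / 3, 3), rep(1 / 3, 3))
  fg_core <- sep_conv3(array(as.numeric(fg), dim(v)), rep(1, 3), rep(1, 3), rep(1, 3)) > 26.5
  cpp_val <- if (any(fg_core)) mean(abs(v[fg_core] - nb_mean[fg_core])) else 0

  # patch means on a coarse 3^3 partition of the grid restricted to fg
  d <- dim(v)
  cell <- pmax(d %/% 3L, 1L)
  gi <- pmin((slice.index(v, 1) - 1L) %/% cell[1], 2L) +
    3L * pmin((slice.index(v, 2) - 1L) %/% cell[2], 2L) +
    9L * pmin((slice.index(v, 3) - 1L) %/% cell[3], 2L)
  pm <- tapply(v[fg], gi[fg], mean)
  cvp <- if (length(pm) > 1 && mean(pm) != 0) stats::sd(pm) / abs(mean(pm)) else 0

  mag <- abs(as.numeric(v))
  enorm <- sqrt(sum(mag^2))
  efc <- if (enorm > 0) {
    x <- mag[mag > 0] / enorm
    -sum(x * log(x))
  } else {
    0
  }

  out <- c(
    fg_mean = mean(f), fg_range = max(f) - min(f), fg_variance = stats::var(f),
    fg_cv = if (mean(f) != 0) fsd / abs(mean(f)) else NaN,
    fg_median = stats::median(f), fg_iqr = stats::IQR(f),
    fg_skewness = moment_skewness(f), fg_kurtosis = moment_kurtosis(f),
    bg_mean = NaN, bg_sd = NaN, cpp = cpp_val,
    snr1 = if (fsd > 0) mean(f) / fsd else NaN,
    snr2 = if (fsd > 0) stats::median(f) / fsd else NaN,
    snr3 = NaN, snr4 = NaN, cnr = NaN, cvp = cvp, cjv = NaN,
    efc = efc, fber = NaN,
    fg_fraction = mean(fg)
  )
  if (length(b) > 1L) {
    bsd <- stats::sd(b)
    out["bg_mean"] <- mean(b); out["bg_sd"] <- bsd
    if (bsd > 0) {
      out["snr3"] <- mean(f) / bsd
      out["snr4"] <- stats::median(f) / bsd
      out["cnr"] <- (mean(f) - mean(b)) / bsd
    } else {
      nan_reason <- c(nan_reason, "snr3/snr4/cnr: zero background sd")
    }
    if (abs(mean(f) - mean(b)) > 0) out["cjv"] <- (fsd + bsd) / abs(mean(f) - mean(b))
    med_b2 <- stats::median(b^2)
    if (med_b2 > 0) {
      out["fber"] <- stats::median(f^2) / med_b2
    } else {
      nan_reason <- c(nan_reason, "fber: zero background energy")
    }
  } else {
    nan_reason <- c(nan_reason, "bg_mean/bg_sd/snr3/snr4/cnr/cjv/fber: empty background")
  }
  out <- out[qc_indicator_names]
  attr(out, "nan_reason") <- nan_reason
  out
}

#' Quality-indicator table for a set of scans
#'
#' @param volumes Named list of [volume_grid()]s.
#' @return Tibble with `scan_id` and the 21 indicator columns.
#' @export
compute_qc_table <- function(volumes) {
  ids <- names(volumes) %||% as.character(seq_along(volumes))
  rows <- purrr::map(volumes, function(v) {
    x <- compute_quality_indicators(v)
    tibble::as_tibble(as.list(x))
  })
  dplyr::bind_cols(tibble::tibble(scan_id = ids), dplyr::bind_rows(rows))
}

#' Normalize an indicator matrix across the dataset
#'
#' `zscore` centres each column to mean 0, sd 1; `minmax` maps each column
#' to \[0, 1\] (constant columns map to 0); `whiten` applies PCA whitening so
#' the sample covariance is the identity. Constant columns raise an error
#' for `zscore` and `whiten`.
#'
#' @param m Numeric matrix / tibble (a `scan_id` column is carried through).
#' @param method `"zscore"`, `"minmax"` or `"whiten"`.
#' @return Normalized matrix (or tibble when a tibble was supplied).
#' @export
normalize_indicator_matrix <- function(m, method = c("zscore", "minmax", "whiten")) {
  method <- match.arg(method)
  id_col <- NULL
  if (is.data.frame(m)) {
    if ("scan_id" %in% names(m)) {
      id_col <- m$scan_id
      m <- m[, setdiff(names(m), "scan_id"), drop = FALSE]
    }
    m <- as.matrix(m)
  }
  if (nrow(m) < 2L) stop("need at least 2 scans", call. = FALSE)
  rng <- apply(m, 2, function(v) max(v) - min(v))
  out <- switch(method,
    zscore = {
      if (any(rng == 0)) stop("constant column: z-score undefined", call. = FALSE)
      scale(m)
    },
    minmax = {
      lo <- apply(m, 2, min)
      sweep(sweep(m, 2, lo), 2, ifelse(rng == 0, 1, rng), `/`)
    },
    whiten = {
      if (any(rng == 0)) stop("constant column: whitening undefined", call. = FALSE)
      mc <- scale(m, scale = FALSE)
      S <- stats::cov(mc)
      e <- eigen(S, symmetric = TRUE)
      if (min(e$values) < 1e-12 * max(e$values)) {
        stop("singular indicator covariance: whitening undefined", call. = FALSE)
      }
      mc %*% e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
    }
  )
  out <- unclass(out)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  colnames(out) <- colnames(m)
  if (!is.null(id_col)) {
    return(dplyr::bind_cols(tibble::tibble(scan_id = id_col),
                            tibble::as_tibble(as.data.frame(out))))
  }
  out
}

#' Project an indicator matrix to two dimensions
#'
#' Deterministic 2D embedding for visualizing center/batch structure in the
#' quality indicators. The embedding algorithm is pluggable behind this
#' contract (deterministic given the seed, n x 2 output, cluster structure
#' preserved); the provided method is principal components with a fixed sign
#' convention.
#'
#' @param m Normalized indicator matrix / tibble.
#' @param seed Integer seed (recorded; the principal-component method is
#'   deterministic by construction).
#' @param method `"pca"`.
#' @return Tibble of class `qc_embedding` with columns `scan_id` (if
#'   available), `x`, `y`.
#' @export
embed_2d <- function(m, seed = 1L, method = c("pca")) {
  method <- match.arg(method)
  id_col <- NULL
  if (is.data.frame(m)) {
    if ("scan_id" %in% names(m)) {
      id_col <- m$scan_id
      m <- m[, setdiff(names(m), "scan_id"), drop = FALSE]
    }
    m <- as.matrix(m)
  }
  if (nrow(m) < 3L) stop("need at least 3 scans to embed", call. = FALSE)
  co <- with_seed_local(seed, {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = 2L)
    sc <- pc$x[, 1:2, drop = FALSE]
    if (ncol(sc) < 2L) sc <- cbind(sc, 0)
    # fixed sign convention: largest-magnitude loading positive
    for (j in 1:2) {
      rot <- pc$rotation[, min(j, ncol(pc$rotation))]
      if (rot[which.max(abs(rot))] < 0) sc[, j] <- -sc[, j]
    }
    sc
  })
  out <- tibble::tibble(x = co[, 1], y = co[, 2])
  if (!is.null(id_col)) out <- dplyr::bind_cols(tibble::tibble(scan_id = id_col), out)
  class(out) <- c("qc_embedding", class(out))
  out
}
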