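# Preprocessing chain: isotropic resampling -> bias-field correction ->
# min-max normalization, plus the ROI crop/resize used by the CNN stage.
# The orchestrator `preprocess_volume()` applies the steps in exactly this
# order.

# Trilinear gather at continuous 1-based voxel indices (clamped).
interp3 <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  xi <- cl(xi, d[1]); yi <- cl(yi, d[2]); zi <- cl(zi, d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), max(d[2] - 1L, 1L))
  z0 <- pmin(floor(zi), max(d[3] - 1L, 1L))
  x0 <- pmax(x0, 1L); y0 <- pmax(y0, 1L); z0 <- pmax(z0, 1L)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  at <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

grid_coords <- function(out_dim, out_spacing, in_spacing) {
  # physical center of output voxel j is (j - 0.5) * out_spacing;
  # continuous input index is phys / in_spacing + 0.5
  lapply(1:3, function(ax) {
    ((seq_len(out_dim[ax]) - 0.5) * out_spacing[ax]) / in_spacing[ax] + 0.5
  })
}

#' Resample a volume (and mask) to isotropic spacing
#'
#' Linear interpolation for intensities, nearest-neighbour for the mask
#' (re-binarised). `mode = "3D"` resamples all three axes to `target_mm`;
#' `mode = "2D"` resamples only the in-plane axes and preserves the slice
#' spacing, matching an axial slice-wise analysis.
#'
#' @param vol A [volume_grid()].
#' @param mask Optional companion [mask_volume()] on the same grid.
#' @param target_mm Target voxel size in mm (> 0); default 1.
#' @param mode `"3D"` or `"2D"`.
#' @return List with `volume` and (if given) `mask`.
#' @export
resample_isotropic <- function(vol, mask = NULL, target_mm = 1, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  stopifnot(is_volume_grid(vol))
  if (target_mm <= 0) stop("target_mm must be > 0", call. = FALSE)
  d <- dim(vol$data)
  if (any(d < 2L)) stop("degenerate input: single-voxel axis", call. = FALSE)
  if (!is.null(mask)) stopifnot_same_grid(vol, mask)

  out_spacing <- if (mode == "3D") rep(target_mm, 3) else c(target_mm, target_mm, vol$spacing[3])
  out_dim <- pmax(1L, as.integer(round(d * vol$spacing / out_spacing)))
  co <- grid_coords(out_dim, out_spacing, vol$spacing)
  xi <- array(rep(co[[1]], times = out_dim[2] * out_dim[3]), out_dim)
  yi <- array(rep(rep(co[[2]], each = out_dim[1]), times = out_dim[3]), out_dim)
  zi <- array(rep(co[[3]], each = out_dim[1] * out_dim[2]), out_dim)

  new_vol <- volume_grid(array(interp3(vol$data, xi, yi, zi), out_dim), out_spacing)
  out <- list(volume = new_vol)
  if (!is.null(mask)) {
    d2 <- dim(mask$data)
    nn <- mask$data[cbind(
      pmin(pmax(round(xi), 1), d2[1]),
      pmin(pmax(round(yi), 1), d2[2]),
      pmin(pmax(round(zi), 1), d2[3])
    )]
    out$mask <- mask_volume(array(as.integer(nn > 0.5), out_dim), out_spacing)
  }
  out
}

#' Correct a smooth multiplicative bias field
#'
#' Estimates low-frequency shading by least-squares fitting an order-3
#' polynomial (in normalized coordinates) to the log-intensities of the
#' foreground, then divides the volume by the exponentiated, mean-centred
#' fit. The estimated field is strictly positive everywhere and the mean
#' foreground log-intensity is preserved, so the operation is idempotent up
#' to tolerance. The foreground defaults to an Otsu partition of the
#' intensities; a mask can restrict the fitting region instead.
#'
#' @param vol A [volume_grid()].
#' @param mask Optional [mask_volume()] defining the fitting foreground.
#' @return A bias-corrected [volume_grid()].
#' @export
correct_bias_field <- function(vol, mask = NULL) {
  stopifnot(is_volume_grid(vol))
  v <- vol$data
  if (all(v == 0)) stop("all-zero volume: no foreground to correct", call. = FALSE)
  d <- dim(v)
  fg <- if (!is.null(mask)) {
    stopifnot_same_grid(vol, mask)
    mask$data > 0L
  } else {
    v > otsu_threshold(v)
  }
  if (!any(fg)) stop("foreground is empty", call. = FALSE)

  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  xs <- array(rep(cx, times = d[2] * d[3]), d)
  ys <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  zs <- array(rep(cz, each = d[1] * d[2]), d)

  eps <- 1e-8 * max(abs(v))
  pos <- fg & (v > eps)
  if (sum(pos) < 30L) return(vol)  # too few usable voxels to estimate shading
  X <- poly3d_design(xs[pos], ys[pos], zs[pos], deg = 3L)
  fit <- stats::lm.fit(X, log(v[pos]))
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  log_field <- array(poly3d_design(as.numeric(xs), as.numeric(ys), as.numeric(zs), deg = 3L) %*% coef, d)
  log_field <- log_field - mean(log_field[pos])
  volume_grid(v / exp(log_field), vol$spacing)
}

#' Min-max normalize intensities to \[0, 1\]
#'
#' @param vol A [volume_grid()].
#' @param region Optional [mask_volume()]; min and max are taken over the
#'   region (default: whole volume) and the affine map is applied everywhere,
#'   then clipped to \[0, 1\].
#' @param id Subject identifier used in error messages.
#' @return A [volume_grid()] with values in \[0, 1\].
#' @export
normalize_minmax <- function(vol, region = NULL, id = "volume") {
  stopifnot(is_volume_grid(vol))
  v <- vol$data
  sel <- if (!is.null(region)) {
    stopifnot_same_grid(vol, region)
    v[region$data > 0L]
  } else {
    v
  }
  lo <- min(sel); hi <- max(sel)
  if (hi <= lo) stop(sprintf("constant normalization region for %s", id), call. = FALSE)
  volume_grid(array(pmin(pmax((v - lo) / (hi - lo), 0), 1), dim(v)), vol$spacing)
}

#' Crop to the mask bounding box and resize
#'
#' The crop is the mask's bounding box expanded by `margin_voxels` on every
#' side and clipped to the volume; the crop is then resized to `out_shape`
#' by linear interpolation. This is the region-of-interest path feeding the
#' convolutional probability stage (native training scale 96^3; the compact
#' desk scale default is 32^3).
#'
#' @param vol A [volume_grid()].
#' @param mask Non-empty [mask_volume()] on the same grid.
#' @param margin_voxels Non-negative integer margin.
#' @param out_shape Integer length-3 output shape.
#' @return A [volume_grid()] of shape `out_shape`.
#' @export
crop_resize_roi <- function(vol, mask, margin_voxels = 4L, out_shape = c(32L, 32L, 32L)) {
  stopifnot(is_volume_grid(vol), is_mask_volume(mask))
  stopifnot_same_grid(vol, mask)
  if (sum(mask$data) == 0L) stop("empty mask: nothing to crop", call. = FALSE)
  out_shape <- as.integer(out_shape)
  d <- dim(vol$data)
  idx <- which(mask$data > 0L, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin_voxels, 1L)
  hi <- pmin(apply(idx, 2, max) + margin_voxels, d)
  sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  len <- dim(sub)
  co <- lapply(1:3, function(ax) (seq_len(out_shape[ax]) - 0.5) / out_shape[ax] * len[ax] + 0.5)
  xi <- array(rep(co[[1]], times = out_shape[2] * out_shape[3]), out_shape)
  yi <- array(rep(rep(co[[2]], each = out_shape[1]), times = out_shape[3]), out_shape)
  zi <- array(rep(co[[3]], each = out_shape[1] * out_shape[2]), out_shape)
  out_spacing <- vol$spacing * len / out_shape
  volume_grid(array(interp3(sub, xi, yi, zi), out_shape), out_spacing)
}

#' Run the full preprocessing chain on one subject
#'
#' Applies, in order: isotropic resampling (1 mm^3 for 3D analysis, 1 mm^2
#' in-plane for 2D), bias-field correction, and min-max normalization. The
#' order is fixed; callers must not reorder the steps.
#'
#' @param vol A [volume_grid()].
#' @param mask Companion cyst [mask_volume()].
#' @param mode `"3D"` or `"2D"`.
#' @param target_mm Isotropic target spacing in mm.
#' @param normalize_region `"volume"` (default) or `"roi"`.
#' @param id Subject identifier for error messages.
#' @return List with preprocessed `volume` and `mask`.
#' @export
preprocess_volume <- function(vol, mask, mode = c("3D", "2D"), target_mm = 1,
                              normalize_region = c("volume", "roi"), id = "volume") {
  mode <- match.arg(mode)
  normalize_region <- match.arg(normalize_region)
  rs <- resample_isotropic(vol, mask, target_mm = target_mm, mode = mode)
  bc <- correct_bias_field(rs$volume)
  region <- if (normalize_region == "roi") rs$mask else NULL
  list(volume = normalize_minmax(bc, region = region, id = id), mask = rs$mask)
}

# Otsu threshold on a numeric array (256-bin histogram).
otsu_threshold <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(as.integer((v - lo) / (hi - lo) * n_bins) + 1L, n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + (k / n_bins) * (hi - lo)
}
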