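# Six-family 2D/3D radiomic feature bank over the cyst ROI: Raw, Gray,
# Gradient, Laws, Haralick (GLCM) and CoLlAGe maps, each aggregated by four
# ROI statistics (median, sd, skewness, excess kurtosis).

#' Feature bank configuration
#'
#' Defaults follow the study design the package models: GLCM windows 3, 5
#' and 7 voxels with 4, 8, 16, 32 and 64 gray levels; a 3-voxel window for
#' the gray filters; CoLlAGe orientation entropy at windows 3 and 5 with 64
#' orientation bins. The exact per-family enumeration is configurable and
#' the resulting count is recorded in the feature metadata.
#'
#' @param windows Odd GLCM window sizes in voxels.
#' @param gray_levels Gray-level counts for quantization.
#' @param gray_window Odd window for the gray (mean/median/sd/range) filters.
#' @param collage_windows Odd windows for CoLlAGe orientation co-occurrence.
#' @param collage_bins Orientation bins over \[0, pi) (even, so in-plane
#'   90-degree rotations permute bins exactly).
#' @param families Character subset of the six families to compute.
#' @return List of class `feature_config`.
#' @export
feature_config <- function(windows = c(3L, 5L, 7L),
                           gray_levels = c(4L, 8L, 16L, 32L, 64L),
                           gray_window = 3L,
                           collage_windows = c(3L, 5L),
                           collage_bins = 64L,
                           families = c("raw", "gray", "gradient", "laws",
                                        "haralick", "collage")) {
  stopifnot(all(windows %% 2 == 1), all(windows >= 3),
            all(gray_levels >= 2), gray_window %% 2 == 1,
            all(collage_windows %% 2 == 1), collage_bins %% 2 == 0)
  families <- match.arg(families, several.ok = TRUE)
  structure(
    list(windows = as.integer(windows), gray_levels = as.integer(gray_levels),
         gray_window = as.integer(gray_window),
         collage_windows = as.integer(collage_windows),
         collage_bins = as.integer(collage_bins), families = families),
    class = "feature_config"
  )
}

#' GLCM offset directions
#'
#' Distance-1 unique symmetric directions: 4 in-plane offsets for 2D, 13 for
#' 3D. Each offset is accumulated symmetrically into a single rotation-pooled
#' co-occurrence matrix.
#'
#' @param mode `"2D"` or `"3D"`.
#' @return Integer matrix, one offset per row.
#' @export
glcm_offsets <- function(mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  if (mode == "2D") {
    rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  } else {
    rbind(
      c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
      c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
      c(0, 1, 1), c(0, 1, -1),
      c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
    )
  }
}

#' Quantize ROI intensities to equal-width gray levels
#'
#' Bins span the ROI minimum to maximum, so the labels are invariant to any
#' positive affine rescaling of the intensities. Voxels outside the mask get
#' label 0 (ignore); a constant ROI maps every ROI voxel to level 1.
#'
#' @param vol A [volume_grid()].
#' @param mask Non-empty [mask_volume()] on the same grid.
#' @param levels Number of gray levels (>= 2).
#' @return Integer array with labels `1..levels` inside the mask, 0 outside.
#' @export
quantize_roi <- function(vol, mask, levels) {
  stopifnot(is_volume_grid(vol), is_mask_volume(mask), levels >= 2)
  stopifnot_same_grid(vol, mask)
  inm <- mask$data > 0L
  if (!any(inm)) stop("empty mask", call. = FALSE)
  v <- vol$data[inm]
  lo <- min(v); hi <- max(v)
  lab <- array(0L, dim(vol$data))
  if (hi <= lo) {
    lab[inm] <- 1L
  } else {
    lab[inm] <- pmin(as.integer(floor((v - lo) / (hi - lo) * levels)) + 1L, as.integer(levels))
  }
  lab
}

#' Normalized co-occurrence matrix of a labelled patch
#'
#' Reference (single-patch) GLCM: counts ordered pairs at every stated offset
#' over the whole patch, accumulated symmetrically and normalized to sum 1.
#' Pairs involving ignore-labelled (0) voxels are skipped.
#'
#' @param patch Integer array of labels (0 = ignore).
#' @param levels Number of levels.
#' @param offsets Offset matrix as from [glcm_offsets()].
#' @param symmetric Accumulate each pair in both orders (default `TRUE`).
#' @return `levels x levels` matrix summing to 1.
#' @export
glcm_window <- function(patch, levels, offsets = glcm_offsets("3D"), symmetric = TRUE) {
  if (is.null(dim(patch))) dim(patch) <- c(length(patch), 1L, 1L)
  if (length(dim(patch)) == 2L) dim(patch) <- c(dim(patch), 1L)
  d <- dim(patch)
  P <- matrix(0, levels, levels)
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      la <- patch[x, y, z]
      if (la <= 0L) next
      qx <- x + off[1]; qy <- y + off[2]; qz <- z + off[3]
      if (qx < 1 || qx > d[1] || qy < 1 || qy > d[2] || qz < 1 || qz > d[3]) next
      lb <- patch[qx, qy, qz]
      if (lb <= 0L) next
      P[la, lb] <- P[la, lb] + 1
      if (symmetric) P[lb, la] <- P[lb, la] + 1
    }
  }
  if (sum(P) == 0) stop("no valid co-occurrence pairs in patch", call. = FALSE)
  P / sum(P)
}

haralick_stat_names <- c(
  "energy", "contrast", "correlation", "variance", "idm", "sum_average",
  "sum_variance", "sum_entropy", "entropy", "difference_variance",
  "difference_entropy", "imc1", "imc2"
)

#' The 13 classic Haralick statistics of a normalized GLCM
#'
#' Energy, contrast, correlation, variance, inverse difference moment, sum
#' average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, and the two information measures of correlation.
#' Entropies use log base 2; degenerate denominators (zero marginal sd or
#' entropy) map to 0 so no non-finite value is emitted. The 14th statistic
#' (maximal correlation coefficient) is deliberately omitted.
#'
#' @param glcm Square normalized co-occurrence matrix.
#' @return Named numeric vector of length 13.
#' @export
haralick_stats <- function(glcm) {
  stopifnot(is.matrix(glcm), nrow(glcm) == ncol(glcm))
  if (abs(sum(glcm) - 1) > 1e-8) stop("glcm must be normalized to sum 1", call. = FALSE)
  out <- cpp_haralick_stats(glcm)
  names(out) <- haralick_stat_names
  out
}

# Internal container for ROI-restricted feature maps: values at the in-mask
# voxels only.
roi_maps <- function(values, idx, dims) {
  structure(list(values = values, idx = idx, dims = dims), class = "roi_maps")
}

mask_radii <- function(w, mode) {
  r <- (w - 1L) %/% 2L
  if (mode == "2D") c(r, r, 0L) else c(r, r, r)
}

#' Sliding-window Haralick feature maps
#'
#' For every (window, gray-level) pair, computes the 13 Haralick statistics
#' of the rotation-pooled GLCM inside a sliding window centred at each
#' in-mask voxel. 2D windows slide within axial slices with 4 in-plane
#' offsets; 3D windows are cubic with 13 offsets. Windows are clipped at the
#' volume bounds; a window with no valid pair yields the neutral
#' constant-patch statistics.
#'
#' @param vol Preprocessed [volume_grid()].
#' @param mask Cyst [mask_volume()].
#' @param windows,levels_list Window sizes and gray-level counts.
#' @param mode `"2D"` or `"3D"`.
#' @return A `roi_maps` object with one map per (window, levels, statistic).
#' @export
compute_haralick_maps <- function(vol, mask, windows = c(3L, 5L, 7L),
                                  levels_list = c(4L, 8L, 16L, 32L, 64L),
                                  mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  stopifnot_same_grid(vol, mask)
  d <- dim(vol$data)
  if (any(windows > d[1]) || any(windows > d[2]) ||
      (mode == "3D" && any(windows > d[3]))) {
    stop("window larger than volume", call. = FALSE)
  }
  idx <- which(mask$data > 0L)
  if (!length(idx)) stop("empty mask", call. = FALSE)
  offs <- matrix(as.integer(glcm_offsets(mode)), ncol = 3)
  labels_multi <- vapply(levels_list, function(L) as.integer(quantize_roi(vol, mask, L)),
                         integer(prod(d)))
  vals <- list()
  for (w in windows) {
    m <- cpp_haralick_maps_multi(labels_multi, as.integer(d), as.integer(idx - 1L),
                                 mask_radii(w, mode), as.integer(levels_list), offs)
    for (q in seq_along(levels_list)) {
      for (s in seq_along(haralick_stat_names)) {
        nm <- sprintf("haralick_w%d_g%d_%s", w, levels_list[q], haralick_stat_names[s])
        vals[[nm]] <- m[, 13L * (q - 1L) + s]
      }
    }
  }
  roi_maps(vals, idx, d)
}

#' CoLlAGe orientation-entropy feature maps
#'
#' Per voxel: central-difference intensity gradients; dominant local gradient
#' orientation as the principal direction of the windowed gradient structure
#' tensor; orientation angles quantized into `bins` equal bins (theta over
#' \[0, pi); additionally phi over \[0, pi/2\] in 3D); co-occurrence of
#' quantized orientations inside the window; and the entropy of that matrix
#' emitted as the feature map. Voxels with zero gradient energy get the
#' reserved ignore bin and are skipped in the co-occurrence counts.
#'
#' @param vol Preprocessed [volume_grid()].
#' @param mask Cyst [mask_volume()].
#' @param window Odd window size in voxels.
#' @param bins Even number of orientation bins.
#' @param mode `"2D"` or `"3D"`.
#' @return A `roi_maps` object (`collage_w*_theta_entropy`, plus
#'   `collage_w*_phi_entropy` in 3D).
#' @export
compute_collage_maps <- function(vol, mask, window = 3L, bins = 64L,
                                 mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  stopifnot_same_grid(vol, mask)
  d <- dim(vol$data)
  idx <- which(mask$data > 0L)
  if (!length(idx)) stop("empty mask", call. = FALSE)
  radii <- mask_radii(window, mode)

  cd <- c(-0.5, 0, 0.5)  # correlation semantics: (v[i+1] - v[i-1]) / 2
  gx <- conv_axis(vol$data, cd, 1L)
  gy <- conv_axis(vol$data, cd, 2L)
  gz <- if (mode == "3D") conv_axis(vol$data, cd, 3L) else array(0, d)

  # orientation bins are needed in the window neighbourhood of every mask
  # voxel: dilate the mask by the window radii
  box <- function(a, r) sep_conv3(a, rep(1, 2 * r[1] + 1), rep(1, 2 * r[2] + 1),
                                  rep(1, 2 * r[3] + 1))
  region <- which(box(array(as.numeric(mask$data), d), radii) > 0.5)

  ev <- cpp_dominant_orientation(as.numeric(gx), as.numeric(gy), as.numeric(gz),
                                 as.integer(d), as.integer(region - 1L),
                                 as.integer(radii))
  nrm <- sqrt(rowSums(ev^2))
  ok <- nrm > 0

  bin_from_angle <- function(angle, span) {
    b <- floor(angle / span * bins) + 1L
    as.integer(pmin(pmax(b, 1L), bins))
  }
  theta <- atan2(ev[, 2], ev[, 1]) %% pi
  theta_lab <- array(0L, d)
  theta_lab[region[ok]] <- bin_from_angle(theta[ok], pi)

  offs <- matrix(as.integer(glcm_offsets(mode)), ncol = 3)
  vals <- list()
  ent <- cpp_haralick_maps(as.integer(theta_lab), as.integer(d),
                           as.integer(idx - 1L), radii, as.integer(bins), offs)[, 9]
  vals[[sprintf("collage_w%d_theta_entropy", window)]] <- ent
  if (mode == "3D") {
    phi <- acos(pmin(abs(ev[, 3]) / pmax(nrm, 1e-300), 1))
    phi_lab <- array(0L, d)
    phi_lab[region[ok]] <- bin_from_angle(phi[ok], pi / 2)
    vals[[sprintf("collage_w%d_phi_entropy", window)]] <-
      cpp_haralick_maps(as.integer(phi_lab), as.integer(d),
                        as.integer(idx - 1L), radii, as.integer(bins), offs)[, 9]
  }
  roi_maps(vals, idx, d)
}

laws_kernels <- function() {
  list(
    L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1), S5 = c(-1, 0, 2, 0, -1),
    W5 = c(-1, 2, 0, -2, 1), R5 = c(1, -4, 6, -4, 1)
  )
}

#' Laws texture-energy maps
#'
#' Separable convolution with every outer product of the five classic
#' length-5 kernels (level L5, edge E5, spot S5, wave W5, ripple R5):
#' 25 maps in 2D (slice-wise), 125 in 3D. The absolute response (energy
#' magnitude) is emitted; edges use replicate padding.
#'
#' @param vol A [volume_grid()].
#' @param mode `"2D"` or `"3D"`.
#' @return Named list of 3D arrays.
#' @export
compute_laws_maps <- function(vol, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  d <- dim(vol$data)
  kn <- names(laws_kernels())
  m <- cpp_laws_maps(as.numeric(vol$data), as.integer(d), mode == "3D")
  nms <- if (mode == "2D") {
    as.vector(t(outer(kn, kn, paste0)))          # x outermost, then y
  } else {
    nm <- character(125); c0 <- 0L
    for (nx in kn) for (ny in kn) for (nz in kn) {
      c0 <- c0 + 1L; nm[c0] <- paste0(nx, ny, nz)
    }
    nm
  }
  out <- lapply(seq_along(nms), function(j) array(m[, j], d))
  names(out) <- paste0("laws_", nms)
  out
}

#' Gradient feature maps
#'
#' Per-axis Sobel responses (derivative kernel `(-1, 0, 1)` with `(1, 2, 1)`
#' smoothing on the orthogonal axes; in-plane only for 2D), the Sobel
#' magnitude, and the central-finite-difference gradient magnitude (voxel
#' units, so a ramp of slope s per voxel yields s at interior voxels).
#'
#' @param vol A [volume_grid()].
#' @param mode `"2D"` or `"3D"`.
#' @return Named list of 3D arrays.
#' @export
compute_gradient_maps <- function(vol, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  v <- vol$data
  der <- c(-1, 0, 1)   # correlation semantics: response = v[i+1] - v[i-1]
  sm <- c(1, 2, 1)
  axes <- if (mode == "2D") 1:2 else 1:3
  out <- list()
  for (ax in axes) {
    r <- v
    for (bx in axes) {
      r <- conv_axis(r, if (bx == ax) der else sm, bx)
    }
    out[[paste0("sobel_", c("x", "y", "z")[ax])]] <- r
  }
  out$sobel_magnitude <- sqrt(Reduce(`+`, lapply(out, function(a) a^2)))
  cd <- c(-0.5, 0, 0.5)  # central difference (v[i+1] - v[i-1]) / 2
  gsq <- array(0, dim(v))
  for (ax in axes) gsq <- gsq + conv_axis(v, cd, ax)^2
  out$gradient_magnitude <- sqrt(gsq)
  out
}

#' Gray filter maps
#'
#' Sliding-window mean, median, standard deviation and range with replicate
#' padding; 2D mode uses in-plane windows.
#'
#' @param vol A [volume_grid()].
#' @param window Odd window size.
#' @param mode `"2D"` or `"3D"`.
#' @return Named list of 3D arrays.
#' @export
compute_gray_maps <- function(vol, window = 3L, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  d <- dim(vol$data)
  st <- cpp_window_stats(as.numeric(vol$data), as.integer(d),
                         as.integer(seq_len(prod(d)) - 1L), mask_radii(window, mode))
  list(
    gray_mean = array(st[, 1], d), gray_median = array(st[, 2], d),
    gray_std = array(st[, 3], d), gray_range = array(st[, 4], d)
  )
}

#' Aggregate a feature map over the ROI
#'
#' The four ROI statistics: median, standard deviation (sample), skewness and
#' excess kurtosis (Fisher, bias-uncorrected). Constant maps yield skewness
#' and kurtosis 0 by convention.
#'
#' @param map A 3D array, or a numeric vector of in-mask values.
#' @param mask A [mask_volume()] (ignored when `map` is already a vector of
#'   in-mask values).
#' @return Named numeric vector `(median, std, skewness, kurtosis)`.
#' @export
aggregate_map <- function(map, mask = NULL) {
  x <- if (is.array(map)) {
    stopifnot(is_mask_volume(mask))
    if (sum(mask$data) == 0L) stop("empty mask", call. = FALSE)
    map[mask$data > 0L]
  } else {
    as.numeric(map)
  }
  if (!length(x)) stop("empty mask", call. = FALSE)
  c(median = stats::median(x),
    std = if (length(x) > 1) stats::sd(x) else 0,
    skewness = moment_skewness(x),
    kurtosis = moment_kurtosis(x))
}

roi_margin <- function(config) {
  # kernel reach: CoLlAGe needs bins in the mask dilated by the window
  # radius, bins need a windowed tensor (radius) of gradients (reach 1);
  # GLCM needs the window radius; Laws reaches 2. Cropping with this margin
  # leaves every in-mask value identical to an uncropped computation.
  r_h <- max((config$windows - 1L) %/% 2L)
  r_c <- max((config$collage_windows - 1L) %/% 2L)
  max(r_h, 2L * r_c + 1L, 2L) + 1L
}

#' Extract the full radiomic feature vector for one subject
#'
#' Orchestrates the six families per the configuration over the cyst ROI.
#' 2D mode computes maps within axial slices and aggregates over the pooled
#' in-mask pixels of all slices. The volume is internally cropped to the
#' mask bounding box plus the kernel-reach margin, which leaves all in-mask
#' map values unchanged while bounding the computation.
#'
#' @param vol Preprocessed [volume_grid()].
#' @param mask Cyst [mask_volume()] on the same grid.
#' @param mode `"3D"` or `"2D"`.
#' @param config A [feature_config()].
#' @return List with `features` (named numeric vector) and `spec` (tibble of
#'   per-feature metadata: family, filter, window, gray_levels, statistic,
#'   dim).
#' @export
extract_features <- function(vol, mask, mode = c("3D", "2D"),
                             config = feature_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "feature_config"))
  stopifnot_same_grid(vol, mask)
  if (sum(mask$data) == 0L) stop("empty mask", call. = FALSE)

  # crop to bounding box + margin (pure speed optimisation, values identical)
  d <- dim(vol$data)
  idx <- which(mask$data > 0L, arr.ind = TRUE)
  mg <- roi_margin(config)
  lo <- pmax(apply(idx, 2, min) - mg, 1L)
  hi <- pmin(apply(idx, 2, max) + mg, d)
  vol <- volume_grid(vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE], vol$spacing)
  mask <- mask_volume(mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE], mask$spacing)

  inm <- mask$data > 0L
  stat_names <- c("median", "std", "skewness", "kurtosis")
  acc <- new.env(parent = emptyenv())
  acc$vals <- list(); acc$name <- character(); acc$family <- character()
  acc$window <- integer(); acc$levels <- integer()
  add_map <- function(name, values, family, window = NA_integer_, levels = NA_integer_) {
    i <- length(acc$vals) + 1L
    acc$vals[[i]] <- aggregate_map(values)
    acc$name[i] <- name; acc$family[i] <- family
    acc$window[i] <- window; acc$levels[i] <- levels
  }

  fam <- config$families
  if ("raw" %in% fam) add_map("raw_intensity", vol$data[inm], "Raw")
  if ("gray" %in% fam) {
    gm <- compute_gray_maps(vol, config$gray_window, mode)
    for (nm in names(gm)) add_map(nm, gm[[nm]][inm], "Gray", window = config$gray_window)
  }
  if ("gradient" %in% fam) {
    gr <- compute_gradient_maps(vol, mode)
    for (nm in names(gr)) add_map(nm, gr[[nm]][inm], "Gradient")
  }
  if ("laws" %in% fam) {
    lw <- compute_laws_maps(vol, mode)
    for (nm in names(lw)) add_map(nm, lw[[nm]][inm], "Laws", window = 5L)
  }
  if ("haralick" %in% fam) {
    hm <- compute_haralick_maps(vol, mask, config$windows, config$gray_levels, mode)
    for (nm in names(hm$values)) {
      w <- as.integer(sub("^haralick_w(\\d+)_g.*$", "\\1", nm))
      g <- as.integer(sub("^haralick_w\\d+_g(\\d+)_.*$", "\\1", nm))
      add_map(nm, hm$values[[nm]], "Haralick", window = w, levels = g)
    }
  }
  if ("collage" %in% fam) {
    for (w in config$collage_windows) {
      cm <- compute_collage_maps(vol, mask, w, config$collage_bins, mode)
      for (nm in names(cm$values)) {
        add_map(nm, cm$values[[nm]], "CoLlAGe", window = w, levels = config$collage_bins)
      }
    }
  }

  n_maps <- length(acc$vals)
  feats <- unlist(acc$vals, use.names = FALSE)
  names(feats) <- paste(rep(acc$name, each = 4L), stat_names, sep = "_")
  spec <- tibble::tibble(
    feature = names(feats),
    family = rep(acc$family, each = 4L),
    filter = rep(acc$name, each = 4L),
    window = rep(acc$window, each = 4L),
    gray_levels = rep(acc$levels, each = 4L),
    statistic = rep(stat_names, times = n_maps),
    dim = mode
  )
  if (any(!is.finite(feats))) {
    stop("non-finite feature values after extraction", call. = FALSE)
  }
  list(features = feats, spec = spec)
}

#' Write / read a feature table as CSV with a JSON metadata sidecar
#'
#' The CSV holds the subjects-by-features matrix; the per-feature metadata
#' (family, filter, window, gray levels, statistic, 2D/3D) travels in a
#' sidecar `<path>.spec.json`.
#'
#' @param features Feature tibble from [extract_cohort_features()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `path` invisibly; `read_feature_table()` returns the tibble with
#'   the metadata re-attached as attribute `"feature_spec"`.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  spec <- attr(features, "feature_spec")
  if (!is.null(spec)) {
    jsonlite::write_json(spec, paste0(path, ".spec.json"), digits = NA)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           check.names = FALSE))
  sidecar <- paste0(path, ".spec.json")
  if (file.exists(sidecar)) {
    attr(out, "feature_spec") <- tibble::as_tibble(jsonlite::read_json(
      sidecar, simplifyVector = TRUE
    ))
  }
  out
}

#' Extract the feature table for a whole cohort
#'
#' Runs the per-subject preprocessing chain (resample to isotropic, bias
#' correction, min-max normalization — all strictly per subject, so no
#' information crosses subjects) and extracts the configured feature bank.
#'
#' @param cohort A [generate_cohort()] result (or compatible list with
#'   `manifest`, `volumes`, `cyst_masks`).
#' @param mode `"3D"` or `"2D"`.
#' @param config A [feature_config()].
#' @param preprocess Apply [preprocess_volume()] first (default `TRUE`).
#' @param target_mm Isotropic spacing for preprocessing.
#' @return Tibble with `subject_id` then one column per feature; the feature
#'   metadata tibble is attached as attribute `"feature_spec"`.
#' @export
extract_cohort_features <- function(cohort, mode = c("3D", "2D"),
                                    config = feature_config(),
                                    preprocess = TRUE, target_mm = 1) {
  mode <- match.arg(mode)
  stopifnot(!is.null(cohort$volumes))
  rows <- purrr::map(cohort$manifest$subject_id, function(id) {
    vol <- cohort$volumes[[id]]
    msk <- cohort$cyst_masks[[id]]
    if (isTRUE(preprocess)) {
      pp <- preprocess_volume(vol, msk, mode = mode, target_mm = target_mm, id = id)
      vol <- pp$volume; msk <- pp$mask
    }
    extract_features(vol, msk, mode = mode, config = config)
  })
  spec <- rows[[1]]$spec
  mat <- do.call(rbind, purrr::map(rows, "features"))
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(tibble::tibble(subject_id = cohort$manifest$subject_id), out)
  attr(out, "feature_spec") <- spec
  out
}
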