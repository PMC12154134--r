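#' Configuration for the synthetic multi-center cohort generator
#'
#' The generator emulates a seven-center T2-weighted MRI cohort of pancreatic
#' cysts: each subject gets a hyperintense ellipsoidal cyst embedded in a
#' duller organ region on a dark background. High-risk cysts carry internal
#' heterogeneity (hypointense mural blobs plus one or two septation planes)
#' whose amplitude scales with `effect_size`; low-risk cysts are homogeneous
#' fluid. Center effects act only on acquisition — slice thickness, smooth
#' multiplicative bias field, additive noise, global intensity scale — never
#' on the class-conditional texture, so center confounds image quality but
#' not the label.
#'
#' Default center identities and slice thicknesses mirror the seven-center
#' study design the package models (slice thickness within the 3–8 mm
#' acquisition range); default cohort size is 359 subjects with 142 high-risk.
#'
#' @param n_subjects Number of subjects.
#' @param n_centers Number of centers used (first `n_centers` profiles).
#' @param class_balance Fraction of high-risk subjects, in (0, 1).
#' @param effect_size Dimensionless separation of class texture parameters;
#'   0 makes the two classes distributionally identical.
#' @param center_profiles Named list of per-center profiles, each a list with
#'   `slice_thickness` (mm, in \[3, 8\] by default), `bias_amplitude`,
#'   `noise_sd`, `intensity_scale`, and `weight` (sampling proportion).
#' @param volume_shape Integer length-3 voxel grid, at least 16 per axis.
#' @param exact_counts If `TRUE` (default) the high-risk count is exactly
#'   `round(class_balance * n_subjects)`; otherwise labels are i.i.d.
#'   Bernoulli draws.
#' @param seed Integer seed; every generator call is bit-reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 359L,
                         n_centers = 7L,
                         class_balance = 142 / 359,
                         effect_size = 1,
                         center_profiles = default_center_profiles(),
                         volume_shape = c(24L, 24L, 16L),
                         exact_counts = TRUE,
                         seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_centers <- as.integer(n_centers)
  if (n_centers < 1L || n_subjects < n_centers) {
    stop("need n_subjects >= n_centers >= 1", call. = FALSE)
  }
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (n_centers > length(center_profiles)) {
    stop("not enough center profiles for n_centers", call. = FALSE)
  }
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 16L)) {
    stop("volume_shape must be three integers >= 16", call. = FALSE)
  }
  for (p in center_profiles) {
    if (p$slice_thickness < 3 || p$slice_thickness > 8) {
      warning("slice_thickness outside the default 3-8 mm acquisition range")
    }
  }
  structure(
    list(
      n_subjects = n_subjects, n_centers = n_centers,
      class_balance = class_balance, effect_size = effect_size,
      center_profiles = center_profiles[seq_len(n_centers)],
      volume_shape = volume_shape, exact_counts = isTRUE(exact_counts),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Default per-center acquisition profiles
#'
#' Seven profiles named after the centers of the multi-center cohort design
#' the generator emulates. Slice thicknesses follow the reported per-center
#' mean voxel heights (MCF 4 mm, NMH 5.5 mm, NYU 5 mm, EMC 7.3 mm clipped to
#' the 3–8 mm range, AHN/IU/MCA 7 mm); bias amplitude, noise and intensity
#' scale differ per center so image quality clusters by site. Sampling
#' weights follow the reported per-center subject counts (AHN & MCA 29
#' combined, EMC 36, IU 35, NYU 71; the remaining 188 split across MCF and
#' NMH).
#'
#' @return Named list of center profiles.
#' @export
default_center_profiles <- function() {
  list(
    AHN = list(slice_thickness = 7.0, bias_amplitude = 0.25, noise_sd = 0.040,
               intensity_scale = 0.85, weight = 14),
    EMC = list(slice_thickness = 7.3, bias_amplitude = 0.30, noise_sd = 0.050,
               intensity_scale = 1.25, weight = 36),
    IU  = list(slice_thickness = 7.0, bias_amplitude = 0.20, noise_sd = 0.045,
               intensity_scale = 0.70, weight = 35),
    MCA = list(slice_thickness = 7.0, bias_amplitude = 0.15, noise_sd = 0.035,
               intensity_scale = 1.10, weight = 15),
    MCF = list(slice_thickness = 4.0, bias_amplitude = 0.10, noise_sd = 0.025,
               intensity_scale = 1.00, weight = 94),
    NMH = list(slice_thickness = 5.5, bias_amplitude = 0.15, noise_sd = 0.030,
               intensity_scale = 0.95, weight = 94),
    NYU = list(slice_thickness = 5.0, bias_amplitude = 0.20, noise_sd = 0.030,
               intensity_scale = 1.15, weight = 71)
  )
}

#' Generate one synthetic cyst volume with its masks
#'
#' Produces a T2W-like volume: dark background, duller organ ellipsoid,
#' hyperintense fluid-filled cyst. For `class_label = 1` the cyst receives
#' hypointense mural blobs and septation planes with amplitude proportional
#' to `effect_size`, raising within-cyst intensity variance; for
#' `class_label = 0` (or `effect_size = 0`) the identical random draws are
#' consumed with zero amplitude, so the two classes share one generator. The
#' volume is then modulated by a smooth multiplicative bias field (order-3
#' log-polynomial, amplitude `bias_amplitude`), additive Gaussian noise of sd
#' `noise_sd`, and a global `intensity_scale`; spacing is 1x1 mm in plane
#' with the profile's slice thickness.
#'
#' @param class_label 0 (low risk) or 1 (high risk).
#' @param center_profile One element of [default_center_profiles()].
#' @param effect_size Heterogeneity amplitude multiplier.
#' @param shape Integer length-3 grid size, at least 16 per axis.
#' @param seed Integer seed.
#' @return List with `volume` ([volume_grid()]), `cyst_mask` and `organ_mask`
#'   ([mask_volume()]).
#' @export
generate_cyst_volume <- function(class_label, center_profile, effect_size = 1,
                                 shape = c(32L, 32L, 16L), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    stop("shape too small to contain a cyst of minimum radius (need >= 16 voxels per axis)",
         call. = FALSE)
  }
  if (!class_label %in% c(0, 1)) stop("class_label must be 0 or 1", call. = FALSE)
  spacing <- c(1, 1, center_profile$slice_thickness)

  with_seed_local(seed, {
    # normalized coordinates in [-1, 1]
    cx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2)
    cy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2)
    cz <- (seq_len(shape[3]) - (shape[3] + 1) / 2) / (shape[3] / 2)
    xs <- array(rep(cx, times = shape[2] * shape[3]), shape)
    ys <- array(rep(rep(cy, each = shape[1]), times = shape[3]), shape)
    zs <- array(rep(cz, each = shape[1] * shape[2]), shape)

    organ_ax <- c(0.80, 0.78, 0.82)
    organ <- (xs / organ_ax[1])^2 + (ys / organ_ax[2])^2 + (zs / organ_ax[3])^2 <= 1

    cyst_center <- stats::runif(3, -0.12, 0.12)
    cyst_ax <- c(0.34, 0.32, 0.30) * stats::runif(3, 0.85, 1.15)
    dx <- (xs - cyst_center[1]) / cyst_ax[1]
    dy <- (ys - cyst_center[2]) / cyst_ax[2]
    dz <- (zs - cyst_center[3]) / cyst_ax[3]
    cyst <- dx^2 + dy^2 + dz^2 <= 1

    vol <- array(0.05, shape)
    vol[organ] <- 0.35
    vol[cyst] <- 0.90

    # internal heterogeneity; draws are consumed for both classes so that
    # effect_size = 0 and class 0 share the exact generator
    amp <- 0.25 * effect_size * as.numeric(class_label)
    n_blobs <- 3L
    het <- array(0, shape)
    for (b in seq_len(n_blobs)) {
      bc <- stats::runif(3, -0.5, 0.5)        # in cyst-normalized coords
      bs <- stats::runif(1, 0.18, 0.30)
      d2 <- (dx - bc[1])^2 + (dy - bc[2])^2 + (dz - bc[3])^2
      het <- het + exp(-d2 / (2 * bs^2))
    }
    n_sept <- sample(1:2, 1)
    for (s in seq_len(n_sept)) {
      nrm <- stats::rnorm(3)
      nrm <- nrm / sqrt(sum(nrm^2))
      off <- stats::runif(1, -0.3, 0.3)
      pd <- dx * nrm[1] + dy * nrm[2] + dz * nrm[3] - off
      het <- het + 0.8 * exp(-(pd / 0.10)^2)
    }
    vol[cyst] <- vol[cyst] - amp * pmin(het[cyst], 1.6)

    # multiplicative bias field: order-3 polynomial in log domain
    design <- poly3d_design(xs, ys, zs, deg = 3L)
    coef <- stats::rnorm(ncol(design))
    pfield <- array(design %*% coef, shape)
    psd <- stats::sd(pfield)
    if (psd > 0) pfield <- pfield / psd
    bias <- exp(center_profile$bias_amplitude * pfield)
    vol <- vol * bias + stats::rnorm(length(vol), sd = center_profile$noise_sd)
    vol <- vol * center_profile$intensity_scale

    list(
      volume = volume_grid(vol, spacing),
      cyst_mask = mask_volume(array(as.integer(cyst), shape), spacing),
      organ_mask = mask_volume(array(as.integer(organ | cyst), shape), spacing)
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Assigns subjects to centers with the profile weights, draws class labels
#' (exact counts by default so downstream tests are non-flaky), draws cyst
#' type (BD / MD / mixed) conditionally on the label with the risk-share
#' structure of the modeled cohort (78.2% of BD and 38.5% of MD/mixed cysts
#' low-risk), and synthesizes one volume plus cyst and organ masks per
#' subject.
#'
#' @param config A [synth_config()].
#' @param volumes If `FALSE`, only the manifest is generated (fast path for
#'   bookkeeping work).
#' @return List of class `synth_cohort` with `manifest` (tibble: subject_id,
#'   center_id, cyst_type, label), `volumes`, `cyst_masks`, `organ_masks`
#'   (named lists) and `config`.
#' @export
generate_cohort <- function(config = synth_config(), volumes = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_subjects
  n_high <- round(config$class_balance * n)
  if (n_high < 1 || n_high > n - 1) {
    stop("class_balance would yield a single-class cohort at this n", call. = FALSE)
  }

  manifest <- with_seed_local(config$seed, {
    centers <- names(config$center_profiles)
    w <- vapply(config$center_profiles, function(p) p$weight %||% 1, numeric(1))
    center_id <- sample(centers, n, replace = TRUE, prob = w / sum(w))
    # guarantee every center appears
    short <- setdiff(centers, unique(center_id))
    if (length(short)) center_id[sample.int(n, length(short))] <- short

    if (config$exact_counts) {
      label <- integer(n)
      label[sample.int(n, n_high)] <- 1L
    } else {
      label <- stats::rbinom(n, 1L, config$class_balance)
      if (length(unique(label)) < 2L) {
        stop("class_balance would yield a single-class cohort at this n", call. = FALSE)
      }
    }
    p_bd_given_low <- 155 / 217
    p_bd_given_high <- 43 / 142
    cyst_type <- vapply(label, function(l) {
      bd <- stats::runif(1) < (if (l == 1L) p_bd_given_high else p_bd_given_low)
      if (bd) "BD" else sample(c("MD", "mixed"), 1)
    }, character(1))
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      center_id = center_id,
      cyst_type = cyst_type,
      label = as.integer(label)
    )
  })

  vols <- cysts <- organs <- NULL
  if (isTRUE(volumes)) {
    per_subject <- purrr::map(seq_len(n), function(i) {
      generate_cyst_volume(
        class_label = manifest$label[i],
        center_profile = config$center_profiles[[manifest$center_id[i]]],
        effect_size = config$effect_size,
        shape = config$volume_shape,
        seed = config$seed * 10000L + i
      )
    })
    names(per_subject) <- manifest$subject_id
    vols <- purrr::map(per_subject, "volume")
    cysts <- purrr::map(per_subject, "cyst_mask")
    organs <- purrr::map(per_subject, "organ_mask")
  }

  structure(
    list(manifest = manifest, volumes = vols, cyst_masks = cysts,
         organ_masks = organs, config = config),
    class = "synth_cohort"
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "<synth_cohort> %d subjects, %d centers, %d high-risk, effect_size %.2f%s\n",
    nrow(x$manifest), length(unique(x$manifest$center_id)),
    sum(x$manifest$label), x$config$effect_size,
    if (is.null(x$volumes)) " (manifest only)" else ""
  ))
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes + CSV manifest + JSON config)
#'
#' @param cohort A [generate_cohort()] result with volumes.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"), !is.null(cohort$volumes))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(
    list(n_subjects = cfg$n_subjects, n_centers = cfg$n_centers,
         class_balance = cfg$class_balance, effect_size = cfg$effect_size,
         volume_shape = cfg$volume_shape, exact_counts = cfg$exact_counts,
         seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE
  )
  for (id in cohort$manifest$subject_id) {
    write_volume_nifti(cohort$volumes[[id]], file.path(dir, paste0(id, "_T2W.nii.gz")))
    write_volume_nifti(
      volume_grid(array(as.numeric(cohort$cyst_masks[[id]]$data), dim(cohort$cyst_masks[[id]]$data)),
                  cohort$cyst_masks[[id]]$spacing),
      file.path(dir, paste0(id, "_cyst.nii.gz"))
    )
  }
  invisible(dir)
}

#' Perturb a binary mask at its boundary
#'
#' Flips voxels inside the boundary band (mask dilated minus eroded by one
#' voxel) according to seeded spatially smooth noise: a band voxel keeps its
#' value when `0.5 * (2 * value - 1) + magnitude * noise > 0`. Magnitude 0
#' returns the mask unchanged; larger magnitudes give monotonically
#' non-increasing expected Dice against the original. Used to emulate
#' independent re-segmentations when testing agreement statistics.
#'
#' @param mask A non-empty [mask_volume()].
#' @param magnitude Non-negative perturbation strength.
#' @param seed Integer seed.
#' @return A [mask_volume()] on the same grid.
#' @export
perturb_mask <- function(mask, magnitude, seed = 1L) {
  stopifnot(is_mask_volume(mask))
  m <- mask$data
  if (sum(m) == 0L) stop("mask is empty", call. = FALSE)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  if (magnitude == 0) return(mask)

  box <- function(a) sep_conv3(a, rep(1, 3), rep(1, 3), rep(1, 3))
  dil <- box(array(as.numeric(m), dim(m))) > 0.5
  ero <- box(array(as.numeric(m), dim(m))) > 26.5
  band <- dil & !ero

  out <- with_seed_local(seed, {
    noise <- smooth_gaussian3(array(stats::rnorm(length(m)), dim(m)), sigma = c(1.2, 1.2, 0.8))
    noise <- noise / stats::sd(noise)
    score <- 0.5 * (2 * as.numeric(m) - 1) + magnitude * as.numeric(noise)
    res <- m
    res[band] <- as.integer(score[band] > 0)
    res
  })
  if (sum(out) == 0L) stop("perturbation emptied the mask", call. = FALSE)
  mask_volume(out, mask$spacing)
}

#' Simulate ordinal rater scores against binary truth
#'
#' Each rater emits one of three ordered levels (`no`, `low`, `high`). A true
#' high-risk subject is scored `high` with the rater's sensitivity; a true
#' low-risk subject is scored `high` with probability `1 - specificity`.
#' Non-high scores split between `low` and `no` (60/40 for true highs, 50/50
#' for true lows), so binarizing at `high` reproduces the configured
#' sensitivity and specificity in expectation.
#'
#' @param labels Binary truth vector (0/1).
#' @param n_raters Number of raters (>= 1).
#' @param per_rater_sens,per_rater_spec Sensitivity/specificity per rater in
#'   \[0, 1\], recycled to `n_raters`.
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `label`, and ordered-factor columns
#'   `rater_1` ... `rater_k`.
#' @export
simulate_ratings <- function(labels, n_raters = 3L,
                             per_rater_sens = 0.7, per_rater_spec = 0.6,
                             seed = 1L) {
  n_raters <- as.integer(n_raters)
  if (n_raters < 1L) stop("n_raters must be >= 1", call. = FALSE)
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  sens <- rep_len(per_rater_sens, n_raters)
  spec <- rep_len(per_rater_spec, n_raters)
  if (any(sens < 0 | sens > 1 | spec < 0 | spec > 1)) {
    stop("per-rater sensitivity/specificity must lie in [0, 1]", call. = FALSE)
  }
  lv <- c("no", "low", "high")
  with_seed_local(seed, {
    out <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_along(labels)),
      label = labels
    )
    # subject-level severity drives the low/no split so that error-free
    # raters emit identical three-level scores
    u_severity <- stats::runif(length(labels))
    p_low_given_nothigh <- ifelse(labels == 1L, 0.6, 0.5)
    sub_low <- u_severity < p_low_given_nothigh
    for (r in seq_len(n_raters)) {
      p_high <- ifelse(labels == 1L, sens[r], 1 - spec[r])
      call_high <- stats::runif(length(labels)) < p_high
      sc <- ifelse(call_high, "high", ifelse(sub_low, "low", "no"))
      out[[paste0("rater_", r)]] <- factor(sc, levels = lv, ordered = TRUE)
    }
    out
  })
}
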