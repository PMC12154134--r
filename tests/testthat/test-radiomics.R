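make_test_roi <- function(d = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  v <- volume_grid(array(runif(prod(d)), d))
  m <- array(0L, d)
  m[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- 1L
  list(vol = v, mask = mask_volume(m))
}

test_that("ROI quantization bins by equal width and ignores scale", {
  d <- c(4, 4, 4)
  v <- volume_grid(array(seq(0, 1, length.out = 64), d))
  m <- mask_volume(array(1L, d))
  q <- quantize_roi(v, m, 4)
  expect_equal(sort(unique(as.integer(q))), 1:4)
  expect_equal(as.integer(table(q)), rep(16L, 4))

  # positive affine rescale leaves labels unchanged
  v2 <- volume_grid(3.5 * v$data + 11)
  expect_identical(quantize_roi(v2, m, 4), q)

  expect_true(all(quantize_roi(volume_grid(array(2, d)), m, 8) == 1L))
  out <- quantize_roi(v, mask_volume(array(c(1L, rep(0L, 63)), d)), 4)
  expect_equal(sum(out != 0), 1)
  expect_error(quantize_roi(v, mask_volume(array(0L, d)), 4), "empty mask")
})

test_that("single-patch GLCM matches hand enumeration", {
  strip <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  P <- glcm_window(strip, 2, offsets = rbind(c(1, 0, 0)))
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(sum(P), 1)

  const <- array(1L, c(3, 3, 1))
  Pc <- glcm_window(const, 2, offsets = glcm_offsets("2D"))
  expect_equal(sum(Pc != 0), 1)
  expect_equal(Pc[1, 1], 1)

  set.seed(3)
  rnd <- array(sample(1:4, 27, replace = TRUE), c(3, 3, 3))
  Pr <- glcm_window(rnd, 4, offsets = glcm_offsets("3D"))
  expect_true(all(Pr >= 0))
  expect_equal(sum(Pr), 1)
  expect_equal(Pr, t(Pr))
})

test_that("haralick statistics match closed forms", {
  # constant patch: a single-entry matrix
  P1 <- matrix(0, 3, 3); P1[2, 2] <- 1
  h <- haralick_stats(P1)
  expect_equal(unname(h["energy"]), 1)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["entropy"]), 0)

  # two-level checkerboard pairs
  P2 <- matrix(0, 2, 2); P2[1, 2] <- 0.5; P2[2, 1] <- 0.5
  h2 <- haralick_stats(P2)
  expect_equal(unname(h2["contrast"]), 1)
  expect_equal(unname(h2["energy"]), 0.5)

  # uniform matrix: entropy = 2 log2 L
  for (L in c(2, 4, 8)) {
    Pu <- matrix(1 / L^2, L, L)
    expect_equal(unname(haralick_stats(Pu)["entropy"]), 2 * log2(L))
  }

  # full 13-vector vs the independent textbook implementation
  set.seed(8)
  for (i in 1:5) {
    M <- matrix(runif(16), 4, 4)
    M <- (M + t(M)); M <- M / sum(M)
    expect_equal(unname(haralick_stats(M)), naive_haralick13(M), tolerance = 1e-12)
  }
})

test_that("sliding haralick maps equal naive per-voxel recomputation", {
  roi <- make_test_roi(c(8, 8, 8), seed = 21)
  for (mode in c("3D", "2D")) {
    offs <- glcm_offsets(mode)
    for (w in c(3, 5)) for (L in c(4, 8)) {
      maps <- compute_haralick_maps(roi$vol, roi$mask, windows = w,
                                    levels_list = L, mode = mode)
      lab <- naive_quantize(roi$vol$data, roi$mask$data, L)
      idx <- which(roi$mask$data > 0, arr.ind = TRUE)
      radii <- if (mode == "2D") c((w - 1) / 2, (w - 1) / 2, 0) else rep((w - 1) / 2, 3)
      got <- sapply(seq_along(cystratify:::haralick_stat_names), function(s) {
        maps$values[[sprintf("haralick_w%d_g%d_%s", w, L,
                             cystratify:::haralick_stat_names[s])]]
      })
      want <- t(apply(idx, 1, function(cc) {
        P <- naive_window_glcm(lab, cc, radii, offs, L)
        naive_haralick13(P)
      }))
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
})

test_that("constant volumes give degenerate haralick maps", {
  d <- c(6, 6, 6)
  v <- volume_grid(array(1, d))
  m <- mask_volume(array(1L, d))
  maps <- compute_haralick_maps(v, m, windows = 3, levels_list = 4, mode = "3D")
  expect_true(all(maps$values$haralick_w3_g4_contrast == 0))
  expect_true(all(maps$values$haralick_w3_g4_energy == 1))
  expect_error(compute_haralick_maps(v, m, windows = 9, levels_list = 4),
               "window larger")
})

test_that("gray filter maps equal the naive sliding-window oracle", {
  set.seed(5)
  arr <- array(rnorm(8^3), c(8, 8, 8))
  got <- compute_gray_maps(volume_grid(arr), window = 3, mode = "3D")
  want <- naive_window_stats(arr, c(1, 1, 1))
  expect_lt(max(abs(got$gray_mean - want[, , , 1])), 1e-9)
  expect_lt(max(abs(got$gray_median - want[, , , 2])), 1e-9)
  expect_lt(max(abs(got$gray_std - want[, , , 3])), 1e-9)
  expect_lt(max(abs(got$gray_range - want[, , , 4])), 1e-9)

  cg <- compute_gray_maps(volume_grid(array(2, c(5, 5, 5))), 3, "3D")
  expect_true(all(cg$gray_mean == 2) && all(cg$gray_median == 2))
  expect_true(all(cg$gray_std == 0) && all(cg$gray_range == 0))

  # single bright voxel: range 1 in its 3^3 neighbourhood, 0 elsewhere
  z <- array(0, c(7, 7, 7)); z[4, 4, 4] <- 1
  rg <- compute_gray_maps(volume_grid(z), 3, "3D")$gray_range
  nb <- array(FALSE, c(7, 7, 7)); nb[3:5, 3:5, 3:5] <- TRUE
  expect_true(all(rg[nb] == 1) && all(rg[!nb] == 0))
})

test_that("laws maps: zero-sum kernels kill constants; separable equals direct", {
  cm <- compute_laws_maps(volume_grid(array(4, c(6, 6, 6))), "3D")
  expect_length(cm, 125)
  nonlevel <- grep("laws_L5L5L5", names(cm), invert = TRUE, value = TRUE)
  expect_true(all(vapply(nonlevel, function(nm) all(abs(cm[[nm]]) < 1e-9), logical(1))))
  expect_length(compute_laws_maps(volume_grid(array(1, c(6, 6, 2))), "2D"), 25)

  set.seed(13)
  arr <- array(rnorm(16 * 16), c(16, 16, 1))
  got2d <- compute_laws_maps(volume_grid(arr), "2D")
  k <- list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1), S5 = c(-1, 0, 2, 0, -1),
            W5 = c(-1, 2, 0, -2, 1), R5 = c(1, -4, 6, -4, 1))
  for (combo in list(c("E5", "L5"), c("S5", "R5"), c("W5", "W5"))) {
    k3 <- array(outer(k[[combo[1]]], k[[combo[2]]]), c(5, 5, 1))
    want <- abs(naive_conv3(arr, k3))
    expect_lt(max(abs(got2d[[paste0("laws_", combo[1], combo[2])]] - want)), 1e-9)
  }

  # one 3D combo against the assembled 5^3 kernel on a small array
  set.seed(14)
  arr3 <- array(rnorm(8^3), c(8, 8, 8))
  got3d <- compute_laws_maps(volume_grid(arr3), "3D")
  k3 <- array(0, c(5, 5, 5))
  for (a in 1:5) for (b in 1:5) for (cc in 1:5) {
    k3[a, b, cc] <- k$E5[a] * k$L5[b] * k$S5[cc]
  }
  expect_lt(max(abs(got3d$laws_E5L5S5 - abs(naive_conv3(arr3, k3)))), 1e-9)
})

test_that("gradient maps follow closed forms", {
  g0 <- compute_gradient_maps(volume_grid(array(5, c(6, 6, 6))), "3D")
  expect_length(g0, 5)
  expect_true(all(vapply(g0, function(a) all(abs(a) < 1e-12), logical(1))))

  d <- c(8, 6, 4)
  ramp <- array(rep(2.5 * (1:d[1]), times = d[2] * d[3]), d)
  g <- compute_gradient_maps(volume_grid(ramp), "3D")
  expect_equal(max(abs(g$gradient_magnitude[2:7, , ] - 2.5)), 0)
  expect_true(all(g$sobel_magnitude >= 0) && all(g$gradient_magnitude >= 0))
  expect_length(compute_gradient_maps(volume_grid(ramp), "2D"), 4)
})

test_that("collage entropy separates ordered from disordered texture", {
  d <- c(14, 14, 10)
  m <- array(0L, d); m[4:11, 4:11, 3:8] <- 1L
  mask <- mask_volume(m)
  ramp <- array(rep(seq(0, 1, length.out = d[1]), times = d[2] * d[3]), d)
  ent_ramp <- compute_collage_maps(volume_grid(ramp), mask, 3, 16, "3D")
  set.seed(77)
  noise <- array(runif(prod(d)), d)
  ent_noise <- compute_collage_maps(volume_grid(noise), mask, 3, 16, "3D")
  # single global gradient direction: near-zero orientation entropy
  expect_lt(mean(ent_ramp$values$collage_w3_theta_entropy), 0.2)
  expect_gt(mean(ent_noise$values$collage_w3_theta_entropy),
            mean(ent_ramp$values$collage_w3_theta_entropy) + 0.5)
})

test_that("collage ROI entropy is invariant to in-plane 90-degree rotation", {
  d <- c(12, 12, 8)
  set.seed(31)
  arr <- smooth_noise <- array(rnorm(prod(d)), d)
  for (ax in 1:2) {
    k <- exp(-(seq(-2, 2))^2 / 2); k <- k / sum(k)
    smooth_noise <- cystratify:::conv_axis(smooth_noise, k, ax)
  }
  m <- array(0L, d); m[4:9, 4:9, 3:6] <- 1L
  rot <- function(a) aperm(a, c(2, 1, 3))[, rev(seq_len(d[1])), , drop = FALSE]
  m_r <- rot(m); arr_r <- rot(smooth_noise)
  e1 <- compute_collage_maps(volume_grid(smooth_noise), mask_volume(m), 3, 16, "3D")
  e2 <- compute_collage_maps(volume_grid(arr_r), mask_volume(m_r), 3, 16, "3D")
  # tolerance covers occasional orientation-bin flips at quantization
  # boundaries under the exact 90-degree relabelling
  expect_equal(mean(e1$values$collage_w3_theta_entropy),
               mean(e2$values$collage_w3_theta_entropy), tolerance = 0.02)
})

test_that("ROI aggregation computes the four statistics", {
  d <- c(4, 4, 4)
  mk <- mask_volume(array(1L, d))
  expect_equal(aggregate_map(array(3, d), mk),
               c(median = 3, std = 0, skewness = 0, kurtosis = 0))
  vals <- c(1, 2, 3, 4, 5)
  ag <- aggregate_map(vals)
  expect_equal(unname(ag["median"]), 3)
  expect_equal(unname(ag["skewness"]), 0)

  set.seed(9)
  x <- rnorm(200)
  ag2 <- aggregate_map(x)
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(ag2["std"]), sd(x))
  expect_equal(unname(ag2["skewness"]), mean((x - mean(x))^3) / m2^1.5)
  expect_equal(unname(ag2["kurtosis"]), mean((x - mean(x))^4) / m2^2 - 3)
  expect_error(aggregate_map(array(1, d), mask_volume(array(0L, d))), "empty mask")
})

test_that("feature extraction is deterministic, complete, and quantization-invariant", {
  roi <- make_test_roi(c(10, 10, 10), seed = 41)
  cfg <- feature_config(windows = c(3, 5), gray_levels = c(4, 8),
                        collage_windows = 3, collage_bins = 16)
  f1 <- extract_features(roi$vol, roi$mask, "3D", cfg)
  f2 <- extract_features(roi$vol, roi$mask, "3D", cfg)
  expect_identical(f1$features, f2$features)
  expect_true(all(is.finite(f1$features)))

  # self-consistent enumeration: 4 stats per map
  n_maps <- 1 + 4 + 5 + 125 + 13 * 2 * 2 + 2
  expect_length(f1$features, 4 * n_maps)
  expect_equal(nrow(f1$spec), length(f1$features))
  expect_equal(unique(f1$spec$dim), "3D")
  expect_setequal(unique(f1$spec$family),
                  c("Raw", "Gray", "Gradient", "Laws", "Haralick", "CoLlAGe"))

  # positive affine rescaling leaves quantization-based families unchanged
  v2 <- volume_grid(2.4 * roi$vol$data + 0.7, roi$vol$spacing)
  f3 <- extract_features(v2, roi$mask, "3D", cfg)
  qb <- f1$spec$feature[f1$spec$family %in% c("Haralick", "CoLlAGe")]
  expect_equal(f3$features[qb], f1$features[qb], tolerance = 1e-9)

  f2d <- extract_features(roi$vol, roi$mask, "2D", cfg)
  n_maps_2d <- 1 + 4 + 4 + 25 + 13 * 2 * 2 + 1
  expect_length(f2d$features, 4 * n_maps_2d)
})

test_that("feature tables round-trip through CSV with their metadata sidecar", {
  co <- tiny_cohort(n = 4, seed = 61)
  cfg <- feature_config(windows = 3, gray_levels = 4,
                        collage_windows = 3, collage_bins = 8)
  feats <- extract_cohort_features(co, mode = "2D", config = cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, f)
  back <- read_feature_table(f)
  expect_equal(back$subject_id, feats$subject_id)
  expect_equal(as.matrix(back[, -1]), as.matrix(feats[, -1]), tolerance = 1e-12)
  expect_equal(attr(back, "feature_spec")$feature,
               attr(feats, "feature_spec")$feature)
})
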