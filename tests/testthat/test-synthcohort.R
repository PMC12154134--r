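test_that("cyst volume generation is seeded, geometric, and class-controlled", {
  prof <- default_center_profiles()$MCF
  a <- generate_cyst_volume(1, prof, effect_size = 1, shape = c(24, 24, 16), seed = 5)
  b <- generate_cyst_volume(1, prof, effect_size = 1, shape = c(24, 24, 16), seed = 5)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$cyst_mask$data, b$cyst_mask$data)

  # geometry: non-empty connected cyst strictly inside the organ
  expect_gt(sum(a$cyst_mask$data), 0)
  expect_true(all(a$organ_mask$data[a$cyst_mask$data > 0] == 1))
  expect_gt(sum(a$organ_mask$data), sum(a$cyst_mask$data))
  expect_true(is_connected(a$cyst_mask$data))

  # spacing carries the center's slice thickness
  expect_equal(a$volume$spacing, c(1, 1, prof$slice_thickness))

  # effect_size 0 makes the classes distributionally identical (same draws)
  p0 <- list(slice_thickness = 4, bias_amplitude = 0.1, noise_sd = 0.02,
             intensity_scale = 1)
  lo <- generate_cyst_volume(0, p0, effect_size = 0, shape = c(24, 24, 16), seed = 9)
  hi <- generate_cyst_volume(1, p0, effect_size = 0, shape = c(24, 24, 16), seed = 9)
  expect_identical(lo$volume$data, hi$volume$data)

  # clean low-risk cyst is homogeneous fluid by construction
  pc <- list(slice_thickness = 4, bias_amplitude = 0, noise_sd = 0, intensity_scale = 1)
  clean <- generate_cyst_volume(0, pc, effect_size = 1, shape = c(24, 24, 16), seed = 2)
  expect_lt(var(clean$volume$data[clean$cyst_mask$data > 0]), 1e-12)

  expect_error(generate_cyst_volume(1, prof, shape = c(8, 24, 16), seed = 1),
               "too small")
})

test_that("within-cyst variance separation grows with effect size", {
  prof <- list(slice_thickness = 4, bias_amplitude = 0.05, noise_sd = 0.02,
               intensity_scale = 1)
  sep <- vapply(c(0, 0.5, 1, 2), function(es) {
    diffs <- vapply(1:6, function(s) {
      hi <- generate_cyst_volume(1, prof, es, c(24, 24, 16), seed = 100 + s)
      lo <- generate_cyst_volume(0, prof, es, c(24, 24, 16), seed = 100 + s)
      var(hi$volume$data[hi$cyst_mask$data > 0]) -
        var(lo$volume$data[lo$cyst_mask$data > 0])
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  expect_equal(sep[1], 0)
  expect_true(all(diff(sep) > 0))
})

test_that("cohort generation respects counts, centers, and the seed", {
  cfg <- synth_config(n_subjects = 359, seed = 4)
  co <- generate_cohort(cfg, volumes = FALSE)
  expect_equal(nrow(co$manifest), 359)
  expect_equal(sum(co$manifest$label), 142)           # exact-count mode
  expect_equal(sort(unique(co$manifest$center_id)),
               c("AHN", "EMC", "IU", "MCA", "MCF", "NMH", "NYU"))
  expect_true(all(co$manifest$cyst_type %in% c("BD", "MD", "mixed")))

  co2 <- generate_cohort(cfg, volumes = FALSE)
  expect_identical(co$manifest, co2$manifest)

  expect_error(generate_cohort(synth_config(n_subjects = 10, n_centers = 2,
                                            class_balance = 0.01)),
               "single-class")
  expect_error(synth_config(n_subjects = 3, n_centers = 7), "n_subjects")
  expect_error(synth_config(class_balance = 1.2), "class_balance")
})

test_that("cohorts round-trip through NIfTI with spacing intact", {
  co <- tiny_cohort(n = 2, seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(man$subject_id, co$manifest$subject_id)
  id <- co$manifest$subject_id[1]
  v <- read_volume_nifti(file.path(dir, paste0(id, "_T2W.nii.gz")))
  expect_equal(v$data, co$volumes[[id]]$data, tolerance = 1e-6)
  expect_equal(v$spacing, co$volumes[[id]]$spacing, tolerance = 1e-6)
  m <- read_mask_nifti(file.path(dir, paste0(id, "_cyst.nii.gz")))
  expect_identical(m$data, co$cyst_masks[[id]]$data)
})

test_that("mask perturbation is seeded, bounded, and magnitude-monotone", {
  co <- tiny_cohort(n = 2, seed = 5)
  m <- co$cyst_masks[[1]]
  expect_identical(perturb_mask(m, 0, seed = 1)$data, m$data)

  p1 <- perturb_mask(m, 0.4, seed = 1)
  expect_identical(p1$data, perturb_mask(m, 0.4, seed = 1)$data)
  expect_true(all(p1$data %in% c(0L, 1L)))
  expect_identical(dim(p1$data), dim(m$data))

  dice_at <- function(mag) {
    mean(vapply(1:20, function(s) {
      dice_coefficient(m, perturb_mask(m, mag, seed = s))
    }, numeric(1)))
  }
  d_small <- dice_at(0.2)
  d_big <- dice_at(0.8)
  expect_lt(d_big, d_small)
  expect_lt(d_small, 1)
})

test_that("simulated raters reproduce the configured operating points", {
  labels <- rep(c(0L, 1L), each = 4)
  perfect <- simulate_ratings(labels, 3, per_rater_sens = 1, per_rater_spec = 1, seed = 1)
  for (rc in c("rater_1", "rater_2", "rater_3")) {
    expect_equal(as.integer(perfect[[rc]] == "high"), labels)
  }
  expect_equal(weighted_kappa(perfect$rater_1, perfect$rater_2), 1)

  # chance-level raters: binarized accuracy near 0.5 at n = 1000
  lab2 <- rep(c(0L, 1L), 500)
  chance <- simulate_ratings(lab2, 1, per_rater_sens = 0.5, per_rater_spec = 0.5, seed = 2)
  acc <- mean((chance$rater_1 == "high") == (lab2 == 1L))
  expect_lt(abs(acc - 0.5), 0.05)

  expect_identical(simulate_ratings(labels, 2, seed = 9),
                   simulate_ratings(labels, 2, seed = 9))
  expect_error(simulate_ratings(labels, 0), "n_raters")
  expect_error(simulate_ratings(labels, 2, per_rater_sens = 1.4), "\\[0, 1\\]")
})
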