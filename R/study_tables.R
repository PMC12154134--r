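# Reference tables of the published seven-center IPMN T2W MRI benchmark the
# synthetic generator emulates: cohort selection flow, subtype-by-risk
# breakdown, the leave-center-out trial sizes, and the per-trial
# classification metrics of the radiomics-only and fusion analyses. These
# printed summaries are inputs to the package's bookkeeping and aggregation
# helpers (they contain no subject-level data).

#' Cohort selection flow of the reference IPMN benchmark
#'
#' Scans collected across seven centers, radiologic exclusions (no
#' pancreatic cyst, other histopathology, or no radiologic result), and
#' histopathologic exclusions (no intervention or findings negative for
#' IPMN); the remainder forms the analysis cohort.
#'
#' @return Tibble with `stage` and `count`.
#' @export
ipmn_cohort_flow <- function() {
  tibble::tibble(
    stage = c("collected", "excluded_radiologic", "excluded_histopathologic"),
    count = c(746L, 216L, 171L)
  )
}

#' Subtype-by-risk breakdown of the reference cohort
#'
#' Counts of branch-duct versus main-duct/mixed IPMN in the low- and
#' high-risk groups (risk defined by dysplasia grade: low-grade dysplasia
#' versus high-grade dysplasia or invasive carcinoma).
#'
#' @return Tibble with `risk`, `bd`, `md_mixed`.
#' @export
ipmn_subtype_table <- function() {
  tibble::tibble(
    risk = c("low", "high"),
    bd = c(155L, 43L),
    md_mixed = c(62L, 99L)
  )
}

#' Leave-center-out trial sizes of the reference design
#'
#' Four trials: each holds out the complete data of one or two centers for
#' testing and cross-validates on the rest.
#'
#' @return Tibble with `trial_id`, list-columns `cv_centers`/`test_centers`,
#'   and subject counts `cv_n`, `test_n`.
#' @export
ipmn_trial_design <- function() {
  tibble::tibble(
    trial_id = c("T1", "T2", "T3", "T4"),
    cv_centers = list(
      c("EMC", "IU", "MCF", "NMH", "NYU"),
      c("AHN", "IU", "MCA", "MCF", "NMH", "NYU"),
      c("AHN", "EMC", "MCA", "MCF", "NMH", "NYU"),
      c("AHN", "EMC", "IU", "MCA", "MCF", "NMH")
    ),
    test_centers = list(c("AHN", "MCA"), "EMC", "IU", "NYU"),
    cv_n = c(330L, 323L, 324L, 288L),
    test_n = c(29L, 36L, 35L, 71L)
  )
}

#' Per-trial benchmark metrics of the reference analyses
#'
#' Published per-trial percentages (means over repetitions) for the
#' radiomics-only random-forest analysis and the radiomics-DL fusion
#' analysis, on cross-validation and held-out testing, for 2D and 3D
#' radiomic features. Metric values are percentages.
#'
#' @param analysis `"radiomics"` or `"fusion"`.
#' @return Tidy tibble: `analysis`, `feature_dim`, `phase`, `trial_id`,
#'   `metric`, `value`.
#' @export
ipmn_benchmark_metrics <- function(analysis = c("radiomics", "fusion")) {
  analysis <- match.arg(analysis)
  grid <- function(feature_dim, phase, metric, values) {
    tibble::tibble(
      analysis = analysis, feature_dim = feature_dim, phase = phase,
      trial_id = c("T1", "T2", "T3", "T4"), metric = metric, value = values
    )
  }
  if (analysis == "radiomics") {
    dplyr::bind_rows(
      grid("2D", "testing", "f1",   c(52.2, 60.4, 72.4, 61.8)),
      grid("2D", "testing", "spec", c(46.2, 62.8, 75.0, 67.8)),
      grid("2D", "testing", "sens", c(62.9, 65.0, 78.2, 77.0)),
      grid("2D", "testing", "ppv",  c(45.9, 57.0, 67.7, 52.1)),
      grid("2D", "testing", "acc",  c(53.1, 63.7, 76.3, 70.6)),
      grid("2D", "testing", "auc",  c(46.7, 61.9, 77.0, 79.6)),
      grid("3D", "testing", "f1",   c(60.3, 57.4, 66.5, 60.2)),
      grid("3D", "testing", "spec", c(58.2, 54.5, 72.9, 70.6)),
      grid("3D", "testing", "sens", c(68.7, 64.7, 70.4, 71.1)),
      grid("3D", "testing", "ppv",  c(53.9, 52.5, 63.8, 52.7)),
      grid("3D", "testing", "acc",  c(62.6, 58.9, 71.9, 70.8)),
      grid("3D", "testing", "auc",  c(59.2, 58.8, 73.5, 74.6)),
      grid("2D", "cv", "f1",   c(62.9, 63.0, 62.2, 62.8)),
      grid("2D", "cv", "spec", c(68.9, 69.7, 68.8, 68.1)),
      grid("2D", "cv", "sens", c(67.7, 67.5, 66.6, 66.1)),
      grid("2D", "cv", "ppv",  c(58.9, 59.3, 58.6, 60.0)),
      grid("2D", "cv", "acc",  c(68.4, 68.9, 67.9, 67.3)),
      grid("2D", "cv", "auc",  c(72.6, 72.7, 71.8, 71.2)),
      grid("3D", "cv", "f1",   c(63.9, 62.9, 59.8, 62.9)),
      grid("3D", "cv", "spec", c(69.8, 68.3, 67.0, 68.2)),
      grid("3D", "cv", "sens", c(68.7, 68.3, 64.2, 66.4)),
      grid("3D", "cv", "ppv",  c(59.9, 58.5, 56.2, 60.1)),
      grid("3D", "cv", "acc",  c(69.3, 68.3, 65.9, 67.4)),
      grid("3D", "cv", "auc",  c(73.5, 72.2, 69.0, 71.5))
    )
  } else {
    dplyr::bind_rows(
      grid("2D", "cv", "spec", c(60.9, 62.9, 77.6, 72.2)),
      grid("2D", "cv", "sens", c(81.2, 78.5, 63.9, 77.6)),
      grid("2D", "cv", "acc",  c(68.7, 68.7, 71.5, 74.9)),
      grid("2D", "cv", "auc",  c(73.3, 74.6, 73.9, 75.6)),
      grid("3D", "cv", "spec", c(100.0, 98.4, 98.3, 96.3)),
      grid("3D", "cv", "sens", c(98.5, 100.0, 98.5, 95.1)),
      grid("3D", "cv", "acc",  c(99.4, 99.1, 98.5, 96.5)),
      grid("3D", "cv", "auc",  c(77.1, 74.0, 70.0, 72.5)),
      grid("2D", "testing", "spec", c(66.7, 66.7, 54.3, 75.5)),
      grid("2D", "testing", "sens", c(35.3, 46.0, 77.1, 63.7)),
      grid("2D", "testing", "acc",  c(48.3, 54.9, 68.0, 67.3)),
      grid("2D", "testing", "auc",  c(47.1, 61.7, 77.5, 79.0)),
      grid("3D", "testing", "spec", c(63.3, 62.7, 35.7, 77.3)),
      grid("3D", "testing", "sens", c(56.5, 57.0, 81.0, 60.4)),
      grid("3D", "testing", "acc",  c(59.3, 59.4, 62.9, 65.6)),
      grid("3D", "testing", "auc",  c(59.3, 63.3, 67.6, 74.7))
    )
  }
}

#' Cohort bookkeeping derived from the reference tables
#'
#' Recomputes, by arithmetic on the reference tables: the analysis cohort
#' size (collected minus the two exclusion waves), the low-risk group size
#' and subtype risk shares (row/column sums of the subtype table), and each
#' trial's cross-validation size (total minus held-out).
#'
#' @return Named list of scalars: `analysis_n`, `low_risk_n`, `high_risk_n`,
#'   `bd_low_share_pct`, `md_mixed_high_share_pct`, and `cv_n` (named vector
#'   per trial).
#' @export
ipmn_cohort_bookkeeping <- function() {
  flow <- ipmn_cohort_flow()
  n <- flow$count[flow$stage == "collected"] -
    sum(flow$count[flow$stage != "collected"])
  st <- ipmn_subtype_table()
  bd_total <- sum(st$bd); mdmx_total <- sum(st$md_mixed)
  design <- ipmn_trial_design()
  list(
    analysis_n = n,
    low_risk_n = st$bd[st$risk == "low"] + st$md_mixed[st$risk == "low"],
    high_risk_n = st$bd[st$risk == "high"] + st$md_mixed[st$risk == "high"],
    bd_low_share_pct = 100 * st$bd[st$risk == "low"] / bd_total,
    md_mixed_high_share_pct = 100 * st$md_mixed[st$risk == "high"] / mdmx_total,
    cv_n = stats::setNames(n - design$test_n, design$trial_id)
  )
}
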