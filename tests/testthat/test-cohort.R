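test_that("retina scenes encode the group- and age-dependent melanin model", {
  spec <- cohort_spec()
  # equal baselines at the first age: identical scenes
  spec_eq <- cohort_spec(baseline_rpe = c(control = 1, knockout = 1),
                         baseline_choroid = c(control = 1, knockout = 1))
  s1 <- make_retina_scene(spec_eq, "control", 5)
  s2 <- make_retina_scene(spec_eq, "knockout", 5)
  expect_equal(s1$layers$reflectivity, s2$layers$reflectivity)
  expect_equal(attr(s1, "choroid_scale"), attr(s2, "choroid_scale"))

  # knockout declines faster: lower melanin at the last timepoint
  sc_c <- make_retina_scene(spec, "control", 17)
  sc_k <- make_retina_scene(spec, "knockout", 17)
  expect_lt(attr(sc_k, "choroid_scale"), attr(sc_c, "choroid_scale"))

  # a decline too steep for the age range is rejected up front
  expect_error(cohort_spec(decline_choroid = c(control = 0.05, knockout = 2)),
               "negative computed scale")
  expect_error(make_retina_scene(spec, "knockout", 17, eye_dev_choroid = -0.6),
               "negative computed melanin scale")
})

test_that("cohort generation is deterministic and matches its truth table", {
  spec <- cohort_spec(eyes_per_group = 1, ages_months = 7,
                      lateral_size = c(6, 6))
  ch <- generate_cohort(spec)
  expect_length(ch$volumes, 2) # one per group
  expect_equal(nrow(ch$truth), 2)
  expect_true(all(c("rpe_scale", "choroid_scale") %in% names(ch$truth)))
  ch2 <- generate_cohort(spec)
  expect_identical(ch$volumes[[1]]$fringes, ch2$volumes[[1]]$fringes)
  expect_identical(ch$truth, ch2$truth)
})

test_that("generator-to-biomarker links are monotone", {
  # paired forward simulations differing only in one melanin scale
  spec <- cohort_spec()
  params <- pipeline_params(roi_len_px = 21)
  center <- (spec$lateral_size + 1) / 2
  run_scale <- function(group_spec, seeds) {
    rows <- purrr::map_dfr(seeds, function(s) {
      v <- simulate_fringe_volume(group_spec$scene, n_k = spec$n_k,
                                  lateral_size = spec$lateral_size,
                                  pitch_xy = spec$pitch_xy, seed = s)
      process_volume(v, center, params, pitch_xy = spec$pitch_xy)
    })
    colMeans(rows[, c("rc_ratio", "mean_1_dopu", "sscov_per_mm")])
  }
  flat <- c(control = 0, knockout = 0)
  lo <- cohort_spec(baseline_choroid = c(control = 0.4, knockout = 0.4),
                    decline_choroid = flat)
  hi <- cohort_spec(baseline_choroid = c(control = 1.2, knockout = 1.2),
                    decline_choroid = flat)
  m_lo <- run_scale(list(scene = make_retina_scene(lo, "control", 5)), 1:3)
  m_hi <- run_scale(list(scene = make_retina_scene(hi, "control", 5)), 1:3)
  expect_gt(m_hi[["sscov_per_mm"]], m_lo[["sscov_per_mm"]])
  expect_gt(m_hi[["mean_1_dopu"]], m_lo[["mean_1_dopu"]])

  # RPE melanin has a compound effect on the RC ratio: more backscatter
  # above, more shadow below
  rlo <- cohort_spec(baseline_rpe = c(control = 0.6, knockout = 0.6))
  rhi <- cohort_spec(baseline_rpe = c(control = 1.2, knockout = 1.2))
  # (RPE declines are mild; no flattening needed)
  r_lo <- run_scale(list(scene = make_retina_scene(rlo, "control", 5)), 4:6)
  r_hi <- run_scale(list(scene = make_retina_scene(rhi, "control", 5)), 4:6)
  expect_gt(r_hi[["rc_ratio"]], r_lo[["rc_ratio"]])
})

test_that("measured choroidal SSCoV ranks with the generating melanin scale", {
  spec <- cohort_spec()
  params <- pipeline_params(roi_len_px = 21)
  center <- (spec$lateral_size + 1) / 2
  scales <- seq(0.3, 1.3, length.out = 8)
  ss <- vapply(seq_along(scales), function(i) {
    sp <- cohort_spec(baseline_choroid = c(control = scales[i],
                                           knockout = scales[i]),
                      decline_choroid = c(control = 0, knockout = 0))
    v <- simulate_fringe_volume(make_retina_scene(sp, "control", 5),
                                n_k = spec$n_k,
                                lateral_size = spec$lateral_size,
                                pitch_xy = spec$pitch_xy, seed = 50 + i)
    process_volume(v, center, params, pitch_xy = spec$pitch_xy)$sscov_per_mm
  }, numeric(1))
  expect_gt(cor(scales, ss, method = "spearman"), 0.8)
})

test_that("run_pipeline emits the full report deterministically", {
  spec <- cohort_spec(eyes_per_group = 2, ages_months = c(5, 11, 17),
                      lateral_size = c(16, 16), pitch_xy = 60)
  ch <- generate_cohort(spec)
  out1 <- withr::local_tempdir()
  res <- run_pipeline(ch$volumes, ch$metadata,
                      params = pipeline_params(roi_len_px = 21),
                      pitch_xy = spec$pitch_xy, out_dir = out1)
  expect_equal(nrow(res$biomarkers), 12)
  expect_equal(nrow(res$trends), 3)
  expect_equal(nrow(res$correlations), 6) # 3 metric pairs x 2 groups
  expect_true(all(file.exists(file.path(
    out1, c("biomarkers.csv", "trends.csv", "correlations.csv",
            "report.json")))))
  # rerun on the same inputs: byte-identical outputs
  out2 <- withr::local_tempdir()
  run_pipeline(ch$volumes, ch$metadata,
               params = pipeline_params(roi_len_px = 21),
               pitch_xy = spec$pitch_xy, out_dir = out2)
  expect_identical(readLines(file.path(out1, "biomarkers.csv")),
                   readLines(file.path(out2, "biomarkers.csv")))
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  # a failing volume aborts with the volume identified
  bad <- ch$volumes
  bad[[3]] <- oct_volume(array(0, dim(bad[[3]]$fringes)), bad[[3]]$k_grid)
  expect_error(run_pipeline(bad, ch$metadata,
                            params = pipeline_params(roi_len_px = 21),
                            pitch_xy = spec$pitch_xy),
               "volume 3")
})
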