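## 10-voxel toy: 6 class-1 voxels at ADC 1.0e-3, 4 class-3 at 2.5e-3.
toy_summary_inputs <- function(vox_spacing = c(1, 1, 1)) {
  shape <- c(5, 2, 1)
  lab <- array(NA_integer_, shape)
  lab[1:6] <- 1L; lab[7:10] <- 3L
  adc <- array(NA_real_, shape)
  adc[1:6] <- 1.0e-3; adc[7:10] <- 2.5e-3
  list(labels = habitat_map(lab, voxel_grid(shape, vox_spacing)),
       adc = parameter_volume(adc, vox_spacing, "ADC mm^2/s",
                              valid = !is.na(adc)),
       voi = mask_volume(array(TRUE, shape), vox_spacing))
}

test_that("habitat summary matches hand arithmetic", {
  t <- toy_summary_inputs()
  s <- summarize_habitats(t$labels, t$adc, t$voi)
  expect_equal(s$fraction, c(0.6, 0, 0.4, 0, 0))
  expect_equal(s$mean_adc[1], 1.0e-3)
  expect_equal(s$mean_adc[3], 2.5e-3)
  expect_true(all(is.na(s$mean_adc[c(2, 4, 5)])))
  expect_equal(sum(s$voxels), attr(s, "total_voxels"))
  expect_equal(sum(s$fraction), 1, tolerance = 1e-9)
  expect_false(s$adc_interpretable[4])
})

test_that("volumes scale with voxel size", {
  t <- toy_summary_inputs(vox_spacing = c(2, 1, 1))  # 2 mm^3 voxels
  s <- summarize_habitats(t$labels, t$adc, t$voi)
  expect_equal(attr(s, "total_volume_mm3"), 20)
  expect_equal(s$volume_mm3[1], 12)
})

test_that("single-class VOI and empty VOI behave per contract", {
  shape <- c(3, 3, 1)
  lab <- habitat_map(array(3L, shape), voxel_grid(shape))
  adc <- parameter_volume(array(2e-3, shape), c(1, 1, 1), "ADC mm^2/s")
  voi <- mask_volume(array(TRUE, shape))
  s <- summarize_habitats(lab, adc, voi)
  expect_equal(s$fraction, c(0, 0, 1, 0, 0))
  expect_equal(s$mean_adc[3], mean(adc$values))
  expect_error(summarize_habitats(lab, adc, mask_volume(array(FALSE, shape))),
               "empty")
})

test_that("Spie geometry conserves 360 degrees and encodes mean ADC", {
  t <- toy_summary_inputs()
  s <- summarize_habitats(t$labels, t$adc, t$voi)
  g <- spie_geometry(s)
  expect_equal(sum(g$angle), 360, tolerance = 1e-6)
  expect_equal(g$angle[1], 216)  # 0.6 of the circle
  ## radius normalized to the largest interpretable class mean ADC
  expect_equal(g$radius[3], 1)
  expect_equal(g$radius[1], 1.0e-3 / 2.5e-3)
  expect_true(all(is.na(g$ref_radius)))

  ## two equal fractions give two 180-degree segments
  shape <- c(2, 1, 1)
  lab <- habitat_map(array(c(1L, 2L), shape), voxel_grid(shape))
  adc <- parameter_volume(array(1e-3, shape), c(1, 1, 1), "ADC mm^2/s")
  s2 <- summarize_habitats(lab, adc, mask_volume(array(TRUE, shape)))
  g2 <- spie_geometry(s2)
  expect_equal(g2$angle[1:2], c(180, 180))
})

test_that("reference summaries attach dashed radii on a shared scale", {
  t <- toy_summary_inputs()
  s_pre <- summarize_habitats(t$labels, t$adc, t$voi)
  adc_post <- t$adc
  adc_post$values[] <- t$adc$values * 1.2
  s_post <- summarize_habitats(t$labels, adc_post, t$voi)
  g <- spie_geometry(s_post, reference = s_pre)
  expect_false(any(is.na(g$ref_radius[c(1, 3)])))
  ## shared radial scale: post class-3 mean is the global maximum
  expect_equal(g$radius[3], 1)
  expect_equal(g$ref_radius[3], 2.5e-3 / (2.5e-3 * 1.2))
})

test_that("longitudinal comparison recovers designed volume change", {
  shape <- c(10, 10, 10)
  adc <- parameter_volume(array(1e-3, shape), c(1, 1, 1), "ADC mm^2/s")
  lab_pre <- array(NA_integer_, shape); lab_pre[1:1000] <- 1L
  lab_post <- array(NA_integer_, shape); lab_post[1:943] <- 1L
  voi_pre <- mask_volume(array(TRUE, shape))
  voi_post_memb <- array(FALSE, shape); voi_post_memb[1:943] <- TRUE
  s_pre <- summarize_habitats(habitat_map(lab_pre, voxel_grid(shape)), adc, voi_pre)
  s_post <- summarize_habitats(habitat_map(lab_post, voxel_grid(shape)), adc,
                               mask_volume(voi_post_memb))
  cmp <- compare_timepoints(s_pre, s_post)
  expect_equal(attr(cmp, "total_pct_volume_change"), -5.7)

  ## identical summaries: all deltas zero
  cmp0 <- compare_timepoints(s_pre, s_pre)
  expect_true(all(cmp0$delta_fraction == 0))
  expect_equal(attr(cmp0, "total_pct_volume_change"), 0)
})

test_that("classes appearing only post-treatment are handled", {
  shape <- c(4, 4, 1)
  adc <- parameter_volume(array(1.5e-3, shape), c(1, 1, 1), "ADC mm^2/s")
  voi <- mask_volume(array(TRUE, shape))
  lab_pre <- habitat_map(array(1L, shape), voxel_grid(shape))
  post <- array(1L, shape); post[1:4] <- 3L
  lab_post <- habitat_map(post, voxel_grid(shape))
  s_pre <- summarize_habitats(lab_pre, adc, voi)
  s_post <- summarize_habitats(lab_post, adc, voi)
  cmp <- compare_timepoints(s_pre, s_post)
  expect_equal(cmp$delta_fraction[3], 0.25)
  expect_false(cmp$adc_delta_defined[3])  # no pre-treatment class-3 ADC
})

test_that("overlay export writes a five-entry legend with standard colors", {
  shape <- c(4, 4, 2)
  lab <- array(NA_integer_, shape); lab[1:8] <- 1L; lab[9:12] <- 3L
  hm <- habitat_map(lab, voxel_grid(shape, c(2, 2, 2)))
  p_lab <- tempfile(fileext = ".nii.gz"); p_leg <- tempfile(fileext = ".json")
  legend <- export_overlay(hm, NULL, p_lab, p_leg)
  expect_equal(nrow(legend), 5)
  expect_equal(legend$color[1], "red")
  expect_equal(legend$color[3], "blue")
  expect_equal(legend$present, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  saved <- jsonlite::read_json(p_leg, simplifyVector = TRUE)
  expect_equal(nrow(saved), 5)
  img <- RNifti::readNifti(p_lab)
  expect_equal(sum(img == 1), 8)
})

test_that("spie plot renders without error", {
  t <- toy_summary_inputs()
  s <- summarize_habitats(t$labels, t$adc, t$voi)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot_spie(spie_geometry(s), main = "toy"))
})
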