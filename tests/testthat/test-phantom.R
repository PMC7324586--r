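test_that("dose block has the configured radial falloff", {
  cfg <- phantom_config(shape = c(106, 106, 106), isocenter = c(52, 52, 52),
                        dose_block_mm = c(101, 101, 101), dose_max = 60,
                        r50 = 18, falloff_q = 2)
  blk <- generate_dose_block(cfg)
  ctr_idx <- (dim(blk$data) + 1) / 2
  # isocenter voxel carries the maximum dose
  expect_equal(max(blk$data), 60, tolerance = 1e-12)
  expect_equal(blk$data[ctr_idx[1], ctr_idx[2], ctr_idx[3]], 60,
               tolerance = 1e-12)
  # half-value at r = r50 (sample 18 mm along +x from the isocenter)
  expect_equal(sample_volume(blk, rbind(cfg$isocenter + c(18, 0, 0))),
               30, tolerance = 1e-9)
  # fraction of voxels at or above the 20% isodose matches the analytic
  # sphere volume of radius r50 * log2(5)^(1/q)
  r20 <- 18 * sqrt(log2(5))
  frac_analytic <- (4 / 3 * pi * r20^3) / prod(cfg$dose_block_mm)
  frac_voxel <- mean(blk$data >= 0.2 * 60)
  expect_equal(frac_voxel, frac_analytic, tolerance = 0.01)
})

test_that("a dose block larger than the CT volume is rejected", {
  cfg <- small_config(dose_block_mm = c(200, 200, 200))
  expect_error(generate_dose_block(cfg), "outside the CT volume")
})

test_that("the noiseless aligned phantom realizes the true response exactly", {
  cfg <- noiseless_config(delta_hu_max = 200, isocenter = c(24, 32, 32))
  pair <- generate_ct_pair(cfg)
  diff <- pair$followup$data - pair$planning$data
  iso_idx <- cfg$isocenter / cfg$spacing + 1
  expect_equal(diff[iso_idx[1], iso_idx[2], iso_idx[3]],
               200 * ntcp_prob(cfg$true_model, cfg$dose_max,
                               cfg$true_d50, cfg$true_gamma50),
               tolerance = 1e-9)
  # no change outside the lungs, and essentially none at far, near-zero-dose
  # lung voxels under a Weibull truth
  expect_true(all(diff[!pair$lung_mask$data] == 0))
  cfgw <- noiseless_config(true_model = "weibull", isocenter = c(24, 32, 32))
  pw <- generate_ct_pair(cfgw)
  dw <- pw$followup$data - pw$planning$data
  far <- which(pw$lung_mask$data, arr.ind = TRUE)
  r <- sqrt(colSums((t(far) - 1 - cfgw$isocenter)^2))
  expect_gt(sum(r > 29), 0)
  expect_lt(max(abs(dw[pw$lung_mask$data][r > 29])), 1e-3)
})

test_that("phantom generation is seed-deterministic", {
  a <- generate_ct_pair(small_config(seed = 9))
  b <- generate_ct_pair(small_config(seed = 9))
  expect_identical(a$planning$data, b$planning$data)
  expect_identical(a$followup$data, b$followup$data)
  c <- generate_ct_pair(small_config(seed = 10))
  expect_false(identical(a$planning$data, c$planning$data))
})

test_that("an isocenter outside the lungs is rejected", {
  cfg <- small_config(isocenter = c(31.5, 31.5, 2))
  expect_error(generate_ct_pair(cfg), "outside every lung")
})

test_that("directly generated curves pass the model through unchanged", {
  edges <- seq(0, 60, by = 6)
  cv <- generate_binned_curve("lyman", 35, 1.35, edges)
  expect_equal(cv$response, ntcp_prob("lyman", seq(3, 57, by = 6), 35, 1.35),
               tolerance = 1e-12)
  expect_false(cv$normalized)
  for (m in NTCP_MODELS)
    expect_true(all(diff(generate_binned_curve(m, 35, 1.35)$response) > 0))
  n1 <- generate_binned_curve("logit", 35, 1.35, noise_sd = 0.05, seed = 7)
  n2 <- generate_binned_curve("logit", 35, 1.35, noise_sd = 0.05, seed = 7)
  expect_identical(n1$response, n2$response)
  expect_error(generate_binned_curve("lyman", 35, 1.35, noise_sd = -1), ">= 0")
  expect_error(generate_binned_curve("lyman", 35, 1.35, bin_edges = c(6, 0)),
               "increasing")
})

test_that("phantom truth round-trips losslessly through JSON", {
  cfg <- small_config(misalignment = rigid_transform(translation = c(4, -2, 3),
                                                     rotation_deg = c(0, 0, 2),
                                                     center = c(31.5, 31.5, 31.5)))
  pair <- generate_ct_pair(cfg)
  path <- tempfile(fileext = ".json")
  write_phantom_truth(pair$truth, path)
  back <- read_phantom_truth(path)
  expect_identical(back$model, pair$truth$model)
  expect_equal(back$d50, pair$truth$d50, tolerance = 1e-15)
  expect_equal(back$gamma50, pair$truth$gamma50, tolerance = 1e-15)
  expect_equal(back$misalignment_matrix, pair$truth$misalignment_matrix,
               tolerance = 1e-15)
  expect_equal(back$hu_means, pair$truth$hu_means)
  unlink(path)
})
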