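test_that("HU change is zero for a self-difference and exact on phantoms", {
  cfg <- noiseless_config(isocenter = c(24, 32, 32))
  pair <- generate_ct_pair(cfg)
  d0 <- compute_hu_change(pair$planning, pair$planning)
  expect_true(all(d0$data == 0))
  d1 <- compute_hu_change(pair$followup, pair$planning)
  truth_resp <- cfg$delta_hu_max *
    ntcp_prob(cfg$true_model,
              ntcpct:::phantom_dose_at(cfg, cfg$shape, cfg$spacing)[pair$lung_mask$data],
              cfg$true_d50, cfg$true_gamma50)
  expect_equal(d1$data[pair$lung_mask$data], truth_resp, tolerance = 1e-9)
})

test_that("block-mean baseline subtracts the planning lung mean", {
  cfg <- noiseless_config()
  pair <- generate_ct_pair(cfg)
  # planning lung is exactly -800 HU in the noiseless phantom
  d <- compute_hu_change(pair$followup, pair$planning, mode = "block_mean",
                         planning_mask = pair$lung_mask, dose = pair$dose)
  expect_equal(d$data, pair$followup$data + 800, tolerance = 1e-9)
  expect_error(compute_hu_change(pair$followup, pair$planning,
                                 mode = "block_mean"),
               "requires")
})

test_that("binning is a mean-preserving partition of masked dosed pixels", {
  cfg <- noiseless_config()
  pair <- generate_ct_pair(cfg)
  dose_f <- map_dose_to_followup(pair$dose, rigid_transform(), pair$followup)
  mask <- pair$lung_mask

  # constant response: every nonempty bin reports the constant
  const <- image_volume(array(7.5, cfg$shape), cfg$spacing)
  cv <- bin_curve(const, dose_f, mask)
  expect_true(all(cv$response[cv$pixel_count > 0] == 7.5))

  # response equal to dose: per-bin mean dose, brute-force oracle
  cv2 <- bin_curve(dose_f, dose_f, mask)
  d <- as.vector(dose_f$data); m <- as.vector(mask$data)
  sel <- m & is.finite(d)
  idx <- findInterval(d[sel], cv2$bin_edges)
  idx[idx > 10] <- 10L
  brute <- tapply(d[sel], factor(idx, levels = 1:10), mean)
  nz <- cv2$pixel_count > 0
  expect_equal(unname(cv2$response[nz]), as.numeric(brute[nz]),
               tolerance = 1e-9)

  # partition conservation
  expect_identical(sum(cv2$pixel_count), sum(sel))
  expect_identical(attr(cv2, "n_masked") - attr(cv2, "n_no_dose"),
                   sum(sel))

  # clamping doses at the top edge
  dd <- dose_f; dd$data[which(sel)[1:5]] <- 60
  cvc <- bin_curve(const, dd, mask)
  expect_identical(sum(cvc$pixel_count), sum(sel))
  cvx <- bin_curve(const, dd, mask, clamp_above = FALSE)
  expect_identical(sum(cvx$pixel_count), sum(sel) - 5L)
})

test_that("normalization scales to the maximum bin and is idempotent", {
  cv <- dose_response_curve(c(0, 6, 12, 18), c(10, 50, 200), c(5L, 5L, 5L))
  n1 <- normalize_curve(cv)
  expect_equal(n1$response, c(0.05, 0.25, 1.0))
  expect_true(n1$normalized)
  expect_equal(normalize_curve(n1)$response, n1$response)
  bad <- dose_response_curve(c(0, 6, 12, 18), c(-5, 0, -1), c(5L, 5L, 5L))
  expect_error(normalize_curve(bad), "no detectable radiographic change")
})

test_that("pooling averages patient-normalized curves and renormalizes", {
  edges <- c(0, 6, 12, 18)
  a <- dose_response_curve(edges, c(0.2, 0.8, 1.0), c(9L, 9L, 9L),
                           normalized = TRUE, patient_id = "a")
  self <- pool_curves(list(a, a, a))
  expect_equal(self$response, a$response, tolerance = 1e-12)
  expect_equal(self$bin_edges, a$bin_edges)
  expect_equal(max(pool_curves(list(a, a))$response), 1)
  b <- dose_response_curve(edges, c(0.4, 1.0, 0.6), c(9L, 9L, 9L),
                           normalized = TRUE, patient_id = "b")
  pooled <- suppressMessages(pool_curves(list(a, b)))
  # hand oracle: means (0.3, 0.9, 0.8), renormalized by 0.9
  expect_equal(pooled$response, c(0.3, 0.9, 0.8) / 0.9, tolerance = 1e-12)
  # bins empty in one patient fall back to the other's mean
  c3 <- dose_response_curve(edges, c(NA, 0.5, 1.0), c(0L, 4L, 4L),
                            normalized = TRUE, patient_id = "c")
  pooled2 <- suppressMessages(pool_curves(list(a, c3)))
  expect_equal(pooled2$response[1], 0.2 / max(c(0.2, 0.65, 1.0)))
  mism <- dose_response_curve(c(0, 10, 20, 30), c(0.2, 0.8, 1.0), c(1L, 1L, 1L),
                              normalized = TRUE)
  expect_error(pool_curves(list(a, mism)), "mismatched bin edges")
  raw <- dose_response_curve(edges, c(1, 2, 3), c(1L, 1L, 1L))
  expect_error(pool_curves(list(a, raw)), "normalized before pooling")
})

test_that("curves round-trip through CSV", {
  edges <- seq(0, 60, by = 6)
  a <- normalize_curve(generate_binned_curve("lyman", 35, 1.3,
                                             patient_id = "p1"))
  b <- normalize_curve(generate_binned_curve("logit", 30, 1.8,
                                             patient_id = "p2"))
  path <- tempfile(fileext = ".csv")
  write_curves_csv(list(a, b), path)
  back <- read_curves_csv(path)
  expect_setequal(names(back), c("p1", "p2"))
  expect_curve_equal(back$p1, a)
  expect_curve_equal(back$p2, b)
  expect_true(back$p1$normalized)
  unlink(path)
})
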