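# Small, fast phantom configurations shared across tests.

# 64^3 1-mm phantom: runs the full pipeline in a few seconds.
small_config <- function(..., dose_block_mm = c(48, 48, 48), r50 = 12) {
  phantom_config(shape = c(64, 64, 64), dose_block_mm = dose_block_mm,
                 r50 = r50, ...)
}

# Noiseless, perfectly aligned variant for exact-value oracles.
noiseless_config <- function(...) small_config(hu_noise_sd = 0, ...)

# Spherically symmetric single-"lung" phantom centered on the isocenter,
# for registration-shift symmetry checks.
symmetric_config <- function(shape = c(64, 64, 64), ...) {
  ctr <- (shape - 1) / 2
  phantom_config(shape = shape, hu_noise_sd = 0,
                 lung_centers = list(ctr),
                 lung_semiaxes = list(c(24, 24, 24)),
                 isocenter = ctr, r50 = 12,
                 dose_block_mm = c(44, 44, 44), ...)
}

expect_curve_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$response, b$response, tolerance = tol)
  expect_equal(a$pixel_count, b$pixel_count)
  expect_equal(a$bin_edges, b$bin_edges)
}
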