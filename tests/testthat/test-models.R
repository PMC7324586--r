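erf_ref <- function(x) 2 * pnorm(x * sqrt(2)) - 1

test_that("all four models pass through one half at D50", {
  for (m in NTCP_MODELS)
    for (d50 in c(20, 35.29, 50))
      for (g in c(0.5, 1.35, 4))
        expect_equal(ntcp_prob(m, d50, d50, g), 0.5, tolerance = 1e-12)
})

test_that("closed forms match frozen high-precision values", {
  # oracle: 0.5 * (1 - erf(1.35 * sqrt(pi))) evaluated with erf via pnorm
  expect_equal(ntcp_prob("lyman", 0, 35.29, 1.35), 3.572574e-4,
               tolerance = 1e-6)
  # oracle: 2^(-exp(e * 1.60)), extended-precision log-space evaluation
  expect_equal(ntcp_prob("poisson", 0, 34.49, 1.60), 4.944507e-24,
               tolerance = 1e-6)
  expect_identical(ntcp_prob("weibull", 0, 35.09, 1.36), 0)
  expect_identical(ntcp_prob("logit", 0, 30, 1), 0)
})

test_that("model identifiers parse case-insensitively and reject junk", {
  expect_identical(parse_model("LyMan"), "lyman")
  expect_identical(parse_model(" Poisson "), "poisson")
  expect_error(parse_model("lkb"), "unknown NTCP model")
  expect_error(parse_model(1), "character")
})

test_that("invalid doses and parameters are rejected", {
  expect_error(ntcp_prob("lyman", -1, 35, 1.35), ">= 0")
  expect_error(ntcp_prob("lyman", NaN, 35, 1.35), "finite")
  expect_error(ntcp_prob("lyman", 30, -5, 1.35), "d50")
  expect_error(ntcp_prob("lyman", 30, 35, 0), "gamma50")
  expect_error(ntcp_gradient("logit", 0, 35, 1.35), "> 0")
})

test_that("analytic slopes satisfy the normalized-gradient identities", {
  h <- 1e-5
  for (m in NTCP_MODELS) {
    for (g in c(0.5, 1, 1.35, 2, 4)) {
      d50 <- 35.29
      slope <- ntcp_gradient(m, d50, d50, g)
      target <- if (m == "poisson") exp(1) * log(2) / 2 * g else g
      expect_equal(d50 * slope, target, tolerance = 1e-10)
      # central-difference oracle
      num <- (ntcp_prob(m, d50 + h, d50, g) - ntcp_prob(m, d50 - h, d50, g)) / (2 * h)
      expect_equal(slope, num, tolerance = 1e-8)
    }
  }
  # spec'd spot values
  expect_equal(ntcp_gradient("lyman", 35.29, 35.29, 1.35), 1.35 / 35.29,
               tolerance = 1e-12)
  expect_equal(ntcp_gradient("logit", 30, 30, 1.0), 1 / 30, tolerance = 1e-12)
  expect_equal(ntcp_gradient("poisson", 30, 30, 1.0),
               exp(1) * log(2) / 2 / 30, tolerance = 1e-10)
})

test_that("responses are strictly increasing and saturate at 1", {
  d <- seq(0.5, 120, by = 0.5)
  for (m in NTCP_MODELS) {
    p <- ntcp_prob(m, d, 35, 1.35)
    # strictly increasing until the response saturates at 1 in double
    # precision (the Weibull tail reaches 1 - 2^-122 before 120 Gy)
    expect_true(all(diff(p) > 0 | p[-1] >= 1 - 1e-12))
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(ntcp_prob(m, 1e4, 35, 1.35), 1, tolerance = 1e-12)
  }
})

test_that("the quadrature form of the Lyman model matches the probit form", {
  # closed form minus the truncated lower-tail mass
  trunc <- function(g) 0.5 * (1 - erf_ref(g * sqrt(pi)))
  expect_equal(lyman_integral(35, 35, 1.35), 0.5 - trunc(1.35),
               tolerance = 1e-8)
  expect_identical(lyman_integral(0, 35, 1.35), 0)
  for (g in c(0.5, 1, 2, 4)) {
    q <- lyman_integral(seq(6, 60, by = 6), 35, g, tol = 1e-9)
    cf <- ntcp_prob("lyman", seq(6, 60, by = 6), 35, g)
    expect_true(all(abs(q - cf) <= 1e-6 + trunc(g)))
  }
  expect_error(lyman_integral(30, 35, 1.35, tol = 1), "tol")
})
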