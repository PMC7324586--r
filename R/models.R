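#' @keywords internal
"_PACKAGE"

#' The four supported NTCP dose-response models
#'
#' Canonical identifiers of the normal tissue complication probability
#' models implemented by the package: the Lyman (probit/Gaussian) model,
#' the logit (parallel-architecture/logistic) model, the Weibull model and
#' the Poisson (cell-survival) model. All are two-parameter sigmoids in
#' dose, parameterized by `d50` (the dose in Gy producing half of the
#' maximal response) and `gamma50` (the dimensionless normalized slope of
#' the response at `d50`).
#'
#' @format Character vector of length four.
#' @export
NTCP_MODELS <- c("lyman", "logit", "weibull", "poisson")

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Parse an NTCP model identifier
#'
#' Case-insensitive; returns the canonical lower-case identifier.
#'
#' @param model Character scalar, one of `"lyman"`, `"logit"`, `"weibull"`,
#'   `"poisson"` (any case).
#' @return Canonical lower-case model name.
#' @export
parse_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || is.na(model))
    stop("`model` must be a single character string", call. = FALSE)
  m <- tolower(trimws(model))
  if (!m %in% NTCP_MODELS)
    stop(sprintf("unknown NTCP model '%s'; must be one of %s",
                 model, paste(NTCP_MODELS, collapse = ", ")), call. = FALSE)
  m
}

#' NTCP model parameters
#'
#' Validates and bundles the (D50, gamma50) parameter pair shared by all
#' four models.
#'
#' @param d50 Dose in Gy giving 50% of maximal response; must be finite
#'   and positive.
#' @param gamma50 Normalized dose-response gradient at `d50`
#'   (dimensionless); must be finite and positive.
#' @return An object of class `ntcp_params`.
#' @export
ntcp_params <- function(d50, gamma50) {
  if (!is.numeric(d50) || length(d50) != 1L || !is.finite(d50) || d50 <= 0)
    stop("`d50` must be a single finite positive number (Gy)", call. = FALSE)
  if (!is.numeric(gamma50) || length(gamma50) != 1L || !is.finite(gamma50) ||
      gamma50 <= 0)
    stop("`gamma50` must be a single finite positive number", call. = FALSE)
  structure(list(d50 = as.numeric(d50), gamma50 = as.numeric(gamma50)),
            class = "ntcp_params")
}

check_dose <- function(dose, positive = FALSE) {
  if (!is.numeric(dose) || length(dose) == 0L)
    stop("`dose` must be numeric", call. = FALSE)
  if (any(!is.finite(dose)))
    stop("`dose` must be finite", call. = FALSE)
  if (positive) {
    if (any(dose <= 0)) stop("`dose` must be > 0", call. = FALSE)
  } else if (any(dose < 0)) {
    stop("`dose` must be >= 0", call. = FALSE)
  }
  invisible(dose)
}

#' Evaluate an NTCP dose-response model
#'
#' Closed-form response probability as a function of dose, in the
#' (D50, gamma50) parameterization:
#' \describe{
#'   \item{lyman}{`P(D) = 0.5 (1 - erf[gamma50 sqrt(pi) (1 - D/D50)])`
#'     (probit form of the Gaussian cumulative model).}
#'   \item{logit}{`P(D) = 1 / (1 + (D50/D)^(4 gamma50))`, with
#'     `P(0) = 0` by continuity.}
#'   \item{weibull}{`P(D) = 1 - exp[-ln2 (D/D50)^((2/ln2) gamma50)]`.}
#'   \item{poisson}{`P(D) = 2^(-exp[e gamma50 (1 - D/D50)])`.}
#' }
#' All four satisfy `P(D50) = 1/2` and are strictly increasing in dose.
#'
#' @param model Model identifier (see [NTCP_MODELS]); case-insensitive.
#' @param dose Numeric vector of doses in Gy, finite and non-negative.
#' @param d50,gamma50 Model parameters (see [ntcp_params()]). A
#'   `ntcp_params` object may be given as `d50` instead.
#' @return Numeric vector of response probabilities in `[0, 1]`.
#' @export
ntcp_prob <- function(model, dose, d50, gamma50 = NULL) {
  model <- parse_model(model)
  if (inherits(d50, "ntcp_params")) {
    gamma50 <- d50$gamma50
    d50 <- d50$d50
  }
  p <- ntcp_params(d50, gamma50)
  check_dose(dose)
  ntcp_prob_unchecked(model, dose, p$d50, p$gamma50)
}

ntcp_prob_unchecked <- function(model, dose, d50, g) {
  switch(model,
    lyman = 0.5 * (1 - erf(g * sqrt(pi) * (1 - dose / d50))),
    logit = {
      out <- numeric(length(dose))
      pos <- dose > 0
      out[pos] <- 1 / (1 + (d50 / dose[pos])^(4 * g))
      out
    },
    weibull = 1 - exp(-log(2) * (dose / d50)^((2 / log(2)) * g)),
    poisson = 2^(-exp(exp(1) * g * (1 - dose / d50)))
  )
}

#' Analytic slope of an NTCP model
#'
#' First derivative `dP/dD` (per Gy) of the closed forms evaluated by
#' [ntcp_prob()]. At `D = D50` the normalized slope `D50 * P'(D50)` equals
#' `gamma50` for the Lyman, logit and Weibull models and
#' `(e ln2 / 2) * gamma50` (about `0.9421 gamma50`) for the Poisson model.
#'
#' @inheritParams ntcp_prob
#' @param dose Numeric vector of doses in Gy, finite and strictly positive.
#' @return Numeric vector of derivatives in 1/Gy.
#' @export
ntcp_gradient <- function(model, dose, d50, gamma50 = NULL) {
  model <- parse_model(model)
  if (inherits(d50, "ntcp_params")) {
    gamma50 <- d50$gamma50
    d50 <- d50$d50
  }
  p <- ntcp_params(d50, gamma50)
  check_dose(dose, positive = TRUE)
  d50 <- p$d50; g <- p$gamma50
  switch(model,
    lyman = {
      u <- g * sqrt(pi) * (1 - dose / d50)
      (g / d50) * exp(-u^2)
    },
    logit = {
      s <- (d50 / dose)^(4 * g)
      out <- 4 * g * s / (dose * (1 + s)^2)
      out[!is.finite(s)] <- 0
      out
    },
    weibull = {
      m <- (2 / log(2)) * g
      u <- dose / d50
      out <- exp(-log(2) * u^m) * log(2) * m * u^(m - 1) / d50
      out[!is.finite(out)] <- 0
      out
    },
    poisson = {
      e1 <- exp(1)
      E <- exp(e1 * g * (1 - dose / d50))
      out <- 2^(-E) * log(2) * E * e1 * g / d50
      out[!is.finite(out)] <- 0
      out
    }
  )
}

# Value and parameter-Jacobian of P(D; d50, gamma50), used by the fitter.
# Returns list(p, d_d50, d_g); non-finite partials from under/overflowed
# tails are zeroed (the probability there is flat at 0 or 1).
ntcp_prob_jacobian <- function(model, dose, d50, g) {
  switch(model,
    lyman = {
      u <- g * sqrt(pi) * (1 - dose / d50)
      p <- 0.5 * (1 - erf(u))
      dpdu <- -exp(-u^2) / sqrt(pi)
      list(p = p,
           d_d50 = dpdu * (g * sqrt(pi) * dose / d50^2),
           d_g   = dpdu * (sqrt(pi) * (1 - dose / d50)))
    },
    logit = {
      s <- (d50 / dose)^(4 * g)
      p <- 1 / (1 + s)
      dpds <- -1 / (1 + s)^2
      j <- list(p = p,
                d_d50 = dpds * (4 * g * s / d50),
                d_g   = dpds * (4 * log(d50 / dose) * s))
      j$p[dose == 0] <- 0
      j
    },
    weibull = {
      u <- dose / d50
      m <- (2 / log(2)) * g
      A <- log(2) * u^m
      p <- 1 - exp(-A)
      dpdA <- exp(-A)
      list(p = p,
           d_d50 = dpdA * (-log(2) * m * u^m / d50),
           d_g   = dpdA * (2 * u^m * ifelse(u > 0, log(u), 0)))
    },
    poisson = {
      e1 <- exp(1)
      E <- exp(e1 * g * (1 - dose / d50))
      p <- 2^(-E)
      dpdE <- -log(2) * p
      list(p = p,
           d_d50 = dpdE * E * (e1 * g * dose / d50^2),
           d_g   = dpdE * E * (e1 * (1 - dose / d50)))
    }
  ) -> j
  j$p[!is.finite(j$p)] <- 0
  j$p <- pmin(pmax(j$p, 0), 1)
  j$d_d50[!is.finite(j$d_d50)] <- 0
  j$d_g[!is.finite(j$d_g)] <- 0
  j
}

#' Quadrature form of the Lyman model
#'
#' Evaluates the Lyman response by adaptive quadrature of its Gaussian
#' integrand from 0 to `dose`, using the normalization under which the
#' full-line integral equals 1: integrand
#' `(gamma50/D50) exp(-pi [gamma50 (x - D50)/D50]^2)`. This reproduces the
#' probit closed form of [ntcp_prob()] exactly, up to the (small) Gaussian
#' mass truncated below `D = 0`, namely `0.5 (1 - erf(gamma50 sqrt(pi)))`.
#' Provided as an independent numerical cross-check of the closed form.
#'
#' @inheritParams ntcp_prob
#' @param dose Numeric vector of doses in Gy, finite and non-negative.
#' @param tol Absolute quadrature tolerance, in `(0, 1e-3]`.
#' @return Numeric vector of probabilities.
#' @export
lyman_integral <- function(dose, d50, gamma50 = NULL, tol = 1e-9) {
  if (inherits(d50, "ntcp_params")) {
    gamma50 <- d50$gamma50
    d50 <- d50$d50
  }
  p <- ntcp_params(d50, gamma50)
  check_dose(dose)
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) ||
      tol <= 0 || tol > 1e-3)
    stop("`tol` must be in (0, 1e-3]", call. = FALSE)
  d50 <- p$d50; g <- p$gamma50
  integrand <- function(x) (g / d50) * exp(-pi * (g * (x - d50) / d50)^2)
  vapply(dose, function(D) {
    if (D == 0) return(0)
    q <- tryCatch(
      stats::integrate(integrand, 0, D, abs.tol = tol,
                       subdivisions = 500L),
      error = function(e) stop("Lyman quadrature failed at D = ", D, " Gy (",
                               conditionMessage(e), ")", call. = FALSE))
    if (q$message != "OK")
      stop("Lyman quadrature did not converge at D = ", D, " Gy: ",
           q$message, call. = FALSE)
    q$value
  }, numeric(1))
}
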