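#' Goodness-of-fit statistics for a least-squares NTCP fit
#'
#' Gaussian least-squares forms with `k` fitted parameters:
#' `SSR = sum(r^2)` (floored at 1e-12, with a warning, to keep the
#' logarithms finite), `R^2 = 1 - SSR/SST` with SST about the response
#' mean, `adj-R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1)`,
#' `AIC = n log(SSR/n) + 2k` and `BIC = n log(SSR/n) + k log(n)`, so that
#' `BIC - AIC = k log(n) - 2k` identically (about 0.605 for `k = 2`,
#' `n = 10`).
#'
#' @param residuals Numeric vector of fit residuals.
#' @param observed Numeric vector of observed responses (same length).
#' @param k Number of fitted parameters (2 for all the NTCP models here).
#' @return A list with `ssr`, `adj_r2`, `aic`, `bic`, `n`, `k`.
#' @export
goodness_stats <- function(residuals, observed, k = 2L) {
  n <- length(residuals)
  stopifnot(length(observed) == n)
  if (n <= k + 1L)
    stop("insufficient data: need more than k + 1 = ", k + 1L, " bins",
         call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("degenerate variance: all observed responses are identical",
         call. = FALSE)
  ssr <- sum(residuals^2)
  if (ssr < 1e-12) {
    warning("SSR below 1e-12; floored to keep information criteria finite",
            call. = FALSE)
    ssr <- 1e-12
  }
  r2 <- 1 - ssr / sst
  list(ssr = ssr,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1),
       aic = n * log(ssr / n) + 2 * k,
       bic = n * log(ssr / n) + k * log(n),
       n = n, k = as.integer(k))
}

default_start_grid <- function() {
  as.matrix(expand.grid(d50 = c(15, 25, 35, 45, 55),
                        gamma50 = c(0.5, 1, 2, 4)))
}

#' Fit an NTCP model to a dose-response curve
#'
#' Bounded nonlinear least squares of the chosen model's closed form
#' against the per-bin responses: minimizes
#' `sum_i (P(bin_dose_i; d50, gamma50) - response_i)^2` over
#' `d50 in [1, 200]` Gy and `gamma50 in [0.05, 20]`, using L-BFGS-B with
#' analytic gradients from a 5 x 4 multi-start grid
#' (`d50 in {15, 25, 35, 45, 55}`, `gamma50 in {0.5, 1, 2, 4}`). Empty
#' bins are excluded. The fit with the lowest SSR wins; ties between
#' models elsewhere are broken lexicographically.
#'
#' The curve must be normalized (maximum bin response 1) so the responses
#' live on the probability scale of the models; curves whose responses are
#' already probabilities (e.g. noiseless synthetic curves from
#' [generate_binned_curve()]) may be fitted directly with
#' `probability_scale = TRUE`.
#'
#' @param model Model identifier, see [NTCP_MODELS].
#' @param curve A [dose_response_curve()].
#' @param probability_scale Accept an unnormalized curve whose responses
#'   are already on the 0-1 probability scale.
#' @param d50_bounds,gamma50_bounds Box constraints.
#' @param start_grid Matrix of starting values (columns d50, gamma50).
#' @return An object of class `ntcp_fit`: `model`, `d50`, `gamma50`,
#'   `ssr`, `adj_r2`, `aic`, `bic`, `n_bins_used`, `converged`,
#'   `n_starts_agreeing`, `non_informative` (parameter at a bound),
#'   `data` (the bins used), `fitted`, `residuals`.
#' @export
fit_model <- function(model, curve, probability_scale = FALSE,
                      d50_bounds = c(1, 200), gamma50_bounds = c(0.05, 20),
                      start_grid = default_start_grid()) {
  model <- parse_model(model)
  stopifnot(inherits(curve, "dose_response_curve"))
  if (!curve$normalized && !probability_scale)
    stop("curve must be normalized before fitting ",
         "(or pass probability_scale = TRUE for probability-scale curves)",
         call. = FALSE)
  use <- curve$pixel_count > 0L & is.finite(curve$response)
  dose <- curve$bin_dose[use]
  y <- curve$response[use]
  n <- length(y)
  if (n < 3L)
    stop("need at least 3 nonempty bins to fit; got ", n, call. = FALSE)

  lower <- c(d50_bounds[1], gamma50_bounds[1])
  upper <- c(d50_bounds[2], gamma50_bounds[2])
  fn <- function(par) {
    j <- ntcp_prob_jacobian(model, dose, par[1], par[2])
    sum((j$p - y)^2)
  }
  gr <- function(par) {
    j <- ntcp_prob_jacobian(model, dose, par[1], par[2])
    r <- j$p - y
    2 * c(sum(r * j$d_d50), sum(r * j$d_g))
  }
  runs <- lapply(seq_len(nrow(start_grid)), function(i) {
    p0 <- start_grid[i, ]
    o <- tryCatch(
      stats::optim(pmin(pmax(p0, lower), upper), fn, gr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(o)) list(value = Inf, par = p0, convergence = 99L) else o
  })
  ssrs <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(ssrs)))
    stop("fit failed: no start converged for model ", model, call. = FALSE)
  best <- which.min(ssrs)
  par <- unname(runs[[best]]$par)
  n_agree <- sum(ssrs <= ssrs[best] + 1e-6)
  fitted <- ntcp_prob(model, dose, par[1], par[2])
  res <- fitted - y
  # a perfectly flat observed curve has zero total variance; keep the fit
  # (flagged non-informative below) with an undefined adjusted R^2
  if (sum((y - mean(y))^2) == 0) {
    ssr <- max(sum(res^2), 1e-12)
    gs <- list(ssr = ssr, adj_r2 = NA_real_,
               aic = n * log(ssr / n) + 4, bic = n * log(ssr / n) + 2 * log(n))
  } else {
    gs <- goodness_stats(res, y, k = 2L)
  }
  at_bound <- any(abs(par - lower) < 1e-6) || any(abs(par - upper) < 1e-6)
  structure(list(model = model, d50 = par[1], gamma50 = par[2],
                 ssr = gs$ssr, adj_r2 = gs$adj_r2, aic = gs$aic,
                 bic = gs$bic, n_bins_used = n,
                 converged = runs[[best]]$convergence == 0L,
                 n_starts_agreeing = n_agree,
                 non_informative = at_bound,
                 data = data.frame(bin_dose = dose, response = y),
                 fitted = fitted, residuals = res),
            class = "ntcp_fit")
}

#' @export
print.ntcp_fit <- function(x, ...) {
  cat(sprintf(
    "<ntcp_fit %s> D50 = %.2f Gy, gamma50 = %.3f | SSR %.4g, adj-R2 %.3f, AIC %.2f, BIC %.2f (n = %d%s)\n",
    x$model, x$d50, x$gamma50, x$ssr, x$adj_r2, x$aic, x$bic, x$n_bins_used,
    if (x$non_informative) ", parameter at bound" else ""))
  invisible(x)
}

#' Fit all (or selected) NTCP models to one curve
#'
#' @inheritParams fit_model
#' @param models Character vector of model identifiers.
#' @return Named list of `ntcp_fit` objects.
#' @export
fit_all_models <- function(curve, models = NTCP_MODELS, ...) {
  models <- vapply(models, parse_model, character(1))
  fits <- lapply(models, fit_model, curve = curve, ...)
  names(fits) <- models
  fits
}

#' Significance of a model fit versus a flat response
#'
#' Extra-sum-of-squares F test of the fitted sigmoid against the
#' constant-mean null: `F = (SSR_null - SSR_fit) / (SSR_fit / (n - 2))`,
#' with `p` from the `F(1, n - 2)` distribution.
#'
#' @param fit An `ntcp_fit` (carries the bins it used).
#' @return List with `F`, `p`, `df1`, `df2` and `p_floored` (`TRUE` when
#'   the fit SSR hit its numerical floor, making `p` an upper bound).
#' @export
fit_significance_anova <- function(fit) {
  stopifnot(inherits(fit, "ntcp_fit"))
  n <- fit$n_bins_used
  if (n <= 3L) stop("need more than 3 bins for the significance test",
                    call. = FALSE)
  y <- fit$data$response
  ssr_null <- sum((y - mean(y))^2)
  ssr_fit <- fit$ssr
  Fstat <- max((ssr_null - ssr_fit) / (ssr_fit / (n - 2)), 0)
  list(F = Fstat, p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
       df1 = 1L, df2 = n - 2L, p_floored = ssr_fit <= 1e-12)
}

#' One-way ANOVA helper
#'
#' Standard fixed-effects one-way analysis of variance via [stats::aov()].
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (or coercible).
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sm <- summary(stats::aov(values ~ groups))[[1]]
  Fv <- sm$`F value`[1]; pv <- sm$`Pr(>F)`[1]
  if (!is.finite(Fv) && sm$`Sum Sq`[1] <= 1e-20) {
    # identical group means with zero residual variance: no effect
    Fv <- 0; pv <- 1
  }
  list(F = Fv, p = pv, df1 = sm$Df[1], df2 = sm$Df[2])
}

#' Cross-model ANOVA on fitted D50 and gamma50
#'
#' One-way ANOVA across the four model groups, separately for the fitted
#' `d50` and `gamma50` values, over a set of per-patient fits.
#'
#' @param fits_df Data frame with columns `model`, `patient_id`, `d50`,
#'   `gamma50`; every model must be fitted for every patient (>= 2
#'   patients).
#' @return List with `F_d50`, `p_d50`, `F_gamma50`, `p_gamma50`.
#' @export
cross_model_anova <- function(fits_df) {
  need <- c("model", "patient_id", "d50", "gamma50")
  if (!all(need %in% names(fits_df)))
    stop("`fits_df` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- table(fits_df$model, fits_df$patient_id)
  if (ncol(tab) < 2L)
    stop("need fits for at least 2 patients", call. = FALSE)
  if (!setequal(rownames(tab), NTCP_MODELS) || any(tab != 1L))
    stop("missing data: every patient needs exactly one fit per model (",
         paste(NTCP_MODELS, collapse = ", "), ")", call. = FALSE)
  a_d50 <- oneway_anova(fits_df$d50, fits_df$model)
  a_g50 <- oneway_anova(fits_df$gamma50, fits_df$model)
  list(F_d50 = a_d50$F, p_d50 = a_d50$p,
       F_gamma50 = a_g50$F, p_gamma50 = a_g50$p)
}

#' Rank competing model fits by goodness-of-fit criteria
#'
#' Ranks fits by SSR, AIC and BIC (lower is better) and adjusted R^2
#' (higher is better); ties are broken by lexicographic model name, so the
#' ordering is deterministic.
#'
#' @param fits List of `ntcp_fit` objects (>= 2).
#' @return A list of class `model_ranking`: `table` (one row per model,
#'   with per-criterion ranks), `best` (named list of the winner per
#'   criterion) and `consensus` (the single model winning all four
#'   criteria, or `NA`).
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "ntcp_fit")))
  tb <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                   d50 = vapply(fits, `[[`, numeric(1), "d50"),
                   gamma50 = vapply(fits, `[[`, numeric(1), "gamma50"),
                   ssr = vapply(fits, `[[`, numeric(1), "ssr"),
                   adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
                   aic = vapply(fits, `[[`, numeric(1), "aic"),
                   bic = vapply(fits, `[[`, numeric(1), "bic"))
  rank_by <- function(v, decreasing = FALSE) {
    o <- order(if (decreasing) -v else v, tb$model)
    r <- integer(length(v)); r[o] <- seq_along(v); r
  }
  tb$rank_ssr <- rank_by(tb$ssr)
  tb$rank_adj_r2 <- rank_by(tb$adj_r2, decreasing = TRUE)
  tb$rank_aic <- rank_by(tb$aic)
  tb$rank_bic <- rank_by(tb$bic)
  best <- list(ssr = tb$model[which(tb$rank_ssr == 1L)],
               adj_r2 = tb$model[which(tb$rank_adj_r2 == 1L)],
               aic = tb$model[which(tb$rank_aic == 1L)],
               bic = tb$model[which(tb$rank_bic == 1L)])
  consensus <- if (length(unique(unlist(best))) == 1L) best$ssr else NA_character_
  structure(list(table = tb[order(tb$rank_ssr), ], best = best,
                 consensus = consensus),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("<model_ranking>\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat("best by criterion:",
      paste(sprintf("%s=%s", names(x$best), unlist(x$best)), collapse = ", "),
      "\n")
  if (!is.na(x$consensus))
    cat("consensus best model:", x$consensus, "\n")
  invisible(x)
}

#' Full model-comparison report for one curve
#'
#' Fits the requested models, computes per-model fit-significance F tests
#' and the per-criterion ranking.
#'
#' @inheritParams fit_all_models
#' @return List of class `comparison_report`: `fits`, `ranking`,
#'   `significance` (per-model F/p).
#' @export
compare_models <- function(curve, models = NTCP_MODELS, ...) {
  fits <- fit_all_models(curve, models = models, ...)
  sig <- lapply(fits, fit_significance_anova)
  structure(list(fits = fits,
                 ranking = if (length(fits) >= 2L) rank_models(fits),
                 significance = sig),
            class = "comparison_report")
}

#' Serialize fits to a Table-1-style data frame / CSV / JSON
#'
#' Columns mirror the published layout: `model, d50, gamma50, ssr, adj_r2,
#' aic, bic`.
#'
#' @param fits List of `ntcp_fit` objects.
#' @param path Optional CSV path (written when given).
#' @return The data frame, invisibly when writing.
#' @export
fits_table <- function(fits, path = NULL) {
  if (inherits(fits, "ntcp_fit")) fits <- list(fits)
  df <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                   d50 = vapply(fits, `[[`, numeric(1), "d50"),
                   gamma50 = vapply(fits, `[[`, numeric(1), "gamma50"),
                   ssr = vapply(fits, `[[`, numeric(1), "ssr"),
                   adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
                   aic = vapply(fits, `[[`, numeric(1), "aic"),
                   bic = vapply(fits, `[[`, numeric(1), "bic"),
                   n_bins_used = vapply(fits, `[[`, numeric(1), "n_bins_used"),
                   converged = vapply(fits, `[[`, logical(1), "converged"))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
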