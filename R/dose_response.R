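#' Validate acute-assay mortality records
#'
#' Checks a data frame of well-level mortality counts against the schema
#' used throughout the package: `compound`, `conc_mg_L`, `n_exposed`,
#' `n_dead`, `replicate`. Controls are rows with `conc_mg_L == 0`; they
#' are retained but excluded from curve fitting (no background-mortality
#' correction is applied).
#'
#' @param records Data frame with the columns above.
#' @return The validated data frame, invisibly coerced to canonical types.
#' @export
mortality_records <- function(records) {
  need <- c("compound", "conc_mg_L", "n_exposed", "n_dead", "replicate")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  records$conc_mg_L <- as.numeric(records$conc_mg_L)
  # counts are usually integers; fractional values are accepted so that
  # exactly specified proportions can be fitted without rounding
  records$n_exposed <- as.numeric(records$n_exposed)
  records$n_dead <- as.numeric(records$n_dead)
  if (any(records$conc_mg_L < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (any(records$n_exposed < 1))
    stop("n_exposed must be >= 1", call. = FALSE)
  if (any(records$n_dead < 0 | records$n_dead > records$n_exposed))
    stop("n_dead must satisfy 0 <= n_dead <= n_exposed", call. = FALSE)
  records
}

#' Fit a logit-log concentration-response curve
#'
#' Fits the two-parameter logit-log model to well-level mortality counts.
#' Two estimators are exposed:
#' \describe{
#'   \item{`binomial_glm`}{maximum-likelihood binomial regression with a
#'     logit link on log10 concentration (the default).}
#'   \item{`empirical_logit_ols`}{ordinary least squares on
#'     empirical-logit-transformed proportions; boundary proportions (all
#'     dead or all alive in a well) use the adjustment
#'     `(n_dead + 0.5) / (n_exposed + 1)` so the transform is defined.}
#' }
#' Controls (concentration 0) are dropped before fitting. The reported
#' R-squared is always computed on the logit scale, comparing empirical
#' logits of the observed proportions with the fitted linear predictor,
#' so the two methods are directly comparable.
#'
#' @param records Mortality records (see [mortality_records()]).
#' @param method `"binomial_glm"` or `"empirical_logit_ols"`.
#' @return A list of class `dose_response_fit` with elements `curve`
#'   (a [logit_curve()]), `vcov` (2x2 parameter covariance), `r_squared`,
#'   `method`, `converged`, `n_obs` and the input `records`.
#' @examples
#' cv <- logit_curve(-2.239, 5.096)
#' d <- simulate_acute_assay(assay_design(c(1, 1.8, 2.75, 4.5, 8)), cv, seed = 1)
#' fit <- fit_dose_response(d)
#' fit$curve
#' @export
fit_dose_response <- function(records,
                              method = c("binomial_glm", "empirical_logit_ols")) {
  method <- match.arg(method)
  records <- mortality_records(records)
  d <- records[records$conc_mg_L > 0, , drop = FALSE]
  if (length(unique(d$conc_mg_L)) < 3L)
    stop("insufficient design: need >= 3 distinct positive concentrations",
         call. = FALSE)
  p_obs <- d$n_dead / d$n_exposed
  if (all(p_obs == 0) || all(p_obs == 1) || all(p_obs %in% c(0, 1)))
    stop("degenerate response: no intermediate mortality at any concentration",
         call. = FALSE)
  lx <- log10(d$conc_mg_L)
  # boundary-safe logit of the observed proportions (used for R^2 and OLS)
  adj <- p_obs
  bdry <- p_obs == 0 | p_obs == 1
  adj[bdry] <- (d$n_dead[bdry] + 0.5) / (d$n_exposed[bdry] + 1)
  elogit <- stats::qlogis(adj)

  if (method == "binomial_glm") {
    fit <- stats::glm(cbind(d$n_dead, d$n_exposed - d$n_dead) ~ lx,
                      family = stats::binomial())
    ab <- stats::coef(fit)
    V <- stats::vcov(fit)
    converged <- fit$converged
    eta <- ab[1] + ab[2] * lx
  } else {
    fit <- stats::lm(elogit ~ lx)
    ab <- stats::coef(fit)
    # suppressed: summary.lm warns on an exact (noise-free) fit
    V <- suppressWarnings(stats::vcov(fit))
    converged <- TRUE
    eta <- stats::fitted(fit)
  }
  r2 <- 1 - sum((elogit - eta)^2) / sum((elogit - mean(elogit))^2)
  curve <- logit_curve(ab[[1]], ab[[2]],
                       compound = if (length(unique(records$compound)) == 1L)
                         unique(records$compound) else NA_character_)
  dimnames(V) <- list(c("alpha", "beta"), c("alpha", "beta"))
  structure(
    list(curve = curve, vcov = V, r_squared = r2, method = method,
         converged = converged, n_obs = nrow(d), records = records),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose-response fit (%s), %d wells, logit-scale R^2 = %.3f\n",
              x$method, x$n_obs, x$r_squared))
  print(x$curve)
  invisible(x)
}

#' LCx estimate with delta-method uncertainty
#'
#' Inverts a fitted curve at effect level `x` percent and propagates the
#' parameter covariance to the arithmetic concentration scale by the
#' delta method. The 95% confidence interval is symmetric,
#' `value +/- 1.96 * SE`, matching the way acute LC tables are
#' conventionally reported.
#'
#' @param curve A [logit_curve()], or a `dose_response_fit` (in which
#'   case its covariance and R-squared are used automatically).
#' @param x Effect level in percent (e.g. 20 or 50).
#' @param covariance 2x2 covariance of (alpha, beta); ignored when
#'   `curve` is a fit object. Defaults to zero (point estimate only).
#' @return A list of class `lcx_estimate`: `x`, `value` (mg/L), `se`,
#'   `ci95` (length-2), `r_squared` (NA unless a fit was supplied).
#' @export
lc_estimate <- function(curve, x, covariance = matrix(0, 2, 2)) {
  r2 <- NA_real_
  if (inherits(curve, "dose_response_fit")) {
    covariance <- curve$vcov
    r2 <- curve$r_squared
    curve <- curve$curve
  }
  stopifnot(inherits(curve, "logit_curve"))
  if (x <= 0 || x >= 100)
    stop("effect level x must be in (0, 100) percent", call. = FALSE)
  if (curve$beta <= 0)
    stop("non-monotone curve: beta must be > 0", call. = FALSE)
  covariance <- as.matrix(covariance)
  stopifnot(all(dim(covariance) == c(2L, 2L)))
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    stop("covariance must be positive semi-definite", call. = FALSE)
  value <- lc_value(curve, x)
  L <- stats::qlogis(x / 100)
  # gradient of 10^((L - alpha)/beta) wrt (alpha, beta)
  grad <- value * log(10) * c(-1 / curve$beta,
                              -(L - curve$alpha) / curve$beta^2)
  se <- sqrt(drop(t(grad) %*% covariance %*% grad))
  structure(
    list(x = x, value = value, se = se,
         ci95 = c(value - 1.96 * se, value + 1.96 * se),
         r_squared = r2),
    class = "lcx_estimate"
  )
}

#' @export
print.lcx_estimate <- function(x, ...) {
  cat(sprintf("LC%g = %.4g +/- %.3g mg/L (95%% CI %.4g-%.4g)\n",
              x$x, x$value, x$se, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Table of LCx estimates for one or more fitted compounds
#'
#' Convenience wrapper producing the conventional acute-toxicity summary
#' table (one row per compound and effect level).
#'
#' @param fits A named list of `dose_response_fit` objects.
#' @param levels Effect levels in percent.
#' @return Data frame with columns `compound`, `parameter`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `r_squared`.
#' @export
lc_table <- function(fits, levels = c(20, 50)) {
  stopifnot(is.list(fits), length(fits) > 0)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    do.call(rbind, lapply(levels, function(x) {
      e <- lc_estimate(f, x)
      data.frame(compound = nm, parameter = sprintf("LC%g", x),
                 estimate = e$value, se = e$se,
                 ci_low = e$ci95[1], ci_high = e$ci95[2],
                 r_squared = e$r_squared)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
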