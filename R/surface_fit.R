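#' Fit a response-surface model to mixture data
#'
#' Least-squares fit of a CA or IA surface (optionally with a deviation
#' function) to observed mixture mortality fractions. The free
#' parameters are the deviation parameters implied by `form` plus,
#' when `refit_curves = TRUE`, the four single-compound curve parameters
#' (alpha, beta per component). Minimising the squared-error sum is
#' equivalent to maximising the Gaussian log-likelihood with a common
#' error variance, which is how the reported `loglik` is computed.
#'
#' To avoid local minima the deviation parameters are multi-started from
#' a 5x5 grid on \[-10, 10\] (plus any user-supplied starts) and refined
#' with derivative-free Nelder-Mead (Brent line search for one free
#' parameter); curve parameters always start at `curve_a`/`curve_b`.
#'
#' @param data Data frame with columns `c1`, `c2` (mg/L) and `obs`
#'   (mortality fraction in \[0, 1\]); optional `weight`.
#' @param reference `"CA"` or `"IA"`.
#' @param form Deviation form, see [deviation_spec()].
#' @param curve_a,curve_b Starting (or fixed) single-compound curves.
#' @param refit_curves Refit the curve parameters jointly with the
#'   deviation? Default `FALSE` (two-stage: curves taken as given).
#' @param extra_starts Optional list of numeric starting vectors for the
#'   free parameters (used to chain fits along the model ladder).
#' @return Object of class `surface_fit`: `model` (fitted
#'   [surface_model()]), `par`, `n_par`, `sse`, `loglik`, `r_squared`,
#'   `n_obs`, `converged`, `reference`, `form`, `refit_curves`, `data`.
#' @export
fit_surface <- function(data, reference = c("CA", "IA"),
                        form = c("none", "SA", "DR", "DL"),
                        curve_a, curve_b, refit_curves = FALSE,
                        extra_starts = list()) {
  reference <- match.arg(reference)
  form <- match.arg(form)
  stopifnot(is.data.frame(data), all(c("c1", "c2", "obs") %in% names(data)))
  if (nrow(data) == 0L) stop("empty data", call. = FALSE)
  if (any(data$obs < 0 | data$obs > 1))
    stop("obs must be mortality fractions in [0, 1]", call. = FALSE)
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  n <- nrow(data)
  n_dev <- switch(form, none = 0L, SA = 1L, DR = 2L, DL = 2L)
  n_par <- n_dev + if (refit_curves) 4L else 0L
  if (n - n_par < 2L)
    stop("need at least 2 more observations than free parameters",
         call. = FALSE)
  sst <- sum(w * (data$obs - stats::weighted.mean(data$obs, w))^2)
  if (sst == 0) stop("constant response: SStot is zero", call. = FALSE)

  build <- function(par) {
    dev <- switch(form,
                  none = deviation_spec("none"),
                  SA   = deviation_spec("SA", a = par[1]),
                  DR   = deviation_spec("DR", a = par[1], b = par[2]),
                  DL   = deviation_spec("DL", a = par[1], b = par[2]))
    if (refit_curves) {
      cp <- par[(n_dev + 1):(n_dev + 4)]
      ca <- logit_curve(cp[1], cp[2], compound = curve_a$compound)
      cb <- logit_curve(cp[3], cp[4], compound = curve_b$compound)
    } else {
      ca <- curve_a; cb <- curve_b
    }
    surface_model(reference, ca, cb, dev)
  }
  objective <- function(par) {
    # deviation parameters live on an O(1-10) scale; walling the box off
    # keeps the optimizer from escaping along degenerate a*b ridges
    if (n_dev > 0L && any(abs(par[seq_len(n_dev)]) > 100)) return(1e10)
    m <- tryCatch(build(par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    pred <- tryCatch(surface_predict(m, data$c1, data$c2),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e10)
    sum(w * (data$obs - pred)^2)
  }

  curve_start <- if (refit_curves)
    c(curve_a$alpha, curve_a$beta, curve_b$alpha, curve_b$beta) else numeric(0)
  dev_grid <- switch(form,
                     none = list(numeric(0)),
                     SA   = as.list(seq(-10, 10, by = 5)),
                     {
                       g <- expand.grid(a = seq(-10, 10, by = 5),
                                        b = seq(-10, 10, by = 5))
                       lapply(seq_len(nrow(g)), function(i) c(g$a[i], g$b[i]))
                     })
  starts <- lapply(dev_grid, function(d) c(d, curve_start))
  starts <- c(starts, extra_starts[lengths(extra_starts) == n_par])

  best <- NULL
  if (n_par == 0L) {
    best <- list(par = numeric(0), value = objective(numeric(0)),
                 convergence = 0L)
  } else if (n_par == 1L) {
    # single free deviation parameter: Brent over the whole start span,
    # refined locally around any user-supplied start
    best <- stats::optim(0, objective, method = "Brent",
                         lower = -30, upper = 30,
                         control = list(reltol = 1e-12))
    for (s in extra_starts[lengths(extra_starts) == 1L]) {
      res <- tryCatch(stats::optim(s, objective, method = "Brent",
                                   lower = s - 5, upper = s + 5,
                                   control = list(reltol = 1e-12)),
                      error = function(e) NULL)
      if (!is.null(res) && res$value < best$value) best <- res
    }
  } else {
    # screen the start grid by objective value, refine the leaders
    vals <- vapply(starts, objective, numeric(1))
    keep <- unique(c(order(vals)[seq_len(min(6L, length(starts)))],
                     which(vals < min(vals) * 1.0001)))
    for (s in starts[keep]) {
      res <- tryCatch(stats::optim(s, objective, method = "Nelder-Mead",
                                   control = list(maxit = 1000,
                                                  reltol = 1e-12)),
                      error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    # polish the winner from its own solution
    res <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-13))
    if (res$value <= best$value) best <- res
  }
  sse <- best$value
  model <- build(best$par)
  sigma2 <- sse / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(
    list(model = model, par = best$par, n_par = n_par, sse = sse,
         loglik = loglik, r_squared = 1 - sse / sst, n_obs = n,
         converged = !is.null(best$convergence) && best$convergence == 0L,
         reference = reference, form = form, refit_curves = refit_curves,
         data = data),
    class = "surface_fit"
  )
}

#' @export
print.surface_fit <- function(x, ...) {
  dv <- x$model$deviation
  tag <- if (x$form == "none") x$reference else paste0(x$reference, "/", x$form)
  cat(sprintf("%s fit: n = %d, SSE = %.5g, R^2 = %.3f%s\n", tag, x$n_obs,
              x$sse, x$r_squared,
              if (x$form == "none") "" else
                sprintf(", a = %.4g%s", dv$a,
                        if (x$form %in% c("DR", "DL"))
                          sprintf(", b = %.4g", dv$b) else "")))
  if (!x$converged) cat("  warning: optimizer did not report convergence\n")
  invisible(x)
}

# ladder order used to decide nesting
.form_rank <- c(none = 0L, SA = 1L, DR = 2L, DL = 2L)

.is_nested <- function(parent, child) {
  if (parent$reference != child$reference) return(FALSE)
  if (parent$refit_curves != child$refit_curves) return(FALSE)
  pf <- parent$form; cf <- child$form
  if (.form_rank[[pf]] >= .form_rank[[cf]]) return(FALSE)
  pf == "none" || (pf == "SA" && cf %in% c("DR", "DL"))
}

#' Chi-squared likelihood-ratio test between nested surface fits
#'
#' Compares a parent surface model with a child that adds deviation
#' parameters, on the same data, using the statistic
#' \deqn{\chi^2 = n \ln(SSE_{parent} / SSE_{child})}
#' referred to a chi-squared distribution with degrees of freedom equal
#' to the number of added parameters. A child fitting worse than its
#' parent (numerically possible only through optimizer failure) is
#' floored at zero with a warning.
#'
#' @param parent,child `surface_fit` objects; `child` must nest `parent`
#'   (reference = reference, deviation ladder none -> SA -> DR/DL).
#' @return Object of class `surface_lrt`: `chi2`, `df`, `p_value`,
#'   `parent`, `child`.
#' @export
likelihood_ratio_test <- function(parent, child) {
  stopifnot(inherits(parent, "surface_fit"), inherits(child, "surface_fit"))
  if (!.is_nested(parent, child))
    stop("not nested: parent must be an ancestor of child on the same data",
         call. = FALSE)
  if (!isTRUE(all.equal(parent$data[c("c1", "c2", "obs")],
                        child$data[c("c1", "c2", "obs")],
                        check.attributes = FALSE)))
    stop("not nested: fits use different data", call. = FALSE)
  df <- child$n_par - parent$n_par
  n <- parent$n_obs
  if (child$sse > parent$sse) {
    warning("child SSE exceeds parent SSE; chi-squared floored at 0")
    chi2 <- 0
  } else {
    chi2 <- n * log(parent$sse / child$sse)
  }
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 parent = parent, child = child),
            class = "surface_lrt")
}

#' @export
print.surface_lrt <- function(x, ...) {
  ptag <- function(f) if (f$form == "none") f$reference else
    paste0(f$reference, "/", f$form)
  cat(sprintf("LR test %s vs %s: chi2 = %.4g (df %d), p = %.3g\n",
              ptag(x$parent), ptag(x$child), x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Deviation-model selection ladder for one reference
#'
#' Fits the reference surface and its three deviation extensions
#' (S/A, DR, DL), chaining starting values down the ladder so nested
#' models can never fit worse than their parents, and reports the
#' likelihood-ratio comparisons reference-vs-each and S/A-vs-{DR, DL}.
#' The `best` element walks the ladder at level `alpha`: the S/A
#' deviation is accepted over the reference if its LR test is
#' significant, and a two-parameter form is accepted only when it
#' significantly improves on both the reference and S/A (taking the
#' lower-SSE form when DR and DL both qualify). Requiring a win over
#' every ancestor keeps a dose-ratio interaction that averages to a null
#' S/A term selectable without making S/A a hard gate.
#'
#' @inheritParams fit_surface
#' @param alpha Significance level for the ladder walk.
#' @return Object of class `surface_selection`: `fits` (named list:
#'   reference, SA, DR, DL), `comparisons` (data frame of LR tests),
#'   `table` (Table-style summary: model, a, b, R^2, p vs reference,
#'   p vs S/A), `best` (name of the selected model), `reference`.
#' @examples
#' \donttest{
#' tab <- coleps_mixture_table("Cd+Zn")
#' dat <- data.frame(c1 = tab$tu_a * 2.75, c2 = tab$tu_b * 20.42,
#'                   obs = tab$obs_mean_pct / 100)
#' sel <- model_selection(dat, "IA", coleps_curve("Cd"), coleps_curve("Zn"))
#' sel$table
#' }
#' @export
model_selection <- function(data, reference = c("CA", "IA"),
                            curve_a, curve_b, refit_curves = FALSE,
                            alpha = 0.05) {
  reference <- match.arg(reference)
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("empty data", call. = FALSE)
  ref_fit <- fit_surface(data, reference, "none", curve_a, curve_b,
                         refit_curves = refit_curves)
  # chain: children start from the parent's solution
  ca0 <- if (refit_curves) ref_fit$par else numeric(0)
  sa_fit <- fit_surface(data, reference, "SA", curve_a, curve_b,
                        refit_curves = refit_curves,
                        extra_starts = list(c(0, ca0)))
  sa_par <- sa_fit$par
  two_starts <- list(c(0, 0, ca0), c(sa_par[1], 0,
                                     if (refit_curves) sa_par[-1] else NULL))
  dr_fit <- fit_surface(data, reference, "DR", curve_a, curve_b,
                        refit_curves = refit_curves, extra_starts = two_starts)
  dl_fit <- fit_surface(data, reference, "DL", curve_a, curve_b,
                        refit_curves = refit_curves, extra_starts = two_starts)
  fits <- list(reference = ref_fit, SA = sa_fit, DR = dr_fit, DL = dl_fit)

  cmp <- list(
    ref_SA = likelihood_ratio_test(ref_fit, sa_fit),
    ref_DR = likelihood_ratio_test(ref_fit, dr_fit),
    ref_DL = likelihood_ratio_test(ref_fit, dl_fit),
    SA_DR  = likelihood_ratio_test(sa_fit, dr_fit),
    SA_DL  = likelihood_ratio_test(sa_fit, dl_fit)
  )
  comparisons <- do.call(rbind, lapply(names(cmp), function(nm) {
    x <- cmp[[nm]]
    data.frame(comparison = nm, chi2 = x$chi2, df = x$df,
               p_value = x$p_value)
  }))

  getp <- function(f, i) if (f$n_par >= i) f$par[i] else NA_real_
  table <- data.frame(
    model = c(reference, paste0(reference, c("/SA", "/DR", "/DL"))),
    a = c(NA, getp(sa_fit, 1), getp(dr_fit, 1), getp(dl_fit, 1)),
    b = c(NA, NA, getp(dr_fit, 2), getp(dl_fit, 2)),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    p_vs_reference = c(NA, cmp$ref_SA$p_value, cmp$ref_DR$p_value,
                       cmp$ref_DL$p_value),
    p_vs_SA = c(NA, NA, cmp$SA_DR$p_value, cmp$SA_DL$p_value)
  )
  rownames(table) <- NULL

  # a model is accepted only if it significantly improves on every
  # ancestor: two-parameter forms must beat both the reference and S/A
  best <- "reference"
  if (cmp$ref_SA$p_value < alpha) best <- "SA"
  qual <- c(DR = cmp$SA_DR$p_value < alpha && cmp$ref_DR$p_value < alpha,
            DL = cmp$SA_DL$p_value < alpha && cmp$ref_DL$p_value < alpha)
  if (any(qual)) {
    sig <- names(qual)[qual]
    best <- sig[which.min(vapply(fits[sig], `[[`, numeric(1), "sse"))]
  }
  structure(list(fits = fits, comparisons = comparisons, table = table,
                 best = best, reference = reference, alpha = alpha),
            class = "surface_selection")
}

#' @export
print.surface_selection <- function(x, ...) {
  cat(sprintf("%s-based deviation-model ladder (best: %s)\n",
              x$reference, x$best))
  tab <- x$table
  tab$a <- signif(tab$a, 4); tab$b <- signif(tab$b, 4)
  tab$r_squared <- round(tab$r_squared, 3)
  tab$p_vs_reference <- signif(tab$p_vs_reference, 3)
  tab$p_vs_SA <- signif(tab$p_vs_SA, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
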