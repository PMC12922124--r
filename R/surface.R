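#' Deviation function specification
#'
#' Parametric deviation from a CA or IA reference surface. The deviation
#' value G is computed from the toxic-unit fractions `z1`, `z2`
#' (`z1 + z2 = 1`) and, for the dose-level form, the total toxic-unit
#' level of the mixture:
#' \describe{
#'   \item{`none`}{G = 0 (the reference itself).}
#'   \item{`SA`}{synergism/antagonism, G = a z1 z2.}
#'   \item{`DR`}{dose-ratio dependent, G = (a + b z1) z1 z2.}
#'   \item{`DL`}{dose-level dependent, G = a z1 z2 (1 - b TUtot), so the
#'     interaction changes sign where b TUtot = 1.}
#' }
#' Under both references the sign convention makes `a < 0` synergistic
#' and `a > 0` antagonistic; `a = b = 0` recovers the reference exactly.
#'
#' @param form One of `"none"`, `"SA"`, `"DR"`, `"DL"`.
#' @param a,b Interaction parameters (`b` unused for `none`/`SA`).
#' @return Object of class `deviation_spec`.
#' @export
deviation_spec <- function(form = c("none", "SA", "DR", "DL"), a = 0, b = 0) {
  form <- match.arg(form)
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (form %in% c("none", "SA")) b <- 0
  if (form == "none") a <- 0
  structure(list(form = form, a = a, b = b), class = "deviation_spec")
}

#' Evaluate a deviation function
#'
#' @param spec A [deviation_spec()].
#' @param z1,z2 Toxic-unit fractions of the two components; must sum to
#'   1 (tolerance 1e-9). Vectors allowed.
#' @param tu_total Total toxic units of the mixture (used by `DL` only).
#' @return G (dimensionless, same length as `z1`).
#' @examples
#' deviation_g(deviation_spec("SA", a = 2), 0.5, 0.5)  # 0.5
#' @export
deviation_g <- function(spec, z1, z2, tu_total = 0) {
  stopifnot(inherits(spec, "deviation_spec"))
  if (any(z1 < 0) || any(z2 < 0) || any(abs(z1 + z2 - 1) > 1e-9))
    stop("invalid toxic-unit fractions: z1, z2 must be >= 0 and sum to 1",
         call. = FALSE)
  switch(spec$form,
         none = rep(0, length(z1)),
         SA   = spec$a * z1 * z2,
         DR   = (spec$a + spec$b * z1) * z1 * z2,
         DL   = spec$a * z1 * z2 * (1 - spec$b * tu_total))
}

#' Binary mixture response-surface model
#'
#' Couples two single-compound logit-log curves through a Concentration
#' Addition (CA) or Independent Action (IA) reference, optionally
#' perturbed by a [deviation_spec()]. CA treats the components as
#' dilutions of one another: the mixture effect F solves
#' \deqn{c_1/EC_1(F) + c_2/EC_2(F) = e^G.}
#' IA multiplies survival probabilities; with a deviation the survival
#' product is raised to the power `exp(-G)`:
#' \deqn{F = 1 - [(1-F_1(c_1))(1-F_2(c_2))]^{e^{-G}}.}
#' In both cases the toxic-unit fractions feeding G are evaluated at the
#' mixture's own effect level, `z_i = (c_i/EC_i(F)) / \sum_j c_j/EC_j(F)`,
#' and the dose level for the DL form is
#' `TUtot = c1/LC50_1 + c2/LC50_2` with the curve-implied LC50s.
#'
#' @param reference `"CA"` or `"IA"`.
#' @param curve_a,curve_b [logit_curve()] objects for the two components
#'   (order matters for the DR asymmetry parameter, which attaches to
#'   component a's toxic-unit fraction).
#' @param deviation A [deviation_spec()].
#' @return Object of class `surface_model`.
#' @export
surface_model <- function(reference = c("CA", "IA"), curve_a, curve_b,
                          deviation = deviation_spec("none")) {
  reference <- match.arg(reference)
  stopifnot(inherits(curve_a, "logit_curve"), inherits(curve_b, "logit_curve"),
            inherits(deviation, "deviation_spec"))
  if (curve_a$beta <= 0 || curve_b$beta <= 0)
    stop("surface models require increasing curves (beta > 0)", call. = FALSE)
  structure(list(reference = reference, curves = list(curve_a, curve_b),
                 deviation = deviation),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  dv <- x$deviation
  tag <- if (dv$form == "none") x$reference
         else sprintf("%s/%s (a = %.4g%s)", x$reference, dv$form, dv$a,
                      if (dv$form %in% c("DR", "DL"))
                        sprintf(", b = %.4g", dv$b) else "")
  cat("response surface:", tag, "\n")
  invisible(x)
}

# effect concentration of curve i at level F (inverse logit-log)
.ec_at <- function(curve, f) {
  f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
  10^((stats::qlogis(f) - curve$alpha) / curve$beta)
}

# marginal mortality, defined as 0 at zero concentration
.marginal <- function(curve, conc) {
  out <- numeric(length(conc))
  pos <- conc > 0
  out[pos] <- stats::plogis(curve$alpha + curve$beta * log10(conc[pos]))
  out
}

.clamp_g <- function(g) pmin(pmax(g, -50), 50)

# total toxic units of a concentration pair under the model's curves
.tu_total <- function(model, c1, c2) {
  c1 / lc_value(model$curves[[1]], 50) + c2 / lc_value(model$curves[[2]], 50)
}

# vectorised CA solve: F such that c1/EC1(F) + c2/EC2(F) = exp(G(z(F))),
# by bisection on F in [1e-9, 1-1e-9]. The toxic-unit sum is decreasing
# in F, so endpoints of one sign mean the solution saturates at a bound.
.ca_solve <- function(model, c1, c2, tu_tot) {
  cv1 <- model$curves[[1]]; cv2 <- model$curves[[2]]
  h <- function(f) {
    t1 <- c1 / .ec_at(cv1, f)
    t2 <- c2 / .ec_at(cv2, f)
    s <- t1 + t2
    g <- .clamp_g(deviation_g(model$deviation, t1 / s, t2 / s, tu_tot))
    s - exp(g)
  }
  n <- length(c1)
  lo <- rep(1e-9, n); hi <- rep(1 - 1e-9, n)
  f_lo <- h(lo); f_hi <- h(hi)
  if (any(!is.finite(f_lo)) || any(!is.finite(f_hi)))
    stop("no surface solution: response function not finite on the bracket",
         call. = FALSE)
  at_lo <- f_lo <= 0   # even a vanishing effect over-satisfies the sum
  at_hi <- f_hi >= 0   # saturated: full effect
  for (i in 1:48) {
    mid <- (lo + hi) / 2
    up <- h(mid) > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  out <- (lo + hi) / 2
  out[at_lo] <- 1e-9
  out[at_hi] <- 1 - 1e-9
  out
}

#' Concentration Addition surface prediction
#'
#' Predicted mixture mortality fraction under the CA reference (with the
#' model's deviation, if any). With one concentration zero this reduces
#' exactly to the single-compound prediction; mixing a compound with
#' itself reproduces its own curve at the summed concentration (the
#' sham-combination identity).
#'
#' @param model A [surface_model()] with `reference = "CA"`.
#' @param c1,c2 Component concentrations in mg/L (vectors allowed).
#' @return Mortality fraction(s) in (0, 1).
#' @export
ca_predict <- function(model, c1, c2) {
  stopifnot(inherits(model, "surface_model"), model$reference == "CA")
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  if (any(c1 < 0) || any(c2 < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (any(c1 == 0 & c2 == 0))
    stop("CA surface undefined at (0, 0)", call. = FALSE)
  tu_tot <- .tu_total(model, c1, c2)
  out <- numeric(n)
  only_a <- c2 == 0; only_b <- c1 == 0
  mix <- !only_a & !only_b
  out[only_a] <- .marginal(model$curves[[1]], c1[only_a])
  out[only_b] <- .marginal(model$curves[[2]], c2[only_b])
  if (any(mix))
    out[mix] <- .ca_solve(model, c1[mix], c2[mix], tu_tot[mix])
  out
}

#' Independent Action surface prediction
#'
#' Predicted mixture mortality fraction under the IA reference (with the
#' model's deviation, if any). The deviation enters as a power on the
#' survival product, `exp(-G)`, and the toxic-unit fractions for G are
#' evaluated at the IA-predicted effect level by fixed-point iteration.
#'
#' @inheritParams ca_predict
#' @param model A [surface_model()] with `reference = "IA"`.
#' @return Mortality fraction(s) in [0, 1).
#' @export
ia_predict <- function(model, c1, c2) {
  stopifnot(inherits(model, "surface_model"), model$reference == "IA")
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  if (any(c1 < 0) || any(c2 < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  cv1 <- model$curves[[1]]; cv2 <- model$curves[[2]]
  surv <- (1 - .marginal(cv1, c1)) * (1 - .marginal(cv2, c2))
  f <- 1 - surv
  if (model$deviation$form == "none") return(f)
  tu_tot <- .tu_total(model, c1, c2)
  mix <- c1 > 0 & c2 > 0  # G vanishes on the margins (z1 z2 = 0)
  if (!any(mix)) return(f)
  fm <- f[mix]
  for (iter in 1:200) {
    t1 <- c1[mix] / .ec_at(cv1, fm)
    t2 <- c2[mix] / .ec_at(cv2, fm)
    g <- .clamp_g(deviation_g(model$deviation, t1 / (t1 + t2),
                              t2 / (t1 + t2), tu_tot[mix]))
    f_new <- 1 - surv[mix]^exp(-g)
    if (max(abs(f_new - fm)) < 1e-12) { fm <- f_new; break }
    fm <- 0.5 * fm + 0.5 * f_new  # damped for stability at strong deviations
  }
  f[mix] <- fm
  f
}

#' Predict from a response-surface model
#'
#' Dispatches to [ca_predict()] or [ia_predict()] by the model's
#' reference.
#'
#' @inheritParams ca_predict
#' @export
surface_predict <- function(model, c1, c2) {
  if (model$reference == "CA") ca_predict(model, c1, c2)
  else ia_predict(model, c1, c2)
}

#' Evaluate a surface and its deviation over a TU grid
#'
#' Tabulates predicted mortality and the deviation magnitude G over a
#' rectangular toxic-unit grid, for isobologram-style plots and export.
#'
#' @param model A [surface_model()].
#' @param tu_a,tu_b Toxic-unit levels for each component (the grid is
#'   their Cartesian product).
#' @param lc50_a,lc50_b Reference LC50s defining 1 TU per component;
#'   default to the curve-implied LC50s.
#' @return Data frame with columns `tu_a`, `tu_b`, `c1`, `c2`,
#'   `predicted`, `g`.
#' @export
surface_grid <- function(model, tu_a, tu_b,
                         lc50_a = lc_value(model$curves[[1]], 50),
                         lc50_b = lc_value(model$curves[[2]], 50)) {
  stopifnot(all(tu_a >= 0), all(tu_b >= 0))
  grid <- expand.grid(tu_a = tu_a, tu_b = tu_b, KEEP.OUT.ATTRS = FALSE)
  grid$c1 <- grid$tu_a * lc50_a
  grid$c2 <- grid$tu_b * lc50_b
  keep <- !(grid$c1 == 0 & grid$c2 == 0 & model$reference == "CA")
  grid <- grid[keep, , drop = FALSE]
  grid$predicted <- surface_predict(model, grid$c1, grid$c2)
  # deviation magnitude at the predicted effect level
  g <- numeric(nrow(grid))
  mix <- grid$c1 > 0 & grid$c2 > 0
  if (any(mix)) {
    t1 <- grid$c1[mix] / .ec_at(model$curves[[1]], grid$predicted[mix])
    t2 <- grid$c2[mix] / .ec_at(model$curves[[2]], grid$predicted[mix])
    g[mix] <- deviation_g(model$deviation, t1 / (t1 + t2), t2 / (t1 + t2),
                          .tu_total(model, grid$c1[mix], grid$c2[mix]))
  }
  grid$g <- g
  rownames(grid) <- NULL
  grid
}
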