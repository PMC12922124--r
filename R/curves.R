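#' Two-parameter logit-log concentration-response curve
#'
#' Constructs a `logit_curve`: mortality fraction is modelled as
#' \deqn{F(c) = 1 / (1 + \exp(-(\alpha + \beta \log_{10} c)))}
#' with intercept `alpha` and slope `beta` per decade of concentration
#' (mg/L). `beta > 0` for a toxicant (mortality increases with
#' concentration).
#'
#' @param alpha Intercept on the logit scale (dimensionless).
#' @param beta Slope per log10(mg/L); must be finite and non-zero.
#' @param compound Optional compound label carried along for reporting.
#' @return An object of class `logit_curve`.
#' @examples
#' cv <- logit_curve(-2.239, 5.096, compound = "Cd")
#' predict_mortality(cv, 2.75)
#' @export
logit_curve <- function(alpha, beta, compound = NA_character_) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  structure(
    list(alpha = unname(alpha), beta = unname(beta),
         compound = as.character(compound)),
    class = "logit_curve"
  )
}

#' @export
print.logit_curve <- function(x, ...) {
  lab <- if (is.na(x$compound)) "" else paste0(" [", x$compound, "]")
  cat(sprintf("logit-log curve%s: alpha = %.4f, beta = %.4f (per log10 mg/L)\n",
              lab, x$alpha, x$beta))
  if (x$beta > 0)
    cat(sprintf("  LC50 = %.4g mg/L\n", lc_value(x, 50)))
  invisible(x)
}

#' Predicted mortality fraction at a concentration
#'
#' Evaluates the fitted logit-log curve. Returns a value strictly inside
#' (0, 1) for any finite positive concentration.
#'
#' @param curve A [logit_curve()].
#' @param concentration Concentration(s) in mg/L; must be > 0.
#' @return Mortality fraction(s) in (0, 1).
#' @export
predict_mortality <- function(curve, concentration) {
  stopifnot(inherits(curve, "logit_curve"))
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("invalid concentration: must be finite and > 0", call. = FALSE)
  stats::plogis(curve$alpha + curve$beta * log10(concentration))
}

#' Effect concentration (LCx) implied by a curve
#'
#' Inverts the logit-log curve at effect level `x` percent:
#' `10^((logit(x/100) - alpha) / beta)`.
#'
#' @param curve A [logit_curve()].
#' @param x Effect level in percent, strictly between 0 and 100.
#' @return Concentration in mg/L.
#' @export
lc_value <- function(curve, x) {
  stopifnot(inherits(curve, "logit_curve"))
  if (any(x <= 0) || any(x >= 100))
    stop("effect level x must be in (0, 100) percent", call. = FALSE)
  if (curve$beta <= 0)
    stop("non-monotone curve: beta must be > 0 for LC estimation",
         call. = FALSE)
  10^((stats::qlogis(x / 100) - curve$alpha) / curve$beta)
}

#' Reconstruct a logit-log curve from two published LC points
#'
#' Solves for the unique (alpha, beta) passing through two effect
#' concentrations, e.g. a reported (LC20, LC50) pair. This is how
#' single-compound curves are rebuilt when only summary LC values are
#' published:
#' \deqn{\beta = \frac{logit(p_b) - logit(p_a)}{\log_{10} c_b - \log_{10} c_a}}
#'
#' @param lc_a,lc_b Numeric pairs `c(effect_percent, concentration_mg_L)`.
#'   Effect levels and concentrations must be distinct, with the higher
#'   effect at the higher concentration.
#' @param compound Optional compound label.
#' @return A [logit_curve()].
#' @examples
#' cd <- curve_from_lcs(c(20, 1.47), c(50, 2.75), compound = "Cd")
#' lc_value(cd, 50)  # 2.75 back
#' @export
curve_from_lcs <- function(lc_a, lc_b, compound = NA_character_) {
  stopifnot(length(lc_a) == 2L, length(lc_b) == 2L)
  xa <- lc_a[[1]]; ca <- lc_a[[2]]
  xb <- lc_b[[1]]; cb <- lc_b[[2]]
  if (xa <= 0 || xa >= 100 || xb <= 0 || xb >= 100)
    stop("effect levels must be in (0, 100) percent", call. = FALSE)
  if (ca <= 0 || cb <= 0)
    stop("concentrations must be > 0", call. = FALSE)
  if (xa == xb || ca == cb)
    stop("underdetermined: need two distinct (effect, concentration) points",
         call. = FALSE)
  if (sign(xb - xa) != sign(cb - ca))
    stop("non-monotone input: higher effect must occur at higher concentration",
         call. = FALSE)
  la <- stats::qlogis(xa / 100)
  lb <- stats::qlogis(xb / 100)
  beta <- (lb - la) / (log10(cb) - log10(ca))
  alpha <- la - beta * log10(ca)
  logit_curve(alpha, beta, compound = compound)
}
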