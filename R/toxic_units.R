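#' Toxic Unit component
#'
#' Binds a compound's concentration-response curve to its reference
#' LC50, which defines 1 Toxic Unit (TU): a mixture component dosed at
#' `tu` TU is at concentration `tu * lc50_ref` mg/L. By construction the
#' curve must predict approximately 50% mortality at `lc50_ref`.
#'
#' @param curve A [logit_curve()].
#' @param lc50_ref Reference LC50 in mg/L defining 1 TU. Defaults to the
#'   LC50 implied by the curve itself.
#' @param compound Optional label (defaults to the curve's).
#' @return An object of class `tu_component`.
#' @examples
#' tu_component(coleps_curve("Cd"))
#' @export
tu_component <- function(curve, lc50_ref = lc_value(curve, 50),
                         compound = curve$compound) {
  stopifnot(inherits(curve, "logit_curve"))
  if (!is.numeric(lc50_ref) || length(lc50_ref) != 1L || lc50_ref <= 0)
    stop("lc50_ref must be a single positive concentration", call. = FALSE)
  if (abs(predict_mortality(curve, lc50_ref) - 0.5) > 0.01)
    stop("curve does not predict ~50% mortality at lc50_ref", call. = FALSE)
  structure(list(compound = as.character(compound), curve = curve,
                 lc50_ref = lc50_ref),
            class = "tu_component")
}

#' @export
print.tu_component <- function(x, ...) {
  cat(sprintf("TU component %s: 1 TU = %.4g mg/L\n", x$compound, x$lc50_ref))
  invisible(x)
}

#' Convert Toxic Units to concentration
#'
#' @param component A [tu_component()].
#' @param tu Dose in Toxic Units (>= 0).
#' @return Concentration(s) in mg/L (`tu * lc50_ref`).
#' @export
tu_to_concentration <- function(component, tu) {
  stopifnot(inherits(component, "tu_component"))
  if (any(tu < 0)) stop("invalid TU: must be >= 0", call. = FALSE)
  tu * component$lc50_ref
}

#' Expected mixture mortality by effect summation
#'
#' Computes the expected percent mortality of a binary mixture as the
#' sum of the single-compound mortalities at each component's own
#' concentration (`tu_i * lc50_i`), capped at 100%. This is the
#' "effect summation" expectation used to benchmark observed mixture
#' mortality in the TU framework; by construction it reaches exactly
#' 100% whenever both components are at or above 1 TU.
#'
#' @param component_a,component_b [tu_component()] objects.
#' @param tu_a,tu_b Doses in Toxic Units (vectors allowed, recycled).
#' @return Expected mortality in percent (0-100).
#' @examples
#' cd <- tu_component(coleps_curve("Cd"), 2.75)
#' zn <- tu_component(coleps_curve("Zn"), 20.42)
#' expected_mixture_mortality(cd, zn, 0.25, 0.25)  # ~15%
#' @export
expected_mixture_mortality <- function(component_a, component_b, tu_a, tu_b) {
  stopifnot(inherits(component_a, "tu_component"),
            inherits(component_b, "tu_component"))
  if (any(tu_a < 0) || any(tu_b < 0))
    stop("invalid TU: must be >= 0", call. = FALSE)
  n <- max(length(tu_a), length(tu_b))
  tu_a <- rep_len(tu_a, n); tu_b <- rep_len(tu_b, n)
  fa <- ifelse(tu_a > 0,
               predict_mortality(component_a$curve,
                                 pmax(tu_to_concentration(component_a, tu_a),
                                      .Machine$double.xmin)),
               0)
  fb <- ifelse(tu_b > 0,
               predict_mortality(component_b$curve,
                                 pmax(tu_to_concentration(component_b, tu_b),
                                      .Machine$double.xmin)),
               0)
  pmin(100, 100 * (fa + fb))
}

#' Classify a mixture trial as synergistic, antagonistic or neutral
#'
#' One-sample two-sided t-test of the observed replicate mortalities
#' against the effect-summation expected value. Significant excess
#' mortality is called synergism, significant deficit antagonism,
#' anything else no interaction. Accepts either replicate values or a
#' mean/SD/n summary. When the observed mean equals the expected value
#' the call is always `no_interaction`; a zero SD with a non-zero
#' difference is treated as unambiguous evidence (p = 0).
#'
#' @param observed Numeric vector of replicate percent mortalities, or a
#'   single mean when `sd` and `n` are given.
#' @param expected Expected percent mortality (scalar).
#' @param sd,n Summary-statistics path: SD and replicate count.
#' @param alpha Significance level (default 0.05).
#' @return List of class `interaction_call`: `call` (one of
#'   `"synergism"`, `"antagonism"`, `"no_interaction"`), `t`, `df`,
#'   `p_value`, `observed_mean`, `expected`.
#' @examples
#' classify_interaction(42.33, 8, sd = 1.94, n = 3)$call  # synergism
#' @export
classify_interaction <- function(observed, expected, sd = NULL, n = NULL,
                                 alpha = 0.05) {
  stopifnot(length(expected) == 1L, expected >= 0, expected <= 100)
  if (is.null(sd)) {
    n <- length(observed)
    m <- mean(observed)
    s <- stats::sd(observed)
  } else {
    stopifnot(length(observed) == 1L, !is.null(n))
    m <- observed; s <- sd; n <- as.integer(n)
  }
  if (n < 2L) stop("no replication: need n >= 2", call. = FALSE)
  if (s < 0) stop("observed SD must be >= 0", call. = FALSE)
  diff <- m - expected
  if (diff == 0) {
    t_stat <- 0; p <- 1
  } else if (s == 0) {
    t_stat <- sign(diff) * Inf; p <- 0
  } else {
    t_stat <- diff / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  call <- if (p < alpha && diff > 0) "synergism"
          else if (p < alpha && diff < 0) "antagonism"
          else "no_interaction"
  structure(list(call = call, t = t_stat, df = n - 1L, p_value = p,
                 observed_mean = m, expected = expected, alpha = alpha),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("%s (observed %.2f%% vs expected %.2f%%, t = %.3g, p = %.3g)\n",
              x$call, x$observed_mean, x$expected, x$t, x$p_value))
  invisible(x)
}

#' Enumerate a binary Toxic Unit design grid
#'
#' Builds the trial grid from total mixture strengths and the TU splits
#' at each total, checking that each split sums to its stated total.
#'
#' @param total_tus Numeric vector of total TU levels.
#' @param splits List (parallel to `total_tus`) of lists/matrices of
#'   `(tu_a, tu_b)` pairs tested at that total.
#' @return Data frame with columns `total_tu`, `tu_a`, `tu_b`.
#' @examples
#' build_tu_design(1, list(list(c(0.5, 0.5))))
#' @export
build_tu_design <- function(total_tus, splits) {
  stopifnot(length(total_tus) == length(splits))
  rows <- list()
  for (i in seq_along(total_tus)) {
    tot <- total_tus[[i]]
    if (tot < 0) stop("total TU must be >= 0", call. = FALSE)
    for (pr in splits[[i]]) {
      stopifnot(length(pr) == 2L)
      if (any(pr < 0)) stop("TU fractions must be >= 0", call. = FALSE)
      if (abs(sum(pr) - tot) > 1e-9)
        stop(sprintf("inconsistent design: split (%g, %g) does not sum to %g",
                     pr[1], pr[2], tot), call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(total_tu = tot,
                                              tu_a = pr[1], tu_b = pr[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Toxic-Unit mixture analysis table
#'
#' Computes the effect-summation expected mortality for each trial of a
#' binary-mixture table and classifies every row. This reproduces the
#' standard observed-vs-expected mixture summary.
#'
#' @param trials Data frame with columns `tu_a`, `tu_b`, `obs_mean_pct`,
#'   `obs_sd_pct`, `n_reps` (e.g. from [coleps_mixture_table()]).
#' @param component_a,component_b [tu_component()] objects (a first).
#' @param alpha Significance level for the interaction call.
#' @return The input with added columns `expected_pct`, `t`, `p_value`,
#'   `call`.
#' @export
tu_mixture_analysis <- function(trials, component_a, component_b,
                                alpha = 0.05) {
  need <- c("tu_a", "tu_b", "obs_mean_pct", "obs_sd_pct", "n_reps")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  trials$expected_pct <- expected_mixture_mortality(
    component_a, component_b, trials$tu_a, trials$tu_b)
  cls <- lapply(seq_len(nrow(trials)), function(i) {
    classify_interaction(trials$obs_mean_pct[i], trials$expected_pct[i],
                         sd = trials$obs_sd_pct[i], n = trials$n_reps[i],
                         alpha = alpha)
  })
  trials$t <- vapply(cls, `[[`, numeric(1), "t")
  trials$p_value <- vapply(cls, `[[`, numeric(1), "p_value")
  trials$call <- vapply(cls, `[[`, character(1), "call")
  trials
}
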