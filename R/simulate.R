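#' Acute microwell assay design
#'
#' Describes the layout of a single-compound acute test: 100 cells per
#' depression-slide well, 3 wells per concentration within each of 3
#' independent biological replicates, scored for 24 h mortality. These
#' defaults mirror the ciliate microwell bioassay the package models.
#'
#' @param concentrations Test concentrations in mg/L (0 allowed for a
#'   control series).
#' @param cells_per_well Cells seeded per well (default 100).
#' @param wells_per_conc Technical replicate wells per concentration per
#'   biological replicate (default 3).
#' @param bio_replicates Independent biological replicates (default 3).
#' @return Object of class `assay_design`.
#' @export
assay_design <- function(concentrations, cells_per_well = 100,
                         wells_per_conc = 3, bio_replicates = 3) {
  stopifnot(length(concentrations) >= 1, all(concentrations >= 0),
            cells_per_well >= 1, wells_per_conc >= 1, bio_replicates >= 1)
  structure(list(concentrations = as.numeric(concentrations),
                 cells_per_well = as.integer(cells_per_well),
                 wells_per_conc = as.integer(wells_per_conc),
                 bio_replicates = as.integer(bio_replicates)),
            class = "assay_design")
}

#' Simulate a single-compound acute assay
#'
#' Draws well-level death counts from the binomial distribution implied
#' by a logit-log curve: `n_dead ~ Binomial(cells_per_well, F(c))` per
#' well. Controls (concentration 0) yield zero deaths, matching the
#' no-background-mortality convention used throughout. Output is a
#' mortality-record table ready for [fit_dose_response()]. The function
#' is a pure function of `(design, curve, seed)`: the global random
#' state is left untouched and identical seeds give identical tables.
#'
#' @param design An [assay_design()].
#' @param curve Generating [logit_curve()].
#' @param seed Integer seed (mandatory).
#' @return Data frame of mortality records (`compound`, `conc_mg_L`,
#'   `n_exposed`, `n_dead`, `replicate`).
#' @export
simulate_acute_assay <- function(design, curve, seed) {
  stopifnot(inherits(design, "assay_design"), inherits(curve, "logit_curve"),
            is.numeric(seed), length(seed) == 1L)
  grid <- expand.grid(
    well = seq_len(design$wells_per_conc),
    bio = seq_len(design$bio_replicates),
    conc_mg_L = design$concentrations,
    KEEP.OUT.ATTRS = FALSE
  )
  p <- ifelse(grid$conc_mg_L > 0,
              stats::plogis(curve$alpha + curve$beta *
                              log10(pmax(grid$conc_mg_L, 1e-300))),
              0)
  n_dead <- withr::with_seed(as.integer(seed),
                             stats::rbinom(nrow(grid), design$cells_per_well, p))
  data.frame(
    compound = if (is.na(curve$compound)) "simulated" else curve$compound,
    conc_mg_L = grid$conc_mg_L,
    n_exposed = design$cells_per_well,
    n_dead = n_dead,
    replicate = sprintf("b%d_w%d", grid$bio, grid$well)
  )
}

#' Simulate binary-mixture trials around a response surface
#'
#' Generates observed replicate mortalities on a toxic-unit grid from a
#' (possibly deviating) CA/IA surface. Default noise is binomial at the
#' well level: each biological replicate scores `cells_per_rep` cells
#' and reports a percent mortality, which are then summarised as
#' mean +/- SD across replicates — the granularity of a published
#' mixture table. Gaussian noise on the percent scale is available as an
#' alternative.
#'
#' @param design Data frame with columns `tu_a`, `tu_b` (e.g. from
#'   [coleps_tu_design()]); zero rows give an empty result.
#' @param model Generating [surface_model()].
#' @param lc50_a,lc50_b Reference LC50s defining 1 TU per component;
#'   default to the model's curve-implied LC50s.
#' @param n_reps Biological replicates per trial (default 3).
#' @param cells_per_rep Cells scored per replicate (default 300 = 3
#'   wells of 100 cells).
#' @param noise `"binomial"` (default) or `"gaussian"`.
#' @param sd_pct Gaussian noise SD in percent (used only for
#'   `noise = "gaussian"`).
#' @param seed Integer seed (mandatory).
#' @return Data frame: `total_tu`, `tu_a`, `tu_b`, `c1`, `c2`,
#'   `true_pct`, per-replicate columns `rep1..repK`, `obs_mean_pct`,
#'   `obs_sd_pct`, `n_reps`. The generating model is attached as
#'   attribute `truth`.
#' @export
simulate_mixture_dataset <- function(design, model,
                                     lc50_a = lc_value(model$curves[[1]], 50),
                                     lc50_b = lc_value(model$curves[[2]], 50),
                                     n_reps = 3, cells_per_rep = 300,
                                     noise = c("binomial", "gaussian"),
                                     sd_pct = 3, seed) {
  noise <- match.arg(noise)
  stopifnot(inherits(model, "surface_model"),
            all(c("tu_a", "tu_b") %in% names(design)),
            is.numeric(seed), length(seed) == 1L)
  if (nrow(design) == 0L) {
    out <- data.frame(total_tu = numeric(0), tu_a = numeric(0),
                      tu_b = numeric(0), c1 = numeric(0), c2 = numeric(0),
                      true_pct = numeric(0), obs_mean_pct = numeric(0),
                      obs_sd_pct = numeric(0), n_reps = integer(0))
    attr(out, "truth") <- model
    return(out)
  }
  c1 <- design$tu_a * lc50_a
  c2 <- design$tu_b * lc50_b
  f <- surface_predict(model, c1, c2)
  reps <- withr::with_seed(as.integer(seed), {
    if (noise == "binomial")
      matrix(stats::rbinom(nrow(design) * n_reps, cells_per_rep, rep(f, n_reps)),
             nrow = nrow(design)) / cells_per_rep * 100
    else
      matrix(pmin(100, pmax(0, rep(f * 100, n_reps) +
                              stats::rnorm(nrow(design) * n_reps, 0, sd_pct))),
             nrow = nrow(design))
  })
  colnames(reps) <- paste0("rep", seq_len(n_reps))
  out <- data.frame(total_tu = design$tu_a + design$tu_b,
                    tu_a = design$tu_a, tu_b = design$tu_b,
                    c1 = c1, c2 = c2, true_pct = f * 100)
  out <- cbind(out, reps)
  out$obs_mean_pct <- rowMeans(reps)
  out$obs_sd_pct <- apply(reps, 1, stats::sd)
  out$n_reps <- as.integer(n_reps)
  attr(out, "truth") <- model
  out
}

#' Simulate correlated antioxidant biomarker panels
#'
#' Generates one panel per endpoint over a shared treatment list, with
#' treatment-level endpoint means coupled at a target Pearson
#' correlation `rho` (via a Gaussian copula across treatments: every
#' endpoint mean is `rho`-correlated with every other) and independent
#' Gaussian replicate noise within treatments. This emulates the
#' coordinated-response structure of antioxidant endpoint batteries
#' under mixture stress, where strongly coupled endpoints show high
#' pairwise R.
#'
#' @param treatments Character vector of treatment labels (>= 3).
#' @param endpoints Character vector of endpoint labels (>= 2).
#' @param rho Target inter-endpoint correlation of treatment means, in
#'   \[-1, 1\] (a single exchangeable value).
#' @param effect_sd SD of treatment means around `baseline` (signal
#'   scale).
#' @param noise_sd Replicate noise SD within treatments.
#' @param baseline Grand mean of every endpoint.
#' @param replicates Biological replicates per treatment (default 3).
#' @param seed Integer seed (mandatory).
#' @return Named list of [biomarker_panel()] objects (one per endpoint).
#' @export
simulate_biomarker_panel <- function(treatments, endpoints, rho,
                                     effect_sd = 1, noise_sd = 0.1,
                                     baseline = 10, replicates = 3, seed) {
  stopifnot(length(treatments) >= 3L, length(endpoints) >= 2L,
            is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(rho) || length(rho) != 1L || rho < -1 || rho > 1)
    stop("rho must be a correlation in [-1, 1]", call. = FALSE)
  k <- length(endpoints)
  sigma <- matrix(rho, k, k); diag(sigma) <- 1
  if (k > 2L && rho < 0) {
    low <- -1 / (k - 1)  # exchangeable correlation must stay PSD
    if (rho < low)
      stop(sprintf("rho < %.3f is not a valid exchangeable correlation for %d endpoints",
                   low, k), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    mu <- baseline + effect_sd *
      MASS::mvrnorm(length(treatments), mu = rep(0, k), Sigma = sigma)
    colnames(mu) <- endpoints
    stats::setNames(lapply(seq_len(k), function(j) {
      d <- expand.grid(bio_replicate = seq_len(replicates),
                       treatment = treatments, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
      d$value <- rep(mu[, j], each = replicates) +
        stats::rnorm(nrow(d), 0, noise_sd)
      biomarker_panel(d, endpoint = endpoints[j])
    }), endpoints)
  })
}
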