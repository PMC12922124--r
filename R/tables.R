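#' Published 24 h LC values for heavy metals and nanoparticles
#'
#' Acute 24 h LC20/LC50 estimates (mg/L, with SE and symmetric 95% CI)
#' for *Coleps hirtus* exposed to ionic metals (Cu, Zn, Cd) and metal
#' oxide nanoparticles (CuO, ZnO, TiO2), as reported for the microwell
#' bioassay this package models. SiO2 showed no effect up to 60,080 mg/L
#' and has no finite LC values, so it is omitted.
#'
#' @return Data frame with columns `compound`, `parameter` (LC20/LC50),
#'   `estimate`, `se`, `ci_low`, `ci_high`, `r_squared` (per compound).
#' @export
coleps_lc_table <- function() {
  data.frame(
    compound = rep(c("Cu", "Zn", "Cd", "CuO", "ZnO", "TiO2"), each = 2),
    parameter = rep(c("LC20", "LC50"), 6),
    estimate = c(0.87, 1.62, 8.26, 20.42, 1.47, 2.75,
                 256.45, 447.83, 138.72, 356.18, 6487.15, 12879.33),
    se = c(0.05, 0.04, 0.68, 0.89, 0.08, 0.06,
           15.32, 11.94, 9.85, 16.32, 462.25, 405.67),
    ci_low = c(0.77, 1.55, 6.93, 18.68, 1.32, 2.63,
               226.43, 424.43, 119.41, 324.19, 5581.14, 12084.22),
    ci_high = c(0.97, 1.69, 9.59, 22.16, 1.62, 2.87,
                286.47, 471.23, 158.03, 388.17, 7393.16, 13679.44),
    r_squared = rep(c(0.997, 0.987, 0.994, 0.996, 0.993, 0.995), each = 2)
  )
}

#' Reconstruct a published single-compound curve
#'
#' Builds the logit-log curve through the published (LC20, LC50) pair of
#' one compound from [coleps_lc_table()].
#'
#' @param compound One of `"Cu"`, `"Zn"`, `"Cd"`, `"CuO"`, `"ZnO"`,
#'   `"TiO2"`.
#' @return A [logit_curve()].
#' @examples
#' coleps_curve("Cd")
#' @export
coleps_curve <- function(compound) {
  tab <- coleps_lc_table()
  tab <- tab[tab$compound == compound, ]
  if (nrow(tab) != 2L)
    stop("unknown compound: ", compound, call. = FALSE)
  lc20 <- tab$estimate[tab$parameter == "LC20"]
  lc50 <- tab$estimate[tab$parameter == "LC50"]
  curve_from_lcs(c(20, lc20), c(50, lc50), compound = compound)
}

#' The 16-point binary Toxic Unit design
#'
#' The TU grid used for the binary mixture trials: total mixture
#' strengths 0.5-2.0 TU split over the two components in steps of
#' 0.25 TU.
#'
#' @return Data frame with columns `total_tu`, `tu_a`, `tu_b` (16 rows).
#' @export
coleps_tu_design <- function() {
  d <- data.frame(
    tu_a = c(0.25, 0.5, 0.25, 0.75, 0.5, 0.25, 0.75, 0.5, 1, 0.25,
             0.5, 0.75, 1, 1, 0.75, 1),
    tu_b = c(0.25, 0.25, 0.5, 0.25, 0.5, 0.75, 0.5, 0.75, 0.25, 1,
             1, 0.75, 0.5, 0.75, 1, 1)
  )
  cbind(total_tu = d$tu_a + d$tu_b, d)
}

#' Observed binary-mixture cytotoxicity (Cd + Zn and Cd + ZnO)
#'
#' Observed 24 h mortality (mean percent +/- SD over three biological
#' replicates) for the two binary mixtures on the 16-point TU grid, as
#' published, together with the published expected-cytotoxicity column
#' and interaction label. For Cd + ZnO the published expected column is
#' not reproducible by effect summation from the published single curves
#' and should not be used as a numerical reference; the observed column
#' is the data of record.
#'
#' @param pair `"Cd+Zn"` or `"Cd+ZnO"`.
#' @return Data frame with columns `total_tu`, `tu_a`, `tu_b`,
#'   `obs_mean_pct`, `obs_sd_pct`, `n_reps`, `expected_published_pct`,
#'   `label_published`. Component a is Cd throughout.
#' @export
coleps_mixture_table <- function(pair = c("Cd+Zn", "Cd+ZnO")) {
  pair <- match.arg(pair)
  d <- coleps_tu_design()
  if (pair == "Cd+Zn") {
    d$obs_mean_pct <- c(13.00, 27.11, 20.89, 49.56, 34.00, 35.44, 42.56,
                        56.67, 55.00, 66.89, 72.67, 53.00, 60.33, 81.00,
                        87.00, 96.56)
    d$obs_sd_pct <- c(3.04, 1.62, 1.27, 2.60, 1.22, 3.28, 1.33, 2.60,
                      2.80, 2.52, 2.35, 1.00, 1.58, 2.12, 2.74, 2.60)
    d$expected_published_pct <- c(15, 29, 26, 46, 40, 38, 57, 52, 62, 53,
                                  67, 69, 73, 85, 84, 100)
    d$label_published <- c("no_interaction", "no_interaction", "antagonism",
                           "synergism", "antagonism", "no_interaction",
                           "antagonism", "synergism", "antagonism",
                           "synergism", "synergism", "antagonism",
                           "antagonism", "antagonism", "no_interaction",
                           "no_interaction")
  } else {
    d$obs_mean_pct <- c(42.33, 51.67, 74.11, 67.44, 84.56, 100.00, 88.67,
                        100.00, 76.22, 100.00, 100.00, 100.00, 95.11,
                        100.00, 100.00, 100.00)
    d$obs_sd_pct <- c(1.94, 1.87, 1.45, 2.46, 1.42, 0.00, 1.00, 0.00,
                      2.11, 0.00, 0.00, 0.00, 1.27, 0.00, 0.00, 0.00)
    d$expected_published_pct <- c(8, 22, 22, 39, 36, 36, 53, 49, 55, 53,
                                  67, 66, 69, 82, 84, 100)
    d$label_published <- c(rep("synergism", 15), "no_interaction")
  }
  d$n_reps <- 3L
  d[, c("total_tu", "tu_a", "tu_b", "obs_mean_pct", "obs_sd_pct",
        "n_reps", "expected_published_pct", "label_published")]
}
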