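# canonical single-compound curves reconstructed from the published
# (LC20, LC50) pairs; used across the suite
cd_curve <- function() coleps_curve("Cd")
zn_curve <- function() coleps_curve("Zn")
zno_curve <- function() coleps_curve("ZnO")

cd_component <- function() tu_component(cd_curve(), 2.75)
zn_component <- function() tu_component(zn_curve(), 20.42)
zno_component <- function() tu_component(zno_curve(), 356.18)

# mixture observations as surface-fit input (fractions, concentrations)
mixture_fit_data <- function(pair = "Cd+Zn") {
  tab <- coleps_mixture_table(pair)
  lc50_b <- if (pair == "Cd+Zn") 20.42 else 356.18
  data.frame(c1 = tab$tu_a * 2.75, c2 = tab$tu_b * lc50_b,
             obs = tab$obs_mean_pct / 100)
}

# exact mortality records from a curve (fractional n_dead, no noise)
noise_free_records <- function(curve, concs, n = 1000) {
  p <- plogis(curve$alpha + curve$beta * log10(concs))
  data.frame(compound = "X", conc_mg_L = concs, n_exposed = n,
             n_dead = p * n, replicate = "r1")
}
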