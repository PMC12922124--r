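test_that("acute-assay simulation is a pure function of design and seed", {
  des <- assay_design(c(0, 1, 2, 4), cells_per_well = 100)
  cv <- cd_curve()
  a <- simulate_acute_assay(des, cv, seed = 42)
  b <- simulate_acute_assay(des, cv, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$n_dead,
                         simulate_acute_assay(des, cv, seed = 43)$n_dead))
  # 3 wells x 3 biological replicates per concentration
  expect_equal(nrow(a), 4 * 9)
  # controls produce no deaths
  expect_true(all(a$n_dead[a$conc_mg_L == 0] == 0))
  # the generator does not disturb the session's random stream
  s1 <- withr::with_seed(1, runif(1))
  invisible(simulate_acute_assay(des, cv, seed = 7))
  expect_identical(s1, withr::with_seed(1, runif(1)))
})

test_that("simulated mortality concentrates on the curve value", {
  cv <- cd_curve()
  # ~10^4 cells at the LC50: observed proportion within 3 binomial SDs
  des <- assay_design(2.75, cells_per_well = 100, wells_per_conc = 10,
                      bio_replicates = 10)
  d <- simulate_acute_assay(des, cv, seed = 99)
  n <- sum(d$n_exposed)
  phat <- sum(d$n_dead) / n
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("mixture simulation records truth and respects the design grid", {
  m <- surface_model("IA", cd_curve(), zn_curve(),
                     deviation_spec("SA", a = -2))
  d <- simulate_mixture_dataset(coleps_tu_design(), m, lc50_a = 2.75,
                                lc50_b = 20.42, seed = 5)
  expect_equal(nrow(d), 16L)
  expect_identical(attr(d, "truth"), m)
  expect_equal(d$obs_mean_pct, rowMeans(d[, c("rep1", "rep2", "rep3")]))
  expect_true(all(d$obs_mean_pct >= 0 & d$obs_mean_pct <= 100))
  expect_identical(d, simulate_mixture_dataset(coleps_tu_design(), m,
                                               lc50_a = 2.75, lc50_b = 20.42,
                                               seed = 5))
  # empty grid in, empty table out
  e <- simulate_mixture_dataset(coleps_tu_design()[0, ], m, lc50_a = 2.75,
                                lc50_b = 20.42, seed = 5)
  expect_equal(nrow(e), 0L)
})

test_that("null surfaces yield mostly no-interaction calls, strong synergism mostly synergism", {
  cd <- cd_component(); zn <- zn_component()
  null_model <- surface_model("IA", cd$curve, zn$curve)
  calls <- character(0)
  for (seed in 1:12) {
    d <- simulate_mixture_dataset(coleps_tu_design(), null_model,
                                  lc50_a = 2.75, lc50_b = 20.42, seed = seed)
    d$expected <- d$true_pct  # test against the generating expectation
    calls <- c(calls, vapply(seq_len(nrow(d)), function(i)
      classify_interaction(d$obs_mean_pct[i], d$expected[i],
                           sd = d$obs_sd_pct[i], n = 3)$call, character(1)))
  }
  # type-I rate of the t-based call near alpha
  expect_gt(mean(calls == "no_interaction"), 0.88)

  syn_model <- surface_model("IA", cd$curve, zn$curve,
                             deviation_spec("SA", a = -5))
  d <- simulate_mixture_dataset(coleps_tu_design(), syn_model,
                                lc50_a = 2.75, lc50_b = 20.42, seed = 31)
  ref <- surface_predict(null_model, d$c1, d$c2) * 100
  ncall <- sum(vapply(seq_len(nrow(d)), function(i)
    classify_interaction(d$obs_mean_pct[i], min(100, ref[i]),
                         sd = d$obs_sd_pct[i], n = 3)$call, character(1))
    == "synergism")
  expect_gte(ncall, 14L)
})

test_that("biomarker generator hits the requested correlation structure", {
  p1 <- simulate_biomarker_panel(paste0("t", 1:6), c("A", "B", "C"),
                                 rho = 1, noise_sd = 0, seed = 8)
  r <- correlation_matrix(p1)
  expect_equal(unname(r), matrix(1, 3, 3), tolerance = 1e-9)

  # seeded reproducibility
  p2 <- simulate_biomarker_panel(paste0("t", 1:6), c("A", "B"), rho = 0.5,
                                 seed = 8)
  p3 <- simulate_biomarker_panel(paste0("t", 1:6), c("A", "B"), rho = 0.5,
                                 seed = 8)
  expect_identical(p2, p3)
  expect_error(simulate_biomarker_panel(paste0("t", 1:6), c("A", "B"),
                                        rho = 1.2, seed = 1), "rho")

  # near-zero coupling: median |R| small across seeds
  meds <- vapply(1:8, function(s) {
    pp <- simulate_biomarker_panel(paste0("t", 1:40), c("A", "B"), rho = 0,
                                   noise_sd = 0.01, seed = 100 + s)
    abs(correlation_matrix(pp)["A", "B"])
  }, numeric(1))
  expect_lt(median(meds), 0.2)
})

test_that("simulate-refit loop recovers the generating LC50", {
  gen <- cd_curve()
  des <- assay_design(2.75 * c(0.3, 0.55, 1, 1.8, 3.3))
  err <- vapply(1:40, function(seed) {
    fit <- fit_dose_response(simulate_acute_assay(des, gen, seed = seed))
    lc_value(fit$curve, 50) / 2.75 - 1
  }, numeric(1))
  expect_lt(abs(median(err)), 0.10)
})
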