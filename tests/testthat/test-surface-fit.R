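ref_grid_data <- function(model, lc50_a = 2.75, lc50_b = 20.42,
                          noise_sd = 0, seed = NULL) {
  d <- coleps_tu_design()
  dat <- data.frame(c1 = d$tu_a * lc50_a, c2 = d$tu_b * lc50_b)
  dat$obs <- surface_predict(model, dat$c1, dat$c2)
  if (noise_sd > 0)
    dat$obs <- withr::with_seed(seed, pmin(1, pmax(0,
      dat$obs + rnorm(nrow(dat), 0, noise_sd))))
  dat
}

test_that("noise-free reference data give a null deviation and R^2 = 1", {
  cd <- cd_curve(); zn <- zn_curve()
  dat <- ref_grid_data(surface_model("IA", cd, zn))
  fit <- fit_surface(dat, "IA", "SA", cd, zn)
  expect_equal(unname(fit$par[1]), 0, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("deviation parameters are recovered from noise-free surfaces", {
  cd <- cd_curve(); zn <- zn_curve()
  cases <- list(
    list(ref = "CA", form = "SA", a = -2,   b = 0),
    list(ref = "CA", form = "DR", a = -2,   b = 3),
    list(ref = "IA", form = "SA", a = 1.5,  b = 0),
    list(ref = "IA", form = "DL", a = -1.5, b = 0.8)
  )
  for (cs in cases) {
    truth <- surface_model(cs$ref, cd, zn,
                           deviation_spec(cs$form, a = cs$a, b = cs$b))
    dat <- ref_grid_data(truth)
    fit <- fit_surface(dat, cs$ref, cs$form, cd, zn)
    expect_equal(unname(fit$par[1]), cs$a, tolerance = 1e-3,
                 label = paste(cs$ref, cs$form, "a"))
    if (cs$form %in% c("DR", "DL"))
      expect_equal(unname(fit$par[2]), cs$b, tolerance = 1e-3,
                   label = paste(cs$ref, cs$form, "b"))
    expect_lt(fit$sse, 1e-10)
  }
})

test_that("nested models never fit worse along the ladder", {
  cd <- cd_curve(); zn <- zn_curve()
  truth <- surface_model("CA", cd, zn, deviation_spec("SA", a = -1))
  dat <- ref_grid_data(truth, noise_sd = 0.05, seed = 21)
  for (ref in c("CA", "IA")) {
    sel <- model_selection(dat, ref, cd, zn)
    sses <- vapply(sel$fits, `[[`, numeric(1), "sse")
    expect_lte(sses[["SA"]], sses[["reference"]])
    expect_lte(sses[["DR"]], sses[["SA"]])
    expect_lte(sses[["DL"]], sses[["SA"]])
    expect_true(all(vapply(sel$fits, `[[`, numeric(1), "r_squared") <= 1))
  }
})

test_that("likelihood-ratio statistic follows its closed form", {
  cd <- cd_curve(); zn <- zn_curve()
  dat <- ref_grid_data(surface_model("IA", cd, zn), noise_sd = 0.04,
                       seed = 5)
  ref <- fit_surface(dat, "IA", "none", cd, zn)
  sa <- fit_surface(dat, "IA", "SA", cd, zn)
  lrt <- likelihood_ratio_test(ref, sa)
  expect_equal(lrt$chi2, nrow(dat) * log(ref$sse / sa$sse), tolerance = 1e-12)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p_value, pchisq(lrt$chi2, 1, lower.tail = FALSE))

  fake <- function(sse, form, n_par) {
    f <- ref
    f$sse <- sse; f$form <- form; f$n_par <- n_par
    f
  }
  # equally good fits: chi2 = 0, p = 1
  same <- likelihood_ratio_test(fake(1, "none", 0L), fake(1, "SA", 1L))
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  # a known SSE ratio of e with n = 16 gives chi2 = 16
  lr <- likelihood_ratio_test(fake(exp(1), "none", 0L), fake(1, "SA", 1L))
  expect_equal(lr$chi2, 16)
  expect_equal(lr$p_value, 6.3e-5, tolerance = 0.01)

  expect_error(likelihood_ratio_test(sa, ref), "not nested")
  expect_error(likelihood_ratio_test(
    fit_surface(dat, "CA", "none", cd, zn), sa), "not nested")
})

test_that("a worse-fitting child floors the statistic at zero", {
  cd <- cd_curve(); zn <- zn_curve()
  dat <- ref_grid_data(surface_model("IA", cd, zn), noise_sd = 0.04, seed = 9)
  ref <- fit_surface(dat, "IA", "none", cd, zn)
  bad <- fit_surface(dat, "IA", "SA", cd, zn)
  bad$sse <- ref$sse * 1.01  # simulate an optimizer failure
  expect_warning(lr <- likelihood_ratio_test(ref, bad), "floored")
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p_value, 1)
})

test_that("model selection recovers a strongly dose-ratio-dependent synergism", {
  cd <- cd_curve(); zn <- zn_curve()
  truth <- surface_model("CA", cd, zn, deviation_spec("DR", a = -3, b = 6))
  dat <- ref_grid_data(truth, noise_sd = 0.02, seed = 17)
  sel <- model_selection(dat, "CA", cd, zn)
  expect_equal(sel$best, "DR")
  expect_lt(sel$comparisons$p_value[sel$comparisons$comparison == "SA_DR"],
            0.05)
  expect_lt(sel$table$a[sel$table$model == "CA/DR"], 0)  # synergism sign
})

test_that("degenerate fitting inputs raise informative errors", {
  cd <- cd_curve(); zn <- zn_curve()
  expect_error(model_selection(data.frame(), "CA", cd, zn), "empty data")
  const <- data.frame(c1 = c(1, 2, 3, 4), c2 = c(5, 6, 7, 8), obs = 0.5)
  expect_error(fit_surface(const, "CA", "none", cd, zn), "constant response")
  small <- data.frame(c1 = 1:2, c2 = 1:2, obs = c(0.2, 0.4))
  expect_error(fit_surface(small, "CA", "SA", cd, zn), "observations")
})
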