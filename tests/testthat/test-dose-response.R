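test_that("curve reconstruction from two LC points matches the closed form", {
  cd <- cd_curve()
  expect_equal(cd$beta, 1.386294 / log10(2.75 / 1.47), tolerance = 1e-5)
  expect_equal(cd$alpha, -cd$beta * log10(2.75), tolerance = 1e-6)
  expect_equal(zn_curve()$beta, 3.527, tolerance = 1e-3)

  # round trip: the curve reproduces both defining LC points exactly
  expect_equal(lc_value(cd, 50), 2.75, tolerance = 1e-12)
  expect_equal(lc_value(cd, 20), 1.47, tolerance = 1e-12)

  expect_error(curve_from_lcs(c(20, 1), c(20, 2)), "underdetermined")
  expect_error(curve_from_lcs(c(20, 2), c(50, 1)), "non-monotone")
})

test_that("predicted mortality matches hand-evaluated logits and is monotone", {
  cd <- cd_curve()
  expect_equal(predict_mortality(cd, 2.75), 0.5, tolerance = 1e-12)
  expect_equal(predict_mortality(cd, 0.6875), 0.0444, tolerance = 1e-3)
  expect_equal(predict_mortality(zn_curve(), 5.105), 0.1069, tolerance = 1e-3)
  expect_error(predict_mortality(cd, 0), "invalid concentration")
  expect_error(predict_mortality(cd, -1), "invalid concentration")

  conc <- 10^seq(-2, 2, length.out = 50)
  expect_true(all(diff(predict_mortality(cd, conc)) > 0))
})

test_that("noise-free proportions are refit to the generating parameters", {
  gen <- logit_curve(-2.2391, 5.0964)
  recs <- noise_free_records(gen, c(0.8, 1.4, 2.75, 5.0, 9.0))
  fit <- fit_dose_response(recs, method = "empirical_logit_ols")
  expect_equal(fit$curve$alpha, gen$alpha, tolerance = 1e-6)
  expect_equal(fit$curve$beta, gen$beta, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("binomial simulation refits LC50 close to the generating value", {
  gen <- cd_curve()
  d <- simulate_acute_assay(
    assay_design(2.75 * c(0.3, 0.55, 1, 1.8, 3.3), wells_per_conc = 3,
                 bio_replicates = 1),
    gen, seed = 11
  )
  fit <- fit_dose_response(d)
  lc50 <- lc_estimate(fit, 50)
  expect_lt(abs(lc50$value / 2.75 - 1), 0.10)
})

test_that("boundary proportions use the empirical-logit adjustment", {
  recs <- data.frame(compound = "X",
                     conc_mg_L = c(0.5, 1, 2, 4, 8),
                     n_exposed = 100,
                     n_dead = c(0, 10, 50, 90, 100),  # both boundaries
                     replicate = "r1")
  expect_silent(fit <- fit_dose_response(recs, method = "empirical_logit_ols"))
  expect_gt(fit$curve$beta, 0)
  # glm path also handles the same data
  expect_gt(fit_dose_response(recs)$curve$beta, 0)
})

test_that("degenerate and underdetermined designs are rejected", {
  two <- data.frame(compound = "X", conc_mg_L = c(1, 2, 0),
                    n_exposed = 100, n_dead = c(10, 60, 0),
                    replicate = "r1")
  expect_error(fit_dose_response(two), "insufficient design")
  allbound <- data.frame(compound = "X", conc_mg_L = c(1, 2, 4),
                         n_exposed = 100, n_dead = c(0, 0, 100),
                         replicate = "r1")
  expect_error(fit_dose_response(allbound), "degenerate response")
  bad <- data.frame(compound = "X", conc_mg_L = 1, n_exposed = 10,
                    n_dead = 12, replicate = "r1")
  expect_error(mortality_records(bad), "n_dead")
})

test_that("glm and empirical-logit estimators agree on balanced designs", {
  gen <- zn_curve()
  design <- assay_design(20.42 * c(0.35, 0.6, 1, 1.7, 2.9),
                         cells_per_well = 200)
  for (seed in 1:5) {
    d <- simulate_acute_assay(design, gen, seed = seed)
    lc_glm <- lc_value(fit_dose_response(d)$curve, 50)
    lc_ols <- lc_value(fit_dose_response(d, "empirical_logit_ols")$curve, 50)
    expect_lt(abs(lc_glm / lc_ols - 1), 0.02)
  }
})

test_that("lc_estimate propagates uncertainty by the delta method", {
  cd <- cd_curve()
  # zero covariance collapses the interval onto the point estimate
  e <- lc_estimate(cd, 50)
  expect_equal(e$se, 0)
  expect_equal(e$ci95, c(e$value, e$value))

  # against a finite-difference delta computation
  V <- matrix(c(0.04, -0.01, -0.01, 0.09), 2)
  e <- lc_estimate(cd, 20, covariance = V)
  f <- function(ab) 10^((qlogis(0.2) - ab[1]) / ab[2])
  h <- 1e-6
  g <- c((f(c(cd$alpha + h, cd$beta)) - f(c(cd$alpha - h, cd$beta))) / (2 * h),
         (f(c(cd$alpha, cd$beta + h)) - f(c(cd$alpha, cd$beta - h))) / (2 * h))
  expect_equal(e$se, sqrt(drop(t(g) %*% V %*% g)), tolerance = 1e-6)
  expect_true(e$ci95[1] < e$value && e$value < e$ci95[2])

  expect_error(lc_estimate(logit_curve(0, -1), 50), "non-monotone")
  expect_error(lc_estimate(cd, 0), "effect level")
})

test_that("lc_table mirrors the single-compound summary layout", {
  d <- simulate_acute_assay(assay_design(2.75 * c(0.4, 0.7, 1, 1.6, 2.6)),
                            cd_curve(), seed = 3)
  tab <- lc_table(list(Cd = fit_dose_response(d)))
  expect_equal(names(tab), c("compound", "parameter", "estimate", "se",
                             "ci_low", "ci_high", "r_squared"))
  expect_equal(tab$parameter, c("LC20", "LC50"))
  expect_true(all(tab$ci_low < tab$estimate & tab$estimate < tab$ci_high))
  expect_lt(tab$estimate[1], tab$estimate[2])  # LC20 < LC50
})
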