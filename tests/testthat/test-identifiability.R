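# a synthetic quadratic relative-NLL curve for closed-form CI checks
quadratic_curve <- function(xhat = 1, sigma = 0.1, n = 121) {
  x <- exp(seq(log(xhat / 3), log(3 * xhat), length.out = n))
  df <- data.frame(value = x, nll = 0.5 * ((x - xhat) / sigma)^2,
                   rel_nll = 0.5 * ((x - xhat) / sigma)^2, converged = TRUE)
  structure(df, param = "x", ref_nll = 0, n_params = 1, mle_value = xhat,
            searched_decades = log10(3), class = c("profile_curve",
                                                   "data.frame"))
}

test_that("chi-squared thresholds follow the simultaneous/pointwise convention", {
  cu <- quadratic_curve()
  expect_equal(likelihood_ci(cu, alpha = 0.05, df = 1)$threshold, 1.9207,
               tolerance = 1e-4)
  expect_equal(likelihood_ci(cu, alpha = 0.01, df = 3)$threshold, 5.6724,
               tolerance = 1e-4)
})

test_that("CI bounds of a quadratic profile match the closed form", {
  xhat <- 1; sigma <- 0.1
  cu <- quadratic_curve(xhat, sigma)
  for (al in c(0.05, 0.01)) {
    ci <- likelihood_ci(cu, alpha = al, df = 1)
    half <- sigma * sqrt(2 * (stats::qchisq(1 - al, 1) / 2))
    expect_equal(ci$lower, xhat - half, tolerance = 2e-3)
    expect_equal(ci$upper, xhat + half, tolerance = 2e-3)
    expect_false(ci$lower_unbounded || ci$upper_unbounded)
  }
})

test_that("a flat profile cannot close its interval and is classified as such", {
  x <- 10^seq(-2, 3, length.out = 51)   # 5 decades, essentially flat
  df <- data.frame(value = x, nll = 0.005 * sin(x / 50), converged = TRUE)
  df$rel_nll <- df$nll - min(df$nll)
  cu <- structure(df, param = "x", ref_nll = 0, n_params = 4, mle_value = 1,
                  searched_decades = 5,
                  class = c("profile_curve", "data.frame"))
  ci <- likelihood_ci(cu, alpha = 0.01)
  expect_true(ci$lower_unbounded && ci$upper_unbounded)
  verdict <- classify_practical_identifiability(cu, ci)
  expect_equal(verdict$verdict, "practically_unidentifiable")

  # the same flat curve over a narrow grid is indeterminate, not unidentifiable
  narrow <- cu[cu$value >= 0.5 & cu$value <= 5, ]
  attributes(narrow)[c("param", "ref_nll", "n_params", "mle_value")] <-
    attributes(cu)[c("param", "ref_nll", "n_params", "mle_value")]
  class(narrow) <- class(cu)
  ci_n <- likelihood_ci(narrow, alpha = 0.01)
  expect_equal(classify_practical_identifiability(narrow, ci_n)$verdict,
               "indeterminate")
})

test_that("two-stage profiles are troughs that dominate the global optimum", {
  m2 <- msce_model(2)
  tab <- simulate_incidence(m2, registry_pars$m2, default_schedule(),
                            seed = 31)
  fit <- fit_mle(m2, tab)
  for (par in c("q", "r")) {
    cu <- profile_likelihood(m2, tab, fit, par)
    # profile dominance of the global optimum
    expect_gte(min(cu$nll), attr(cu, "ref_nll") - 1e-6)
    # relative NLL at the MLE grid point is ~0
    expect_lt(min(cu$rel_nll), 1e-6)
    ci <- likelihood_ci(cu, alpha = 0.01)
    expect_false(ci$lower_unbounded || ci$upper_unbounded)
    expect_equal(
      classify_practical_identifiability(cu, ci)$verdict, "identifiable")
    # truth is inside the simultaneous 99% interval
    expect_gt(registry_pars$m2[[par]], ci$lower)
    expect_lt(registry_pars$m2[[par]], ci$upper)
  }
})

test_that("CI bounds are stable under grid refinement", {
  m2 <- msce_model(2)
  tab <- simulate_incidence(m2, registry_pars$m2, default_schedule(),
                            seed = 31)
  fit <- fit_mle(m2, tab)
  cu1 <- profile_likelihood(m2, tab, fit, "r", n_per_decade = 10)
  cu2 <- profile_likelihood(m2, tab, fit, "r", n_per_decade = 20)
  ci1 <- likelihood_ci(cu1); ci2 <- likelihood_ci(cu2)
  expect_lt(abs(ci1$lower / ci2$lower - 1), 0.01)
  expect_lt(abs(ci1$upper / ci2$upper - 1), 0.01)
})

test_that("dependency scans certify the three-stage product structure", {
  m3s <- msce_model(3, "structural")
  m3 <- msce_model(3, "reparam")
  tab <- simulate_incidence(m3, registry_pars$m3, default_schedule(),
                            seed = 42)
  fs <- fit_mle(m3s, tab)
  grid <- 10^seq(2, 5, length.out = 7)
  sc <- dependency_scan(m3s, tab, fs, "nuX", grid, "mu1_over_alpha")
  expect_lt(abs(attr(sc, "slope") + 1), 0.01)
  expect_gte(attr(sc, "r_squared"), 0.999)
  # product conservation along the scan, against the reparameterized r^2
  f <- fit_mle(m3, tab)
  expect_lt(max(abs(sc$product / f$params[["r"]]^2 - 1)), 0.01)

  # a structurally independent responding parameter shows no compensation
  sc0 <- dependency_scan(m3s, tab, fs, "nuX", grid, "q")
  expect_lt(abs(attr(sc0, "slope")), 0.01)
})
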