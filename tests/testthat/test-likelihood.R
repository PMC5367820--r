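test_that("expected cases are person-years times midpoint hazard", {
  m2 <- msce_model(2)
  tab <- incidence_table(c(50, 55), c(55, 60), c(0L, 0L), c(2e6, 2e6))
  pars <- registry_pars$m2
  E <- expected_cases(m2, pars, tab)
  expect_equal(E, 2e6 * hazard_2(c(52.5, 57.5), pars[["r"]], pq_of(pars)))

  # a vanishing malignant-conversion rate (q = 0) kills the hazard entirely
  zero <- c(p = -0.1, q = 0, r = 1e-2)
  expect_equal(expected_cases(m2, zero, tab), c(0, 0))
})

test_that("midpoint evaluation tracks the group-averaged hazard", {
  # Where the hazard is near-linear (midlife onward, where almost all cases
  # sit) the midpoint and the 11-point-Simpson group average agree closely;
  # in the early exponential phase the relative gap grows to ~ 2% but the
  # affected expected counts are negligible, so the case-weighted
  # discrepancy stays small. Both the fitting likelihood and the simulator
  # share the midpoint convention, so the pipeline is internally exact.
  for (nm in c("m2", "m3")) {
    n <- as.integer(sub("m", "", nm))
    m <- msce_model(n)
    pars <- registry_pars[[nm]]
    sch <- default_schedule()
    tab <- incidence_table(sch$age_lo, sch$age_hi, rep(0L, nrow(sch)),
                           sch$person_years)
    E_mid <- expected_cases(m, pars, tab)
    E_avg <- vapply(seq_len(nrow(tab)), function(a) {
      x <- seq(tab$age_lo[a], tab$age_hi[a], length.out = 11)
      w <- c(1, 4, 2, 4, 2, 4, 2, 4, 2, 4, 1) / 30
      tab$person_years[a] * sum(w * model_hazard(m, x, pars))
    }, numeric(1))
    old <- tab$age_lo >= 60                    # linear-phase groups
    expect_lt(max(abs(E_mid[old] / E_avg[old] - 1)), 0.012)
    expect_lt(abs(sum(E_mid) / sum(E_avg) - 1), 0.02)
  }
})

test_that("poisson_nll matches the closed-form sum E - c log E", {
  m2 <- msce_model(2)
  pars <- registry_pars$m2
  h <- hazard_2(c(52.5, 57.5), pars[["r"]], pq_of(pars))
  # person-years chosen so the expected counts are exactly (2.5, 8.0)
  tab <- incidence_table(c(50, 55), c(55, 60), c(3L, 7L), c(2.5, 8.0) / h)
  expect_equal(poisson_nll(m2, pars, tab), -6.804963, tolerance = 1e-6)
})

test_that("NLL differences are invariant to the dropped factorial constant", {
  m2 <- msce_model(2)
  tab <- noise_free_table(m2, registry_pars$m2)
  pars_a <- registry_pars$m2
  pars_b <- pars_a * c(1.05, 1, 1.02)
  const <- sum(lgamma(tab$cases + 1))
  full_a <- poisson_nll(m2, pars_a, tab) + const
  full_b <- poisson_nll(m2, pars_b, tab) + const
  expect_equal(full_a - full_b,
               poisson_nll(m2, pars_a, tab) - poisson_nll(m2, pars_b, tab),
               tolerance = 1e-10)
})

test_that("the NLL is minimized over level at the saturated expectation", {
  # Poisson MLE property: scaling all E away from E = c raises the NLL
  m2 <- msce_model(2)
  tab <- noise_free_table(m2, registry_pars$m2)
  base <- poisson_nll(m2, registry_pars$m2, tab)
  for (s in c(0.8, 0.95, 1.05, 1.25)) {
    scaled <- registry_pars$m2 * c(1, 1, s)
    expect_gt(poisson_nll(m2, scaled, tab), base)
  }
  # doubling person-years doubles E: monotone response of the NLL score
  tab2 <- incidence_table(tab$age_lo, tab$age_hi, tab$cases,
                          2 * tab$person_years)
  expect_gt(poisson_nll(m2, registry_pars$m2, tab2), base)
})

test_that("fit recovers generating parameters from noise-free data", {
  for (nm in c("m2", "m3")) {
    n <- as.integer(sub("m", "", nm))
    m <- msce_model(n)
    tab <- noise_free_table(m, registry_pars[[nm]])
    fit <- fit_mle(m, tab)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$params / registry_pars[[nm]] - 1)), 0.01)
  }
})

test_that("the fit is invariant to the fixed (X, alpha) constants", {
  m3 <- msce_model(3, "reparam", fixed_X = 1e7, fixed_alpha = 10)
  tab <- simulate_incidence(m3, registry_pars$m3, default_schedule(),
                            seed = 42)
  f <- fit_mle(m3, tab)
  m3b <- msce_model(3, "reparam", fixed_X = 1e8, fixed_alpha = 100)
  fb <- fit_mle(m3b, tab)
  expect_lt(abs(f$nll - fb$nll), 1e-4)
  expect_lt(max(abs(fb$params / f$params - 1)), 1e-4)
})

test_that("reparameterized and structural fits achieve the same likelihood", {
  m3 <- msce_model(3, "reparam")
  m3s <- msce_model(3, "structural")
  tab <- simulate_incidence(m3, registry_pars$m3, default_schedule(),
                            seed = 42)
  f <- fit_mle(m3, tab)
  fs <- fit_mle(m3s, tab)
  expect_lt(abs(f$nll - fs$nll), 1e-4)
  # the structural optimum conserves the identifiable product
  expect_equal(sqrt(fs$params[["nuX"]] * fs$params[["mu1_over_alpha"]]),
               f$params[["r"]], tolerance = 1e-3)
  # and agrees on (p, q)
  expect_equal(fs$params[["p"]], f$params[["p"]], tolerance = 1e-3)
  expect_equal(fs$params[["q"]], f$params[["q"]], tolerance = 1e-3)
})

test_that("AIC comparison ranks models and reports both k conventions", {
  m2 <- msce_model(2)
  tab <- simulate_incidence(m2, registry_pars$m2, default_schedule(),
                            seed = 5)
  f2 <- fit_mle(m2, tab)
  f3 <- fit_mle(msce_model(3, "reparam"), tab)
  f4 <- fit_mle(msce_model(4, "reparam"), tab)

  cmp <- aic_compare(list(f2, f3, f4))
  expect_equal(cmp$delta_aic[which.min(cmp$aic)], 0)
  expect_equal(cmp$k, c(3L, 4L, 5L))
  cmp_f <- aic_compare(list(f2, f3, f4), convention = "fitted")
  expect_equal(cmp_f$k, c(3L, 3L, 3L))
  # the conventions differ by at most 4 AIC units (2 extra combinations)
  expect_true(all(abs(cmp$aic - cmp_f$aic) <= 4 + 1e-9))

  # on data generated by the two-stage model, the generating model is
  # preferred or within the parameter-count penalty of the winner
  expect_lt(cmp$delta_aic[1], 2 * (f4$k_structural - f2$k_structural) + 1e-6)

  # identical fits tie at delta AIC = 0
  expect_equal(aic_compare(list(f2, f2))$delta_aic, c(0, 0))

  # fits on different tables are rejected
  tab_b <- simulate_incidence(m2, registry_pars$m2, default_schedule(),
                              seed = 6)
  f2b <- fit_mle(m2, tab_b)
  expect_error(aic_compare(list(f2, f2b)), "same incidence table")
})
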