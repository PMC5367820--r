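test_that("all hazards vanish at t = 0 and stay finite and non-negative", {
  for (nm in names(registry_pars)) {
    pars <- registry_pars[[nm]]
    pq <- pq_of(pars)
    n <- as.integer(sub("m", "", nm))
    m <- msce_model(n, "reparam")
    tg <- seq(0, 120, by = 2.5)
    h <- model_hazard(m, tg, pars)
    expect_equal(h[1], 0)
    expect_true(all(is.finite(h)))
    expect_true(all(h >= 0))
    # non-decreasing at registry-scale parameter values
    expect_true(all(diff(h) >= -1e-15))
  }
})

test_that("two- and three-stage hazards reach their analytic asymptotes", {
  p2 <- registry_pars$m2
  h_inf <- hazard_2(1e6, p2[["r"]], pq_of(p2))
  expect_equal(h_inf, -p2[["p"]] * p2[["r"]], tolerance = 1e-6)

  # at registry-scale mu1/alpha the 3-stage plateau arrives on the
  # (mu1 (1 - beta/alpha))^-1 ~ 1e7-year scale: far beyond any lifespan
  # (the root of the practical identifiability problem), so probe 1e8
  pq3 <- pq_of(registry_pars$m3)
  nuX <- 235
  expect_equal(hazard_3(1e8, nuX, 2.35e-6, pq3), nuX, tolerance = 1e-6)
  expect_lt(hazard_3(120, nuX, 2.35e-6, pq3) / nuX, 0.01)
  # a fast-mutation instance plateaus within 1e6 years
  pq <- compute_pq(1, 0.5, 0.01)
  expect_equal(hazard_3(1e6, 1, 0.1, pq), 1, tolerance = 1e-6)
})

test_that("hazards are overflow-free far beyond observable ages", {
  pq <- compute_pq(1, 0.5, 1e-5)   # |p| ~ 0.5, so |p| t = 500 at t = 1000
  h <- hazard_2(c(200, 1000), 0.1, pq)
  expect_true(all(is.finite(h)))
  h3 <- hazard_3(c(200, 1000), 1, 1e-6, pq)
  expect_true(all(is.finite(h3)))
  expect_error(hazard_2(-1, 0.1, pq), ">= 0")
})

test_that("reparameterized hazards are algebraically equivalent to the structural forms", {
  tg <- seq(0, 120, by = 2)
  pq3 <- pq_of(registry_pars$m3)
  r3 <- registry_pars$m3[["r"]]
  for (Xa in list(c(1e7, 10), c(1e9, 1), c(1e5, 100))) {
    sax <- sqrt(Xa[2] * Xa[1])
    expect_equal(hazard_3_reparam(tg, r3, Xa[1], Xa[2], pq3),
                 hazard_3(tg, r3 * sax, r3 / sax, pq3),
                 tolerance = 1e-14)
  }
  pq4 <- pq_of(registry_pars$m4)
  r4 <- registry_pars$m4[["r"]]
  X <- 1e7; a <- 10
  nuX <- r4 * (X^2 * a)^(1 / 3)
  mu1 <- r4 * (a / X)^(1 / 3)
  m2a <- r4 / (a^2 * X)^(1 / 3)
  expect_equal(nuX * mu1 * m2a, r4^3, tolerance = 1e-12)
  expect_equal(hazard_4_reparam(tg[-1], r4, X, a, pq4),
               hazard_4(tg[-1], nuX, mu1, m2a, pq4),
               tolerance = 1e-12)
})

test_that("hazards are invariant to the fixed (X, alpha) choice at equal r", {
  # the practical-unidentifiability property: with the composite rate held
  # fixed, moving (X, alpha) across orders of magnitude leaves the hazard
  # essentially unchanged wherever nuX >> max hazard
  tg <- seq(1, 100, by = 1)
  r3 <- registry_pars$m3[["r"]]; pq3 <- pq_of(registry_pars$m3)
  base3 <- hazard_3_reparam(tg, r3, 1e7, 10, pq3)
  alt3 <- hazard_3_reparam(tg, r3, 1e9, 1000, pq3)
  expect_lt(max(abs(alt3 / base3 - 1)), 1e-3)

  r4 <- registry_pars$m4[["r"]]; pq4 <- pq_of(registry_pars$m4)
  base4 <- hazard_4_reparam(tg, r4, 1e7, 10, pq4)
  alt4 <- hazard_4_reparam(tg, r4, 1e9, 1000, pq4)
  expect_lt(max(abs(alt4 / base4 - 1)), 1e-3)
})

test_that("four-stage quadrature is self-convergent in its tolerance", {
  pars <- registry_pars$m4
  pq <- pq_of(pars)
  tg <- c(1, 5, 20, 60, 120)
  args <- list(nuX = 2660, mu1 = 2.66e-4, mu2_over_alpha = 2.66e-5, pq = pq)
  h_mid <- do.call(hazard_4, c(list(t = tg, quadrature_tol = 1e-10), args))
  h_lo <- do.call(hazard_4, c(list(t = tg, quadrature_tol = 5e-11), args))
  h_hi <- do.call(hazard_4, c(list(t = tg, quadrature_tol = 2e-10), args))
  expect_lt(max(abs(h_lo / h_mid - 1)), 1e-8)
  expect_lt(max(abs(h_hi / h_mid - 1)), 1e-8)
})
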