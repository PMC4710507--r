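pars <- model_params()

test_that("parameter defaults match the reference table and validate", {
  expect_equal(pars$alpha, 2.02)
  expect_equal(pars$beta, 2.00)
  expect_equal(pars$tau, 0.35)
  expect_equal(pars$gamma, 0.17)
  expect_equal(pars$Omega, 1.1)
  expect_equal(pars$sigma, 1.5)
  expect_equal(pars$Phi, 0.10)
  expect_equal(pars$steepness, 40)
  expect_error(model_params(alpha = -1), ">= 0")
  expect_error(model_params(Phi = 0), "> 0")
})

test_that("parameters round-trip through the flat config format", {
  f <- withr::local_tempfile(fileext = ".cfg")
  p <- model_params(delta = 8e-5, eta = 1.4e-4, sigma = 0)
  write_params(p, f)
  expect_equal(read_params(f), p)
  writeLines("nonsense = 1", f)
  expect_error(read_params(f), "unknown parameter")
})

test_that("total concentration sums the four compartments", {
  st <- list(P = matrix(0.2), I = matrix(0.1), B = matrix(0.6), N = matrix(0.1))
  expect_equal(total_concentration(st), matrix(1.0))
  st0 <- list(P = matrix(0), I = matrix(0), B = matrix(0), N = matrix(0))
  expect_equal(total_concentration(st0), matrix(0))
  st$B <- matrix(0.6, 2, 2)
  expect_error(total_concentration(st), "shape")
})

test_that("hypoxic and necrotic thresholds follow the angiogenesis law", {
  expect_equal(hypoxic_threshold(0, pars), 1.1)
  expect_equal(hypoxic_threshold(1, pars), 1.1 + 1.5 * log(2))
  expect_equal(hypoxic_threshold(1, pars), 2.1397, tolerance = 1e-4)
  p0 <- model_params(sigma = 0)            # anti-angiogenesis
  expect_equal(hypoxic_threshold(c(0, 1, 5), p0), rep(1.1, 3))
  pd <- model_params(log_base = "decimal")
  expect_equal(hypoxic_threshold(9, pd), 1.1 + 1.5)
  expect_error(hypoxic_threshold(-0.1, pars), ">= 0")

  expect_equal(necrotic_threshold(1.1, pars), 1.2)
  chyp <- matrix(c(1.1, 2, 3), 1)
  expect_equal(necrotic_threshold(chyp, pars), chyp + 0.1)
})

test_that("the hypoxia switch is a bounded increasing tanh in C", {
  expect_equal(hypoxia_measure(1.1, 1.1, pars), 0.5)
  expect_equal(hypoxia_measure(1.2, 1.1, pars), (1 - tanh(-4)) / 2)
  expect_equal(hypoxia_measure(1.2, 1.1, pars), 0.999665, tolerance = 1e-6)
  expect_lt(hypoxia_measure(0, 1.1, pars), 1e-16)
  C <- seq(0, 3, by = 0.01)
  H <- hypoxia_measure(C, 1.1, pars)
  expect_true(all(H >= 0 & H <= 1))
  expect_true(all(diff(H) >= 0))          # monotone in C
})

test_that("mitotic rate scales tau by normoxia and efficiency", {
  expect_equal(mitotic_rate(0, 0.35), 0.35)
  expect_equal(mitotic_rate(1, 0.35), 0)
  expect_equal(mitotic_rate(0.5, 0.35), 0.175)
  tauf <- matrix(c(0.35, 0.1), 1, 2)
  expect_equal(mitotic_rate(matrix(0, 1, 2), tauf), tauf)
  expect_equal(mitotic_rate(0, 0.35, efficiency = 0.5), 0.175)
})

test_that("the necrosis rate switches on above the threshold and diverges as B dies", {
  st <- list(P = matrix(0), I = matrix(0), B = matrix(1), N = matrix(0))
  # C = Cltm: half-open switch, healthy multiplier ~ 1/1.01
  gf <- necrosis_rate(st, C = matrix(1.2), Cltm = matrix(1.2), pars)
  expect_equal(gf[1], 0.17 * (1 / 1.01) * 0.5, tolerance = 1e-12)
  expect_equal(gf[1], 0.08416, tolerance = 1e-4)
  # far below threshold: essentially zero
  expect_lt(necrosis_rate(st, matrix(0.5), matrix(1.2), pars)[1], 1e-16)
  # dead brain with C above threshold: rate approaches 100 * gamma
  std <- list(P = matrix(0), I = matrix(0), B = matrix(0), N = matrix(2.4))
  expect_equal(necrosis_rate(std, matrix(2.4), matrix(1.2), pars)[1], 17,
               tolerance = 1e-3)
})

test_that("reaction terms satisfy the growth-only-source identity", {
  geom <- test_geometry()
  for (seed in 1:5) {
    st <- random_state(geom, seed)
    rt <- reaction_terms(st, pars)
    expect_equal(rt$dP + rt$dI + rt$dB + rt$dN, rt$M * st$P, tolerance = 1e-12)
  }
  # structure: H = 0 leaves only growth, back-conversion and necrosis on P
  st <- list(P = matrix(0.5), I = matrix(0.2), B = matrix(0.3), N = matrix(0))
  rt <- reaction_terms(st, pars)
  expect_equal(rt$dP, rt$M * st$P - pars$alpha * rt$H * st$P +
                 pars$beta * (1 - rt$H) * st$I - rt$gammaF * st$P)
  expect_equal(rt$dB, -rt$gammaF * st$B)
  expect_equal(rt$dN, rt$gammaF * (st$P + st$I + st$B))
  st$P <- matrix(NaN)
  expect_error(reaction_terms(st, pars), "non-finite")
})

test_that("closure outputs are finite and monotone on random states", {
  geom <- test_geometry()
  st <- random_state(geom, 42)
  rt <- reaction_terms(st, pars)
  for (f in rt) expect_true(all(is.finite(f)))
  expect_true(all(rt$H >= 0 & rt$H <= 1))   # open interval up to double rounding
  # gammaF non-increasing in B at fixed C and thresholds
  stA <- list(P = matrix(0.5), I = matrix(0.5), B = matrix(0.8), N = matrix(0))
  stB <- list(P = matrix(0.5), I = matrix(0.5), B = matrix(0.2), N = matrix(0))
  expect_lt(necrosis_rate(stA, matrix(2), matrix(1.5), pars)[1],
            necrosis_rate(stB, matrix(2), matrix(1.5), pars)[1])
})
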