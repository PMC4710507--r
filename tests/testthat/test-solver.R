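pars <- model_params()

test_that("diffusion stencil reproduces the discrete Laplacian and conserves mass", {
  g <- strip_geometry(3)
  I <- matrix(c(0, 1, 0), 1)
  out <- diffusion_term(I, g, state = NULL, delta = 1)
  h2 <- g$spacing^2
  expect_equal(out, matrix(c(1, -2, 1), 1) / h2)

  # uniform field: zero everywhere; any field: zero total flux
  gm <- test_geometry()
  Iu <- 0.3 * gm$mask
  expect_equal(max(abs(diffusion_term(Iu, gm, NULL, 4e-3))), 0)
  Ir <- random_state(gm, 1)$I
  expect_lt(abs(sum(diffusion_term(Ir, gm, NULL, 4e-3))), 1e-12)
  expect_error(diffusion_term(Ir, gm, NULL, delta = -1), ">= 0")
})

test_that("diffusion support collapses in the necrotic core", {
  g <- strip_geometry(3)
  st <- list(P = matrix(0, 1, 3), I = matrix(c(0, 1, 0), 1),
             B = matrix(c(1, 0.1, 1), 1), N = matrix(0, 1, 3))
  out <- diffusion_term(st$I, g, st, delta = 1)
  # the dead centre voxel barely leaks: face D ~ (1 + 1e-6)/2 vs 1
  full <- diffusion_term(st$I, g, NULL, delta = 1)
  expect_lt(out[1, 1] / full[1, 1], 0.51)
})

test_that("upwind advection moves I up the B gradient and conserves it", {
  g <- strip_geometry(2)
  I <- matrix(c(1, 0), 1)
  B <- matrix(c(0, 1), 1)
  out <- advection_term(I, B, g, eta = 1.4e-3)
  u <- 1.4e-3 * 1 / g$spacing
  expect_equal(out, matrix(c(-u, u), 1) / g$spacing)
  expect_equal(sum(out), 0)

  # uniform B: no transport
  gm <- test_geometry()
  st <- random_state(gm, 2)
  expect_equal(max(abs(advection_term(st$I, 1 * gm$mask, gm, 1.4e-3))), 0)
  expect_lt(abs(sum(advection_term(st$I, st$B, gm, 1.4e-3))), 1e-12)
  expect_error(advection_term(I, B, g, eta = -1), ">= 0")
})

test_that("upwind advection keeps I non-negative under the stability bound", {
  # 1-D brute force over random fields
  g <- strip_geometry(12)
  for (seed in 1:20) {
    with_seed(seed, {
      I <- matrix(runif(12), 1)
      B <- matrix(runif(12), 1)
    })
    dt <- g$spacing^2 / (1.4e-3 * max(B)) * 0.5
    I2 <- I + dt * advection_term(I, B, g, 1.4e-3)
    expect_true(all(I2 >= 0))
    expect_equal(sum(I2), sum(I), tolerance = 1e-12)
  }
})

test_that("1-D advection of a block converges to the exact front under refinement", {
  # constant B gradient => constant transport speed u = eta * g; the
  # half-maximum front of an advected block must sit at x0 + u*t, with the
  # position error shrinking as the mesh is refined
  eta <- 1.4e-3; g <- 0.4; t_end <- 20000
  front_error <- function(h) {
    n <- round(90 / h)
    geom <- strip_geometry(n, spacing = h)
    x <- (seq_len(n) - 0.5) * h
    B <- matrix(g * x / max(x) * 60, 1)            # linear in x
    u <- eta * (B[1, 2] - B[1, 1]) / h
    I <- matrix(as.numeric(x > 20 & x < 40), 1)
    dt <- 0.4 * h / u
    for (k in seq_len(ceiling(t_end / dt))) {
      I <- I + min(dt, t_end - (k - 1) * dt) * advection_term(I, B, geom, eta)
    }
    half <- max(I) / 2
    i <- max(which(I >= half))                      # trailing edge of the front
    # linear interpolation of the half-max crossing
    x_front <- x[i] + h * (I[1, i] - half) / max(I[1, i] - I[1, i + 1], 1e-12)
    abs(x_front - (40 + u * t_end))
  }
  e_coarse <- front_error(1.5)
  e_fine <- front_error(0.5)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_fine, 1.5)                            # within one coarse voxel
})

test_that("stable_dt honours the three bounds", {
  gm <- test_geometry()
  # reaction bound dominates at reference rates
  dt <- stable_dt(pars, gm)
  expect_equal(dt, 0.5 / (2.02 + 2.00 + 17))
  expect_lt(dt, 0.05)
  # motility-free limit: reaction bound alone
  p0 <- model_params(delta = 0, eta = 0)
  expect_equal(stable_dt(p0, gm), 0.5 / (2.02 + 2.00 + 17))
  # halving h quarters the diffusion bound once diffusion dominates
  pbig <- model_params(delta = 10, eta = 0, alpha = 0, beta = 0, gamma = 0)
  g1 <- brain_geometry(gm$mask, spacing = 1.5)
  g2 <- brain_geometry(gm$mask, spacing = 0.75)
  expect_equal(stable_dt(pbig, g1) / stable_dt(pbig, g2), 4)
})

test_that("euler_step matches the compiled stepper and rejects unstable dt", {
  gm <- test_geometry()
  st <- seed_tumor(gm)
  dt <- stable_dt(pars, gm)
  sR <- euler_step(st, gm, pars, dt)
  sC <- gliotrials:::advance(st, gm, pars, dt, 1L)
  for (f in c("P", "I", "B", "N"))
    expect_equal(sR[[f]], sC[[f]], tolerance = 1e-14)
  expect_error(euler_step(st, gm, pars, dt * 3), "stability bound")
  # zero state stays zero
  z <- st; z$P[] <- 0; z$I[] <- 0; z$B[] <- 0; z$N[] <- 0
  z2 <- euler_step(z, gm, pars, dt)
  expect_true(all(z2$P == 0 & z2$I == 0 & z2$B == 0 & z2$N == 0))
})

test_that("with tau = 0 the scheme conserves total mass", {
  gm <- test_geometry()
  st <- seed_tumor(gm)
  p0 <- model_params(tau = 0)
  m0 <- sum(st$P) + sum(st$I) + sum(st$B) + sum(st$N)
  s <- gliotrials:::advance(st, gm, p0, stable_dt(p0, gm), 1000L)
  m1 <- sum(s$P) + sum(s$I) + sum(s$B) + sum(s$N)
  expect_lt(abs(m1 - m0) / m0, 1e-8)
})

test_that("early low-density growth matches a scalar ODE reference", {
  # a seeded voxel below the hypoxic threshold grows like the pointwise ODE
  gm <- test_geometry()
  p <- model_params(delta = 0, eta = 0)
  st <- seed_tumor(gm, p0 = 0.02, i0 = 0.002)
  out <- gliotrials:::advance(st, gm, p, 0.01, 1000L)  # 10 hours
  # independent reference: fine-step RK4 on the two-species pointwise system
  f <- function(y) {
    C <- sum(y) + 1
    H <- (1 - tanh(40 * (1.5 * log1p(y[1] + y[2]) + 1.1 - C))) / 2
    M <- 0.35 * (1 - H) * (y[1] + y[2]) / (y[1] + y[2] + 0.05)
    c(M * y[1] - 2.02 * H * y[1] + 2 * (1 - H) * y[2],
      2.02 * H * y[1] - 2 * (1 - H) * y[2])
  }
  y <- c(0.02, 0.002); hh <- 0.001
  for (i in seq_len(10000)) {
    k1 <- f(y); k2 <- f(y + hh / 2 * k1); k3 <- f(y + hh / 2 * k2); k4 <- f(y + hh * k3)
    y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  # first-order Euler at dt = 0.01 hr carries a few-tenths-percent bias
  expect_equal(max(out$P), y[1], tolerance = 5e-3)
  expect_equal(max(out$I), y[2], tolerance = 5e-3)
})

test_that("simulation is deterministic, records events, and censors at max time", {
  gm <- test_geometry()
  st <- seed_tumor(gm)
  sched <- list(schedule_event(function(t, s) s$pct_hiden >= 1,
                               function(p) { p$sigma <- 0; p }, "anti_angiogenesis"))
  t1 <- simulate_growth(gm, st, pars, schedule = sched,
                        stop = function(t, s) t >= 240, cadence = 12)
  t2 <- simulate_growth(gm, st, pars, schedule = sched,
                        stop = function(t, s) t >= 240, cadence = 12)
  expect_identical(t1$summaries, t2$summaries)
  expect_equal(t1$events$name, "anti_angiogenesis")
  expect_true(all(diff(t1$summaries$t_hr) > 0))

  # no stop predicate: the max-time guard reports censoring
  t3 <- simulate_growth(gm, st, pars, stop = NULL, cadence = 50, max_time = 100)
  expect_true(t3$censored)

  # no tumour: constant summaries
  empty <- st; empty$P[] <- 0; empty$I[] <- 0
  t4 <- simulate_growth(gm, empty, pars, stop = function(t, s) t >= 48, cadence = 12)
  expect_true(all(t4$summaries$pct_flair == 0))
  expect_true(all(t4$summaries$pct_necrosis == 0))
})

test_that("trajectories export to CSV with the documented columns", {
  gm <- test_geometry()
  tr <- simulate_growth(gm, seed_tumor(gm), pars,
                        stop = function(t, s) t >= 48, cadence = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  got <- read.csv(f)
  expect_equal(names(got), c("t_hr", "pct_flair", "pct_hiden", "pct_necrosis"))
  expect_equal(nrow(got), nrow(tr$summaries))
})
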