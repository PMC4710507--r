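# a tiny fast geometry for protocol-level tests
tiny_geom <- function() test_geometry(28, 22, seed = 3)

test_that("phenotypes map to the reference motility coefficients", {
  expect_equal(phenotype_params("highly_dispersive")$delta, 4e-3)
  expect_equal(phenotype_params("moderately_dispersive")$delta, 8e-5)
  expect_equal(phenotype_params("hypoxia_driven")$delta, 8e-7)
  for (ph in c("highly_dispersive", "moderately_dispersive", "hypoxia_driven"))
    expect_equal(phenotype_params(ph)$eta, 1.4e-3)
  expect_equal(phenotype_params("hypoxia_driven", "low")$eta, 1.4e-4)
  expect_error(phenotype_params("weird"), "arg")
})

test_that("the reference design titrates the documented criterion ranges", {
  arms <- reference_trial_arms(seed = 2)
  expect_equal(vapply(arms, `[[`, 0L, "n"), c(30L, 25L, 25L, 25L, 25L, 25L))
  hd <- arms[[1]]
  co <- make_cohort(hd)
  expect_equal(range(co$trigger_hiden), c(2.0, 2.8))
  expect_equal(range(co$trigger_necrosis), c(0.09, 0.32))
  expect_equal(range(co$death_flair), c(55, 88))
  expect_equal(range(co$death_necrosis), c(3.5, 4.4))
  # control rows die by tumour size or necrosis instead of FLAIR
  ctrl <- make_cohort(arms[[4]])
  expect_equal(range(ctrl$death_hiden), c(10, 18))

  # reproducible; different seed shuffles the pairing but not the grids
  expect_identical(co, make_cohort(hd))
  hd2 <- hd; hd2$seed <- 99L
  co2 <- make_cohort(hd2)
  expect_equal(sort(co2$death_flair), sort(co$death_flair))
  expect_false(identical(co2$death_flair, co$death_flair))
})

test_that("interventions modify the intended parameters only", {
  p <- model_params()
  aa <- apply_intervention(p, list(type = "anti_angiogenesis"))
  expect_equal(aa$sigma, 0)
  expect_equal(aa[names(aa) != "sigma"], p[names(p) != "sigma"])

  rr <- apply_intervention(p, list(type = "rate_reduction", efficacy = 0.4))
  expect_equal(rr$tau, 0.35 * 0.6)
  mr <- apply_intervention(p, list(type = "motility_reduction", efficacy = 0.5))
  expect_equal(mr$eta, p$eta * 0.5)
  expect_identical(apply_intervention(p, list(type = "none")), p)
  expect_error(apply_intervention(p, list(type = "nonsense")), "unknown intervention")
})

test_that("a patient triggers at the first criterion crossing and records survival", {
  g <- tiny_geom()
  pars <- model_params()           # highly-dispersive defaults
  rec <- run_patient(g, pars, trigger = c(hiden = 1.5, necrosis = 0.5),
                     death = c(flair = 30, necrosis = 2.5),
                     intervention = list(type = "anti_angiogenesis"),
                     cadence = 12, max_time = 4000)
  expect_gt(rec$treatment_time, 0)
  expect_gte(rec$death_time, rec$treatment_time)
  expect_equal(rec$os_months,
               (rec$death_time - rec$treatment_time) / 730)
  expect_false(rec$censored)

  # an unreachable death criterion censors at the guard
  rec2 <- run_patient(g, pars, trigger = c(hiden = 1.5),
                      death = c(flair = 99.9),
                      intervention = list(type = "none"),
                      cadence = 24, max_time = 480)
  expect_true(rec2$censored)
})

test_that("trigger/death times bracket the first cadence crossing", {
  g <- tiny_geom()
  pars <- model_params()
  arm <- trial_arm("x", 3, "highly_dispersive",
                   list(metric = "hiden", lo = 1.0, hi = 2.0),
                   list(metric = "necrosis", lo = 2.0, hi = 3.0),
                   list(type = "none"), seed = 1)
  pts <- run_arm(arm, g, pars, cadence = 12, max_time = 4000)
  traj <- simulate_growth(g, seed_tumor(g), pars,
                          stop = function(t, s) s$pct_necrosis >= 3.0,
                          cadence = 12, max_time = 4000)
  s <- traj$summaries
  for (i in 1:3) {
    k <- match(TRUE, s$pct_hiden >= pts$trigger_hiden[i])
    expect_equal(pts$treatment_time[i], s$t_hr[k])
    # no crossing earlier than the reported time
    expect_true(all(s$pct_hiden[s$t_hr < pts$treatment_time[i]] < pts$trigger_hiden[i]))
  }
})

test_that("trials assemble arms, pool controls, and compare survival", {
  g <- tiny_geom()
  mk <- function(name, seed) trial_arm(name, 3, "highly_dispersive",
                                       list(metric = "hiden", lo = 1.0, hi = 2.0),
                                       list(metric = "necrosis", lo = 2.0, hi = 3.0),
                                       list(type = "none"), seed = seed)
  expect_error(run_trial(list(), g), "empty arm list")
  tr <- run_trial(list(mk("A", 1), mk("B", 1)), g, group_controls = FALSE,
                  max_time = 4000)
  expect_equal(sort(unique(tr$patients$group)), c("A", "B"))
  # identical arms: log-rank finds nothing
  expect_gt(tr$logrank$p[1], 0.999)
  expect_equal(unname(tr$medians["A"]), unname(tr$medians["B"]))

  tr2 <- run_trial(list(mk("A", 1), mk("B", 2)), g, group_controls = TRUE,
                   max_time = 4000)
  expect_equal(unique(tr2$patients$group), "Control")
})

test_that("trial runs are reproducible and export their outputs", {
  g <- tiny_geom()
  d <- withr::local_tempdir()
  arms <- list(trial_arm("A", 2, "highly_dispersive",
                         list(metric = "hiden", lo = 1.0, hi = 2.0),
                         list(metric = "necrosis", lo = 2.0, hi = 3.0),
                         list(type = "anti_angiogenesis"), seed = 4))
  t1 <- run_trial(arms, g, max_time = 4000)
  t2 <- run_trial(arms, g, max_time = 4000)
  expect_identical(t1$patients, t2$patients)

  tr <- cmd_trial(g, d, scale = 2 / 30, seed = 3, max_time = 2000)
  expect_true(file.exists(file.path(d, "patients.csv")))
  expect_true(file.exists(file.path(d, "logrank.csv")))
  expect_true(file.exists(file.path(d, "manifest.txt")))
  man <- readLines(file.path(d, "manifest.txt"))
  expect_true(any(grepl("config_md5", man)))
  expect_true(any(grepl("seed = 3", man)))
})
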