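# Shared fixtures.  Expensive simulations are computed lazily and cached in
# .run_cache so several tests can assert on one run.

# always run and report the whole suite, whatever the failure count
options(testthat.progress.max_fails = 100)

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

test_geometry <- function(rows = 40, cols = 30, seed = 11)
  cached(sprintf("geom_%d_%d_%d", rows, cols, seed),
         generate_synthetic_brain(rows, cols, seed = seed))

# a tiny all-brain strip geometry for stencil tests
strip_geometry <- function(n = 3, spacing = 1.5) {
  mask <- matrix(TRUE, 1, n)
  brain_geometry(mask, spacing = spacing)
}

# random admissible states on a geometry (vectorised, reproducible)
random_state <- function(geom, seed) {
  with_seed(seed, {
    shp <- geom$shape
    m <- geom$mask
    rnd <- function(max) matrix(runif(prod(shp), 0, max), shp[1], shp[2]) * m
    structure(list(P = rnd(2), I = rnd(2), B = rnd(1), N = rnd(2.5), t = 0),
              class = "tumor_state")
  })
}

# treated phenotype run at reduced scale: grow to the mid-range trigger
# (tumour 2.4% or necrosis 0.2%, first met), anti-angiogenesis, then follow
# to the mid-range death criterion (FLAIR 71.5% or necrosis 3.95%);
# returns summaries plus the treatment / follow-up / death time points
treated_run <- function(phenotype, eta_level = "high", rows = 60, cols = 45) {
  key <- sprintf("treated_%s_%s_%d_%d", phenotype, eta_level, rows, cols)
  cached(key, {
    geom <- test_geometry(rows, cols, seed = 7)
    mp <- phenotype_params(phenotype, eta_level)
    pars <- model_params(delta = mp$delta, eta = mp$eta)
    ph1 <- simulate_growth(geom, seed_tumor(geom), pars,
                           stop = function(t, s)
                             s$pct_hiden >= 2.4 || s$pct_necrosis >= 0.2,
                           cadence = 12, max_time = 43800)
    at_treat <- ph1$summaries[nrow(ph1$summaries), ]
    pars2 <- apply_intervention(pars, list(type = "anti_angiogenesis"))
    ph2 <- simulate_growth(geom, ph1$final_state, pars2,
                           stop = function(t, s)
                             s$pct_flair >= 71.5 || s$pct_necrosis >= 3.95,
                           cadence = 12, max_time = 26000)
    s2 <- ph2$summaries
    fu <- s2[which.min(abs(s2$t_hr - followup_time(at_treat$t_hr, s2$t_hr[nrow(s2)]))), ]
    list(geom = geom, at_treat = at_treat, fu = fu, end = s2[nrow(s2), ],
         summaries = rbind(ph1$summaries, s2[-1, ]),
         pattern = progression_pattern(at_treat, fu, s2[nrow(s2), ]))
  })
}

# reduced-scale reference trial shared by the acceptance blocks
reduced_trial <- function() {
  cached("reduced_trial", {
    geom <- generate_synthetic_brain(48, 36, seed = 11)
    arms <- reference_trial_arms(scale = 0.4, seed = 5)
    run_trial(arms, geom, max_time = 8760)
  })
}
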