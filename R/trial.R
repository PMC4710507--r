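# In-silico clinical trials: cohorts by criterion titration, per-patient
# runs with interventions, trial assembly.

PHENOTYPE_DELTA <- c(highly_dispersive = 4e-3,
                     moderately_dispersive = 8e-5,
                     hypoxia_driven = 8e-7)
ETA_LEVELS <- c(high = 1.4e-3, low = 1.4e-4)

#' Motility parameters of the three tumour phenotypes
#'
#' Maps a phenotype to its concentration-driven diffusion coefficient
#' `delta` and hypoxia-driven transport coefficient `eta`:
#' highly-dispersive (4e-3 mm2/hr), moderately-dispersive (8e-5 mm2/hr),
#' hypoxia-driven (8e-7 mm2/hr), each with high hypoxia-driven motility
#' (1.4e-3 mm/hr) by default; `eta_level = "low"` selects 1.4e-4 mm/hr.
#'
#' @param phenotype One of `"highly_dispersive"`, `"moderately_dispersive"`,
#'   `"hypoxia_driven"`.
#' @param eta_level `"high"` (default) or `"low"`.
#' @return List with elements `delta` (mm2/hr) and `eta` (mm/hr).
#' @export
phenotype_params <- function(phenotype = c("highly_dispersive",
                                           "moderately_dispersive",
                                           "hypoxia_driven"),
                             eta_level = c("high", "low")) {
  phenotype <- match.arg(phenotype)
  eta_level <- match.arg(eta_level)
  list(delta = unname(PHENOTYPE_DELTA[phenotype]),
       eta = unname(ETA_LEVELS[eta_level]))
}

#' Define a trial arm
#'
#' @param name Arm label.
#' @param n Number of patients (>= 1).
#' @param phenotype Tumour phenotype (see [phenotype_params()]).
#' @param treatment_criteria One criterion `list(metric, lo, hi)` or a list
#'   of several: the intervention (or diagnosis, for controls) fires when
#'   the first named imaging metric (`"hiden"`, `"necrosis"` or `"flair"`,
#'   in percent of brain) reaches its patient-specific threshold titrated
#'   over `[lo, hi]`.  The reference design triggers on high-density
#'   tumour size or necrosis, whichever crosses first.
#' @param death_criteria As `treatment_criteria`; death is declared at the
#'   first crossing among the listed criteria (FLAIR or necrosis for
#'   treated arms; tumour size or necrosis for controls).
#' @param intervention One of `list(type = "none")`,
#'   `list(type = "anti_angiogenesis")`,
#'   `list(type = "rate_reduction", efficacy = e)` (or `field = <matrix>`
#'   for a spatial efficacy map), `list(type = "motility_reduction",
#'   efficacy = e)`.
#' @param eta_level Hypoxia-driven motility level (`"high"` default).
#' @param seed Seed for the cohort shuffle.
#' @return A `trial_arm` object.
#' @export
trial_arm <- function(name, n, phenotype, treatment_criteria, death_criteria,
                      intervention = list(type = "none"),
                      eta_level = "high", seed = 1L) {
  stopifnot(n >= 1)
  as_criteria <- function(cr) {
    if (!is.null(cr$metric)) cr <- list(cr)    # single criterion
    for (c1 in cr)
      if (!all(c("metric", "lo", "hi") %in% names(c1)) || c1$lo > c1$hi ||
          !c1$metric %in% c("hiden", "necrosis", "flair"))
        stop("criterion must be list(metric = hiden|necrosis|flair, lo, hi)", call. = FALSE)
    cr
  }
  structure(list(name = name, n = as.integer(n), phenotype = phenotype,
                 treatment_criteria = as_criteria(treatment_criteria),
                 death_criteria = as_criteria(death_criteria),
                 intervention = intervention, eta_level = eta_level,
                 seed = as.integer(seed)),
            class = "trial_arm")
}

#' The reference four-group trial design
#'
#' Three anti-angiogenesis-treated arms (highly-dispersive n=30,
#' moderately-dispersive n=25, hypoxia-driven n=25) plus an untreated
#' control group of all three phenotypes (n=25 each).  Treatment (or
#' diagnosis) fires at the first of two titrated criteria: high-density
#' tumour 2.0-2.8% of brain or necrosis 0.09-0.32%.  Death is the first of
#' FLAIR 55-88% or necrosis 3.5-4.4% for treated arms, and of
#' high-density tumour 10-18% or necrosis 3.5-4.4% (4.3% for the
#' moderately-dispersive row) for controls.
#'
#' @param scale Multiplies every arm size (e.g. `scale = 0.4` for a reduced
#'   desk-scale cohort); sizes are rounded up.
#' @param seed Base seed; each arm gets a distinct offset.
#' @return List of [trial_arm()]s.
#' @export
reference_trial_arms <- function(scale = 1, seed = 1L) {
  n <- function(k) max(1L, as.integer(ceiling(k * scale)))
  trig <- list(list(metric = "hiden", lo = 2.0, hi = 2.8),
               list(metric = "necrosis", lo = 0.09, hi = 0.32))
  death_tx <- list(list(metric = "flair", lo = 55, hi = 88),
                   list(metric = "necrosis", lo = 3.5, hi = 4.4))
  death_ctrl <- function(nec_hi = 4.4)
    list(list(metric = "hiden", lo = 10, hi = 18),
         list(metric = "necrosis", lo = 3.5, hi = nec_hi))
  aa <- list(type = "anti_angiogenesis")
  none <- list(type = "none")
  list(
    trial_arm("HD+AA", n(30), "highly_dispersive", trig, death_tx, aa, seed = seed),
    trial_arm("MD+AA", n(25), "moderately_dispersive", trig, death_tx, aa, seed = seed + 1L),
    trial_arm("HypD+AA", n(25), "hypoxia_driven", trig, death_tx, aa, seed = seed + 2L),
    trial_arm("Control-HD", n(25), "highly_dispersive", trig, death_ctrl(),
              none, seed = seed + 3L),
    trial_arm("Control-MD", n(25), "moderately_dispersive", trig, death_ctrl(4.3),
              none, seed = seed + 4L),
    trial_arm("Control-HypD", n(25), "hypoxia_driven", trig, death_ctrl(),
              none, seed = seed + 5L))
}

#' Build a titrated cohort for an arm
#'
#' Each criterion range becomes an evenly spaced grid of `n` patient
#' thresholds (deterministic, reproducible); the first trigger grid stays
#' sorted and every other grid is shuffled against it (seed-offset per
#' criterion), so patients sample the criterion product space.
#'
#' @param arm A [trial_arm()].
#' @return Data frame with column `patient` plus one column per criterion,
#'   named `trigger_<metric>` / `death_<metric>`.
#' @export
make_cohort <- function(arm) {
  grid <- function(cr) if (arm$n == 1) (cr$lo + cr$hi) / 2
                       else seq(cr$lo, cr$hi, length.out = arm$n)
  out <- data.frame(patient = seq_len(arm$n))
  k <- 0L
  for (set in c("trigger", "death")) {
    crits <- if (set == "trigger") arm$treatment_criteria else arm$death_criteria
    for (cr in crits) {
      k <- k + 1L
      vals <- grid(cr)
      if (k > 1L) vals <- with_seed(arm$seed + k, sample(vals))
      out[[paste(set, cr$metric, sep = "_")]] <- vals
    }
  }
  out
}

# per-patient threshold list for one criterion set
cohort_thresholds <- function(cohort, criteria, set, i) {
  vapply(criteria, function(cr) cohort[[paste(set, cr$metric, sep = "_")]][i], 0)
}

# first row index (>= from) of summaries where any criterion crosses
first_crossing <- function(summaries, criteria, thresholds, from = 1L) {
  hit <- rep(FALSE, nrow(summaries))
  for (j in seq_along(criteria))
    hit <- hit | summaries[[metric_col(criteria[[j]]$metric)]] >= thresholds[j]
  hit[seq_len(from - 1L)] <- FALSE
  match(TRUE, hit)
}

#' Apply an intervention to model parameters
#'
#' Anti-angiogenesis sets the angiogenic rate `sigma` to zero; rate
#' reduction scales the mitotic rate `tau` by `1 - efficacy` (or multiplies
#' it pointwise by a spatial efficacy field); motility reduction scales the
#' hypoxia-driven transport coefficient `eta` by `1 - efficacy`.
#'
#' @param params A [model_params()].
#' @param intervention Intervention spec (see [trial_arm()]).
#' @return Modified `model_params`.
#' @export
apply_intervention <- function(params, intervention) {
  switch(intervention$type,
    none = params,
    anti_angiogenesis = { params$sigma <- 0; params },
    rate_reduction = {
      if (!is.null(intervention$field)) params$tau <- params$tau * intervention$field
      else params$tau <- params$tau * (1 - intervention$efficacy)
      params
    },
    motility_reduction = { params$eta <- params$eta * (1 - intervention$efficacy); params },
    stop(sprintf("unknown intervention type '%s'", intervention$type), call. = FALSE))
}

metric_col <- function(metric) paste0("pct_", metric)

#' Simulate a single virtual patient
#'
#' Grows a seeded tumour until the treatment (or diagnosis) criterion first
#' crosses the patient's threshold, applies the intervention, and continues
#' until the death criterion crosses.  Overall survival is the difference
#' between death and treatment times (censored at `max_time`).  The
#' radiologic progression pattern compares the first follow-up (see
#' [followup_time()]) with the appearance at death.
#'
#' @param geom A [brain_geometry()].
#' @param params A [model_params()] (phenotype motility already set).
#' @param trigger,death Named numeric vectors of thresholds in percent of
#'   brain, e.g. `c(hiden = 2.4, necrosis = 0.2)`; the first crossing among
#'   the named metrics fires.
#' @param intervention Intervention spec (see [trial_arm()]).
#' @param init Optional initial `tumor_state` (default: central seed).
#' @param cadence Monitoring interval, hours (default 12).
#' @param max_time Censoring guard, hours (default 5 years).
#' @return One-row data frame (a patient record).
#' @export
run_patient <- function(geom, params, trigger, death,
                        intervention = list(type = "none"),
                        init = NULL, cadence = 12, max_time = 43800) {
  if (is.null(init)) init <- seed_tumor(geom)
  any_cross <- function(s, thresholds) {
    any(vapply(names(thresholds),
               function(m) s[[metric_col(m)]] >= thresholds[[m]], TRUE))
  }
  # phase 1: untreated growth to the trigger (or death, or censoring)
  ph1 <- simulate_growth(geom, init, params,
                         stop = function(t, s) any_cross(s, trigger) || any_cross(s, death),
                         cadence = cadence, max_time = max_time)
  s1 <- ph1$summaries[nrow(ph1$summaries), ]
  if (ph1$censored || any_cross(s1, death)) {
    # never reached the trigger (or dead on arrival): degenerate record
    return(patient_record(params, t_treat = s1$t_hr, t_death = s1$t_hr,
                          censored = ph1$censored, at_treat = s1,
                          fu = s1, at_death = s1))
  }
  t_treat <- s1$t_hr
  params2 <- apply_intervention(params, intervention)
  ph2 <- simulate_growth(geom, ph1$final_state, params2,
                         stop = function(t, s) any_cross(s, death),
                         cadence = cadence, max_time = max_time)
  s2 <- ph2$summaries
  t_death <- s2$t_hr[nrow(s2)]
  fu_t <- followup_time(t_treat, t_death)
  fu <- s2[which.min(abs(s2$t_hr - fu_t)), ]
  patient_record(params, t_treat, t_death, ph2$censored,
                 at_treat = s1, fu = fu, at_death = s2[nrow(s2), ])
}

patient_record <- function(params, t_treat, t_death, censored,
                           at_treat, fu, at_death) {
  pattern <- progression_pattern(at_treat, fu, at_death)
  data.frame(delta = params$delta, eta = params$eta,
             tau = if (is.matrix(params$tau)) mean(params$tau) else params$tau,
             treatment_time = t_treat, death_time = t_death,
             os_months = hours_to_months(max(t_death - t_treat, 0)),
             censored = censored, pattern = pattern,
             pct_flair_death = at_death$pct_flair,
             pct_hiden_death = at_death$pct_hiden,
             pct_necrosis_death = at_death$pct_necrosis)
}

#' Run one trial arm
#'
#' The untreated growth phase is deterministic and shared: it is simulated
#' once per arm (with state snapshots at the monitoring cadence) and each
#' patient branches off at the first cadence point where their titrated
#' trigger threshold is crossed.  Arms without an intervention read death
#' times off the same shared trajectory.
#'
#' @param arm A [trial_arm()].
#' @param geom A [brain_geometry()].
#' @param base_params A [model_params()]; `delta`/`eta` are overridden by
#'   the arm's phenotype.
#' @param cadence Monitoring interval (hours).
#' @param max_time Censoring guard (hours).
#' @return Data frame of patient records (one row per patient).
#' @export
run_arm <- function(arm, geom, base_params = model_params(),
                    cadence = 12, max_time = 43800) {
  mp <- phenotype_params(arm$phenotype, arm$eta_level)
  params <- base_params
  params$delta <- mp$delta; params$eta <- mp$eta
  cohort <- make_cohort(arm)
  passive <- identical(arm$intervention$type, "none")
  # every patient's threshold pair is componentwise <= the upper range ends,
  # so the last branching point is the first crossing at those upper ends:
  # run the shared baseline exactly that far
  lax <- function(criteria) vapply(criteria, `[[`, 0, "hi")
  base <- simulate_growth(geom, seed_tumor(geom), params,
                          stop = function(t, s) {
                            if (passive)
                              !is.na(first_crossing(s, arm$death_criteria,
                                                    lax(arm$death_criteria)))
                            else
                              !is.na(first_crossing(s, arm$treatment_criteria,
                                                    lax(arm$treatment_criteria)))
                          },
                          cadence = cadence, max_time = max_time,
                          keep_states = !passive)
  bs <- base$summaries
  rows <- vector("list", arm$n)
  for (i in seq_len(arm$n)) {
    trig <- cohort_thresholds(cohort, arm$treatment_criteria, "trigger", i)
    dth <- cohort_thresholds(cohort, arm$death_criteria, "death", i)
    k_t <- first_crossing(bs, arm$treatment_criteria, trig)
    if (is.na(k_t)) {            # trigger never reached: censored at max time
      last <- bs[nrow(bs), ]
      rows[[i]] <- patient_record(params, last$t_hr, last$t_hr, TRUE, last, last, last)
      next
    }
    at_treat <- bs[k_t, ]
    if (passive) {
      k_d <- first_crossing(bs, arm$death_criteria, dth, from = k_t)
      censored <- is.na(k_d)
      if (censored) k_d <- nrow(bs)
      at_death <- bs[k_d, ]
      fu_t <- followup_time(at_treat$t_hr, at_death$t_hr)
      fu <- bs[which.min(abs(bs$t_hr - fu_t)), ]
      rows[[i]] <- patient_record(params, at_treat$t_hr, at_death$t_hr,
                                  censored, at_treat, fu, at_death)
    } else {
      params2 <- apply_intervention(params, arm$intervention)
      dcrit <- arm$death_criteria
      ph2 <- simulate_growth(geom, base$states[[k_t]], params2,
                             stop = function(t, s)
                               !is.na(first_crossing(s, dcrit, dth)),
                             cadence = cadence, max_time = max_time)
      s2 <- ph2$summaries
      at_death <- s2[nrow(s2), ]
      fu_t <- followup_time(at_treat$t_hr, at_death$t_hr)
      fu <- s2[which.min(abs(s2$t_hr - fu_t)), ]
      rows[[i]] <- patient_record(params, at_treat$t_hr, at_death$t_hr,
                                  ph2$censored, at_treat, fu, at_death)
    }
  }
  out <- do.call(rbind, rows)
  cbind(arm = arm$name, cohort, out)
}

#' Run a multi-arm trial
#'
#' Runs every arm, assembles the patient table, and computes per-arm
#' Kaplan-Meier curves, median survival, and pairwise log-rank comparisons.
#'
#' @param arms List of [trial_arm()]s (non-empty).
#' @param geom A [brain_geometry()].
#' @param base_params Base [model_params()].
#' @param group_controls Pool all arms whose intervention is `"none"` into a
#'   single `"Control"` group for the survival analysis (default `TRUE`,
#'   matching the reference design's single control curve).
#' @param cadence,max_time Passed to [run_arm()].
#' @return A `gbm_trial`: `patients` (data frame), `curves` (named list of
#'   [km_estimate()] results), `medians` (named vector, months), `logrank`
#'   (data frame of pairwise chi-square and p-values).
#' @export
run_trial <- function(arms, geom, base_params = model_params(),
                      group_controls = TRUE, cadence = 12, max_time = 43800) {
  if (!length(arms)) stop("empty arm list", call. = FALSE)
  tabs <- lapply(arms, run_arm, geom = geom, base_params = base_params,
                 cadence = cadence, max_time = max_time)
  # arms may differ in criterion columns; align before stacking
  cols <- unique(unlist(lapply(tabs, names)))
  pts <- do.call(rbind, lapply(tabs, function(d) {
    d[setdiff(cols, names(d))] <- NA
    d[cols]
  }))
  grp <- pts$arm
  if (group_controls) {
    ctrl <- vapply(arms, function(a) identical(a$intervention$type, "none"), TRUE)
    grp[pts$arm %in% vapply(arms[ctrl], `[[`, "", "name")] <- "Control"
  }
  pts$group <- grp
  groups <- unique(grp)
  curves <- lapply(groups, function(g)
    km_estimate(pts$os_months[grp == g], !pts$censored[grp == g]))
  names(curves) <- groups
  medians <- vapply(curves, median_survival, 0)
  pairs <- if (length(groups) > 1) t(combn(groups, 2)) else matrix(character(), 0, 2)
  lr <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    res <- logrank(pts$os_months[grp == a], !pts$censored[grp == a],
                   pts$os_months[grp == b], !pts$censored[grp == b])
    data.frame(group_a = a, group_b = b, chi2 = res$chi2, p = res$p)
  }))
  structure(list(patients = pts, curves = curves, medians = medians,
                 logrank = lr), class = "gbm_trial")
}

#' @export
print.gbm_trial <- function(x, ...) {
  cat("gbm_trial:", nrow(x$patients), "patients in",
      length(x$curves), "groups\n")
  cat("median overall survival (months):\n")
  print(round(x$medians, 2))
  if (!is.null(x$logrank) && nrow(x$logrank)) {
    cat("pairwise log-rank:\n")
    print(transform(x$logrank, chi2 = signif(chi2, 4), p = signif(p, 3)))
  }
  invisible(x)
}

#' @importFrom utils combn
NULL
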