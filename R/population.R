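# Efficacy sweeps: single-phenotype titration trials and the pooled
# population trial over all three phenotypes and variable mitotic rates.

# criteria for titration/population cohorts: reference diagnosis triggers;
# control-style deaths (the agent under test is the only intervention, so
# progression looks like untreated growth: expanding tumour mass/necrosis)
titration_arm <- function(phenotype, intervention, n, seed, label) {
  trig <- list(list(metric = "hiden", lo = 2.0, hi = 2.8),
               list(metric = "necrosis", lo = 0.09, hi = 0.32))
  death <- list(list(metric = "hiden", lo = 10, hi = 18),
                list(metric = "necrosis", lo = 3.5, hi = 4.4))
  trial_arm(label, n, phenotype, trig, death, intervention, seed = seed)
}

#' Titrate an intervention's efficacy in one phenotype
#'
#' Runs one cohort per efficacy value with a rate-reducing
#' (`parameter = "tau"`) or motility-reducing (`parameter = "eta"`) agent
#' applied at the treatment trigger, and reports the median overall
#' survival at each efficacy.  This is the single-phenotype dose-response
#' sweep behind futility assessment: hypoxia-driven tumours are expected to
#' be insensitive to rate reduction but to respond to motility reduction.
#'
#' @param phenotype Tumour phenotype (see [phenotype_params()]).
#' @param efficacies Fractions in `[0, 1)`: percent lowering of the mitotic
#'   (or motility) rate divided by 100.
#' @param parameter `"tau"` (rate-reducing agent) or `"eta"`
#'   (motility-reducing agent).
#' @param n Patients per efficacy value.
#' @param geom A [brain_geometry()].
#' @param base_params Base [model_params()].
#' @param seed Cohort seed.
#' @param cadence,max_time Passed to [run_arm()].
#' @return Data frame with `efficacy`, `median_os` (months), `n_censored`,
#'   plus the patient records as attribute `"patients"`.
#' @export
titration_trial <- function(phenotype, efficacies,
                            parameter = c("tau", "eta"), n = 10,
                            geom, base_params = model_params(), seed = 1L,
                            cadence = 12, max_time = 43800) {
  parameter <- match.arg(parameter)
  all_pts <- list()
  rows <- lapply(seq_along(efficacies), function(k) {
    e <- efficacies[k]
    iv <- if (parameter == "tau") list(type = "rate_reduction", efficacy = e)
          else list(type = "motility_reduction", efficacy = e)
    arm <- titration_arm(phenotype, iv,
                         n, seed + k, sprintf("%s-%s-%.2f", phenotype, parameter, e))
    pts <- run_arm(arm, geom, base_params, cadence = cadence, max_time = max_time)
    all_pts[[k]] <<- pts
    km <- km_estimate(pts$os_months, !pts$censored)
    data.frame(efficacy = e, median_os = median_survival(km),
               n_censored = sum(pts$censored))
  })
  out <- do.call(rbind, rows)
  attr(out, "patients") <- do.call(rbind, all_pts)
  out
}

#' Pooled population trial over phenotypes and mitotic rates
#'
#' For each efficacy of a rate-reducing agent, simulates cohorts spanning
#' all three motility phenotypes (equally represented) and `n_rates`
#' baseline mitotic rates drawn uniformly from `rate_interval`, with
#' `per_cell_n` criterion-titrated patients per (phenotype, rate) cell
#' (reference design: 25 x 3 x 13 = 975 patients per efficacy).  Patients
#' are untreated apart from the rate-reducing agent, which is applied at
#' the diagnosis trigger; the pooled median overall survival is reported
#' per efficacy.
#'
#' @param geom A [brain_geometry()].
#' @param efficacies Fractions in `[0, 1)`.
#' @param n_rates Number of baseline mitotic rates (default 13).
#' @param rate_interval Interval for the baseline rates, /hr
#'   (default `c(0.294, 0.35)`).
#' @param per_cell_n Patients per (phenotype, rate) cell (default 25).
#' @param base_params Base [model_params()].
#' @param seed Seed for the rate draws and cohort shuffles.
#' @param cadence,max_time Passed to [run_arm()].
#' @return Data frame with `efficacy` and pooled `median_os` (months);
#'   patient records in attribute `"patients"`.
#' @export
population_trial <- function(geom, efficacies = seq(0, 0.9, by = 0.1),
                             n_rates = 13, rate_interval = c(0.294, 0.35),
                             per_cell_n = 25, base_params = model_params(),
                             seed = 1L, cadence = 12, max_time = 43800) {
  phenos <- names(PHENOTYPE_DELTA)
  rates <- with_seed(seed, runif(n_rates, rate_interval[1], rate_interval[2]))
  all_pts <- list()
  rows <- lapply(seq_along(efficacies), function(k) {
    e <- efficacies[k]
    pts <- list()
    for (ph in phenos) for (j in seq_along(rates)) {
      pars <- base_params
      pars$tau <- rates[j]
      iv <- if (e > 0) list(type = "rate_reduction", efficacy = e)
            else list(type = "none")
      arm <- titration_arm(ph, list(type = "none"), per_cell_n,
                           seed + 100 * k + j,
                           sprintf("%s-r%.4f-e%.2f", ph, rates[j], e))
      arm$intervention <- iv
      pts[[paste(ph, j)]] <- cbind(run_arm(arm, geom, pars,
                                           cadence = cadence,
                                           max_time = max_time),
                                   efficacy = e, base_tau = rates[j])
    }
    pts <- do.call(rbind, pts)
    all_pts[[k]] <<- pts
    km <- km_estimate(pts$os_months, !pts$censored)
    data.frame(efficacy = e, median_os = median_survival(km),
               n = nrow(pts), n_censored = sum(pts$censored))
  })
  out <- do.call(rbind, rows)
  attr(out, "patients") <- do.call(rbind, all_pts)
  out
}
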