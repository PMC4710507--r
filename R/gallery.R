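# Orchestration: phenotype gallery, trial/population runners with file
# output, and a manifest for reproducibility.  These functions back the
# command-line interface in inst/cli/gliotrials.R.

#' Run the six-combination phenotype gallery
#'
#' Simulates the 3 x 2 grid of concentration-driven (high / medium / low
#' delta) by hypoxia-driven (high / low eta) motility combinations:
#' each tumour grows untreated to the first-met mid-range trigger
#' (high-density tumour 2.4% of brain or necrosis 0.2%), receives
#' anti-angiogenic treatment, and is followed for `post_months`.  Each run is labelled with its radiologic progression
#' pattern; growth curves are retained.
#'
#' @param geom A [brain_geometry()].
#' @param base_params Base [model_params()].
#' @param post_months Post-treatment follow-up horizon (months; the
#'   progression label compares the 2-month follow-up with the end of this
#'   horizon or death, whichever is first).
#' @param treated Apply anti-angiogenesis at the trigger (default `TRUE`);
#'   `FALSE` follows untreated growth over the same horizon.
#' @param cadence Monitoring cadence (hours).
#' @return A data frame with one row per combination (`delta`, `eta`,
#'   `phenotype`, `pattern`, trigger time and end-state areas); the
#'   trajectories are attached as attribute `"trajectories"`.
#' @export
phenotype_gallery <- function(geom, base_params = model_params(),
                              post_months = 4, treated = TRUE, cadence = 12) {
  combos <- expand.grid(phenotype = names(PHENOTYPE_DELTA),
                        eta_level = names(ETA_LEVELS),
                        stringsAsFactors = FALSE)
  trajs <- list()
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    ph <- combos$phenotype[k]; el <- combos$eta_level[k]
    mp <- phenotype_params(ph, el)
    pars <- base_params; pars$delta <- mp$delta; pars$eta <- mp$eta
    ph1 <- simulate_growth(geom, seed_tumor(geom), pars,
                           stop = function(t, s)
                             s$pct_hiden >= 2.4 || s$pct_necrosis >= 0.2,
                           cadence = cadence, max_time = 43800)
    at_treat <- ph1$summaries[nrow(ph1$summaries), ]
    pars2 <- if (treated) apply_intervention(pars, list(type = "anti_angiogenesis")) else pars
    horizon <- at_treat$t_hr + post_months * HOURS_PER_MONTH
    ph2 <- simulate_growth(geom, ph1$final_state, pars2,
                           stop = function(t, s) t >= horizon,
                           cadence = cadence, max_time = 43800)
    s2 <- ph2$summaries
    end <- s2[nrow(s2), ]
    fu <- s2[which.min(abs(s2$t_hr - followup_time(at_treat$t_hr, end$t_hr))), ]
    trajs[[k]] <<- rbind(ph1$summaries, s2[-1, ])
    data.frame(phenotype = ph, eta_level = el,
               delta = mp$delta, eta = mp$eta, treated = treated,
               trigger_hr = at_treat$t_hr,
               pattern = progression_pattern(at_treat, fu, end),
               pct_flair_end = end$pct_flair, pct_hiden_end = end$pct_hiden,
               pct_necrosis_end = end$pct_necrosis)
  })
  out <- do.call(rbind, rows)
  attr(out, "trajectories") <- trajs
  out
}

write_manifest <- function(dir, config, seed) {
  cfg_path <- file.path(dir, "config.txt")
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(x) paste(format(x), collapse = " "), "")),
             cfg_path)
  writeLines(c(sprintf("config_md5 = %s", unname(tools::md5sum(cfg_path))),
               sprintf("seed = %s", seed),
               sprintf("package_version = %s",
                       as.character(utils::packageVersion("gliotrials")))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Run the reference trial design and write its outputs
#'
#' Writes `patients.csv`, one `km_<group>.csv` per survival curve,
#' `logrank.csv`, and a `manifest.txt` (config hash, seed, version) under
#' `out_dir`.
#'
#' @param geom A [brain_geometry()].
#' @param out_dir Output directory (created if missing).
#' @param scale Cohort scale factor (see [reference_trial_arms()]).
#' @param seed Cohort seed.
#' @param base_params,cadence,max_time Passed to [run_trial()].
#' @return The [run_trial()] result, invisibly.
#' @export
cmd_trial <- function(geom, out_dir, scale = 1, seed = 1L,
                      base_params = model_params(), cadence = 12,
                      max_time = 43800) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arms <- reference_trial_arms(scale = scale, seed = seed)
  tr <- run_trial(arms, geom, base_params, cadence = cadence, max_time = max_time)
  write.table(tr$patients, file.path(out_dir, "patients.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  for (g in names(tr$curves)) {
    cv <- tr$curves[[g]]
    write.table(data.frame(time = cv$time, surv = cv$surv,
                           n_risk = cv$n_risk, n_event = cv$n_event),
                file.path(out_dir, paste0("km_", gsub("[^A-Za-z0-9]+", "_", g), ".csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
  }
  write.table(tr$logrank, file.path(out_dir, "logrank.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, list(scale = scale, cadence = cadence,
                               max_time = max_time, grid = geom$shape), seed)
  invisible(tr)
}

#' Run a population efficacy sweep and write its outputs
#'
#' Writes `population_curve.csv` (efficacy vs pooled median survival) and a
#' manifest under `out_dir`.
#'
#' @param geom A [brain_geometry()].
#' @param out_dir Output directory.
#' @param efficacies,n_rates,per_cell_n,seed Passed to [population_trial()].
#' @param base_params,cadence,max_time Passed to [population_trial()].
#' @return The [population_trial()] result, invisibly.
#' @export
cmd_population <- function(geom, out_dir, efficacies = seq(0, 0.9, by = 0.1),
                           n_rates = 13, per_cell_n = 25, seed = 1L,
                           base_params = model_params(), cadence = 12,
                           max_time = 43800) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- population_trial(geom, efficacies = efficacies, n_rates = n_rates,
                         per_cell_n = per_cell_n, base_params = base_params,
                         seed = seed, cadence = cadence, max_time = max_time)
  write.table(pc, file.path(out_dir, "population_curve.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, list(efficacies = efficacies, n_rates = n_rates,
                               per_cell_n = per_cell_n, grid = geom$shape), seed)
  invisible(pc)
}
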