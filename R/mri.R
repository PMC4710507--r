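# Virtual MRI: voxel classification, percent-of-brain summaries, and
# radiologic progression-pattern labels.

MRI_LEVELS <- c("normal", "flair", "hiden", "necrotic")

#' Classify voxels into virtual-MRI categories
#'
#' A brain voxel is `necrotic` if more than 80% of its brain cells are dead
#' (`B/B0 < 0.2`); otherwise `hiden` (high-density tumour, the
#' gadolinium-enhancement proxy) if `P + I > 0.7`; otherwise `flair` if
#' `0.05 <= P + I <= 0.7`; otherwise `normal`.  Precedence is
#' necrotic > hiden > flair, so a voxel with dead brain but residual tumour
#' reads as necrosis (the "hole in the brain").  Non-mask voxels are
#' unlabeled (`NA`).
#'
#' @param state A `tumor_state`.
#' @param geom A [brain_geometry()].
#' @return A factor matrix (levels `normal`, `flair`, `hiden`, `necrotic`).
#' @export
classify_voxels <- function(state, geom) {
  if (any(geom$B0[geom$mask] <= 0)) stop("B0 must be positive inside the mask", call. = FALSE)
  tumor <- state$P + state$I
  frac_alive <- matrix(NA_real_, geom$shape[1], geom$shape[2])
  frac_alive[geom$mask] <- state$B[geom$mask] / geom$B0[geom$mask]
  lab <- matrix(NA_integer_, geom$shape[1], geom$shape[2])
  lab[geom$mask] <- 1L
  lab[geom$mask & tumor >= 0.05 & tumor <= 0.7] <- 2L
  lab[geom$mask & tumor > 0.7] <- 3L
  lab[geom$mask & frac_alive < 0.2] <- 4L
  structure(lab, levels = MRI_LEVELS, class = c("mri_labels", "matrix"))
}

#' Summarise a label field as percent-of-brain areas
#'
#' @param labels Output of [classify_voxels()].
#' @param geom A [brain_geometry()].
#' @param t Time stamp (hours) attached to the summary.
#' @return A one-row data frame: `t_hr`, `pct_flair`, `pct_hiden`,
#'   `pct_necrosis` (percent of brain-mask voxels).
#' @export
summarize_labels <- function(labels, geom, t = NA_real_) {
  nb <- sum(geom$mask)
  data.frame(t_hr = t,
             pct_flair = 100 * sum(labels == 2L, na.rm = TRUE) / nb,
             pct_hiden = 100 * sum(labels == 3L, na.rm = TRUE) / nb,
             pct_necrosis = 100 * sum(labels == 4L, na.rm = TRUE) / nb)
}

#' One-call imaging summary of a state
#'
#' @inheritParams classify_voxels
#' @return As [summarize_labels()], stamped with `state$t`.
#' @export
imaging_summary <- function(state, geom) {
  summarize_labels(classify_voxels(state, geom), geom, t = state$t)
}

# direction of change: relative threshold plus an absolute band in
# percent-of-brain units (area changes below ~1% of the brain read as "no
# change" on MRI, so near-zero areas do not flag spurious progression)
change_arrow <- function(from, to, rel = 0.25, abs_floor = 1.0) {
  if (abs(to - from) <= abs_floor) return("stable")
  if (from <= 0) return(if (to > 0) "up" else "stable")
  r <- (to - from) / from
  if (r > rel) "up" else if (r < -rel) "down" else "stable"
}

#' Label the radiologic progression pattern
#'
#' Compares FLAIR and necrosis areas at progression against the first
#' follow-up using relative change (default threshold 25%, mirroring the
#' gadolinium response criterion): FLAIR up with stable necrosis is
#' `ExpandingFLAIR`; both up is `ExpandingFLAIRplusNecrosis`; stable FLAIR
#' with rising necrosis is `ExpandingNecrosis`; anything else is
#' `NoProgression`.
#'
#' @param at_treatment,first_fu,at_progression Imaging summaries (one-row
#'   data frames from [imaging_summary()]) in chronological order: at
#'   treatment start, at first follow-up (about 2 months on), and at
#'   progression/death.
#' @param rel_change_threshold Relative change defining the up/down arrows
#'   (default 0.25).  Changes below 1 percentage point of brain area count
#'   as "no change" regardless of the relative move.
#' @return One of `"ExpandingFLAIR"`, `"ExpandingFLAIRplusNecrosis"`,
#'   `"ExpandingNecrosis"`, `"NoProgression"`.
#' @export
progression_pattern <- function(at_treatment, first_fu, at_progression,
                                rel_change_threshold = 0.25) {
  ts <- c(at_treatment$t_hr, first_fu$t_hr, at_progression$t_hr)
  if (!any(is.na(ts)) && is.unsorted(ts))
    stop("summaries must be in chronological order", call. = FALSE)
  flair <- change_arrow(first_fu$pct_flair, at_progression$pct_flair, rel_change_threshold)
  necro <- change_arrow(first_fu$pct_necrosis, at_progression$pct_necrosis, rel_change_threshold)
  if (flair == "up" && necro == "stable") "ExpandingFLAIR"
  else if (flair == "up" && necro == "up") "ExpandingFLAIRplusNecrosis"
  else if (flair == "stable" && necro == "up") "ExpandingNecrosis"
  else "NoProgression"
}

#' First follow-up time for progression assessment
#'
#' Two simulated months after treatment; for patients who die sooner, the
#' midpoint between treatment and death, so the follow-up always falls
#' strictly between the two anchor scans.
#'
#' @param t_treat,t_death Treatment and death times (hours).
#' @return Follow-up time (hours).
#' @export
followup_time <- function(t_treat, t_death) {
  t_treat + pmin(2 * HOURS_PER_MONTH, (t_death - t_treat) / 2)
}

#' Export a label field as a PGM image
#'
#' Fixed 4-level palette: normal 64, FLAIR 128, high-density 192,
#' necrosis 255; non-brain 0.
#'
#' @param labels Output of [classify_voxels()].
#' @param path Output `.pgm` path.
#' @return `path`, invisibly.
#' @export
write_labels_pgm <- function(labels, path) {
  pal <- c(64L, 128L, 192L, 255L)
  img <- matrix(0L, nrow(labels), ncol(labels))
  ok <- !is.na(unclass(labels))
  img[ok] <- pal[unclass(labels)[ok]]
  write_pgm(img, path, maxval = 255)
}
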