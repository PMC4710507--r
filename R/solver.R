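# Spatial discretisation and explicit time integration on the brain grid.
#
# Scheme: forward Euler, 5-point Laplacian for concentration-driven
# diffusion, donor-cell (first-order upwind) fluxes for hypoxia-driven
# advection, no-flux faces at the mask boundary (skin and bones are
# impermeable).  The per-cadence inner loop runs in compiled code
# (advance_cpp); the R-level terms below define the same discretisation and
# serve as its reference.

CORE_DEATH_FRAC <- 0.2   # >= 80% brain death marks the necrotic core
CORE_D_EPS <- 1e-6       # residual diffusion support inside the core

# effective diffusion support: geometry D, collapsed in the necrotic core
effective_D <- function(geom, state = NULL) {
  De <- geom$D
  if (!is.null(state)) {
    dead <- geom$mask & (state$B <= CORE_DEATH_FRAC * geom$B0)
    De[dead] <- CORE_D_EPS
  }
  De
}

# apply f(a_voxel, b_voxel) over interior faces and accumulate +/- into out
face_accumulate <- function(mask, flux_fun) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  # vertical faces (r, r+1)
  up <- mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE]
  fl <- flux_fun(rbind(up, FALSE), rbind(FALSE, up))      # masks of face ends
  out[-nr, ] <- out[-nr, ] + fl[-nr, ]
  out[-1, ] <- out[-1, ] - fl[-nr, ]
  # horizontal faces (c, c+1)
  le <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
  fl <- flux_fun(cbind(le, FALSE), cbind(FALSE, le))
  out[, -nc] <- out[, -nc] + fl[, -nc]
  out[, -1] <- out[, -1] - fl[, -nc]
  out
}

#' Concentration-driven diffusion term
#'
#' Discrete `delta * div(D_eff grad I)` with no-flux faces at the mask
#' boundary, where `D_eff` equals the geometry's diffusion-enhancement field
#' except in the necrotic core (>= 80% brain death), where it collapses to
#' `1e-6` so invasive cells do not diffuse back into the dead centre.  Face
#' diffusivity is the arithmetic mean of the two voxels, making the
#' operator conservative: the output sums to zero over the grid.
#'
#' @param I Invasive-cell field (matrix on the geometry grid).
#' @param geom A [brain_geometry()].
#' @param state Optional `tumor_state` supplying `B` for core detection.
#' @param delta Diffusion coefficient (mm2/hr), `>= 0`.
#' @return Matrix of rates dI/dt (per hr).
#' @export
diffusion_term <- function(I, geom, state = NULL, delta) {
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  De <- effective_D(geom, state)
  h2 <- geom$spacing^2
  # flux into voxel a from voxel b across the shared face
  shift_flux <- function(ma, mb) {
    fl <- matrix(0, nrow(I), ncol(I))
    Dface <- 0.5 * (De + shift_like(De, ma, mb))
    dI <- shift_like(I, ma, mb) - I
    fl[ma] <- (delta * Dface * dI / h2)[ma]
    fl
  }
  face_accumulate(geom$mask, shift_flux)
}

# value of x at the face partner: ma marks the first end, mb the partner
# position (mb is ma shifted by one voxel); returns x shifted back onto ma
shift_like <- function(x, ma, mb) {
  out <- matrix(0, nrow(x), ncol(x))
  out[ma] <- x[mb]
  out
}

#' Hypoxia-driven advection term
#'
#' Discrete `-eta * div(I grad B)`: invasive cells move up the healthy-brain
#' gradient, away from necrosis, at speed `eta * |grad B|`.  Face velocities
#' use centred differences of `B`; the transported `I` is taken from the
#' donor (upwind) cell, and faces into non-mask voxels carry no flux, so
#' the term conserves the total of `I`.
#'
#' @param I Invasive-cell field.
#' @param B Brain-cell field.
#' @param geom A [brain_geometry()].
#' @param eta Active-transport coefficient (mm/hr), `>= 0`.
#' @return Matrix of rates dI/dt (per hr).
#' @export
advection_term <- function(I, B, geom, eta) {
  if (eta < 0) stop("eta must be >= 0", call. = FALSE)
  h <- geom$spacing
  shift_flux <- function(ma, mb) {
    fl <- matrix(0, nrow(I), ncol(I))
    u <- eta * (shift_like(B, ma, mb) - B) / h    # velocity away from a if > 0
    donor <- ifelse(u > 0, I, shift_like(I, ma, mb))
    fl[ma] <- (-u * donor / h)[ma]                # flux into a (negative if leaving)
    fl
  }
  face_accumulate(geom$mask, shift_flux)
}

#' Stable explicit time step
#'
#' `dt = safety * min(h^2 / (4 delta maxD), h^2 / (eta maxB0), 1 / (alpha +
#' beta + 100 gamma))`: the diffusion CFL bound, the advection CFL bound
#' with `|grad B| <= maxB0 / h`, and the stiffest pointwise reaction rate
#' (the necrosis rate approaches `100 gamma` as `B -> 0`).
#'
#' @param params A [model_params()].
#' @param geom A [brain_geometry()].
#' @param safety Safety factor (default 0.5).
#' @return Time step in hours.
#' @export
stable_dt <- function(params, geom, safety = 0.5) {
  h <- geom$spacing
  maxD <- max(geom$D, 1)
  dt_diff <- if (params$delta > 0) h^2 / (4 * params$delta * maxD) else Inf
  dt_adv <- if (params$eta > 0) h^2 / (params$eta * max(geom$B0)) else Inf
  dt_react <- 1 / (params$alpha + params$beta + 100 * params$gamma)
  safety * min(dt_diff, dt_adv, dt_react)
}

#' Advance the state by one forward-Euler step
#'
#' Applies the reaction terms plus the motility terms on `I`, then clips
#' negative values to zero (the clipped mass is recorded in the
#' `"clipped"` attribute of the result).
#'
#' @param state A `tumor_state`.
#' @param geom A [brain_geometry()].
#' @param params A [model_params()].
#' @param dt Step size (hours); must not exceed [stable_dt()] unless
#'   `override = TRUE`.
#' @param override Allow `dt` beyond the stability bound.
#' @return The updated `tumor_state`.
#' @export
euler_step <- function(state, geom, params, dt, override = FALSE) {
  if (!override && dt > stable_dt(params, geom))
    stop(sprintf("dt = %g exceeds the stability bound %g (use override = TRUE to force)",
                 dt, stable_dt(params, geom)), call. = FALSE)
  rt <- reaction_terms(state, params)
  dI_mot <- diffusion_term(state$I, geom, state, params$delta) +
    advection_term(state$I, state$B, geom, params$eta)
  new <- state
  new$P <- state$P + dt * rt$dP
  new$I <- state$I + dt * (rt$dI + dI_mot)
  new$B <- state$B + dt * rt$dB
  new$N <- state$N + dt * rt$dN
  clipped <- 0
  for (nm in c("P", "I", "B", "N")) {
    neg <- new[[nm]] < 0
    if (any(neg)) {
      clipped <- clipped - sum(new[[nm]][neg])
      new[[nm]][neg] <- 0
    }
  }
  new$t <- state$t + dt
  attr(new, "clipped") <- clipped
  new
}

as_tau_field <- function(params, geom) {
  if (is.matrix(params$tau)) {
    if (!same_shape(params$tau, geom$mask)) stop("tau field shape mismatch", call. = FALSE)
    params$tau
  } else matrix(params$tau, geom$shape[1], geom$shape[2])
}

# one compiled chunk of nsteps Euler steps
advance <- function(state, geom, params, dt, nsteps) {
  res <- advance_cpp(state$P, state$I, state$B, state$N,
                     geom$mask, geom$D, geom$B0, as_tau_field(params, geom),
                     geom$spacing, dt, as.integer(nsteps),
                     params$alpha, params$beta, params$gamma,
                     params$delta, params$eta, params$Omega, params$sigma,
                     params$Phi, params$steepness, params$allee,
                     params$angiogenic_drive == "total_tumor",
                     params$log_base == "natural",
                     CORE_DEATH_FRAC, CORE_D_EPS)
  out <- structure(list(P = res$P, I = res$I, B = res$B, N = res$N,
                        t = state$t + dt * nsteps),
                   class = "tumor_state")
  attr(out, "clipped") <- res$clipped
  out
}

#' Create a schedule event
#'
#' @param trigger A time (hours) or a predicate `function(t, summary)` on the
#'   current imaging summary; the event fires once, at the first cadence
#'   point where the trigger holds.
#' @param action A `function(params)` returning modified [model_params()]
#'   (e.g. set `sigma = 0`, scale `tau` or `eta`).
#' @param name Label recorded in the trajectory's event log.
#' @return A `schedule_event` object; pass a list of these to [simulate()].
#' @export
schedule_event <- function(trigger, action, name = "event") {
  stopifnot(is.function(action))
  structure(list(trigger = trigger, action = action, name = name),
            class = "schedule_event")
}

#' Simulate tumour growth with scheduled interventions
#'
#' Integrates the system from `init` with forward Euler at the stable step,
#' recording an imaging summary every `cadence` hours, firing schedule
#' events at their triggers, and stopping when `stop` holds (or at
#' `max_time`, in which case the run is flagged censored).
#'
#' @param geom A [brain_geometry()].
#' @param init Initial `tumor_state` (see [seed_tumor()]).
#' @param params A [model_params()].
#' @param schedule List of [schedule_event()]s (at most one treatment event
#'   per run).
#' @param stop Optional predicate `function(t, summary)`; the run ends at the
#'   first cadence point where it holds.
#' @param cadence Output/monitoring interval in hours (default 12).
#' @param max_time Censoring guard in hours (default 5 years).
#' @param keep_states Record a full state snapshot at every cadence point.
#' @return A `gbm_trajectory`: data frame `summaries` (columns `t_hr`,
#'   `pct_flair`, `pct_hiden`, `pct_necrosis`), event log `events`,
#'   `final_state`, `censored` flag, total `clipped` mass, and (optionally)
#'   `states`.
#' @export
simulate_growth <- function(geom, init, params, schedule = NULL, stop = NULL,
                     cadence = 12, max_time = 43800, keep_states = FALSE) {
  dt_max <- stable_dt(params, geom)
  nsub <- ceiling(cadence / dt_max)
  dt <- cadence / nsub
  state <- init
  fired <- logical(length(schedule))
  rows <- list(); events <- list(); states <- list()
  clipped <- 0; censored <- TRUE
  k <- 0L
  repeat {
    summ <- imaging_summary(state, geom)
    k <- k + 1L
    rows[[k]] <- summ
    if (keep_states) states[[k]] <- state
    for (j in seq_along(schedule)) {
      if (fired[j]) next
      ev <- schedule[[j]]
      hit <- if (is.function(ev$trigger)) isTRUE(ev$trigger(state$t, summ)) else state$t >= ev$trigger
      if (hit) {
        params <- ev$action(params)
        fired[j] <- TRUE
        events[[length(events) + 1L]] <- data.frame(name = ev$name, t_hr = state$t)
        # the stable step may change with the new parameters
        dt_max <- stable_dt(params, geom)
        nsub <- ceiling(cadence / dt_max)
        dt <- cadence / nsub
      }
    }
    if (!is.null(stop) && isTRUE(stop(state$t, summ))) { censored <- FALSE; break }
    if (state$t >= max_time) break
    state <- advance(state, geom, params, dt, nsub)
    clipped <- clipped + attr(state, "clipped")
  }
  total_mass <- sum(state$P) + sum(state$I) + sum(state$B) + sum(state$N)
  if (clipped > 1e-6 * total_mass)
    stop(sprintf("clipped negative mass %.3g exceeds 1e-6 of total mass %.3g: unstable run",
                 clipped, total_mass), call. = FALSE)
  structure(list(summaries = do.call(rbind, rows),
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(name = character(), t_hr = numeric()),
                 final_state = state,
                 states = if (keep_states) states else NULL,
                 censored = censored,
                 clipped = clipped,
                 params = params,
                 cadence = cadence),
            class = "gbm_trajectory")
}

#' @export
print.gbm_trajectory <- function(x, ...) {
  n <- nrow(x$summaries)
  last <- x$summaries[n, ]
  cat(sprintf("gbm_trajectory: %d samples to t = %.0f hr (%.2f months)%s\n",
              n, last$t_hr, hours_to_months(last$t_hr),
              if (x$censored) " [censored]" else ""))
  cat(sprintf("  end: FLAIR %.2f%%, high-density %.2f%%, necrosis %.2f%% of brain\n",
              last$pct_flair, last$pct_hiden, last$pct_necrosis))
  if (nrow(x$events))
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s @ %.0f hr", x$events$name, x$events$t_hr), collapse = ", ")))
  invisible(x)
}

#' Write a trajectory's summaries to CSV
#'
#' Columns: `t_hr`, `pct_flair`, `pct_hiden`, `pct_necrosis`.
#'
#' @param traj A `gbm_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.table(traj$summaries[, c("t_hr", "pct_flair", "pct_hiden", "pct_necrosis")],
              path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
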