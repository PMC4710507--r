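# Pointwise model closures and reaction terms of the growth/invasion system.
#
# State variables (dimensionless concentrations per voxel):
#   P proliferative cells, I invasive cells, B brain cells, N necrotic cells.
# Derived fields: C total concentration, Chyp hypoxic threshold, Cltm
# necrotic threshold, H local hypoxia in (0,1), M mitotic rate, gammaF
# necrosis rate.

#' Total cell concentration
#'
#' `C = P + I + B + N` pointwise.
#'
#' @param state A `tumor_state` (see [seed_tumor()]).
#' @return Matrix `C`.
#' @export
total_concentration <- function(state) {
  if (!same_shape(state$P, state$I) || !same_shape(state$P, state$B) ||
      !same_shape(state$P, state$N))
    stop("state fields must share one shape", call. = FALSE)
  state$P + state$I + state$B + state$N
}

#' Hypoxic threshold with angiogenesis
#'
#' `Chyp = sigma * log(1 + P) + Omega`, where `P` is the angiogenic drive
#' density.  Angiogenesis raises the local hypoxic threshold with tumour
#' density (a denser tumour recruits vessels and tolerates a higher total
#' concentration before turning hypoxic); `sigma = 0` emulates
#' anti-angiogenic treatment, fixing `Chyp = Omega`.  Inside
#' [reaction_terms()] the drive is the total tumour density `P + I` by
#' default (see `angiogenic_drive` in [model_params()]).
#'
#' @param P Angiogenic drive density (matrix or vector), `>= 0`.
#' @param params A [model_params()].
#' @return Field `Chyp`.
#' @export
hypoxic_threshold <- function(P, params) {
  if (any(P < 0)) stop("P must be >= 0", call. = FALSE)
  lg <- if (params$log_base == "decimal") log10(1 + P) else log1p(P)
  params$sigma * lg + params$Omega
}

#' Necrotic threshold
#'
#' `Cltm = Chyp + Phi`: cells die where the total concentration exceeds the
#' hypoxic threshold by the fixed gap `Phi`.
#'
#' @param Chyp Hypoxic-threshold field.
#' @param params A [model_params()].
#' @return Field `Cltm`.
#' @export
necrotic_threshold <- function(Chyp, params) Chyp + params$Phi

#' Measure of local hypoxia
#'
#' `H = (1 - tanh(k * (Chyp - C))) / 2` with steepness `k` (default 40):
#' a smooth switch in (0,1) that turns on as the total concentration
#' crosses the hypoxic threshold.
#'
#' @param C Total-concentration field.
#' @param Chyp Hypoxic-threshold field.
#' @param params A [model_params()].
#' @return Field `H` in (0,1).
#' @export
hypoxia_measure <- function(C, Chyp, params) {
  stopifnot_finite(C, "C"); stopifnot_finite(Chyp, "Chyp")
  (1 - tanh(params$steepness * (Chyp - C))) / 2
}

#' Mitotic rate
#'
#' `M = tau * (1 - H) * efficiency`: proliferation is maximal under
#' normoxia and shuts down under hypoxia.  `tau` may be a per-voxel field
#' (spatial rate reduction), in which case multiplication is pointwise.
#' `efficiency` is an optional extra factor in `[0, 1]`; [reaction_terms()]
#' passes the cooperative-growth factor `T/(T + allee)`.
#'
#' @param H Hypoxia field.
#' @param tau Maximal mitotic rate (/hr), scalar or matrix.
#' @param efficiency Optional pointwise efficiency factor (default 1).
#' @return Field `M`.
#' @export
mitotic_rate <- function(H, tau, efficiency = 1) {
  if (is.matrix(tau) && !same_shape(tau, as.matrix(H)))
    stop("tau field must match the grid shape", call. = FALSE)
  tau * (1 - H) * efficiency
}

#' Rate of necrosis
#'
#' `gammaF = gamma * ((P+I)/100 + 1/(B+0.01)) * (1 - tanh(k*(Cltm - C)))/2`.
#' The first factor caps the tumour mass (grows with P+I) and diverges as
#' the brain dies (B -> 0), so that no cell survives in the necrotic core;
#' the tanh switch confines necrosis to voxels above the necrotic threshold.
#'
#' @param state A `tumor_state`.
#' @param C Total-concentration field.
#' @param Cltm Necrotic-threshold field.
#' @param params A [model_params()].
#' @return Field `gammaF >= 0` (/hr).
#' @export
necrosis_rate <- function(state, C, Cltm, params) {
  mult <- (state$P + state$I) / 100 + 1 / (state$B + 0.01)
  params$gamma * mult * (1 - tanh(params$steepness * (Cltm - C))) / 2
}

#' Reaction terms of the growth/invasion system
#'
#' Pointwise (non-motility) right-hand sides:
#' \deqn{dP = M P - \alpha H P + \beta (1-H) I - \gamma_F P}
#' \deqn{dI = \alpha H P - \beta (1-H) I - \gamma_F I}
#' \deqn{dB = -\gamma_F B}
#' \deqn{dN = +\gamma_F (P + I + B)}
#' Motility (diffusion and active transport of I) is handled by the solver.
#' The terms satisfy the identity `dP + dI + dB + dN = M * P`: net growth of
#' proliferative cells is the only source of mass.
#'
#' @param state A `tumor_state`.
#' @param params A [model_params()].
#' @return List of matrices `dP`, `dI`, `dB`, `dN`, plus the derived fields
#'   `H`, `M`, `gammaF`.
#' @export
reaction_terms <- function(state, params) {
  for (nm in c("P", "I", "B", "N")) stopifnot_finite(state[[nm]], nm)
  C <- total_concentration(state)
  tumor <- state$P + state$I
  drive <- if (params$angiogenic_drive == "proliferative") state$P else tumor
  Chyp <- hypoxic_threshold(drive, params)
  Cltm <- necrotic_threshold(Chyp, params)
  H <- hypoxia_measure(C, Chyp, params)
  eff <- if (params$allee > 0) tumor / (tumor + params$allee) else 1
  M <- mitotic_rate(H, params$tau, eff)
  gF <- necrosis_rate(state, C, Cltm, params)
  conv_PI <- params$alpha * H * state$P
  conv_IP <- params$beta * (1 - H) * state$I
  list(dP = M * state$P - conv_PI + conv_IP - gF * state$P,
       dI = conv_PI - conv_IP - gF * state$I,
       dB = -gF * state$B,
       dN = gF * (state$P + state$I + state$B),
       H = H, M = M, gammaF = gF)
}
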