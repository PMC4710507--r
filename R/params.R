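# Model parameters and their reference values.

#' Model parameters for the growth/invasion system
#'
#' Rate and threshold constants of the go-or-grow model.  Defaults are the
#' reference parameterisation; `delta` and `eta` select the motility
#' phenotype (see [phenotype_params()]).
#'
#' @param alpha Transition rate P -> I under hypoxia (/hr).
#' @param beta Transition rate I -> P under normoxia (/hr).
#' @param tau Maximal mitotic rate of P cells (/hr); a scalar, or a per-voxel
#'   matrix for spatially varying rate reduction (tumour-treating-fields
#'   style).
#' @param delta Diffusion coefficient of invasive cells (mm2/hr);
#'   concentration-driven motility.
#' @param eta Active-transport coefficient of invasive cells (mm/hr);
#'   hypoxia-driven motility up the healthy-brain gradient.
#' @param gamma Necrotic rate of living cells (/hr).
#' @param Omega Initial hypoxic threshold (dimensionless concentration).
#' @param sigma Angiogenic rate; 1.5 simulates angiogenesis, 0 simulates
#'   anti-angiogenic treatment.
#' @param Phi Fixed gap between the necrotic and hypoxic thresholds
#'   (Cltm - Chyp > 0).
#' @param steepness Steepness constant of the tanh switches (default 40).
#' @param allee Cooperative-growth (Allee) density scale: the mitotic rate is
#'   multiplied by `T/(T + allee)` with `T = P + I`, so proliferation is
#'   inefficient below roughly this tumour density.  This suppresses the
#'   continuum-model artifact of invasion fronts carried by sub-cellular
#'   densities and makes invasion speed genuinely dependent on the motility
#'   coefficients.  Default 0.05 (the MRI detection floor).
#' @param angiogenic_drive Density driving the angiogenic rise of the hypoxic
#'   threshold: `"total_tumor"` (P+I, default) or `"proliferative"` (P only).
#' @param log_base Base of the logarithm in the angiogenesis term:
#'   `"natural"` (default) or `"decimal"`.
#' @return An object of class `model_params` (a named list).
#' @export
model_params <- function(alpha = 2.02, beta = 2.00, tau = 0.35,
                         delta = 4e-3, eta = 1.4e-3, gamma = 0.17,
                         Omega = 1.1, sigma = 1.5, Phi = 0.10,
                         steepness = 40, allee = 0.05,
                         angiogenic_drive = c("total_tumor", "proliferative"),
                         log_base = c("natural", "decimal")) {
  log_base <- match.arg(log_base)
  angiogenic_drive <- match.arg(angiogenic_drive)
  if (allee < 0) stop("allee must be >= 0", call. = FALSE)
  for (nm in c("alpha", "beta", "delta", "eta", "gamma", "Omega", "sigma", "steepness"))
    if (any(get(nm) < 0)) stop(sprintf("%s must be >= 0", nm), call. = FALSE)
  if (any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  if (Phi <= 0) stop("Phi must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, tau = tau, delta = delta,
                 eta = eta, gamma = gamma, Omega = Omega, sigma = sigma,
                 Phi = Phi, steepness = steepness, allee = allee,
                 angiogenic_drive = angiogenic_drive, log_base = log_base),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  tau_str <- if (is.matrix(x$tau)) sprintf("field (mean %.3g)", mean(x$tau)) else format(x$tau)
  cat(sprintf(paste0("model_params: alpha=%.3g beta=%.3g tau=%s delta=%.3g eta=%.3g\n",
                     "              gamma=%.3g Omega=%.3g sigma=%.3g Phi=%.3g steepness=%g (%s log)\n"),
              x$alpha, x$beta, tau_str, x$delta, x$eta,
              x$gamma, x$Omega, x$sigma, x$Phi, x$steepness, x$log_base))
  invisible(x)
}

#' Read or write model parameters as a flat key-value config file
#'
#' One `key = value` pair per line; unknown keys error.  `tau` fields
#' (matrices) are not serialised.
#'
#' @param path File path.
#' @param params A [model_params()] object (for writing).
#' @return For `read_params`, a `model_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- grep("=", readLines(path, warn = FALSE), fixed = TRUE, value = TRUE)
  kv <- do.call(rbind, strsplit(lines, "\\s*=\\s*"))
  vals <- as.list(setNames(kv[, 2], trimws(kv[, 1])))
  known <- names(formals(model_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop(sprintf("unknown parameter key(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  chr <- names(vals) %in% c("log_base", "angiogenic_drive")
  vals[!chr] <- lapply(vals[!chr], as.numeric)
  do.call(model_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  flat <- params[!vapply(params, is.matrix, TRUE)]
  writeLines(sprintf("%s = %s", names(flat), vapply(flat, format, "")), path)
  invisible(path)
}
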