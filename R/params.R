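#' Parameter set of an inducible auto-activation circuit
#'
#' Bundles the parameters of the deterministic rate model and its stochastic
#' (master-equation) counterpart: a transcription factor (TF) that must be
#' activated (e.g. phosphorylated) to work, and whose active form activates
#' transcription of its own gene through a Hill-type promoter.
#'
#' The promoter transcribes at the basal rate `alpha_max / fold` when no active
#' TF is present and saturates at `alpha_max`; `fold` is therefore the maximal
#' fold change of the promoter. Each transcription event instantly produces
#' `burst` proteins (mRNA is not modelled explicitly). Copy numbers N convert
#' to concentrations as N / volume.
#'
#' The derived composite `c = burst * alpha_max / (beta * volume * K)` is the
#' maximal steady-state TF concentration in units of the operator dissociation
#' constant `K`; together with `fold` and `hill_n` it fully determines the
#' shape of the dimensionless response.
#'
#' @param alpha_max Maximal transcription rate (transcription events per unit
#'   time; minutes are used throughout the shipped presets).
#' @param fold Maximal fold change f of the promoter (dimensionless, >= 1).
#' @param hill_n Hill coefficient n (> 0, not necessarily integer).
#' @param K Dissociation constant of the active TF at its operator
#'   (concentration units).
#' @param beta Degradation/dilution rate constant of the TF (per unit time).
#' @param burst Burst size b: proteins produced per transcription event
#'   (integer >= 1).
#' @param volume Cell volume V (converts copy number to concentration).
#' @return An object of class `circuit_params` (a validated named list with an
#'   additional element `c_comp`, the composite defined above).
#' @examples
#' p <- circuit_params(alpha_max = 1, fold = 100, hill_n = 1, K = 1,
#'                     beta = 1, burst = 1, volume = 1)
#' p$c_comp
#' @export
circuit_params <- function(alpha_max, fold, hill_n, K, beta, burst, volume) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single strictly positive finite number", nm),
           call. = FALSE)
  }
  chk_pos(alpha_max, "alpha_max")
  chk_pos(hill_n, "hill_n")
  chk_pos(K, "K")
  chk_pos(beta, "beta")
  chk_pos(volume, "volume")
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) || fold < 1)
    stop("'fold' must satisfy fold >= 1", call. = FALSE)
  if (!is.numeric(burst) || length(burst) != 1L || !is.finite(burst) ||
      burst < 1 || burst != round(burst))
    stop("'burst' must be an integer >= 1", call. = FALSE)
  p <- list(alpha_max = as.numeric(alpha_max), fold = as.numeric(fold),
            hill_n = as.numeric(hill_n), K = as.numeric(K),
            beta = as.numeric(beta), burst = as.integer(round(burst)),
            volume = as.numeric(volume))
  p$c_comp <- p$burst * p$alpha_max / (p$beta * p$volume * p$K)
  stopifnot(p$c_comp > 0)
  class(p) <- "circuit_params"
  p
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Auto-activation circuit parameters\n")
  cat(sprintf("  alpha_max = %g (max transcription rate)\n", x$alpha_max))
  cat(sprintf("  fold      = %g (basal rate = %g)\n", x$fold,
              x$alpha_max / x$fold))
  cat(sprintf("  hill_n    = %g\n", x$hill_n))
  cat(sprintf("  K         = %g\n", x$K))
  cat(sprintf("  beta      = %g\n", x$beta))
  cat(sprintf("  burst     = %d\n", x$burst))
  cat(sprintf("  volume    = %g\n", x$volume))
  cat(sprintf("  composite c = b*alpha/(beta*V*K) = %g\n", x$c_comp))
  invisible(x)
}

as_circuit_params <- function(p) {
  if (inherits(p, "circuit_params")) return(p)
  if (is.list(p))
    return(do.call(circuit_params,
                   p[c("alpha_max", "fold", "hill_n", "K", "beta", "burst",
                       "volume")]))
  stop("cannot interpret 'p' as circuit parameters", call. = FALSE)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta < 0) || any(theta > 1))
    stop("'theta' (activated fraction) must lie in [0, 1]", call. = FALSE)
  theta
}

#' Hill-type regulation function of the auto-activated promoter
#'
#' Transcription rate as a function of the active-TF concentration:
#' `alpha_max * (1/fold + (x_hat/K)^n) / (1 + (x_hat/K)^n)`.
#' Equals the basal rate `alpha_max/fold` at `x_hat = 0` and saturates at
#' `alpha_max`; half of the regulated range is recovered at `x_hat = K`.
#'
#' @param x_hat Concentration of active (modified) TF, >= 0. Vectorised.
#' @param p A [circuit_params()] object (or coercible list).
#' @return Transcription rate(s), in the units of `alpha_max`.
#' @examples
#' p <- circuit_params(1, 100, 1, 1, 1, 1, 1)
#' regulation_rate(0, p)    # basal: alpha_max / fold
#' regulation_rate(1, p)    # midpoint: (1/f + 1)/2 * alpha_max
#' @export
regulation_rate <- function(x_hat, p) {
  p <- as_circuit_params(p)
  if (any(!is.finite(x_hat) & !is.infinite(x_hat)) || any(x_hat < 0))
    stop("'x_hat' must be non-negative", call. = FALSE)
  u <- (x_hat / p$K)^p$hill_n
  r <- p$alpha_max * (1 / p$fold + u) / (1 + u)
  r[is.infinite(x_hat)] <- p$alpha_max
  r
}

#' Deterministic drift of the TF concentration
#'
#' Right-hand side of the rate equation
#' `dx/dt = (burst/volume) * g(theta * x) - beta * x`, where `g` is
#' [regulation_rate()]: bursty production from the promoter, read out at the
#' active-TF concentration `theta * x`, minus first-order degradation/dilution.
#'
#' @param x Total TF concentration, >= 0. Vectorised.
#' @param theta Activated fraction of TFs in `[0, 1]` (the circuit input).
#' @param p A [circuit_params()] object.
#' @return dx/dt in concentration per unit time.
#' @export
drift <- function(x, theta, p) {
  p <- as_circuit_params(p)
  check_theta(theta)
  if (any(x < 0)) stop("'x' must be non-negative", call. = FALSE)
  (p$burst / p$volume) * regulation_rate(theta * x, p) - p$beta * x
}
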