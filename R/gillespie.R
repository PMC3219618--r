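## Exact stochastic simulation (direct-method SSA) of the two-channel jump
## process: burst production at the promoter rate, single-molecule decay.
## The compiled core uses its own 64-bit Mersenne Twister so that replicate
## substreams (seed + replicate index) are reproducible independently of R's
## global RNG.

#' Simulate a stochastic trace of the circuit
#'
#' Statistically exact sample path of the copy-number jump process: jumps of
#' `+burst` at rate [regulation_rate()] evaluated at the active-TF
#' concentration `theta * N / volume`, and `-1` at rate `beta * N`. The input
#' schedule switches from `theta_before` to `theta_after` at `t_switch`
#' (defaults describe an induction experiment: signal off, then saturating
#' from t = 0).
#'
#' @param p A [circuit_params()] object.
#' @param t_end End time of the simulation.
#' @param n0 Initial copy number (integer >= 0).
#' @param seed Seed of the trace's RNG substream (mandatory; identical seeds
#'   give identical traces).
#' @param theta_before,theta_after,t_switch Input schedule (defaults 0, 1, 0).
#' @param max_events Event budget guard (default 1e7); exceeding it sets the
#'   `truncated` flag.
#' @return An object of class `ssa_trace`: list with `times`, `counts`
#'   (copy number after each event, starting state included), `truncated`,
#'   `seed`, `params`, `theta_schedule`.
#' @export
simulate_trace <- function(p, t_end, n0, seed, theta_before = 0,
                           theta_after = 1, t_switch = 0,
                           max_events = 1e7) {
  p <- as_circuit_params(p)
  if (t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  if (n0 < 0 || n0 != round(n0))
    stop("'n0' must be a non-negative integer", call. = FALSE)
  check_theta(c(theta_before, theta_after))
  r <- .ssa_trace_cpp(p$alpha_max, p$fold, p$hill_n, p$K, p$beta, p$burst,
                      p$volume, theta_before, theta_after, t_switch, t_end,
                      as.integer(n0), as.numeric(seed),
                      as.numeric(max_events))
  out <- list(times = r$times, counts = r$counts, truncated = r$truncated,
              seed = seed, params = p,
              theta_schedule = c(before = theta_before, after = theta_after,
                                 t_switch = t_switch))
  class(out) <- "ssa_trace"
  out
}

#' @export
print.ssa_trace <- function(x, ...) {
  cat(sprintf("SSA trace: %d events to t = %.4g (seed %s)%s\n",
              length(x$times) - 1L, max(x$times), format(x$seed),
              if (isTRUE(x$truncated)) " [event budget truncated]" else ""))
  invisible(x)
}

#' Sample stochastic induction times
#'
#' Each replicate draws its initial copy number from the stationary
#' distribution with the signal absent (`theta = 0`, inverse-CDF sampling of
#' the master-equation solution, keeping the two stochastic modules
#' consistent by construction), switches the signal to saturation, and runs
#' the SSA until the copy number first reaches the induction threshold
#' `N_th = ceiling(level * <N>_1)`. Replicates starting at or above the
#' threshold report a waiting time of 0.
#'
#' @param p A [circuit_params()] object.
#' @param reps Number of replicates (>= 1).
#' @param seed Base seed; replicate r uses substream `seed + r`.
#' @param level Threshold fraction of the induced stationary mean
#'   (default 0.5).
#' @param init Optional fixed initial copy number (overrides stationary
#'   sampling; used e.g. to probe the bare first-transcription waiting time
#'   from `N = 0`).
#' @param max_events Per-replicate event budget (default 1e7).
#' @return Numeric vector of first-passage times, with attribute
#'   `threshold_N`.
#' @export
sample_induction_times <- function(p, reps, seed, level = 0.5, init = NULL,
                                   max_events = 1e7) {
  p <- as_circuit_params(p)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  d1 <- steady_state_dist(1, p)
  threshold <- max(1L, as.integer(ceiling(level * d1$mean)))
  if (is.null(init)) {
    d0 <- steady_state_dist(0, p, n_max = d1$n_max)
    cdf <- cumsum(d0$p)
    ## inverse-CDF draws from a deterministic substream of the base seed
    u <- local_uniforms(seed, reps)
    n0 <- findInterval(u, cdf) # P(N <= k) = cdf[k+1]; value in 0..n_max
  } else {
    if (init < 0 || init != round(init))
      stop("'init' must be a non-negative integer", call. = FALSE)
    n0 <- rep(as.integer(init), reps)
  }
  ts <- .ssa_induction_cpp(p$alpha_max, p$fold, p$hill_n, p$K, p$beta,
                           p$burst, p$volume, as.integer(n0),
                           as.integer(threshold), as.numeric(seed),
                           as.numeric(max_events))
  if (anyNA(ts)) warning("some replicates exceeded the event budget")
  attr(ts, "threshold_N") <- threshold
  ts
}

## deterministic uniforms from the base seed without touching R's global RNG
local_uniforms <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  stats::runif(n)
}
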