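## Chemical master equation of the circuit on a truncated copy-number
## lattice {0, ..., n_max}: production in bursts of size b at rate
## g(theta * N / V) (promoter binding equilibrated), degradation N -> N-1 at
## rate beta * N. Stationary distributions by sparse linear solve, exact mean
## induction times and their second moments by first-passage linear solves.

#' Transition-rate generator of the stochastic circuit model
#'
#' Builds the conservative Markov generator Q on copy numbers
#' `{0, ..., n_max}`: `N -> N + burst` at rate
#' `regulation_rate(theta * N / volume, p)` and `N -> N - 1` at rate
#' `beta * N`. Production jumps that would overshoot the truncation are
#' redirected to `n_max` (reflecting cap), so every row of Q sums to zero;
#' the error committed is monitored through the stationary tail mass.
#'
#' @param theta Input in `[0, 1]`.
#' @param p A [circuit_params()] object.
#' @param n_max Truncation (integer >= burst).
#' @return A `Matrix::sparseMatrix` generator of dimension
#'   `(n_max + 1) x (n_max + 1)`, rows indexed by N = 0..n_max.
#' @export
build_generator <- function(theta, p, n_max) {
  p <- as_circuit_params(p)
  check_theta(theta)
  if (n_max < p$burst) stop("'n_max' must be at least the burst size",
                            call. = FALSE)
  Ns <- 0:n_max
  prod_rate <- regulation_rate(theta * Ns / p$volume, p)
  deg_rate <- p$beta * Ns
  to <- pmin(Ns + p$burst, n_max)
  i <- c(Ns, Ns[-1], Ns) + 1L
  j <- c(to, Ns[-1] - 1L, Ns) + 1L
  x <- c(prod_rate, deg_rate[-1], -(prod_rate + deg_rate))
  ## self-jumps at the cap (to == N) cancel against the diagonal
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(n_max + 1L, n_max + 1L))
}

auto_n_max <- function(theta, p) {
  r <- steady_states(1, p)$roots       # size to the induced state
  x_star <- max(r$x_star)
  max(ceiling(4 * x_star * p$volume), 20L * p$burst)
}

#' Stationary copy-number distribution
#'
#' Solves the null vector of the (transposed) generator by a sparse linear
#' solve with a normalisation row. The truncation starts at
#' `max(4 x* V, 20 b)` — four times the induced deterministic steady-state
#' copy number — and is doubled until the stationary mass in the top burst
#' band falls below `tail_tol`.
#'
#' @param theta Input in `[0, 1]`.
#' @param p A [circuit_params()] object.
#' @param n_max Optional truncation override (auto-sized by default).
#' @param tail_tol Tolerance on the stationary mass in states
#'   `> n_max - burst` (default 1e-8).
#' @return An object of class `copy_number_dist`: list with `p` (probability
#'   vector over N = 0..n_max), `n_max`, `mass_tail`, `theta`, and `mean`.
#' @examples
#' par <- circuit_params(5, 1, 1, 1, 1, 1, 1)
#' d <- steady_state_dist(1, par)   # Poisson(5): constant-rate birth-death
#' d$mean
#' @export
steady_state_dist <- function(theta, p, n_max = NULL, tail_tol = 1e-8) {
  p <- as_circuit_params(p)
  if (is.null(n_max)) n_max <- auto_n_max(theta, p)
  for (tries in 1:8) {
    Q <- build_generator(theta, p, n_max)
    A <- Matrix::t(Q)
    A[n_max + 1L, ] <- 1                      # normalisation replaces one eq.
    rhs <- c(rep(0, n_max), 1)
    pi_vec <- tryCatch(
      as.numeric(Matrix::solve(A, rhs)),
      error = function(e) NULL)
    if (is.null(pi_vec) || any(!is.finite(pi_vec))) {
      ## ill-conditioned: fall back to long-time propagation via power steps
      pi_vec <- propagate_uniform(Q, n_max)
    }
    pi_vec[pi_vec < 0] <- 0
    pi_vec <- pi_vec / sum(pi_vec)
    tail <- sum(pi_vec[(n_max - p$burst + 1L):(n_max + 1L)])
    if (tail < tail_tol) break
    n_max <- 2L * n_max
  }
  out <- list(p = pi_vec, n_max = n_max, mass_tail = tail, theta = theta,
              mean = sum((0:n_max) * pi_vec))
  class(out) <- "copy_number_dist"
  out
}

## uniformised power iteration fallback for the stationary vector
propagate_uniform <- function(Q, n_max) {
  lam <- max(-Matrix::diag(Q)) * 1.01
  P <- Matrix::Diagonal(n_max + 1L) + Q / lam
  v <- rep(1 / (n_max + 1L), n_max + 1L)
  for (k in 1:20000) {
    v_new <- as.numeric(Matrix::crossprod(P, v))
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < 1e-14) { v <- v_new; break }
    v <- v_new
  }
  v
}

#' @export
print.copy_number_dist <- function(x, ...) {
  cat(sprintf(
    "Copy-number distribution (theta = %g): mean %.2f, n_max %d, tail %.2e\n",
    x$theta, x$mean, x$n_max, x$mass_tail))
  invisible(x)
}

#' Detect bimodality of a copy-number distribution
#'
#' Peaks are local maxima of the (optionally width-3 smoothed) probability
#' vector; `N = 0` counts as a peak iff `p(0) > p(1)`. The distribution is
#' bimodal iff at least two peaks each hold at least `peak_mass_min`
#' probability in their basin (basins split at the minima between peaks).
#' Bistability (two deterministic stable states) and bimodality (two peaks of
#' the stationary distribution) are distinct notions: non-cooperative
#' circuits are never bistable, yet become bimodal whenever the basal
#' transcription rate drops below the degradation rate and the zero state
#' turns into a long-lived trap.
#'
#' @param dist A `copy_number_dist` (or bare probability vector over
#'   N = 0..n_max).
#' @param smooth Apply width-3 moving-average smoothing first (default TRUE).
#' @param peak_mass_min Minimum basin probability for a peak to count
#'   (default 1e-4).
#' @return A list with `is_bimodal`, `peaks` (copy numbers of retained
#'   peaks), `basin_mass`.
#' @export
detect_bimodality <- function(dist, smooth = TRUE, peak_mass_min = 1e-4) {
  pv <- if (inherits(dist, "copy_number_dist")) dist$p else as.numeric(dist)
  if (abs(sum(pv) - 1) > 1e-6) stop("'dist' must be normalised", call. = FALSE)
  ps <- pv
  if (smooth && length(pv) >= 3L) {
    ps <- stats::filter(pv, rep(1 / 3, 3), sides = 2)
    ps[1] <- pv[1]; ps[length(pv)] <- pv[length(pv)]
    ps <- as.numeric(ps)
  }
  n <- length(ps)
  is_peak <- logical(n)
  is_peak[1] <- ps[1] > ps[2]          # N = 0 is a peak iff p(0) > p(1)
  if (n > 2L)
    is_peak[2:(n - 1)] <- ps[2:(n - 1)] > ps[1:(n - 2)] &
                          ps[2:(n - 1)] >= ps[3:n]
  peaks <- which(is_peak) - 1L
  if (length(peaks) >= 2L) {
    ## basin boundaries: minima of ps between consecutive peaks
    bounds <- vapply(seq_len(length(peaks) - 1L), function(k) {
      lo <- peaks[k] + 1L; hi <- peaks[k + 1L] + 1L
      lo + which.min(ps[lo:hi]) - 1L
    }, numeric(1))
    edges <- c(0L, bounds, n)
    mass <- vapply(seq_along(peaks), function(k)
      sum(pv[(edges[k] + 1L):edges[k + 1L]]), numeric(1))
    keep <- mass >= peak_mass_min
    peaks <- peaks[keep]; mass <- mass[keep]
  } else {
    mass <- if (length(peaks)) 1 else numeric(0)
  }
  list(is_bimodal = length(peaks) >= 2L, peaks = peaks, basin_mass = mass)
}

## first-passage linear system: mean (and optionally second moment) of the
## time to first reach N >= threshold under the theta = 1 generator.
## Transient states 0..threshold-1; A h = 1, A m2 = 2 h, with
## A = diag(outflow) - transient-to-transient jumps.
first_passage_solve <- function(p, threshold, second_moment = FALSE) {
  Ns <- 0:(threshold - 1L)
  prod_rate <- regulation_rate(1 * Ns / p$volume, p)
  deg_rate <- p$beta * Ns
  nt <- threshold
  ii <- 1:nt; jj <- 1:nt; xx <- prod_rate + deg_rate
  keep <- which(Ns + p$burst < threshold)        # production staying transient
  ii <- c(ii, keep); jj <- c(jj, keep + p$burst); xx <- c(xx, -prod_rate[keep])
  keep2 <- which(Ns >= 1L)                       # degradation
  ii <- c(ii, keep2); jj <- c(jj, keep2 - 1L); xx <- c(xx, -deg_rate[keep2])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nt, nt))
  h <- as.numeric(Matrix::solve(A, rep(1, nt)))
  out <- list(h = h)
  if (second_moment) out$m2 <- as.numeric(Matrix::solve(A, 2 * h))
  out
}

#' Exact mean induction time from the master equation
#'
#' The circuit equilibrates with the signal absent (`theta = 0`); at t = 0
#' the signal switches to saturation (`theta = 1`). The induction time is the
#' first-passage time of the copy number to the threshold
#' `N_th = ceiling(level * <N>_1)`, where `<N>_1` is the stationary mean at
#' `theta = 1` (set `threshold_from = "deterministic"` to use the
#' deterministic steady state instead). Its mean over the stationary initial
#' distribution is computed exactly by solving the first-passage linear
#' system with absorbing set `{N >= N_th}`; initial states already at or
#' above the threshold contribute zero waiting time.
#'
#' @param p A [circuit_params()] object.
#' @param level Fraction of the induced level defining the threshold
#'   (default 0.5).
#' @param init Either `"stationary"` (default: the `theta = 0` stationary
#'   distribution) or a single non-negative integer copy number.
#' @param threshold_from `"stochastic"` (stationary mean at `theta = 1`;
#'   default) or `"deterministic"` (deterministic induced steady state).
#' @param cv Also compute the coefficient of variation of the induction time
#'   via the second-moment first-passage solve (default TRUE).
#' @return An object of class `induction_result`: list with `mean_time`,
#'   `threshold_N`, `cv` (or NA), `init_mean`, `method = "first_passage"`.
#' @examples
#' ## basal waiting time: threshold 1, start empty -> exactly fold/alpha_max
#' p <- circuit_params(1, 50, 1, 20, 0.025, 5, 1)
#' mean_induction_time(p, init = 0)$mean_time  # dominated by the first burst
#' @export
mean_induction_time <- function(p, level = 0.5, init = "stationary",
                                threshold_from = c("stochastic",
                                                   "deterministic"),
                                cv = TRUE) {
  p <- as_circuit_params(p)
  threshold_from <- match.arg(threshold_from)
  d1 <- steady_state_dist(1, p)
  induced <- if (threshold_from == "stochastic") d1$mean else {
    r <- steady_states(1, p)$roots
    max(r$x_star) * p$volume
  }
  threshold <- max(1L, as.integer(ceiling(level * induced)))
  fp <- first_passage_solve(p, threshold, second_moment = cv)
  if (identical(init, "stationary")) {
    d0 <- steady_state_dist(0, p, n_max = d1$n_max)
    w <- d0$p
    init_mean <- d0$mean
  } else {
    if (!is.numeric(init) || length(init) != 1L || init < 0 ||
        init != round(init))
      stop("'init' must be \"stationary\" or a non-negative integer",
           call. = FALSE)
    w <- numeric(max(threshold, init + 1L)); w[init + 1L] <- 1
    init_mean <- init
  }
  h_full <- c(fp$h, rep(0, max(0L, length(w) - threshold)))
  mean_time <- sum(w * h_full[seq_along(w)])
  cv_val <- NA_real_
  if (cv) {
    m2_full <- c(fp$m2, rep(0, max(0L, length(w) - threshold)))
    ex2 <- sum(w * m2_full[seq_along(w)])
    v <- max(ex2 - mean_time^2, 0)
    cv_val <- if (mean_time > 0) sqrt(v) / mean_time else NA_real_
  }
  out <- list(mean_time = mean_time, threshold_N = threshold, cv = cv_val,
              init_mean = init_mean, induced_mean = induced,
              method = "first_passage")
  class(out) <- "induction_result"
  out
}

#' @export
print.induction_result <- function(x, ...) {
  cat(sprintf(
    "Induction (method %s): mean time %.3f, threshold N >= %d, CV %s\n",
    x$method, x$mean_time, x$threshold_N,
    ifelse(is.na(x$cv), "-", sprintf("%.3f", x$cv))))
  invisible(x)
}

#' Distribution of induction times
#'
#' Summary of the induction-time distribution, either exactly via the first
#' two first-passage moments (`method = "moments"`: mean, sd, cv) or by
#' Gillespie sampling (`method = "simulate"`: adds empirical quantiles). In
#' the slow-induction regime (basal rate well below the degradation rate) the
#' wait for the first transcription event dominates and the distribution is
#' approximately exponential, so the CV approaches 1: induction is then both
#' slow and unpredictable.
#'
#' @param p A [circuit_params()] object.
#' @param level Threshold fraction (default 0.5).
#' @param method `"moments"` (default) or `"simulate"`.
#' @param reps,seed Replicates and seed for `method = "simulate"`.
#' @return A list with `mean`, `sd`, `cv`, `method`, and for simulation also
#'   `quantiles` (10/25/50/75/90%) and `times`.
#' @export
induction_time_distribution <- function(p, level = 0.5,
                                        method = c("moments", "simulate"),
                                        reps = 1000, seed = 1) {
  p <- as_circuit_params(p)
  method <- match.arg(method)
  if (method == "moments") {
    r <- mean_induction_time(p, level = level, cv = TRUE)
    list(mean = r$mean_time, sd = r$cv * r$mean_time, cv = r$cv,
         threshold_N = r$threshold_N, method = "moments")
  } else {
    ts <- sample_induction_times(p, reps = reps, seed = seed, level = level)
    list(mean = mean(ts), sd = stats::sd(ts),
         cv = stats::sd(ts) / mean(ts),
         quantiles = stats::quantile(ts, c(0.1, 0.25, 0.5, 0.75, 0.9)),
         times = ts, method = "simulate")
  }
}
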