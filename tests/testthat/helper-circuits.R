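## Shared fixtures: parameter sets used across the suite (built in code).

toy_params <- function(...) {
  defaults <- list(alpha_max = 1, fold = 100, hill_n = 1, K = 1, beta = 1,
                   burst = 1, volume = 1)
  do.call(circuit_params, modifyList(defaults, list(...)))
}

## induction-study conditions: minutes, c = b*alpha/(beta*V*K) = 10
induction_params <- function(...) {
  defaults <- list(alpha_max = 1, fold = 100, hill_n = 1, K = 20,
                   beta = 0.025, burst = 5, volume = 1)
  do.call(circuit_params, modifyList(defaults, list(...)))
}

## brute-force multiplicity scan: number of steady states from a dense sign
## scan of the drift (independent of the package root bracketing)
count_states_scan <- function(theta, p, n_grid = 20000) {
  x_hi <- 1.05 * p$burst * p$alpha_max / (p$beta * p$volume)
  xs <- c(0, exp(seq(log(x_hi * 1e-10), log(x_hi), length.out = n_grid)))
  d <- drift(xs, theta, p)
  sum(d[-1] * d[-length(d)] < 0)
}

## detailed-balance product form for burst = 1 (birth-death chain)
product_form_dist <- function(theta, p, n_max) {
  stopifnot(p$burst == 1L)
  birth <- regulation_rate(theta * (0:(n_max - 1)) / p$volume, p)
  death <- p$beta * (1:n_max)
  log_pi <- c(0, cumsum(log(birth) - log(death)))
  pi_vec <- exp(log_pi - max(log_pi))
  pi_vec / sum(pi_vec)
}

## transient distribution of the truncated master equation by matrix
## exponential (independent oracle for the SSA exactness check)
transient_dist <- function(theta, p, n_max, t, p0) {
  Q <- build_generator(theta, p, n_max)
  as.numeric(Matrix::expm(Matrix::t(Q) * t) %*% p0)
}

tv_dist <- function(a, b) {
  n <- max(length(a), length(b))
  sum(abs(c(a, numeric(n - length(a))) - c(b, numeric(n - length(b))))) / 2
}
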