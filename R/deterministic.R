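## Deterministic analysis: steady states, response curves, bistability,
## induction time, large-fold limits.
##
## In the dimensionless variables u = x/K (total TF) and w = theta*u (active
## TF), steady states of the rate equation satisfy
##     h(w) = c * theta,   h(w) = w (1 + w^n) / (1/f + w^n),
## with c = b*alpha/(beta*V*K). The turning points of h, obtained from a
## quadratic in z = w^n, carry the whole bifurcation structure: h is monotone
## (one steady state for every theta) iff f <= f_c(n) = ((n+1)/(n-1))^2, and
## otherwise steady-state multiplicity is 3 exactly for c*theta between the
## local minimum and local maximum of h.

h_response <- function(w, fold, hill_n) {
  w * (1 + w^hill_n) / (1 / fold + w^hill_n)
}

## Turning points of h(w): solutions of z^2 + B z + q = 0 in z = w^n with
## q = 1/f, B = 1 - n + (n+1) q. Returns NULL when h is monotone.
h_turning_points <- function(fold, hill_n) {
  q <- 1 / fold
  n <- hill_n
  B <- 1 - n + (n + 1) * q
  disc <- B^2 - 4 * q
  if (B >= 0 || disc <= 0) return(NULL)
  z_lo <- (-B - sqrt(disc)) / 2   # local max of h (smaller w)
  z_hi <- (-B + sqrt(disc)) / 2   # local min of h (larger w)
  w_max <- z_lo^(1 / n)
  w_min <- z_hi^(1 / n)
  ## bistable for c*theta in (m1, m2)
  list(w_at_max = w_max, w_at_min = w_min,
       m1 = h_response(w_min, fold, n), m2 = h_response(w_max, fold, n))
}

#' Critical fold change for bistability
#'
#' Smallest promoter fold change at which positive autoregulation with Hill
#' coefficient `hill_n` can be bistable: `f_c = ((n+1)/(n-1))^2` for `n > 1`.
#' For `fold < f_c` the circuit has a unique steady state for every input and
#' every value of the composite `c`; for `fold > f_c` a bistable input window
#' exists (possibly at inputs beyond the physical range `theta <= 1`).
#' Non-cooperative circuits (`n <= 1`) are never bistable (`f_c = Inf`).
#'
#' @param hill_n Hill coefficient (> 0). Vectorised.
#' @return Critical fold change(s); `Inf` for `hill_n <= 1`.
#' @examples
#' critical_fold(2)  # 9
#' critical_fold(3)  # 4
#' @export
critical_fold <- function(hill_n) {
  if (any(hill_n <= 0)) stop("'hill_n' must be positive", call. = FALSE)
  ifelse(hill_n > 1, ((hill_n + 1) / (hill_n - 1))^2, Inf)
}

#' Deterministic steady states at a given input
#'
#' Locates all roots of [drift()] on the a-priori bounded interval
#' `[0, 1.05 * burst * alpha_max / (beta * volume)]` (production is bounded,
#' so no steady state can exceed this) by a dense sign scan followed by
#' bracketed root polishing, and classifies each root's stability from the
#' sign of the drift's derivative.
#'
#' @param theta Activated fraction in `[0, 1]`.
#' @param p A [circuit_params()] object.
#' @param n_scan Number of scan points (log-spaced plus 0), default 400.
#' @param tol Relative tolerance for the residual check.
#' @return An object of class `steady_state_set`: a list with `theta` and a
#'   data frame `roots` (`x_star`, `stability`), roots sorted ascending with
#'   stabilities alternating stable/unstable/stable.
#' @examples
#' p <- circuit_params(1, 100, 2, 1, 1, 1, 1)
#' steady_states(0.5, p)
#' @export
steady_states <- function(theta, p, n_scan = 400, tol = 1e-8) {
  p <- as_circuit_params(p)
  check_theta(theta)
  x_hi <- 1.05 * p$burst * p$alpha_max / (p$beta * p$volume)
  xs <- c(0, exp(seq(log(x_hi * 1e-9), log(x_hi), length.out = n_scan)))
  d <- drift(xs, theta, p)
  ## drift(0) = basal production > 0, so the scan starts positive
  idx <- which(d[-1] * d[-length(d)] <= 0 & d[-length(d)] != 0)
  roots <- vapply(idx, function(j) {
    stats::uniroot(function(x) drift(x, theta, p),
                   interval = c(xs[j], xs[j + 1]), tol = 1e-13)$root
  }, numeric(1))
  roots <- sort(unique(roots))
  if (length(roots) == 0L || length(roots) %% 2L == 0L)
    stop(sprintf(paste0("failed to bracket an odd number of steady states ",
                        "(found %d) at scan resolution %d; increase 'n_scan'"),
                 length(roots), n_scan), call. = FALSE)
  resid <- abs(drift(roots, theta, p))
  if (any(resid > tol * p$beta * pmax(roots, p$K)))
    stop("steady-state residual exceeds tolerance; increase 'n_scan'",
         call. = FALSE)
  ## stability: sign of d(drift)/dx at the root
  eps <- pmax(roots, p$K) * 1e-6 + 1e-12
  slope <- (drift(roots + eps, theta, p) -
              drift(pmax(roots - eps, 0), theta, p)) / (2 * eps)
  stab <- ifelse(slope < 0, "stable", "unstable")
  out <- list(theta = theta,
              roots = data.frame(x_star = roots, stability = stab,
                                 stringsAsFactors = FALSE))
  class(out) <- "steady_state_set"
  out
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat(sprintf("Steady states at theta = %g:\n", x$theta))
  print(x$roots, row.names = FALSE)
  invisible(x)
}

#' Steady-state response curve of the circuit
#'
#' Total TF concentration `x*(theta)` and active-TF concentration
#' `x_hat*(theta) = theta * x*(theta)` over a grid of inputs. Where the
#' circuit is bistable both stable branches are reported (`branch` = "low" /
#' "high", plus "unstable" for the middle root when
#' `branch_policy = "all"`).
#'
#' @param theta_grid Ascending inputs in `[0, 1]`.
#' @param p A [circuit_params()] object.
#' @param branch_policy `"stable"` (default; stable branches only) or
#'   `"all"` (include the unstable middle branch).
#' @return A data frame with columns `theta`, `x_total`, `x_active`, `branch`,
#'   of class `response_curve`. The attribute `bistable_theta` holds the range
#'   of grid inputs with three steady states (or NULL).
#' @export
response_curve <- function(theta_grid, p, branch_policy = c("stable", "all")) {
  p <- as_circuit_params(p)
  branch_policy <- match.arg(branch_policy)
  check_theta(theta_grid)
  if (is.unsorted(theta_grid)) stop("'theta_grid' must be ascending",
                                    call. = FALSE)
  rows <- lapply(theta_grid, function(th) {
    r <- steady_states(th, p)$roots
    if (nrow(r) == 1L) {
      data.frame(theta = th, x_total = r$x_star, x_active = th * r$x_star,
                 branch = "single", stringsAsFactors = FALSE)
    } else {
      lab <- c("low", "unstable", "high")
      keep <- if (branch_policy == "stable") c(1L, 3L) else 1:3
      data.frame(theta = th, x_total = r$x_star[keep],
                 x_active = th * r$x_star[keep], branch = lab[keep],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  bi <- unique(out$theta[out$branch %in% c("low", "high")])
  attr(out, "bistable_theta") <- if (length(bi)) range(bi) else NULL
  class(out) <- c("response_curve", class(out))
  out
}

#' Classify the bistability regime of a parameter set
#'
#' Three regimes: `"I"` — a unique steady state for every input (no bistable
#' input window anywhere); `"II"` — a bistable window exists but does not
#' include the saturating input `theta = 1` (the window, located at
#' `theta` in `[m1/c, m2/c]` where `m1 < m2` are the turning-point values of
#' the dimensionless response, may lie partly or wholly beyond `theta = 1`);
#' `"III"` — bistable at saturating input. The I/(II,III) boundary is the
#' closed form [critical_fold()] and is independent of the composite `c`; the
#' II/III boundary depends on `c`.
#'
#' @param p A [circuit_params()] object.
#' @return A character scalar `"I"`, `"II"` or `"III"` with attributes
#'   `bistable_window` (theta interval, possibly extending beyond 1) when not
#'   `"I"`.
#' @export
classify_regime <- function(p) {
  p <- as_circuit_params(p)
  tp <- h_turning_points(p$fold, p$hill_n)
  if (is.null(tp)) return("I")
  lab <- if (tp$m1 <= p$c_comp && p$c_comp <= tp$m2) "III" else "II"
  attr(lab, "bistable_window") <- c(tp$m1 / p$c_comp, tp$m2 / p$c_comp)
  lab
}

#' Deterministic induction time
#'
#' Time for the TF concentration, started at the steady state of the
#' pre-induction input `theta_from` (or at `x0_override`), to first reach
#' `level` times the final stable steady state reached from that initial
#' condition at `theta_to`. Integration uses `deSolve::lsodar` (stiff-capable)
#' with a terminating root function at the threshold crossing.
#'
#' @param p A [circuit_params()] object.
#' @param theta_from,theta_to Pre- and post-induction inputs (defaults 0, 1).
#' @param level Fraction of the final steady state defining induction
#'   (default 0.5).
#' @param x0_override Optional initial concentration overriding the
#'   `theta_from` steady state.
#' @param horizon Integration cap in time units; if the threshold is not
#'   reached the result is `Inf` with attribute `horizon_exceeded = TRUE`
#'   (this happens in regime III, where the low branch never crosses).
#' @return Induction time (same time units as the rates); 0 if the initial
#'   state is already above the threshold.
#' @examples
#' p <- circuit_params(1, 1, 1, 1, 1, 1, 1)
#' induction_time_det(p, x0_override = 0)  # log(2): simple relaxation
#' @export
induction_time_det <- function(p, theta_from = 0, theta_to = 1, level = 0.5,
                               x0_override = NULL, horizon = NULL) {
  p <- as_circuit_params(p)
  check_theta(c(theta_from, theta_to))
  x0 <- if (is.null(x0_override)) {
    r <- steady_states(theta_from, p)$roots
    min(r$x_star[r$stability == "stable"])   # branch reached from basal state
  } else {
    if (x0_override < 0) stop("'x0_override' must be >= 0", call. = FALSE)
    x0_override
  }
  ss_to <- steady_states(theta_to, p)$roots
  stable <- ss_to$x_star[ss_to$stability == "stable"]
  ## final state on the branch reached from x0: smallest stable state >= the
  ## basin of x0 (the first stable state above the unstable root below x0,
  ## i.e. where the flow from x0 converges)
  x_final <- flow_target(x0, ss_to)
  target <- level * max(stable)   # 50% of the full induced level
  if (x0 >= target) return(0)
  if (is.null(horizon)) horizon <- 1e4 / p$beta
  if (x_final < target) {     # trapped on the low branch (regime III)
    out <- Inf
    attr(out, "horizon_exceeded") <- TRUE
    return(out)
  }
  o <- deSolve::lsodar(y = c(x = x0), times = c(0, horizon),
                       func = function(t, x, parms)
                         list(drift(unname(x), theta_to, p)),
                       parms = NULL,
                       rootfunc = function(t, x, parms) unname(x) - target,
                       rtol = 1e-10, atol = 1e-12 * p$K)
  t_root <- attr(o, "troot")
  if (is.null(t_root) || length(t_root) == 0L) {
    out <- Inf
    attr(out, "horizon_exceeded") <- TRUE
    return(out)
  }
  t_root[1]
}

## stable steady state the deterministic flow converges to from x0
flow_target <- function(x0, roots_df) {
  st <- roots_df$x_star[roots_df$stability == "stable"]
  un <- roots_df$x_star[roots_df$stability == "unstable"]
  if (length(st) == 1L) return(st)
  if (length(un) && x0 < un[1]) st[1] else st[length(st)]
}

#' Large-fold-change limiting response of the non-cooperative circuit
#'
#' In the limit `fold -> Inf` with `hill_n = 1`, the response becomes a sharp
#' threshold at `theta_c = 1/c`: below it expression is fully off (the basal
#' level vanishes as `1/fold`); above it the active-TF concentration is
#' threshold-linear, `x_active = K (c theta - 1)`, and the total TF
#' concentration is the shifted saturating curve `x_total = K (c - 1/theta)`.
#'
#' @param p A [circuit_params()] object with `hill_n = 1` (the limit forms
#'   are stated for the non-cooperative case).
#' @param theta Input(s) in `[0, 1]`. Vectorised.
#' @return A list with `theta_c`, and vectors `x_total_limit`,
#'   `x_active_limit` (0 below threshold).
#' @export
large_f_limits <- function(p, theta) {
  p <- as_circuit_params(p)
  if (abs(p$hill_n - 1) > 1e-12)
    stop("limit forms are defined for hill_n = 1", call. = FALSE)
  check_theta(theta)
  theta_c <- 1 / p$c_comp
  on <- theta > theta_c
  x_act <- ifelse(on, p$K * (p$c_comp * theta - 1), 0)
  x_tot <- ifelse(on, p$K * (p$c_comp - 1 / theta), 0)
  list(theta_c = theta_c, x_total_limit = x_tot, x_active_limit = x_act)
}
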