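## Log-log sensitivity measures of the circuit response x_active(theta):
## the maximal slope S_max (with exact closed form for the auto-activation
## circuit) and the average slope S_bar over the 10%-90% switching domain,
## plus the open-loop (cooperative-promoter) comparisons.

#' Exact maximal log-log sensitivity of the auto-activation response
#'
#' Closed form for the maximum of `d log(x_active) / d log(theta)` over the
#' monostable response of the auto-activation circuit:
#' `S_max = (1 + sqrt(f)) / ((n + 1) - (n - 1) * sqrt(f))`.
#' It equals 1 at `fold = 1` (no feedback), grows with `fold`, and diverges as
#' `fold` approaches [critical_fold()] — the onset of bistability. For the
#' non-cooperative circuit (`n = 1`) this reduces to `(1 + sqrt(f)) / 2`,
#' unbounded in `fold`: ultrasensitivity without molecular cooperativity.
#'
#' @param fold Fold change, in `[1, critical_fold(hill_n))`.
#' @param hill_n Hill coefficient (> 0).
#' @return `S_max` (dimensionless, >= 1), with attribute `theta_at_max` giving
#'   the input where the maximum slope is attained per unit composite
#'   (`theta_at_max = h(w*)/c` with `w* = f^(-1/(2n))`; the attribute reports
#'   `c * theta_at_max`, the c-invariant location).
#' @examples
#' smax_closed_form(100, 1)  # 5.5
#' smax_closed_form(9, 1)    # 2
#' @export
smax_closed_form <- function(fold, hill_n) {
  if (any(hill_n <= 0)) stop("'hill_n' must be positive", call. = FALSE)
  if (any(fold < 1)) stop("'fold' must be >= 1", call. = FALSE)
  fc <- critical_fold(hill_n)
  if (any(fold >= fc))
    stop("fold >= critical_fold(hill_n): response is bistable and S_max is undefined",
         call. = FALSE)
  rf <- sqrt(fold)
  s <- (1 + rf) / ((hill_n + 1) - (hill_n - 1) * rf)
  w_star <- fold^(-1 / (2 * hill_n))
  attr(s, "c_theta_at_max") <- h_response(w_star, fold, hill_n)
  s
}

#' Numeric maximal log-log slope of a response curve
#'
#' Independent numerical counterpart of [smax_closed_form()]: the maximum
#' centred finite-difference `d log y / d log theta` over a strictly positive,
#' single-valued curve, with 3-point parabolic refinement of the grid maximum.
#'
#' @param theta Ascending, strictly positive inputs.
#' @param y Strictly positive response values (e.g. `x_active` from
#'   [response_curve()]).
#' @return A list with `s_max` and `theta_at_max`.
#' @export
smax_numeric <- function(theta, y) {
  if (any(theta <= 0) || any(y <= 0))
    stop("log-log slope needs strictly positive 'theta' and 'y'",
         call. = FALSE)
  if (is.unsorted(theta, strictly = TRUE))
    stop("'theta' must be strictly ascending", call. = FALSE)
  lt <- log(theta); ly <- log(y)
  ## centred differences on the interior, one-sided at the ends
  n <- length(lt)
  if (n < 3L) stop("need at least 3 grid points", call. = FALSE)
  slope <- c((ly[2] - ly[1]) / (lt[2] - lt[1]),
             (ly[3:n] - ly[1:(n - 2)]) / (lt[3:n] - lt[1:(n - 2)]),
             (ly[n] - ly[n - 1]) / (lt[n] - lt[n - 1]))
  i <- which.max(slope)
  s_max <- slope[i]
  th_max <- theta[i]
  if (i > 1L && i < n) {  # parabolic refinement in log(theta)
    x3 <- lt[(i - 1):(i + 1)]; s3 <- slope[(i - 1):(i + 1)]
    d1 <- (s3[2] - s3[1]) / (x3[2] - x3[1])
    d2 <- (s3[3] - s3[2]) / (x3[3] - x3[2])
    if (is.finite(d1) && is.finite(d2) && d2 < d1) {
      xv <- (x3[1] + x3[2]) / 2 + d1 * (x3[3] - x3[1]) / (2 * (d1 - d2))
      ## quadratic vertex of the slope; keep it inside the bracket
      if (xv > x3[1] && xv < x3[3]) {
        th_max <- exp(xv)
        s_max <- max(s3)
      }
    }
  }
  list(s_max = s_max, theta_at_max = th_max)
}

#' Average log-log slope over the switching domain
#'
#' `S_bar = (log y(theta90) - log y(theta10)) / (log theta90 - log theta10)`,
#' where `theta10`/`theta90` are the inputs at which the monotone response
#' crosses 10% and 90% of its maximum value (the switching domain).
#'
#' @param theta Ascending, strictly positive inputs.
#' @param y Positive, non-decreasing response attaining its maximum at the
#'   last grid point.
#' @param thresholds Fractions of the maximum bounding the switching domain
#'   (default `c(0.1, 0.9)`). The alternative convention — fractions of the
#'   dynamic range above the basal level — is available via
#'   `range_above_basal = TRUE`.
#' @param range_above_basal Logical; see above. Default FALSE (fractions of
#'   the maximum).
#' @return A list with `s_bar` and `switching_domain = c(theta10, theta90)`.
#' @export
sbar <- function(theta, y, thresholds = c(0.1, 0.9),
                 range_above_basal = FALSE) {
  if (any(theta <= 0) || any(y < 0))
    stop("'theta' must be positive and 'y' non-negative", call. = FALSE)
  y_max <- y[length(y)]
  y_lo <- if (range_above_basal) y[1] + thresholds[1] * (y_max - y[1])
          else thresholds[1] * y_max
  y_hi <- if (range_above_basal) y[1] + thresholds[2] * (y_max - y[1])
          else thresholds[2] * y_max
  if (y[1] >= y_lo || y_max <= y_hi)
    stop("switching thresholds are not bracketed on the grid", call. = FALSE)
  cross <- function(level) {
    j <- which(y[-1] >= level & y[-length(y)] < level)[1]
    if (is.na(j)) stop("threshold not bracketed", call. = FALSE)
    ## log-linear interpolation
    exp(log(theta[j]) + (log(theta[j + 1]) - log(theta[j])) *
          (level - y[j]) / (y[j + 1] - y[j]))
  }
  t10 <- cross(y_lo); t90 <- cross(y_hi)
  list(s_bar = (log(y_hi) - log(y_lo)) / (log(t90) - log(t10)),
       switching_domain = c(t10, t90))
}

#' Sensitivity of an open-loop cooperative target promoter
#'
#' Maximal log-log sensitivity with which a target gene responds to the input
#' when the TF is expressed constitutively (open loop) and binds fully
#' cooperatively to `m_sites` sites on the target promoter with fold change
#' `fold_target`: `S = m_sites * (sqrt(f) - 1) / (sqrt(f) + 1)`.
#' Bounded above by `m_sites` (reached only as `fold_target -> Inf`): without
#' feedback, sensitivity at best equals the number of cooperative binding
#' sites.
#'
#' @param m_sites Number of fully cooperative TF binding sites (integer >= 1).
#' @param fold_target Fold change of the target promoter (>= 1).
#' @return `S_max` of the open-loop target response.
#' @examples
#' smax_open_loop(7, 100)   # 5.727...: the smallest m reaching 5.5 at f = 100
#' @export
smax_open_loop <- function(m_sites, fold_target) {
  if (any(m_sites < 1) || any(m_sites != round(m_sites)))
    stop("'m_sites' must be an integer >= 1", call. = FALSE)
  if (any(fold_target < 1)) stop("'fold_target' must be >= 1", call. = FALSE)
  rf <- sqrt(fold_target)
  m_sites * (rf - 1) / (rf + 1)
}

#' Minimal number of cooperative sites matching a target sensitivity
#'
#' Smallest integer `m` such that [smax_open_loop()] at fold change
#' `fold_target` reaches `s_target`.
#'
#' @param s_target Sensitivity to match.
#' @param fold_target Fold change of the open-loop target promoter.
#' @return Integer number of binding sites (`Inf` if unreachable at this
#'   fold, i.e. `fold_target = 1`).
#' @export
min_sites_matching <- function(s_target, fold_target) {
  per_site <- smax_open_loop(1, fold_target)
  if (per_site <= 0) return(Inf)
  as.integer(ceiling(s_target / per_site))
}

#' Average log-log slope of a basal-included Hill response (closed form)
#'
#' For a Hill response with basal level, `y = (1/f + u^n) / (1 + u^n)`
#' (maximum = saturation value 1), the switching-domain average slope is
#' `S_bar = 2 n log(3) / log(9 (0.9 - 1/f) / (0.1 - 1/f))`,
#' i.e. `(n/2) * phi(f)` with `phi(f) -> 1` from below as `f` grows. Defined
#' for `fold > 10` (the 10% threshold must exceed the basal level `1/f`).
#'
#' @param hill_n Hill coefficient of the promoter (> 0).
#' @param fold Fold change (> 10).
#' @return `S_bar` of the Hill response.
#' @export
sbar_hill <- function(hill_n, fold) {
  if (any(hill_n <= 0)) stop("'hill_n' must be positive", call. = FALSE)
  if (any(fold <= 10))
    stop("'fold' must exceed 10 (10% threshold must exceed the basal level)",
         call. = FALSE)
  q <- 1 / fold
  2 * hill_n * log(3) / log(9 * (0.9 - q) / (0.1 - q))
}

#' Full sensitivity report for a circuit
#'
#' Computes the response curve of the circuit on a geometric input grid and
#' reports both sensitivity measures: `s_max` (numeric, cross-checked against
#' the closed form when monostable) and `s_bar` with its switching domain.
#'
#' @param p A [circuit_params()] object (must be monostable, regime I).
#' @param theta_min,n_grid Geometric grid `[theta_min, 1]` with `n_grid`
#'   points (defaults 1e-3, 2000).
#' @return A list of class `sensitivity_report`: `s_max`, `theta_at_max`,
#'   `s_max_closed_form`, `s_bar`, `switching_domain`.
#' @export
sensitivity_report <- function(p, theta_min = 1e-3, n_grid = 2000) {
  p <- as_circuit_params(p)
  if (classify_regime(p) != "I")
    stop("sensitivity is defined for monostable (regime I) circuits",
         call. = FALSE)
  thg <- exp(seq(log(theta_min), 0, length.out = n_grid))
  rc <- response_curve(thg, p)
  sm <- smax_numeric(rc$theta, rc$x_active)
  sb <- sbar(rc$theta, rc$x_active)
  out <- list(s_max = sm$s_max, theta_at_max = sm$theta_at_max,
              s_max_closed_form = as.numeric(smax_closed_form(p$fold, p$hill_n)),
              s_bar = sb$s_bar, switching_domain = sb$switching_domain)
  class(out) <- "sensitivity_report"
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity of the activated-TF response\n")
  cat(sprintf("  S_max (numeric)      = %.4f at theta = %.4g\n",
              x$s_max, x$theta_at_max))
  cat(sprintf("  S_max (closed form)  = %.4f\n", x$s_max_closed_form))
  cat(sprintf("  S_bar                = %.4f over theta in [%.4g, %.4g]\n",
              x$s_bar, x$switching_domain[1], x$switching_domain[2]))
  invisible(x)
}
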