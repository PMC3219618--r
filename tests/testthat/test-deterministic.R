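test_that("steady states: no-feedback and basal limits are exact", {
  p1 <- toy_params(fold = 1)
  for (th in c(0, 0.5, 1)) {
    ss <- steady_states(th, p1)
    expect_equal(nrow(ss$roots), 1L)
    expect_equal(ss$roots$x_star, 1, tolerance = 1e-9)
    expect_equal(ss$roots$stability, "stable")
  }
  ## theta = 0: basal expression b*alpha/(f*beta*V) for any shape
  for (p in list(toy_params(), toy_params(fold = 7, hill_n = 3),
                 induction_params(fold = 40))) {
    ss <- steady_states(0, p)
    expect_equal(nrow(ss$roots), 1L)
    expect_equal(ss$roots$x_star,
                 p$burst * p$alpha_max / (p$fold * p$beta * p$volume),
                 tolerance = 1e-9)
  }
})

test_that("bistable window carries stable/unstable/stable structure", {
  p <- toy_params(fold = 25, hill_n = 2, K = 1 / 3)  # c = 3
  ss <- steady_states(0.75, p)
  expect_equal(nrow(ss$roots), 3L)
  expect_equal(ss$roots$stability, c("stable", "unstable", "stable"))
  expect_true(!is.unsorted(ss$roots$x_star, strictly = TRUE))
})

test_that("critical fold matches a brute-force multiplicity scan", {
  ## oracle: multiple steady states exist for some input iff the
  ## steady-state relation theta(x_active) is non-monotone; bisection on the
  ## smallest fold where monotonicity is lost (pure algebra of the
  ## steady-state condition, independent of the closed form)
  oracle_fc <- function(n, lo = 1.5, hi = 400) {
    has_window <- function(f) {
      w <- exp(seq(log(1e-4), log(1e4), length.out = 40000))
      theta_of_w <- w * (1 + w^n) / (1 / f + w^n)   # up to the factor 1/c
      any(diff(theta_of_w) < 0)
    }
    for (i in 1:40) {
      mid <- sqrt(lo * hi)
      if (has_window(mid)) hi <- mid else lo <- mid
    }
    sqrt(lo * hi)
  }
  expect_equal(oracle_fc(2), critical_fold(2), tolerance = 1e-4)
  expect_equal(oracle_fc(3), critical_fold(3), tolerance = 1e-4)
  expect_equal(oracle_fc(1.5), critical_fold(1.5), tolerance = 1e-4)
  expect_identical(critical_fold(1), Inf)
  expect_identical(critical_fold(0.6), Inf)
  expect_gt(critical_fold(1.01), 4e4)   # diverges as n -> 1+
})

test_that("regime classification follows the phase-diagram structure", {
  ## n = 1 is never bistable, whatever the fold
  for (f in c(1, 10, 1e4)) {
    expect_equal(classify_regime(toy_params(fold = f)), "I",
                 ignore_attr = TRUE)
  }
  ## below the critical fold: regime I for any c
  expect_equal(classify_regime(toy_params(fold = 8.9, hill_n = 2)), "I",
               ignore_attr = TRUE)
  ## just above: a bistable window exists; II vs III set by c
  expect_equal(classify_regime(toy_params(fold = 25, hill_n = 2, K = 1 / 3)),
               "II", ignore_attr = TRUE)                       # window inside
  expect_equal(classify_regime(induction_params(fold = 400, hill_n = 4)),
               "III", ignore_attr = TRUE)                      # saturating
  ## III really means bistable at theta = 1 (scan oracle)
  p3 <- induction_params(fold = 400, hill_n = 4)
  expect_equal(count_states_scan(1, p3), 3)
  ## I/(II,III) boundary independent of c; II/III boundary moves with c
  for (cc in c(0.5, 2, 10)) {
    p_lo <- toy_params(fold = 8.5, hill_n = 2, K = 1 / cc)
    p_hi <- toy_params(fold = 9.5, hill_n = 2, K = 1 / cc)
    expect_equal(classify_regime(p_lo), "I", ignore_attr = TRUE)
    expect_true(classify_regime(p_hi) %in% c("II", "III"))
  }
  regimes <- vapply(c(0.5, 2, 10), function(cc)
    as.character(classify_regime(toy_params(fold = 50, hill_n = 2.5,
                                            K = 1 / cc))), character(1))
  expect_true(length(unique(regimes)) > 1)
})

test_that("response curves: flat at f = 1, dimensionless collapse, near-critical steepness", {
  p1 <- toy_params(fold = 1)
  rc <- response_curve(seq(0.1, 1, by = 0.1), p1)
  expect_true(all(abs(rc$x_total - 1) < 1e-8))
  expect_equal(rc$x_active, rc$theta * rc$x_total)

  ## two parameter sets sharing (fold, hill_n, c) collapse after x -> x/K
  pa <- circuit_params(alpha_max = 2, fold = 30, hill_n = 1.5, K = 8,
                       beta = 0.5, burst = 1, volume = 1)   # c = 0.5
  pb <- circuit_params(alpha_max = 1, fold = 30, hill_n = 1.5, K = 4,
                       beta = 1, burst = 2, volume = 1)     # c = 0.5
  thg <- seq(0.05, 1, length.out = 30)
  ra <- response_curve(thg, pa); rb <- response_curve(thg, pb)
  expect_equal(ra$x_total / pa$K, rb$x_total / pb$K, tolerance = 1e-8)

  ## just below the critical fold: steep but single-valued
  p_near <- toy_params(fold = 8.95, hill_n = 2)
  rc2 <- response_curve(seq(0.01, 1, length.out = 120), p_near)
  expect_true(all(table(rc2$theta) == 1))                   # single branch
  expect_true(all(rc2$branch == "single"))
  ## monotone in theta for the active species (monostable set)
  expect_true(all(diff(rc2$x_active) > -1e-12))
})

test_that("deterministic induction time: exact limits and mild slowdown", {
  expect_equal(induction_time_det(toy_params(fold = 1)), 0)
  ## pure relaxation from empty: x(t) = x_ss (1 - exp(-beta t)) -> log(2)
  expect_equal(induction_time_det(toy_params(fold = 1), x0_override = 0),
               log(2), tolerance = 1e-6)
  p_b <- toy_params(fold = 1, beta = 0.25)
  expect_equal(induction_time_det(p_b, x0_override = 0), log(2) / 0.25,
               tolerance = 1e-6)
  ## regime III: trapped on the low branch -> Inf with flag
  t3 <- induction_time_det(induction_params(fold = 400, hill_n = 4))
  expect_true(is.infinite(t3))
  expect_true(attr(t3, "horizon_exceeded"))
})

test_that("induction time in units of 1/beta depends only on (fold, hill_n, c)", {
  pa <- induction_params(fold = 50)                       # beta = 0.025
  pb <- circuit_params(alpha_max = 2, fold = 50, hill_n = 1, K = 20,
                       beta = 0.05, burst = 5, volume = 1) # same c = 10
  ta <- induction_time_det(pa) * pa$beta
  tb <- induction_time_det(pb) * pb$beta
  expect_equal(ta, tb, tolerance = 1e-6)
})

test_that("large-fold limits: threshold at 1/c, threshold-linear active TF", {
  p <- induction_params(K = 50)          # c = 4 -> theta_c = 0.25
  lim <- large_f_limits(p, c(0.1, 0.2, 0.5, 1))
  expect_equal(lim$theta_c, 0.25)
  expect_equal(lim$x_active_limit, c(0, 0, 1, 3) * p$K)
  ## numeric response at fold = 1e6 approaches the limit forms
  p_big <- induction_params(K = 50, fold = 1e6)
  above <- vapply(c(0.5, 1), function(th)
    th * max(steady_states(th, p_big)$roots$x_star), numeric(1))
  expect_equal(above, lim$x_active_limit[3:4], tolerance = 5e-3)
  below <- max(steady_states(0.2, p_big)$roots$x_star)
  expect_lt(below, 2 * p$burst * p$alpha_max / (p_big$fold * p$beta) * 10)
  expect_error(large_f_limits(toy_params(hill_n = 2), 0.5), "hill_n")
})
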