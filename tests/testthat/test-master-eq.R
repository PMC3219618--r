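test_that("generator is conservative with the correct elementary rates", {
  p <- induction_params(fold = 50)
  Q <- build_generator(1, p, 200)
  expect_equal(max(abs(Matrix::rowSums(Q))), 0, tolerance = 1e-12)
  ## state 0: only outflow is basal production alpha/f
  expect_equal(Q[1, 1], -p$alpha_max / p$fold)
  expect_equal(Q[1, 1 + p$burst], p$alpha_max / p$fold)
  ## degradation N -> N-1 at beta*N
  expect_equal(Q[11, 10], p$beta * 10)
  ## fold = 1: production rate identical in every state
  Q1 <- build_generator(1, induction_params(fold = 1), 100)
  prod_rates <- vapply(1:90, function(k) Q1[k, k + induction_params()$burst],
                       numeric(1))
  expect_true(all(abs(prod_rates - 1) < 1e-12))
  expect_error(build_generator(1, p, 2), "burst")
})

test_that("stationary solution: Poisson limit, flux balance, product form", {
  ## f = 1, b = 1: constant-rate birth-death -> Poisson(alpha/beta)
  p <- circuit_params(alpha_max = 5, fold = 1, hill_n = 1, K = 1, beta = 1,
                      burst = 1, volume = 1)
  d <- steady_state_dist(1, p)
  expect_lt(tv_dist(d$p, dpois(0:d$n_max, 5)), 1e-6)
  ## f = 1, any burst: mean = b*alpha/beta exactly
  for (b in c(1, 5, 20)) {
    pb <- circuit_params(alpha_max = 2, fold = 1, hill_n = 1, K = 1,
                         beta = 0.5, burst = b, volume = 1)
    db <- steady_state_dist(1, pb)
    expect_equal(db$mean, b * 2 / 0.5, tolerance = 1e-6)
  }
  ## burst = 1 with feedback: detailed-balance product form
  pf <- toy_params(fold = 20, alpha_max = 8, K = 4)    # c = 2
  for (th in c(0.3, 1)) {
    df <- steady_state_dist(th, pf)
    expect_lt(tv_dist(df$p, product_form_dist(th, pf, df$n_max)), 1e-8)
  }
})

test_that("stationarity and conservation hold to solver precision", {
  p <- induction_params(fold = 60)
  d <- steady_state_dist(1, p)
  expect_equal(sum(d$p), 1, tolerance = 1e-10)
  Q <- build_generator(1, p, d$n_max)
  resid <- as.numeric(Matrix::t(Q) %*% d$p)
  expect_lt(max(abs(resid)), 1e-8)
  expect_lt(d$mass_tail, 1e-8)
  ## propagation preserves mass: p(t) = expm(Q^T t) p0
  p0 <- numeric(d$n_max + 1); p0[1] <- 1
  pt <- transient_dist(1, p, d$n_max, 5, p0)
  expect_equal(sum(pt), 1, tolerance = 1e-9)
})

test_that("stationary mean approaches the deterministic steady state at high copy number", {
  ## macroscopic agreement within 5% once the mean exceeds ~50 copies
  for (f in c(4, 10)) {
    p <- induction_params(fold = f)
    d <- steady_state_dist(1, p)
    x_det <- max(steady_states(1, p)$roots$x_star) * p$volume
    expect_gt(d$mean, 50)
    expect_equal(d$mean / x_det, 1, tolerance = 0.05)
  }
})

test_that("bimodality detection: unimodal references and the zero-state peak", {
  expect_false(detect_bimodality(dpois(0:60, 10))$is_bimodal)
  ## explicit two-peak mixture
  mix <- 0.4 * dpois(0:300, 2) + 0.6 * dpois(0:300, 120)
  det <- detect_bimodality(mix / sum(mix))
  expect_true(det$is_bimodal)
  expect_equal(length(det$peaks), 2L)
  ## n = 1 circuit with basal rate above beta: never bimodal
  p_hi <- induction_params(fold = 10)        # basal 0.1 >> beta 0.025
  expect_false(detect_bimodality(steady_state_dist(1, p_hi))$is_bimodal)
  ## low basal at modest copy number: the zero-state trap competes with a
  ## maintained on-state and the stationary law develops a peak at N = 0
  p_lo <- circuit_params(alpha_max = 0.5, fold = 200, hill_n = 1, K = 8,
                         beta = 0.05, burst = 2, volume = 1)  # basal/beta 0.05
  det_lo <- detect_bimodality(steady_state_dist(1, p_lo))
  expect_true(det_lo$is_bimodal)
  expect_true(0 %in% det_lo$peaks)
  expect_true(all(det_lo$basin_mass > 1e-4))
})

test_that("mean induction time: exact basal-wait limits", {
  ## threshold 1 from an empty cell: a single exponential wait at rate
  ## alpha/f -> mean exactly f/alpha
  p <- circuit_params(alpha_max = 1, fold = 50, hill_n = 1, K = 20, beta = 1,
                      burst = 5, volume = 1)   # induced mean ~ O(1) copies
  r <- mean_induction_time(p, init = 0)
  expect_lte(r$threshold_N, p$burst)           # first burst crosses
  expect_equal(r$mean_time, 50, tolerance = 1e-9)
  ## same holds whenever burst >= threshold
  p2 <- circuit_params(alpha_max = 2, fold = 30, hill_n = 1, K = 20,
                       beta = 1, burst = 10, volume = 1)
  r2 <- mean_induction_time(p2, init = 0)
  expect_lte(r2$threshold_N, p2$burst)
  expect_equal(r2$mean_time, 15, tolerance = 1e-9)
})

test_that("stochastic and deterministic induction agree at low fold only", {
  p_lo <- induction_params(fold = 4)
  r_lo <- mean_induction_time(p_lo)
  t_det_lo <- induction_time_det(p_lo)
  expect_equal(r_lo$mean_time / t_det_lo, 1, tolerance = 0.25)
  ## slowdown law: increasing in fold at fixed alpha_max
  folds <- c(4, 20, 100, 500)
  tms <- vapply(folds, function(f)
    mean_induction_time(induction_params(fold = f), cv = FALSE)$mean_time,
    numeric(1))
  expect_true(all(diff(tms) > 0))
  ## basal << beta: induction time of order f/alpha (within factor 2)
  p_hi <- induction_params(fold = 500)
  r_hi <- mean_induction_time(p_hi)
  expect_gt(r_hi$mean_time, 0.5 * 500)
  expect_lt(r_hi$mean_time, 2 * 500)
  ## ... and far above the deterministic prediction
  expect_gt(r_hi$mean_time / induction_time_det(p_hi), 2)
})

test_that("induction-time distribution: exponential regime and sharp regime", {
  ## slow regime: waiting for the first transcription dominates -> CV ~ 1
  d_slow <- induction_time_distribution(induction_params(fold = 1000))
  expect_gte(d_slow$cv, 0.8)
  expect_lte(d_slow$cv, 1.1)
  ## low fold at high copy number: induction proceeds through many
  ## near-deterministic accumulation steps -> much more predictable
  p_sharp <- circuit_params(alpha_max = 10, fold = 4, hill_n = 1, K = 200,
                            beta = 0.025, burst = 1, volume = 1)
  d_fast <- induction_time_distribution(p_sharp)
  expect_lt(d_fast$cv, 0.5)
  ## moments vs simulation agree
  d_sim <- induction_time_distribution(induction_params(fold = 50),
                                       method = "simulate", reps = 4000,
                                       seed = 11)
  d_mom <- induction_time_distribution(induction_params(fold = 50))
  se <- d_sim$sd / sqrt(length(d_sim$times))
  expect_lt(abs(d_sim$mean - d_mom$mean), 3 * se)
})

test_that("bimodality at n = 1 requires basal rate below degradation rate", {
  ## random sweep: the criterion basal < beta is necessary for bimodality
  set.seed(20240917)
  n_sets <- 60
  checked <- 0
  for (k in seq_len(n_sets)) {
    cc <- exp(stats::runif(1, log(0.5), log(20)))
    KV <- stats::runif(1, 2, 30)
    b <- sample(c(1, 2, 5, 10), 1)
    beta <- exp(stats::runif(1, log(0.02), log(1)))
    alpha <- cc * beta * KV / b
    fold <- exp(stats::runif(1, log(1), log(1000)))
    p <- circuit_params(alpha_max = alpha, fold = fold, hill_n = 1, K = KV,
                        beta = beta, burst = b, volume = 1)
    bi <- detect_bimodality(steady_state_dist(1, p))$is_bimodal
    if (bi) {
      checked <- checked + 1
      expect_lt(alpha / fold, beta,
                label = sprintf("bimodal set %d (c=%.2f f=%.1f b=%d)",
                                k, cc, fold, b))
    }
  }
  expect_gt(checked, 0)   # the sweep must actually exercise bimodal sets
})
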