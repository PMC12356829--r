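test_that("SDE discretization matches scalar closed forms and limits", {
  d <- discretize_sde(matrix(-1), 0, matrix(1), 1)
  expect_equal(drop(d$A_d), exp(-1), tolerance = 1e-10)
  expect_equal(drop(d$Q_d), (1 - exp(-2)) / 2, tolerance = 1e-10)
  expect_equal(drop(d$b_d), 0)

  # dt -> 0 continuity
  d0 <- discretize_sde(matrix(-1), 2, matrix(1), 1e-8)
  expect_equal(drop(d0$A_d), 1, tolerance = 1e-6)
  expect_lt(abs(drop(d0$Q_d)), 1e-6)
  expect_lt(abs(drop(d0$b_d)), 1e-6)

  expect_error(discretize_sde(matrix(c(0.5, 0, 0, -1), 2), c(0, 0), diag(2), 1),
               "not stationary")
  expect_error(discretize_sde(matrix(-1), 0, matrix(1), 0), "positive")
})

test_that("discretization satisfies semigroup and Lyapunov fixed point", {
  set.seed(11)
  for (rep in 1:5) {
    m <- sample(2:3, 1)
    A <- random_stationary_A(m)
    b <- rnorm(m)
    G <- diag(runif(m, 0.3, 1.5), m); G[lower.tri(G)] <- rnorm(m * (m - 1) / 2, 0, 0.2)
    dt <- runif(1, 0.3, 1.5)
    d1 <- discretize_sde(A, b, G, dt)
    d2 <- discretize_sde(A, b, G, 2 * dt)
    # Chapman-Kolmogorov: one step of 2*dt == two composed steps of dt
    expect_equal(d2$A_d, d1$A_d %*% d1$A_d, tolerance = 1e-10)
    expect_equal(d2$b_d, drop(d1$A_d %*% d1$b_d) + d1$b_d, tolerance = 1e-10)
    expect_equal(d2$Q_d, d1$A_d %*% d1$Q_d %*% t(d1$A_d) + d1$Q_d,
                 tolerance = 1e-10)
    # propagating the stationary covariance returns it unchanged
    expect_equal(d1$A_d %*% d1$Sinf %*% t(d1$A_d) + d1$Q_d, d1$Sinf,
                 tolerance = 1e-10)
  }
})

test_that("Kalman likelihood equals closed forms and the joint-Gaussian oracle", {
  # single scalar observation: predictive N(0, prior + meas) density
  sp <- ctsde_spec(matrix(-1), 0, matrix(1), meas_sd = 1,
                   init = list(mean = 0, cov = matrix(1)))
  pan <- ou_panel(list(a = list(times = 0, Y = matrix(0, 1, 1))), "y")
  expect_equal(kalman_loglik(sp, pan)$loglik, -0.5 * log(4 * pi),
               tolerance = 1e-10)

  # m = 2, T = 4 panels vs brute-force joint Gaussian, with missing values
  set.seed(13)
  for (rep in 1:5) {
    A <- random_stationary_A(2)
    b <- rnorm(2); G <- diag(runif(2, 0.4, 1.2)); ms <- runif(2, 0.1, 0.5)
    times <- cumsum(runif(4, 0.4, 1.6))
    Y <- matrix(rnorm(8), 2, 4)
    if (rep >= 3) Y[sample(8, 2)] <- NA  # partial missingness
    mu0 <- rnorm(2); P0 <- crossprod(matrix(rnorm(4), 2)) + diag(0.3, 2)
    sp2 <- ctsde_spec(A, b, G, ms, init = list(mean = mu0, cov = P0))
    pan2 <- ou_panel(list(s = list(times = times, Y = Y)), c("y1", "y2"))
    ll <- kalman_loglik(sp2, pan2)$loglik
    oracle <- joint_gaussian_loglik(times, Y, A, b, G, ms, mu0, P0)
    expect_equal(ll, oracle, tolerance = 1e-8)
    # C++ fast path agrees with the R reference filter
    llc <- racdyn:::cpp_kalman_loglik(times, Y, A, b, G, ms, mu0, P0)
    expect_equal(llc, ll, tolerance = 1e-10)
  }
})

test_that("fully-missing time points do not change the likelihood", {
  set.seed(17)
  A <- random_stationary_A(2); b <- rnorm(2); G <- diag(c(0.8, 1.1))
  ms <- c(0.3, 0.2)
  times <- c(0, 1, 2.5, 3.2)
  Y <- matrix(rnorm(8), 2, 4)
  sp <- ctsde_spec(A, b, G, ms, init = list(mean = c(0, 0), cov = diag(2)))
  ll1 <- kalman_loglik(sp, ou_panel(list(s = list(times = times, Y = Y)),
                                    c("y1", "y2")))$loglik
  t2 <- sort(c(times, 1.7, 2.9))
  Y2 <- matrix(NA_real_, 2, 6); Y2[, match(times, t2)] <- Y
  # direct filter run (panel constructor rejects all-missing columns by design)
  ll2 <- racdyn:::kalman_site(t2, Y2, A, b, G, ms, c(0, 0), diag(2))$loglik
  expect_lt(abs(ll1 - ll2), 1e-10)

  # evenly spaced data: equals the discrete VAR(1) likelihood (same oracle)
  teq <- 0:3
  lle <- racdyn:::kalman_site(teq, Y, A, b, G, ms, c(0, 0), diag(2))$loglik
  oracle <- joint_gaussian_loglik(teq, Y, A, b, G, ms, c(0, 0), diag(2))
  expect_lt(abs(lle - oracle), 1e-10)

  # global time shift leaves the likelihood invariant
  lls <- racdyn:::kalman_site(times + 123.4, Y, A, b, G, ms, c(0, 0),
                              diag(2))$loglik
  expect_lt(abs(ll1 - lls), 1e-10)
})

test_that("smoother: prior propagation, interpolation, variance reduction", {
  A <- matrix(-0.8); b <- 0.8; G <- matrix(0.9)
  # no observations: smoothed mean is the deterministic mean trajectory
  sp <- ctsde_spec(A, b, G, meas_sd = 0.3,
                   init = list(mean = 2, cov = matrix(0.4)))
  panel1 <- ou_panel(list(s = list(times = c(0, 1), Y = matrix(c(2, NA), 1))),
                     "y")
  sm <- kalman_smooth(sp, panel1, grid = seq(0, 4, by = 0.5))
  # beyond data the mean must relax toward the fixed point b/|a| = 1
  expect_equal(sm$mean[sm$time == 4],
               1 + (sm$mean[sm$time == 0] - 1) * exp(-0.8 * 4),
               tolerance = 1e-6)

  # noiseless exact observations are interpolated exactly
  set.seed(19)
  times <- cumsum(runif(6, 0.5, 1.2))
  sim <- simulate_ou_trajectories(list(A = A, b = b, G = G, meas_sd = 0,
                                       times = times), seed = 23)
  sp0 <- ctsde_spec(A, b, G, meas_sd = 0, init = "stationary")
  pan0 <- ou_panel(list(s = list(times = times, Y = sim$obs)), "y")
  sm0 <- kalman_smooth(sp0, pan0)
  expect_equal(sm0$mean, drop(sim$obs), tolerance = 1e-8)

  # smoothed variance never exceeds filtered variance
  sp1 <- ctsde_spec(A, b, G, meas_sd = 0.4, init = "stationary")
  sim1 <- simulate_ou_trajectories(list(A = A, b = b, G = G, meas_sd = 0.4,
                                        times = times), seed = 29)
  el <- list(times = times, Y = sim1$obs)
  ini <- racdyn:::spec_init(sp1, "s")
  kf <- racdyn:::kalman_site(times, el$Y, A, b, G, 0.4, ini$mean, ini$cov,
                             keep = TRUE)
  rts <- racdyn:::rts_smooth_site(kf)
  expect_true(all(rts$Ps[1, 1, ] <= kf$Pf[1, 1, ] + 1e-9))
})

test_that("grand-mean standardization centers, scales, and round-trips", {
  pan <- ou_panel(list(s1 = list(times = 1:3, Y = matrix(c(1, 2, 3), 1)),
                       s2 = list(times = 1:2, Y = matrix(c(4, NA), 1))),
                  "x")
  st <- standardize_panel(pan)
  allv <- c(st$panel$sites$s1$Y, st$panel$sites$s2$Y)
  expect_equal(mean(allv, na.rm = TRUE), 0)
  expect_equal(sd(allv, na.rm = TRUE), 1)
  expect_true(is.na(st$panel$sites$s2$Y[1, 2]))
  # back-transform recovers the original
  expect_equal(st$panel$sites$s1$Y * st$scale + st$center,
               pan$sites$s1$Y)
  # single-site (1,2,3) series standardizes to (-1, 0, 1)
  p1 <- ou_panel(list(s = list(times = 1:3, Y = matrix(c(1, 2, 3), 1))), "x")
  expect_equal(drop(standardize_panel(p1)$panel$sites$s$Y), c(-1, 0, 1))
  # constant variable is rejected by name
  pc <- ou_panel(list(s = list(times = 1:3, Y = matrix(c(2, 2, 2), 1))), "flat")
  expect_error(standardize_panel(pc), "flat")
})

test_that("ML fit: equilibrium intercept, rescaling covariance, methods", {
  # G = 0 equilibrium data pins down the fixed point -A^{-1} b
  eq <- c(1.5, -0.5)
  Y <- matrix(rep(eq, 5), 2, 5)
  pan <- ou_panel(list(s = list(times = cumsum(runif(5, 0.5, 1)), Y = Y)),
                  c("y1", "y2"))
  f <- fit_ctsde(pan, multistart = 2, seed = 3)
  mu_hat <- drop(solve(coef(f)$A, -coef(f)$b))
  expect_equal(mu_hat, eq, tolerance = 0.05, ignore_attr = TRUE)

  # time-unit covariance: doubling the time stamps halves the drift
  set.seed(37)
  times <- cumsum(runif(120, 0.5, 1.5))
  sim <- simulate_ou_trajectories(list(A = matrix(-1.5), b = 0, G = matrix(1),
                                       meas_sd = 0.2, times = times), seed = 41)
  p1 <- ou_panel(list(s = list(times = times, Y = matrix(sim$obs, 1))), "y")
  p2 <- ou_panel(list(s = list(times = 2 * times, Y = matrix(sim$obs, 1))), "y")
  f1 <- fit_ctsde(p1, multistart = 2, seed = 5)
  f2 <- fit_ctsde(p2, multistart = 2, seed = 5)
  expect_equal(f2$auto_effects / f1$auto_effects, 0.5, tolerance = 1e-3,
               ignore_attr = TRUE)

  # S3 surface
  expect_output(print(f1), "auto effects")
  s <- summary(f1)
  expect_s3_class(s, "summary.ctsde_fit")
  expect_true(all(c("parameter", "estimate", "se") %in% names(s$table)))
  expect_equal(dim(confint(f1)), c(f1$layout$n, 2L))
  expect_equal(nrow(residuals(f1)), 120L)
  sims <- simulate(f1, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "ou_panel")
  pr <- predict(f1)
  expect_true(all(pr$lo95 <= pr$hi95))
  # back-transformation to original units is the stored affine map
  prb <- predict(f1, center = c(y = 10), scale = c(y = 2))
  expect_equal(prb$mean, pr$mean * 2 + 10)
  expect_equal(prb$hi95 - prb$lo95, (pr$hi95 - pr$lo95) * 2)
})

test_that("auto-effect summaries order by persistence and flag signs", {
  set.seed(43)
  times <- cumsum(runif(150, 0.5, 1.5))
  A <- diag(c(-1.6543, -3.528)); dimnames(A) <- list(c("MMT", "CN"), c("MMT", "CN"))
  sim <- simulate_ou_trajectories(list(A = A, b = c(0, 0), G = diag(sqrt(2 * c(1.6543, 3.528))),
                                       meas_sd = c(0.2, 0.2), times = times), seed = 47)
  rownames(sim$obs) <- c("MMT", "CN")
  pan <- ou_panel(list(s = list(times = times, Y = sim$obs)), c("MMT", "CN"))
  # measurement noise fixed at its simulated value: this test exercises the
  # ordering/flag contract, not the meas-vs-drift identifiability frontier
  f <- fit_ctsde(pan, multistart = 2, seed = 7, fixed_meas_sd = 0.2)
  tab <- summarize_auto_effects(f)
  # simulated at the published scale: MMT is the more persistent variable
  expect_equal(tab$variable[which.min(abs(tab$auto_effect - max(tab$auto_effect)))],
               "MMT")
  expect_equal(tab$auto_effect, sort(tab$auto_effect, decreasing = TRUE))
  expect_type(tab$significant_negative, "logical")
  expect_false(any(tab$nonstationary))
})

test_that("hierarchical fit is reproducible and collapses to pooling", {
  set.seed(53)
  mk_site <- function(seed) {
    times <- cumsum(runif(50, 0.5, 1.5))
    sim <- simulate_ou_trajectories(list(A = matrix(-0.8), b = 0.4,
                                         G = matrix(1), meas_sd = 0.2,
                                         times = times), seed = seed)
    list(times = times, Y = matrix(sim$obs, 1))
  }
  pan <- ou_panel(list(s1 = mk_site(61), s2 = mk_site(62), s3 = mk_site(63)),
                  "y")
  h1 <- fit_ctsde_hierarchical(pan, draws = 400, warmup = 400, seed = 71,
                               priors = list(tau_a_fixed = 1e-4,
                                             tau_b_fixed = 1e-4))
  h2 <- fit_ctsde_hierarchical(pan, draws = 400, warmup = 400, seed = 71,
                               priors = list(tau_a_fixed = 1e-4,
                                             tau_b_fixed = 1e-4))
  expect_identical(h1$draws, h2$draws)            # same seed, same chains

  # degenerate hierarchy (tau -> 0): population drift agrees with the pooled
  # ML drift within the (wide) sampling uncertainty of both
  ml <- fit_ctsde(pan, multistart = 2, seed = 11)
  expect_lt(abs(unname(h1$auto_effects) - unname(ml$auto_effects)),
            2 * ml$se[1])
  expect_true(h1$auto_lo95 < ml$auto_effects &&
                ml$auto_effects < h1$auto_hi95)
  # all sites share one value when tau is pinned near zero
  site_meds <- vapply(h1$site_auto, function(x) x[1, 2], 0)
  expect_lt(diff(range(site_meds)), 1e-2)
  tab <- summarize_auto_effects(h1)
  expect_true(all(c("auto_effect", "lo95", "hi95") %in% names(tab)))
})
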