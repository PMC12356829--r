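test_that("subcommunity profiles honor dominance and the simplex", {
  beta <- make_subcommunity_profiles(K = 1, W = 10, dominance = 0.91, seed = 1)
  expect_equal(beta[1, 1], 0.91)
  expect_equal(sum(beta), 1)
  expect_equal(hyperdominance_count(beta[1, ]), 1L)

  # flat case: dominance 1/W with uniform residual is the uniform row
  flat <- make_subcommunity_profiles(1, 10, 1 / 10, sdlog = 0, seed = 1)
  expect_equal(unname(flat[1, ]), rep(0.1, 10))

  b3 <- make_subcommunity_profiles(3, 40, c(0.2, 0.5, 0.9), seed = 2)
  expect_equal(unname(rowSums(b3)), rep(1, 3))
  expect_equal(unname(diag(b3[, 1:3])), c(0.2, 0.5, 0.9))

  expect_error(make_subcommunity_profiles(1, 10, 1.0), "dominance")
})

test_that("generate_lda_counts follows the generative model", {
  # K = 1 collapse: every read label is 1, counts ~ Multinomial(beta1)
  g1 <- generate_lda_counts(list(K = 1, W = 5, D = 3, alpha = 1, gamma = 1,
                                 depths = 50), seed = 4)
  expect_true(all(unlist(g1$truth$z) == 1L))
  expect_equal(unname(rowSums(g1$counts)), rep(50L, 3))

  # determinism: same seed, bitwise-identical output
  g2 <- generate_lda_counts(list(K = 3, W = 20, D = 5, alpha = 0.5,
                                 gamma = 0.2, depths = 100), seed = 9)
  g3 <- generate_lda_counts(list(K = 3, W = 20, D = 5, alpha = 0.5,
                                 gamma = 0.2, depths = 100), seed = 9)
  expect_identical(g2, g3)

  expect_error(generate_lda_counts(list(K = 2, W = 5, D = 2, alpha = 0,
                                        gamma = 1, depths = 10)), "alpha")
})

test_that("pooled taxon frequencies match the analytic mixture (LLN)", {
  g <- generate_lda_counts(list(K = 3, W = 30, D = 200, alpha = 0.1,
                                gamma = 0.1, depths = 1000), seed = 7)
  total <- sum(g$counts)
  emp <- colSums(g$counts) / total
  # conditional on realized theta/beta, reads are iid draws from the mixture
  expected <- colMeans(g$truth$theta %*% g$truth$beta)
  se <- sqrt(expected * (1 - expected) / total)
  expect_true(all(abs(emp - expected) < 3 * se + 1e-12))
})

test_that("tree-structured heterogeneity perturbs only below the cut", {
  set.seed(21)
  W <- 16
  beta <- make_subcommunity_profiles(2, W, c(0.3, 0.5), seed = 3)
  phy <- ape::rtree(W, tip.label = colnames(beta))
  tt <- taxon_tree(phy)

  # sd = 0 is the identity
  p0 <- perturb_profiles_ltn(beta, tt, C = 1, sd = 0, n_samples = 3, seed = 5)
  expect_equal(p0[, , 2], beta)

  # cut at/above the maximum depth is a no-op
  pmaxd <- perturb_profiles_ltn(beta, tt, C = tt$max_depth, sd = 1,
                                n_samples = 2, seed = 5)
  expect_equal(pmaxd[, , 1], beta)

  # perturbation moves mass, rows stay on the simplex
  p1 <- perturb_profiles_ltn(beta, tt, C = 2, sd = 0.8, n_samples = 4, seed = 6)
  expect_gt(max(abs(p1[, , 1] - beta)), 1e-4)
  expect_equal(unname(apply(p1, 3, rowSums)), matrix(1, 2, 4))

  # mass aggregated at depth-C nodes is invariant under the perturbation
  C <- 2
  labs <- racdyn:::ancestor_labels_at_depth(tt, colnames(beta), C)
  agg <- function(mat) sapply(split(seq_len(W), labs),
                              function(j) rowSums(mat[, j, drop = FALSE]))
  for (s in 1:4) expect_equal(agg(p1[, , s]), agg(beta), tolerance = 1e-9)

  expect_error(perturb_profiles_ltn(beta, tt, C = 1, sd = -1, n_samples = 1),
               "sd")
})

test_that("OU trajectories: equilibrium, stationary variance, gap growth", {
  # deterministic equilibrium: G = 0, exact obs, start at the fixed point
  A <- matrix(c(-1, 0.3, 0, -2), 2, 2)
  b <- c(1, 0.5)
  eq <- drop(solve(A, -b))
  sim <- simulate_ou_trajectories(list(A = A, b = b, G = diag(0, 2),
                                       meas_sd = c(0, 0), times = 1:6,
                                       y0 = eq), seed = 1)
  expect_equal(sim$obs, matrix(eq, 2, 6), tolerance = 1e-12,
               ignore_attr = TRUE)

  # univariate a = -1, g = 1: stationary variance 1/2
  tlong <- seq(0, 3000, by = 1)
  s1 <- simulate_ou_trajectories(list(A = matrix(-1), b = 0, G = matrix(1),
                                      meas_sd = 0, times = tlong), seed = 2)
  v <- var(drop(s1$states))
  rho <- exp(-1)  # lag-1 autocorrelation at unit spacing
  se_v <- 0.5 * sqrt(2 / length(tlong) * (1 + rho^2) / (1 - rho^2))
  expect_lt(abs(v - 0.5), 3 * se_v)

  # per-step noise variance increases with the gap toward g^2 / (2|a|)
  qs <- sapply(c(0.25, 0.5, 1, 2, 4), function(d)
    discretize_sde(matrix(-1), 0, matrix(1), d)$Q_d)
  expect_true(all(diff(qs) > 0))
  expect_lt(max(qs), 0.5)

  expect_error(simulate_ou_trajectories(list(A = matrix(1), b = 0,
                                             G = matrix(1), meas_sd = 0,
                                             times = 1:3)),
               "not stationary")
})

test_that("generate_study reproduces the stated design and is pure", {
  st <- generate_study(config = list(depth_min = 200L, depth_extra_mu = 50),
                       seed = 31)
  expect_equal(nrow(st$counts), 59L)
  tab <- table(st$metadata$site)[st$config$sites]
  expect_equal(unname(as.integer(tab)), c(13L, 12L, 11L, 12L, 11L))
  expect_equal(st$lda_truth$K, 5L)
  # strictly increasing days within each site
  for (s in st$config$sites)
    expect_true(all(diff(st$metadata$time_days[st$metadata$site == s]) > 0))
  # all six OU-driven variables observed at every sample
  expect_false(anyNA(st$metadata[, c("mmt", "mmp", "cn_ratio", "ph")]))
  expect_equal(length(st$ou_truth$panel$sites), 5L)

  st2 <- generate_study(config = list(depth_min = 200L, depth_extra_mu = 50),
                        seed = 31)
  expect_identical(st, st2)

  expect_error(generate_study(config = list(n_per_site = c(1, 2)), seed = 1),
               "lengths differ")
})
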