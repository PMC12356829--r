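test_that("rare-taxon filter keeps exactly the >= min_total columns", {
  ct <- count_table(matrix(c(75, 75, 50, 60, 50, 39), nrow = 2, byrow = TRUE,
                           dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
  # column totals 135, 125, 89  -> boundary check with min_total = 125
  f <- filter_rare_taxa(ct, min_total = 125)
  expect_equal(colnames(f), c("t1", "t2"))
  expect_equal(rownames(f), rownames(ct))
  expect_identical(filter_rare_taxa(ct, min_total = 0), ct)
  expect_error(filter_rare_taxa(ct, min_total = 1000), "every taxon")

  # boundary: exactly min_total is retained ("fewer than" excluded)
  ct2 <- count_table(matrix(c(150, 99, 100), nrow = 1,
                            dimnames = list("s", c("x", "y", "z"))))
  expect_equal(colnames(suppressMessages(filter_rare_taxa(ct2, 100))),
               c("x", "z"))
})

test_that("rarefaction subsamples to depth without replacement", {
  set.seed(2)
  ct <- count_table(matrix(rpois(30, 20), 3, 10))
  r <- rarefy(ct, depth = 100, seed = 5)
  expect_true(all(rowSums(r) == 100))
  expect_true(all(unclass(r) <= unclass(ct)[rownames(r), ]))
  expect_identical(rarefy(ct, depth = 100, seed = 5), r)

  # a sample at exactly the target depth is returned unchanged
  ct2 <- count_table(matrix(c(5L, 5L), 1, 2))
  expect_identical(unclass(rarefy(ct2, depth = 10, seed = 1)), unclass(ct2))

  expect_warning(rr <- rarefy(count_table(rbind(c(50L, 60L), c(2L, 3L))),
                              depth = 100, seed = 1), "dropped")
  expect_equal(nrow(rr), 1L)
  expect_error(rarefy(ct2, depth = 1e6, seed = 1), "below rarefaction depth")
})

test_that("tree-depth aggregation sums taxa into depth-C ancestors", {
  ct <- toy_counts()          # taxa a, b, c; depths a=b=2, c=1
  tt <- toy_tree()
  a1 <- aggregate_tree_depth(ct, tt, C = 1)
  expect_equal(ncol(a1), 2L)
  ab_col <- setdiff(colnames(a1), "c")
  expect_equal(unname(a1[, ab_col]), unname(ct[, "a"] + ct[, "b"]))
  expect_equal(unname(a1[, "c"]), unname(ct[, "c"]))
  expect_equal(sum(a1), sum(ct))                       # conservation
  expect_identical(aggregate_tree_depth(ct, tt, C = 5), ct)  # cut below leaves
  a0 <- aggregate_tree_depth(ct, tt, C = 0)            # everything to root
  expect_equal(ncol(a0), 1L)
  expect_equal(unname(a0[, 1]), unname(rowSums(ct)))
})

test_that("single-subcommunity fit has the smoothed closed form", {
  ct <- count_table(matrix(c(30L, 10L, 5L, 15L, 20L, 20L), 2, 3,
                           dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
  gamma <- 0.1
  fit <- fit_lda(ct, K = 1, gamma = gamma, n_burnin = 5, n_keep = 5, seed = 1)
  nw <- colSums(ct); N <- sum(ct); W <- ncol(ct)
  expect_equal(unname(fit$beta_hat[1, ]), unname((nw + gamma) / (N + W * gamma)),
               tolerance = 1e-12)
  expect_equal(unname(fit$theta_hat[, 1]), c(1, 1))
})

test_that("fits are deterministic and recover disjoint-vocabulary profiles", {
  # two samples with disjoint vocabularies: truth is the empirical profiles
  ct <- count_table(rbind(s1 = c(60L, 40L, 0L, 0L), s2 = c(0L, 0L, 70L, 30L)))
  fit <- fit_lda(ct, K = 2, alpha = 0.1, gamma = 0.1, n_burnin = 200,
                 n_keep = 100, seed = 3)
  truth <- rbind(c(0.6, 0.4, 0, 0), c(0, 0, 0.7, 0.3))
  al <- align_subcommunities(fit$beta_hat, truth)
  expect_lt(max(al$tv), 0.05)

  fit2 <- fit_lda(ct, K = 2, alpha = 0.1, gamma = 0.1, n_burnin = 200,
                  n_keep = 100, seed = 3)
  expect_identical(fit$theta_hat, fit2$theta_hat)

  expect_warning(fit_lda(ct, K = 5, n_burnin = 2, n_keep = 2, seed = 1),
                 "exceeds")

  # zero-read samples get the prior-mean mixture and are flagged
  ctz <- count_table(rbind(s1 = c(5L, 5L), s2 = c(0L, 0L)))
  fz <- fit_lda(ctz, K = 2, n_burnin = 5, n_keep = 5, seed = 1)
  expect_equal(unname(fz$theta_hat["s2", ]), c(0.5, 0.5))
  expect_equal(fz$zero_read_samples, "s2")
})

test_that("profile recovery improves with sequencing depth", {
  tvs <- sapply(c(100, 1000, 10000), function(nd) {
    mean(sapply(1:2, function(r) {
      g <- generate_lda_counts(list(K = 2, W = 25, D = 12, alpha = 0.1,
                                    gamma = 0.1, depths = nd), seed = 70 + r)
      f <- fit_lda(g$counts, K = 2, alpha = 0.1, gamma = 0.1, n_burnin = 300,
                   n_keep = 150, seed = r)
      align_subcommunities(f$beta_hat, g$truth$beta)$mean_tv
    }))
  })
  expect_true(all(diff(tvs) < 0))
})

test_that("held-out perplexity matches closed forms", {
  ct <- count_table(matrix(c(3L, 2L, 1L, 4L), 1, 4,
                           dimnames = list("d", c("a", "b", "c", "d"))))
  fit <- fit_lda(ct, K = 2, n_burnin = 5, n_keep = 5, seed = 1)
  # uniform profiles: every read has likelihood 1/4 whatever the mixture
  fit$beta_hat[] <- 0.25
  expect_equal(heldout_perplexity(fit, ct, seed = 2), 4, tolerance = 1e-12)
  expect_equal(heldout_perplexity(fit, ct, method = "foldin", seed = 2), 4,
               tolerance = 1e-12)

  # single-read sample: perplexity is 1 / p(word) under the folded-in mixture
  one <- count_table(matrix(1L, 1, 1, dimnames = list("x", "a")))
  fit1 <- fit_lda(ct, K = 1, gamma = 0.1, n_burnin = 5, n_keep = 5, seed = 1)
  pw <- fit1$beta_hat[1, "a"]
  expect_equal(suppressWarnings(heldout_perplexity(fit1, one, seed = 3)),
               1 / pw, tolerance = 1e-10)

  # taxa absent from the fit are dropped with a warning
  extra <- count_table(matrix(c(2L, 5L), 1, 2, dimnames = list("x", c("a", "zz"))))
  expect_warning(heldout_perplexity(fit1, extra, seed = 1), "dropped")
})

test_that("a richer model fits train-like data at least as well as K = 1", {
  g <- generate_lda_counts(list(K = 3, W = 30, D = 16, alpha = 0.1,
                                gamma = 0.1, depths = 400), seed = 12)
  f1 <- fit_lda(g$counts, K = 1, n_burnin = 100, n_keep = 50, seed = 1)
  f3 <- fit_lda(g$counts, K = 3, n_burnin = 300, n_keep = 150, seed = 1)
  p1 <- heldout_perplexity(f1, g$counts, seed = 5)
  p3 <- heldout_perplexity(f3, g$counts, seed = 5)
  expect_lte(p3, p1)
})

test_that("model selection: trivial grid, determinism, failed cells", {
  g <- generate_lda_counts(list(K = 2, W = 15, D = 10, alpha = 0.2,
                                gamma = 0.1, depths = 200), seed = 8)
  s1 <- select_model(g$counts, K_grid = 1, n_reps = 2, n_burnin = 50,
                     n_keep = 20, seed = 2)
  expect_equal(s1$chosen$K, 1)
  s2 <- select_model(g$counts, K_grid = c(1, 2), n_reps = 2, n_burnin = 50,
                     n_keep = 20, seed = 2)
  s3 <- select_model(g$counts, K_grid = c(1, 2), n_reps = 2, n_burnin = 50,
                     n_keep = 20, seed = 2)
  expect_identical(s2$grid, s3$grid)
  expect_identical(s2$chosen, s3$chosen)
  expect_equal(nrow(s2$grid), 2L * 2L * 2L)
})

test_that("hyperdominance count follows the cumulative-share definition", {
  expect_equal(hyperdominance_count(c(0.91, 0.05, 0.02, 0.01, 0.01)), 1L)
  expect_equal(hyperdominance_count(rep(0.1, 10)), 5L)
  expect_equal(hyperdominance_count(c(0.30, 0.25, 0.25, 0.20)), 2L)
  expect_error(hyperdominance_count(c(0.5, 0.2)), "sum to 1")
})

test_that("subcommunity alignment equals the exhaustive minimum", {
  set.seed(5)
  truth <- make_subcommunity_profiles(3, 12, c(0.3, 0.4, 0.5), seed = 6)
  perm <- c(3, 1, 2)
  al <- align_subcommunities(truth[perm, ], truth)
  expect_equal(al$perm, perm)
  expect_equal(al$tv, rep(0, 3))

  # independent oracle: enumerate all 3! assignments by hand
  est <- truth[perm, ] + matrix(runif(36, 0, 0.05), 3, 12)
  est <- est / rowSums(est)
  al2 <- align_subcommunities(est, truth)
  tvmat <- outer(1:3, 1:3, Vectorize(function(i, j)
    0.5 * sum(abs(est[i, ] - truth[j, ]))))
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- min(sapply(perms, function(p) sum(tvmat[cbind(1:3, p)])))
  expect_equal(sum(al2$tv), best)

  expect_error(align_subcommunities(truth, truth[, 1:5]), "mismatch")
})

test_that("label identity is stable under taxon column permutation", {
  g <- generate_lda_counts(list(K = 2, W = 12, D = 8, alpha = 0.2,
                                gamma = 0.1, depths = 300), seed = 14)
  f <- fit_lda(g$counts, K = 2, n_burnin = 300, n_keep = 150, seed = 7)
  perm <- sample(ncol(g$counts))
  ctp <- count_table(unclass(g$counts)[, perm, drop = FALSE])
  fp <- fit_lda(ctp, K = 2, n_burnin = 300, n_keep = 150, seed = 7)
  # profiles agree (up to subcommunity matching) after undoing the relabeling
  al <- align_subcommunities(fp$beta_hat[, colnames(g$counts)], f$beta_hat)
  expect_lt(al$mean_tv, 0.05)
})
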