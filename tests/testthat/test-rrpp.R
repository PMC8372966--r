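test_that("the whitening transform has its defining properties", {
  set.seed(1)
  tr <- ape::rcoal(6)
  C <- phylo_covariance(tr)
  Y <- matrix(rnorm(12), 6, 2, dimnames = list(tr$tip.label, NULL))
  X <- cbind(1, rep(0:1, 3))
  g <- gls_transform(Y, X, C)
  expect_equal(g$P %*% C %*% t(g$P), diag(6), tolerance = 1e-10)
  # identity covariance leaves data untouched
  gi <- gls_transform(Y, X, diag(6))
  expect_equal(gi$Y, Y, ignore_attr = TRUE)
  expect_equal(gi$X, X, ignore_attr = TRUE)
  # transformed OLS equals the GLS normal equations
  beta_ols <- qr.coef(qr(g$X), g$Y)
  Ci <- solve(C)
  beta_gls <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% Y)
  expect_equal(beta_ols, beta_gls, ignore_attr = TRUE)
  expect_error(gls_transform(Y, X, matrix(1, 6, 6)), "singular")
})

test_that("rrpp matches exhaustive permutation ANOVA on six subjects", {
  set.seed(2)
  y <- matrix(c(0.3, 1.2, 0.8, 2.9, 3.4, 2.1), ncol = 1,
              dimnames = list(paste0("s", 1:6), NULL))
  groups <- stats::setNames(rep(c("g1", "g2"), each = 3), rownames(y))
  perms <- all_permutations(6)
  # oracle: classical permutation ANOVA over all 720 arrangements
  F_all <- apply(perms, 1L, function(ix) trace_f_oracle(y[ix, ], groups))
  F_obs <- trace_f_oracle(y, groups)
  p_oracle <- mean(F_all >= F_obs)
  # identity-ancestry RRPP with the exhaustive non-identity schedule
  non_id <- perms[rowSums(perms == matrix(1:6, 720, 6, byrow = TRUE)) < 6, ]
  fit <- rrpp_anova(y, groups, C = NULL, perm_index = non_id)
  expect_equal(fit$F_obs, F_obs)
  expect_equal(fit$p, p_oracle)
})

test_that("with identity covariance the statistic is the classical trace F", {
  set.seed(3)
  Y <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
  groups <- stats::setNames(rep(c("a", "b", "c"), each = 4), rownames(Y))
  fit <- rrpp_anova(Y, groups, C = NULL, n_perm = 99, seed = 1)
  expect_equal(fit$F_obs, trace_f_oracle(Y, groups), tolerance = 1e-10)
})

test_that("degenerate responses and bad designs are rejected", {
  Y <- matrix(1, 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  groups <- rep(c("a", "b"), each = 3)
  expect_error(rrpp_anova(Y, groups, n_perm = 99), "variation")
  Y2 <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  expect_error(rrpp_anova(Y2, c("a", rep("b", 5)), n_perm = 99), ">= 2")
  expect_error(rrpp_anova(Y2, rep("a", 6), n_perm = 99), "two groups")
})

test_that("results are seed-deterministic and order-invariant", {
  set.seed(4)
  tr <- ape::rcoal(10)
  C <- phylo_covariance(tr)
  Y <- matrix(rnorm(20), 10, 2, dimnames = list(tr$tip.label, NULL))
  groups <- stats::setNames(rep(c("a", "b"), 5), tr$tip.label)
  f1 <- rrpp_anova(Y, groups, C, n_perm = 199, seed = 7)
  f2 <- rrpp_anova(Y, groups, C, n_perm = 199, seed = 7)
  expect_identical(f1$p, f2$p)
  expect_identical(f1$Z, f2$Z)
  # permuting the input row order changes nothing (post-sort schedule)
  ord <- sample(10)
  f3 <- rrpp_anova(Y[ord, ], groups[ord], C, n_perm = 199, seed = 7)
  expect_equal(f3$p, f1$p)
  expect_equal(f3$F_obs, f1$F_obs)
})

test_that("p-values follow the observed-included permutation convention", {
  set.seed(5)
  Y <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("s", 1:8), NULL))
  groups <- rep(c("a", "b"), each = 4)
  fit <- rrpp_anova(Y, groups, n_perm = 199, seed = 1)
  # observed-included exceedance count (ties counted as exceedances)
  expect_equal(fit$p,
               mean(fit$perm_stats >= fit$F_obs - 1e-6 * abs(fit$F_obs)))
  expect_gt(fit$p, 0)
  expect_lte(fit$p, 1)
  expect_equal(length(fit$perm_stats), 200L)
})

test_that("GLS group means equal the direct normal-equations solution", {
  set.seed(6)
  tr <- ape::rcoal(6)
  C <- phylo_covariance(tr)
  Y <- matrix(rnorm(12), 6, 2, dimnames = list(tr$tip.label, NULL))
  groups <- stats::setNames(rep(c("a", "b"), 3), tr$tip.label)
  fit <- rrpp_anova(Y, groups, C, n_perm = 99, seed = 1)
  ord <- order(tr$tip.label)
  Yo <- Y[ord, ]
  Xo <- stats::model.matrix(~ factor(groups[ord]) - 1)
  Co <- C[ord, ord]
  Ci <- solve(Co)
  oracle <- solve(t(Xo) %*% Ci %*% Xo, t(Xo) %*% Ci %*% Yo)
  expect_equal(unname(fit$coefficients$means), unname(oracle),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$contrasts["a - b", ],
               fit$coefficients$means["a", ] - fit$coefficients$means["b", ])
})

test_that("with two groups the pairwise test reproduces the overall test", {
  set.seed(7)
  Y <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  groups <- stats::setNames(rep(c("a", "b"), c(5, 7)), rownames(Y))
  fit <- rrpp_anova(Y, groups, C = NULL, n_perm = 499, seed = 11)
  pw <- pairwise_comparisons(Y, groups, C = NULL, n_perm = 499, seed = 11)
  expect_equal(nrow(pw), 1L)
  expect_equal(pw$p, fit$p)
})

test_that("pairwise significance flags follow the 1.645 cutoff", {
  set.seed(8)
  Y <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  grp <- rep(c("a", "b", "c"), each = 10)
  Y[grp == "a", ] <- Y[grp == "a", ] + 4
  pw <- pairwise_comparisons(Y, stats::setNames(grp, rownames(Y)),
                             n_perm = 199, seed = 2)
  expect_equal(pw$significant, pw$Z > 1.645)
  expect_equal(nrow(pw), 3L)
})

test_that("a displaced group is flagged against both others", {
  hits_displaced <- 0L
  hits_null <- 0L
  n_rep <- 100L
  set.seed(9)
  for (i in seq_len(n_rep)) {
    Y <- matrix(rnorm(48), 24, 2)
    rownames(Y) <- paste0("s", 1:24)
    grp <- stats::setNames(rep(c("a", "b", "c"), each = 8), rownames(Y))
    Y[grp == "a", ] <- Y[grp == "a", ] + 3
    pw <- pairwise_comparisons(Y, grp, n_perm = 199, seed = i)
    da <- pw$significant[pw$group_a == "a" | pw$group_b == "a"]
    nn <- pw$significant[!(pw$group_a == "a" | pw$group_b == "a")]
    if (all(da)) hits_displaced <- hits_displaced + 1L
    if (!any(nn)) hits_null <- hits_null + 1L
  }
  expect_gte(hits_displaced, 95L)
  expect_gte(hits_null, 88L)  # nominal 95% minus Monte-Carlo margin
})

test_that("the Holm ladder reproduces the printed adjusted alphas", {
  p12 <- c(0.001, 0.001, 0.003, 0.116, 0.103, 0.588, 0.010, 0.564,
           0.102, 0.654, 0.001, 0.775)
  h12 <- sequential_bonferroni(p12, 0.05)
  expect_equal(round(min(h12$alpha), 4), 0.0042)
  expect_equal(max(h12$alpha), 0.05)
  p5 <- c(0.001, 0.002, 0.656, 0.022, 0.088)
  h5 <- sequential_bonferroni(p5, 0.05)
  expect_equal(round(h5$alpha[h5$rank == 1], 4), 0.0100)
  # adjusted alphas nondecreasing in rank
  expect_true(all(diff(h12$alpha[order(h12$rank)]) >= 0))
  # single test keeps the family alpha
  expect_equal(sequential_bonferroni(0.03, 0.05)$alpha, 0.05)
  expect_equal(nrow(sequential_bonferroni(numeric(0))), 0L)
})

test_that("Holm stopping blocks everything after the first failure", {
  h <- sequential_bonferroni(c(0.001, 0.04, 0.012, 0.6), 0.05)
  # sorted p: 0.001 (alpha 0.0125, sig), 0.012 (0.0167, sig),
  # 0.04 (0.025, fail) -> 0.6 blocked even though its alpha is 0.05
  expect_equal(h$significant, c(TRUE, FALSE, TRUE, FALSE))
  # stable tie handling: equal p keep input order
  ht <- sequential_bonferroni(c(0.01, 0.01, 0.01), 0.05)
  expect_equal(ht$rank, 1:3)
})

test_that("posterior-tree robustness intervals behave", {
  set.seed(10)
  tr <- ape::rcoal(16)
  lab <- stats::setNames(rep(c("A", "T"), 8), tr$tip.label)
  Y <- matrix(rnorm(32), 16, 2, dimnames = list(tr$tip.label, NULL))
  Y[lab == "A", ] <- Y[lab == "A", ] + 3
  same <- posterior_robustness(Y, lab, list(tr, tr, tr), n_perm = 199,
                               seed = 1)
  expect_equal(diff(range(same$Z)), 0)
  expect_equal(unname(diff(same$interval)), 0)
  trees <- replicate(12, ape::rcoal(16), simplify = FALSE)
  trees <- lapply(trees, function(t) {
    t$tip.label <- tr$tip.label
    t
  })
  rb <- posterior_robustness(Y, lab, trees, n_perm = 199, seed = 2)
  expect_true(rb$interval[1] <= stats::median(rb$Z) &&
                stats::median(rb$Z) <= rb$interval[2])
  # a tree missing species is skipped with a diagnostic
  short <- ape::drop.tip(tr, "t1")
  expect_message(rb2 <- posterior_robustness(Y, lab, list(tr, short),
                                             n_perm = 199, seed = 3),
                 "skipped")
  expect_equal(rb2$n_skipped, 1L)
})

test_that("a strong synthetic effect stays above the cutoff across trees", {
  set.seed(11)
  base <- ape::rcoal(24)
  lab <- stats::setNames(rep(c("A", "T"), 12), base$tip.label)
  Y <- matrix(rnorm(48), 24, 2, dimnames = list(base$tip.label, NULL))
  Y[lab == "A", ] <- Y[lab == "A", ] + 4
  trees <- replicate(50, {
    t <- ape::rcoal(24)
    t$tip.label <- base$tip.label
    t
  }, simplify = FALSE)
  rb <- posterior_robustness(Y, lab, trees, n_perm = 199, seed = 4,
                             statistic = "pairwise", pair = c("A", "T"))
  expect_gt(rb$interval[1], 1.645)
})
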