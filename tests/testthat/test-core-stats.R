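test_that("trimmed test: no shift gives large one-sided p, full shift tiny p", {
  x <- as.numeric(1:50)
  expect_gte(trimmed_group_test(x, x, 0.3, "greater")$p_value, 0.4)
  res <- trimmed_group_test(x + 10, x, 0.3, "greater")
  expect_lt(res$p_value, 0.01)
  expect_equal(res$mu_c, mean(sort(x + 10)[1:15]))
  expect_equal(res$mu_n, mean(sort(x)[1:15]))
})

test_that("trimmed test handles degenerate and invalid inputs", {
  # constant after trim: flagged, p = 1, no exception
  res <- trimmed_group_test(rep(0, 10), rep(0, 10), 0.3)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  # too few finite entries
  expect_true(trimmed_group_test(c(1, NA, Inf), 1:10, 0.3)$degenerate)
  expect_error(trimmed_group_test(1:10, 1:10, 0), "trim_fraction")
  expect_error(trimmed_group_test(1:10, 1:10, 1.2), "trim_fraction")
})

test_that("trimmed test direction flips with alternative", {
  set.seed(3)
  x <- rnorm(50, 2)
  y <- rnorm(50, 0)
  expect_lt(trimmed_group_test(x, y, 0.3, "greater")$p_value, 0.001)
  expect_gt(trimmed_group_test(x, y, 0.3, "less")$p_value, 0.5)
  expect_lt(trimmed_group_test(y, x, 0.3, "less")$p_value, 0.001)
})

test_that("BH adjustment matches the step-up oracle and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.05), 0.05)
  set.seed(42)
  p <- runif(1000)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  # q >= p elementwise; permutation equivariance
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- sample.int(1000)
  expect_equal(bh_adjust(p[perm]), q[perm])
  # NA entries propagate without corrupting neighbours
  p2 <- c(0.01, NA, 0.5)
  q2 <- bh_adjust(p2)
  expect_true(is.na(q2[2]))
  expect_equal(q2[c(1, 3)], bh_adjust(c(0.01, 0.5)))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher enrichment: cross-product OR and exact hypergeometric p", {
  expect_equal(fisher_enrichment(10, 20, 10, 20)$odds_ratio, 1)
  expect_equal(fisher_enrichment(20, 25, 5, 25)$odds_ratio, 16)
  # one-sided p equals the exhaustive hypergeometric tail for small tables
  set.seed(7)
  for (i in 1:25) {
    t1 <- sample(5:30, 1); t2 <- sample(5:30, 1)
    h1 <- sample(0:t1, 1); h2 <- sample(0:t2, 1)
    got <- fisher_enrichment(h1, t1, h2, t2)$p_value
    # tail sum over the hypergeometric: draws = column-1 margin
    ks <- h1:min(t1, h1 + h2)
    want <- sum(dhyper(ks, h1 + h2, (t1 - h1) + (t2 - h2), t1))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # Haldane correction only when a zero cell is present
  expect_equal(fisher_enrichment(5, 5, 0, 5)$odds_ratio,
               (5.5 * 5.5) / (0.5 * 0.5))
  expect_error(fisher_enrichment(1, 0, 1, 5), "in_set_total")
  expect_error(fisher_enrichment(6, 5, 1, 5), "exceeds")
})

test_that("mutual information equals the brute-force contingency oracle", {
  # perfect dependence on balanced binary data: 1 bit, nmi 1
  x <- rep(c(0, 1), each = 20)
  r <- mutual_information(x, x, n_bins = 2)
  expect_equal(r$mi, 1)
  expect_equal(r$nmi, 1)
  # closed form for joint [[2,0],[0,2]]
  expect_equal(oracle_mi_bits(matrix(c(2, 0, 0, 2), 2)), 1)
  # random vectors: package MI equals the double-sum oracle on the same bins
  set.seed(5)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    nb <- sample(2:5, 1)
    x <- rnorm(n); y <- x * runif(1) + rnorm(n)
    got <- mutual_information(x, y, nb)
    joint <- table(oracle_bin(x, nb), oracle_bin(y, nb))
    expect_equal(got$mi, oracle_mi_bits(joint), tolerance = 1e-10)
    # symmetry and range invariants
    expect_equal(got$mi, mutual_information(y, x, nb)$mi, tolerance = 1e-10)
    expect_gte(got$mi, 0)
    expect_gte(got$nmi, 0)
    expect_lte(got$nmi, 1)
  }
  expect_warning(r0 <- mutual_information(rep(1, 30), rnorm(30), 2),
                 "constant")
  expect_equal(r0$nmi, 0)
})

test_that("MI permutation p: dependence detected, determinism, degeneracy", {
  set.seed(8)
  x <- rnorm(200)
  y <- x + rnorm(200, sd = 0.1)
  r <- mi_permutation_p(x, y, n_perm = 200, seed = 3)
  expect_lt(r$p_value, 0.001)
  r2 <- mi_permutation_p(x, y, n_perm = 200, seed = 3)
  expect_identical(r, r2)
  r3 <- mi_permutation_p(x, y, n_perm = 200, seed = 4)
  expect_false(identical(r$z_perm_mean, r3$z_perm_mean))
  expect_error(mi_permutation_p(x, y, n_perm = 50), "n_perm")
  # constant y: everything collapses, degenerate flag set, p pinned
  suppressWarnings(rd <- mi_permutation_p(x, rep(1, 200), n_perm = 100,
                                          seed = 1))
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 1)
})

test_that("partial Spearman matches the rank-residual oracle (first order)", {
  set.seed(21)
  for (i in 1:100) {
    n <- 100
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- 0.5 * z + rnorm(n)
    got <- partial_spearman(x, y, list(z))
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    ex <- resid(lm(rx ~ rz)); ey <- resid(lm(ry ~ rz))
    expect_equal(got$rho_partial, cor(ex, ey), tolerance = 1e-10)
  }
})

test_that("partial Spearman: mediation, irrelevance, symmetry, degeneracy", {
  set.seed(22)
  n <- 300
  z <- rnorm(n)
  se <- z + rnorm(n, sd = 0.3)
  g <- z                      # g IS the conditioner pathway
  r <- partial_spearman(se, g, list(z))
  expect_lt(abs(r$rho_partial), 0.05)
  # irrelevant conditioner leaves rho approximately unchanged
  w <- rnorm(n)
  r2 <- partial_spearman(se, g, list(w))
  expect_lt(abs(r2$rho_partial - r2$rho_raw), 0.05)
  # second-order conditioning is symmetric in the two conditioners
  a <- z + rnorm(n, sd = 0.5); b <- z + rnorm(n, sd = 0.5)
  r3 <- partial_spearman(se, g, list(a, b))
  r4 <- partial_spearman(se, g, list(b, a))
  expect_equal(r3$rho_partial, r4$rho_partial, tolerance = 1e-12)
  # degenerate conditioning flagged, not non-finite
  rd <- partial_spearman(se, g, list(g))
  expect_true(rd$degenerate)
  expect_equal(rd$rho_partial, 0)
  expect_error(partial_spearman(se, g, list(rep(1, n))), "constant")
  expect_error(partial_spearman(1:5, 1:5, list(rnorm(5))), "at least 8")
})

test_that("conditional independence test separates CI from dependence", {
  set.seed(31)
  n <- 200
  tf <- rnorm(n)
  # conditionally independent: g depends on tf only
  g_ci <- tf + rnorm(n, sd = 0.5)
  se <- tf + rnorm(n, sd = 0.5)
  p_ci <- conditional_independence_test(se, g_ci, list(tf), n_perm = 200,
                                        seed = 2)
  expect_gte(p_ci, 0.05)
  # conditional dependence: g depends on se beyond tf
  g_dep <- se + rnorm(n, sd = 0.3)
  p_dep <- conditional_independence_test(se, g_dep, list(tf), n_perm = 200,
                                         seed = 2)
  expect_lt(p_dep, 0.05)
  # determinism
  expect_identical(p_ci,
                   conditional_independence_test(se, g_ci, list(tf),
                                                 n_perm = 200, seed = 2))
})

test_that("CMI statistic equals the brute-force stratified sum", {
  set.seed(33)
  n <- 120
  se <- rnorm(n); g <- rnorm(n); z <- rnorm(n)
  nb <- 3
  xb <- oracle_bin(se, nb); yb <- oracle_bin(g, nb)
  zb <- oracle_bin(z, 2)
  want <- 0
  for (s in unique(zb)) {
    sel <- zb == s
    want <- want + mean(sel) *
      oracle_mi_bits(table(factor(xb[sel], 1:nb), factor(yb[sel], 1:nb)))
  }
  got <- secrc:::cmi_from_codes(xb, yb, zb, nb, nb)
  expect_equal(got, want, tolerance = 1e-10)
})
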