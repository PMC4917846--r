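test_that("EB variance prior matches the independent limma fit", {
  set.seed(14)
  s2 <- 0.1 * 4 / rchisq(300, df = 4)
  s2_obs <- s2 * rchisq(300, df = 2) / 2
  ours <- eb_variance_prior(s2_obs, 2)
  ref <- limma::squeezeVar(s2_obs, df = 2)
  expect_equal(ours$d0, ref$df.prior, tolerance = 1e-8)
  expect_equal(ours$s02, ref$var.prior, tolerance = 1e-8)
  # and the moderated variances agree
  mod <- kcone:::moderate_variance(s2_obs, 2, ours)
  expect_equal(mod, ref$var.post, tolerance = 1e-8)
})

test_that("moderated Welch reduces to known limits", {
  set.seed(15)
  zn <- matrix(rnorm(50 * 3), 50)
  zd <- matrix(rnorm(50 * 3, 0, 2), 50)
  # d0 = 0: ordinary Welch, against stats::t.test on 50 datasets
  t0 <- moderated_welch_test(zn, zd, prior = list(d0 = 0, s02 = 1))
  ref <- vapply(1:50, function(i) t.test(zn[i, ], zd[i, ])$p.value,
                numeric(1))
  expect_equal(t0$p, ref, tolerance = 1e-12)
  # d0 -> Inf: all variances collapse to s0^2, z-like equal-variance form
  tinf <- moderated_welch_test(zn, zd, prior = list(d0 = Inf, s02 = 1.5))
  expect_equal(tinf$t,
               (rowMeans(zn) - rowMeans(zd)) / sqrt(1.5 / 3 + 1.5 / 3),
               tolerance = 1e-12)
  # equal group variances and equal n: Welch se equals Student se
  tfit <- moderated_welch_test(zn, zn + 0.5)
  prior <- attr(tfit, "prior")
  svn <- kcone:::moderate_variance(apply(zn, 1, var), 2, prior)
  expect_equal(tfit$t, -0.5 / sqrt(2 * svn / 3), tolerance = 1e-12)
})

test_that("type-I error stays near nominal and power grows with effect", {
  nd <- null_log_terms(400, sd = 0.3, seed = 16)
  tt <- moderated_welch_test(nd$n, nd$d)
  rate <- mean(tt$p < 0.05)
  expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / 400))
  rates <- vapply(c(0.5, 1, 2), function(delta) {
    nd <- null_log_terms(300, sd = 0.3, seed = 17)
    tt <- moderated_welch_test(nd$n + delta, nd$d)
    mean(tt$p < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.99)
})

test_that("BH adjustment equals hand computation and is order-invariant", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.2), 0.2)
  set.seed(18)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
})

test_that("combinatorial lfcs have the stated counts and exact zero mean", {
  set.seed(19)
  zn <- matrix(rnorm(20 * 3), 20)
  zd <- matrix(rnorm(20 * 3), 20)
  lfc <- combinatorial_lfc(zn, zd)
  expect_equal(ncol(lfc$control), 6)       # 3 * 2 ordered pairs
  expect_equal(ncol(lfc$differential), 9)  # 3 * 3 combinations
  expect_equal(rowMeans(lfc$control), rep(0, 20),
               ignore_attr = TRUE, tolerance = 1e-15)
  # identical replicate values give all-zero lfcs
  z1 <- matrix(2, 5, 3)
  lfc0 <- combinatorial_lfc(z1, z1)
  expect_true(all(lfc0$control == 0) && all(lfc0$differential == 0))
  # general replicate counts
  lfc24 <- combinatorial_lfc(matrix(rnorm(8), 2, 4), matrix(rnorm(4), 2, 2))
  expect_equal(ncol(lfc24$control), 12)
  expect_equal(ncol(lfc24$differential), 8)
  expect_error(combinatorial_lfc(matrix(1, 2, 1), z1), ">= 2")
})

test_that("Bayes bootstrap is degenerate-safe, centered and reproducible", {
  expect_equal(unname(bayes_bootstrap_ci(rep(1.3, 5))), c(1.3, 1.3))
  # symmetric sample set: the posterior of the weighted mean is symmetric,
  # so the interval midpoint converges to the sample mean
  y <- 0.3 * (1:9)
  ci <- bayes_bootstrap_ci(y, draws = 1e5, seed = 1)
  expect_lt(abs(mean(ci) - mean(y)), 0.01)
  expect_identical(bayes_bootstrap_ci(y, draws = 500, seed = 7),
                   bayes_bootstrap_ci(y, draws = 500, seed = 7))
  expect_warning(bayes_bootstrap_ci(y, draws = 50), "100")
  # matrix interface returns one interval per reaction
  M <- matrix(rnorm(30), 10, 3)
  cis <- bayes_bootstrap_ci(M, draws = 500, seed = 2)
  expect_equal(nrow(cis), 10)
  expect_true(all(cis$ci_low <= cis$ci_high))
})

test_that("heterogeneity screen applies the sigma ratio rule", {
  set.seed(22)
  ctrl <- matrix(rnorm(30 * 6, 0, 1), 30,
                 dimnames = list(paste0("r", 1:30), NULL))
  diff4 <- matrix(rnorm(30 * 9, 0, 4), 30,
                  dimnames = list(paste0("r", 1:30), NULL))
  h <- heterogeneity_screen(ctrl, diff4)
  manual <- apply(diff4, 1, sd) / apply(ctrl, 1, sd) > 3
  expect_equal(unname(h$heterogeneous), unname(manual))
  # sigma_d = sigma_c is never flagged
  h0 <- heterogeneity_screen(ctrl, cbind(ctrl, ctrl[, 1:3]))
  expect_false(any(h0$heterogeneous[h0$ratio < 1.2]))
  # zero control spread is reported, not flagged
  ctrl0 <- rbind(const = rep(0, 6))
  d0 <- rbind(const = rnorm(9))
  hz <- heterogeneity_screen(ctrl0, d0)
  expect_true(is.na(hz$heterogeneous))
  expect_equal(attr(hz, "degenerate"), "const")
})

test_that("co-regulation matrix is a Pearson correlation matrix", {
  set.seed(23)
  X <- matrix(rnorm(20 * 9), 20, dimnames = list(paste0("r", 1:20), NULL))
  C <- coregulation_matrix(X)
  expect_equal(C, cor(t(X)), tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, 20))
  expect_equal(C, t(C))
  # proportional lfc vectors correlate perfectly
  P <- rbind(a = 1:9, b = 2 * (1:9) + 5)
  expect_equal(coregulation_matrix(P)["a", "b"], 1)
  expect_error(coregulation_matrix(X[, 1:2]), ">= 3")
})
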