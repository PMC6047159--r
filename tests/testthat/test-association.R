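test_that("null model fits by least squares with ML variance", {
  set.seed(61)
  n <- 40
  dat <- tibble::tibble(y = rnorm(n), x1 = rnorm(n), x2 = runif(n))
  fit <- fit_null_model(dat, "y", c("x1", "x2"))
  # coefficients match the normal-equations oracle
  X <- cbind(1, dat$x1, dat$x2)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% dat$y)
  expect_equal(unname(fit$coefficients), as.vector(beta_oracle),
               tolerance = 1e-10)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  # residuals orthogonal to the design; leverages sum to k
  expect_lt(max(abs(t(X) %*% fit$residuals)), 1e-8 * sum(abs(dat$y)))
  expect_equal(sum(fit$leverage), 3, tolerance = 1e-10)
  expect_equal(fit$sigma2, sum(fit$residuals^2) / n, tolerance = 1e-12)

  # exact linear response -> degenerate flag
  dat$y2 <- 1 + 2 * dat$x1
  expect_true(fit_null_model(dat, "y2", "x1")$degenerate)

  # collinear design errors with the offending column named
  dat$x3 <- dat$x1
  expect_error(fit_null_model(dat, "y", c("x1", "x3")), "x3")
})

test_that("score test reproduces the hand-computed hard-call example", {
  dat <- tibble::tibble(y = c(1, 2, 3, 4))
  null <- fit_null_model(dat, "y")
  g <- hard_calls(matrix(c(0L, 0L, 1L, 1L)), make_variants(1, raf = 0.25))
  res <- score_test(null, g)
  expect_equal(res$U, 1.6, tolerance = 1e-12)
  expect_equal(res$V, 0.8, tolerance = 1e-12)
  expect_equal(res$stat, 3.2, tolerance = 1e-12)
  expect_equal(res$beta, 2.0, tolerance = 1e-12)
  # one-step effect equals the OLS slope
  expect_equal(res$beta, unname(coef(lm(y ~ g, data = cbind(
    dat, g = c(0, 0, 1, 1))))["g"]), tolerance = 1e-12)
})

test_that("with hard genotypes the score test is the OLS score test", {
  set.seed(71)
  for (rep in 1:100) {
    n <- 30 + rep
    dat <- tibble::tibble(y = rnorm(n), x1 = rnorm(n),
                          x2 = rbinom(n, 1, 0.5))
    gvec <- rbinom(n, 2, 0.3)
    if (length(unique(gvec)) == 1) next
    null <- fit_null_model(dat, "y", c("x1", "x2"))
    res <- score_test(null, hard_calls(matrix(gvec),
                                       make_variants(1, raf = 0.3)))
    oracle <- ols_score_oracle(dat$y, data.frame(x1 = dat$x1, x2 = dat$x2),
                               gvec)
    expect_equal(res$stat, oracle$S, tolerance = 1e-8)
    expect_equal(res$beta, oracle$beta, tolerance = 1e-8)
  }
})

test_that("uninformative triples carry no score information", {
  set.seed(81)
  n <- 200
  dat <- tibble::tibble(y = rnorm(n))
  null <- fit_null_model(dat, "y")
  vars <- make_variants(1, raf = 0.5)
  prior <- geno_triples(matrix(0.25, n, 1), matrix(0.5, n, 1),
                        matrix(0.25, n, 1), vars)
  res <- score_test(null, prior)
  expect_true(!res$testable || res$stat < 1e-16)
})

test_that("uncertainty never increases information, hard bound holds", {
  set.seed(91)
  n <- 500
  vars <- make_variants(1, raf = 0.3)
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1)
  dat <- tibble::tibble(y = rnorm(n) - 0.1 * g[, 1])
  null <- fit_null_model(dat, "y")
  v_hard <- score_test(null, hard_calls(g, vars))$V
  for (cc in c(0.9, 0.7, 0.5)) {
    v_soft <- score_test(null, degrade_to_probabilistic(g, cc, vars))$V
    expect_lt(v_soft, v_hard)
  }
})

test_that("exact HWE test matches enumeration", {
  expect_equal(hwe_exact_test(3, 0, 0), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # full enumeration oracle over all configurations with n <= 20
  for (n in c(2, 5, 11, 20)) {
    for (n1 in 0:n) {
      for (n2 in 0:(n - n1)) {
        n0 <- n - n1 - n2
        expect_equal(hwe_exact_test(n0, n1, n2),
                     hwe_enum_oracle(n0, n1, n2), tolerance = 1e-10,
                     label = sprintf("(%d,%d,%d)", n0, n1, n2))
      }
    }
  }
})

test_that("screening and regional variant filters apply the stated rules", {
  stats <- tibble::tribble(
    ~snpid, ~study, ~present, ~maf, ~info, ~hwe_p,
    "both_ok",     "s1", TRUE, 0.06, 1.00, 0.5,
    "both_ok",     "s2", TRUE, 0.06, 1.00, 0.5,
    "one_ok",      "s1", TRUE, 0.12, 1.00, 0.5,
    "one_low",     "s1", TRUE, 0.07, 1.00, 0.5,
    "imperfect",   "s1", TRUE, 0.20, 1.00, 0.5,
    "imperfect",   "s2", TRUE, 0.20, 0.95, 0.5,
    "hwe_fail",    "s1", TRUE, 0.30, 1.00, 5e-6,
    "hwe_fail",    "s2", TRUE, 0.30, 1.00, 0.5)
  strict <- variant_filters(stats, "strict")
  keep <- function(res, id) res$keep[res$snpid == id]
  expect_true(keep(strict, "both_ok"))
  expect_true(keep(strict, "one_ok"))
  expect_false(keep(strict, "one_low"))
  expect_false(keep(strict, "imperfect"))
  expect_false(keep(strict, "hwe_fail"))
  regional <- variant_filters(stats, "regional")
  expect_true(keep(regional, "imperfect"))
  expect_false(keep(regional, "hwe_fail"))
})

test_that("effects are reported on the published scales", {
  rep1 <- report_effect(log(0.85), log(1.03), "log")
  expect_equal(rep1$beta_reported, 0.85, tolerance = 1e-12)
  expect_equal(rep1$se_reported, 1.03, tolerance = 1e-12)
  # 0.85 per reference allele is ~17% more per major allele
  expect_equal(rep1$pct_per_major_allele, 17, tolerance = 0.05)
  rep2 <- report_effect(-0.664, 0.1, "sqrt", s0 = 12)
  expect_equal(rep2$beta_reported, -4.60, tolerance = 1e-3)
  expect_true(is.na(rep2$pct_per_major_allele))
  # increasing effects report no major-allele flip
  expect_true(is.na(report_effect(log(1.17), 0.02, "log")$pct_per_major_allele))
})

test_that("ML effect estimation reduces to OLS for hard genotypes", {
  set.seed(555)
  n <- 120
  dat <- tibble::tibble(y = rnorm(n), x1 = rnorm(n))
  g <- rbinom(n, 2, 0.3)
  null <- fit_null_model(dat, "y", "x1")
  geno <- hard_calls(matrix(g), make_variants(1, raf = 0.3))
  ml <- ml_effect(null, geno)
  ols <- unname(coef(lm(y ~ x1 + g, data = cbind(dat, g = g)))["g"])
  expect_equal(ml$beta_ml, ols, tolerance = 1e-7)
  expect_true(ml$converged)
  # observed-information SE agrees with the score-test SE under hard calls
  sc <- score_test(null, geno)
  expect_equal(ml$se_ml, sc$se, tolerance = 0.02)

  # soft genotypes: ML remains finite, SE exceeds the hard-call SE
  soft <- degrade_to_probabilistic(matrix(g), 0.7, make_variants(1, raf = 0.3))
  ml_soft <- ml_effect(null, soft)
  expect_gt(ml_soft$se_ml, 0.9 * sc$se)
})
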