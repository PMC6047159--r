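# Shared fixtures and independent oracles, built in code at test time.

make_variants <- function(n = 3, raf = NULL, chrom = "11",
                          pos0 = 61547000L) {
  tibble::tibble(
    snpid = sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    pos = pos0 + seq_len(n) * 1000L,
    refA = rep(c("t", "a", "c"), length.out = n),
    altA = rep(c("c", "g", "a"), length.out = n),
    raf = raf %||% rep(0.3, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force maternal posterior: enumerate all 9 mother x father HWE
# genotype pairs, weight by Mendelian transmission to the child, condition.
trio_posterior_oracle <- function(child, p) {
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)      # P(count = 0,1,2)
  transmit <- function(parent) c(1 - parent / 2, parent / 2)  # P(allele 0/1)
  post <- numeric(3)
  for (m in 0:2) {
    for (f in 0:2) {
      pm <- transmit(m); pf <- transmit(f)
      # P(child = c | m, f): convolution of the two transmitted alleles
      pc <- c(pm[1] * pf[1],
              pm[1] * pf[2] + pm[2] * pf[1],
              pm[2] * pf[2])[child + 1]
      post[m + 1] <- post[m + 1] + hwe[m + 1] * hwe[f + 1] * pc
    }
  }
  post / sum(post)
}

# Classical OLS score statistic for adding g to y ~ X, via residual sums of
# squares of two lm() fits (ML variance divisor n): S = n (RSS0 - RSS1)/RSS0.
ols_score_oracle <- function(y, X, g) {
  d0 <- data.frame(y = y, X)
  f0 <- lm(y ~ ., data = d0)
  f1 <- lm(y ~ . + g, data = cbind(d0, g = g))
  rss0 <- sum(resid(f0)^2); rss1 <- sum(resid(f1)^2)
  list(S = length(y) * (rss0 - rss1) / rss0,
       beta = unname(coef(f1)["g"]))
}

# Exact HWE p-value by direct enumeration with factorial ratios (independent
# of the lgamma implementation under test).
hwe_enum_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n2 + n1; nB <- 2 * n0 + n1
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  pr <- vapply(hs, function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((nB - h) / 2)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n1, hs)] * (1 + 1e-12)])
}

# One minimal two-study synthetic design with a causal AA variant.
make_two_study_design <- function(seed1 = 101, seed2 = 202, n1 = 532,
                                  n2 = 610, factor = 0.85, raf = 0.17,
                                  extra_null = 2) {
  vars <- make_variants(1 + extra_null,
                        raf = c(raf, rep(0.4, extra_null)))
  vars$snpid[1] <- "rs_causal"
  eff <- tibble::tibble(snpid = "rs_causal", phenotype = "AA",
                        factor = factor)
  s1 <- simulate_study(sim_config(n1, vars, effects = eff, seed = seed1))
  s2 <- simulate_study(sim_config(n2, vars,
                                  fa_profile = fa_reference("crypto_mirpur"),
                                  effects = eff, seed = seed2), site = 1L)
  list(provide = s1, crypto = s2)
}

# flatten a one-row triple tibble to a numeric vector
triple_vec <- function(tb) unname(unlist(tb))
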