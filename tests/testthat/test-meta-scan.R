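meta_input <- function(beta, se, study = NULL, snpid = "rs1") {
  k <- length(beta)
  tibble::tibble(study = study %||% paste0("s", seq_len(k)), snpid = snpid,
                 beta = beta, se = se, testable = TRUE, n = 100L,
                 refA = "t", altA = "c")
}

test_that("fixed-effects meta-analysis closed forms", {
  m <- meta_fixed_effects(meta_input(c(0.1, 0.3), c(0.1, 0.1)))
  expect_equal(m$beta_meta, 0.2, tolerance = 1e-12)
  expect_equal(m$se_meta, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$dir, "++")

  # single study passes through unchanged
  s <- meta_fixed_effects(meta_input(0.25, 0.07))
  expect_equal(s$beta_meta, 0.25); expect_equal(s$se_meta, 0.07)

  # opposite equal effects cancel
  o <- meta_fixed_effects(meta_input(c(0.2, -0.2), c(0.05, 0.05)))
  expect_equal(o$beta_meta, 0, tolerance = 1e-12)
  expect_equal(o$dir, "+-")

  # k identical studies: same effect, SE shrinks by sqrt(k)
  k <- 4
  i <- meta_fixed_effects(meta_input(rep(0.11, k), rep(0.2, k)))
  expect_equal(i$beta_meta, 0.11, tolerance = 1e-12)
  expect_equal(i$se_meta, 0.2 / sqrt(k), tolerance = 1e-12)

  # allele mismatch across studies is an error, not a silent flip
  bad <- meta_input(c(0.1, 0.1), c(0.1, 0.1))
  bad$refA <- c("t", "c"); bad$altA <- c("c", "t")
  expect_error(meta_fixed_effects(bad), "mismatch")
})

test_that("meta-analysis agrees with an independent implementation", {
  skip_if_not_installed("metafor")
  set.seed(33)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    beta <- rnorm(k, 0.1, 0.2); se <- runif(k, 0.05, 0.3)
    got <- meta_fixed_effects(meta_input(beta, se))
    ref <- metafor::rma(yi = beta, sei = se, method = "FE")
    expect_equal(got$beta_meta, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(got$se_meta, as.numeric(ref$se), tolerance = 1e-10)
    expect_equal(got$p, as.numeric(ref$pval), tolerance = 1e-10)
  }
})

test_that("the causal variant tops the scan with consistent directions", {
  for (seeds in list(c(101, 202), c(303, 404))) {
    studies <- make_two_study_design(seeds[1], seeds[2])
    scan <- genome_scan(studies, phenotypes = c("AA", "DHA"))
    aa <- dplyr::filter(scan, phenotype == "AA")
    expect_equal(aa$snpid[1], "rs_causal")
    expect_equal(aa$dir[1], "--")
    expect_equal(aa$n[1], 1142L)
    # reported effect is multiplicative, near the simulated 0.85
    expect_lt(abs(aa$beta_reported[1] - 0.85), 0.06)
  }
})

test_that("a null scan stays above the experiment-wise threshold", {
  m <- 4000; n <- 400
  vars <- make_variants(m, raf = runif(m, 0.15, 0.85))
  st <- simulate_study(sim_config(n, vars, seed = 515))
  scan <- genome_scan(list(only = st), phenotypes = "AA")
  expect_gt(min(scan$p, na.rm = TRUE), 4.2e-9)
  # genomic control inflation is modest under the null
  lg <- lambda_gc(scan)
  expect_lt(abs(lg$lambda - 1), 0.1)
})

test_that("regional bounds are honoured exactly", {
  pos <- c(61546999L, 61547000L, 61600000L, 61673000L, 61673001L)
  vars <- tibble::tibble(snpid = paste0("v", 1:5), chrom = "11", pos = pos,
                         refA = "t", altA = "c", raf = 0.3)
  st <- simulate_study(sim_config(300, vars, seed = 77))
  scan <- genome_scan(list(st), phenotypes = "AA",
                      region = list(chrom = "11", start = 61547000,
                                    end = 61673000),
                      filter_mode = "regional")
  expect_setequal(unique(scan$snpid), c("v2", "v3", "v4"))
})

test_that("scan output is invariant to variant input order", {
  vars <- make_variants(6, raf = seq(0.2, 0.7, by = 0.1))
  st <- simulate_study(sim_config(250, vars, seed = 88))
  scan1 <- genome_scan(list(st), phenotypes = "AA")
  perm <- c(4, 1, 6, 2, 5, 3)
  st2 <- st
  st2$geno <- subset_variants(st$geno, perm)
  scan2 <- genome_scan(list(st2), phenotypes = "AA")
  expect_equal(as.data.frame(scan1), as.data.frame(scan2), tolerance = 1e-12)
})

test_that("conditioning removes mediated and self signals", {
  # one causal variant drives AA; its apparent DPA6 signal is pure mediation
  vars <- make_variants(1, raf = 0.17)
  vars$snpid <- "rs_causal"
  eff <- tibble::tibble(snpid = "rs_causal", phenotype = "AA", factor = 0.7)
  mk <- function(seed, n) {
    st <- simulate_study(sim_config(n, vars, effects = eff, seed = seed))
    # rebuild DPA6 so its *entire* dependence structure runs through the AA
    # fraction (intra-pathway coupling plus independent noise): the genotype
    # then reaches DPA6 only via AA
    set.seed(seed + 5000L)
    st$phenotypes$DPA6 <- 0.12 * (st$phenotypes$AA / 0.53) *
      exp(rnorm(n, 0, 0.3))
    st
  }
  studies <- list(a = mk(1201, 700), b = mk(1202, 700))
  region <- list(chrom = "11", start = 61547000, end = 61673000)

  un <- regional_conditional_scan(studies, region, phenotypes = "DPA6")
  expect_lt(un$p[un$snpid == "rs_causal"], 1e-5)   # mediated signal present
  cond_aa <- regional_conditional_scan(studies, region,
                                       condition_on = list(phenotype = "AA"),
                                       phenotypes = "DPA6")
  expect_gt(cond_aa$p[cond_aa$snpid == "rs_causal"], 1e-5)  # and removed

  # conditioning the causal variant on its own dosage annihilates its signal
  un_aa <- regional_conditional_scan(studies, region, phenotypes = "AA")
  expect_lt(un_aa$p[un_aa$snpid == "rs_causal"], 1e-6)
  cond_snp <- regional_conditional_scan(
    studies, region, condition_on = list(variant = "rs_causal"),
    phenotypes = "AA")
  row <- dplyr::filter(cond_snp, snpid == "rs_causal")
  expect_true(is.na(row$p) || row$p > 0.99)

  # conditioning a phenotype on itself leaves nothing testable
  self <- regional_conditional_scan(studies, region,
                                    condition_on = list(phenotype = "AA"),
                                    phenotypes = "AA")
  expect_true(all(is.na(self$p)))
})

test_that("locus grouping merges transitively within the window", {
  mk <- function(n, chrom, pos, p) {
    tibble::tibble(phenotype = "AA", snpid = paste0("s", seq_len(n)),
                   chrom = chrom, pos = pos, p = p)
  }
  # 24 experiment-wise-significant variants spanning 126 kb -> one locus
  res <- mk(24, "11", as.integer(seq(61547000, 61673000, length.out = 24)),
            rep(1e-10, 24))
  loci <- group_loci(res, threshold = 4.2e-9, genomewide = 5e-8,
                     window = 5e5)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_sig_strict, 24L)
  expect_equal(loci$n_snps, "24/24")

  # two significant variants 2 Mb apart -> two loci
  res2 <- mk(2, "2", c(1e6L, 3e6L), c(1e-9, 1e-9))
  expect_equal(nrow(group_loci(res2)), 2)

  # mixed significance: lead is the smallest p; counts split by threshold
  res3 <- mk(3, "13", c(100L, 50100L, 100100L), c(1e-10, 1e-8, 0.5))
  loci3 <- group_loci(res3)
  expect_equal(loci3$lead_snp, "s1")
  expect_equal(loci3$n_snps, "1/2")

  # empty input -> empty output
  expect_equal(nrow(group_loci(mk(1, "1", 1L, 0.5))), 0)
})

test_that("scans are deterministic end to end under a fixed config", {
  studies <- make_two_study_design(7, 8, n1 = 150, n2 = 160)
  s1 <- genome_scan(studies, phenotypes = "AA")
  s2 <- genome_scan(make_two_study_design(7, 8, n1 = 150, n2 = 160),
                    phenotypes = "AA")
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
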