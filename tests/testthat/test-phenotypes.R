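test_that("derived summary fractions are class sums, ratio guarded", {
  # synthetic profiles: recompute class sums independently
  vars <- make_variants(1, raf = 0.4)
  prof <- simulate_fa_profiles(simulate_dyad_genotypes(sim_config(200, vars,
                                                                  seed = 8)))
  out <- derive_summary_fractions(prof)
  panel <- fa_reference()
  for (cls in c("SFA", "MUFA", "PUFA6", "PUFA3", "TFA")) {
    manual <- rowSums(as.matrix(prof[, panel$abbrev[panel$class == cls]]))
    expect_equal(out[[cls]], manual, tolerance = 1e-12)
  }
  expect_equal(out$PUFA, out$PUFA6 + out$PUFA3, tolerance = 1e-12)
  expect_equal(out$PUFA6_PUFA3, out$PUFA6 / out$PUFA3, tolerance = 1e-12)

  # idempotent
  expect_equal(derive_summary_fractions(out), out)

  # degenerate composition: only palmitic acid present
  row1 <- prof[1, ]
  row1[, panel$abbrev] <- 0
  row1$PAL <- 100
  expect_warning(d <- derive_summary_fractions(row1), "PUFA3")
  expect_equal(d$SFA, 100)
  expect_true(is.na(d$PUFA6_PUFA3))
})

test_that("published class totals are internally consistent", {
  # two independent cohort columns: PUFA equals PUFA6 + PUFA3 as printed
  for (coh in c("provide_malchip", "provide_gwas")) {
    tot <- fa_published_totals(coh)
    get <- function(ph) tot$mean[tot$phenotype == ph]
    expect_equal(get("PUFA"), get("PUFA6") + get("PUFA3"), tolerance = 0.005)
    # and the printed class totals equal the sums of the printed components
    ref <- fa_reference(coh)
    for (cls in c("SFA", "MUFA", "PUFA6", "PUFA3", "TFA")) {
      expect_equal(get(cls), sum(ref$mean[ref$class == cls]),
                   tolerance = 0.025, label = paste(coh, cls))
    }
  }
})

test_that("transforms follow the per-phenotype specs", {
  specs <- phenotype_specs()
  expect_equal(nrow(specs), 33)
  expect_equal(sum(specs$transform == "log"), 32)
  expect_equal(specs$transform[specs$phenotype == "PUFA6_PUFA3"], "sqrt")

  tbl <- tibble::tibble(AA = c(0.53, 0.53 * 1.17, 0),
                        PUFA6_PUFA3 = c(12, 9, 16))
  tr <- transform_phenotypes(tbl, specs)
  expect_equal(tr$AA[1], log(0.53), tolerance = 1e-12)
  expect_equal(tr$PUFA6_PUFA3[1], sqrt(12), tolerance = 1e-12)
  # multiplicative x1.17 becomes additive +log(1.17)
  expect_equal(tr$AA[2] - tr$AA[1], log(1.17), tolerance = 1e-12)
  # zero under log is excluded for that phenotype only
  expect_true(is.na(tr$AA[3]))
  expect_false(anyNA(tr$PUFA6_PUFA3))
  expect_equal(attr(tr, "n_excluded")[["AA"]], 1L)

  # transform / inverse-transform round trip
  expect_equal(inverse_transform(log(0.53), "log"), 0.53, tolerance = 1e-12)
  expect_equal(inverse_transform(sqrt(12), "sqrt"), 12, tolerance = 1e-12)
})

test_that("phenotype correlation matrix behaves", {
  set.seed(14)
  n <- 1e4
  tbl <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  C <- phenotype_correlation(tbl, c("a", "b", "c"))
  expect_equal(diag(unclass(C)), c(a = 1, b = 1, c = 1))
  expect_lt(max(abs(C[upper.tri(C)])), 0.03)

  tbl$d <- tbl$a
  C2 <- phenotype_correlation(tbl, c("a", "d"))
  expect_equal(C2["a", "d"], 1)

  tbl$e <- 5
  expect_error(phenotype_correlation(tbl, c("a", "e")), "Constant.*e")

  # in compositional profiles PUFA tracks PUFA6 (the dominant component)
  vars <- make_variants(1, raf = 0.4)
  prof <- transform_phenotypes(derive_summary_fractions(
    simulate_fa_profiles(simulate_dyad_genotypes(sim_config(500, vars,
                                                            seed = 15)))))
  C3 <- phenotype_correlation(prof, c("PUFA", "PUFA6"))
  expect_gt(C3["PUFA", "PUFA6"], 0.95)
})

test_that("effective test count follows the eigenvalue rule", {
  expect_equal(effective_tests(diag(33))$meff, 33)
  ones <- matrix(1, 3, 3)
  expect_equal(effective_tests(ones)$meff, 1)
  r <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_equal(effective_tests(r)$meff, 2.0, tolerance = 1e-12)
  expect_equal(sort(effective_tests(r)$eigenvalues), c(0.4, 1.6),
               tolerance = 1e-12)

  # Meff stays inside [1, K] for random correlation matrices
  set.seed(99)
  for (i in 1:20) {
    X <- matrix(rnorm(40 * 6), 40, 6)
    C <- cor(X)
    meff <- effective_tests(C)$meff
    expect_gte(meff, 1); expect_lte(meff, 6)
    # eigenvalues of a correlation matrix sum to K
    expect_equal(sum(effective_tests(C)$eigenvalues), 6, tolerance = 1e-8)
  }
  expect_error(effective_tests(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("experiment-wise threshold is the Bonferroni quotient", {
  expect_equal(experiment_wise_threshold(5e-8, 12.0), 5e-8 / 12)
  expect_equal(signif(experiment_wise_threshold(5e-8, 12.0), 2), 4.2e-9)
  expect_equal(experiment_wise_threshold(0.05, 1), 0.05)
  th <- sapply(c(1, 2, 5, 12, 33), experiment_wise_threshold,
               alpha_gw = 5e-8)
  expect_true(all(diff(th) < 0))
})

test_that("variance explained moment-matches the published scenario", {
  # log-normal matched to AA mean 0.53, SD 0.15; raf 0.17; factor 0.85
  ve <- variance_explained(0.53, 0.15, 0.17, 0.85)
  expect_equal(100 * ve, 9.6, tolerance = 0.02)   # relative
  expect_equal(variance_explained(0.53, 0.15, 0.17, 1.0), 0)
})
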