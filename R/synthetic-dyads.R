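#' Configure a synthetic mother-father-infant cohort
#'
#' The generator inverts the analysis model: parental genotypes are drawn
#' under Hardy-Weinberg equilibrium at each variant's reference-allele
#' frequency, infants receive one allele from each parent, and compositional
#' fatty-acid profiles are drawn multivariate-normal on the log scale with
#' moment-matched means and SDs, multiplied by per-allele genetic effects of
#' the *maternal* genotype, then closed to sum 100.
#'
#' @param n_dyads Number of mother-infant dyads.
#' @param variants Tibble with columns `snpid`, `chrom`, `pos`, `refA`,
#'   `altA`, `raf` (reference-allele frequency strictly inside (0, 1)).
#' @param fa_profile Tibble with columns `abbrev`, `class`, `mean`, `sd` for
#'   the 26 assayed fractions; defaults to the built-in PROVIDE GWAS cohort
#'   profile ([fa_reference()]).
#' @param rho_within Latent log-scale correlation within a fatty-acid class
#'   (default 0.5).
#' @param rho_sfa_pufa Latent correlation between the SFA block and each PUFA
#'   block (default -0.3); all other between-class correlations are 0.  The
#'   blocks are qualitative stand-ins for the published correlation heat map,
#'   which prints no numeric values, and are fully configurable.
#' @param effects Tibble with columns `snpid`, `phenotype` (an assayed
#'   abbreviation), `factor` (> 0): each maternal reference allele multiplies
#'   that fraction by `factor`.  `NULL` for no genetic effects.
#' @param covariate_effects Tibble with columns `covariate`, `phenotype`,
#'   `beta` — additive effects on the log scale per covariate unit.  `NULL`
#'   (default) for none.
#' @param seed Integer seed; every simulation from the same config is
#'   bit-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_dyads, variants, fa_profile = fa_reference(),
                       rho_within = 0.5, rho_sfa_pufa = -0.3,
                       effects = NULL, covariate_effects = NULL,
                       seed = 1L) {
  variants <- validate_variants(variants)
  if (!"raf" %in% names(variants)) abort("`variants` needs a `raf` column.")
  if (any(variants$raf <= 0 | variants$raf >= 1)) {
    abort("monomorphic variant: all rafs must lie strictly in (0, 1).")
  }
  fa_profile <- as_tibble(fa_profile)
  stopifnot(all(c("abbrev", "class", "mean", "sd") %in% names(fa_profile)))
  if (any(fa_profile$mean <= 0)) abort("Fraction means must be positive.")
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    stopifnot(all(c("snpid", "phenotype", "factor") %in% names(effects)))
    if (any(effects$factor <= 0)) abort("Multiplicative factors must be > 0.")
    if (!all(effects$snpid %in% variants$snpid)) {
      abort("Effect snpid not present in the variant list.")
    }
    if (!all(effects$phenotype %in% fa_profile$abbrev)) {
      abort("Effects must target assayed fractions (derived sums are computed downstream).")
    }
  }
  R <- build_fa_correlation(fa_profile$class, rho_within, rho_sfa_pufa)
  structure(list(
    n_dyads = as.integer(n_dyads), variants = variants,
    fa_profile = fa_profile, corr = R, rho_within = rho_within,
    rho_sfa_pufa = rho_sfa_pufa, effects = effects,
    covariate_effects = covariate_effects, seed = as.integer(seed)),
    class = "sim_config")
}

#' Latent log-scale correlation matrix for the fatty-acid panel
#'
#' Exchangeable correlation `rho_within` inside each class; `rho_sfa_pufa`
#' between the SFA block and each of the PUFA6/PUFA3 blocks; 0 elsewhere.
#' Positive semi-definiteness is verified numerically before use.
#'
#' @param classes Character vector of class labels, one per fraction.
#' @inheritParams sim_config
#' @return A correlation matrix.
#' @export
build_fa_correlation <- function(classes, rho_within = 0.5,
                                 rho_sfa_pufa = -0.3) {
  K <- length(classes)
  same <- outer(classes, classes, "==")
  R <- matrix(0, K, K)
  R[same] <- rho_within
  sfa <- classes == "SFA"; pufa <- classes %in% c("PUFA6", "PUFA3")
  R[outer(sfa, pufa) | outer(pufa, sfa)] <- rho_sfa_pufa
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf("Latent correlation matrix is not positive semi-definite (min eigenvalue %.3g).",
                  min(ev)))
  }
  R
}

#' Simulate dyad genotypes under HWE and Mendelian transmission
#'
#' Mothers and fathers are i.i.d. HWE draws per variant; each infant receives
#' one allele sampled uniformly from each parent's two.  Genotypes are hard
#' reference-allele counts.
#'
#' @param config A [sim_config()].
#' @return A `dyad_cohort` list with `mother`, `father`, `infant` count
#'   matrices (n_dyads x n_variants), the variant table, sample ids, and a
#'   covariate tibble (`mat_age` years, `inf_age_days`, `inf_sex` 0/1,
#'   `site` 0/1).
#' @export
simulate_dyad_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_dyads; p <- config$variants$raf; m <- length(p)
  draw_hwe <- function() {
    matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  }
  mother <- draw_hwe(); father <- draw_hwe()
  # transmitted allele: Bernoulli(count/2) per parent
  infant <- matrix(rbinom(n * m, 1L, mother / 2), nrow = n) +
            matrix(rbinom(n * m, 1L, father / 2), nrow = n)
  samples <- sprintf("D%05d", seq_len(n))
  covariates <- tibble(
    sample = samples,
    mat_age = round(pmin(pmax(rnorm(n, 24, 5), 16), 45), 1),
    inf_age_days = pmin(pmax(round(rnorm(n, 8, 4)), 3), 43),
    inf_sex = rbinom(n, 1, 0.5),
    site = 0L)
  structure(list(mother = mother, father = father, infant = infant,
                 variants = config$variants, samples = samples,
                 covariates = covariates, config = config),
            class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("<dyad_cohort> %d dyads x %d variants (hard trio genotypes)\n",
              nrow(x$mother), ncol(x$mother)))
  invisible(x)
}

#' Simulate compositional fatty-acid profiles for a dyad cohort
#'
#' Latent fractions are log-normal with moment-matched parameters
#' (`sigma2_log = log(1 + CV^2)`, `mu_log = log(mean) - sigma2_log / 2`) and
#' the configured latent correlation.  Each genetic effect multiplies its
#' target fraction by `factor^(maternal reference-allele count)`; covariate
#' effects add on the log scale.  Finally the 26 fractions are closed
#' (renormalised) to sum exactly 100 per mother, as %wt/wt measurement
#' imposes; for trace fractions like AA (~0.5% of total) the closure
#' attenuation of realised effects is negligible.
#'
#' @param cohort A `dyad_cohort`.
#' @param config The same [sim_config()] used to generate it (defaults to the
#'   one stored in the cohort).
#' @return A tibble: `sample`, 26 fraction columns, covariate columns.
#' @export
simulate_fa_profiles <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "dyad_cohort"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  prof <- config$fa_profile
  n <- nrow(cohort$mother); K <- nrow(prof)
  cv2 <- (prof$sd / prof$mean)^2
  sigma_log <- sqrt(log(1 + cv2))
  mu_log <- log(prof$mean) - sigma_log^2 / 2
  L <- chol(config$corr)
  z <- matrix(rnorm(n * K), n, K) %*% L
  xlog <- sweep(sweep(z, 2, sigma_log, "*"), 2, mu_log, "+")
  colnames(xlog) <- prof$abbrev
  if (!is.null(config$effects)) {
    for (i in seq_len(nrow(config$effects))) {
      e <- config$effects[i, ]
      j <- match(e$snpid, cohort$variants$snpid)
      xlog[, e$phenotype] <- xlog[, e$phenotype] +
        log(e$factor) * cohort$mother[, j]
    }
  }
  if (!is.null(config$covariate_effects)) {
    ce <- as_tibble(config$covariate_effects)
    for (i in seq_len(nrow(ce))) {
      xlog[, ce$phenotype[i]] <- xlog[, ce$phenotype[i]] +
        ce$beta[i] * cohort$covariates[[ce$covariate[i]]]
    }
  }
  x <- exp(xlog)
  x <- 100 * x / rowSums(x)                 # closure to %wt/wt
  bind_cols(tibble(sample = cohort$samples), as_tibble(x),
            cohort$covariates[, setdiff(names(cohort$covariates), "sample")])
}

#' Degrade hard genotypes into probabilistic triples
#'
#' Emulates imputation uncertainty: the true class keeps probability
#' `certainty`, and the remaining mass is split between the other two classes
#' proportionally to their priors (Hardy-Weinberg at the variant's `raf`
#' unless `priors` is supplied).  `certainty = 1` returns degenerate triples;
#' with uniform priors `certainty = 1/3` is fully uninformative.
#'
#' @param g Hard reference-allele count matrix (samples x variants).
#' @param certainty Scalar in `(1/3, 1]` (or exactly 1/3 in the uninformative
#'   limit).
#' @param variants Variant tibble with `raf` (ignored when `priors` given).
#' @param priors Optional length-3 prior over counts 0/1/2 applied to every
#'   variant (overrides HWE priors).
#' @return A `geno_triples` object.
#' @export
degrade_to_probabilistic <- function(g, certainty, variants, priors = NULL) {
  if (certainty < 1 / 3 - 1e-12 || certainty > 1) {
    abort("`certainty` must lie in (1/3, 1] (1/3 = uninformative limit).")
  }
  g <- as.matrix(g)
  variants <- validate_variants(variants, n = ncol(g))
  n <- nrow(g); m <- ncol(g)
  pri <- if (is.null(priors)) {
    if (!"raf" %in% names(variants)) abort("`variants` needs `raf` for HWE priors.")
    p <- variants$raf
    rbind((1 - p)^2, 2 * p * (1 - p), p^2)   # 3 x m
  } else {
    matrix(rep(priors / sum(priors), m), nrow = 3)
  }
  out <- list(matrix(0, n, m), matrix(0, n, m), matrix(0, n, m))
  for (k in 0:2) {                           # true class k
    sel <- g == k
    other <- setdiff(0:2, k)
    po <- pri[other + 1, , drop = FALSE]
    share <- sweep(po, 2, colSums(po), "/")
    for (cls in 0:2) {
      add <- if (cls == k) certainty else
        (1 - certainty) * share[match(cls, other), ]
      out[[cls + 1]][sel] <- (matrix(add, n, m, byrow = TRUE))[sel]
    }
  }
  out[[1]][is.na(g)] <- 0; out[[2]][is.na(g)] <- 0; out[[3]][is.na(g)] <- 0
  geno_triples(out[[1]], out[[2]], out[[3]], variants,
               rownames(g) %||% NULL, normalise = FALSE)
}

#' Simulate one complete study (infant genotypes + phenotype table)
#'
#' Convenience wrapper chaining [simulate_dyad_genotypes()] and
#' [simulate_fa_profiles()], optionally degrading the infant hard calls to
#' probabilistic triples, and packaging the result in the study format the
#' scan functions consume.
#'
#' @inheritParams simulate_fa_profiles
#' @param certainty Infant genotype certainty passed to
#'   [degrade_to_probabilistic()]; 1 (default) keeps hard calls.
#' @param site Value for the `site` covariate column.
#' @return A list with elements `geno` (infant `geno_triples`), `phenotypes`
#'   (fraction + covariate tibble), `covariates` (names to adjust for), and
#'   `truth` (the underlying `dyad_cohort`).
#' @export
simulate_study <- function(config, certainty = 1, site = 0L) {
  cohort <- simulate_dyad_genotypes(config)
  cohort$covariates$site <- site
  phen <- simulate_fa_profiles(cohort, config)
  phen$site <- site
  geno <- if (certainty < 1) {
    degrade_to_probabilistic(cohort$infant, certainty, cohort$variants)
  } else {
    hard_calls(cohort$infant, cohort$variants, cohort$samples)
  }
  geno$samples <- cohort$samples
  list(geno = geno, phenotypes = phen,
       covariates = c("mat_age", "inf_age_days", "inf_sex"),
       truth = cohort)
}
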