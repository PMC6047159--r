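#' Fixed-effects inverse-variance meta-analysis of per-study effects
#'
#' Combines per-study transformed-scale effects with weights `w_k = SE_k^-2`:
#' `beta_meta = sum(w_k beta_k) / sum(w_k)`, `SE_meta = sum(w_k)^-1/2`,
#' `Z = beta_meta / SE_meta`, two-sided normal p.  A single-study record is
#' returned unchanged.  Alleles must match across studies exactly — no
#' automatic strand/orientation flipping.
#'
#' @param results Long tibble of per-study score-test rows: columns `study`,
#'   `snpid`, `beta`, `se`, `testable`, `n`, and (for allele checking)
#'   `refA`, `altA`; a `phenotype` column is honoured when present.
#' @return A tibble with one row per variant (x phenotype): combined effect,
#'   SE, `z`, `p`, per-study direction string `dir` (`"?"` for untestable),
#'   and total `n`.
#' @export
meta_fixed_effects <- function(results) {
  stopifnot(all(c("study", "snpid", "beta", "se", "testable", "n")
                %in% names(results)))
  if (!"phenotype" %in% names(results)) results$phenotype <- "."
  if (all(c("refA", "altA") %in% names(results))) {
    chk <- results %>%
      group_by(.data$snpid) %>%
      summarise(nall = dplyr::n_distinct(paste(.data$refA, .data$altA)),
                .groups = "drop")
    if (any(chk$nall > 1)) {
      abort(paste0("Allele mismatch between studies (no auto-flip): ",
                   paste(chk$snpid[chk$nall > 1], collapse = ", ")))
    }
  }
  studies <- unique(results$study)
  results %>%
    mutate(study = factor(.data$study, levels = studies)) %>%
    arrange(.data$phenotype, .data$snpid, .data$study) %>%
    group_by(.data$phenotype, .data$snpid) %>%
    summarise(
      dir = paste(ifelse(.data$testable,
                         ifelse(.data$beta >= 0, "+", "-"), "?"),
                  collapse = ""),
      n = sum(.data$n[.data$testable]),
      k_studies = sum(.data$testable),
      beta_meta = {
        w <- 1 / .data$se[.data$testable]^2
        if (length(w)) sum(w * .data$beta[.data$testable]) / sum(w) else NA_real_
      },
      se_meta = {
        w <- 1 / .data$se[.data$testable]^2
        if (length(w)) 1 / sqrt(sum(w)) else NA_real_
      },
      .groups = "drop") %>%
    mutate(z = .data$beta_meta / .data$se_meta,
           p = 2 * pnorm(-abs(.data$z))) %>%
    (function(d) if (identical(unique(d$phenotype), ".")) select(d, -"phenotype") else d)
}

# --- study preparation ------------------------------------------------------

prep_study <- function(study, specs, region = NULL) {
  geno <- study$geno
  stopifnot(inherits(geno, "geno_triples"))
  if (!is.null(region)) {
    sel <- geno$variants$chrom == as.character(region$chrom) &
      geno$variants$pos >= region$start & geno$variants$pos <= region$end
    geno <- subset_variants(geno, sel)
  }
  phen <- study$phenotypes
  idx <- match(geno$samples, phen$sample)
  if (anyNA(idx)) abort("Phenotype table lacks rows for some genotyped samples.")
  phen <- phen[idx, , drop = FALSE]

  # infant-side per-variant QC statistics
  raf <- estimate_raf(geno)
  info <- info_score(geno, raf)
  hard <- round(triple_mean(geno))           # best-guess counts for HWE
  hwe_p <- vapply(seq_len(n_variants(geno)), function(j) {
    g <- hard[, j]; g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  stats <- tibble(snpid = geno$variants$snpid, present = TRUE,
                  maf = pmin(raf, 1 - raf), info = info, hwe_p = hwe_p)

  mothers <- suppressWarnings(impute_mothers(geno, raf))
  phen_t <- transform_phenotypes(derive_summary_fractions(phen), specs)
  list(mothers = mothers, stats = stats, phen_t = phen_t,
       covariates = study$covariates %||% character())
}

#' Genome (or regional) association scan with meta-analysis
#'
#' Orchestrates the full pipeline per study — estimate infant allele
#' frequencies, impute maternal genotype posteriors, derive and transform the
#' compositional phenotypes, apply the variant QC filters, run the
#' missing-data score test for every surviving variant x phenotype pair —
#' then combines studies by fixed-effects meta-analysis and ranks by
#' combined significance (ties broken by position).
#'
#' Conditional models append either the transformed conditioning phenotype
#' (e.g. log AA fraction) or the conditioning variant's posterior-mean
#' maternal dosage as an extra covariate.
#'
#' @param studies Named list of studies; each is a list with `geno` (infant
#'   `geno_triples`), `phenotypes` (tibble with `sample`, the 26 fraction
#'   columns and covariates), and `covariates` (character vector of
#'   adjustment columns).
#' @param phenotypes Phenotype names to scan; default all 33.
#' @param specs Phenotype specifications ([phenotype_specs()]).
#' @param filter_mode `"strict"` (screening: info = 1) or `"regional"`
#'   (info > 0.9, MAF > 0.05).
#' @param region Optional list `(chrom, start, end)`; bounds are inclusive,
#'   1-based.
#' @param condition_on Optional list with element `phenotype` (name) or
#'   `variant` (snpid) to condition every model on.
#' @param hwe_min Infant HWE exact-test p-value filter floor.
#' @return A `milkgwas_scan` tibble: one row per variant x phenotype with
#'   per-study effects, meta-analysis columns, reported (back-transformed)
#'   effect sizes and the direction string; attributes `lambda_gc` (genomic
#'   control diagnostics, no correction applied), `filtered` (per-variant
#'   keep/drop reasons) and `manifest`.
#' @export
genome_scan <- function(studies, phenotypes = NULL,
                        specs = phenotype_specs(),
                        filter_mode = c("strict", "regional"),
                        region = NULL, condition_on = NULL,
                        hwe_min = 1e-5) {
  filter_mode <- match.arg(filter_mode)
  if (is.null(names(studies)) || any(names(studies) == "")) {
    names(studies) <- paste0("study", seq_along(studies))
  }
  if (is.null(phenotypes)) phenotypes <- specs$phenotype
  prepped <- purrr::map(studies, prep_study, specs = specs, region = region)

  stats <- bind_rows(purrr::imap(prepped, function(p, nm) {
    mutate(p$stats, study = nm)
  }))
  filt <- variant_filters(stats, mode = filter_mode, hwe_min = hwe_min)
  keep_ids <- filt$snpid[filt$keep]
  if (!is.null(condition_on$variant) &&
      !condition_on$variant %in% keep_ids) {
    abort(sprintf("Conditioning variant %s fails the %s-mode filters.",
                  condition_on$variant, filter_mode))
  }
  if (length(keep_ids) == 0) {
    warn("No variant passed the QC filters; returning an empty scan.")
    out <- tibble()
    attr(out, "filtered") <- filt
    class(out) <- c("milkgwas_scan", class(tibble()))
    return(out)
  }

  per_study <- purrr::imap(prepped, function(pr, nm) {
    mo <- pr$mothers
    sel <- mo$variants$snpid %in% keep_ids
    if (!any(sel)) return(NULL)
    mo <- subset_variants(mo, sel)
    dat <- pr$phen_t
    covs <- pr$covariates
    if (dplyr::n_distinct(dat$site %||% 0) > 1) covs <- union(covs, "site")
    if (!is.null(condition_on$phenotype)) {
      dat$.cond <- dat[[condition_on$phenotype]]
      covs <- c(covs, ".cond")
    }
    if (!is.null(condition_on$variant)) {
      j <- match(condition_on$variant, mo$variants$snpid)
      dat$.cond_dose <- triple_mean(mo)[, j]
      covs <- c(covs, ".cond_dose")
    }
    purrr::map(phenotypes, function(ph) {
      if (!ph %in% names(dat)) return(NULL)
      null <- tryCatch(fit_null_model(dat, ph, covs), error = function(e) NULL)
      if (is.null(null) || null$degenerate) {
        return(bind_cols(mo$variants,
                         tibble(n = 0L, U = NA_real_, V = NA_real_,
                                testable = FALSE, beta = NA_real_,
                                se = NA_real_, stat = NA_real_, p = NA_real_,
                                direction = "?", phenotype = ph, study = nm)))
      }
      mutate(score_test(null, mo), phenotype = ph, study = nm)
    }) %>% bind_rows()
  }) %>% bind_rows()

  lambda_gc <- per_study %>%
    filter(.data$testable) %>%
    group_by(.data$study, .data$phenotype) %>%
    summarise(lambda = median(.data$stat) / stats::qchisq(0.5, 1, lower.tail = FALSE),
              n_tests = dplyr::n(), .groups = "drop")

  meta <- meta_fixed_effects(
    select(per_study, "study", "phenotype", "snpid", "refA", "altA",
           "beta", "se", "testable", "n"))
  wide <- per_study %>%
    select("study", "phenotype", "snpid", "beta", "se", "p") %>%
    tidyr::pivot_wider(names_from = "study",
                       values_from = c("beta", "se", "p"))
  vmeta <- purrr::map(prepped, function(p) {
    select(p$mothers$variants,
           any_of(c("snpid", "chrom", "pos", "refA", "altA", "raf", "info")))
  }) %>% bind_rows() %>% dplyr::distinct(.data$snpid, .keep_all = TRUE)
  out <- meta %>%
    left_join(vmeta, by = "snpid") %>%
    left_join(wide, by = c("phenotype", "snpid")) %>%
    left_join(select(specs, "phenotype", "transform", "s0"),
              by = "phenotype") %>%
    mutate(report_effect(.data$beta_meta, .data$se_meta, .data$transform,
                         s0 = dplyr::coalesce(.data$s0, 12))) %>%
    select(-"transform", -"s0") %>%
    arrange(.data$p, .data$chrom, .data$pos) %>%
    select("phenotype", "snpid", "chrom", "pos", "refA", "altA", "raf",
           dplyr::everything())
  attr(out, "lambda_gc") <- lambda_gc
  attr(out, "filtered") <- filt
  attr(out, "manifest") <- list(
    studies = names(studies), phenotypes = phenotypes,
    filter_mode = filter_mode, region = region, condition_on = condition_on,
    hwe_min = hwe_min, n_variants_kept = length(keep_ids))
  class(out) <- c("milkgwas_scan", class(out))
  out
}

#' @rdname genome_scan
#' @param ... Passed on to [genome_scan()].
#' @export
regional_conditional_scan <- function(studies, region, condition_on = NULL,
                                      ...) {
  genome_scan(studies, region = region, condition_on = condition_on,
              filter_mode = "regional", ...)
}

#' Group significant scan results into physical loci
#'
#' Significant variants on the same chromosome (for the same phenotype) are
#' merged transitively whenever consecutive positions lie within the merge
#' window.  Each locus reports its lead (smallest-p) variant and the member
#' counts at the experiment-wise and genome-wide thresholds, in the
#' `"n_strict/n_genomewide"` convention.
#'
#' @param results A scan tibble with `phenotype`, `snpid`, `chrom`, `pos`,
#'   `p` columns.
#' @param threshold Experiment-wise significance threshold (default 4.2e-9).
#' @param genomewide Genome-wide threshold used for locus membership
#'   (default 5e-8).
#' @param window Merge window in base pairs (default 500 kb).
#' @return A tibble, one row per locus, ordered by lead p.
#' @export
group_loci <- function(results, threshold = 4.2e-9, genomewide = 5e-8,
                       window = 5e5) {
  sig <- filter(results, !is.na(.data$p), .data$p < genomewide)
  if (nrow(sig) == 0) {
    return(tibble(phenotype = character(), chrom = character(),
                  start = integer(), end = integer(), lead_snp = character(),
                  lead_pos = integer(), lead_p = numeric(),
                  n_sig_strict = integer(), n_sig_genomewide = integer(),
                  n_snps = character(), members = list()))
  }
  sig %>%
    group_by(.data$phenotype, .data$chrom) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    mutate(cluster = cumsum(c(1, diff(.data$pos) > window))) %>%
    group_by(.data$phenotype, .data$chrom, .data$cluster) %>%
    summarise(
      start = min(.data$pos), end = max(.data$pos),
      lead_snp = .data$snpid[which.min(.data$p)],
      lead_pos = .data$pos[which.min(.data$p)],
      lead_p = min(.data$p),
      n_sig_strict = sum(.data$p < threshold),
      n_sig_genomewide = dplyr::n(),
      members = list(.data$snpid),
      .groups = "drop") %>%
    mutate(n_snps = sprintf("%d/%d", .data$n_sig_strict,
                            .data$n_sig_genomewide)) %>%
    select(-"cluster") %>%
    arrange(.data$lead_p)
}

#' Genomic-control diagnostics of a scan
#'
#' @param scan A `milkgwas_scan`.
#' @return The per-study, per-phenotype lambda tibble computed during the
#'   scan (no correction is applied to the results).
#' @export
lambda_gc <- function(scan) attr(scan, "lambda_gc")

#' Scatter plot of scan significance along the genome or a region
#'
#' @param object A `milkgwas_scan`.
#' @param threshold,genomewide Significance lines to draw.
#' @param highlight Optional phenotype name to emphasise.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot milkgwas_scan
autoplot.milkgwas_scan <- function(object, threshold = 4.2e-9,
                                   genomewide = 5e-8, highlight = NULL, ...) {
  df <- filter(as_tibble(object), !is.na(.data$p))
  df$mlp <- -log10(pmax(df$p, 1e-300))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$pos / 1e6, .data$mlp))
  if (!is.null(highlight)) {
    gg <- gg +
      ggplot2::geom_point(data = filter(df, .data$phenotype != highlight),
                          colour = "grey60", size = 1) +
      ggplot2::geom_point(data = filter(df, .data$phenotype == highlight),
                          colour = "#2166AC", size = 1.6)
  } else {
    gg <- gg + ggplot2::geom_point(ggplot2::aes(colour = .data$phenotype),
                                   size = 1.2, show.legend = FALSE)
  }
  gg +
    ggplot2::geom_hline(yintercept = -log10(c(genomewide, threshold)),
                        linetype = c("dotted", "dashed"), colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_bw()
}
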