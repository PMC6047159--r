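#' Add the seven derived summary fractions
#'
#' Computes, per mother, the class sums SFA, MUFA, PUFA6, PUFA3 and TFA, the
#' total PUFA (= PUFA6 + PUFA3) and the PUFA6/PUFA3 ratio, by simple
#' summation of the assayed component fractions.  Rows with PUFA3 = 0 get an
#' `NA` ratio (flagged, excluded from ratio analyses only).  Idempotent:
#' existing derived columns are recomputed.
#'
#' @param tbl A phenotype tibble containing the 26 assayed fraction columns.
#' @return The tibble with seven additional (or refreshed) columns.
#' @export
derive_summary_fractions <- function(tbl) {
  panel <- fa_panel_data()
  missing <- setdiff(panel$abbrev, names(tbl))
  if (length(missing)) {
    abort(paste0("Missing assayed fraction column(s): ",
                 paste(missing, collapse = ", ")))
  }
  class_sum <- function(cls) {
    rowSums(as.matrix(tbl[, panel$abbrev[panel$class == cls], drop = FALSE]))
  }
  tbl$SFA <- class_sum("SFA")
  tbl$MUFA <- class_sum("MUFA")
  tbl$PUFA6 <- class_sum("PUFA6")
  tbl$PUFA3 <- class_sum("PUFA3")
  tbl$PUFA <- tbl$PUFA6 + tbl$PUFA3
  tbl$TFA <- class_sum("TFA")
  tbl$PUFA6_PUFA3 <- ifelse(tbl$PUFA3 > 0, tbl$PUFA6 / tbl$PUFA3, NA_real_)
  if (any(!is.na(tbl$PUFA3) & tbl$PUFA3 == 0)) {
    warn(sprintf("%d row(s) with PUFA3 = 0: PUFA6/PUFA3 ratio undefined, flagged NA.",
                 sum(tbl$PUFA3 == 0, na.rm = TRUE)))
  }
  tbl
}

#' Variance-stabilising transforms for the analysis phenotypes
#'
#' Applies the transform given by each phenotype's spec: natural log for the
#' 32 fraction phenotypes, square root for the PUFA6/PUFA3 ratio.  A
#' multiplicative per-allele genetic effect on a fraction is thereby additive
#' on the analysis scale.  Non-positive values under log are set `NA` for
#' that phenotype only (complete-case within phenotype) and the exclusion
#' counts are recorded in the `"n_excluded"` attribute.
#'
#' @param tbl Phenotype tibble (after [derive_summary_fractions()]).
#' @param specs Phenotype specification tibble, default [phenotype_specs()].
#' @return Tibble with transformed phenotype columns (same names), other
#'   columns untouched.
#' @export
transform_phenotypes <- function(tbl, specs = phenotype_specs()) {
  excluded <- integer(0)
  for (i in seq_len(nrow(specs))) {
    ph <- specs$phenotype[i]
    if (!ph %in% names(tbl)) next
    x <- tbl[[ph]]
    bad <- !is.na(x) & x <= 0
    if (specs$transform[i] == "log") {
      x[bad] <- NA_real_
      tbl[[ph]] <- log(x)
    } else if (specs$transform[i] == "sqrt") {
      x[bad & x < 0] <- NA_real_
      tbl[[ph]] <- sqrt(x)
    }
    if (any(bad)) excluded[ph] <- sum(bad)
  }
  if (length(excluded)) {
    inform(paste0("Excluded non-positive values under transform: ",
                  paste(sprintf("%s (%d)", names(excluded), excluded),
                        collapse = ", ")))
  }
  attr(tbl, "n_excluded") <- excluded
  tbl
}

#' Back-transform a transformed phenotype value
#'
#' @param x Transformed value(s).
#' @param transform `"log"` or `"sqrt"`.
#' @return Value(s) on the original fraction scale.
#' @export
inverse_transform <- function(x, transform = c("log", "sqrt")) {
  switch(match.arg(transform), log = exp(x), sqrt = x^2)
}

#' Pairwise Pearson correlation of the analysis phenotypes
#'
#' @param tbl Transformed phenotype tibble.
#' @param phenotypes Columns to correlate; defaults to the 33 spec phenotypes
#'   present in `tbl`.
#' @return A correlation matrix (class `fa_corr`), pairwise-complete.
#' @export
phenotype_correlation <- function(tbl, phenotypes = NULL) {
  if (is.null(phenotypes)) {
    phenotypes <- intersect(phenotype_specs()$phenotype, names(tbl))
  }
  X <- as.matrix(tbl[, phenotypes, drop = FALSE])
  if (sum(complete.cases(X)) < 3) abort("Need at least 3 complete rows.")
  sds <- apply(X, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    abort(paste0("Constant phenotype(s): ",
                 paste(phenotypes[sds == 0 | is.na(sds)], collapse = ", ")))
  }
  C <- cor(X, use = "pairwise.complete.obs")
  structure(C, class = c("fa_corr", "matrix"))
}

#' Effective number of independent tests from a correlation matrix
#'
#' Eigenvalue-based multiplicity correction for correlated phenotypes.  The
#' default (Li-Ji) counts each eigenvalue as `I(lambda >= 1) +
#' (lambda - floor(lambda))`; the simpler variant without the floor term
#' (`method = "li"`, `sum(pmin(lambda, 1))`) is available for sensitivity
#' analysis.  Tiny negative
#' eigenvalues from near-singular matrices are clamped to zero.
#'
#' @param C A symmetric correlation matrix.
#' @param method `"liji"` (default) or `"li"`.
#' @return A `meff_result` list: `eigenvalues`, `meff`, `method`, `K`.
#' @export
effective_tests <- function(C, method = c("liji", "li")) {
  method <- match.arg(method)
  C <- unclass(C)
  if (!isSymmetric(C, tol = 1e-8)) abort("Correlation matrix must be symmetric.")
  lambda <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0] <- 0
  # guard float round-off at integer eigenvalues (e.g. 3 - 4e-16)
  frac <- lambda - floor(lambda + 1e-9)
  meff <- switch(method,
    liji = sum((lambda >= 1 - 1e-9) + frac),
    li = sum(pmin(lambda, 1)))
  meff <- min(max(meff, 1), ncol(C))
  structure(list(eigenvalues = lambda, meff = meff, method = method,
                 K = ncol(C)), class = "meff_result")
}

#' @export
print.meff_result <- function(x, ...) {
  cat(sprintf("<meff_result> K = %d phenotypes, Meff = %.2f (%s)\n",
              x$K, x$meff, x$method))
  invisible(x)
}

#' @export
#' @method tidy meff_result
tidy.meff_result <- function(x, ...) {
  tibble(eigenvalue = x$eigenvalues,
         contribution = (x$eigenvalues >= 1) +
           (x$eigenvalues - floor(x$eigenvalues)))
}

#' @export
#' @method glance meff_result
glance.meff_result <- function(x, ...) {
  tibble(K = x$K, meff = x$meff, method = x$method)
}

#' Experiment-wise significance threshold
#'
#' Bonferroni division of the genome-wide alpha by the effective number of
#' independent phenotypes: `alpha_exp = alpha_gw / meff`.
#'
#' @param alpha_gw Genome-wide alpha (default the conventional 5e-8).
#' @param meff Effective test count (a number or a `meff_result`).
#' @return The experiment-wise alpha.
#' @export
experiment_wise_threshold <- function(alpha_gw = 5e-8, meff) {
  if (inherits(meff, "meff_result")) meff <- meff$meff
  stopifnot(alpha_gw > 0, alpha_gw < 1, meff >= 1)
  alpha_gw / meff
}

#' Heat-map of the phenotype correlation matrix
#'
#' @param object An `fa_corr` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot fa_corr
autoplot.fa_corr <- function(object, ...) {
  ord <- rownames(object) %||% colnames(object) %||%
    as.character(seq_len(ncol(object)))
  df <- as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("x", "y", "r")
  df$x <- factor(df$x, levels = ord)
  df$y <- factor(df$y, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 7),
                   axis.text.y = ggplot2::element_text(size = 7))
}

#' Variance in a log fraction explained by a multiplicative per-allele effect
#'
#' Moment-matches a log-normal to a fraction's published mean and SD
#' (`sigma2_log = log(1 + CV^2)`) and computes the share of that log-scale
#' variance attributable to an additive allelic effect `log(factor)` at a
#' biallelic variant with reference-allele frequency `p` under HWE (genotype
#' variance `2 p (1 - p)`).
#'
#' @param mean,sd Fraction mean and SD on the raw %wt/wt scale.
#' @param raf Reference-allele frequency.
#' @param factor Multiplicative change in the fraction per reference allele.
#' @return Fraction of log-scale variance explained, in `[0, 1]`.
#' @export
variance_explained <- function(mean, sd, raf, factor) {
  check_raf(raf)
  stopifnot(mean > 0, sd >= 0, factor > 0)
  sigma2_log <- log(1 + (sd / mean)^2)
  gvar <- log(factor)^2 * 2 * raf * (1 - raf)
  gvar / sigma2_log
}
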