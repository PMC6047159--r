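#' Genotype-probability container
#'
#' A `geno_triples` object stores, for every sample x variant cell, the
#' probability distribution `(pi0, pi1, pi2)` over carrying 0, 1 or 2 copies
#' of the *reference* allele.  Hard calls are degenerate triples with a single
#' entry equal to 1; a missing genotype is encoded as `(0, 0, 0)` and is
#' excluded from per-variant statistics.
#'
#' @param p0,p1,p2 Numeric matrices (samples x variants) of probabilities of
#'   carrying 0, 1, 2 reference-allele copies.
#' @param variants A tibble of per-variant metadata with at least columns
#'   `snpid`, `chrom`, `pos` (1-based), `refA`, `altA`.  Optional columns
#'   `raf` and `info` are carried along when present.
#' @param samples Character vector of sample identifiers, one per row.
#' @param normalise Renormalise each triple to sum 1?  Triples whose raw sum
#'   falls outside `[0.98, 1.02]` are rejected (all-zero cells are kept as
#'   missing).
#'
#' @return An object of class `geno_triples`.
#' @export
geno_triples <- function(p0, p1, p2, variants, samples = NULL,
                         normalise = TRUE) {
  p0 <- as.matrix(p0); p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  stopifnot(all(dim(p0) == dim(p1)), all(dim(p0) == dim(p2)))
  variants <- validate_variants(variants, n = ncol(p0))
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(nrow(p0)))
  if (length(samples) != nrow(p0)) {
    abort("`samples` must have one id per row of the probability matrices.")
  }
  if (any(p0 < -1e-12 | p1 < -1e-12 | p2 < -1e-12, na.rm = TRUE)) {
    abort("Genotype probabilities must be non-negative.")
  }
  s <- p0 + p1 + p2
  missing <- s == 0
  bad <- !missing & (s < 0.98 | s > 1.02)
  if (any(bad, na.rm = TRUE)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Probability triple sums to %.4f (outside [0.98, 1.02]) at sample %d, variant %d.",
      s[bad][1], idx[1], idx[2]))
  }
  if (normalise) {
    s[missing] <- 1          # leave missing cells at (0,0,0)
    p0 <- p0 / s; p1 <- p1 / s; p2 <- p2 / s
  }
  structure(
    list(p0 = p0, p1 = p1, p2 = p2, variants = variants,
         samples = as.character(samples)),
    class = "geno_triples")
}

validate_variants <- function(variants, n = NULL) {
  variants <- as_tibble(variants)
  req <- c("snpid", "chrom", "pos", "refA", "altA")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    abort(paste0("Variant table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!is.null(n) && nrow(variants) != n) {
    abort(sprintf("Variant table has %d rows but genotype matrices have %d columns.",
                  nrow(variants), n))
  }
  if (any(variants$pos < 1)) abort("Positions are 1-based; pos must be >= 1.")
  if (any(variants$refA == variants$altA)) {
    abort("refA and altA must differ for every variant.")
  }
  if ("raf" %in% names(variants) &&
      any(variants$raf < 0 | variants$raf > 1, na.rm = TRUE)) {
    abort("raf must lie in [0, 1].")
  }
  if ("info" %in% names(variants) &&
      any(variants$info < 0 | variants$info > 1 + 1e-8, na.rm = TRUE)) {
    abort("info must lie in [0, 1].")
  }
  variants
}

#' @export
print.geno_triples <- function(x, ...) {
  cat(sprintf("<geno_triples> %d samples x %d variants\n",
              nrow(x$p0), ncol(x$p0)))
  nm <- sum(is_missing_triple(x))
  if (nm > 0) cat(sprintf("  %d missing cell(s) encoded as (0,0,0)\n", nm))
  print(head(x$variants, 5))
  invisible(x)
}

#' @export
dim.geno_triples <- function(x) dim(x$p0)

#' Number of samples / variants in a genotype container
#' @param x A `geno_triples` object.
#' @return An integer.
#' @export
n_samples <- function(x) nrow(x$p0)

#' @rdname n_samples
#' @export
n_variants <- function(x) ncol(x$p0)

#' Hard-call genotype matrix to degenerate probability triples
#'
#' @param g Integer matrix (samples x variants) of reference-allele counts
#'   in `{0, 1, 2}`; `NA` becomes the missing triple `(0,0,0)`.
#' @inheritParams geno_triples
#' @return A `geno_triples` object of degenerate (hard) triples.
#' @export
hard_calls <- function(g, variants, samples = NULL) {
  g <- as.matrix(g)
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g))) {
    abort("Hard calls must be 0, 1, 2 or NA.")
  }
  p0 <- (g == 0) * 1; p1 <- (g == 1) * 1; p2 <- (g == 2) * 1
  p0[is.na(g)] <- 0; p1[is.na(g)] <- 0; p2[is.na(g)] <- 0
  geno_triples(p0, p1, p2, variants, samples, normalise = FALSE)
}

#' Per-cell posterior mean and variance of the reference-allele count
#'
#' `triple_mean()` returns `mu = pi1 + 2*pi2`, `triple_var()` returns
#' `v = tau - mu^2` with `tau = pi1 + 4*pi2` — the ingredients of both the
#' IMPUTE-style information score and the missing-data score test.  Missing
#' cells give `NA`.
#'
#' @param x A `geno_triples` object.
#' @return A samples x variants numeric matrix.
#' @export
triple_mean <- function(x) {
  mu <- x$p1 + 2 * x$p2
  mu[is_missing_triple(x)] <- NA_real_
  mu
}

#' @rdname triple_mean
#' @export
triple_var <- function(x) {
  mu <- x$p1 + 2 * x$p2
  v <- x$p1 + 4 * x$p2 - mu^2
  v[v < 0] <- 0                      # guard float round-off
  v[is_missing_triple(x)] <- NA_real_
  v
}

#' @rdname triple_mean
#' @export
is_missing_triple <- function(x) (x$p0 + x$p1 + x$p2) == 0

#' Estimate per-variant reference-allele frequencies
#'
#' `p-hat = sum_i mu_i / (2 n)` over non-missing samples, with `mu_i` the
#' posterior-mean reference-allele count of sample *i*.
#'
#' @param x A `geno_triples` object.
#' @return Numeric vector of length `n_variants(x)`.
#' @export
estimate_raf <- function(x) {
  mu <- triple_mean(x)
  nn <- colSums(!is.na(mu))
  if (any(nn == 0)) abort("Allele frequency undefined: variant with all genotypes missing.")
  colMeans(mu, na.rm = TRUE) / 2
}

#' IMPUTE-style information score
#'
#' `info = 1 - sum_i v_i / (2 n p(1-p))` with `v_i` the per-sample variance of
#' the reference-allele count and `p` the estimated reference-allele
#' frequency; defined as 1 when `p` is 0 or 1.  Hard calls give exactly 1;
#' triples at the Hardy-Weinberg prior give 0.
#'
#' @param x A `geno_triples` object.
#' @param raf Optional known reference-allele frequencies; estimated from `x`
#'   by default.
#' @return Numeric vector in `[0, 1]`, length `n_variants(x)`.
#' @export
info_score <- function(x, raf = NULL) {
  if (is.null(raf)) raf <- estimate_raf(x)
  v <- triple_var(x)
  nn <- colSums(!is.na(v))
  denom <- 2 * nn * raf * (1 - raf)
  out <- ifelse(denom == 0, 1, 1 - colSums(v, na.rm = TRUE) / denom)
  pmin(pmax(out, 0), 1)
}

#' Long-format view of a genotype container
#'
#' @param x A `geno_triples` object.
#' @param ... Unused.
#' @return A tibble with one row per sample x variant cell.
#' @export
#' @method as_tibble geno_triples
as_tibble.geno_triples <- function(x, ...) {
  tibble(
    sample = rep(x$samples, times = n_variants(x)),
    snpid  = rep(x$variants$snpid, each = n_samples(x)),
    pi0 = as.vector(x$p0), pi1 = as.vector(x$p1), pi2 = as.vector(x$p2))
}

#' Subset a genotype container by variant
#'
#' @param x A `geno_triples` object.
#' @param j Variant index (logical, integer or snpid character vector).
#' @return A `geno_triples` with the selected variants.
#' @export
subset_variants <- function(x, j) {
  if (is.character(j)) j <- match(j, x$variants$snpid)
  if (anyNA(j)) abort("Unknown snpid in variant subset.")
  geno_triples(x$p0[, j, drop = FALSE], x$p1[, j, drop = FALSE],
               x$p2[, j, drop = FALSE], x$variants[j, , drop = FALSE],
               x$samples, normalise = FALSE)
}
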