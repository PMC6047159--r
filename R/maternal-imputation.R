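#' Posterior distribution of a maternal genotype given her infant's genotype
#'
#' Under Hardy-Weinberg equilibrium at reference-allele frequency `p` and
#' Mendelian transmission, with the (ungenotyped) father treated as a random
#' population member, the maternal reference-allele count has the closed-form
#' posterior, given the infant's hard count `c`:
#'
#' * `c = 0`: `(1 - p, p, 0)`
#' * `c = 1`: `((1 - p)/2, 1/2, p/2)`
#' * `c = 2`: `(0, 1 - p, p)`
#'
#' in the order `(pi0, pi1, pi2)`.  A hard infant call excludes the
#' Mendelian-inconsistent maternal homozygote, and mixing the three posteriors
#' over the infant's own HWE distribution recovers the maternal HWE prior.
#'
#' @param c Infant reference-allele count(s) in `{0, 1, 2}` (recycled against
#'   `p`).
#' @param p Reference-allele frequency in (0, 1).
#' @return A tibble with columns `pi0`, `pi1`, `pi2`, one row per input.
#' @export
maternal_posterior <- function(c, p) {
  check_raf(p)
  if (!all(c %in% c(0, 1, 2))) abort("Infant count `c` must be 0, 1 or 2.")
  k <- max(length(c), length(p))
  c <- rep_len(c, k); p <- rep_len(p, k)
  tibble(
    pi0 = ifelse(c == 0, 1 - p, ifelse(c == 1, (1 - p) / 2, 0)),
    pi1 = ifelse(c == 0, p,     ifelse(c == 1, 1 / 2, 1 - p)),
    pi2 = ifelse(c == 0, 0,     ifelse(c == 1, p / 2, p)))
}

#' Maternal posterior from a probabilistic infant genotype
#'
#' When the infant genotype is itself uncertain (e.g. imputed), the maternal
#' posterior is the convolution of the two uncertainty sources: the mixture
#' `sum_c child_pi_c * maternal_posterior(c, p)`.
#'
#' @param child A numeric vector `(pi0, pi1, pi2)` or a 3-column matrix of
#'   infant genotype triples (reference-allele count order).
#' @inheritParams maternal_posterior
#' @return A tibble with columns `pi0`, `pi1`, `pi2`.
#' @export
maternal_posterior_soft <- function(child, p) {
  check_raf(p)
  child <- if (is.null(dim(child))) matrix(child, nrow = 1) else as.matrix(child)
  if (ncol(child) != 3) abort("`child` must have 3 columns (pi0, pi1, pi2).")
  s <- rowSums(child)
  ok <- s > 0
  if (any(abs(s[ok] - 1) > 1e-6)) {
    abort("Infant triples must sum to 1 (or 0 for missing).")
  }
  p <- rep_len(p, nrow(child))
  post0 <- maternal_posterior(0, p)
  post1 <- maternal_posterior(1, p)
  post2 <- maternal_posterior(2, p)
  tibble(
    pi0 = child[, 1] * post0$pi0 + child[, 2] * post1$pi0 + child[, 3] * post2$pi0,
    pi1 = child[, 1] * post0$pi1 + child[, 2] * post1$pi1 + child[, 3] * post2$pi1,
    pi2 = child[, 1] * post0$pi2 + child[, 2] * post1$pi2 + child[, 3] * post2$pi2)
}

#' Impute maternal genotype posteriors for a whole infant cohort
#'
#' Applies the Mendelian/HWE posterior to every sample x variant cell of an
#' infant genotype container.  Missing infant entries receive the maternal HWE
#' prior `((1-p)^2, 2p(1-p), p^2)` — with no data the posterior is the prior.
#' Monomorphic variants (estimated or supplied `p` of 0 or 1) are dropped
#' with a warning: the maternal posterior is degenerate there and the
#' association scan analyses only polymorphic sites.
#'
#' @param infant A `geno_triples` object of infant genotypes (hard or soft).
#' @param raf Optional numeric vector of known reference-allele frequencies
#'   (one per variant); estimated from the infant cohort by default, as
#'   published cohort allele frequencies are.
#' @return A `geno_triples` object of maternal posteriors, with `raf` and
#'   `info` columns filled in the variant table and a `typed` flag set to
#'   `FALSE` where any infant triple was soft (convolved uncertainty).
#' @export
impute_mothers <- function(infant, raf = NULL) {
  stopifnot(inherits(infant, "geno_triples"))
  if (is.null(raf)) raf <- estimate_raf(infant)
  if (length(raf) != n_variants(infant)) {
    abort("`raf` must supply one frequency per variant.")
  }
  mono <- raf <= 0 | raf >= 1
  if (any(mono)) {
    warn(sprintf("Dropping %d monomorphic variant(s): %s", sum(mono),
                 paste(head(infant$variants$snpid[mono], 5), collapse = ", ")))
    infant <- subset_variants(infant, !mono)
    raf <- raf[!mono]
  }
  n <- n_samples(infant); m <- n_variants(infant)
  P <- matrix(raf, nrow = n, ncol = m, byrow = TRUE)
  miss <- is_missing_triple(infant)
  c0 <- infant$p0; c1 <- infant$p1; c2 <- infant$p2
  # mixture over infant triple of the three closed-form posteriors
  q0 <- c0 * (1 - P) + c1 * (1 - P) / 2
  q1 <- c0 * P + c1 / 2 + c2 * (1 - P)
  q2 <- c1 * P / 2 + c2 * P
  # no infant data -> maternal HWE prior
  q0[miss] <- (1 - P[miss])^2
  q1[miss] <- 2 * P[miss] * (1 - P[miss])
  q2[miss] <- P[miss]^2
  soft <- apply(pmax(c0, c1, c2) < 1 - 1e-9 & !miss, 2, any)
  variants <- infant$variants
  variants$raf <- raf
  out <- geno_triples(q0, q1, q2, variants, infant$samples, normalise = FALSE)
  out$variants$info <- info_score(out, raf = raf)
  out$variants$typed <- !soft
  out
}

check_raf <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    abort("monomorphic variant: reference-allele frequency must lie strictly in (0, 1).")
  }
  invisible(p)
}

#' Hardy-Weinberg prior triples
#'
#' @param p Reference-allele frequency (vector allowed).
#' @return A tibble with columns `pi0`, `pi1`, `pi2`.
#' @export
hwe_prior <- function(p) {
  tibble(pi0 = (1 - p)^2, pi1 = 2 * p * (1 - p), pi2 = p^2)
}
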