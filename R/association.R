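#' Fit the covariate-only null model for a score test
#'
#' Ordinary least squares of the transformed phenotype on an intercept plus
#' covariates.  Rows with a missing response or covariate are dropped (their
#' index is kept so genotype columns can be aligned).  The residual variance
#' uses the maximum-likelihood divisor `n`, the score-test convention.
#'
#' @param data Tibble holding the response and covariate columns.
#' @param response Name of the (already transformed) phenotype column.
#' @param covariates Character vector of covariate column names (possibly
#'   empty for an intercept-only null).
#' @return A `null_fit` object: QR factorisation of the design, residuals,
#'   `sigma2`, leverages, and the logical row-keep index.
#' @export
fit_null_model <- function(data, response, covariates = character()) {
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  y <- data[[response]]
  X <- matrix(1, nrow(data), 1)
  if (length(covariates)) {
    X <- cbind(X, as.matrix(as.data.frame(lapply(data[covariates],
                                                 as.numeric))))
  }
  colnames(X) <- c("(Intercept)", covariates)
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y); k <- ncol(X)
  if (n <= k) abort("Need more observations than design columns.")
  qrX <- qr(X)
  if (qrX$rank < k) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(drop_cols, collapse = ", ")))
  }
  coef <- qr.coef(qrX, y)
  r <- as.vector(qr.resid(qrX, y))
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  sigma2 <- sum(r^2) / n
  structure(list(
    coefficients = coef, residuals = r, sigma2 = sigma2, leverage = h,
    Q = Q, qr = qrX, X = X, y = y, n = n, k = k, keep = keep,
    response = response, covariates = covariates,
    degenerate = sigma2 < 1e-12),
    class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("<null_fit> %s ~ %s; n = %d, sigma2(ML) = %.4g%s\n",
              x$response,
              if (length(x$covariates)) paste(x$covariates, collapse = " + ")
              else "1",
              x$n, x$sigma2, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
#' @method tidy null_fit
tidy.null_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
#' @method glance null_fit
glance.null_fit <- function(x, ...) {
  tibble(n = x$n, sigma2 = x$sigma2, df = x$n - x$k,
         degenerate = x$degenerate)
}

#' Missing-data score test of genotype probability triples
#'
#' Tests each variant's additive effect on the null-model phenotype without
#' reducing genotypes to a point dosage.  With per-sample posterior mean
#' `mu_i = pi1 + 2 pi2` and variance `v_i = (pi1 + 4 pi2) - mu_i^2`,
#' residuals `r_i`, ML residual variance `sigma2` and leverages `h_ii` of the
#' null design:
#' \deqn{U = \sum_i \mu_i r_i / \hat\sigma^2}
#' \deqn{I_{complete} = (\mu' M \mu + \sum_i v_i (1 - h_{ii})) / \hat\sigma^2}
#' \deqn{I_{missing} = \sum_i v_i r_i^2 / \hat\sigma^4}
#' \deqn{V = I_{complete} - I_{missing}}
#' with `M` the residual projector of the design (applied through the QR
#' factors, never materialised).  The statistic `S = U^2 / V` is chi-square
#' on 1 df; the one-step effect is `beta = U / V` with `SE = V^{-1/2}` (equal
#' to the OLS slope when all triples are hard).  Variants with `V <= 0`
#' (extreme genotype uncertainty) are flagged untestable with `NA` p.
#'
#' @param null A [fit_null_model()] object (not degenerate).
#' @param geno A `geno_triples` aligned with the rows of the data the null
#'   was fitted to (the fit's row filter is applied internally).  Cells
#'   missing in `geno` drop that sample for that variant only.
#' @return A tibble, one row per variant: variant metadata plus `n`, `U`,
#'   `V`, `beta`, `se`, `stat`, `p`, `direction`, `testable`.
#' @export
score_test <- function(null, geno) {
  stopifnot(inherits(null, "null_fit"), inherits(geno, "geno_triples"))
  if (null$degenerate) {
    abort("Null fit is degenerate (zero residual variance); nothing to test.")
  }
  if (n_samples(geno) != length(null$keep)) {
    abort("Genotype rows do not align with the null model's input rows.")
  }
  mu <- triple_mean(geno)[null$keep, , drop = FALSE]
  v <- triple_var(geno)[null$keep, , drop = FALSE]
  r <- null$residuals; s2 <- null$sigma2; h <- null$leverage; Q <- null$Q
  m <- ncol(mu)
  if (anyNA(mu)) {
    res <- purrr::map(seq_len(m), function(j) {
      obs <- !is.na(mu[, j])
      score_one(mu[obs, j], v[obs, j], r[obs], s2, h[obs], Q[obs, , drop = FALSE],
                exact_proj = FALSE)
    })
    out <- bind_rows(res)
  } else {
    Mmu <- mu - Q %*% crossprod(Q, mu)
    U <- as.vector(crossprod(mu, r)) / s2
    Ic <- (colSums(Mmu^2) + colSums(v * (1 - h))) / s2
    Im <- as.vector(crossprod(v, r^2)) / s2^2
    V <- Ic - Im
    out <- tibble(n = nrow(mu), U = U, V = V)
  }
  eps <- 1e-10
  out$testable <- out$V > eps
  out$beta <- ifelse(out$testable, out$U / out$V, NA_real_)
  out$se <- ifelse(out$testable, 1 / sqrt(out$V), NA_real_)
  out$stat <- ifelse(out$testable, out$U^2 / out$V, NA_real_)
  out$p <- ifelse(out$testable,
                  pchisq(ifelse(out$testable, out$stat, 0), df = 1,
                         lower.tail = FALSE),
                  NA_real_)
  out$direction <- ifelse(is.na(out$beta), "?",
                          ifelse(out$beta >= 0, "+", "-"))
  bind_cols(geno$variants, out)
}

# single-variant score test on a row subset (missing-genotype path);
# the projector is recomputed on the subset via least squares on Q's span.
score_one <- function(mu, v, r, s2, h, Q, exact_proj = FALSE) {
  n <- length(mu)
  fit <- stats::lm.fit(Q, mu)
  Mmu <- fit$residuals
  U <- sum(mu * r) / s2
  Ic <- (sum(Mmu^2) + sum(v * (1 - h))) / s2
  Im <- sum(v * r^2) / s2^2
  tibble(n = n, U = U, V = Ic - Im)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele counts:
#' the p-value is the total probability of all heterozygote configurations no
#' more probable than the observed one.
#'
#' @param n0,n1,n2 Genotype counts (carriers of 0, 1, 2 reference alleles);
#'   vectors are accepted and recycled to equal length.
#' @return P-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n0, n1, n2) {
  k <- max(length(n0), length(n1), length(n2))
  n0 <- rep_len(n0, k); n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  vapply(seq_len(k), function(i) hwe_exact_one(n0[i], n1[i], n2[i]), numeric(1))
}

hwe_exact_one <- function(n0, n1, n2) {
  stopifnot(n0 >= 0, n1 >= 0, n2 >= 0)
  n <- n0 + n1 + n2
  if (n == 0) abort("HWE test needs at least one genotype.")
  nA <- 2 * n2 + n1                     # reference-allele count
  nB <- 2 * n0 + n1
  rare <- min(nA, nB)
  hs <- seq(rare %% 2, rare, by = 2)    # feasible heterozygote counts
  logp <- lgamma(n + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((nB - hs) / 2 + 1) + hs * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[match(n1, hs)] * (1 + 1e-12)]))
}

#' Apply the per-variant QC filters of the genome scan
#'
#' Strict (screening) mode keeps a variant when: MAF > 0.05 if the variant is
#' present in both studies, or MAF > 0.1 if present in only one; info = 1 in
#' every study where present; and infant HWE exact p > `hwe_min` (1e-5).
#' Regional (permissive) mode relaxes to info > 0.9 in both studies and
#' MAF > 0.05.
#'
#' @param stats Long tibble with columns `snpid`, `study`, `present`
#'   (logical), `maf`, `info`, `hwe_p`.
#' @param mode `"strict"` or `"regional"`.
#' @param hwe_min Infant HWE exact-test p-value floor.
#' @return Tibble `snpid`, `keep`, `reason` (`""` when kept).
#' @export
variant_filters <- function(stats, mode = c("strict", "regional"),
                            hwe_min = 1e-5) {
  mode <- match.arg(mode)
  stopifnot(all(c("snpid", "study", "present", "maf", "info", "hwe_p")
                %in% names(stats)))
  stats %>%
    group_by(.data$snpid) %>%
    summarise(
      n_present = sum(.data$present),
      min_maf = suppressWarnings(min(.data$maf[.data$present])),
      min_info = suppressWarnings(min(.data$info[.data$present])),
      min_hwe = suppressWarnings(min(.data$hwe_p[.data$present])),
      .groups = "drop") %>%
    mutate(
      reason = dplyr::case_when(
        .data$n_present == 0 ~ "absent from all studies",
        mode == "strict" & .data$n_present >= 2 & .data$min_maf <= 0.05 ~
          "MAF <= 0.05 (present in both studies)",
        mode == "strict" & .data$n_present == 1 & .data$min_maf <= 0.1 ~
          "MAF <= 0.1 (present in one study)",
        mode == "strict" & .data$min_info < 1 - 1e-9 ~ "info < 1",
        mode == "regional" & .data$min_maf <= 0.05 ~ "MAF <= 0.05",
        mode == "regional" & .data$min_info <= 0.9 ~ "info <= 0.9",
        .data$min_hwe <= hwe_min ~ sprintf("infant HWE p <= %g", hwe_min),
        TRUE ~ ""),
      keep = .data$reason == "") %>%
    select("snpid", "keep", "reason")
}

#' Convert a transformed-scale effect to its reported form
#'
#' Log-scale phenotypes report the exponentiated effect — the multiplicative
#' change in the fraction per reference allele — and exponentiated SE.
#' The square-root ratio phenotype reports `2 * sqrt(s0) * beta`, the change
#' in the ratio per allele at a standardisation point `s0` (default 12).
#' When the multiplicative effect is below 1 the equivalent
#' per-*major*-allele percent increase `(1/exp(beta) - 1) * 100` is also
#' given.
#'
#' @param beta,se Effect and SE on the transformed scale (vectors fine).
#' @param transform `"log"` or `"sqrt"` per phenotype (recycled).
#' @param s0 Ratio standardisation point.
#' @return Tibble: `beta_reported`, `se_reported`, `pct_per_ref_allele`,
#'   `pct_per_major_allele`.
#' @export
report_effect <- function(beta, se, transform = "log", s0 = 12) {
  k <- max(length(beta), length(se), length(transform))
  beta <- rep_len(beta, k); se <- rep_len(se, k)
  transform <- rep_len(transform, k)
  is_log <- transform == "log"
  br <- ifelse(is_log, exp(beta), 2 * sqrt(s0) * beta)
  sr <- ifelse(is_log, exp(se), 2 * sqrt(s0) * se)
  tibble(
    beta_reported = br, se_reported = sr,
    pct_per_ref_allele = ifelse(is_log, (exp(beta) - 1) * 100, NA_real_),
    pct_per_major_allele = ifelse(is_log & exp(beta) < 1,
                                  (1 / exp(beta) - 1) * 100, NA_real_))
}

#' Maximum-likelihood effect estimate under genotype uncertainty
#'
#' Fits the normal regression with a latent three-class genotype by EM,
#' treating each sample's probability triple as its genotype prior:
#' `y_i = x_i'alpha + beta g_i + e`, `g_i ~ (pi0, pi1, pi2)`.  The standard
#' error comes from the numerically differentiated observed-data
#' log-likelihood (observed information).  With hard (degenerate) triples
#' the estimate reduces exactly to the OLS slope.  Recommended for reporting
#' effect sizes of selected variants: away from the null the one-step score
#' estimate `U/V` acquires a small away-from-zero bias and understates its
#' variance, while the score statistic and p-value are unaffected.
#'
#' @inheritParams score_test
#' @param max_iter,tol EM iteration cap and parameter-change tolerance.
#' @return A tibble, one row per variant: `beta_ml`, `se_ml`, `converged`.
#' @export
ml_effect <- function(null, geno, max_iter = 200, tol = 1e-9) {
  stopifnot(inherits(null, "null_fit"), inherits(geno, "geno_triples"))
  if (n_samples(geno) != length(null$keep)) {
    abort("Genotype rows do not align with the null model's input rows.")
  }
  X <- null$X; y <- null$y
  P <- list(geno$p0[null$keep, , drop = FALSE],
            geno$p1[null$keep, , drop = FALSE],
            geno$p2[null$keep, , drop = FALSE])
  start <- score_test(null, geno)
  out <- purrr::map(seq_len(n_variants(geno)), function(j) {
    p3 <- cbind(P[[1]][, j], P[[2]][, j], P[[3]][, j])
    obs <- rowSums(p3) > 0
    fit <- em_one(y[obs], X[obs, , drop = FALSE], p3[obs, , drop = FALSE],
                  b0 = if (is.na(start$beta[j])) 0 else start$beta[j],
                  a0 = null$coefficients, s20 = null$sigma2,
                  max_iter = max_iter, tol = tol)
    tibble(beta_ml = fit$beta, se_ml = fit$se, converged = fit$converged)
  })
  bind_cols(geno$variants, bind_rows(out))
}

# EM + numeric observed-information SE for one variant.
em_one <- function(y, X, P, b0, a0, s20, max_iter = 200, tol = 1e-9) {
  n <- length(y); k <- ncol(X)
  a <- a0; b <- b0; s2 <- s20
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  lp <- log(pmax(P, 1e-300))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e0 <- as.vector(y - X %*% a)
    lw <- vapply(0:2, function(cc) {
      lp[, cc + 1] + stats::dnorm(e0 - b * cc, 0, sqrt(s2), log = TRUE)
    }, numeric(n))
    mx <- apply(lw, 1, max)
    w <- exp(lw - mx); w <- w / rowSums(w)
    m1 <- w[, 2] + 2 * w[, 3]; m2 <- w[, 2] + 4 * w[, 3]
    A <- rbind(cbind(XtX, crossprod(X, m1)),
               c(crossprod(m1, X), sum(m2)))
    th <- unname(solve(A, c(Xty, sum(m1 * y))))
    a_new <- th[seq_len(k)]; b_new <- th[k + 1]
    res <- as.vector(y - X %*% a_new - b_new * m1)
    s2_new <- (sum(res^2) + b_new^2 * sum(m2 - m1^2)) / n
    done <- max(abs(c(a_new - a, b_new - b, s2_new - s2))) < tol
    a <- a_new; b <- b_new; s2 <- s2_new
    if (done) { converged <- TRUE; break }
  }
  loglik <- function(th) {
    bb <- th[1]; aa <- th[2:(k + 1)]; ss <- exp(th[k + 2])
    e <- as.vector(y - X %*% aa)
    m <- vapply(0:2, function(cc) {
      lp[, cc + 1] + stats::dnorm(e - bb * cc, 0, sqrt(ss), log = TRUE)
    }, numeric(n))
    mx <- apply(m, 1, max)
    sum(mx + log(rowSums(exp(m - mx))))
  }
  se <- tryCatch({
    H <- stats::optimHess(c(b, a, log(s2)), loglik)
    sqrt(solve(-H)[1, 1])
  }, error = function(e) NA_real_)
  list(beta = b, se = se, converged = converged)
}
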