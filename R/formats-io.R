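#' Read genotype probability data from Oxford GEN (+ SAMPLE) or VCF
#'
#' The GEN dialect has five leading columns — `chrom snpid pos refA altA` —
#' followed by three probabilities per sample ordered hom-ref, het, hom-alt
#' (the Oxford "AA AB BB" order with allele A the reference allele, i.e.
#' `P(2 ref copies) P(1) P(0)`).  In memory triples are always stored as
#' `(pi0, pi1, pi2)` indexed by reference-allele count.  Coordinates are
#' 1-based (hg19 convention).  A missing genotype is `0 0 0`.
#'
#' Triples are renormalised to sum 1; a non-missing triple whose raw sum
#' falls outside `[0.98, 1.02]` raises a validation error.
#'
#' @param path Path to a `.gen` or `.vcf` file.
#' @param format `"gen"` or `"vcf"`; guessed from the file extension by
#'   default.
#' @param sample_path Companion SAMPLE file (GEN only); defaults to `path`
#'   with extension `.sample` when that file exists.
#' @return A `geno_triples` object.
#' @export
read_genotype_file <- function(path, format = c("auto", "gen", "vcf"),
                               sample_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "gen"
  }
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  switch(format, gen = read_gen(path, sample_path), vcf = read_vcf_geno(path))
}

read_gen <- function(path, sample_path = NULL) {
  if (is.null(sample_path)) {
    cand <- sub("\\.gen$", ".sample", path)
    if (cand != path && file.exists(cand)) sample_path <- cand
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  samples <- if (!is.null(sample_path)) read_sample_file(sample_path)$sample
  if (length(lines) == 0) {
    return(geno_triples(
      matrix(0, length(samples %||% character()), 0),
      matrix(0, length(samples %||% character()), 0),
      matrix(0, length(samples %||% character()), 0),
      tibble(snpid = character(), chrom = character(), pos = integer(),
             refA = character(), altA = character()),
      samples))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != nf[1] | nf < 8 | (nf - 5) %% 3 != 0)) {
    bad <- which(nf != nf[1] | nf < 8 | (nf - 5) %% 3 != 0)[1]
    abort(sprintf("Malformed GEN row at line %d: %d fields (expected 5 + 3 per sample).",
                  bad, nf[bad]))
  }
  m <- length(fields); ns <- (nf[1] - 5) / 3
  meta <- t(vapply(fields, function(f) f[1:5], character(5)))
  probs <- suppressWarnings(
    matrix(as.numeric(t(vapply(fields, function(f) f[-(1:5)],
                               character(nf[1] - 5)))),
           nrow = m, byrow = FALSE))
  if (anyNA(probs)) {
    bad <- which(apply(is.na(probs), 1, any))[1]
    abort(sprintf("Malformed GEN row at line %d: non-numeric probability.", bad))
  }
  idx <- function(k) seq(k, by = 3, length.out = ns)   # within-row offsets
  # disk order hom-ref, het, hom-alt -> (pi2, pi1, pi0)
  p2 <- t(probs[, idx(1), drop = FALSE])
  p1 <- t(probs[, idx(2), drop = FALSE])
  p0 <- t(probs[, idx(3), drop = FALSE])
  variants <- tibble(
    chrom = meta[, 1], snpid = meta[, 2], pos = as.integer(meta[, 3]),
    refA = meta[, 4], altA = meta[, 5])
  if (!is.null(samples) && length(samples) != ns) {
    abort(sprintf("SAMPLE file lists %d samples but GEN rows carry %d.",
                  length(samples), ns))
  }
  geno_triples(p0, p1, p2, variants, samples)
}

#' Write genotype probabilities as Oxford GEN + SAMPLE
#'
#' Serialises with 6 significant digits (round-trips triples to well below
#' 1e-6).  Covariate columns, when supplied, are appended to the SAMPLE file
#' with the Oxford continuous/discrete type header.
#'
#' @param x A `geno_triples` object.
#' @param path Output `.gen` path.
#' @param sample_path Output SAMPLE path; default swaps the extension.
#' @param covariates Optional tibble of per-sample covariates (row order must
#'   match `x$samples`).
#' @return `path`, invisibly.
#' @export
write_genotype_file <- function(x, path, sample_path = NULL,
                                covariates = NULL) {
  stopifnot(inherits(x, "geno_triples"))
  if (is.null(sample_path)) sample_path <- sub("\\.gen$", ".sample", path)
  if (sample_path == path) sample_path <- paste0(path, ".sample")
  m <- n_variants(x); ns <- n_samples(x)
  lines <- character(m)
  if (m > 0) {
    probs <- matrix(NA_real_, nrow = m, ncol = 3 * ns)
    probs[, seq(1, by = 3, length.out = ns)] <- t(x$p2)  # hom-ref first
    probs[, seq(2, by = 3, length.out = ns)] <- t(x$p1)
    probs[, seq(3, by = 3, length.out = ns)] <- t(x$p0)
    ptxt <- matrix(sprintf("%.6g", probs), nrow = m)
    v <- x$variants
    lines <- paste(v$chrom, v$snpid, v$pos, v$refA, v$altA,
                   apply(ptxt, 1, paste, collapse = " "))
  }
  writeLines(lines, path)
  write_sample_file(x$samples, sample_path, covariates)
  invisible(path)
}

read_sample_file <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(tab) < 1) abort("SAMPLE file has no type row.")
  tab <- tab[-1, , drop = FALSE]            # drop the 0/C/D type row
  out <- tibble(sample = as.character(tab$ID_1))
  extra <- setdiff(names(tab), c("ID_1", "ID_2", "missing"))
  for (cn in extra) out[[cn]] <- utils::type.convert(tab[[cn]], as.is = TRUE)
  out
}

write_sample_file <- function(samples, path, covariates = NULL) {
  hdr <- c("ID_1", "ID_2", "missing")
  types <- c("0", "0", "0")
  body <- data.frame(ID_1 = samples, ID_2 = samples,
                     missing = rep(0, length(samples)))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(samples)) {
      abort("Covariate rows must match the number of samples.")
    }
    for (cn in names(covariates)) {
      hdr <- c(hdr, cn)
      types <- c(types, if (is.numeric(covariates[[cn]])) "C" else "D")
      body[[cn]] <- covariates[[cn]]
    }
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(hdr, collapse = " "), con)
  writeLines(paste(types, collapse = " "), con)
  utils::write.table(body, con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

# Minimal VCF support: GT or GP FORMAT fields only, via vcfR.
read_vcf_geno <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- if (is.null(dim(fix))) matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix))) else fix
  variants <- tibble(
    chrom = fix[, "CHROM"],
    snpid = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                   paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    pos = as.integer(fix[, "POS"]),
    refA = fix[, "REF"], altA = fix[, "ALT"])
  has_gp <- any(grepl("(^|:)GP(:|$)", vcf@gt[, "FORMAT"]))
  samples <- colnames(vcf@gt)[-1]
  ns <- length(samples); m <- nrow(variants)
  if (has_gp) {
    gp <- vcfR::extract.gt(vcf, element = "GP")
    parts <- array(NA_real_, dim = c(m, ns, 3))
    spl <- strsplit(as.vector(gp), ",")
    ok <- lengths(spl) == 3
    vals <- matrix(NA_real_, nrow = m * ns, ncol = 3)
    vals[ok, ] <- matrix(as.numeric(unlist(spl[ok])), ncol = 3, byrow = TRUE)
    # VCF GP order P(0/0),P(0/1),P(1/1) = ref-count 2,1,0
    p2 <- matrix(vals[, 1], m, ns); p1 <- matrix(vals[, 2], m, ns)
    p0 <- matrix(vals[, 3], m, ns)
    p0[is.na(p0)] <- 0; p1[is.na(p1)] <- 0; p2[is.na(p2)] <- 0
    geno_triples(t(p0), t(p1), t(p2), variants, samples)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alt_count <- matrix(NA_integer_, m, ns)
    clean <- gsub("\\|", "/", as.vector(gt))
    alt_count[] <- ifelse(clean %in% c("0/0"), 0L,
                   ifelse(clean %in% c("0/1", "1/0"), 1L,
                   ifelse(clean %in% c("1/1"), 2L, NA_integer_)))
    ref_count <- 2L - alt_count
    hard_calls(t(ref_count), variants, samples)
  }
}

#' Read / write the breast-milk fatty-acid phenotype table
#'
#' A tab-delimited table with a `sample` id column, the 26 assayed fraction
#' columns named by their standard abbreviations (`CAP`, `LAU`, ..., `LLA`),
#' and any covariate columns (e.g. `mat_age`, `inf_age_days`, `inf_sex`,
#' `site`).  Fractions are %wt/wt; negative values are rejected, `NA` is
#' allowed and flagged downstream.
#'
#' @param path File path.
#' @return A tibble (`read_phenotype_table`); `path` invisibly
#'   (`write_phenotype_table`).
#' @export
read_phenotype_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expected <- fa_panel_data()$abbrev
  missing <- setdiff(expected, names(tbl))
  if (length(missing)) {
    abort(paste0("Phenotype table lacks expected fatty-acid column(s): ",
                 paste(missing, collapse = ", "),
                 ". Expected the 26 abbreviations: ",
                 paste(expected, collapse = ", "), "."))
  }
  if (!"sample" %in% names(tbl)) {
    abort("Phenotype table needs a `sample` id column.")
  }
  fr <- as.matrix(tbl[, expected])
  if (!is.numeric(fr)) abort("Fatty-acid fractions must be numeric.")
  if (any(fr < 0, na.rm = TRUE)) {
    abort("Negative fatty-acid fraction found; fractions are %wt/wt in [0, 100].")
  }
  tbl$sample <- as.character(tbl$sample)
  tbl
}

#' @rdname read_phenotype_table
#' @param tbl A phenotype tibble as produced by [simulate_fa_profiles()].
#' @export
write_phenotype_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
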