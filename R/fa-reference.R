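#' Breast-milk fatty-acid panel and cohort reference profiles
#'
#' The analysis panel comprises 26 assayed fatty-acid fractions (%wt/wt of
#' total identified fatty acids, summing to 100 per mother) in five classes —
#' saturated (SFA), cis-monounsaturated (MUFA), cis-polyunsaturated omega-6
#' (PUFA6) and omega-3 (PUFA3), and trans (TFA) — plus seven derived summary
#' phenotypes (class sums, total PUFA and the PUFA6/PUFA3 ratio), 33
#' phenotypes in all.
#'
#' `fa_reference()` returns the published per-fraction mean and SD for each of
#' the four Bangladeshi mother-infant cohort columns (PROVIDE study: MalChip
#' n=616 and GWAS n=532 subsets; CRYPTO study: Mirpur n=402 and Mirzapur
#' n=208).  These are the default targets of the synthetic cohort generator.
#' `fa_published_totals()` returns the independently printed class totals for
#' the same cohorts, used to cross-check compositional bookkeeping.
#'
#' @param cohort One of `"provide_gwas"` (default), `"provide_malchip"`,
#'   `"crypto_mirpur"`, `"crypto_mirzapur"`, or `"all"` for a long table.
#'
#' @return A tibble with columns `abbrev`, `name`, `formula`, `class`, and
#'   (`mean`, `sd`) for the chosen cohort, or (`cohort`, `mean`, `sd`) when
#'   `cohort = "all"`.
#' @export
fa_reference <- function(cohort = c("provide_gwas", "provide_malchip",
                                    "crypto_mirpur", "crypto_mirzapur",
                                    "all")) {
  cohort <- match.arg(cohort)
  wide <- fa_panel_data()
  if (cohort == "all") {
    return(tidyr::pivot_longer(
      wide, cols = -c("abbrev", "name", "formula", "class"),
      names_to = c("cohort", ".value"), names_pattern = "(.*)_(mean|sd)$"))
  }
  dplyr::select(wide, "abbrev", "name", "formula", "class",
                mean = all_of(paste0(cohort, "_mean")),
                sd = all_of(paste0(cohort, "_sd")))
}

# 26 assayed fractions; means/SDs as published per cohort column.
fa_panel_data <- function() {
  tibble::tribble(
    ~abbrev, ~name, ~formula, ~class,
    ~provide_malchip_mean, ~provide_malchip_sd,
    ~provide_gwas_mean, ~provide_gwas_sd,
    ~crypto_mirpur_mean, ~crypto_mirpur_sd,
    ~crypto_mirzapur_mean, ~crypto_mirzapur_sd,
    "CAP",  "Capric",                "C10:0",    "SFA",  1.17, 0.52, 1.15, 0.52, 0.78, 0.44, 0.62, 0.40,
    "LAU",  "Lauric",                "C12:0",    "SFA",  8.20, 3.01, 8.18, 2.99, 5.85, 2.32, 5.10, 2.41,
    "MYR",  "Myristic",              "C14:0",    "SFA",  8.04, 3.06, 8.01, 3.04, 6.40, 2.62, 6.55, 2.81,
    "PAL",  "Palmitic",              "C16:0",    "SFA", 26.67, 3.71, 26.64, 3.76, 26.60, 3.63, 26.79, 3.23,
    "STE",  "Stearic",               "C18:0",    "SFA",  3.93, 0.82, 3.89, 0.77, 4.67, 0.96, 4.26, 0.78,
    "ARA",  "Arachidic",             "C20:0",    "SFA",  0.14, 0.03, 0.14, 0.03, 0.15, 0.04, 0.14, 0.03,
    "BEH",  "Behenic",               "C22:0",    "SFA",  0.07, 0.02, 0.07, 0.02, 0.07, 0.02, 0.06, 0.02,
    "LIG",  "Lignoceric",            "C24:0",    "SFA",  0.08, 0.03, 0.08, 0.03, 0.08, 0.03, 0.10, 0.05,
    "PLE",  "Palmitoleic",           "C16:1n7",  "MUFA", 2.94, 1.09, 2.96, 1.10, 2.67, 0.91, 3.76, 1.14,
    "OLE",  "Oleic",                 "C18:1n9",  "MUFA", 33.18, 4.59, 33.24, 4.67, 33.09, 4.53, 33.03, 4.37,
    "EIC",  "Eicosenoic",            "C20:1n9",  "MUFA", 0.41, 0.16, 0.41, 0.16, 0.50, 0.20, 0.82, 0.47,
    "NER",  "Nervonic",              "C24:1n9",  "MUFA", 0.15, 0.11, 0.15, 0.11, 0.19, 0.14, 0.48, 0.36,
    "LA",   "Linoleic",              "C18:2n6",  "PUFA6", 11.21, 5.03, 11.29, 5.09, 14.36, 5.15, 13.05, 4.08,
    "GLA",  "gamma-Linolenic",       "C18:3n6",  "PUFA6", 0.16, 0.11, 0.16, 0.11, 0.21, 0.12, 0.17, 0.10,
    "EDA",  "Eicosadienoic",         "C20:2n6",  "PUFA6", 0.41, 0.17, 0.41, 0.18, 0.54, 0.20, 0.66, 0.20,
    "DGLA", "Dihomo-gamma-linolenic","C20:3n6",  "PUFA6", 0.55, 0.17, 0.55, 0.17, 0.64, 0.20, 0.73, 0.22,
    "AA",   "Arachidonic",           "C20:4n6",  "PUFA6", 0.53, 0.15, 0.53, 0.15, 0.65, 0.14, 0.81, 0.17,
    "DTA",  "Docosatetraenoic",      "C22:4n6",  "PUFA6", 0.18, 0.10, 0.18, 0.10, 0.21, 0.10, 0.34, 0.18,
    "DPA6", "Docosapentaenoic-n6",   "C22:5n6",  "PUFA6", 0.12, 0.05, 0.12, 0.05, 0.13, 0.05, 0.20, 0.08,
    "ALA",  "alpha-Linolenic",       "C18:3n3",  "PUFA3", 0.53, 0.40, 0.54, 0.40, 0.78, 0.53, 0.82, 0.37,
    "EPA",  "Eicosapentaenoic",      "C20:5n3",  "PUFA3", 0.06, 0.07, 0.06, 0.07, 0.05, 0.04, 0.05, 0.02,
    "DPA",  "Docosapentaenoic-n3",   "C22:5n3",  "PUFA3", 0.14, 0.08, 0.14, 0.08, 0.15, 0.07, 0.22, 0.09,
    "DHA",  "Docosahexaenoic",       "C22:6n3",  "PUFA3", 0.39, 0.14, 0.39, 0.14, 0.40, 0.14, 0.55, 0.14,
    "PLA",  "Palmitelaidic",         "C16:1n7t", "TFA",  0.06, 0.03, 0.06, 0.03, 0.07, 0.03, 0.08, 0.03,
    "ELA",  "Elaidic",               "C18:1t",   "TFA",  0.36, 0.25, 0.35, 0.24, 0.41, 0.25, 0.32, 0.19,
    "LLA",  "Linoelaidic",           "C18:2n6t", "TFA",  0.32, 0.16, 0.32, 0.16, 0.33, 0.17, 0.27, 0.14)
}

#' @rdname fa_reference
#' @export
fa_published_totals <- function(cohort = c("provide_gwas", "provide_malchip",
                                           "crypto_mirpur", "crypto_mirzapur")) {
  cohort <- match.arg(cohort)
  tot <- tibble::tribble(
    ~phenotype,
    ~provide_malchip_mean, ~provide_malchip_sd,
    ~provide_gwas_mean, ~provide_gwas_sd,
    ~crypto_mirpur_mean, ~crypto_mirpur_sd,
    ~crypto_mirzapur_mean, ~crypto_mirzapur_sd,
    "SFA",         48.29, 6.63, 48.16, 6.51, 44.61, 5.95, 43.62, 5.89,
    "MUFA",        36.69, 5.00, 36.76, 5.06, 36.45, 4.94, 38.10, 5.03,
    "PUFA6",       13.17, 5.30, 13.24, 5.36, 16.75, 5.45, 15.96, 4.29,
    "PUFA3",        1.12, 0.50,  1.12, 0.50,  1.39, 0.59,  1.65, 0.45,
    "PUFA",        14.29, 5.69, 14.36, 5.75, 18.14, 5.92, 17.61, 4.59,
    "TFA",          0.74, 0.34,  0.73, 0.32,  0.81, 0.32,  0.67, 0.26,
    "PUFA6_PUFA3", 12.40, 3.25, 12.48, 3.28, 12.84, 3.14,  9.98, 2.15)
  dplyr::select(tot, "phenotype",
                mean = all_of(paste0(cohort, "_mean")),
                sd = all_of(paste0(cohort, "_sd")))
}

#' Phenotype specifications for the 33 analysis phenotypes
#'
#' The 26 assayed fractions and six derived class sums are log-transformed to
#' stabilise variance; the PUFA6/PUFA3 ratio is square-root transformed.  The
#' ratio's effect sizes are reported at a standardisation point `s0` (change
#' in the ratio per allele at PUFA6/PUFA3 = `s0`), default 12.
#'
#' @param s0 Standardisation point for the ratio phenotype.
#' @return A tibble with columns `phenotype`, `class`, `transform`, `s0`.
#' @export
phenotype_specs <- function(s0 = 12) {
  panel <- fa_panel_data()
  assayed <- tibble(phenotype = panel$abbrev, class = panel$class,
                    transform = "log", s0 = NA_real_)
  derived <- tibble(
    phenotype = c("SFA", "MUFA", "PUFA6", "PUFA3", "PUFA", "TFA",
                  "PUFA6_PUFA3"),
    class = "derived",
    transform = c(rep("log", 6), "sqrt"),
    s0 = c(rep(NA_real_, 6), s0))
  bind_rows(assayed, derived)
}

fa_class_members <- function(class) {
  panel <- fa_panel_data()
  panel$abbrev[panel$class == class]
}
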