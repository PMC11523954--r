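#' Per-SNP effect from a signed coefficient and a minor-allele frequency
#'
#' Under Hardy-Weinberg equilibrium a SNP with minor-allele frequency p
#' contributes `c * 2p(1-p) + 2c * p^2` to the expected population score —
#' heterozygotes carry the coefficient once, minor homozygotes twice. The
#' expression simplifies algebraically to `2cp`, the coefficient times the
#' expected minor-allele count.
#'
#' @param coefficient Signed coefficient c (±1 for simple-score panels).
#' @param maf Minor-allele frequency in \[0, 0.5\].
#' @return Numeric effect value.
#' @examples
#' snp_effect(1, 0.25) # 0.5
#' @export
snp_effect <- function(coefficient, maf) {
  if (any(!is.finite(maf)) || any(maf < 0) || any(maf > 0.5)) {
    abort("Minor-allele frequencies must lie in [0, 0.5].",
          class = "pwlscore_invalid_parameter")
  }
  coefficient * 2 * maf * (1 - maf) + 2 * coefficient * maf^2
}

#' Estimated panel effect in one population
#'
#' Sums [snp_effect()] over all panel SNPs with an available frequency in
#' the requested population; SNPs with missing frequency are excluded from
#' the sum and counted. Internal sums are unrounded; display rounding is
#' two decimals by convention.
#'
#' @param panel Allele-frequency panel: a tibble with columns `snp_id`,
#'   `coefficient`, and one frequency column per population (`NA` where
#'   unavailable), e.g. from [read_frequency_table()].
#' @param population Name of the frequency column to use.
#' @return One-row tibble: `population`, `effect`, `n_snps_used`.
#' @examples
#' panel <- read_frequency_table(
#'   system.file("extdata", "snp_panel_frequencies.tsv",
#'               package = "pwlscore"))
#' population_effect(panel, "EAS")
#' @export
population_effect <- function(panel, population) {
  if (!population %in% names(panel)) {
    abort(sprintf("Population column `%s` not in the panel.", population),
          class = "pwlscore_schema_error")
  }
  p <- panel[[population]]
  usable <- !is.na(p)
  if (!any(usable)) {
    abort("No SNPs with an available frequency in that population.",
          class = "pwlscore_invalid_parameter")
  }
  eff <- sum(snp_effect(panel$coefficient[usable], p[usable]))
  tibble::tibble(population = population, effect = eff,
                 n_snps_used = sum(usable))
}

#' Estimated panel effect across several populations
#'
#' @param panel As in [population_effect()].
#' @param populations Character vector of population column names; default
#'   is every numeric column except `coefficient`.
#' @return Tibble with one row per population.
#' @export
population_effects <- function(panel, populations = NULL) {
  if (is.null(populations)) {
    populations <- setdiff(
      names(panel)[vapply(panel, is.numeric, logical(1))], "coefficient")
  }
  purrr::map_dfr(populations, function(pp) population_effect(panel, pp))
}

#' Read a signed SNP panel with per-population minor-allele frequencies
#'
#' Expects a delimited file with columns `snp_id`, `coefficient` (±1) and
#' one column per population; `NA` marks unavailable frequencies. SNPs
#' without frequencies stay in the panel but are excluded from sums.
#'
#' The package ships such a panel for the 19-SNP castration-resistance
#' score with 1000 Genomes continental frequencies (16 SNPs available) at
#' `system.file("extdata", "snp_panel_frequencies.tsv", package = "pwlscore")`.
#'
#' @param file Path to a tab- or comma-delimited file.
#' @return The panel tibble.
#' @export
read_frequency_table <- function(file) {
  panel <- tryCatch(
    readr::read_delim(file, show_col_types = FALSE, progress = FALSE,
                      na = c("NA", "")),
    error = function(e) {
      abort(sprintf("Cannot parse frequency table `%s`: %s",
                    file, conditionMessage(e)),
            class = "pwlscore_parse_error")
    })
  if (nrow(panel) == 0 || !all(c("snp_id", "coefficient") %in% names(panel))) {
    abort("Frequency table needs a header with `snp_id`, `coefficient` and population columns, and at least one row.",
          class = "pwlscore_parse_error")
  }
  if (!all(panel$coefficient %in% c(-1, 1))) {
    bad <- which(!panel$coefficient %in% c(-1, 1))
    abort(sprintf("Coefficient outside {-1, +1} at line %d.", bad[1] + 1L),
          class = "pwlscore_parse_error")
  }
  pops <- setdiff(names(panel), c("snp_id", "coefficient"))
  for (pp in pops) {
    v <- panel[[pp]]
    bad <- which(!is.na(v) & (v < 0 | v > 0.5))
    if (length(bad) > 0) {
      abort(sprintf(
        "Minor-allele frequency outside [0, 0.5] in column `%s`, line %d.",
        pp, bad[1] + 1L), class = "pwlscore_parse_error")
    }
  }
  panel
}
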