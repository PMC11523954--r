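#' Write / read a cohort as delimited text with a JSON sidecar
#'
#' The cohort is written as tab-separated text (one header row, samples as
#' rows). A `<path>.json` sidecar records the simulation config and seed
#' when the cohort carries them, making every generated dataset auditable.
#'
#' @param cohort Cohort tibble (e.g. from [simulate_cohort()]).
#' @param path Output file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble (with the sidecar, if present, attached as
#'   attribute `sidecar`).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  cfg <- attr(cohort, "config")
  sidecar <- list(
    n_samples = nrow(cohort),
    columns = names(cohort),
    config = if (!is.null(cfg)) unclass(cfg) else NULL,
    seed = if (!is.null(cfg)) cfg$seed else NULL
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    attr(out, "sidecar") <- jsonlite::read_json(sidecar_path,
                                                simplifyVector = TRUE)
  }
  out
}

#' Write / read a long PSA measurement table
#'
#' @param psa_long Long tibble `sample_id`, `day`, `psa`.
#' @param path File path.
#' @export
write_psa_series <- function(psa_long, path) {
  readr::write_tsv(psa_long, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_psa_series
#' @export
read_psa_series <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read biallelic VCF records as minor-allele counts
#'
#' Converts the GT field of a VCF to per-sample allele counts, then flips
#' any site where the ALT allele is the *major* allele in the file so that
#' counts always refer to the minor allele. Multi-allelic records are
#' dropped with a warning. Requires the \pkg{vcfR} package.
#'
#' @param file Path to a (plain-text) VCF file.
#' @return Tibble with `sample_id` and one column of \{0, 1, 2\} counts
#'   per SNP (named by the VCF ID, or `chrom:pos` when missing).
#' @export
read_genotypes_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Package `vcfR` is required for VCF input.",
          class = "pwlscore_missing_dependency")
  }
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"])
  if (!all(biallelic)) {
    warn(sprintf("Dropping %d multi-allelic records.", sum(!biallelic)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]

  count_alt <- function(g) {
    ifelse(is.na(g), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) {
             sum(a == "1")
           }, integer(1)))
  }
  counts <- t(apply(gt, 1, count_alt))
  # orient to the minor allele within the file
  afreq <- rowMeans(counts, na.rm = TRUE) / 2
  flip <- !is.na(afreq) & afreq > 0.5
  counts[flip, ] <- 2L - counts[flip, , drop = FALSE]

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  out <- tibble::as_tibble(as.data.frame(t(counts)))
  names(out) <- ids
  tibble::add_column(out, sample_id = colnames(gt), .before = 1)
}
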