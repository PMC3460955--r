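## Packaged fixtures: the published clinical table (46 GBM cases) and the
## 46-gene CN-expression correlation table, shipped verbatim as TSV, plus
## a synthetic hg17-like gene model set used by the cohort generator.

## md5 of the shipped fixture files; a mismatch means the installed copy
## was altered and the loaders refuse to return it.
FIXTURE_MD5 <- c(
  table1_clinical.tsv = "27b3f7f4fffaf7aead6e75d3eb8b4c8b",
  table2_dosage.tsv = "4a8e3d803531b323991d10530d70e42d",
  genes_hg17like_synthetic.bed = "87125c98cc7c5747576faaae45cd9329"
)

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "gbmcna", mustWork = TRUE)
  want <- FIXTURE_MD5[[file]]
  got <- unname(tools::md5sum(path))
  if (!identical(got, want)) {
    abort(sprintf("fixture checksum mismatch for %s (md5 %s, expected %s)",
                  file, got, want))
  }
  path
}

#' Load the packaged clinical table (46 GBM cases)
#'
#' Clinical characteristics of the 46-patient cohort: case id, age, gender,
#' Karnofsky index, tumor localization, extent of surgical removal, relapse
#' count, survival after surgery in months, the SNP-array type used, and
#' vital status (one patient, G93, remained alive at study closure; all
#' others died).
#'
#' @return Tibble with 46 rows.
#' @examples
#' \dontrun{
#' table1 <- load_table1_fixture()
#' }
#' @export
load_table1_fixture <- function() {
  readr::read_tsv(
    fixture_path("table1_clinical.tsv"),
    col_types = readr::cols(
      case_id = "c", age = "i", gender = "c", karnofsky_pct = "i",
      localization = "c", surgical_removal = "c", n_relapses = "i",
      survival_months = "d", snp_array = "c", vital_status = "c"
    ),
    progress = FALSE
  )
}

#' Load the packaged 46-gene dosage-correlation table
#'
#' The genes whose mRNA levels tracked their DNA copy number across the 23
#' paired tumors (Pearson R-squared > 0.70): gene name, symbol, cytoband
#' and the printed R-squared, plus a flag for the two genes (IMMP1L, XIST)
#' that were neither amplified nor deleted.
#'
#' @return Tibble with 46 rows: `gene_name`, `symbol`, `cytoband`,
#'   `r_squared`, `not_amplified_or_deleted`.
#' @export
load_table2_fixture <- function() {
  readr::read_tsv(
    fixture_path("table2_dosage.tsv"),
    col_types = readr::cols(
      gene_name = "c", symbol = "c", cytoband = "c", r_squared = "d",
      not_amplified_or_deleted = "l"
    ),
    progress = FALSE
  )
}

#' Load the synthetic hg17-like gene models
#'
#' A small constructed gene set placing the recurrently amplified / deleted
#' GBM genes (EGFR, PDGFRA, CDK4, MDM2, CDKN2A/B, MTAP, PTEN, ...) at
#' plausible hg17-scale coordinates inside the default synthetic event
#' regions. Synthetic stand-in coordinates, not an annotation release.
#'
#' @return Gene model tibble: `symbol`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
load_gene_models <- function() {
  read_bed(fixture_path("genes_hg17like_synthetic.bed"))
}
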