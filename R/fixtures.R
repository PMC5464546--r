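# Shipped reference tables: the 18-protein DMFS screen hits of the
# discovery cohort, the named reduced-predictor compositions, and the
# UniProt accession -> gene symbol map they imply.

fixture_path <- function(file) {
  system.file("extdata", file, package = "tnbcsig", mustWork = TRUE)
}

#' Published 18-protein DMFS screen table
#'
#' The proteins found significantly associated (univariate Cox,
#' p < 0.01) with distant metastasis-free survival in the discovery
#' cohort, with their reported hazard ratios and p-values. Shipped as
#' a reference fixture: the underlying clinical outcomes are not
#' public, so these values document the expected output shape, not a
#' recomputable target.
#'
#' @return A data.frame with columns `accession`, `uniprot_id`,
#'   `gene`, `hazard_ratio`, `p_value`.
#' @export
tnbc_screen_table <- function() {
  utils::read.delim(fixture_path("screen_table.tsv"),
                    stringsAsFactors = FALSE)
}

#' Named reduced-predictor compositions
#'
#' The two externally validated reduced profiles: `P1`
#' (BLVRA/ISG15/PSMB9/GBAS accessions) and `P5`
#' (BLVRA/RAB6A/RAC2/PPA1 accessions).
#'
#' @return A named list of accession character vectors.
#' @export
tnbc_predictors <- function() {
  tab <- utils::read.delim(fixture_path("predictors.tsv"),
                           stringsAsFactors = FALSE)
  stats::setNames(strsplit(tab$proteins, ";", fixed = TRUE),
                  tab$predictor)
}

#' UniProt accession to gene symbol map
#'
#' Editable mapping used when a protein signature is applied to
#' transcriptomics data; seeded from the screen table's gene symbols.
#'
#' @return A data.frame with columns `accession`, `gene`.
#' @export
protein_gene_map <- function() {
  tab <- tnbc_screen_table()
  data.frame(accession = tab$accession, gene = tab$gene,
             stringsAsFactors = FALSE)
}
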