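# Applying a frozen protein signature to probe-level transcriptomics:
# per-gene probe selection, triple-negative sample filtering, and
# discovery-median normalization.

#' Probe-level expression matrix with probe-to-gene map
#'
#' @param values probes x samples numeric matrix (log2 array scale).
#' @param map data.frame with columns `probe`, `gene`; every probe maps
#'   to exactly one gene.
#' @return A list of class `probe_matrix`.
#' @export
probe_matrix <- function(values, map) {
  values <- as.matrix(values)
  if (!all(c("probe", "gene") %in% names(map))) {
    stop("map needs columns 'probe' and 'gene'")
  }
  if (anyDuplicated(map$probe)) stop("a probe maps to more than one gene")
  if (!all(rownames(values) %in% map$probe)) {
    stop("unmapped probe(s): ",
         paste(setdiff(rownames(values), map$probe), collapse = ", "))
  }
  structure(list(values = values,
                 map = map[match(rownames(values), map$probe), ]),
            class = "probe_matrix")
}

#' Select one probe per gene by coefficient of variation
#'
#' When a gene has multiple probes, the probe with the highest
#' coefficient of variation (SD / mean, computed on the matrix's
#' native scale) is kept; single-probe genes pass through. Probes with
#' non-positive mean have an undefined CV and are skipped with a
#' warning; CV ties go to the lexicographically smallest probe id.
#'
#' @param pm a [probe_matrix].
#' @return A genes x samples numeric matrix.
#' @export
select_probe_per_gene <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  v <- pm$values
  mu <- rowMeans(v)
  sd <- apply(v, 1, stats::sd)
  bad <- mu <= 0
  if (any(bad)) {
    warning("skipping probe(s) with non-positive mean: ",
            paste(rownames(v)[bad], collapse = ", "))
  }
  cv <- ifelse(bad, NA_real_, sd / mu)
  keep <- character(0)
  for (g in unique(pm$map$gene)) {
    probes <- pm$map$probe[pm$map$gene == g]
    cvs <- cv[probes]
    if (all(is.na(cvs))) next
    best <- max(cvs, na.rm = TRUE)
    cand <- sort(probes[!is.na(cvs) & cvs == best])
    keep[g] <- cand[1]
  }
  out <- v[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out
}

#' Filter samples to a triple-negative expression phenotype
#'
#' Excludes any sample with ESR1 expression strictly above
#' `esr1_threshold` or ERBB2 expression strictly above
#' `erbb2_threshold` (boundary values are kept). Thresholds are on the
#' matrix's relative (log2 array) scale.
#'
#' @param gm genes x samples matrix containing `ESR1` and `ERBB2` rows.
#' @param esr1_threshold,erbb2_threshold exclusion thresholds
#'   (defaults 12 and 11.8).
#' @return Character vector of retained sample ids (warning if empty).
#' @export
filter_tnbc <- function(gm, esr1_threshold = 12, erbb2_threshold = 11.8) {
  need <- c("ESR1", "ERBB2")
  if (!all(need %in% rownames(gm))) {
    stop("matrix must contain rows: ", paste(need, collapse = ", "))
  }
  keep <- gm["ESR1", ] <= esr1_threshold & gm["ERBB2", ] <= erbb2_threshold
  out <- colnames(gm)[keep]
  if (length(out) == 0) warning("no samples pass the TNBC filter")
  out
}

#' Normalize validation genes to discovery medians
#'
#' Per gene, shifts the validation values so their median equals the
#' discovery cohort's median for that gene:
#' `value - median(validation) + discovery_median`. Genes without a
#' discovery median are dropped with a warning. Idempotent for fixed
#' discovery medians.
#'
#' @param gm genes x samples matrix.
#' @param discovery_medians named numeric vector of per-gene medians
#'   from the discovery cohort.
#' @return The normalized matrix (possibly fewer rows).
#' @export
median_normalize_to_discovery <- function(gm, discovery_medians) {
  known <- rownames(gm) %in% names(discovery_medians)
  if (!all(known)) {
    warning("dropping gene(s) without a discovery median: ",
            paste(rownames(gm)[!known], collapse = ", "))
    gm <- gm[known, , drop = FALSE]
  }
  med <- apply(gm, 1, stats::median)
  gm - med + discovery_medians[rownames(gm)]
}

#' Validate a frozen signature model on transcriptomics data
#'
#' Maps the model's protein accessions to gene symbols, extracts the
#' corresponding gene rows, and applies the same frozen-model transfer
#' rule as [validate_prm()]: within-cohort z-scoring, frozen loadings,
#' rank-quantile cutoff at `cutoff_fraction`.
#'
#' @param model a frozen [signature_model].
#' @param gm genes x samples matrix (probe-selected, TNBC-filtered,
#'   median-normalized).
#' @param clin a [clinical_table] for the array cohort.
#' @param cutoff_fraction low-risk fraction (default 0.5).
#' @param gene_map data.frame (accession, gene); defaults to the
#'   shipped map, see [protein_gene_map()].
#' @param t_years DMFS readout horizon.
#' @return A [group_comparison()] result.
#' @export
validate_transcriptomics <- function(model, gm, clin,
                                     cutoff_fraction = 0.5,
                                     gene_map = protein_gene_map(),
                                     t_years = 5) {
  idx <- match(model$protein_ids, gene_map$accession)
  if (anyNA(idx)) {
    stop("no gene mapping for protein(s): ",
         paste(model$protein_ids[is.na(idx)], collapse = ", "))
  }
  genes <- gene_map$gene[idx]
  missing <- setdiff(genes, rownames(gm))
  if (length(missing) > 0) {
    stop("expression matrix lacks gene(s): ",
         paste(missing, collapse = ", "))
  }
  sub <- gm[genes, , drop = FALSE]
  rownames(sub) <- model$protein_ids   # back to accession space
  validate_frozen_model(model, sub, clin, cutoff_fraction,
                        t_years = t_years)
}
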