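# Parallel reaction monitoring: light/heavy ratio computation from
# transition-area tables and application of a frozen signature model
# to the PRM validation cohort.

validate_transition_table <- function(tt) {
  need <- c("peptide", "protein", "sample", "channel", "ion", "area")
  if (!all(need %in% names(tt))) {
    stop("transition table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(tt$channel %in% c("light", "heavy"))) {
    stop("channel must be 'light' or 'heavy'")
  }
  if (any(tt$area < 0, na.rm = TRUE)) stop("negative product-ion area")
  key <- paste(tt$peptide, tt$sample, tt$channel, tt$ion, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (peptide, sample, channel, ion) row(s)")
  }
  invisible(tt)
}

#' Read a transition-area table (Skyline-export-like)
#'
#' Long-format TSV/CSV with one row per product-ion chromatogram area.
#' Column names are matched case-insensitively against the common
#' Skyline export headers: `Peptide` (or `Peptide Sequence`),
#' `Protein` (`Protein Name`), `Replicate` (`Replicate Name` /
#' `sample`), `Isotope Label` (`Isotope Label Type` / `channel`),
#' `Fragment Ion` (`ion`), `Area`.
#'
#' @param path path to the delimited file.
#' @return A `data.frame` of class `transition_table`.
#' @export
read_transition_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  tab <- read_table_chr(path, sep)
  aliases <- list(
    peptide = c("peptide", "peptide sequence", "peptide modified sequence"),
    protein = c("protein", "protein name", "protein accession"),
    sample = c("sample", "replicate", "replicate name"),
    channel = c("channel", "isotope label", "isotope label type"),
    ion = c("ion", "fragment ion"),
    area = c("area", "total area"))
  lower <- tolower(names(tab))
  out <- list()
  for (f in names(aliases)) {
    hit <- which(lower %in% aliases[[f]])
    if (length(hit) == 0) stop("cannot find a '", f, "' column")
    out[[f]] <- tab[[hit[1]]]
  }
  out$channel <- tolower(out$channel)
  out$area <- suppressWarnings(as.numeric(out$area))
  if (anyNA(out$area)) stop("non-numeric area values")
  tt <- as.data.frame(out, stringsAsFactors = FALSE)
  class(tt) <- c("transition_table", "data.frame")
  validate_transition_table(tt)
  tt
}

#' Compute log2 light/heavy peptide ratios
#'
#' For each (peptide, sample), the ratio is the sum of the endogenous
#' (light) product-ion areas divided by the sum of the reference
#' (heavy) product-ion areas, transformed to log2. A zero light or
#' heavy sum leaves the entry missing and adds a QC flag.
#'
#' @param tt a `transition_table`.
#' @return A list of class `peptide_ratio_matrix`: `values`
#'   (peptides x samples log2 L/H), `peptide_protein` (named map), and
#'   `qc_flags` (data.frame of skipped entries).
#' @export
compute_lh_ratios <- function(tt) {
  validate_transition_table(tt)
  peptides <- sort(unique(tt$peptide))
  samples <- unique(tt$sample)
  sums <- function(chan) {
    sub <- tt[tt$channel == chan, , drop = FALSE]
    agg <- stats::aggregate(area ~ peptide + sample, data = sub, FUN = sum)
    m <- matrix(NA_real_, length(peptides), length(samples),
                dimnames = list(peptides, samples))
    m[cbind(agg$peptide, agg$sample)] <- agg$area
    m
  }
  light <- sums("light")
  heavy <- sums("heavy")
  vals <- matrix(NA_real_, length(peptides), length(samples),
                 dimnames = list(peptides, samples))
  ok <- !is.na(light) & !is.na(heavy) & light > 0 & heavy > 0
  vals[ok] <- log2(light[ok] / heavy[ok])
  bad <- which(!ok, arr.ind = TRUE)
  qc <- data.frame(peptide = peptides[bad[, 1]],
                   sample = samples[bad[, 2]],
                   reason = ifelse(is.na(light[!ok]) | is.na(heavy[!ok]),
                                   "channel absent",
                                   ifelse(heavy[!ok] <= 0, "zero heavy sum",
                                          "zero light sum")),
                   stringsAsFactors = FALSE)
  map <- tt$protein[match(peptides, tt$peptide)]
  out <- list(values = vals,
              peptide_protein = stats::setNames(map, peptides),
              qc_flags = qc)
  class(out) <- "peptide_ratio_matrix"
  out
}

#' Aggregate peptide log-ratios to protein level
#'
#' Per (protein, sample), takes the median (default; robust to one
#' interfered peptide) or mean of the available peptide log2 L/H
#' ratios. An all-missing cell stays missing: aggregation never
#' manufactures values.
#'
#' @param pr a `peptide_ratio_matrix` from [compute_lh_ratios()].
#' @param method `"median"` (default) or `"mean"`.
#' @return A proteins x samples numeric matrix.
#' @export
aggregate_to_protein <- function(pr, method = c("median", "mean")) {
  method <- match.arg(method)
  f <- if (method == "median") stats::median else mean
  prots <- unique(pr$peptide_protein)
  out <- matrix(NA_real_, length(prots), ncol(pr$values),
                dimnames = list(prots, colnames(pr$values)))
  for (p in prots) {
    rows <- pr$values[pr$peptide_protein == p, , drop = FALSE]
    out[p, ] <- apply(rows, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else f(v)
    })
  }
  out
}

# shared core of the cross-platform validations: re-standardize each
# model protein within the validation cohort, score with the frozen
# loadings, split at the stated fraction's rank quantile of the
# validation scores, and compare groups.
validate_frozen_model <- function(model, values, clin, cutoff_fraction,
                                  t_years = 5, ties = "efron") {
  miss <- setdiff(model$protein_ids, rownames(values))
  if (length(miss) > 0) {
    stop("validation matrix lacks model protein(s): ",
         paste(miss, collapse = ", "))
  }
  sub <- values[model$protein_ids, , drop = FALSE]
  bad <- colnames(sub)[colSums(is.na(sub)) > 0]
  if (length(bad) > 0) {
    warning("dropping sample(s) with missing model-protein values: ",
            paste(bad, collapse = ", "))
    sub <- sub[, setdiff(colnames(sub), bad), drop = FALSE]
  }
  mom <- row_moments(sub)
  if (any(is.na(mom$sd) | mom$sd == 0)) {
    stop("zero-variance model protein(s) in validation cohort")
  }
  scores <- score_with_model(model, sub, means = mom$mean, sds = mom$sd)
  n <- length(scores)
  k <- ceiling(cutoff_fraction * n)
  cutoff <- sort(scores)[min(max(k, 1), n)]
  grp <- factor(ifelse(scores > cutoff, "high", "low"),
                levels = c("low", "high"))
  asg <- data.frame(sample = colnames(sub), score = scores, group = grp,
                    stringsAsFactors = FALSE)
  class(asg) <- c("risk_assignment", "data.frame")
  cmp <- group_comparison(asg, clin, t_years = t_years, ties = ties)
  cmp$assignment <- asg
  cmp$cutoff_fraction <- cutoff_fraction
  cmp
}

#' Validate a frozen signature model on a PRM protein matrix
#'
#' Applies the cross-platform transfer rule: each model protein is
#' re-standardized (z-score) within the PRM cohort, samples are scored
#' with the frozen loading vector, and the low/high split is the
#' a-priori rank quantile of the validation-score distribution at
#' `cutoff_fraction` (e.g. 0.7 for a 70:30 split).
#'
#' @param model a frozen [signature_model].
#' @param protein_matrix proteins x samples matrix of aggregated log2
#'   L/H ratios ([aggregate_to_protein()]).
#' @param clin a [clinical_table] for the PRM cohort.
#' @param cutoff_fraction low-risk fraction (default 0.7).
#' @param t_years DMFS readout horizon.
#' @return A [group_comparison()] result (with the risk assignment
#'   attached).
#' @export
validate_prm <- function(model, protein_matrix, clin,
                         cutoff_fraction = 0.7, t_years = 5) {
  validate_frozen_model(model, as.matrix(protein_matrix), clin,
                        cutoff_fraction, t_years = t_years)
}

#' Write a transition table to a tab-separated file
#' @param tt a `transition_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(tt, path) {
  df <- as.data.frame(tt)
  df$area <- format_num(df$area)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
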