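# Per-protein univariate Cox screening against DMFS.

#' Screen proteins by univariate Cox association with survival
#'
#' Fits one univariate Cox model per protein row of the processed
#' matrix against the clinical outcome (samples aligned by id) and
#' returns the proteins with Wald `p < alpha` (strict inequality, no
#' multiplicity correction), sorted by ascending p-value. Flagged fits
#' (separation, uninformative rows) are excluded from the selection and
#' listed in the `flagged` attribute.
#'
#' @param m a processed (complete) [quant_matrix].
#' @param clin a [clinical_table] covering every sample of `m`.
#' @param alpha selection threshold on the Wald p-value (default 0.01).
#' @param ties tie-handling method, see [cox_fit()].
#' @return A `data.frame` of class `screen_result` with columns
#'   `protein_id`, `beta`, `se`, `hr`, `p`, `n_events`, restricted to
#'   `p < alpha`; the complete per-protein table is in attribute
#'   `full`.
#' @export
screen_proteins <- function(m, clin, alpha = 0.01,
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(m, "quant_matrix"))
  if (any(m$missing)) stop("screen requires a fully imputed matrix")
  cl <- align_clinical(clin, sample_ids(m))
  fits <- cox_fit_many(t(m$values), cl$time, cl$event, ties = ties)
  full <- data.frame(protein_id = protein_ids(m), fits,
                     row.names = NULL, stringsAsFactors = FALSE)
  sel <- full[!full$flagged & full$p < alpha, , drop = FALSE]
  sel <- sel[order(sel$p), c("protein_id", "beta", "se", "hr", "p",
                             "n_events")]
  rownames(sel) <- NULL
  attr(sel, "full") <- full
  attr(sel, "flagged") <- full$protein_id[full$flagged]
  attr(sel, "alpha") <- alpha
  class(sel) <- c("screen_result", "data.frame")
  sel
}

#' Write a screening result as a tab-separated table
#'
#' Columns: accession, beta, HR, p — the shape of a per-protein
#' survival-screen report.
#'
#' @param x a `screen_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(x, path) {
  df <- data.frame(accession = x$protein_id,
                   beta = format_num(x$beta),
                   HR = format_num(x$hr),
                   p = format_num(x$p))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
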