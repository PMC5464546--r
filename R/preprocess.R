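# Matrix conditioning chain for label-free discovery data:
# quantifiable-protein filter -> outlier-sample exclusion -> log2 ->
# downshifted-Gaussian imputation -> z-score -> batch correction.

#' Keep quantifiable proteins
#'
#' A protein is quantifiable when it is supported by at least
#' `min_unique_peptides` unique peptides and detected (unmasked) in at
#' least `min_detect_frac` of the samples. Both boundaries are
#' inclusive ("at least"). The sample set is unchanged.
#'
#' @param m a [quant_matrix].
#' @param min_unique_peptides integer peptide floor (default 2).
#' @param min_detect_frac detection-fraction floor (default 0.75).
#' @return The filtered [quant_matrix].
#' @export
filter_quantifiable <- function(m, min_unique_peptides = 2L,
                                min_detect_frac = 0.75) {
  stopifnot(inherits(m, "quant_matrix"))
  detect <- rowMeans(!m$missing)
  pep <- m$unique_peptides
  if (all(is.na(pep))) stop("unique_peptides are required for this filter")
  keep <- !is.na(pep) & pep >= min_unique_peptides &
    detect >= min_detect_frac
  if (!any(keep)) warning("no quantifiable proteins remain")
  subset_quant(m, proteins = which(keep))
}

#' Flag outlier samples by identified-peptide count
#'
#' Applies the "mean minus twice the standard deviation" rule once (not
#' iterated) to per-sample identified-unique-peptide counts: samples
#' whose count falls strictly below `mean - 2 * sd` (sample SD) are
#' excluded.
#'
#' @param counts named numeric vector of identified-unique-peptide
#'   counts, one per sample (>= 3 samples).
#' @return Character vector of excluded sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(counts) {
  if (length(counts) < 3) stop("need at least 3 samples")
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  thr <- mean(counts) - 2 * stats::sd(counts)
  names(counts)[counts < thr]
}

#' Log2-transform a quantification matrix
#'
#' @param m a [quant_matrix] on the raw scale; every unmasked value
#'   must be strictly positive.
#' @return The [quant_matrix] with unmasked values replaced by their
#'   log2; the mask is untouched.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  obs <- m$values[!m$missing]
  if (any(obs <= 0)) stop("non-positive unmasked intensity; cannot log2")
  m$values[!m$missing] <- log2(obs)
  m$scale <- "log2"
  m
}

#' Impute left-censored missing values (downshifted Gaussian)
#'
#' Replaces each masked entry with a draw from
#' `Normal(mean_p - downshift * sd_p, (width * sd_p)^2)` where `mean_p`
#' and `sd_p` are the protein's observed mean and sample SD — the
#' standard label-free convention that missing values sit in the
#' low-abundance tail. Proteins with fewer than two observed values
#' fall back to the sample's (column-wise) observed moments; the
#' fallback is recorded.
#'
#' @param m a [quant_matrix] on the log2 scale.
#' @param width imputation width as a fraction of the row SD
#'   (default 0.3).
#' @param downshift downshift in row SDs (default 1.8).
#' @return The completed [quant_matrix] (mask cleared), with attribute
#'   `imputation` recording counts and fallback proteins. Draws come
#'   from the ambient RNG stream; seed with `set.seed()` for
#'   reproducibility.
#' @export
impute_missing <- function(m, width = 0.3, downshift = 1.8) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$scale != "log2") stop("impute_missing expects a log2-scale matrix")
  vals <- m$values
  rm_ <- row_moments(vals)
  cm_ <- row_moments(t(vals))
  fallback <- which(is.na(rm_$sd) | rm_$sd == 0)
  n_imp <- 0L
  for (i in seq_len(nrow(vals))) {
    mi <- which(m$missing[i, ])
    if (length(mi) == 0) next
    if (i %in% fallback) {
      mu <- cm_$mean[mi] - downshift * cm_$sd[mi]
      sd <- width * cm_$sd[mi]
    } else {
      mu <- rep(rm_$mean[i] - downshift * rm_$sd[i], length(mi))
      sd <- rep(width * rm_$sd[i], length(mi))
    }
    if (anyNA(mu) || anyNA(sd)) {
      stop("cannot impute protein ", rownames(vals)[i],
           ": no usable row or column moments")
    }
    vals[i, mi] <- stats::rnorm(length(mi), mu, sd)
    n_imp <- n_imp + length(mi)
  }
  out <- quant_matrix(vals, matrix(FALSE, nrow(vals), ncol(vals),
                                   dimnames = dimnames(vals)),
                      m$unique_peptides, m$batch, scale = "log2")
  attr(out, "imputation") <- list(
    imputed_count = n_imp,
    fallback_proteins = rownames(vals)[intersect(fallback,
                                                 which(rowSums(m$missing) > 0))])
  out
}

#' Z-score each protein across samples
#'
#' Subtracts the per-protein mean and divides by the per-protein sample
#' SD (n - 1 denominator).
#'
#' @param m a complete [quant_matrix].
#' @return The standardized [quant_matrix] (`scale = "zscore"`).
#' @export
zscore <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (any(m$missing)) stop("zscore requires a complete (imputed) matrix")
  mom <- row_moments(m$values)
  bad <- which(is.na(mom$sd) | mom$sd == 0)
  if (length(bad) > 0) {
    stop("zero-variance protein(s): ",
         paste(rownames(m$values)[bad], collapse = ", "))
  }
  m$values <- (m$values - mom$mean) / mom$sd
  m$scale <- "zscore"
  m
}

#' Run the full preprocessing chain
#'
#' Enforces the fixed stage order: quantifiable-protein filter,
#' outlier-sample exclusion, log2 transform, imputation, z-score, batch
#' correction. Stage dimensions, excluded samples, and imputation
#' counts are collected in a `preprocess_report`.
#'
#' @param m a raw-scale [quant_matrix].
#' @param config a [default_config()] list.
#' @param sample_peptide_counts optional named per-sample
#'   identified-unique-peptide counts for the outlier rule; when `NULL`
#'   a proxy (sum of unique-peptide counts over detected proteins) is
#'   used.
#' @return A list with `quant` (processed matrix) and `report`.
#' @export
preprocess_pipeline <- function(m, config = default_config(),
                                sample_peptide_counts = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  report <- list(n_proteins_in = nrow(m$values),
                 n_samples_in = ncol(m$values))
  counts <- sample_peptide_counts %||%
    colSums(m$unique_peptides * !m$missing, na.rm = TRUE)
  out_samples <- detect_outlier_samples(counts)
  report$excluded_samples <- out_samples
  report$exclusion_reason <-
    if (length(out_samples)) "unique-peptide count below mean - 2 SD" else NA
  if (length(out_samples) > 0) {
    keep <- setdiff(sample_ids(m), out_samples)
    m <- subset_quant(m, samples = keep)
  }
  m <- filter_quantifiable(m, config$min_unique_peptides,
                           config$min_detect_frac)
  report$n_proteins_quantifiable <- nrow(m$values)
  m <- log2_transform(m)
  m <- impute_missing(m, config$impute_width, config$impute_downshift)
  report$imputed_count <- attr(m, "imputation")$imputed_count
  m <- zscore(m)
  if (!is.null(m$batch) && nlevels(droplevels(m$batch)) > 1) {
    pre <- batch_means(m$values, m$batch)
    m$values <- combat_correct(m$values, m$batch)
    report$batch_means_before <- pre
    report$batch_means_after <- batch_means(m$values, m$batch)
  }
  report$n_proteins_out <- nrow(m$values)
  report$n_samples_out <- ncol(m$values)
  class(report) <- "preprocess_report"
  list(quant = m, report = report)
}

batch_means <- function(x, batch) {
  vapply(levels(droplevels(batch)),
         function(b) mean(x[, batch == b, drop = FALSE]), numeric(1))
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess: %d x %d -> %d x %d\n", x$n_proteins_in,
              x$n_samples_in, x$n_proteins_out, x$n_samples_out))
  if (length(x$excluded_samples)) {
    cat("  excluded samples:", paste(x$excluded_samples, collapse = ", "),
        sprintf("(%s)\n", x$exclusion_reason))
  }
  cat(sprintf("  quantifiable proteins: %d; imputed entries: %d\n",
              x$n_proteins_quantifiable, x$imputed_count))
  invisible(x)
}
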