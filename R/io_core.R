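# Readers/writers for the pipeline's tabular formats, plus the two core
# containers: the protein quantification matrix and the clinical table.

#' Protein quantification matrix
#'
#' Container for a proteins x samples quantification matrix as produced
#' by label-free proteomics software (MaxQuant-style LFQ intensities).
#' Masked (not-detected) entries are `NA` in `values` with the
#' corresponding `missing` flag set; an LFQ intensity of zero means
#' "not quantified" and is always stored as missing.
#'
#' @param values numeric matrix, proteins in rows (rownames = accession),
#'   samples in columns (colnames = sample ids).
#' @param missing logical matrix of the same dimension; `TRUE` marks a
#'   not-detected entry. Defaults to `is.na(values)`.
#' @param unique_peptides non-negative integer vector, one per protein:
#'   the number of unique peptides supporting each protein group.
#' @param batch optional factor/character of per-sample batch labels.
#' @param scale one of `"raw"`, `"log2"`, `"zscore"`; bookkeeping flag
#'   for the transformation state of `values`.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, missing = NULL, unique_peptides = NULL,
                         batch = NULL, scale = c("raw", "log2", "zscore")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  # zero-extent dimensions legitimately carry NULL dimnames
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      (is.null(colnames(values)) && ncol(values) > 0)) {
    stop("values must have protein rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.matrix(missing)
  if (!identical(dim(missing), dim(values))) {
    stop("missing mask and values dimensions disagree")
  }
  if (!is.logical(missing)) stop("missing mask must be logical")
  values[missing] <- NA_real_
  if (any(is.na(values) & !missing)) {
    stop("NA values present outside the missing mask")
  }
  if (is.null(unique_peptides)) {
    unique_peptides <- rep(NA_integer_, nrow(values))
  }
  unique_peptides <- as.integer(unique_peptides)
  if (length(unique_peptides) != nrow(values)) {
    stop("unique_peptides must have one entry per protein")
  }
  if (any(unique_peptides < 0, na.rm = TRUE)) {
    stop("unique_peptides must be non-negative")
  }
  names(unique_peptides) <- rownames(values)
  if (!is.null(batch)) {
    batch <- as.factor(batch)
    if (length(batch) != ncol(values)) {
      stop("batch must have one label per sample")
    }
    names(batch) <- colnames(values)
  }
  dimnames(missing) <- dimnames(values)
  structure(
    list(values = values, missing = missing,
         unique_peptides = unique_peptides, batch = batch, scale = scale),
    class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d proteins x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(x$missing),
              100 * mean(x$missing)))
  if (!is.null(x$batch)) {
    cat("  batches:", paste(levels(x$batch), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

protein_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

# Subset a quant_matrix by protein and/or sample ids (or indices).
subset_quant <- function(m, proteins = NULL, samples = NULL) {
  pi <- proteins %||% seq_len(nrow(m$values))
  si <- samples %||% seq_len(ncol(m$values))
  quant_matrix(m$values[pi, si, drop = FALSE],
               m$missing[pi, si, drop = FALSE],
               m$unique_peptides[pi],
               if (!is.null(m$batch)) m$batch[si] else NULL,
               scale = m$scale)
}

#' Clinical outcome table
#'
#' Per-sample distant metastasis-free survival (DMFS) outcome: follow-up
#' time in years, binary event indicator, and TNM tumor-size / nodal
#' stage categories.
#'
#' @param sample character sample ids (unique).
#' @param time positive follow-up times in years.
#' @param event event indicator, 0 (censored) or 1 (distant relapse).
#' @param t_stage,n_stage optional stage categories (e.g. `T1`..`T4`,
#'   `multifocal`; `N0`..`N3`, `Nx`); `"unknown"` is a valid level.
#' @return A `data.frame` of class `clinical_table`.
#' @export
clinical_table <- function(sample, time, event, t_stage = NULL,
                           n_stage = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) {
    stop("duplicate sample ids: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  time <- as.numeric(time)
  if (anyNA(time) || any(time <= 0)) {
    stop("time must be strictly positive")
  }
  event <- as.numeric(event)
  if (anyNA(event) || !all(event %in% c(0, 1))) {
    stop("event must be 0 or 1")
  }
  n <- length(sample)
  stopifnot(length(time) == n, length(event) == n)
  df <- data.frame(sample = sample, time = time, event = as.integer(event),
                   stringsAsFactors = FALSE)
  df$t_stage <- as.factor(t_stage %||% rep("unknown", n))
  df$n_stage <- as.factor(n_stage %||% rep("unknown", n))
  class(df) <- c("clinical_table", "data.frame")
  df
}

# --- text-format readers -------------------------------------------------

# sniff the field separator from the header line: tab wins over comma
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_table_chr <- function(path, sep) {
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read a protein quantification matrix from a delimited text file
#'
#' Expects proteins in rows with the first column holding accession ids
#' and one intensity column per sample. A column named
#' `unique_peptides` (or the MaxQuant-style `Unique peptides`) is used
#' as the per-protein unique-peptide count. Intensity cells that are
#' empty or exactly zero are recorded as missing (the label-free
#' convention: LFQ 0 means "not quantified"). The separator (tab or
#' comma) is sniffed from the header.
#'
#' @param path path to a TSV/CSV file.
#' @param dialect `"maxquant_like"` (peptide-count column expected) or
#'   `"plain"` (intensity columns only).
#' @param batch_file optional two-column delimited sidecar
#'   (sample, batch) assigning batch labels by sample id.
#' @return A [quant_matrix] on the raw intensity scale.
#' @export
read_quant_matrix <- function(path, dialect = c("maxquant_like", "plain"),
                              batch_file = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  # read.table silently uniquifies duplicate header fields, so check
  # the raw header line first
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("duplicate sample ids: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  tab <- read_table_chr(path, sep)
  if (ncol(tab) < 2) stop("need at least one protein id and one sample column")
  prot <- tab[[1]]
  if (anyDuplicated(prot)) {
    stop("duplicate protein ids: ",
         paste(unique(prot[duplicated(prot)]), collapse = ", "))
  }
  rest <- tab[-1]
  pep_col <- which(tolower(names(rest)) %in%
                     c("unique_peptides", "unique peptides"))
  unique_peptides <- NULL
  if (length(pep_col) > 0) {
    unique_peptides <- suppressWarnings(as.integer(rest[[pep_col[1]]]))
    if (anyNA(unique_peptides)) {
      stop("non-integer unique-peptide count in rows: ",
           paste(prot[is.na(unique_peptides)], collapse = ", "))
    }
    rest <- rest[-pep_col]
  } else if (dialect == "maxquant_like") {
    stop("maxquant_like dialect requires a 'unique_peptides' column")
  }
  if (anyDuplicated(names(rest))) {
    stop("duplicate sample ids: ",
         paste(unique(names(rest)[duplicated(names(rest))]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = length(prot), ncol = ncol(rest),
                 dimnames = list(prot, names(rest)))
  for (j in seq_along(rest)) {
    cell <- trimws(rest[[j]])
    empty <- cell == "" | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      stop(sprintf("non-numeric intensity '%s' at protein %s, sample %s",
                   cell[which(bad)[1]], prot[which(bad)[1]], names(rest)[j]))
    }
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  miss <- is.na(vals) | (!is.na(vals) & vals == 0)
  batch <- NULL
  if (!is.null(batch_file)) {
    bsep <- sniff_sep(batch_file)
    btab <- read_table_chr(batch_file, bsep)
    idx <- match(colnames(vals), btab[[1]])
    if (anyNA(idx)) {
      stop("batch sidecar missing sample(s): ",
           paste(colnames(vals)[is.na(idx)], collapse = ", "))
    }
    batch <- btab[[2]][idx]
  }
  quant_matrix(vals, miss, unique_peptides, batch, scale = "raw")
}

#' Write a quantification matrix to a tab-separated file
#'
#' Values are written at full double precision so that
#' `read_quant_matrix(write_quant_matrix(m))` round-trips bit-exactly;
#' missing entries are written as empty cells.
#'
#' @param m a [quant_matrix].
#' @param path output path.
#' @param batch_file optional path for the batch sidecar.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(m, path, batch_file = NULL) {
  vals <- m$values
  txt <- matrix(format_num(vals), nrow = nrow(vals))
  txt[m$missing] <- ""
  header <- c("protein", colnames(vals))
  has_pep <- !all(is.na(m$unique_peptides))
  if (has_pep) header <- c(header[1], "unique_peptides", header[-1])
  lines <- vapply(seq_len(nrow(vals)), function(i) {
    row <- c(rownames(vals)[i],
             if (has_pep) as.character(m$unique_peptides[i]),
             txt[i, ])
    paste(row, collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path, useBytes = TRUE)
  if (!is.null(batch_file) && !is.null(m$batch)) {
    writeLines(c("sample\tbatch",
                 paste(colnames(vals), as.character(m$batch), sep = "\t")),
               batch_file, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a clinical outcome table
#'
#' Expects columns `sample`, `time` (years), `event` (0/1) and optional
#' `t_stage` / `n_stage` columns; separator sniffed from the header.
#'
#' @param path path to a TSV/CSV file.
#' @return A [clinical_table].
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  tab <- read_table_chr(path, sep)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(tab))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  time <- suppressWarnings(as.numeric(tab$time))
  event <- suppressWarnings(as.numeric(tab$event))
  if (anyNA(time)) stop("non-numeric time values")
  if (anyNA(event)) stop("non-numeric event values")
  clinical_table(tab$sample, time, event,
                 t_stage = tab[["t_stage"]], n_stage = tab[["n_stage"]])
}

#' Write a clinical table to a tab-separated file
#' @param clin a [clinical_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  df <- as.data.frame(clin)
  df$time <- format_num(df$time)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# --- run configuration ---------------------------------------------------

#' Default run configuration
#'
#' Bundles every tunable threshold of the discovery pipeline with its
#' default value. Fractions must lie in `[0, 1]`; counts are integers
#' `>= 1`.
#'
#' @param ... named overrides of the defaults.
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_unique_peptides = 2L,   # quantifiable-protein peptide floor
    min_detect_frac = 0.75,     # quantifiable-protein detection floor
    impute_width = 0.3,         # imputation width, fraction of row SD
    impute_downshift = 1.8,     # imputation downshift, in row SDs
    screen_alpha = 0.01,        # univariate Cox p-value cut (strict <)
    corr_threshold = 0.5,       # Pearson r for correlation grouping
    profile_size_range = c(3L, 7L),
    per_group = c(1L, 2L),      # proteins drawn per correlation group
    n_profiles = 12L,
    cutoff_fraction = 0.5,      # low-risk fraction of the a-priori split
    n_permutations = 1000L,
    ties = "efron",
    rng_seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  frac <- c("min_detect_frac", "screen_alpha", "corr_threshold",
            "cutoff_fraction")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must be in [0, 1]")
  }
  ints <- c("min_unique_peptides", "n_profiles", "n_permutations")
  for (f in ints) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 1 || v != round(v)) stop(f, " must be an integer >= 1")
  }
  if (length(cfg$profile_size_range) != 2 ||
      cfg$profile_size_range[1] > cfg$profile_size_range[2]) {
    stop("profile_size_range must be (min, max) with min <= max")
  }
  invisible(cfg)
}

#' Read a run configuration from a JSON file
#' @param path JSON file with a subset of [default_config()] fields.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, raw)
}
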