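# Correlation groups, random reduced profiles, and supervised
# principal-component risk models with a-priori rank-quantile cutoffs.

#' Group screened proteins by expression correlation
#'
#' Builds the graph with an edge between any two proteins whose Pearson
#' correlation (across samples, on processed values) exceeds
#' `r_threshold` (strict), and returns its connected components. The
#' components partition the input: correlation is not transitive, but
#' "grouped together" is read as the transitive closure, the minimal
#' grouping consistent with putting every correlated pair in one group.
#'
#' @param m a processed [quant_matrix].
#' @param proteins character vector of protein ids (subset of rows).
#' @param r_threshold Pearson correlation threshold (default 0.5).
#' @return A list of character vectors of class `correlation_groups`;
#'   groups are disjoint and cover `proteins`.
#' @export
correlation_groups <- function(m, proteins, r_threshold = 0.5) {
  stopifnot(all(proteins %in% protein_ids(m)))
  k <- length(proteins)
  if (k == 0) return(structure(list(), class = "correlation_groups"))
  cc <- stats::cor(t(m$values[proteins, , drop = FALSE]))
  # union-find over the r > threshold adjacency
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!is.na(cc[i, j]) && cc[i, j] > r_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  groups <- split(proteins, roots)
  names(groups) <- sprintf("G%d", seq_along(groups))
  structure(groups, class = "correlation_groups")
}

#' Randomly sample reduced protein profiles across correlation groups
#'
#' Builds candidate signatures by drawing one or two proteins from each
#' of several distinct correlation groups until the profile size falls
#' in `size_range`; profiles are de-duplicated (as sets) and
#' deterministic under a seeded RNG.
#'
#' @param groups a [correlation_groups] partition (>= 2 groups).
#' @param size_range integer `(min, max)` profile size, default (3, 7).
#' @param per_group how many proteins may be drawn from one group
#'   (default 1 or 2).
#' @param n_profiles number of distinct profiles to return.
#' @param max_tries sampling attempts before declaring the request
#'   infeasible.
#' @return A named list of character vectors (`P1`, `P2`, ...).
#' @export
sample_reduced_profiles <- function(groups, size_range = c(3L, 7L),
                                    per_group = c(1L, 2L),
                                    n_profiles = 12L, max_tries = 2000L) {
  if (length(groups) < 2) stop("need at least 2 correlation groups")
  smin <- size_range[1]; smax <- size_range[2]
  max_size <- sum(pmin(lengths(groups), max(per_group)))
  if (max_size < smin) {
    stop(sprintf(
      "infeasible size_range: at most %d proteins reachable, %d required",
      max_size, smin))
  }
  profiles <- list(); seen <- character(0)
  tries <- 0
  while (length(profiles) < n_profiles && tries < max_tries) {
    tries <- tries + 1
    target <- sample(seq(smin, smax), 1)
    acc <- character(0)
    for (g in sample(seq_along(groups))) {
      room <- target - length(acc)
      if (room <= 0) break
      k <- min(sample(per_group, 1), length(groups[[g]]), room)
      acc <- c(acc, sample(groups[[g]], k))
    }
    if (length(acc) < smin || length(acc) > smax) next
    key <- paste(sort(acc), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    profiles[[length(profiles) + 1]] <- sort(acc)
  }
  if (length(profiles) < n_profiles) {
    stop(sprintf(
      "could only build %d distinct profiles in %d tries (requested %d)",
      length(profiles), max_tries, n_profiles))
  }
  names(profiles) <- sprintf("P%d", seq_along(profiles))
  profiles
}

#' Fit a supervised principal-component risk model
#'
#' The supervision is the preceding survival screen: given the screened
#' proteins, their rows are standardized by training mean/SD, the first
#' right singular vector of the samples x proteins submatrix becomes
#' the loading vector (unit L2 norm), and each sample's risk score is
#' the inner product of loading and standardized profile. The loading
#' sign is fixed so that higher score means higher hazard (Cox beta of
#' the score >= 0; if the score carries no hazard information the sign
#' makes the first loading coordinate positive). The cutoff is set *a
#' priori* as a rank quantile of the training scores: with
#' `cutoff_fraction = f` and `n` samples, the `ceiling(f * n)`-th
#' smallest score is the last low-risk sample.
#'
#' @param m a processed [quant_matrix].
#' @param proteins >= 2 screened protein ids.
#' @param clin a [clinical_table].
#' @param cutoff_fraction low-risk fraction of the a-priori split
#'   (0.5 for 50:50, 0.7 for 70:30).
#' @param ties Cox tie handling for the orientation fit.
#' @return An object of class `signature_model`.
#' @export
fit_supervised_pc <- function(m, proteins, clin, cutoff_fraction = 0.5,
                              ties = "efron") {
  stopifnot(inherits(m, "quant_matrix"))
  if (length(proteins) < 2) stop("need at least 2 proteins")
  if (!all(proteins %in% protein_ids(m))) {
    stop("missing protein(s): ",
         paste(setdiff(proteins, protein_ids(m)), collapse = ", "))
  }
  sub <- m$values[proteins, , drop = FALSE]
  mom <- row_moments(sub)
  if (any(is.na(mom$sd) | mom$sd == 0)) {
    stop("zero-variance protein(s) in profile: ",
         paste(proteins[is.na(mom$sd) | mom$sd == 0], collapse = ", "))
  }
  z <- (sub - mom$mean) / mom$sd           # proteins x samples
  cl <- align_clinical(clin, sample_ids(m))
  # risk-align each protein before the SVD: when survivors span several
  # independent correlation groups mixing up- and down-regulated
  # proteins, the raw first PC can be a between-group contrast
  # orthogonal to hazard; flipping rows by the sign of their univariate
  # Cox coefficient keeps one component pointed at risk. The signs fold
  # into the stored loading, so downstream scoring is unchanged.
  uni <- cox_fit_many(t(z), cl$time, cl$event, ties = ties)
  signs <- ifelse(!is.na(uni$beta) & uni$beta < 0, -1, 1)
  sv <- svd(t(z * signs))                  # samples x proteins
  if (sv$d[1] < 1e-12) stop("degenerate (rank-0) profile submatrix")
  loading <- signs * sv$v[, 1]
  scores <- drop(t(z) %*% loading)
  fit <- cox_fit(scores, cl$time, cl$event, ties = ties)
  beta_score <- if (fit$flagged) NA_real_ else fit$beta
  if (!is.na(beta_score) && beta_score != 0) {
    if (beta_score < 0) {
      loading <- -loading; scores <- -scores; beta_score <- -beta_score
    }
  } else if (loading[1] < 0) {
    loading <- -loading; scores <- -scores
  }
  n <- length(scores)
  k <- ceiling(cutoff_fraction * n)
  cutoff_value <- if (k >= 1) unname(sort(scores)[min(k, n)]) else -Inf
  model <- list(protein_ids = proteins,
                train_means = stats::setNames(mom$mean, proteins),
                train_sds = stats::setNames(mom$sd, proteins),
                loading = stats::setNames(loading, proteins),
                cox_beta_on_score = beta_score,
                cutoff_fraction = cutoff_fraction,
                cutoff_value = cutoff_value,
                n_train = n)
  class(model) <- "signature_model"
  model
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d proteins [%s]\n", length(x$protein_ids),
              paste(x$protein_ids, collapse = ", ")))
  cat(sprintf("  cutoff: fraction %.2f low-risk, score threshold %.4f\n",
              x$cutoff_fraction, x$cutoff_value))
  cat(sprintf("  Cox beta on training score: %.4f\n", x$cox_beta_on_score))
  invisible(x)
}

# score samples of a quant_matrix (or plain matrix) with a frozen model
score_with_model <- function(model, values, means = model$train_means,
                             sds = model$train_sds) {
  miss <- setdiff(model$protein_ids, rownames(values))
  if (length(miss) > 0) {
    stop("matrix lacks model protein(s): ", paste(miss, collapse = ", "))
  }
  sub <- values[model$protein_ids, , drop = FALSE]
  if (anyNA(sub)) stop("missing values among model proteins")
  z <- (sub - means) / sds
  drop(t(z) %*% model$loading[model$protein_ids])
}

#' Assign risk groups with a frozen signature model
#'
#' Standardizes with the model's frozen training means/SDs, scores, and
#' thresholds at the frozen cutoff value. A score strictly greater than
#' the cutoff is high-risk; a score exactly at the cutoff is low-risk
#' (boundary convention).
#'
#' @param model a [signature_model].
#' @param m a [quant_matrix] containing all model proteins.
#' @return A `data.frame` of class `risk_assignment` with columns
#'   `sample`, `score`, `group` (factor low/high).
#' @export
assign_risk <- function(model, m) {
  values <- if (inherits(m, "quant_matrix")) m$values else as.matrix(m)
  scores <- score_with_model(model, values)
  grp <- factor(ifelse(scores > model$cutoff_value, "high", "low"),
                levels = c("low", "high"))
  out <- data.frame(sample = colnames(values), score = scores,
                    group = grp, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_assignment", "data.frame")
  out
}

#' Leave-one-out cross-validated risk groups
#'
#' Honest LOOCV of the full discovery pipeline: for each held-out
#' sample the screen is re-run on the remaining samples (the protein
#' list is refit), the supervised-PC model and its cutoff are refit,
#' and the held-out sample is assigned with the fold's frozen
#' constants. Folds with zero events, or where fewer than two proteins
#' pass the screen, are flagged `NA`.
#'
#' @param m a processed [quant_matrix].
#' @param clin a [clinical_table].
#' @param alpha screening threshold inside each fold.
#' @param cutoff_fraction low-risk fraction of the a-priori split.
#' @param ties Cox tie handling.
#' @return A `data.frame` (`sample`, `score`, `group`) of class
#'   `risk_assignment`; flagged folds carry `NA`.
#' @export
loocv_risk <- function(m, clin, alpha = 0.01, cutoff_fraction = 0.5,
                       ties = "efron") {
  ids <- sample_ids(m)
  n <- length(ids)
  if (n < 3) stop("need at least 3 samples for LOOCV")
  cl <- align_clinical(clin, ids)
  score <- rep(NA_real_, n)
  grp <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    keep <- ids[-i]
    if (sum(cl$event[-i]) == 0) next  # zero-event fold
    sub <- subset_quant(m, samples = keep)
    scr <- tryCatch(screen_proteins(sub, clin, alpha = alpha, ties = ties),
                    error = function(e) NULL)
    if (is.null(scr) || nrow(scr) < 2) next
    fold_model <- tryCatch(
      fit_supervised_pc(sub, scr$protein_id, clin,
                        cutoff_fraction = cutoff_fraction, ties = ties),
      error = function(e) NULL)
    if (is.null(fold_model)) next
    s_i <- score_with_model(fold_model,
                            m$values[, i, drop = FALSE])
    score[i] <- s_i
    grp[i] <- if (s_i > fold_model$cutoff_value) "high" else "low"
  }
  out <- data.frame(sample = ids, score = score,
                    group = factor(grp, levels = c("low", "high")),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("risk_assignment", "data.frame")
  out
}

#' Permutation p-value for a survival-split statistic
#'
#' Permutes the (time, event) pairs jointly against the samples `B`
#' times, re-runs the full model-fitting closure on each permuted
#' outcome, and returns the add-one permutation p-value
#' `(1 + #{permuted statistic >= observed}) / (B + 1)`.
#'
#' @param observed the observed statistic (e.g. log-rank chi-square).
#' @param fit_fun closure taking a permuted [clinical_table] and
#'   returning the statistic (return 0 for a degenerate refit).
#' @param clin the observed [clinical_table].
#' @param B number of permutations (default 1000).
#' @return The permutation p-value. Uses the ambient RNG stream.
#' @export
permutation_pvalue <- function(observed, fit_fun, clin, B = 1000L) {
  if (B < 1) stop("B must be >= 1")
  n <- nrow(clin)
  count <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    perm <- clin
    perm$time <- clin$time[idx]
    perm$event <- clin$event[idx]
    stat <- fit_fun(perm)
    if (!is.na(stat) && stat >= observed) count <- count + 1L
  }
  (1 + count) / (B + 1)
}

# Fit-split-test closure used by discovery permutation tests: screen,
# fit supervised PC on the survivors (or a fixed profile), split, and
# return the log-rank chi-square of the split (0 when degenerate).
discovery_statistic <- function(m, clin, alpha = 0.01,
                                cutoff_fraction = 0.5, proteins = NULL,
                                ties = "efron") {
  prots <- proteins
  if (is.null(prots)) {
    scr <- tryCatch(screen_proteins(m, clin, alpha = alpha, ties = ties),
                    error = function(e) NULL)
    if (is.null(scr) || nrow(scr) < 2) return(0)
    prots <- scr$protein_id
  }
  model <- tryCatch(
    fit_supervised_pc(m, prots, clin, cutoff_fraction = cutoff_fraction,
                      ties = ties),
    error = function(e) NULL)
  if (is.null(model)) return(0)
  assign <- assign_risk(model, m)
  cl <- align_clinical(clin, assign$sample)
  lowi <- assign$group == "low"
  if (all(lowi) || !any(lowi)) return(0)
  lr <- logrank_test(cl$time[lowi], cl$event[lowi],
                     cl$time[!lowi], cl$event[!lowi])
  if (is.na(lr$chi2)) 0 else lr$chi2
}

#' Serialize a signature model to JSON
#'
#' Numeric fields are written at full precision so that a frozen model
#' applied after a round-trip yields bit-identical scores.
#'
#' @param model a [signature_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a signature model from JSON
#' @param path path written by [write_signature_model()].
#' @return A [signature_model].
#' @export
read_signature_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("train_means", "train_sds", "loading")) {
    # JSON arrays carry no names; rebind to the protein order
    raw[[f]] <- stats::setNames(as.numeric(raw[[f]]), raw$protein_ids)
  }
  class(raw) <- "signature_model"
  raw
}
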