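# Parametric empirical-Bayes batch correction (ComBat-style
# location/scale adjustment), no covariates, no reference batch.

#' Empirical-Bayes batch correction
#'
#' Removes additive and multiplicative batch effects from a complete
#' features x samples matrix by the parametric empirical-Bayes
#' location/scale method: standardize each feature against the
#' batch-size-weighted grand mean and pooled variance, estimate
#' per-batch location (`gamma`) and scale (`delta^2`) effects, shrink
#' them toward batch-level normal / inverse-gamma priors by an
#' iterative conditional solution, remove the shrunken effects, and
#' restore the original scale.
#'
#' @param x complete numeric matrix, features in rows, samples in
#'   columns.
#' @param batch factor/character of batch labels, one per column; every
#'   batch needs at least 2 samples.
#' @param tol relative convergence tolerance of the EB iteration.
#' @return The adjusted matrix. With a single batch the input is
#'   returned unchanged (with a message).
#' @export
combat_correct <- function(x, batch, tol = 1e-4) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("combat_correct requires a complete matrix")
  batch <- droplevels(as.factor(batch))
  if (length(batch) != ncol(x)) stop("one batch label per sample required")
  if (nlevels(batch) == 1) {
    message("single batch: returning input unchanged")
    return(x)
  }
  nb <- table(batch)
  if (any(nb < 2)) {
    stop("every batch needs >= 2 samples; too small: ",
         paste(names(nb)[nb < 2], collapse = ", "))
  }
  n <- ncol(x)
  batches <- levels(batch)
  idx <- lapply(batches, function(b) which(batch == b))

  # per-feature batch means and the weighted grand mean
  bmean <- vapply(idx, function(j) rowMeans(x[, j, drop = FALSE]),
                  numeric(nrow(x)))
  w <- as.numeric(nb) / n
  grand <- as.numeric(bmean %*% w)
  fitted <- bmean[, as.integer(batch), drop = FALSE]
  var_pooled <- rowSums((x - fitted)^2) / n
  if (any(var_pooled == 0)) {
    stop("zero pooled variance for feature(s): ",
         paste(rownames(x)[var_pooled == 0], collapse = ", "))
  }
  z <- (x - grand) / sqrt(var_pooled)

  out <- z
  for (k in seq_along(batches)) {
    j <- idx[[k]]
    zb <- z[, j, drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- apply(zb, 1, stats::var)
    # hyperpriors: normal on gamma, inverse-gamma on delta^2
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    nk <- length(j)
    g_new <- g_hat; d_new <- d_hat
    repeat {
      g_old <- g_new; d_old <- d_new
      g_new <- (nk * t2 * g_hat + d_new * g_bar) / (nk * t2 + d_new)
      sse <- rowSums((zb - g_new)^2)
      d_new <- (b_prior + 0.5 * sse) / (nk / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      if (change < tol) break
    }
    out[, j] <- (zb - g_new) / sqrt(d_new)
  }
  out * sqrt(var_pooled) + grand
}
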