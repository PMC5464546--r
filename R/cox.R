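# Cox proportional-hazards machinery, written against the partial
# likelihood directly: a general Newton-Raphson fitter for small
# multivariate models and a column-vectorized single-covariate fitter
# for the per-protein screen (thousands of fits share the risk-set
# bookkeeping of one outcome vector).

# Precompute sort order and tied-event groups for an outcome.
cox_layout <- function(time, event) {
  stopifnot(length(time) == length(event))
  ord <- order(time, -event)  # within a tied time, events first (cosmetic)
  time <- time[ord]; event <- as.integer(event[ord])
  ev_idx <- which(event == 1)
  if (length(ev_idx) == 0) stop("zero events: Cox model undefined")
  ev_times <- unique(time[ev_idx])
  groups <- lapply(ev_times, function(tt) {
    list(deaths = which(time == tt & event == 1),
         risk_start = match(TRUE, time >= tt))  # first index in risk set
  })
  list(ord = ord, time = time, event = event, groups = groups,
       n_events = length(ev_idx))
}

# reverse cumulative sums down the rows of a matrix (risk-set sums)
rev_cumsum_mat <- function(m) {
  n <- nrow(m)
  if (n == 1) return(m)
  cs <- apply(m[n:1, , drop = FALSE], 2, cumsum)
  cs[n:1, , drop = FALSE]
}

#' Fit univariate Cox models for many covariates at once
#'
#' Maximizes the Cox partial likelihood (Efron or Breslow tie handling)
#' by Newton-Raphson independently for each column of `X`, sharing the
#' risk-set layout of the common outcome. Used by the per-protein
#' screen.
#'
#' @param X numeric matrix, samples in rows, covariates in columns.
#' @param time,event survival outcome.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Newton-Raphson convergence tolerance on the step size.
#' @param maxit maximum iterations.
#' @return A data.frame with one row per column: `beta`, `se`, `hr`,
#'   `p` (Wald vs chi-square(1)), `n_events`, `flagged` (`TRUE` for
#'   non-convergence, monotone likelihood, or an uninformative
#'   covariate; such rows carry `NA` estimates).
#' @export
cox_fit_many <- function(X, time, event, ties = c("efron", "breslow"),
                         tol = 1e-8, maxit = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  lay <- cox_layout(time, event)
  Xs <- X[lay$ord, , drop = FALSE]
  p <- ncol(Xs)
  beta <- rep(0, p)
  flagged <- rep(FALSE, p)
  info <- rep(NA_real_, p)
  for (it in seq_len(maxit)) {
    eta <- sweep(Xs, 2, beta, "*")
    eta <- pmin(pmax(eta, -500), 500)
    W <- exp(eta)
    XW <- Xs * W
    X2W <- Xs * XW
    R0 <- rev_cumsum_mat(W)
    R1 <- rev_cumsum_mat(XW)
    R2 <- rev_cumsum_mat(X2W)
    U <- rep(0, p); I <- rep(0, p)
    for (g in lay$groups) {
      d <- length(g$deaths)
      s0r <- R0[g$risk_start, ]; s1r <- R1[g$risk_start, ]
      s2r <- R2[g$risk_start, ]
      if (d == 1) {
        U <- U + Xs[g$deaths, ] - s1r / s0r
        I <- I + s2r / s0r - (s1r / s0r)^2
      } else {
        s0t <- colSums(W[g$deaths, , drop = FALSE])
        s1t <- colSums(XW[g$deaths, , drop = FALSE])
        s2t <- colSums(X2W[g$deaths, , drop = FALSE])
        xsum <- colSums(Xs[g$deaths, , drop = FALSE])
        U <- U + xsum
        for (l in seq_len(d) - 1L) {
          fr <- if (ties == "efron") l / d else 0
          s0 <- s0r - fr * s0t; s1 <- s1r - fr * s1t; s2 <- s2r - fr * s2t
          U <- U - s1 / s0
          I <- I + s2 / s0 - (s1 / s0)^2
        }
      }
    }
    dead <- !is.finite(U) | !is.finite(I) | I <= 1e-12
    flagged <- flagged | dead
    step <- ifelse(flagged, 0, U / pmax(I, 1e-12))
    step <- pmin(pmax(step, -2), 2)   # damp huge early steps
    beta <- beta + step
    info <- I
    if (all(abs(step) < tol)) break
  }
  flagged <- flagged | abs(beta) > 15 | !is.finite(beta) |
    abs(if (exists("step")) step else 0) >= tol * 10
  se <- sqrt(1 / info)
  z2 <- (beta / se)^2
  pval <- stats::pchisq(z2, df = 1, lower.tail = FALSE)
  beta[flagged] <- NA_real_; se[flagged] <- NA_real_
  pval[flagged] <- NA_real_
  data.frame(beta = beta, se = se, hr = exp(beta), p = pval,
             n_events = lay$n_events, flagged = flagged,
             row.names = colnames(X))
}

#' Fit a univariate Cox proportional-hazards model
#'
#' Single-covariate Newton-Raphson maximization of the Cox partial
#' likelihood; the p-value is the Wald statistic `(beta/se)^2` against
#' chi-square(1). A monotone partial likelihood (separation) or an
#' uninformative covariate yields a flagged result with `NA`
#' estimates, never an error.
#'
#' @param x numeric covariate, one value per sample.
#' @param time,event survival outcome (at least one event required).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A list `(beta, se, hr, p, n_events, flagged)`.
#' @export
cox_fit <- function(x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  res <- cox_fit_many(matrix(x, ncol = 1), time, event, ties = ties)
  out <- as.list(res[1, , drop = TRUE])
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$flagged) {
    cat("cox_fit: flagged (separation or uninformative covariate)\n")
  } else {
    cat(sprintf("cox_fit: beta = %.4f (se %.4f), HR = %.4f, p = %.4g [%d events]\n",
                x$beta, x$se, x$hr, x$p, x$n_events))
  }
  invisible(x)
}

# --- general multivariate fitter ----------------------------------------

# Partial log-likelihood, score and information at beta for an n x p
# design (small p). Returns list(loglik, U, I).
cox_derivatives <- function(Xs, lay, beta, ties) {
  eta <- drop(Xs %*% beta)
  eta <- pmin(pmax(eta, -500), 500)
  w <- exp(eta)
  p <- ncol(Xs)
  ll <- 0; U <- rep(0, p); I <- matrix(0, p, p)
  n <- nrow(Xs)
  # suffix sums of w, w*x, w*x x^T
  s0 <- rev(cumsum(rev(w)))
  s1 <- apply(Xs * w, 2, function(col) rev(cumsum(rev(col))))
  s1 <- matrix(s1, nrow = n)
  for (g in lay$groups) {
    d <- length(g$deaths)
    rs <- g$risk_start
    risk <- rs:n
    s0r <- s0[rs]
    s1r <- s1[rs, ]
    S2r <- crossprod(Xs[risk, , drop = FALSE] * w[risk],
                     Xs[risk, , drop = FALSE])
    xd <- Xs[g$deaths, , drop = FALSE]
    ll <- ll + sum(eta[g$deaths])
    U <- U + colSums(xd)
    if (d == 1) {
      xb <- s1r / s0r
      ll <- ll - log(s0r)
      U <- U - xb
      I <- I + S2r / s0r - tcrossprod(xb)
    } else {
      s0t <- sum(w[g$deaths])
      s1t <- colSums(Xs[g$deaths, , drop = FALSE] * w[g$deaths])
      S2t <- crossprod(xd * w[g$deaths], xd)
      for (l in seq_len(d) - 1L) {
        fr <- if (ties == "efron") l / d else 0
        s0l <- s0r - fr * s0t
        s1l <- s1r - fr * s1t
        S2l <- S2r - fr * S2t
        xb <- s1l / s0l
        ll <- ll - log(s0l)
        U <- U - xb
        I <- I + S2l / s0l - tcrossprod(xb)
      }
    }
  }
  list(loglik = ll, U = U, I = I)
}

#' Fit a multivariate Cox proportional-hazards model
#'
#' Newton-Raphson with step-halving on the Efron (or Breslow) partial
#' likelihood. Factors in `covariates` are expanded to treatment
#' indicators against their first level (so `T1` / `N0` act as the
#' reference stage when levels are in natural order). Rank-deficient
#' designs are an error naming the aliased columns.
#'
#' @param covariates data.frame (factors and numerics) or numeric
#'   matrix of per-sample covariates.
#' @param time,event survival outcome.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol,maxit Newton-Raphson controls.
#' @return A data.frame with one row per coefficient: `beta`, `se`,
#'   `hr`, `ci_low`, `ci_high` (95% normal on log HR), `p` (Wald).
#' @export
cox_multivariate <- function(covariates, time, event,
                             ties = c("efron", "breslow"),
                             tol = 1e-8, maxit = 50L) {
  ties <- match.arg(ties)
  if (is.data.frame(covariates)) {
    X <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  } else {
    X <- as.matrix(covariates)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    stop("constant (inestimable) column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  lay <- cox_layout(time, event)
  Xs <- X[lay$ord, , drop = FALSE]
  p <- ncol(Xs)
  beta <- rep(0, p)
  der <- cox_derivatives(Xs, lay, beta, ties)
  for (it in seq_len(maxit)) {
    step <- tryCatch(solve(der$I, der$U), error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix")
    beta_new <- beta + step
    der_new <- cox_derivatives(Xs, lay, beta_new, ties)
    halvings <- 0
    while (der_new$loglik < der$loglik && halvings < 20) {
      step <- step / 2
      beta_new <- beta + step
      der_new <- cox_derivatives(Xs, lay, beta_new, ties)
      halvings <- halvings + 1
    }
    converged <- max(abs(step)) < tol
    beta <- beta_new; der <- der_new
    if (converged) break
  }
  if (max(abs(beta)) > 15) {
    warning("possible monotone likelihood (separation); estimates unstable")
  }
  se <- sqrt(diag(solve(der$I)))
  z <- beta / se
  data.frame(beta = beta, se = se, hr = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             p = stats::pchisq(z^2, 1, lower.tail = FALSE),
             row.names = colnames(X))
}

# Score test of a single covariate at beta = 0 (equals the log-rank
# statistic for a binary group indicator on tie-free data).
cox_score_test <- function(x, time, event, ties = "efron") {
  lay <- cox_layout(time, event)
  Xs <- matrix(x[lay$ord], ncol = 1)
  der <- cox_derivatives(Xs, lay, 0, ties)
  chi2 <- der$U^2 / der$I[1, 1]
  list(chi2 = as.numeric(chi2),
       p = stats::pchisq(as.numeric(chi2), 1, lower.tail = FALSE))
}
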