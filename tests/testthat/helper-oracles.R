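# Shared test fixtures and independent oracles. The oracles are kept
# deliberately naive (direct double loops, brute-force grids) so they
# share no code path with the implementation they check.

# Breslow partial log-likelihood by direct summation (tie-free data:
# identical to Efron). Independent of the package's fitter.
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Brute-force grid argmax of the partial likelihood: coarse bracket,
# then a fine grid inside it.
oracle_cox_argmax <- function(x, time, event, lim = 16, fine = 1e-5) {
  coarse <- seq(-lim, lim, by = 0.01)
  ll <- vapply(coarse, oracle_cox_loglik, numeric(1),
               x = x, time = time, event = event)
  b0 <- coarse[which.max(ll)]
  grid <- seq(b0 - 0.02, b0 + 0.02, by = fine)
  ll2 <- vapply(grid, oracle_cox_loglik, numeric(1),
                x = x, time = time, event = event)
  grid[which.max(ll2)]
}

# 2-D brute-force argmax for the multivariate fitter check.
oracle_cox_argmax2 <- function(X, time, event, lim = 4, step = 0.05) {
  grid <- seq(-lim, lim, by = step)
  best <- c(NA, NA); best_ll <- -Inf
  ll2 <- function(b) {
    ll <- 0
    eta <- X %*% b
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
    ll
  }
  for (b1 in grid) for (b2 in grid) {
    v <- ll2(c(b1, b2))
    if (v > best_ll) { best_ll <- v; best <- c(b1, b2) }
  }
  # refine once around the winner
  fine1 <- seq(best[1] - step, best[1] + step, by = step / 25)
  fine2 <- seq(best[2] - step, best[2] + step, by = step / 25)
  for (b1 in fine1) for (b2 in fine2) {
    v <- ll2(c(b1, b2))
    if (v > best_ll) { best_ll <- v; best <- c(b1, b2) }
  }
  best
}

# tiny quant matrix builder with full control of mask and peptides
toy_quant <- function(values, missing = NULL, peptides = NULL,
                      batch = NULL, scale = "raw") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  quant_matrix(values, missing,
               peptides %||% rep(3L, nrow(values)), batch, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small planted cohort with complete data, used across signature tests
quick_cohort <- function(seed, n = 60, p = 40, planted = 8,
                         beta = 0.8, block = 5) {
  spec <- sim_spec(n_samples = n, n_proteins = p, n_prognostic = planted,
                   beta_per_sd = beta, missing_intercept = -Inf,
                   batch_shift = 0, corr_block_size = block, seed = seed)
  co <- simulate_cohort(spec)
  co$processed <- zscore(log2_transform(co$quant))
  co
}
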