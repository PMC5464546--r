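# Synthetic cohort generation: log-intensity matrices with
# intensity-dependent (left-censored) missingness, additive batch
# effects, correlated protein blocks, and a planted prognostic protein
# set whose latent score drives an exponential hazard.

#' Specification of a synthetic proteomics survival cohort
#'
#' Captures the stochastic model the discovery analysis assumes:
#' proteins live in equicorrelated blocks on the log2 scale; a small
#' planted set drives an exponential event hazard through its latent
#' score; censoring is independent exponential; missingness is missing
#' not-at-random with logistic probability decreasing in intensity
#' (label-free left-censoring); batches add a constant log2 offset
#' before masking.
#'
#' Defaults emulate a discovery-scale label-free experiment: log2 LFQ
#' means uniform on 20-30, unit within-protein SD, blocks of 10
#' proteins at rho = 0.6, a 0.7 log-hazard per latent SD, and event and
#' censor rates that give roughly half the cohort an event.
#'
#' @param n_samples,n_proteins cohort dimensions.
#' @param n_prognostic number of planted prognostic proteins (the first
#'   `n_prognostic` rows).
#' @param beta_per_sd marginal log hazard ratio per 1 SD of a planted
#'   protein; 0 gives a null cohort. Internally the latent-score
#'   coefficient is scaled up by the mean protein-latent correlation so
#'   this per-protein effect size holds despite correlation
#'   attenuation.
#' @param baseline_hazard,censor_rate exponential rates, events/year.
#' @param missing_intercept,missing_slope logistic MNAR parameters:
#'   an entry of log2 intensity `x` is masked with probability
#'   `plogis(missing_intercept - missing_slope * x)`. Set
#'   `missing_intercept = -Inf` (or slope 0 with intercept `-Inf`) for
#'   complete data.
#' @param batch_shift additive log2 offset applied to every batch after
#'   the first; `n_batches` batches are interleaved over samples.
#' @param corr_block_size,corr_rho size and equicorrelation of the
#'   null-protein blocks; `corr_rho` is also the within-block
#'   correlation of the planted blocks.
#' @param n_signal_blocks number of correlation blocks the planted
#'   proteins form (default 2, so correlation grouping has several
#'   prognostic groups to find).
#' @param signal_cross_rho correlation between planted proteins in
#'   different signal blocks — their shared loading on the latent
#'   factor. Must satisfy `signal_cross_rho <= corr_rho`; the default
#'   0.25 keeps distinct blocks below the grouping threshold while
#'   every planted protein still reads out the latent.
#' @param mean_range range of per-protein log2 mean abundances.
#' @param protein_sd within-protein marginal SD (log2 units).
#' @param peptide_lambda Poisson rate for `unique_peptides - 1`.
#' @param seed integer seed; the generator is fully deterministic given
#'   (spec, seed).
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 150L, n_proteins = 1000L,
                     n_prognostic = 20L, beta_per_sd = 0.7,
                     baseline_hazard = 0.1, censor_rate = 0.1,
                     missing_intercept = 20, missing_slope = 1.0,
                     batch_shift = 0.5, n_batches = 2L,
                     corr_block_size = 10L, corr_rho = 0.6,
                     n_signal_blocks = 2L, signal_cross_rho = NULL,
                     mean_range = c(20, 30), protein_sd = 1.0,
                     peptide_lambda = 5, seed = NULL) {
  if (is.null(signal_cross_rho)) signal_cross_rho <- min(0.25, corr_rho)
  spec <- as.list(environment())
  if (n_prognostic > n_proteins) stop("n_prognostic must be <= n_proteins")
  if (baseline_hazard <= 0 || censor_rate <= 0) stop("rates must be > 0")
  if (corr_rho < 0 || corr_rho >= 1) stop("corr_rho must be in [0, 1)")
  if (signal_cross_rho < 0 || signal_cross_rho > corr_rho) {
    stop("signal_cross_rho must lie in [0, corr_rho]")
  }
  if (n_samples < 2) stop("need at least 2 samples")
  class(spec) <- "sim_spec"
  spec
}

#' Simulate a proteomics survival cohort
#'
#' Draws log2 intensities with a factor structure, adds batch shifts,
#' applies intensity-dependent masking, and generates survival times as
#' the minimum of an exponential event time and an independent
#' exponential censoring time.
#'
#' The prognostic structure follows the factor model that supervised
#' principal components assumes: a standard-normal latent score `u`
#' drives the hazard (`baseline_hazard * exp(b * u)`), and each planted
#' protein is a noisy readout of `u`. Planted proteins form
#' `n_signal_blocks` correlation blocks with within-block correlation
#' `corr_rho` and cross-block correlation `signal_cross_rho` (their
#' shared loading on `u`), so correlation grouping finds several
#' distinct prognostic groups. The latent coefficient `b` is
#' `beta_per_sd` divided by each planted protein's correlation with
#' `u`, making `beta_per_sd` the marginal per-protein effect exactly as
#' stated. Null proteins live in independent equicorrelated blocks. The
#' returned quantification matrix is on the raw intensity scale
#' (`2^log2`), so the full preprocessing chain applies unchanged.
#'
#' Common random numbers are used for the event/censor exponentials:
#' for a fixed seed, raising `baseline_hazard` can only convert
#' censored samples to events, making the event fraction monotone in
#' the baseline hazard.
#'
#' @param spec a [sim_spec].
#' @return A list with `quant` ([quant_matrix], raw scale), `clinical`
#'   ([clinical_table]), and `truth` (planted protein ids, latent
#'   scores, true log2 levels of the planted proteins, per-sample
#'   peptide totals).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    p <- spec$n_proteins
    prot <- sprintf("SYN%04d", seq_len(p))
    samp <- sprintf("S%03d", seq_len(n))

    mu <- stats::runif(p, spec$mean_range[1], spec$mean_range[2])
    k <- spec$n_prognostic
    latent <- stats::rnorm(n)
    e <- matrix(stats::rnorm(p * n), p, n)
    x <- matrix(0, p, n, dimnames = list(prot, samp))

    # planted proteins: noisy readouts of the latent, arranged in
    # n_signal_blocks blocks (within-block corr corr_rho, cross-block
    # corr signal_cross_rho = shared latent loading)
    attenuation <- 1
    if (k > 0) {
      nsb <- max(1L, min(spec$n_signal_blocks, k))
      a <- if (nsb == 1) spec$corr_rho else spec$signal_cross_rho
      sblock <- rep(seq_len(nsb), length.out = k)
      fs <- matrix(stats::rnorm(nsb * n), nsb, n)
      x[1:k, ] <- spec$protein_sd *
        (sqrt(a) * rep(1, k) %o% latent +
           sqrt(spec$corr_rho - a) * fs[sblock, , drop = FALSE] +
           sqrt(1 - spec$corr_rho) * e[1:k, , drop = FALSE])
      attenuation <- sqrt(a)
      if (spec$beta_per_sd != 0 && attenuation == 0) {
        stop("a prognostic signal requires corr_rho > 0 (planted ",
             "proteins must correlate with the latent score)")
      }
    }

    # null proteins: independent equicorrelated blocks
    if (p > k) {
      idx <- (k + 1):p
      block <- ((idx - k - 1) %/% spec$corr_block_size) + 1
      nb <- max(block)
      f <- matrix(stats::rnorm(nb * n), nb, n)
      x[idx, ] <- spec$protein_sd *
        (sqrt(spec$corr_rho) * f[block, , drop = FALSE] +
           sqrt(1 - spec$corr_rho) * e[idx, , drop = FALSE])
    }
    x <- x + mu

    planted <- prot[seq_len(k)]
    b_latent <- if (spec$beta_per_sd == 0) 0 else
      spec$beta_per_sd / attenuation
    hazard <- spec$baseline_hazard * exp(b_latent * latent)
    e_std <- stats::rexp(n)        # common random numbers: shared across
    c_std <- stats::rexp(n)        # hazard settings under one seed
    t_event <- e_std / hazard
    t_cens <- c_std / spec$censor_rate
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    if (mean(event) < 0.05) {
      warning("degenerate spec: fewer than 5% of samples have events")
    }

    batch <- factor(sprintf("B%d", ((seq_len(n) - 1) %% spec$n_batches) + 1))
    shift <- spec$batch_shift * (as.integer(batch) - 1)
    x_obs <- sweep(x, 2, shift, "+")

    pmiss <- stats::plogis(spec$missing_intercept -
                             spec$missing_slope * x_obs)
    mask <- matrix(stats::runif(p * n) < pmiss, p, n,
                   dimnames = dimnames(x))

    unique_peptides <- 1L + stats::rpois(p, spec$peptide_lambda)
    # per-sample identified-peptide totals (outlier-rule input):
    # sum of peptide counts over detected proteins
    pep_totals <- colSums(unique_peptides * !mask)

    vals <- 2^x_obs
    vals[mask] <- NA_real_
    quant <- quant_matrix(vals, mask, unique_peptides, batch, scale = "raw")
    clin <- clinical_table(samp, time, event,
                           t_stage = sample(c("T1", "T2", "T3"), n, TRUE,
                                            prob = c(0.19, 0.73, 0.08)),
                           n_stage = sample(c("N1", "N2"), n, TRUE,
                                            prob = c(0.68, 0.32)))
    truth <- list(planted = planted, latent = latent,
                  log2_levels = x[planted, , drop = FALSE],
                  true_log2 = x, sample_peptide_counts = pep_totals,
                  masked_true = x_obs[mask])
    list(quant = quant, clinical = clin, truth = truth)
  })
}

#' Simulate a PRM transition-area table from a cohort's true levels
#'
#' For each monitored protein, generates isotope-labelled peptide
#' transitions: the light (endogenous) channel carries product-ion
#' areas proportional to `2^(protein log2 level)` times multiplicative
#' lognormal noise; the heavy (spiked reference) channel is constant
#' per peptide across samples. The summed-area log2 light/heavy ratio
#' therefore recovers the protein level up to a per-peptide offset,
#' exactly when `noise_sd = 0`.
#'
#' @param cohort result of [simulate_cohort()]; its `truth$log2_levels`
#'   provide the underlying protein levels.
#' @param n_peptides_per_protein peptides monitored per protein (1-4 in
#'   a typical assay).
#' @param noise_sd SD (log2 units) of the per-(peptide, sample)
#'   measurement noise.
#' @param proteins which proteins to monitor; defaults to the planted
#'   set.
#' @param seed integer seed.
#' @return A `data.frame` of class `transition_table` with columns
#'   `peptide`, `protein`, `sample`, `channel`, `ion`, `area`.
#' @export
simulate_prm_cohort <- function(cohort, n_peptides_per_protein = 3L,
                                noise_sd = 0.1, proteins = NULL,
                                seed = NULL) {
  levels2 <- cohort$truth$true_log2
  proteins <- proteins %||% cohort$truth$planted
  missing <- setdiff(proteins, rownames(levels2))
  if (length(missing) > 0) {
    stop("cohort has no true levels for protein(s): ",
         paste(missing, collapse = ", "))
  }
  levels2 <- levels2[proteins, , drop = FALSE]
  samp <- colnames(levels2)
  with_seed(seed, {
    rows <- list()
    for (pr in proteins) {
      lev <- levels2[pr, ] - mean(levels2[pr, ])  # centered level
      for (k in seq_len(n_peptides_per_protein)) {
        pep <- sprintf("%s_PEP%d", pr, k)
        n_ions <- sample(3:6, 1)
        ion_base <- stats::rlnorm(n_ions, meanlog = log(1e5), sdlog = 0.5)
        # heavy spike chosen near the endogenous scale (constant/sample)
        heavy_off <- stats::rnorm(1, 0, 0.5)
        noise <- stats::rnorm(length(samp), 0, noise_sd)
        for (j in seq_len(n_ions)) {
          light <- ion_base[j] * 2^(lev + noise)
          heavy <- rep(ion_base[j] * 2^heavy_off, length(samp))
          rows[[length(rows) + 1]] <- data.frame(
            peptide = pep, protein = pr, sample = samp,
            channel = rep(c("light", "heavy"), each = length(samp)),
            ion = sprintf("y%d", j + 2),
            area = c(light, heavy), stringsAsFactors = FALSE)
        }
      }
    }
    tt <- do.call(rbind, rows)
    rownames(tt) <- NULL
    class(tt) <- c("transition_table", "data.frame")
    validate_transition_table(tt)
    tt
  })
}

#' Simulate a probe-level transcriptomics cohort
#'
#' Maps the cohort's planted protein levels into array space: each gene
#' receives `n_probes_per_gene` probes with probe-specific offsets and
#' noise (so coefficient-of-variation probe selection has structure to
#' find), and ESR1 / ERBB2 marker genes are added with expression
#' spanning the triple-negative exclusion thresholds.
#'
#' @param cohort result of [simulate_cohort()].
#' @param n_probes_per_gene probes per gene.
#' @param esr1_range,erbb2_range uniform ranges for the marker genes'
#'   log2 expression; defaults straddle the 12 / 11.8 thresholds.
#' @param gene_map optional data.frame (accession, gene) mapping planted
#'   protein ids to gene symbols; unmapped accessions keep their id.
#' @param noise_sd probe-level noise SD (log2 units).
#' @param proteins which proteins to carry into array space; defaults
#'   to the planted set.
#' @param seed integer seed.
#' @return A list with `values` (probes x samples matrix), `map`
#'   (data.frame probe, gene), and `genes` (gene of each planted
#'   protein).
#' @export
simulate_array_cohort <- function(cohort, n_probes_per_gene = 2L,
                                  esr1_range = c(10.5, 13.5),
                                  erbb2_range = c(10.5, 12.5),
                                  gene_map = NULL, noise_sd = 0.3,
                                  proteins = NULL, seed = NULL) {
  levels2 <- cohort$truth$true_log2
  levels2 <- levels2[proteins %||% cohort$truth$planted, , drop = FALSE]
  samp <- colnames(levels2)
  n <- length(samp)
  acc <- rownames(levels2)
  genes <- acc
  if (!is.null(gene_map)) {
    hit <- match(acc, gene_map[[1]])
    genes[!is.na(hit)] <- gene_map[[2]][hit[!is.na(hit)]]
  }
  with_seed(seed, {
    gene_levels <- levels2 - rowMeans(levels2) + 8  # array log2 scale
    rownames(gene_levels) <- genes
    extra <- rbind(ESR1 = stats::runif(n, esr1_range[1], esr1_range[2]),
                   ERBB2 = stats::runif(n, erbb2_range[1], erbb2_range[2]))
    gl <- rbind(gene_levels, extra)
    probes <- list(); map <- list()
    for (g in rownames(gl)) {
      for (k in seq_len(n_probes_per_gene)) {
        pid <- sprintf("%s_at%d", g, k)
        off <- stats::rnorm(1, 0, 0.5)
        probes[[pid]] <- gl[g, ] + off + stats::rnorm(n, 0, noise_sd * k)
        map[[pid]] <- g
      }
    }
    values <- do.call(rbind, probes)
    colnames(values) <- samp
    list(values = values,
         map = data.frame(probe = names(map), gene = unlist(map),
                          row.names = NULL, stringsAsFactors = FALSE),
         genes = stats::setNames(genes, acc))
  })
}
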