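# Orchestration of the discovery and validation workflows, with run
# manifests that make every numeric output reproducible from
# (config, seed).

#' Run the full discovery workflow
#'
#' Executes preprocess -> screen -> correlation groups -> reduced
#' profiles -> supervised-PC fit per profile -> training split
#' evaluation -> permutation log-rank test, plus the all-survivors
#' signature with leave-one-out cross-validation. Everything after
#' preprocessing is driven by `config$rng_seed`, so a fixed
#' (config, seed) pair reproduces the report byte-for-byte.
#'
#' @param quant a raw-scale [quant_matrix].
#' @param clin a [clinical_table].
#' @param config a [default_config()] list.
#' @param run_loocv whether to cross-validate the all-survivors
#'   signature (the expensive honest-CV step).
#' @return A list of class `discovery_result`: `report` (one row per
#'   profile: composition, 5-year DMFS low/high, HR with CI, log-rank
#'   p, permutation p), `models`, `screen`, `groups`, `full_model`,
#'   `loocv`, `preprocess_report`, `manifest`.
#' @export
run_discovery <- function(quant, clin, config = default_config(),
                          run_loocv = TRUE) {
  stages <- list()
  with_seed(config$rng_seed, {
    pp <- preprocess_pipeline(quant, config)
    m <- pp$quant
    cl <- align_clinical(clin, sample_ids(m))
    stages$preprocess <- list(n_proteins = nrow(m$values),
                              n_samples = ncol(m$values))
    scr <- screen_proteins(m, cl, alpha = config$screen_alpha,
                           ties = config$ties)
    if (nrow(scr) < 2) {
      stop("screen stage: fewer than 2 proteins pass p < ",
           config$screen_alpha)
    }
    stages$screen <- list(n_selected = nrow(scr))
    groups <- correlation_groups(m, scr$protein_id,
                                 r_threshold = config$corr_threshold)
    stages$groups <- list(n_groups = length(groups))
    profiles <- sample_reduced_profiles(
      groups, size_range = config$profile_size_range,
      per_group = config$per_group, n_profiles = config$n_profiles)

    eval_profile <- function(name, prots) {
      model <- fit_supervised_pc(m, prots, cl,
                                 cutoff_fraction = config$cutoff_fraction,
                                 ties = config$ties)
      asg <- assign_risk(model, m)
      cmp <- group_comparison(asg, cl, ties = config$ties)
      # the all-survivors signature re-screens inside each permutation
      # (protects the selection step); a named reduced profile keeps its
      # composition and refits loadings/orientation/cutoff only
      perm_proteins <- if (name == "FULL") NULL else prots
      perm_p <- permutation_pvalue(
        cmp$logrank_chi2,
        function(perm) discovery_statistic(
          m, perm, alpha = config$screen_alpha,
          cutoff_fraction = config$cutoff_fraction,
          proteins = perm_proteins, ties = config$ties),
        cl, B = config$n_permutations)
      list(model = model,
           row = data.frame(
             profile = name,
             proteins = paste(prots, collapse = ";"),
             n_proteins = length(prots),
             n_low = cmp$n_low, n_high = cmp$n_high,
             dmfs5_low = cmp$dmfs_low, dmfs5_high = cmp$dmfs_high,
             hr = cmp$hr, ci_low = cmp$ci_low, ci_high = cmp$ci_high,
             logrank_p = cmp$logrank_p, perm_p = perm_p,
             stringsAsFactors = FALSE))
    }

    full <- eval_profile("FULL", scr$protein_id)
    evals <- lapply(names(profiles),
                    function(nm) eval_profile(nm, profiles[[nm]]))
    report <- do.call(rbind, c(list(full$row), lapply(evals, `[[`, "row")))
    models <- c(list(FULL = full$model),
                stats::setNames(lapply(evals, `[[`, "model"),
                                names(profiles)))
    loocv <- NULL
    if (run_loocv) {
      loocv <- loocv_risk(m, cl, alpha = config$screen_alpha,
                          cutoff_fraction = config$cutoff_fraction,
                          ties = config$ties)
    }
    out <- list(report = report, models = models, screen = scr,
                groups = groups, profiles = profiles,
                full_model = full$model, loocv = loocv,
                preprocess_report = pp$report,
                manifest = build_manifest(config, stages))
    class(out) <- "discovery_result"
    out
  })
}

#' Apply a frozen model to a validation platform
#'
#' Dispatches to [validate_prm()] (platform `"prm"`) or
#' [validate_transcriptomics()] (platform `"array"`). The model is
#' never refit: loadings and protein list are used frozen.
#'
#' @param model a frozen [signature_model].
#' @param data a proteins x samples matrix (PRM) or genes x samples
#'   matrix (array).
#' @param clin a [clinical_table] for the validation cohort.
#' @param platform `"prm"` or `"array"`.
#' @param cutoff_fraction low-risk fraction; defaults to 0.7 (70:30)
#'   for PRM and 0.5 (50:50) for arrays.
#' @param ... passed through to the platform validator.
#' @return A [group_comparison()] result.
#' @export
run_validation <- function(model, data, clin,
                           platform = c("prm", "array"),
                           cutoff_fraction = NULL, ...) {
  platform <- match.arg(platform)
  if (!inherits(model, "signature_model")) {
    stop("model must be a signature_model (platform/model mismatch?)")
  }
  if (platform == "prm") {
    validate_prm(model, data, clin,
                 cutoff_fraction = cutoff_fraction %||% 0.7, ...)
  } else {
    validate_transcriptomics(model, data, clin,
                             cutoff_fraction = cutoff_fraction %||% 0.5,
                             ...)
  }
}

build_manifest <- function(config, stages) {
  cfg_chr <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA)
  list(package = "tnbcsig",
       version = as.character(utils::packageVersion("tnbcsig")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = config$rng_seed,
       config = unclass(config),
       config_hash = fnv1a_hash(as.character(cfg_chr)),
       stages = stages)
}

#' Write a run manifest as JSON
#' @param manifest manifest list from a pipeline run.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a discovery report as a tab-separated table
#'
#' Byte-identical output for identical (config, seed) inputs: numbers
#' are formatted at full precision with a fixed locale-independent
#' format.
#'
#' @param result a `discovery_result` (or its `report` data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_discovery_report <- function(result, path) {
  df <- if (inherits(result, "discovery_result")) result$report else result
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("discovery_result: %d screened proteins, %d groups, %d profiles\n",
              nrow(x$screen), length(x$groups), length(x$profiles)))
  print(x$report[, c("profile", "n_proteins", "dmfs5_low", "dmfs5_high",
                     "hr", "logrank_p", "perm_p")], digits = 3)
  invisible(x)
}
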