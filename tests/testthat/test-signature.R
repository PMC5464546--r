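make_corr_quant <- function(Sigma, n = 500, seed = 77) {
  set.seed(seed)
  L <- chol(Sigma)
  x <- t(matrix(rnorm(n * nrow(Sigma)), n) %*% L)
  rownames(x) <- paste0("P", seq_len(nrow(Sigma)))
  colnames(x) <- paste0("S", seq_len(n))
  toy_quant(x, scale = "zscore")
}

test_that("correlation groups are connected components at r > threshold", {
  # perfectly correlated pair joins; independents stay singletons
  set.seed(3)
  base <- rnorm(200)
  x <- rbind(P1 = base, P2 = 2 * base, P3 = rnorm(200), P4 = rnorm(200))
  colnames(x) <- paste0("S", 1:200)
  m <- toy_quant(x, scale = "zscore")
  g <- correlation_groups(m, rownames(x), r_threshold = 0.5)
  sizes <- sort(lengths(g), decreasing = TRUE)
  expect_equal(unname(sizes), c(2L, 1L, 1L))
  expect_true(any(vapply(g, function(gr) setequal(gr, c("P1", "P2")),
                         logical(1))))
  # chain: r(1,2) = .6, r(2,3) = .6, r(1,3) = .1 -> one transitive group
  Sigma <- matrix(c(1, .6, .1, .6, 1, .6, .1, .6, 1), 3, 3)
  mc <- make_corr_quant(Sigma, n = 2000)
  gc <- correlation_groups(mc, paste0("P", 1:3))
  expect_equal(length(gc), 1L)
  expect_setequal(gc[[1]], paste0("P", 1:3))
})

test_that("reduced-profile sampling respects sizes, groups, determinism", {
  groups <- structure(list(G1 = "A", G2 = "B", G3 = "C"),
                      class = "correlation_groups")
  set.seed(1)
  forced <- sample_reduced_profiles(groups, size_range = c(3, 3),
                                    per_group = 1, n_profiles = 1)
  expect_setequal(forced[[1]], c("A", "B", "C"))
  big <- structure(split(sprintf("P%02d", 1:18),
                         rep(1:3, each = 6)),
                   class = "correlation_groups")
  set.seed(7)
  profs <- sample_reduced_profiles(big, n_profiles = 12)
  expect_equal(length(profs), 12L)
  expect_true(all(lengths(profs) >= 3 & lengths(profs) <= 7))
  keys <- vapply(profs, paste, character(1), collapse = "|")
  expect_equal(anyDuplicated(keys), 0L)
  # at most 2 proteins per correlation group in any profile
  for (pr in profs) {
    per <- table(rep(1:3, each = 6)[match(pr, sprintf("P%02d", 1:18))])
    expect_true(all(per <= 2))
  }
  set.seed(7)
  expect_identical(sample_reduced_profiles(big, n_profiles = 12), profs)
  expect_error(sample_reduced_profiles(groups, size_range = c(5, 7),
                                       per_group = 1),
               "infeasible")
})

test_that("supervised PC has the closed form on a correlated pair", {
  set.seed(11)
  base <- rnorm(60)
  x <- rbind(P1 = 5 + 2 * base, P2 = -3 + 0.5 * base)
  colnames(x) <- paste0("S", 1:60)
  m <- toy_quant(x, scale = "log2")
  cl <- clinical_table(colnames(x), rexp(60, 0.2) + 0.01,
                       rbinom(60, 1, 0.5))
  model <- fit_supervised_pc(m, c("P1", "P2"), cl)
  expect_equal(abs(unname(model$loading)), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
  z1 <- (x["P1", ] - mean(x["P1", ])) / sd(x["P1", ])
  expect_equal(abs(unname(score_vals <- assign_risk(model, m)$score)),
               sqrt(2) * abs(unname(z1)), tolerance = 1e-8)
})

test_that("rank-quantile cutoff splits exactly as specified", {
  co <- quick_cohort(53, n = 10, p = 10, planted = 4)
  model <- fit_supervised_pc(co$processed, protein_ids(co$processed)[1:4],
                             co$clinical, cutoff_fraction = 0.5)
  asg <- assign_risk(model, co$processed)
  expect_equal(unname(table(asg$group)["low"]), 5)
  expect_equal(unname(table(asg$group)["high"]), 5)
  # boundary sample (score == cutoff) is low risk
  at_cut <- asg$score == model$cutoff_value
  expect_true(all(asg$group[at_cut] == "low"))
  m7 <- fit_supervised_pc(co$processed, protein_ids(co$processed)[1:4],
                          co$clinical, cutoff_fraction = 0.7)
  asg7 <- assign_risk(m7, co$processed)
  expect_equal(unname(table(asg7$group)["low"]), 7)
})

test_that("higher score means higher hazard on a planted cohort", {
  co <- quick_cohort(59, n = 80, p = 40, planted = 8, beta = 0.9)
  scr <- screen_proteins(co$processed, co$clinical)
  model <- fit_supervised_pc(co$processed, scr$protein_id, co$clinical)
  expect_gte(model$cox_beta_on_score, 0)
  asg <- assign_risk(model, co$processed)
  cmp <- group_comparison(asg, co$clinical)
  expect_gt(cmp$hr, 1)
  expect_gt(cmp$dmfs_low, cmp$dmfs_high)
})

test_that("frozen standardization keeps the split under profile shifts", {
  co <- quick_cohort(61, n = 30, p = 8, planted = 4)
  prots <- protein_ids(co$processed)[1:4]
  model <- fit_supervised_pc(co$processed, prots, co$clinical)
  base <- assign_risk(model, co$processed)
  # adding a constant c to every protein of a sample shifts its score
  # by c * sum(loading / train_sd): verified against hand arithmetic
  shifted <- co$processed
  shifted$values <- shifted$values + 0.37
  sh <- assign_risk(model, shifted)
  expected_shift <- 0.37 * sum(model$loading / model$train_sds)
  expect_equal(sh$score - base$score, rep(expected_shift, 30),
               tolerance = 1e-10, ignore_attr = TRUE)
  # applying the model to its own training data reproduces the split
  expect_identical(as.character(base$group),
                   as.character(assign_risk(model, co$processed)$group))
})

test_that("signature model JSON round-trips to identical scores", {
  co <- quick_cohort(67, n = 25, p = 10, planted = 4)
  model <- fit_supervised_pc(co$processed, protein_ids(co$processed)[1:5],
                             co$clinical)
  path <- tempfile(fileext = ".json")
  write_signature_model(model, path)
  model2 <- read_signature_model(path)
  expect_identical(assign_risk(model2, co$processed)$score,
                   assign_risk(model, co$processed)$score)
  expect_identical(model2$cutoff_value, model$cutoff_value)
})

test_that("permutation p-value follows the add-one rule", {
  cl <- clinical_table(paste0("S", 1:20), rexp(20, 1) + 0.1,
                       rbinom(20, 1, 0.5))
  set.seed(1)
  # observed above anything the closure returns
  expect_equal(permutation_pvalue(10, function(perm) 0, cl, B = 1000),
               1 / 1001)
  # single permutation at least as extreme
  expect_equal(permutation_pvalue(1, function(perm) 5, cl, B = 1),
               1)
  expect_error(permutation_pvalue(1, function(perm) 0, cl, B = 0),
               ">= 1")
})

test_that("LOOCV returns held-out groups that track planted risk", {
  co <- quick_cohort(71, n = 40, p = 30, planted = 8, beta = 1.0)
  cv <- loocv_risk(co$processed, co$clinical, alpha = 0.05)
  expect_equal(nrow(cv), 40)
  expect_true(sum(!is.na(cv$group)) > 30)
  hr <- group_hr(cv[!is.na(cv$group), ], co$clinical)
  expect_gt(hr$hr, 1)
})
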