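test_that("quantifiable filter applies inclusive boundaries", {
  vals <- matrix(1, 3, 4, dimnames = list(c("keep", "few_pep", "sparse"),
                                          paste0("S", 1:4)))
  miss <- matrix(FALSE, 3, 4, dimnames = dimnames(vals))
  miss["keep", 4] <- TRUE      # detected 3/4 = 0.75, boundary kept
  miss["sparse", 2:4] <- TRUE  # detected 1/4
  m <- toy_quant(vals, miss, peptides = c(2L, 1L, 5L))
  kept <- filter_quantifiable(m)
  expect_identical(rownames(kept$values), "keep")
  expect_equal(ncol(kept$values), 4)  # sample set unchanged
  expect_warning(filter_quantifiable(m, min_unique_peptides = 10),
                 "no quantifiable")
})

test_that("filter is monotone in the detection threshold", {
  set.seed(8)
  vals <- matrix(rexp(200, 1 / 100), 20, 10)
  miss <- matrix(runif(200) < 0.3, 20, 10)
  m <- toy_quant(vals, miss, peptides = sample(1:6, 20, TRUE))
  kept <- lapply(c(0.2, 0.5, 0.8), function(f)
    rownames(filter_quantifiable(m, min_detect_frac = f)$values))
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("outlier rule reproduces the hand-computed thresholds", {
  counts <- setNames(c(rep(1000, 23), 400), paste0("S", 1:24))
  # mean 975, sd 122.47 -> threshold 730.06
  expect_identical(detect_outlier_samples(counts), "S24")
  expect_identical(detect_outlier_samples(setNames(rep(500, 5),
                                                   paste0("S", 1:5))),
                   character(0))
  # small-n insensitivity: threshold goes negative, nothing excluded
  counts2 <- setNames(c(1000, 1000, 1000, 1000, 0), paste0("S", 1:5))
  expect_identical(detect_outlier_samples(counts2), character(0))
  expect_error(detect_outlier_samples(c(a = 1, b = 2)), "at least 3")
})

test_that("log2 transform touches only unmasked values", {
  vals <- matrix(c(8, 1, NA, 4), 2, 2)
  miss <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2)
  m <- toy_quant(vals, miss)
  lt <- log2_transform(m)
  expect_equal(lt$values[1, 1], 3)
  expect_equal(lt$values[2, 1], 0)
  expect_identical(lt$missing, m$missing)
  vals0 <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_error(log2_transform(toy_quant(vals0)), "non-positive")
})

test_that("imputation draws from the downshifted row distribution", {
  # observed part of the row has mean exactly 20 and sample SD exactly 2
  obs <- 20 + 2 * as.numeric(scale(rnorm(50)))
  n_miss <- 10000
  vals <- matrix(c(obs, rep(NA_real_, n_miss)), nrow = 1)
  m <- toy_quant(vals, is.na(vals), scale = "raw")
  m$scale <- "log2"
  set.seed(99)
  imp <- impute_missing(m)
  drawn <- imp$values[1, (length(obs) + 1):(length(obs) + n_miss)]
  expect_equal(mean(drawn), 20 - 1.8 * 2, tolerance = 0.01)
  expect_equal(sd(drawn), 0.3 * 2, tolerance = 0.02)
  expect_identical(imp$values[1, seq_along(obs)],
                   m$values[1, seq_along(obs)])
  expect_equal(sum(imp$missing), 0)
  # same seed, same draws
  set.seed(99)
  expect_identical(impute_missing(m)$values, imp$values)
})

test_that("imputation changes only masked entries and logs fallbacks", {
  co <- simulate_cohort(sim_spec(n_samples = 12, n_proteins = 40,
                                 missing_intercept = 22, seed = 13))
  m <- log2_transform(co$quant)
  set.seed(1)
  imp <- impute_missing(m)
  same <- !m$missing
  expect_identical(imp$values[same], m$values[same])
  # a row with < 2 observations falls back to column moments
  vals <- matrix(rnorm(40, 20), 4, 10)
  vals[1, 2:10] <- NA
  m2 <- toy_quant(vals, is.na(vals))
  m2$scale <- "log2"
  set.seed(2)
  imp2 <- impute_missing(m2)
  expect_equal(attr(imp2, "imputation")$fallback_proteins, "P01")
  expect_false(anyNA(imp2$values))
  # no missing entries: identity
  full <- toy_quant(matrix(rnorm(12, 20), 3, 4))
  full$scale <- "log2"
  expect_identical(impute_missing(full)$values, full$values)
})

test_that("z-scoring standardizes rows with the n-1 convention", {
  m <- toy_quant(matrix(c(1, 2, 3), 1, 3))
  m$scale <- "log2"
  z <- zscore(m)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  set.seed(3)
  m2 <- toy_quant(matrix(rnorm(50, 20), 5, 10))
  m2$scale <- "log2"
  z2 <- zscore(m2)
  expect_lt(max(abs(rowMeans(z2$values))), 1e-12)
  expect_equal(unname(apply(z2$values, 1, sd)), rep(1, 5))
  const <- toy_quant(matrix(5, 2, 3))
  const$scale <- "log2"
  expect_error(zscore(const), "zero-variance protein")
})

test_that("pipeline enforces stage order and reports dimensions", {
  co <- simulate_cohort(sim_spec(n_samples = 30, n_proteins = 80,
                                 n_prognostic = 5, seed = 23))
  set.seed(5)
  pp <- preprocess_pipeline(co$quant)
  rep <- pp$report
  expect_equal(rep$n_proteins_in, 80)
  expect_equal(rep$n_samples_in, 30)
  expect_equal(rep$n_proteins_out, nrow(pp$quant$values))
  expect_equal(rep$n_samples_out, ncol(pp$quant$values))
  expect_equal(pp$quant$scale, "zscore")
  expect_equal(sum(pp$quant$missing), 0)
})
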