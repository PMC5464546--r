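test_that("KM reproduces the hand product-limit with deaths first", {
  km <- km_estimate(c(1, 2, 2, 3), c(1, 1, 0, 1))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$surv, c(0.75, 0.50, 0))
  expect_equal(km$n_risk, c(4, 3, 1))  # censored at 2 still at risk at 2
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM degenerate cases follow the product-limit identities", {
  none <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(none), 0)
  expect_equal(as.numeric(survival_at(none, 10)), 1)
  # no censoring: empirical survival function
  t <- c(1, 2, 3, 4)
  km <- km_estimate(t, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
})

test_that("survival_at is the right-continuous step with extrapolation flag", {
  km <- km_estimate(c(1, 2, 2, 3), c(1, 1, 0, 1))
  expect_equal(as.numeric(survival_at(km, 0)), 1)
  expect_equal(as.numeric(survival_at(km, 2.5)), 0.50)
  expect_equal(as.numeric(survival_at(km, 2)), 0.50)    # right continuity
  past <- survival_at(km, 99)
  expect_equal(as.numeric(past), 0)
  expect_true(attr(past, "extrapolated"))
  expect_false(attr(survival_at(km, 2.5), "extrapolated"))
  # reading the curve at each event time reproduces stored values
  for (i in seq_len(nrow(km))) {
    expect_identical(as.numeric(survival_at(km, km$time[i])), km$surv[i])
  }
})

test_that("log-rank matches the hand hypergeometric sums", {
  lr <- logrank_test(c(1, 3), c(1, 1), c(2, 4), c(1, 0))
  expect_equal(lr$observed_A - lr$expected_A, 2 / 3, tolerance = 1e-12)
  expect_equal(lr$chi2, (2 / 3)^2 / (13 / 18), tolerance = 1e-4)
  expect_equal(lr$chi2, 0.6154, tolerance = 1e-4)
  # identical groups: zero statistic
  same <- logrank_test(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(same$chi2, 0)
  # label swap leaves chi2 unchanged
  sw <- logrank_test(c(2, 4), c(1, 0), c(1, 3), c(1, 1))
  expect_equal(sw$chi2, lr$chi2)
  # zero events -> NA
  z <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(is.na(z$chi2))
})

test_that("log-rank equals the Cox score test on tie-free data", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 30
    time <- runif(n, 0.5, 12)
    event <- rbinom(n, 1, 0.6)
    grp <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(grp)) == 1) next
    lr <- logrank_test(time[grp == 0], event[grp == 0],
                       time[grp == 1], event[grp == 1])
    sc <- tnbcsig:::cox_score_test(grp, time, event)
    expect_equal(lr$chi2, sc$chi2, tolerance = 1e-6)
  }
})

test_that("group_hr equals the grid-oracle hazard ratio on the toy", {
  asg <- data.frame(sample = paste0("S", 1:4),
                    score = c(-1, -1, 1, 1),
                    group = factor(c("low", "low", "high", "high"),
                                   levels = c("low", "high")))
  class(asg) <- c("risk_assignment", "data.frame")
  cl <- clinical_table(paste0("S", 1:4), c(1, 3, 2, 4), c(1, 1, 1, 0))
  hr <- group_hr(asg, cl)
  oracle_beta <- oracle_cox_argmax(c(0, 0, 1, 1), c(1, 3, 2, 4),
                                   c(1, 1, 1, 0))
  expect_equal(log(hr$hr), oracle_beta, tolerance = 1e-4)
  expect_true(hr$ci_low <= hr$hr && hr$hr <= hr$ci_high)
  # identical survival in both groups -> HR ~ 1
  cl2 <- clinical_table(paste0("S", 1:8), rep(c(1, 2, 3, 4), 2),
                        rep(c(1, 1, 0, 1), 2))
  asg2 <- data.frame(sample = paste0("S", 1:8), score = 0,
                     group = factor(rep(c("low", "high"), each = 4),
                                    levels = c("low", "high")))
  class(asg2) <- c("risk_assignment", "data.frame")
  expect_equal(group_hr(asg2, cl2)$hr, 1, tolerance = 1e-6)
})

test_that("separated groups yield a flagged NA hazard ratio", {
  cl <- clinical_table(paste0("S", 1:6), c(1, 2, 3, 10, 11, 12),
                       c(1, 1, 1, 0, 0, 0))
  asg <- data.frame(sample = paste0("S", 1:6), score = 0,
                    group = factor(rep(c("high", "low"), each = 3),
                                   levels = c("low", "high")))
  class(asg) <- c("risk_assignment", "data.frame")
  hr <- group_hr(asg, cl)
  expect_true(hr$flagged)
  expect_true(is.na(hr$hr))
})

test_that("group_comparison bundles DMFS, HR and log-rank consistently", {
  co <- quick_cohort(83, n = 60, p = 20, planted = 6, beta = 1.0)
  scr <- screen_proteins(co$processed, co$clinical, alpha = 0.05)
  model <- fit_supervised_pc(co$processed, scr$protein_id, co$clinical)
  cmp <- group_comparison(assign_risk(model, co$processed), co$clinical)
  expect_equal(cmp$n_low + cmp$n_high, 60)
  expect_true(cmp$dmfs_low >= 0 && cmp$dmfs_low <= 1)
  expect_true(cmp$logrank_p > 0 && cmp$logrank_p <= 1)
  path <- tempfile()
  write_km_coordinates(cmp, path)
  km <- utils::read.delim(path)
  expect_setequal(unique(km$group), c("low", "high"))
  expect_equal(km$surv[km$time == 0], c(1, 1))
})
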