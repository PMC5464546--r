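test_that("probe selection maximizes the coefficient of variation", {
  vals <- rbind(g1_a = c(1, 2, 3),      # CV = 0.5
                g1_b = c(10, 10, 10),   # CV = 0
                g2_a = c(5, 6, 7))
  colnames(vals) <- paste0("S", 1:3)
  map <- data.frame(probe = rownames(vals), gene = c("G1", "G1", "G2"))
  gm <- select_probe_per_gene(probe_matrix(vals, map))
  expect_equal(unname(gm["G1", ]), c(1, 2, 3))
  expect_equal(unname(gm["G2", ]), c(5, 6, 7))  # single probe: identity
  # CV tie -> lexicographically smallest probe id
  tie <- rbind(zz_probe = c(1, 2, 3), aa_probe = c(2, 4, 6))
  colnames(tie) <- paste0("S", 1:3)
  tmap <- data.frame(probe = rownames(tie), gene = "G")
  gt <- select_probe_per_gene(probe_matrix(tie, tmap))
  expect_equal(unname(gt["G", ]), c(2, 4, 6))
  # non-positive mean: probe skipped with a warning
  neg <- rbind(bad = c(-1, 0, 1), ok = c(1, 2, 3))
  colnames(neg) <- paste0("S", 1:3)
  nmap <- data.frame(probe = rownames(neg), gene = c("G1", "G1"))
  expect_warning(gn <- select_probe_per_gene(probe_matrix(neg, nmap)),
                 "non-positive mean")
  expect_equal(unname(gn["G1", ]), c(1, 2, 3))
})

test_that("probe matrix rejects ambiguous probe maps", {
  vals <- matrix(1:4, 2, 2,
                 dimnames = list(c("p1", "p2"), c("S1", "S2")))
  expect_error(probe_matrix(vals, data.frame(probe = c("p1", "p1"),
                                             gene = c("A", "B"))),
               "more than one gene")
  expect_error(probe_matrix(vals, data.frame(probe = "p1", gene = "A")),
               "unmapped")
})

test_that("TNBC filter excludes strictly above thresholds, keeps boundary", {
  gm <- rbind(ESR1 = c(12.0, 12.1, 11.0, 13.0),
              ERBB2 = c(11.8, 11.0, 11.9, 13.0),
              X = 1:4)
  colnames(gm) <- paste0("S", 1:4)
  kept <- filter_tnbc(gm)
  expect_identical(kept, "S1")  # boundary values 12.0 / 11.8 are kept
  expect_error(filter_tnbc(gm[-1, , drop = FALSE]), "ESR1")
  high <- gm; high["ESR1", ] <- 13
  expect_warning(none <- filter_tnbc(high), "no samples")
  expect_length(none, 0)
  # idempotent subsetting
  expect_identical(filter_tnbc(gm[, kept, drop = FALSE]), kept)
})

test_that("discovery-median normalization is exact and idempotent", {
  gm <- rbind(G1 = c(1, 2, 3), G2 = c(5, 5, 8))
  colnames(gm) <- paste0("S", 1:3)
  med <- c(G1 = 10, G2 = 5)
  norm <- median_normalize_to_discovery(gm, med)
  expect_equal(unname(norm["G1", ]), c(9, 10, 11))
  expect_equal(unname(norm["G2", ]), c(5, 5, 8))  # medians already equal
  expect_equal(apply(norm, 1, median), med)
  expect_equal(median_normalize_to_discovery(norm, med), norm)
  expect_warning(dropped <- median_normalize_to_discovery(
    rbind(gm, G3 = c(1, 1, 1)), med), "G3")
  expect_equal(rownames(dropped), c("G1", "G2"))
})

test_that("frozen models transfer to arrays through the gene map", {
  map <- protein_gene_map()
  expect_equal(map$gene[map$accession == "P15153"], "RAC2")
  expect_equal(map$gene[map$accession == "P53004"], "BLVRA")
  co <- quick_cohort(103, n = 120, p = 30, planted = 6, beta = 1.0)
  # name four planted proteins after real accessions so the map applies
  planted4 <- co$truth$planted[1:4]
  acc <- c("P15153", "P20340", "P53004", "Q15181")
  rn <- rownames(co$processed$values)
  rownames(co$processed$values)[match(planted4, rn)] <- acc
  rownames(co$processed$missing) <- rownames(co$processed$values)
  names(co$processed$unique_peptides) <- rownames(co$processed$values)
  rownames(co$truth$log2_levels)[match(planted4,
                                       rownames(co$truth$log2_levels))] <- acc
  rownames(co$truth$true_log2)[match(planted4,
                                     rownames(co$truth$true_log2))] <- acc
  co$truth$planted[match(planted4, co$truth$planted)] <- acc
  model <- fit_supervised_pc(co$processed, acc, co$clinical)
  arr <- simulate_array_cohort(co, n_probes_per_gene = 2,
                               gene_map = protein_gene_map(), seed = 9)
  gm <- select_probe_per_gene(probe_matrix(arr$values, arr$map))
  keep <- filter_tnbc(gm)
  gmk <- gm[, keep, drop = FALSE]
  med <- apply(gmk, 1, median)  # stand-in discovery medians
  gmn <- median_normalize_to_discovery(gmk, med)
  cmp <- validate_transcriptomics(model, gmn, co$clinical,
                                  cutoff_fraction = 0.5)
  expect_equal(cmp$n_low, ceiling(0.5 * length(keep)))
  expect_gt(cmp$hr, 1)
  # a batch-shifted copy normalizes back to identical risk groups
  gmb <- median_normalize_to_discovery(gmn + 1.7, med)
  cmp2 <- validate_transcriptomics(model, gmb, co$clinical,
                                   cutoff_fraction = 0.5)
  expect_identical(as.character(cmp2$assignment$group),
                   as.character(cmp$assignment$group))
  bad_model <- model; bad_model$protein_ids[1] <- "Q00000"
  expect_error(validate_transcriptomics(bad_model, gmn, co$clinical),
               "no gene mapping")
})
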