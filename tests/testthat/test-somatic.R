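test_that("Fisher somatic p matches enumeration and fisher.test", {
  # hand-picked table against the exhaustive oracle
  expect_equal(fisher_somatic_p(5, 5, 10, 0), fisher_enum_oracle(5, 5, 10, 0),
               tolerance = 1e-12)
  # no variant reads anywhere -> p = 1
  expect_equal(fisher_somatic_p(100, 0, 100, 0), 1)
  # monotone: more tumor variant reads never increase p
  ps <- vapply(0:20, function(v) fisher_somatic_p(1000 - v, v, 1000, 2),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  # agreement with stats::fisher.test one-sided
  for (tab in list(c(50, 3, 55, 1), c(10, 2, 12, 0), c(7, 7, 14, 1))) {
    ft <- fisher.test(matrix(c(tab[2], tab[4], tab[1], tab[3]), 2,
                             byrow = TRUE), alternative = "greater")
    expect_equal(fisher_somatic_p(tab[1], tab[2], tab[3], tab[4]),
                 ft$p.value, tolerance = 1e-12)
  }
  expect_error(fisher_somatic_p(0, 0, 5, 1), "coverage")
  expect_error(fisher_somatic_p(-1, 2, 5, 1), "nonnegative")
})

test_that("Fisher p stays exact at clinical amplicon coverages", {
  # the log-tail stays finite and matches a direct log-sum-exp enumeration
  # over the feasible tables (only var_t..var_t+var_n terms at this margin)
  ref_t <- 396800; var_t <- 3200; ref_n <- 399960; var_n <- 40
  lp <- fisher_somatic_p(ref_t, var_t, ref_n, var_n, log = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, -200)
  m <- var_t + var_n; n <- ref_t + ref_n; k <- ref_t + var_t
  xs <- var_t:min(k, m)
  logw <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  lp_oracle <- max(logw) + log(sum(exp(logw - max(logw))))
  expect_equal(lp, lp_oracle, tolerance = 1e-10)
})

test_that("purity scales the effective minimum variant frequency", {
  expect_equal(effective_min_vf(call_config(0.20, 1)), 0.20)
  expect_equal(effective_min_vf(call_config(0.20, 0.05)), 0.01)
  # floor clamps tiny products
  expect_equal(effective_min_vf(call_config(0.20, 1e-4)), 1e-4)
  expect_error(call_config(purity = 0), "purity")
})

test_that("call_somatic combines significance, VF threshold and guard", {
  cfg <- call_config(purity = 1)
  # strong somatic signal at 10% VF and purity 1 fails base_min_vf 0.20...
  pair <- list(tumor_ref = 900, tumor_var = 100, normal_ref = 1000,
               normal_var = 0)
  expect_false(call_somatic(pair, cfg)$called)
  # ...but is called once purity reflects a mixed sample
  cfg2 <- call_config(purity = 0.5)
  call <- call_somatic(pair, cfg2)
  expect_true(call$called)
  expect_lt(call$somatic_p, 0.05)
  expect_equal(call$vf_tumor, 0.1)
  # no variant reads -> never called
  expect_false(call_somatic(list(tumor_ref = 1000, tumor_var = 0,
                                 normal_ref = 1000, normal_var = 0),
                            cfg2)$called)
  # germline guard: normal VF 5% blocks the call regardless of p
  germ <- list(tumor_ref = 800, tumor_var = 200, normal_ref = 950,
               normal_var = 50)
  expect_false(call_somatic(germ, cfg2)$called)
  expect_lt(call_somatic(germ, cfg2)$somatic_p, 0.05)
})

test_that("consensus keeps only loci called in every replicate", {
  rep1 <- data.frame(locus_id = c("a", "b", "c"),
                     somatic_p = c(0.001, 0.02, 0.2),
                     called = c(TRUE, TRUE, FALSE))
  rep2 <- data.frame(locus_id = c("a", "b", "c"),
                     somatic_p = c(0.02, 0.3, 0.01),
                     called = c(TRUE, FALSE, TRUE))
  cons <- consensus_calls(list(rep1, rep2))
  expect_identical(cons$locus_id, "a")
  expect_equal(cons$somatic_p_rep1, 0.001)
  expect_equal(cons$somatic_p_rep2, 0.02)
  # consensus is a subset of every replicate call set
  expect_true(all(cons$locus_id %in% rep1$locus_id[rep1$called]))
  expect_true(all(cons$locus_id %in% rep2$locus_id[rep2$called]))
  # empty replicate sets give an empty consensus
  rep0 <- rep1; rep0$called <- FALSE
  expect_equal(nrow(consensus_calls(list(rep0, rep2))), 0)
  expect_error(consensus_calls(list(rep1)), "2 technical")
})

test_that("evaluation metrics follow their definitions", {
  m <- evaluate_calls(called = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                      truth = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(m$ppv, 0.75)
  expect_equal(m$fdr, 0.25)
  expect_equal(m$ppv + m$fdr, 1)
  expect_equal(m$sensitivity, 0.75)
  # all calls true
  m2 <- evaluate_calls(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(m2$ppv, 1); expect_equal(m2$fdr, 0)
  # no calls: PPV/FDR undefined, sensitivity 0
  m3 <- evaluate_calls(c(FALSE, FALSE), c(TRUE, FALSE))
  expect_false(m3$ppv_defined)
  expect_true(is.na(m3$ppv))
  expect_equal(m3$sensitivity, 0)
})

test_that("linearity fit matches the closed-form least-squares oracle", {
  x <- c(0.0008, 0.008, 0.0268, 0.08, 0.05)
  y <- 0.97 * x + c(1e-4, -2e-4, 5e-5, -1e-4, 2e-4)
  fit <- fit_linearity(x, y)
  oracle <- ols_oracle(x, y)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-12)
  # exact line
  fit2 <- fit_linearity(x, 0.97 * x)
  expect_equal(fit2$slope, 0.97, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  # order invariance
  perm <- c(3, 1, 5, 2, 4)
  fit3 <- fit_linearity(x[perm], y[perm])
  expect_equal(fit3$r_squared, fit$r_squared, tolerance = 1e-12)
  expect_error(fit_linearity(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_linearity(c(1, 2), c(1, 2)), "3 points")
})

test_that("dilution benchmark recovers slope near 1 at assay coverage", {
  b <- benchmark_linearity(seed = 2024)
  expect_gt(b$fit$r_squared, 0.99)
  expect_gt(b$fit$slope, 0.95)
  expect_lt(b$fit$slope, 1.05)
  expect_equal(b$metadata$coverage, 4e5)
})

test_that("consensus benchmark: full sensitivity, FDR never above single", {
  b <- benchmark_consensus(n_samples = 5, vf = 0.008, seed = 77)
  expect_equal(b$consensus$sensitivity, 1)
  expect_equal(b$single$sensitivity, 1)
  fdr_single <- if (b$single$ppv_defined) b$single$fdr else 0
  fdr_cons <- if (b$consensus$ppv_defined) b$consensus$fdr else 0
  expect_lte(fdr_cons, fdr_single)
  # consensus calls are a subset of replicate-1 calls
  r1 <- b$replicate_tables[[1]]
  expect_true(all(b$consensus_table$locus_id %in% r1$locus_id[r1$called]))
})

test_that("VCF writer emits valid records that parse back", {
  calls <- data.frame(locus_id = c("s1_locus01", "s1_locus07"),
                      chrom = c("chr7", "chr17"), pos = c(55259515L, 7579472L),
                      ref = c("T", "G"), alt = c("A", "T"),
                      somatic_p = c(1e-10, 0.003),
                      vf_tumor = c(0.0081, 0.0042),
                      vf_normal = c(1e-4, 2e-4),
                      consensus = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  lines <- readLines(path)
  expect_identical(sum(!startsWith(lines, "#")), 2L)
  expect_true(any(grepl("^##fileformat=VCFv4.2$", lines)))
  # header-only file for an empty call set
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], path2)
  expect_identical(sum(!startsWith(readLines(path2), "#")), 0L)
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_identical(nrow(v@fix), 2L)
  info <- vcfR::extract.info(v, "SOMATIC_P")
  expect_equal(as.numeric(info), calls$somatic_p, tolerance = 1e-6)
  expect_identical(unname(v@fix[, "POS"]), as.character(calls$pos))
})
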