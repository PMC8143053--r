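# Rare-variant filtering, exact 2x2 test, per-variant scan and
# gene-collapsing burden test.

test_that("rare-damaging filter applies strict MAF, SIFT and class rules", {
  v <- make_variants_df(6,
    gene = sprintf("G%03d", 1:6),
    maf = c(0.01, 0.05, 0.049, 0.2, 0.01, 0.01),
    sift = c("damaging", "damaging", "tolerated", "damaging", "damaging",
             "unknown"),
    func_class = c("nonsynonymous_SNV", "stopgain", "frameshift",
                   "splicing", "synonymous_SNV", "nonsynonymous_SNV"))
  carriers <- matrix(1L, 6, 4,
                     dimnames = list(v$id, sprintf("s%02d", 1:4)))
  vs <- make_variant_set(v, carriers)
  f <- filter_rare_damaging(vs)
  # v2 fails strict MAF<0.05, v3 tolerated, v4 common, v5 synonymous,
  # v6 SIFT unknown
  expect_identical(f$variants$id, "v0001")
  # SIFT requirement can be lifted
  f2 <- filter_rare_damaging(vs, require_sift_damaging = FALSE)
  expect_setequal(f2$variants$id, c("v0001", "v0003", "v0006"))
  expect_warning(filter_rare_damaging(vs, maf_max = 0), "no variants")
})

test_that("filter output matches a brute-force row predicate scan", {
  set.seed(41)
  n <- 400
  v <- make_variants_df(
    n, gene = sprintf("G%03d", sample(1:50, n, replace = TRUE)),
    maf = round(runif(n, 0, 0.2), 3),
    sift = sample(c("damaging", "tolerated", "unknown"), n, replace = TRUE),
    func_class = sample(c("nonsynonymous_SNV", "stopgain", "frameshift",
                          "splicing", "synonymous_SNV", "other"),
                        n, replace = TRUE))
  carriers <- matrix(rbinom(n * 10, 1, 0.1), n, 10,
                     dimnames = list(v$id, sprintf("s%02d", 1:10)))
  vs <- make_variant_set(v, carriers)
  f <- filter_rare_damaging(vs)
  keep <- vapply(seq_len(n), function(i) {
    v$maf[i] < 0.05 && v$sift[i] == "damaging" &&
      v$func_class[i] %in% c("nonsynonymous_SNV", "stopgain", "frameshift",
                             "splicing")
  }, logical(1))
  expect_identical(f$variants$id, v$id[keep])
  cls <- attr(f, "class_summary")
  expect_equal(sum(cls$n), sum(keep))
})

test_that("fisher_exact_2x2 reproduces hand-enumerated and degenerate tables", {
  # margins (4,4)/(4,4): five tables, two-sided mass 34/70
  r <- fisher_exact_2x2(3, 1, 1, 3)
  expect_equal(r$p, 34 / 70, tolerance = 1e-12)
  expect_equal(r$odds_ratio, 9)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  z <- fisher_exact_2x2(0, 0, 0, 0)
  expect_equal(z$p, 1)
  expect_true(is.nan(z$odds_ratio))
  expect_equal(fisher_exact_2x2(3, 0, 1, 5)$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(-1, 0, 0, 0), "non-negative")
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test on random tables", {
  set.seed(99)
  for (i in 1:200) {
    tb <- rpois(4, 5)
    mine <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("variant scan flags monomorphic variants and composes row-wise", {
  design <- make_design(4, 4)
  v <- make_variants_df(3, gene = c("GA", "GA", "GB"))
  carriers <- rbind(c(1, 1, 1, 0, 0, 0, 0, 0),
                    c(0, 0, 0, 0, 0, 0, 0, 0),
                    c(1, 0, 0, 0, 1, 0, 0, 0))
  dimnames(carriers) <- list(v$id, design$sample)
  vs <- make_variant_set(v, carriers)
  scan <- variant_fisher_scan(vs, design)
  mono <- scan[scan$id == "v0002", ]
  expect_equal(mono$p, 1)
  expect_true(mono$monomorphic)
  for (i in seq_len(nrow(scan))) {
    ref <- fisher_exact_2x2(scan$case_carriers[i],
                            scan$control_carriers[i],
                            4 - scan$case_carriers[i],
                            4 - scan$control_carriers[i])
    expect_equal(scan$p[i], ref$p)
  }
  expect_false(is.unsorted(scan$p))
})

test_that("null label permutation keeps the scan uniform-conservative", {
  set.seed(7)
  n_var <- 2000
  design <- make_design(30, 30)
  v <- make_variants_df(n_var, gene = sprintf("G%04d", seq_len(n_var)))
  carriers <- matrix(rbinom(n_var * 60, 1, 0.15), n_var, 60,
                     dimnames = list(v$id, design$sample))
  vs <- make_variant_set(v, carriers)
  scan <- variant_fisher_scan(vs, design)
  frac <- mean(scan$p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n_var)
  expect_lte(frac, 0.05 + 3 * mc_se)
})

test_that("burden test collapses carriers per gene and matches the union oracle", {
  design <- make_design(5, 5)
  v <- make_variants_df(4, gene = c("GA", "GA", "GA", "GB"))
  carriers <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                    c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                    c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                    c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0))
  dimnames(carriers) <- list(v$id, design$sample)
  vs <- make_variant_set(v, carriers)
  res <- gene_burden_test(vs, design)
  # sample case_001 carries three GA variants but is one carrier
  expect_equal(res$case_carriers[res$gene == "GA"], 2L)
  # a single-variant gene's burden p equals its scan p
  scan <- variant_fisher_scan(vs, design)
  expect_equal(res$burden_p[res$gene == "GB"], scan$p[scan$id == "v0004"])

  set.seed(11)
  n_var <- 120
  design2 <- make_design(20, 15)
  v2 <- make_variants_df(n_var,
    gene = sprintf("G%03d", sample(1:25, n_var, replace = TRUE)))
  car2 <- matrix(rbinom(n_var * 35, 1, 0.1), n_var, 35,
                 dimnames = list(v2$id, design2$sample))
  vs2 <- make_variant_set(v2, car2)
  res2 <- gene_burden_test(vs2, design2)
  for (g in res2$gene) {
    rows <- which(v2$gene == g)
    carrier_samples <- design2$sample[colSums(car2[rows, , drop = FALSE]) > 0]
    a <- sum(carrier_samples %in% design2$sample[design2$group == "case"])
    b <- length(carrier_samples) - a
    ref <- fisher_exact_2x2(a, b, 20 - a, 15 - b)
    row <- res2[res2$gene == g, ]
    expect_equal(row$burden_p, ref$p)
    expect_equal(row$case_carriers, a)
    expect_equal(row$control_carriers, b)
  }
})

test_that("adding a case-only carrier never increases the collapsed p", {
  for (b in c(0, 2, 5)) for (a in 0:8) {
    p1 <- fisher_exact_2x2(a, b, 20 - a, 15 - b)$p
    p2 <- fisher_exact_2x2(a + 1, b, 20 - (a + 1), 15 - b)$p
    if (a >= b * 20 / 15) expect_lte(p2, p1 + 1e-12)
  }
})

test_that("candidate selection flags and modes follow inclusion-exclusion", {
  res <- data.frame(gene = sprintf("G%d", 1:6),
                    case_carriers = 5, control_carriers = 1,
                    n_case = 50, n_control = 50, odds_ratio = 5,
                    fisher_min_p = c(0.04, 0.2, 0.004, 0.6, 0.03, 0.2),
                    burden_p = c(0.2, 0.04, 0.002, 0.7, 0.01, 0.04),
                    n_variants = 2)
  uni <- select_candidate_genes(res, mode = "union")
  int <- select_candidate_genes(res, mode = "intersection")
  fis <- select_candidate_genes(res, mode = "fisher_only")
  bur <- select_candidate_genes(res, mode = "burden_only")
  g1 <- uni[uni$gene == "G1", ]
  expect_true(g1$fisher_hit)
  expect_false(g1$burden_hit)
  expect_false("G1" %in% int$gene)
  expect_equal(nrow(uni), nrow(fis) + nrow(bur) - nrow(int))
  expect_true(int$top_tier[int$gene == "G3"])
  expect_error(select_candidate_genes(res, mode = "everything"))
})
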