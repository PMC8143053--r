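# Three mutation-methylation criteria and the Venn accounting.

test_that("DMS-overlap criterion assigns gene-level directions", {
  dms <- data.frame(probe = sprintf("p%d", 1:5),
                    gene = c("GA", "GA", "GB", "GC;GD", "GE"),
                    direction = c("hyper", "hypo", "hyper", "hypo", "hyper"))
  out <- genes_with_dms_overlap(c("GA", "GB", "GC", "GZ"), dms)
  expect_setequal(out$gene, c("GA", "GB", "GC"))
  expect_equal(out$direction[out$gene == "GA"], "mixed")
  expect_equal(out$direction[out$gene == "GB"], "hyper")
  # semicolon multi-gene annotation expands
  expect_equal(out$direction[out$gene == "GC"], "hypo")
  # candidate without any probe is excluded
  expect_false("GZ" %in% out$gene)
})

test_that("planted hyper/hypo partition is recovered at gene level", {
  # 34 candidate genes carry DMS: 22 planted positive, 12 negative
  genes <- sprintf("G%03d", 1:34)
  dms <- data.frame(probe = sprintf("p%03d", 1:34), gene = genes,
                    direction = rep(c("hyper", "hypo"), c(22, 12)))
  out <- genes_with_dms_overlap(genes, dms)
  expect_equal(sum(out$direction == "hyper"), 22)
  expect_equal(sum(out$direction == "hypo"), 12)
})

test_that("island criterion uses BED boundaries and matches the pair oracle", {
  v <- make_variants_df(4, gene = c("GA", "GB", "GC", "GD"),
                        pos = c(100L, 99L, 200L, 201L))
  carriers <- matrix(1L, 4, 2, dimnames = list(v$id, c("s1", "s2")))
  vs <- make_variant_set(v, carriers)
  islands <- data.frame(chrom = "chr1", start = 99L, end = 200L)
  out <- genes_with_island_variants(c("GA", "GB", "GC", "GD"), vs, islands)
  expect_setequal(out$gene, c("GA", "GC"))  # pos 100 and 200 in, 99/201 out

  set.seed(17)
  n <- 150
  v2 <- make_variants_df(n, gene = sprintf("G%03d", sample(1:40, n, TRUE)),
                         chrom = sample(c("chr1", "chr2"), n, TRUE),
                         pos = sample.int(3000, n))
  car2 <- matrix(1L, n, 2, dimnames = list(v2$id, c("s1", "s2")))
  vs2 <- make_variant_set(v2, car2)
  isl2 <- data.frame(chrom = sample(c("chr1", "chr2"), 25, TRUE),
                     start = sample.int(2900, 25))
  isl2$end <- isl2$start + sample.int(120, 25)
  cands <- sprintf("G%03d", 1:30)
  out2 <- genes_with_island_variants(cands, vs2, isl2)
  expect_identical(sort(out2$gene), brute_island_genes(cands, vs2, isl2))
})

test_that("meQTL criterion respects DMS-target requirement and locus matching", {
  v <- make_variants_df(2, gene = c("GA", "GB"), pos = c(100L, 500L))
  carriers <- matrix(1L, 2, 2, dimnames = list(v$id, c("s1", "s2")))
  vs <- make_variant_set(v, carriers)
  dms <- data.frame(probe = "pDMS", direction = "hyper")
  meqtl <- data.frame(chrom = "chr1", pos = c(100L, 500L),
                      gene = c("GA", "GB"), probe = c("pOther", "pDMS"),
                      mode = c("cis", "trans"))
  strict <- genes_with_meqtl_links(c("GA", "GB"), vs, meqtl, dms)
  expect_identical(strict$gene, "GB")
  expect_identical(strict$modes, "trans")
  expect_identical(strict$direction, "hyper")
  loose <- genes_with_meqtl_links(c("GA", "GB"), vs, meqtl, dms,
                                  require_dms_target = FALSE)
  expect_setequal(loose$gene, c("GA", "GB"))
  # pairs with probes absent from the manifest are skipped with a warning
  man <- data.frame(probe = "pDMS")
  expect_warning(
    vetted <- genes_with_meqtl_links(c("GA", "GB"), vs, meqtl, dms,
                                     manifest = man),
    "absent from the manifest")
  expect_identical(vetted$gene, "GB")
})

test_that("planted meQTL-linked genes are recovered from a full fixture", {
  p <- sim_params(n_case = 40, n_control = 30, n_genes = 40, n_probes = 300,
                  n_enriched = 5, n_spiked = 30, meth_case_n = 8,
                  meth_control_n = 6, seed = 19)
  st <- simulate_study(p)
  filt <- filter_rare_damaging(st$variants)
  dms <- call_dms(dms_stats(st$beta, st$meth_design, st$manifest))
  out <- genes_with_meqtl_links(unique(filt$variants$gene), filt, st$meqtl,
                                dms, manifest = st$manifest)
  expect_setequal(out$gene, st$truth$meqtl_linked_genes)
})

test_that("Venn regions partition the union", {
  singles <- integrate_criteria(
    data.frame(gene = "a", direction = "hyper", probes = "p1"),
    data.frame(gene = "b", variants = "v1"),
    data.frame(gene = "c", modes = "cis", probes = "p2", direction = "none"))
  expect_equal(nrow(singles$candidates), 3)
  v <- setNames(singles$venn$n, singles$venn$region)
  expect_equal(unname(v[c("dms", "island", "meqtl")]), c(1L, 1L, 1L))
  expect_true(all(v[grepl("&", names(v))] == 0))

  same <- data.frame(gene = c("x", "y"), direction = "hypo", probes = "p",
                     variants = "v", modes = "cis")
  ident <- integrate_criteria(same, same, same)
  vi <- setNames(ident$venn$n, ident$venn$region)
  expect_equal(unname(vi["dms&island&meqtl"]), 2L)
  expect_equal(sum(vi), 2L)

  set.seed(23)
  for (rep in 1:20) {
    pool <- sprintf("g%02d", 1:30)
    s1 <- sample(pool, sample(0:20, 1))
    s2 <- sample(pool, sample(0:20, 1))
    s3 <- sample(pool, sample(1:20, 1))
    known <- sample(pool, 8)
    res <- integrate_criteria(dms_set_of(s1), island_set_of(s2),
                              meqtl_set_of(s3), known = known)
    expect_equal(nrow(res$venn), 15)
    expect_equal(sum(res$venn$n),
                 length(unique(c(s1, s2, s3, known))))
    expect_equal(nrow(res$candidates), length(unique(c(s1, s2, s3))))
  }
})

test_that("candidate records satisfy the flag/direction invariants", {
  res <- integrate_criteria(
    data.frame(gene = "a", direction = "hyper", probes = "p1"),
    data.frame(gene = c("a", "b"), variants = c("v1", "v2")),
    data.frame(gene = "c", modes = "trans", probes = "p9",
               direction = "hypo"))
  cand <- res$candidates
  expect_true(all(cand$flag_dms_overlap | cand$flag_island_variant |
                    cand$flag_meqtl_link))
  # direction none only when neither DMS nor meQTL flag is set
  expect_equal(cand$direction[cand$gene == "b"], "none")
  expect_equal(cand$direction[cand$gene == "c"], "hypo")
  expect_equal(cand$direction[cand$gene == "a"], "hyper")
})

test_that("damage-associated reporting keeps case-enriched genes only", {
  cand <- data.frame(gene = c("a", "b", "c"), flag_dms_overlap = TRUE,
                     flag_island_variant = FALSE, flag_meqtl_link = FALSE,
                     direction = "hyper")
  burden <- data.frame(gene = c("a", "b"), case_carriers = c(10L, 2L),
                       control_carriers = c(1L, 5L), n_case = 50L,
                       n_control = 50L)
  out <- damage_associated_genes(cand, burden)
  expect_identical(out$gene, "a")
  expect_gt(out$case_freq, out$control_freq)
})
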