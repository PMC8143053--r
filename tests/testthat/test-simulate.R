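# Synthetic-study generator: determinism, planted carrier enrichment,
# beta-matrix properties, annotation placement, truth consistency.

small_params <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_case = 40, n_control = 30, n_genes = 40, n_probes = 200,
         n_enriched = 4, n_spiked = 20, meth_case_n = 6,
         meth_control_n = 4, n_meqtl_pairs = 10, seed = seed),
    list(...))
  do.call(sim_params, args)
}

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(seed = 1, background_carrier_rate = 1.2),
               "probability")
  expect_error(sim_params(seed = 1, beta_dispersion = -1), "positive")
  expect_error(sim_params(seed = 1, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_params(seed = 1, n_enriched = 2, enriched_or = Inf),
               "odds ratio")
  expect_error(sim_params(seed = 1, n_probes = 10, n_spiked = 20),
               "n_spiked")
  expect_error(sim_params(seed = 1, n_spiked = 2, spike_delta = 1.5),
               "delta")
  expect_error(sim_params(n_case = 10), "seed")
})

test_that("no enrichment request yields an empty planted-signal truth", {
  p <- small_params(3, n_enriched = 0, n_meqtl_pairs = 0)
  coh <- generate_cohort(p)
  expect_length(coh$truth$enriched_genes, 0)
  expect_length(coh$truth$planted_crosstalk_genes, 0)
})

test_that("identical params and seed reproduce the bundle byte-for-byte", {
  p <- small_params(11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- simulate_bundle(p, d1)
  b2 <- simulate_bundle(p, d2)
  for (f in setdiff(names(b1), "study")) {
    expect_identical(unname(tools::md5sum(b1[[f]])),
                     unname(tools::md5sum(b2[[f]])), label = f)
  }
  # and a different seed changes the truth while schemas hold
  b3 <- simulate_bundle(small_params(12), withr::local_tempdir())
  expect_false(identical(b1$study$truth$island_variants,
                         b3$study$truth$island_variants))
})

test_that("planted carrier enrichment raises the case frequency", {
  hits <- vapply(1:100, function(s) {
    p <- sim_params(n_case = 200, n_control = 100, n_genes = 10,
                    n_enriched = 1, enriched_or = 8,
                    background_carrier_rate = 0.05,
                    n_probes = 10, n_spiked = 0, seed = 5000 + s)
    coh <- generate_cohort(p)
    vs <- coh$variants
    g <- coh$truth$enriched_genes
    rows <- vs$variants$gene == g
    is_case <- coh$design$group == "case"
    case_f <- mean(colSums(vs$carriers[rows, is_case, drop = FALSE]) > 0)
    ctrl_f <- mean(colSums(vs$carriers[rows, !is_case, drop = FALSE]) > 0)
    case_f > ctrl_f
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("beta values stay in [0,1] and spiked deltas are recovered", {
  p <- small_params(21, n_spiked = 10, spike_delta = 0.25,
                    meth_case_n = 11, meth_control_n = 5)
  st <- simulate_study(p)
  expect_true(all(st$beta >= 0 & st$beta <= 1))
  d <- compute_delta_beta(st$beta, st$meth_design)
  spiked <- st$truth$spiked_probes
  # closed-form SE of the mean difference under the logit-normal model,
  # computed by numerical integration independent of the generator
  for (i in seq_len(nrow(spiked))) {
    obs <- d$delta_beta[d$probe == spiked$probe[i]]
    target <- spiked$delta[i]
    ctrl_mean <- d$beta_control[d$probe == spiked$probe[i]]
    mom_c <- logitnorm_moments(ctrl_mean, p$beta_dispersion)
    mom_t <- logitnorm_moments(ctrl_mean + target, p$beta_dispersion)
    se <- sqrt(mom_t$sd^2 / 11 + mom_c$sd^2 / 5)
    expect_lt(abs(obs - target), 3 * se + 0.01)
  }
  # null probes: mean difference averages to zero within Monte-Carlo error
  null_d <- d$delta_beta[!(d$probe %in% spiked$probe)]
  expect_lt(abs(mean(null_d)), 3 * sd(null_d) / sqrt(length(null_d)))
})

test_that("unspiked generation has zero planted methylation signal", {
  p <- small_params(22, n_spiked = 0)
  st <- simulate_study(p)
  d <- compute_delta_beta(st$beta, st$meth_design)
  expect_lt(abs(mean(d$delta_beta)), 3 * sd(d$delta_beta) / sqrt(nrow(d)))
  expect_equal(nrow(st$truth$spiked_probes), 0)
})

test_that("island placement covers exactly the planted island variants", {
  p <- small_params(31, island_coverage = 1)
  st <- simulate_study(p)
  vt <- st$variants$variants
  inside <- vapply(seq_len(nrow(vt)), function(i) {
    any(st$islands$chrom == vt$chrom[i] &
          st$islands$start < vt$pos[i] & vt$pos[i] <= st$islands$end)
  }, logical(1))
  expect_setequal(vt$id[inside], st$truth$island_variants)
  # with coverage 1, every cross-talk gene variant is an island variant
  expect_setequal(st$truth$island_variants,
                  vt$id[vt$gene %in% st$truth$planted_crosstalk_genes])
  # coverage 0: no variant overlaps any island
  st0 <- simulate_study(small_params(31, island_coverage = 0))
  expect_equal(nrow(st0$islands), 0)
  expect_length(st0$truth$island_variants, 0)
})

test_that("meQTL labelling follows coordinates and frac_cis", {
  p <- small_params(41, frac_cis = 1, n_meqtl_pairs = 4, n_enriched = 4)
  st <- simulate_study(p)
  planted <- st$meqtl[st$meqtl$gene %in% st$truth$meqtl_linked_genes, ]
  expect_true(all(planted$mode == "cis"))
  # labels recomputed from the manifest coordinates agree
  pm <- match(st$meqtl$probe, st$manifest$probe)
  relabel <- ifelse(st$manifest$chrom[pm] == st$meqtl$chrom &
                      abs(st$manifest$pos[pm] - st$meqtl$pos) <= p$cis_window,
                    "cis", "trans")
  expect_identical(st$meqtl$mode, relabel)
  expect_setequal(st$truth$meqtl_linked_genes,
                  st$truth$planted_crosstalk_genes)
})

test_that("every planted cross-talk gene sits one hop from the known core", {
  st <- simulate_study(small_params(51))
  g <- igraph::graph_from_data_frame(st$ppi_edges[1:2], directed = FALSE)
  dmat <- igraph::distances(g, v = st$truth$planted_crosstalk_genes,
                            to = intersect(st$known_genes,
                                           igraph::V(g)$name))
  expect_true(all(apply(dmat, 1, min) == 1))
})

test_that("ground truth is recomputable from the emitted files", {
  p <- small_params(61)
  d <- withr::local_tempdir()
  b <- simulate_bundle(p, d)
  truth <- jsonlite::read_json(b$truth, simplifyVector = TRUE)
  vs <- read_variants(b$variants_tsv, "tsv")
  islands <- read_intervals(b$islands)
  recomputed <- brute_island_genes(unique(vs$variants$gene), vs, islands)
  expect_setequal(recomputed,
                  unique(vs$variants$gene[vs$variants$id %in%
                                            truth$island_variants]))
  man <- read_manifest(b$manifest)
  expect_true(all(truth$spiked_probes$probe %in% man$probe))
  meqtl <- read_meqtl(b$meqtl)
  planted <- meqtl[paste(meqtl$chrom, meqtl$pos) %in%
                     paste(vs$variants$chrom, vs$variants$pos)[
                       vs$variants$gene %in% truth$meqtl_linked_genes], ]
  expect_setequal(unique(planted$gene[planted$gene %in%
                                        truth$meqtl_linked_genes]),
                  truth$meqtl_linked_genes)
})
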