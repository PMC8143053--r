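# Synthetic-cohort generator: WES-style rare-variant cohort, bimodal
# beta-value methylation matrix with spiked differential probes, and the
# annotation layers (CpG islands, meQTL pairs, gene sets, PPI, known-gene
# panel) that tie them together. Every planted signal is recorded in a
# ground-truth object so downstream stages can be checked exactly.

#' Simulation parameters for a synthetic variant-methylation study
#'
#' Builds and validates the parameter set controlling the synthetic cohort.
#' Defaults mirror the study design the pipeline targets: 216 cases and 100
#' controls genotyped exome-wide, and an 11-case / 5-control beta-value
#' matrix from a methylation array, with per-gene carrier enrichment and
#' spiked differential probes as the planted signal.
#'
#' @param n_case,n_control cohort sizes for the variant arm.
#' @param n_genes number of genes carrying variants.
#' @param variants_per_gene integer range `c(min, max)` of variants per gene.
#' @param background_carrier_rate per-variant carrier probability under the
#'   null, shared by cases and controls.
#' @param enriched_genes `data.frame(gene, or)` of genes whose case carrier
#'   odds are multiplied by `or`, or `NULL` to derive from `n_enriched` /
#'   `enriched_or` (genes evenly spaced through the gene list).
#' @param n_enriched,enriched_or convenience defaults for `enriched_genes`.
#' @param maf_range interval in `[0, 0.5]` for annotated minor allele
#'   frequencies.
#' @param frac_sift_damaging probability a background variant is annotated
#'   SIFT-damaging (planted variants are always damaging non-synonymous so
#'   the signal survives filtering).
#' @param n_probes number of array probes.
#' @param meth_case_n,meth_control_n methylation-arm group sizes.
#' @param beta_modes two means in (0,1) for the bimodal baseline of probe
#'   methylation (unmethylated / methylated compartments).
#' @param beta_dispersion logit-scale standard deviation of per-sample noise
#'   around the probe mean.
#' @param spiked_probes `data.frame(probe, delta)` of probe indices and
#'   planted case-minus-control beta shifts, or `NULL` to derive from
#'   `n_spiked` / `spike_delta` (alternating sign, first indices).
#' @param n_spiked,spike_delta convenience defaults for `spiked_probes`.
#' @param spike_island_relation,spike_feature if non-`NULL`, force every
#'   spiked probe into this island relation / gene-region feature; by
#'   default spikes are biased toward islands and promoter features.
#' @param island_coverage probability that a variant of a planted cross-talk
#'   gene lies inside a CpG island.
#' @param n_meqtl_pairs total meQTL rows emitted (planted links first, then
#'   decoy pairs on null genes and unspiked probes).
#' @param frac_cis probability a planted meQTL link targets a probe of the
#'   same gene (same chromosome, within `cis_window`).
#' @param cis_window distance in bp within which a same-chromosome pair is
#'   labelled cis; beyond it, or across chromosomes, trans.
#' @param ppi_known_core character vector of known disease-gene symbols
#'   forming the core of the interaction network.
#' @param seed integer seed; mandatory, all generation is deterministic
#'   given `params`.
#'
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_case = 216, n_control = 100,
                       n_genes = 500, variants_per_gene = c(1L, 4L),
                       background_carrier_rate = 0.05,
                       enriched_genes = NULL, n_enriched = 10, enriched_or = 8,
                       maf_range = c(0.001, 0.049),
                       frac_sift_damaging = 0.7,
                       n_probes = 5000, meth_case_n = 11, meth_control_n = 5,
                       beta_modes = c(0.2, 0.8), beta_dispersion = 0.08,
                       spiked_probes = NULL, n_spiked = 200, spike_delta = 0.25,
                       spike_island_relation = NULL, spike_feature = NULL,
                       island_coverage = 0.8,
                       n_meqtl_pairs = 40, frac_cis = 0.7, cis_window = 1e6,
                       ppi_known_core = sprintf("KNOWN%02d", 1:15),
                       seed) {
  if (missing(seed)) stop("seed is mandatory in sim_params()", call. = FALSE)
  assert_count(c(n_case, n_control, n_genes, n_probes,
                 meth_case_n, meth_control_n), "cohort/probe counts")
  assert_count(n_meqtl_pairs, "n_meqtl_pairs", positive = FALSE)
  assert_count(variants_per_gene, "variants_per_gene")
  if (length(variants_per_gene) != 2L ||
      variants_per_gene[1] > variants_per_gene[2]) {
    stop("variants_per_gene must be c(min, max) with min <= max", call. = FALSE)
  }
  assert_prob(c(background_carrier_rate, frac_sift_damaging,
                island_coverage, frac_cis), "rate parameters")
  if (background_carrier_rate <= 0 || background_carrier_rate >= 1) {
    stop("background_carrier_rate must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (length(maf_range) != 2L || any(maf_range < 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an ordered interval inside [0, 0.5]", call. = FALSE)
  }
  if (length(beta_modes) != 2L || any(beta_modes <= 0) || any(beta_modes >= 1)) {
    stop("beta_modes must be two means strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(beta_dispersion) || beta_dispersion <= 0) {
    stop("beta_dispersion must be a positive real", call. = FALSE)
  }
  gene_names <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(enriched_genes)) {
    assert_count(n_enriched, "n_enriched", positive = FALSE)
    idx <- if (n_enriched > 0) {
      unique(round(seq(1, n_genes, length.out = min(n_enriched, n_genes))))
    } else integer(0)
    enriched_genes <- data.frame(gene = gene_names[idx],
                                 or = rep(enriched_or, length(idx)),
                                 stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(enriched_genes),
            all(c("gene", "or") %in% names(enriched_genes)))
  if (!all(enriched_genes$gene %in% gene_names)) {
    stop("enriched_genes refers to genes outside the simulated gene list",
         call. = FALSE)
  }
  if (any(!is.finite(enriched_genes$or)) || any(enriched_genes$or <= 0)) {
    stop("carrier odds ratios must be finite and positive: an infinite or ",
         "non-positive ratio pushes the carrier probability outside (0, 1)",
         call. = FALSE)
  }
  if (is.null(spiked_probes)) {
    assert_count(n_spiked, "n_spiked", positive = FALSE)
    if (n_spiked > n_probes) stop("n_spiked exceeds n_probes", call. = FALSE)
    spiked_probes <- data.frame(
      probe = seq_len(n_spiked),
      delta = rep_len(c(spike_delta, -spike_delta), n_spiked))
  }
  stopifnot(is.data.frame(spiked_probes),
            all(c("probe", "delta") %in% names(spiked_probes)))
  if (any(spiked_probes$probe < 1) || any(spiked_probes$probe > n_probes) ||
      anyDuplicated(spiked_probes$probe)) {
    stop("spiked probe indices must be unique and within 1..n_probes",
         call. = FALSE)
  }
  if (any(abs(spiked_probes$delta) > 1)) {
    stop("|delta| of a spiked probe cannot exceed 1", call. = FALSE)
  }
  p <- list(n_case = n_case, n_control = n_control, n_genes = n_genes,
            gene_names = gene_names,
            variants_per_gene = as.integer(variants_per_gene),
            background_carrier_rate = background_carrier_rate,
            enriched_genes = enriched_genes, maf_range = maf_range,
            frac_sift_damaging = frac_sift_damaging,
            n_probes = n_probes, meth_case_n = meth_case_n,
            meth_control_n = meth_control_n,
            beta_modes = sort(beta_modes), beta_dispersion = beta_dispersion,
            spiked_probes = spiked_probes,
            spike_island_relation = spike_island_relation,
            spike_feature = spike_feature,
            island_coverage = island_coverage,
            n_meqtl_pairs = n_meqtl_pairs, frac_cis = frac_cis,
            cis_window = cis_window,
            ppi_known_core = as.character(ppi_known_core),
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
GENE_FEATURES <- c("TSS1500", "TSS200", "5'UTR", "1stExon",
                   "Body", "ExonBnd", "3'UTR", "IGR")

# sample from a vector without the length-1 pitfall of sample()
resample <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

# deterministic genome layout: genes tile 22 chromosomes 100 kb apart
gene_locus <- function(idx) {
  data.frame(chrom = paste0("chr", ((idx - 1L) %% 22L) + 1L),
             start = 1e6 + ((idx - 1L) %/% 22L) * 1e5)
}

new_variant_set <- function(variants, carriers, samples) {
  stopifnot(is.data.frame(variants), is.matrix(carriers),
            nrow(carriers) == nrow(variants),
            ncol(carriers) == length(samples))
  dimnames(carriers) <- list(variants$id, samples)
  structure(list(variants = variants, carriers = carriers,
                 samples = as.character(samples)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants x %d samples, %d genes\n",
              nrow(x$variants), length(x$samples),
              length(unique(x$variants$gene))))
  invisible(x)
}

#' Generate a synthetic case-control variant cohort
#'
#' Draws per-sample carrier states for every variant: Bernoulli at the
#' background rate for null genes, and with the configured odds ratio applied
#' to case samples for enriched genes. Variants of enriched genes are always
#' annotated as rare, damaging and non-synonymous so the planted signal
#' survives the standard filter; background variants get mixed annotations.
#'
#' @param params a [sim_params()] object.
#' @return list with `variants` (a `variant_set`), `design`
#'   (`data.frame(sample, group)`) and `truth` (partial ground truth:
#'   enriched and planted cross-talk genes).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(stage_seed(params$seed, 0L), {
    genes <- params$gene_names
    vpg <- params$variants_per_gene
    k <- resample(seq.int(vpg[1], vpg[2]), params$n_genes)
    gene_of <- rep(genes, k)
    gene_idx <- rep(seq_along(genes), k)
    nv <- length(gene_of)
    loci <- gene_locus(gene_idx)
    within_rank <- sequence(k)
    variants <- data.frame(
      id = sprintf("v%06d", seq_len(nv)),
      chrom = loci$chrom,
      pos = loci$start + within_rank * 60L,
      ref = resample(c("A", "C", "G", "T"), nv),
      gene = gene_of,
      func_class = resample(
        c("nonsynonymous_SNV", "stopgain", "frameshift", "splicing",
          "synonymous_SNV", "other"), nv,
        prob = c(0.60, 0.06, 0.06, 0.06, 0.16, 0.06)),
      sift = resample(c("damaging", "tolerated", "unknown"), nv,
                      prob = c(params$frac_sift_damaging,
                               (1 - params$frac_sift_damaging) * 0.9,
                               (1 - params$frac_sift_damaging) * 0.1)),
      maf = runif(nv, params$maf_range[1], params$maf_range[2]),
      stringsAsFactors = FALSE)
    variants$alt <- vapply(variants$ref, function(r)
      resample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    variants <- variants[c("id", "chrom", "pos", "ref", "alt", "gene",
                           "func_class", "sift", "maf")]

    enr <- params$enriched_genes
    is_enr <- variants$gene %in% enr$gene
    # planted variants must qualify under the rare-damaging filter
    variants$sift[is_enr] <- "damaging"
    variants$func_class[is_enr] <- "nonsynonymous_SNV"

    samples <- c(sprintf("case_%03d", seq_len(params$n_case)),
                 sprintf("ctrl_%03d", seq_len(params$n_control)))
    is_case <- rep(c(TRUE, FALSE), c(params$n_case, params$n_control))
    p0 <- params$background_carrier_rate
    prob <- matrix(p0, nrow = nv, ncol = length(samples))
    if (nrow(enr)) {
      odds <- p0 / (1 - p0)
      p1 <- (enr$or * odds) / (1 + enr$or * odds)
      if (any(p1 <= 0 | p1 >= 1)) {
        stop("odds ratio pushes carrier probability outside (0, 1)",
             call. = FALSE)
      }
      row_p1 <- p1[match(variants$gene, enr$gene)]
      prob[is_enr, is_case] <- row_p1[is_enr]
    }
    carriers <- matrix(runif(length(prob)) < prob, nrow = nv)

    design <- data.frame(sample = samples,
                         group = ifelse(is_case, "case", "control"),
                         stringsAsFactors = FALSE)
    truth <- list(enriched_genes = enr$gene,
                  planted_crosstalk_genes = enr$gene,
                  spiked_probes = NULL, island_variants = character(0),
                  meqtl_linked_genes = character(0))
    list(variants = new_variant_set(variants, carriers, samples),
         design = design, truth = truth)
  })
}

#' Generate a synthetic beta-value matrix and probe manifest
#'
#' Probe baseline means follow a bimodal (unmethylated/methylated) mixture;
#' per-sample values are logit-normal around the group mean, so every value
#' stays in \[0, 1\]. Spiked probes shift the case-group mean by the planted
#' delta. Spiked probes are assigned round-robin to the planted cross-talk
#' genes so the probe-overlap integration criterion holds by construction;
#' remaining probes get random genes from the cohort.
#'
#' @param params a [sim_params()] object.
#' @param truth ground-truth list from [generate_cohort()].
#' @param cohort the [generate_cohort()] output (supplies the gene universe
#'   and gene loci for probe placement).
#' @return list with `beta` (probes x samples matrix), `manifest`
#'   (`data.frame(probe, chrom, pos, gene, feature, island_relation)`),
#'   `design` for the methylation arm, and the updated `truth`.
#' @export
generate_methylation <- function(params, truth, cohort) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(stage_seed(params$seed, 1L), {
    np <- params$n_probes
    probes <- sprintf("p%05d", seq_len(np))
    spk <- params$spiked_probes
    delta <- numeric(np)
    delta[spk$probe] <- spk$delta
    is_spiked <- seq_len(np) %in% spk$probe

    genes <- params$gene_names
    crosstalk <- truth$planted_crosstalk_genes
    probe_gene <- resample(genes, np)
    if (length(crosstalk) && nrow(spk)) {
      probe_gene[spk$probe] <- rep_len(crosstalk, nrow(spk))
    }
    gi <- match(probe_gene, genes)
    loci <- gene_locus(gi)
    # probes sit inside their gene's locus, a few kb from the variant sites
    pos <- loci$start + 4000L + as.integer(ave(gi, gi, FUN = seq_along)) * 13L

    feature <- resample(GENE_FEATURES, np,
                        prob = c(0.13, 0.08, 0.09, 0.05, 0.40, 0.02, 0.04, 0.19))
    island <- resample(ISLAND_RELATIONS, np, prob = c(0.30, 0.25, 0.10, 0.35))
    if (any(is_spiked)) {
      ns <- sum(is_spiked)
      feature[is_spiked] <- if (!is.null(params$spike_feature)) {
        rep(params$spike_feature, ns)
      } else {
        resample(GENE_FEATURES, ns, prob = c(0.25, 0.30, 0.10, 0.10, 0.20, 0, 0.05, 0))
      }
      island[is_spiked] <- if (!is.null(params$spike_island_relation)) {
        rep(params$spike_island_relation, ns)
      } else {
        resample(ISLAND_RELATIONS, ns, prob = c(0.70, 0.15, 0.05, 0.10))
      }
    }
    manifest <- data.frame(probe = probes, chrom = loci$chrom, pos = pos,
                           gene = probe_gene, feature = feature,
                           island_relation = island, stringsAsFactors = FALSE)

    # baseline means: two-mode mixture, jittered on the logit scale;
    # spiked probes start from the mode that leaves room for the shift
    modes <- params$beta_modes
    m <- plogis(rnorm(np, qlogis(resample(modes, np)), 0.5))
    m[is_spiked] <- plogis(rnorm(sum(is_spiked),
                                 qlogis(ifelse(delta[is_spiked] > 0,
                                               modes[1], modes[2])), 0.25))
    shifted <- m + delta
    if (any(shifted <= 0 | shifted >= 1)) {
      stop("spiked delta pushes a probe mean outside (0, 1); reduce |delta| ",
           "or move beta_modes away from the boundaries", call. = FALSE)
    }
    n1 <- params$meth_case_n; n2 <- params$meth_control_n
    samples <- c(sprintf("mcase_%02d", seq_len(n1)),
                 sprintf("mctrl_%02d", seq_len(n2)))
    loc <- cbind(matrix(qlogis(shifted), np, n1), matrix(qlogis(m), np, n2))
    beta <- plogis(loc + matrix(rnorm(np * (n1 + n2), 0, params$beta_dispersion),
                                np, n1 + n2))
    dimnames(beta) <- list(probes, samples)
    design <- data.frame(sample = samples,
                         group = rep(c("case", "control"), c(n1, n2)),
                         stringsAsFactors = FALSE)
    truth$spiked_probes <- data.frame(probe = probes[spk$probe],
                                      delta = spk$delta,
                                      gene = probe_gene[spk$probe],
                                      stringsAsFactors = FALSE)
    list(beta = beta, manifest = manifest, design = design, truth = truth)
  })
}

#' Generate annotation layers: CpG islands, meQTL pairs, gene sets, PPI
#'
#' Islands are placed so that exactly the planted island variants fall inside
#' one (each selected variant gets a 51-bp island centred on it; placement is
#' verified against all variant positions and the generator aborts on any
#' contradiction). Planted meQTL pairs connect each cross-talk gene's first
#' variant locus to a spiked probe — its own (cis) or another cross-talk
#' gene's on a different chromosome (trans) — with decoy pairs on null genes
#' and unspiked probes filling the table. The PPI is a preferential-attachment
#' graph over all genes plus the known core, with one guaranteed direct edge
#' from every cross-talk gene to a known-core gene.
#'
#' @param params a [sim_params()] object.
#' @param truth ground truth after [generate_methylation()].
#' @param cohort output of [generate_cohort()].
#' @param meth output of [generate_methylation()].
#' @return list with `islands` (BED-convention `data.frame(chrom, start,
#'   end)`), `meqtl` (`data.frame(chrom, pos, gene, probe, mode)`),
#'   `gene_sets` (named list of character vectors), `ppi_edges`
#'   (`data.frame(geneA, geneB, score)`), `known_genes`, and updated `truth`.
#' @export
generate_annotations <- function(params, truth, cohort, meth) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(stage_seed(params$seed, 2L), {
    vt <- cohort$variants$variants
    crosstalk <- truth$planted_crosstalk_genes

    ## CpG islands around a coverage-fraction of cross-talk gene variants
    cand_var <- vt[vt$gene %in% crosstalk, , drop = FALSE]
    take <- runif(nrow(cand_var)) < params$island_coverage
    island_var <- cand_var[take, , drop = FALSE]
    islands <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
    if (nrow(island_var)) {
      # 0-based half-open interval covering 1-based positions pos-25 .. pos+25
      islands <- data.frame(chrom = island_var$chrom,
                            start = island_var$pos - 26L,
                            end = island_var$pos + 25L,
                            stringsAsFactors = FALSE)
      inside <- logical(nrow(vt))
      for (i in seq_len(nrow(islands))) {
        inside <- inside | (vt$chrom == islands$chrom[i] &
                              vt$pos > islands$start[i] &
                              vt$pos <= islands$end[i])
      }
      if (!setequal(vt$id[inside], island_var$id)) {
        stop("island placement contradicts the planted island-variant set",
             call. = FALSE)
      }
    }
    truth$island_variants <- island_var$id

    ## meQTL pairs: planted links first, then decoys
    spiked <- truth$spiked_probes
    man <- meth$manifest
    meqtl <- NULL
    linked <- character(0)
    if (length(crosstalk) && !is.null(spiked) && nrow(spiked)) {
      rows <- lapply(crosstalk, function(g) {
        v <- vt[vt$gene == g, , drop = FALSE][1L, ]
        own <- spiked$probe[spiked$gene == g]
        other <- spiked[spiked$gene != g, , drop = FALSE]
        other_chrom <- man$chrom[match(other$probe, man$probe)]
        far <- other$probe[other_chrom != v$chrom]
        use_cis <- runif(1) < params$frac_cis || length(far) == 0L
        probe <- if (use_cis && length(own)) resample(own, 1L)
                 else if (length(far)) resample(far, 1L)
                 else return(NULL)
        data.frame(chrom = v$chrom, pos = v$pos, gene = g, probe = probe,
                   stringsAsFactors = FALSE)
      })
      meqtl <- do.call(rbind, rows)
      linked <- unique(meqtl$gene)
    }
    n_decoy <- max(0L, params$n_meqtl_pairs - NROW(meqtl))
    if (n_decoy > 0) {
      null_var <- vt[!(vt$gene %in% truth$enriched_genes), , drop = FALSE]
      null_probe <- setdiff(man$probe, spiked$probe)
      if (nrow(null_var) && length(null_probe)) {
        vi <- sample.int(nrow(null_var), min(n_decoy, nrow(null_var)))
        decoy <- data.frame(chrom = null_var$chrom[vi], pos = null_var$pos[vi],
                            gene = null_var$gene[vi],
                            probe = resample(null_probe, length(vi)),
                            stringsAsFactors = FALSE)
        meqtl <- rbind(meqtl, decoy)
      }
    }
    if (is.null(meqtl)) {
      meqtl <- data.frame(chrom = character(0), pos = integer(0),
                          gene = character(0), probe = character(0))
    }
    pm <- match(meqtl$probe, man$probe)
    meqtl$mode <- ifelse(man$chrom[pm] == meqtl$chrom &
                           abs(man$pos[pm] - meqtl$pos) <= params$cis_window,
                         "cis", "trans")
    truth$meqtl_linked_genes <- linked

    ## gene sets (GMT): one planted term plus random background terms
    universe <- c(params$gene_names, params$ppi_known_core)
    gene_sets <- list()
    if (length(crosstalk)) {
      gene_sets[["T01"]] <- unique(c(crosstalk, params$ppi_known_core))
    }
    for (i in seq_len(24L)) {
      gene_sets[[sprintf("T%02d", i + 1L)]] <-
        unique(resample(universe, resample(10:40, 1L)))
    }

    ## scale-free PPI with a guaranteed edge from each cross-talk gene
    ## to the known core
    nodes <- sample(universe)  # shuffle so hubs are not positional
    g <- igraph::sample_pa(length(nodes), power = 1, m = 2, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    ppi <- data.frame(geneA = nodes[el[, 1]], geneB = nodes[el[, 2]],
                      score = runif(nrow(el), 0.15, 0.95),
                      stringsAsFactors = FALSE)
    if (length(crosstalk)) {
      planted <- data.frame(geneA = crosstalk,
                            geneB = resample(params$ppi_known_core,
                                             length(crosstalk)),
                            score = runif(length(crosstalk), 0.7, 0.95),
                            stringsAsFactors = FALSE)
      ppi <- rbind(ppi, planted)
    }
    ppi <- ppi[ppi$geneA != ppi$geneB, , drop = FALSE]
    key <- paste(pmin(ppi$geneA, ppi$geneB), pmax(ppi$geneA, ppi$geneB))
    ppi <- ppi[order(key, -ppi$score), , drop = FALSE]
    ppi <- ppi[!duplicated(paste(pmin(ppi$geneA, ppi$geneB),
                                 pmax(ppi$geneA, ppi$geneB))), , drop = FALSE]
    rownames(ppi) <- NULL

    list(islands = islands, meqtl = meqtl, gene_sets = gene_sets,
         ppi_edges = ppi, known_genes = params$ppi_known_core, truth = truth)
  })
}

#' Run the full generator and collect all study components
#'
#' @param params a [sim_params()] object.
#' @return list with `params`, `variants`, `design`, `beta`, `manifest`,
#'   `meth_design`, `islands`, `meqtl`, `gene_sets`, `ppi_edges`,
#'   `known_genes` and the final `truth`.
#' @export
simulate_study <- function(params) {
  coh <- generate_cohort(params)
  met <- generate_methylation(params, coh$truth, coh)
  ann <- generate_annotations(params, met$truth, coh, met)
  list(params = params,
       variants = coh$variants, design = coh$design,
       beta = met$beta, manifest = met$manifest, meth_design = met$design,
       islands = ann$islands, meqtl = ann$meqtl, gene_sets = ann$gene_sets,
       ppi_edges = ann$ppi_edges, known_genes = ann$known_genes,
       truth = ann$truth)
}

#' Write a complete synthetic study bundle to disk
#'
#' Emits every external file the pipeline consumes: VCF + flat variant TSV,
#' cohort design TSV, beta matrix TSV, probe manifest TSV, methylation design
#' TSV, island BED, meQTL TSV, GMT term sets, PPI edge TSV, known-gene list,
#' and the ground truth as JSON.
#'
#' @param params a [sim_params()] object.
#' @param dir output directory (created if absent).
#' @return invisibly, a named list of file paths plus the in-memory study.
#' @export
simulate_bundle <- function(params, dir) {
  study <- simulate_study(params)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "variants.vcf"),
    variants_tsv = file.path(dir, "variants.tsv"),
    design = file.path(dir, "design.tsv"),
    beta = file.path(dir, "beta_matrix.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    meth_design = file.path(dir, "meth_design.tsv"),
    islands = file.path(dir, "islands.bed"),
    meqtl = file.path(dir, "meqtl.tsv"),
    gmt = file.path(dir, "terms.gmt"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    known = file.path(dir, "known_genes.txt"),
    truth = file.path(dir, "truth.json"))
  write_variants_vcf(study$variants, paths$vcf)
  write_variants_tsv(study$variants, paths$variants_tsv)
  write_tsv(study$design, paths$design)
  write_beta_matrix(study$beta, paths$beta)
  write_tsv(study$manifest, paths$manifest)
  write_tsv(study$meth_design, paths$meth_design)
  write_bed(study$islands, paths$islands)
  write_tsv(study$meqtl, paths$meqtl)
  write_gmt(study$gene_sets, paths$gmt)
  write_tsv(study$ppi_edges, paths$ppi)
  writeLines(study$known_genes, paths$known)
  jsonlite::write_json(study$truth, paths$truth, auto_unbox = FALSE,
                       dataframe = "columns", digits = NA)
  invisible(c(paths, list(study = study)))
}
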