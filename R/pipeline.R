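# End-to-end orchestration: variant filter -> association -> differential
# methylation -> three-criterion integration -> enrichment -> network
# prioritization, from a single validated configuration, with every stage
# table written to disk and a machine-readable summary. The pipeline itself
# is deterministic (no RNG); the recorded seed documents the provenance of
# simulated inputs.

#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds, validating every threshold
#' against its legal range and every referenced file for existence before
#' any stage runs. Default file names match [simulate_bundle()] output, so
#' `pipeline_config(input_dir = d, outdir = o)` runs on a bundle directly.
#'
#' @param input_dir directory holding the input bundle (used to default the
#'   individual paths).
#' @param outdir output directory for stage tables and the summary.
#' @param variants,design,beta,manifest,meth_design,islands,meqtl,gmt,ppi,known
#'   individual input paths, defaulting into `input_dir`. `gmt`, `ppi`,
#'   `known`, `islands` and `meqtl` may be `NA` to skip the dependent
#'   stages.
#' @param variant_dialect `"tsv"`, `"vcf"`, or `"auto"` (by extension).
#' @param maf_max,require_sift_damaging,delta_min,p_dms,fisher_alpha,burden_alpha
#'   association and DMS thresholds (see the stage functions).
#' @param candidate_mode candidate-selection mode, see
#'   [select_candidate_genes()].
#' @param require_dms_target meQTL criterion switch, see
#'   [genes_with_meqtl_links()].
#' @param use_mvalues test methylation on the M-value scale.
#' @param enrich_p,enrich_fdr enrichment report thresholds.
#' @param ppi_min_score,max_distance network thresholds.
#' @param seed integer recorded in the run log (the analysis itself draws no
#'   random numbers).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, outdir,
                            variants = file.path(input_dir, "variants.tsv"),
                            design = file.path(input_dir, "design.tsv"),
                            beta = file.path(input_dir, "beta_matrix.tsv"),
                            manifest = file.path(input_dir, "manifest.tsv"),
                            meth_design = file.path(input_dir, "meth_design.tsv"),
                            islands = file.path(input_dir, "islands.bed"),
                            meqtl = file.path(input_dir, "meqtl.tsv"),
                            gmt = file.path(input_dir, "terms.gmt"),
                            ppi = file.path(input_dir, "ppi_edges.tsv"),
                            known = file.path(input_dir, "known_genes.txt"),
                            variant_dialect = "auto",
                            maf_max = 0.05, require_sift_damaging = TRUE,
                            delta_min = 0.1, p_dms = 0.01,
                            fisher_alpha = 0.05, burden_alpha = 0.05,
                            candidate_mode = "union",
                            require_dms_target = TRUE, use_mvalues = FALSE,
                            enrich_p = 0.05, enrich_fdr = 0.05,
                            ppi_min_score = 0.4, max_distance = 1,
                            seed = 1L) {
  chk01 <- function(x, name, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      stop(sprintf("%s must be a number in [%g, %g]", name, lo, hi),
           call. = FALSE)
    }
  }
  chk01(maf_max, "maf_max", 0, 0.5)
  chk01(delta_min, "delta_min")
  chk01(p_dms, "p_dms"); chk01(fisher_alpha, "fisher_alpha")
  chk01(burden_alpha, "burden_alpha"); chk01(enrich_p, "enrich_p")
  chk01(enrich_fdr, "enrich_fdr"); chk01(ppi_min_score, "ppi_min_score")
  if (!is.numeric(max_distance) || length(max_distance) != 1 ||
      is.na(max_distance) || max_distance < 0) {
    stop("max_distance must be a non-negative number (Inf allowed)",
         call. = FALSE)
  }
  candidate_mode <- match.arg(candidate_mode,
                              c("union", "intersection", "fisher_only",
                                "burden_only"))
  variant_dialect <- match.arg(variant_dialect, c("auto", "tsv", "vcf"))
  paths <- list(variants = variants, design = design, beta = beta,
                manifest = manifest, meth_design = meth_design,
                islands = islands, meqtl = meqtl, gmt = gmt, ppi = ppi,
                known = known)
  required <- c("variants", "design", "beta", "manifest", "meth_design")
  for (nm in names(paths)) {
    pth <- paths[[nm]]
    optional_missing <- !(nm %in% required) &&
      (length(pth) != 1 || is.na(pth))
    if (optional_missing) { paths[nm] <- list(NA_character_); next }
    if (length(pth) != 1 || is.na(pth) || !file.exists(pth)) {
      stop("input file for '", nm, "' not found: ", pth, call. = FALSE)
    }
  }
  structure(list(paths = paths, outdir = outdir,
                 variant_dialect = variant_dialect,
                 maf_max = maf_max,
                 require_sift_damaging = require_sift_damaging,
                 delta_min = delta_min, p_dms = p_dms,
                 fisher_alpha = fisher_alpha, burden_alpha = burden_alpha,
                 candidate_mode = candidate_mode,
                 require_dms_target = require_dms_target,
                 use_mvalues = use_mvalues,
                 enrich_p = enrich_p, enrich_fdr = enrich_fdr,
                 ppi_min_score = ppi_min_score, max_distance = max_distance,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full variant-methylation cross-talk pipeline
#'
#' Executes filter, association, differential methylation, three-criterion
#' integration, enrichment and network prioritization in order, writing one
#' TSV per stage plus `venn_counts.json`, a machine-readable `summary.json`
#' (counts at every stage, Venn regions, final candidates) and `log.txt`
#' (package version, seed and thresholds) under `config$outdir`. A rerun
#' with identical inputs and configuration reproduces every output
#' bit-identically. A failing stage aborts with the stage name in the error.
#'
#' @param config a [pipeline_config()] object.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  p <- config$paths

  vs <- stage("read_variants", {
    dialect <- config$variant_dialect
    if (dialect == "auto") {
      dialect <- if (grepl("\\.vcf(\\.gz)?$", p$variants)) "vcf" else "tsv"
    }
    read_variants(p$variants, dialect)
  })
  design <- stage("read_design", read_design(p$design))

  filtered <- stage("filter", filter_rare_damaging(
    vs, maf_max = config$maf_max,
    require_sift_damaging = config$require_sift_damaging))
  write_tsv(attr(filtered, "class_summary"), out("variant_class_summary.tsv"))

  scan <- stage("assoc", variant_fisher_scan(filtered, design))
  write_tsv(scan, out("variant_scan.tsv"))
  burden <- stage("assoc", gene_burden_test(filtered, design))
  write_tsv(burden, out("gene_burden.tsv"))
  cand <- stage("assoc", select_candidate_genes(
    burden, fisher_alpha = config$fisher_alpha,
    burden_alpha = config$burden_alpha, mode = config$candidate_mode))
  write_tsv(cand, out("candidate_genes.tsv"))

  beta <- stage("dms", read_beta_matrix(p$beta))
  manifest <- stage("dms", read_manifest(p$manifest))
  meth_design <- stage("dms", read_design(p$meth_design))
  corr <- stage("dms", sample_correlation(beta, meth_design))
  write_tsv(data.frame(sample = rownames(corr), corr, check.names = FALSE),
            out("sample_correlation.tsv"))
  stats <- stage("dms", dms_stats(beta, meth_design, manifest,
                                  use_mvalues = config$use_mvalues))
  write_tsv(stats, out("dms_stats.tsv"))
  dms <- stage("dms", call_dms(stats, delta_min = config$delta_min,
                               p_max = config$p_dms))
  write_tsv(dms, out("dms.tsv"))
  region <- stage("dms", region_distribution(dms, manifest))
  write_tsv(region, out("region_distribution.tsv"))

  islands <- if (!is.na(p$islands)) stage("integrate", read_intervals(p$islands))
             else NULL
  meqtl <- if (!is.na(p$meqtl)) stage("integrate", read_meqtl(p$meqtl))
           else NULL
  set_dms <- stage("integrate", genes_with_dms_overlap(cand$gene, dms))
  set_isl <- if (is.null(islands)) {
    data.frame(gene = character(0), variants = character(0))
  } else {
    stage("integrate", genes_with_island_variants(cand$gene, filtered, islands))
  }
  set_meq <- if (is.null(meqtl)) {
    data.frame(gene = character(0), modes = character(0),
               probes = character(0))
  } else {
    stage("integrate", genes_with_meqtl_links(
      cand$gene, filtered, meqtl, dms, manifest = manifest,
      require_dms_target = config$require_dms_target))
  }
  known <- if (!is.na(p$known)) stage("integrate", read_gene_list(p$known))
           else NULL
  integ <- stage("integrate",
                 integrate_criteria(set_dms, set_isl, set_meq, known = known))
  write_tsv(integ$candidates, out("crosstalk_candidates.tsv"))
  write_tsv(integ$venn, out("venn_counts.tsv"))
  jsonlite::write_json(stats::setNames(as.list(integ$venn$n),
                                       integ$venn$region),
                       out("venn_counts.json"), auto_unbox = TRUE)
  damage <- stage("integrate",
                  damage_associated_genes(integ$candidates, burden))
  write_tsv(damage, out("damage_associated_genes.tsv"))

  enr <- NULL
  if (!is.na(p$gmt) && nrow(integ$candidates)) {
    term_map <- stage("enrich", read_gene_sets(p$gmt))
    enr <- stage("enrich", suppressWarnings(
      enrich(integ$candidates$gene, term_map,
             p_max = config$enrich_p, fdr_max = config$enrich_fdr)))
    write_tsv(enr, out("enrichment.tsv"))
  }

  final <- integ$candidates
  subnetwork <- data.frame(geneA = character(0), geneB = character(0),
                           score = numeric(0))
  if (!is.na(p$ppi) && !is.null(known)) {
    edges <- stage("network", read_edge_list(p$ppi))
    graph <- stage("network", build_graph(
      edges, min_score = config$ppi_min_score,
      keep_nodes = union(integ$candidates$gene, known)))
    pri <- stage("network", prioritize_candidates(
      integ$candidates, graph, known, max_distance = config$max_distance))
    final <- pri$kept
    subnetwork <- pri$subnetwork
  }
  write_tsv(final, out("final_candidates.tsv"))
  write_tsv(subnetwork, out("subnetwork.tsv"))

  summary <- list(
    n_samples_variant_arm = nrow(design),
    n_variants_input = nrow(vs$variants),
    n_variants_filtered = nrow(filtered$variants),
    n_genes_tested = nrow(burden),
    n_fisher_genes = sum(burden$fisher_min_p < config$fisher_alpha),
    n_burden_genes = sum(burden$burden_p < config$burden_alpha),
    n_candidate_genes = nrow(cand),
    n_probes = nrow(beta),
    n_dms = nrow(dms),
    prop_hyper = attr(dms, "direction_summary")$prop_hyper,
    n_criterion_dms = nrow(set_dms),
    n_criterion_island = nrow(set_isl),
    n_criterion_meqtl = nrow(set_meq),
    n_crosstalk_union = nrow(integ$candidates),
    venn = stats::setNames(as.list(integ$venn$n), integ$venn$region),
    n_enriched_terms = if (is.null(enr)) NA_integer_
                       else sum(enr$significant),
    n_final_candidates = nrow(final),
    final_candidates = final$gene,
    thresholds = config[setdiff(names(config), c("paths", "outdir"))])
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  writeLines(c(
    sprintf("methcrosstalk version: %s",
            as.character(utils::packageVersion("methcrosstalk"))),
    sprintf("seed: %d", config$seed),
    sprintf("candidate_mode: %s", config$candidate_mode),
    vapply(c("maf_max", "delta_min", "p_dms", "fisher_alpha", "burden_alpha",
             "enrich_p", "enrich_fdr", "ppi_min_score", "max_distance"),
           function(nm) sprintf("%s: %g", nm, config[[nm]]), character(1))),
    out("log.txt"))
  invisible(summary)
}
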