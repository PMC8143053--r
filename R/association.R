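# Rare-variant association: annotation filter, exact per-variant Fisher
# scan, and CMC-style gene-collapsing burden test, all carrier-based
# (dominant coding: a sample carries a variant if it has any non-reference
# allele). Selection uses raw p-value thresholds; no multiple-testing
# correction is applied at this stage, so downstream counts stay auditable.

NONSYN_CLASSES <- c("nonsynonymous_SNV", "stopgain", "frameshift", "splicing")

#' Filter variants to the rare, damaging, non-synonymous set
#'
#' Keeps variants with `maf < maf_max` (strict), SIFT `damaging` (when
#' required) and a qualifying functional class. A per-class count summary of
#' the retained variants is attached as the `class_summary` attribute.
#'
#' @param vs a `variant_set`.
#' @param maf_max strict upper bound on annotated MAF.
#' @param require_sift_damaging keep only SIFT-damaging variants.
#' @param classes functional classes that qualify.
#' @return the filtered `variant_set` (empty with a warning if nothing
#'   survives).
#' @export
filter_rare_damaging <- function(vs, maf_max = 0.05,
                                 require_sift_damaging = TRUE,
                                 classes = NONSYN_CLASSES) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  keep <- v$maf < maf_max & v$func_class %in% classes
  if (require_sift_damaging) keep <- keep & v$sift == "damaging"
  if (!any(keep)) warning("no variants pass the rare-damaging filter",
                          call. = FALSE)
  out <- new_variant_set(v[keep, , drop = FALSE],
                         vs$carriers[keep, , drop = FALSE], vs$samples)
  cls <- table(factor(v$func_class[keep],
                      levels = union(classes, unique(v$func_class))))
  attr(out, "class_summary") <- as.data.frame(cls, responseName = "n",
                                              stringsAsFactors = FALSE) |>
    stats::setNames(c("func_class", "n"))
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over all tables with the
#' observed margins, the hypergeometric probabilities no larger than that of
#' the observed table (with a relative tolerance of 1e-7 for ties). The odds
#' ratio is the sample cross-product `(a*d)/(b*c)`, `+Inf` when `b*c == 0`
#' with `a*d > 0`, and `NaN` for the all-zero (undefined) table, in which
#' case p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)) || anyNA(cells)) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  or <- if (a * d == 0 && b * c == 0) NaN
        else if (b * c == 0) Inf
        else (a * d) / (b * c)
  m <- a + b          # row-1 total
  n <- c + d          # row-2 total
  k <- a + c          # column-1 total
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) {
    return(list(odds_ratio = or, p = 1))
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  list(odds_ratio = or, p = p)
}

variant_counts <- function(vs, design) {
  g <- design_groups(design)
  if (!identical(vs$samples, g$samples)) {
    idx <- match(g$samples, vs$samples)
    if (anyNA(idx)) stop("design samples missing from variant set",
                         call. = FALSE)
    carriers <- vs$carriers[, idx, drop = FALSE]
  } else carriers <- vs$carriers
  list(case = as.integer(carriers %*% g$is_case),
       control = as.integer(carriers %*% (!g$is_case)),
       n_case = g$n_case, n_control = g$n_control)
}

fisher_rowwise <- function(case_car, ctrl_car, n_case, n_control) {
  n <- length(case_car)
  p <- numeric(n); or <- numeric(n)
  for (i in seq_len(n)) {
    r <- fisher_exact_2x2(case_car[i], ctrl_car[i],
                          n_case - case_car[i], n_control - ctrl_car[i])
    p[i] <- r$p; or[i] <- r$odds_ratio
  }
  list(p = p, odds_ratio = or)
}

#' Per-variant Fisher scan of carrier counts
#'
#' For each variant, tests the 2x2 table carriers/non-carriers x
#' case/control with [fisher_exact_2x2()]. Variants carried by no sample are
#' retained with p = 1 and flagged monomorphic rather than dropped.
#'
#' @param vs a (typically filtered) `variant_set`.
#' @param design `data.frame(sample, group)`.
#' @return data.frame sorted by ascending p with columns `id`, `chrom`,
#'   `pos`, `gene`, `case_carriers`, `control_carriers`, `odds_ratio`, `p`,
#'   `neg_log10_p`, `monomorphic` (Manhattan-plot ready).
#' @export
variant_fisher_scan <- function(vs, design) {
  stopifnot(inherits(vs, "variant_set"))
  cc <- variant_counts(vs, design)
  ft <- fisher_rowwise(cc$case, cc$control, cc$n_case, cc$n_control)
  out <- data.frame(id = vs$variants$id, chrom = vs$variants$chrom,
                    pos = vs$variants$pos, gene = vs$variants$gene,
                    case_carriers = cc$case, control_carriers = cc$control,
                    odds_ratio = ft$odds_ratio, p = ft$p,
                    neg_log10_p = -log10(ft$p),
                    monomorphic = cc$case + cc$control == 0,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-collapsing (CMC) burden test
#'
#' A sample is a gene carrier iff it carries at least one qualifying variant
#' of the gene; the collapsed carrier 2x2 table is tested exactly. The
#' per-variant minimum p from [variant_fisher_scan()] is reported alongside
#' as `fisher_min_p`, supplying the separate per-variant-test gene list.
#' Genes with no variants after filtering are absent from the output.
#'
#' @param vs a filtered `variant_set`.
#' @param design `data.frame(sample, group)`.
#' @return data.frame with one row per gene: carrier counts, group sizes,
#'   `odds_ratio`, `fisher_min_p`, `burden_p`, `n_variants`.
#' @export
gene_burden_test <- function(vs, design) {
  stopifnot(inherits(vs, "variant_set"))
  g <- design_groups(design)
  idx <- match(g$samples, vs$samples)
  if (anyNA(idx)) stop("design samples missing from variant set", call. = FALSE)
  carriers <- vs$carriers[, idx, drop = FALSE]
  gene <- vs$variants$gene
  genes <- sort(unique(gene))
  if (!length(genes)) {
    return(data.frame(gene = character(0), case_carriers = integer(0),
                      control_carriers = integer(0), n_case = integer(0),
                      n_control = integer(0), odds_ratio = numeric(0),
                      fisher_min_p = numeric(0), burden_p = numeric(0),
                      n_variants = integer(0)))
  }
  # collapse: any qualifying variant in the gene makes the sample a carrier
  gene_car <- rowsum(carriers * 1L, gene) > 0
  case_car <- as.integer(gene_car %*% g$is_case)
  ctrl_car <- as.integer(gene_car %*% (!g$is_case))
  ft <- fisher_rowwise(case_car, ctrl_car, g$n_case, g$n_control)
  scan <- variant_fisher_scan(vs, design)
  min_p <- tapply(scan$p, scan$gene, min)
  out <- data.frame(gene = genes, case_carriers = case_car,
                    control_carriers = ctrl_car,
                    n_case = g$n_case, n_control = g$n_control,
                    odds_ratio = ft$odds_ratio,
                    fisher_min_p = as.numeric(min_p[genes]),
                    burden_p = ft$p,
                    n_variants = as.integer(table(gene)[genes]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select candidate genes from association results
#'
#' Flags genes as per-variant Fisher hits (`fisher_min_p < fisher_alpha`)
#' and/or burden hits (`burden_p < burden_alpha`), returns the set selected
#' by `mode`, and labels a `top_tier` at p < 0.01 on the selecting
#' statistic(s).
#'
#' @param results output of [gene_burden_test()].
#' @param fisher_alpha,burden_alpha raw p-value thresholds (strict `<`).
#' @param mode one of `"union"`, `"intersection"`, `"fisher_only"`,
#'   `"burden_only"`.
#' @param top_alpha threshold for the top tier.
#' @return subset of `results` with logical columns `fisher_hit`,
#'   `burden_hit`, `top_tier`.
#' @export
select_candidate_genes <- function(results, fisher_alpha = 0.05,
                                   burden_alpha = 0.05,
                                   mode = c("union", "intersection",
                                            "fisher_only", "burden_only"),
                                   top_alpha = 0.01) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("association results must be a non-empty data.frame", call. = FALSE)
  }
  mode <- match.arg(mode)
  results$fisher_hit <- results$fisher_min_p < fisher_alpha
  results$burden_hit <- results$burden_p < burden_alpha
  keep <- switch(mode,
                 union = results$fisher_hit | results$burden_hit,
                 intersection = results$fisher_hit & results$burden_hit,
                 fisher_only = results$fisher_hit,
                 burden_only = results$burden_hit)
  results$top_tier <- switch(mode,
    union = pmin(results$fisher_min_p, results$burden_p) < top_alpha,
    intersection = pmax(results$fisher_min_p, results$burden_p) < top_alpha,
    fisher_only = results$fisher_min_p < top_alpha,
    burden_only = results$burden_p < top_alpha)
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
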