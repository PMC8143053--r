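# Mutation-methylation integration: the three criteria linking a candidate
# gene's variants to the methylation layer (differential probes on the gene,
# variants inside CpG islands, meQTL linkage to differential probes), plus
# the Venn accounting over the criterion sets.

# expand semicolon-separated multi-gene annotations to one row per gene
expand_genes <- function(df, col = "gene") {
  genes <- strsplit(as.character(df[[col]]), ";", fixed = TRUE)
  out <- df[rep(seq_len(nrow(df)), lengths(genes)), , drop = FALSE]
  out[[col]] <- unlist(genes)
  rownames(out) <- NULL
  out
}

#' Criterion 1: candidate genes carrying differential methylation sites
#'
#' A candidate gene qualifies when at least one called DMS probe is
#' annotated to it. The gene-level direction is `hyper` / `hypo` from the
#' probe deltaBeta signs, or `mixed` when both occur.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param dms DMS table with `probe`, `gene` (semicolon lists allowed) and
#'   `direction` columns.
#' @return data.frame with `gene`, `direction`, `probes`
#'   (comma-collapsed supporting probe ids).
#' @export
genes_with_dms_overlap <- function(candidates, dms) {
  if (is.null(dms$gene)) stop("DMS table lacks gene annotation", call. = FALSE)
  dx <- expand_genes(dms[c("probe", "gene", "direction")])
  dx <- dx[dx$gene %in% candidates, , drop = FALSE]
  if (!nrow(dx)) {
    return(data.frame(gene = character(0), direction = character(0),
                      probes = character(0)))
  }
  sp <- split(dx, dx$gene)
  out <- data.frame(
    gene = names(sp),
    direction = vapply(sp, function(d) {
      dirs <- unique(d$direction)
      if (length(dirs) > 1) "mixed" else dirs
    }, character(1)),
    probes = vapply(sp, function(d)
      paste(sort(unique(d$probe)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

# is 1-based position p inside the 0-based half-open interval [start, end)?
pos_in_interval <- function(pos, start0, end0) start0 < pos & pos <= end0

#' Criterion 2: candidate genes with variants inside CpG islands
#'
#' A candidate gene qualifies when at least one of its (filtered) variants
#' lies inside an island interval. Islands follow the BED convention, so a
#' 1-based variant position `p` is inside `chrom start end` iff
#' `start < p <= end`.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param vs a filtered `variant_set`.
#' @param islands an `interval_set` from [read_intervals()] (or any
#'   `data.frame(chrom, start, end)` in BED coordinates).
#' @return data.frame with `gene` and `variants` (comma-collapsed
#'   supporting variant ids).
#' @export
genes_with_island_variants <- function(candidates, vs, islands) {
  v <- vs$variants
  v <- v[v$gene %in% candidates, , drop = FALSE]
  if (!nrow(v) || !nrow(islands)) {
    return(data.frame(gene = character(0), variants = character(0)))
  }
  inside <- logical(nrow(v))
  for (chr in unique(v$chrom)) {
    vi <- which(v$chrom == chr)
    isl <- islands[islands$chrom == chr, , drop = FALSE]
    if (!nrow(isl)) next
    # sorted starts: position is covered iff some interval has
    # start < pos <= end; islands are short, so scan intervals per chrom
    for (k in seq_len(nrow(isl))) {
      inside[vi] <- inside[vi] |
        pos_in_interval(v$pos[vi], isl$start[k], isl$end[k])
    }
  }
  hit <- v[inside, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(gene = character(0), variants = character(0)))
  }
  sp <- split(hit$id, hit$gene)
  data.frame(gene = names(sp),
             variants = vapply(sp, function(x)
               paste(sort(x), collapse = ","), character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Criterion 3: candidate genes linked to methylation through meQTL pairs
#'
#' A candidate gene qualifies when one of its variants matches an meQTL SNP
#' — by exact locus (`chrom` + `pos`) where coordinates are present, falling
#' back to the annotated SNP gene symbol with a logged downgrade — and the
#' pair's target probe is (when `require_dms_target`) a called DMS. meQTL
#' rows whose probe is absent from the manifest are skipped with a warning.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param vs a filtered `variant_set`.
#' @param meqtl meQTL pair table (see [read_meqtl()]).
#' @param dms called DMS table (needs `probe`).
#' @param manifest probe manifest used to vet meQTL target probes (optional;
#'   skipped when `NULL`).
#' @param require_dms_target only count pairs whose target probe is a DMS.
#' @return data.frame with `gene`, `modes` (comma-collapsed cis/trans) and
#'   `probes` (supporting target probes).
#' @export
genes_with_meqtl_links <- function(candidates, vs, meqtl, dms,
                                   manifest = NULL,
                                   require_dms_target = TRUE) {
  if (!nrow(meqtl)) {
    return(data.frame(gene = character(0), modes = character(0),
                      probes = character(0)))
  }
  if (!is.null(manifest)) {
    known <- meqtl$probe %in% manifest$probe
    if (any(!known)) {
      warning(sum(!known), " meQTL pair(s) with probes absent from the ",
              "manifest skipped", call. = FALSE)
      meqtl <- meqtl[known, , drop = FALSE]
    }
  }
  if (require_dms_target) {
    meqtl <- meqtl[meqtl$probe %in% dms$probe, , drop = FALSE]
  }
  if (!nrow(meqtl)) {
    return(data.frame(gene = character(0), modes = character(0),
                      probes = character(0)))
  }
  v <- vs$variants[vs$variants$gene %in% candidates, , drop = FALSE]
  has_coords <- all(c("chrom", "pos") %in% names(meqtl)) &&
    !all(is.na(meqtl$pos))
  if (has_coords) {
    vloc <- paste(v$chrom, v$pos)
    qloc <- paste(meqtl$chrom, meqtl$pos)
    mi <- match(qloc, vloc)
    hit_gene <- v$gene[mi]
  } else {
    message("meQTL table lacks loci; matching on SNP gene symbol")
    hit_gene <- ifelse(meqtl$gene %in% v$gene, meqtl$gene, NA_character_)
  }
  hit <- data.frame(gene = hit_gene, mode = meqtl$mode, probe = meqtl$probe,
                    stringsAsFactors = FALSE)
  hit <- hit[!is.na(hit$gene), , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(gene = character(0), modes = character(0),
                      probes = character(0), direction = character(0)))
  }
  probe_dir <- if (!is.null(dms$direction)) {
    dms$direction[match(hit$probe, dms$probe)]
  } else rep(NA_character_, nrow(hit))
  hit$direction <- probe_dir
  sp <- split(hit, hit$gene)
  data.frame(gene = names(sp),
             modes = vapply(sp, function(d)
               paste(sort(unique(d$mode)), collapse = ","), character(1)),
             probes = vapply(sp, function(d)
               paste(sort(unique(d$probe)), collapse = ","), character(1)),
             direction = vapply(sp, function(d) {
               dirs <- unique(d$direction[!is.na(d$direction)])
               if (!length(dirs)) "none"
               else if (length(dirs) > 1) "mixed" else dirs
             }, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

venn_region_counts <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)))
  counts <- table(factor(pattern, levels = combos))
  data.frame(region = names(counts), n = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Integrate the three mutation-methylation criteria
#'
#' Produces one record per gene in the union of the criterion sets with
#' per-criterion flags, methylation direction, and supporting variant/probe
#' ids, plus the exclusive Venn region counts over the 3 sets (7 regions) or
#' 4 with a known-gene set (15 regions). The regions partition the union, so
#' the counts sum exactly to the union size.
#'
#' @param dms_set output of [genes_with_dms_overlap()].
#' @param island_set output of [genes_with_island_variants()].
#' @param meqtl_set output of [genes_with_meqtl_links()].
#' @param known optional character vector of known disease genes for a
#'   four-way overlap.
#' @return list with `candidates` (data.frame) and `venn` (region counts).
#' @export
integrate_criteria <- function(dms_set, island_set, meqtl_set, known = NULL) {
  sets <- list(dms = dms_set$gene, island = island_set$gene,
               meqtl = meqtl_set$gene)
  union_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  candidates <- data.frame(
    gene = union_genes,
    flag_dms_overlap = union_genes %in% sets$dms,
    flag_island_variant = union_genes %in% sets$island,
    flag_meqtl_link = union_genes %in% sets$meqtl,
    stringsAsFactors = FALSE)
  # direction from DMS probes on the gene; meQTL target probes otherwise
  dir_dms <- dms_set$direction[match(union_genes, dms_set$gene)]
  dir_meq <- if (!is.null(meqtl_set$direction)) {
    meqtl_set$direction[match(union_genes, meqtl_set$gene)]
  } else rep(NA_character_, length(union_genes))
  candidates$direction <- ifelse(
    candidates$flag_dms_overlap, dir_dms,
    ifelse(!is.na(dir_meq), dir_meq, "none"))
  candidates$supporting_variants <-
    island_set$variants[match(union_genes, island_set$gene)]
  candidates$supporting_probes <- ifelse(
    candidates$flag_dms_overlap,
    dms_set$probes[match(union_genes, dms_set$gene)],
    meqtl_set$probes[match(union_genes, meqtl_set$gene)])
  candidates$meqtl_modes <- meqtl_set$modes[match(union_genes, meqtl_set$gene)]
  venn_sets <- sets
  if (!is.null(known)) venn_sets$known <- known
  venn <- if (length(union_genes) || !is.null(known)) {
    venn_region_counts(venn_sets)
  } else {
    data.frame(region = character(0), n = integer(0))
  }
  list(candidates = candidates, venn = venn)
}

#' Report genes whose case carrier frequency exceeds the control frequency
#'
#' Filters integrated candidates to those whose collapsed carrier frequency
#' is higher in cases than in controls — the damage-associated reporting
#' tier.
#'
#' @param candidates `candidates` data.frame from [integrate_criteria()].
#' @param burden output of [gene_burden_test()] (carrier counts).
#' @return subset of `candidates` with `case_freq` / `control_freq` columns.
#' @export
damage_associated_genes <- function(candidates, burden) {
  bi <- match(candidates$gene, burden$gene)
  case_freq <- burden$case_carriers[bi] / burden$n_case[bi]
  ctrl_freq <- burden$control_carriers[bi] / burden$n_control[bi]
  keep <- !is.na(case_freq) & case_freq > ctrl_freq
  out <- candidates[keep, , drop = FALSE]
  out$case_freq <- case_freq[keep]
  out$control_freq <- ctrl_freq[keep]
  rownames(out) <- NULL
  out
}
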