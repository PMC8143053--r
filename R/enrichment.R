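# Term over-representation: one-sided hypergeometric (Fisher) test of a
# gene set against a term-to-gene map, with Benjamini-Hochberg control.

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`: step-up
#' adjustment with enforced monotonicity; ties map to equal adjusted values.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation test
#'
#' For each term, tests whether the gene set hits the term more often than
#' expected under hypergeometric sampling from the background:
#' `p = P(X >= k)` with `k` hits, term size `K`, set size `n`, background
#' `N`. Genes outside the background are dropped with a warning. BH FDR is
#' computed over all tested terms and results are sorted by ascending p.
#' Terms passing `p <= p_max` and `fdr < fdr_max` are flagged `significant`.
#'
#' @param gene_set character vector of query genes.
#' @param term_map named list of term gene vectors (see [read_gene_sets()]).
#' @param background character vector defining the universe; defaults to
#'   the union of all term genes and the query set.
#' @param p_max,fdr_max report thresholds for the `significant` flag.
#' @return data.frame with `term`, `description`, `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, `genes`, `significant`.
#' @export
enrich <- function(gene_set, term_map, background = NULL,
                   p_max = 0.05, fdr_max = 0.05) {
  if (!length(term_map)) {
    stop("term map is empty", call. = FALSE)
  }
  background <- unique(background %||%
                         c(unlist(term_map, use.names = FALSE), gene_set))
  if (!length(background)) stop("background is empty", call. = FALSE)
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped",
            call. = FALSE)
    gene_set <- intersect(gene_set, background)
  }
  N <- length(background)
  n <- length(gene_set)
  desc <- attr(term_map, "description") %||% rep("", length(term_map))
  rows <- lapply(seq_along(term_map), function(i) {
    term_genes <- intersect(term_map[[i]], background)
    K <- length(term_genes)
    hits <- intersect(gene_set, term_genes)
    k <- length(hits)
    # upper tail P(X >= k); k = 0 gives p = 1 exactly
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    data.frame(term = names(term_map)[i], description = desc[i],
               k = k, K = K, n = n, N = N, p = min(1, p),
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$p <= p_max & out$fdr < fdr_max
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out[c("term", "description", "k", "K", "n", "N", "p", "fdr", "genes",
        "significant")]
}
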