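# Independent oracles and tiny fixture builders used across the suite.
# Oracles are deliberately naive (enumeration, per-pair scans, dense
# all-pairs algorithms) and never share code with the implementation paths
# they check.

# two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, probabilities from binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# upper-tail hypergeometric P(X >= k) by direct combinatorial summation
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  if (k > min(K, n)) return(0)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# all-pairs shortest hop counts on a dense adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  dimnames(d) <- dimnames(adj)
  d
}

# per-pair membership scan: which candidate genes have a variant inside an
# island (1-based pos p in 0-based half-open [start, end) iff start < p <= end)
brute_island_genes <- function(candidates, vs, islands) {
  v <- vs$variants
  hits <- character(0)
  for (i in seq_len(nrow(v))) {
    if (!(v$gene[i] %in% candidates)) next
    for (j in seq_len(nrow(islands))) {
      if (v$chrom[i] == islands$chrom[j] &&
          islands$start[j] < v$pos[i] && v$pos[i] <= islands$end[j]) {
        hits <- c(hits, v$gene[i])
        break
      }
    }
  }
  sort(unique(hits))
}

# mean and sd of a logit-normal(location qlogis(m), sd) variable by
# numerical integration on a fine grid
logitnorm_moments <- function(m, sd) {
  z <- seq(-8, 8, length.out = 4001)
  w <- dnorm(z)
  w <- w / sum(w)
  x <- plogis(qlogis(m) + sd * z)
  mu <- sum(w * x)
  list(mean = mu, sd = sqrt(sum(w * (x - mu)^2)))
}

# minimal variant_set builder: carriers as a variants x samples 0/1 matrix
make_variant_set <- function(variants, carriers) {
  samples <- colnames(carriers)
  methcrosstalk:::new_variant_set(variants, carriers > 0, samples)
}

# criterion-set data.frames of the shapes integrate_criteria() expects,
# robust to empty gene vectors
dms_set_of <- function(genes, direction = "hyper") {
  data.frame(gene = genes, direction = rep_len(direction, length(genes)),
             probes = rep_len("p", length(genes)), stringsAsFactors = FALSE)
}
island_set_of <- function(genes) {
  data.frame(gene = genes, variants = rep_len("v", length(genes)),
             stringsAsFactors = FALSE)
}
meqtl_set_of <- function(genes, direction = "none") {
  data.frame(gene = genes, modes = rep_len("cis", length(genes)),
             probes = rep_len("p", length(genes)),
             direction = rep_len(direction, length(genes)),
             stringsAsFactors = FALSE)
}

make_design <- function(n_case, n_control, prefix = c("case", "ctrl")) {
  data.frame(
    sample = c(sprintf("%s_%03d", prefix[1], seq_len(n_case)),
               sprintf("%s_%03d", prefix[2], seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE)
}

# small annotated variant table with default qualifying annotations
make_variants_df <- function(n, gene = sprintf("G%03d", seq_len(n)),
                             chrom = "chr1", pos = seq_len(n) * 100L,
                             maf = 0.01, sift = "damaging",
                             func_class = "nonsynonymous_SNV") {
  data.frame(id = sprintf("v%04d", seq_len(n)), chrom = chrom, pos = pos,
             ref = "A", alt = "G", gene = gene, func_class = func_class,
             sift = sift, maf = maf, stringsAsFactors = FALSE)
}
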