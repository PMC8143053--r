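# Two-group differential methylation on beta values: QC correlation, an
# empirical-Bayes moderated t-statistic (variance shrinkage across probes by
# moment matching on the log residual variances), the deltaBeta effect size,
# threshold-based DMS calling, and genomic-context summaries.

row_group_stats <- function(mat, is_case) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  x1 <- mat[, is_case, drop = FALSE]; x2 <- mat[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  list(m1 = m1, m2 = m2, n1 = n1, n2 = n2,
       s2 = (ss1 + ss2) / (n1 + n2 - 2))
}

# inverse of the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf)); used to match the variance of log residual variances
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# scaled-F moment estimation of the variance prior (d0, s0^2) from the
# per-probe residual variances s2 on d_g df each
estimate_variance_prior <- function(s2, dg) {
  pos <- s2 > 0
  if (!any(pos)) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2[pos])
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- if (length(e) > 1) stats::var(e) - trigamma(dg / 2) else -Inf
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Sample-sample Pearson correlation QC
#'
#' Pearson correlations across probes between every pair of samples. A
#' sample with zero variance gets an explicit `undefined` flag and `NA`
#' correlations instead of propagating `NaN`. When a design is supplied,
#' samples whose median correlation to the rest of their own group falls
#' below `flag_threshold` are flagged.
#'
#' @param mat probes x samples beta matrix.
#' @param design optional `data.frame(sample, group)`.
#' @param flag_threshold median within-group correlation below which a
#'   sample is flagged.
#' @return symmetric correlation matrix with unit diagonal; attributes
#'   `undefined` (zero-variance samples) and `flagged_low`.
#' @export
sample_correlation <- function(mat, design = NULL, flag_threshold = 0.9) {
  if (ncol(mat) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(mat, 2L, stats::sd)
  undef <- colnames(mat)[sds == 0]
  r <- suppressWarnings(stats::cor(mat))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  flagged <- character(0)
  if (!is.null(design)) {
    g <- design_groups(design)
    for (j in seq_along(g$samples)) {
      peers <- setdiff(g$samples[g$is_case == g$is_case[j]], g$samples[j])
      if (length(peers)) {
        med <- stats::median(r[g$samples[j], peers], na.rm = TRUE)
        if (!is.na(med) && med < flag_threshold) {
          flagged <- c(flagged, g$samples[j])
        }
      }
    }
  }
  attr(r, "undefined") <- undef
  attr(r, "flagged_low") <- flagged
  r
}

#' Empirical-Bayes moderated two-group test per probe
#'
#' Per probe, the pooled two-group residual variance \eqn{s_g^2} on
#' \eqn{d_g = n_1 + n_2 - 2} df is shrunk toward a prior \eqn{s_0^2} with
#' \eqn{d_0} prior df estimated from all probes by matching the moments of
#' \eqn{\log s_g^2} (digamma/trigamma inversion). The posterior variance
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)} yields the
#' moderated statistic \eqn{t = \Delta / (\tilde s_g \sqrt{1/n_1 + 1/n_2})}
#' on \eqn{d_0 + d_g} df. When the moment estimate degenerates (log
#' variances less dispersed than sampling noise, e.g. all \eqn{s_g^2}
#' equal), the pooled limit \eqn{d_0 = \infty} is used with a warning.
#'
#' @param mat probes x samples matrix.
#' @param design `data.frame(sample, group)`; both groups need >= 2 samples.
#' @param d0 optional override of the prior df: `0` recovers the ordinary
#'   pooled two-sample t, `Inf` the fully shrunk (constant-variance) limit.
#' @return data.frame with `probe`, `mean_case`, `mean_control`,
#'   `mean_diff`, `s2`, `t_mod`, `df_total`, `p`, `zero_variance`;
#'   attributes `d0` and `s02` carry the prior.
#' @export
fit_two_group_moderated <- function(mat, design, d0 = NULL) {
  g <- design_groups(design)
  idx <- match(g$samples, colnames(mat))
  if (anyNA(idx)) stop("design samples missing from matrix", call. = FALSE)
  mat <- mat[, idx, drop = FALSE]
  if (g$n_case < 2 || g$n_control < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  st <- row_group_stats(mat, g$is_case)
  dg <- st$n1 + st$n2 - 2
  prior <- estimate_variance_prior(st$s2, dg)
  if (is.null(d0)) {
    d0 <- prior$d0
    if (!is.finite(d0) && stats::var(st$s2) == 0) {
      warning("log-variance moments degenerate; using pooled-variance limit",
              call. = FALSE)
    }
  }
  s02 <- prior$s02
  s2_post <- if (d0 == 0) st$s2
             else if (is.infinite(d0)) rep(s02, length(st$s2))
             else (d0 * s02 + dg * st$s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / st$n1 + 1 / st$n2))
  t_mod <- (st$m1 - st$m2) / se
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(probe = rownames(mat), mean_case = st$m1,
                    mean_control = st$m2, mean_diff = st$m1 - st$m2,
                    s2 = st$s2, t_mod = t_mod, df_total = df_total, p = p,
                    zero_variance = st$s2 == 0, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Group-mean methylation difference (deltaBeta) per probe
#'
#' deltaBeta is the plain arithmetic case-group mean minus control-group
#' mean of the beta values — no shrinkage, no transformation.
#'
#' @param mat probes x samples beta matrix.
#' @param design `data.frame(sample, group)`; both groups non-empty.
#' @return data.frame with `probe`, `beta_case`, `beta_control`,
#'   `delta_beta`.
#' @export
compute_delta_beta <- function(mat, design) {
  g <- design_groups(design)
  idx <- match(g$samples, colnames(mat))
  if (anyNA(idx)) stop("design samples missing from matrix", call. = FALSE)
  if (g$n_case < 1 || g$n_control < 1) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mat <- mat[, idx, drop = FALSE]
  m1 <- rowMeans(mat[, g$is_case, drop = FALSE])
  m2 <- rowMeans(mat[, !g$is_case, drop = FALSE])
  data.frame(probe = rownames(mat), beta_case = m1, beta_control = m2,
             delta_beta = m1 - m2, row.names = NULL, stringsAsFactors = FALSE)
}

#' Full per-probe differential methylation statistics
#'
#' Combines the moderated test with the beta-scale deltaBeta and, when a
#' manifest is supplied, the probe's gene, gene-region feature and island
#' relation. The moderated statistic is computed on beta values by default;
#' `use_mvalues = TRUE` switches the test (not the deltaBeta) to the
#' logit-transformed M-value scale. BH-adjusted q-values are included as an
#' extra transparency column; DMS calling uses raw p.
#'
#' @param mat probes x samples beta matrix.
#' @param design `data.frame(sample, group)`.
#' @param manifest optional probe manifest (see [read_manifest()]).
#' @param use_mvalues test on `log2(beta/(1-beta))` instead of beta.
#' @param d0 optional prior-df override, passed to
#'   [fit_two_group_moderated()].
#' @param mval_eps boundary offset for the M-value transform.
#' @return data.frame, one row per probe, with deltaBeta, moderated
#'   statistic, p, q, and manifest annotation when available.
#' @export
dms_stats <- function(mat, design, manifest = NULL, use_mvalues = FALSE,
                      d0 = NULL, mval_eps = 1e-3) {
  delta <- compute_delta_beta(mat, design)
  test_mat <- if (use_mvalues) {
    log2(pmin(pmax(mat, mval_eps), 1 - mval_eps) /
           (1 - pmin(pmax(mat, mval_eps), 1 - mval_eps)))
  } else mat
  fit <- fit_two_group_moderated(test_mat, design, d0 = d0)
  stopifnot(identical(delta$probe, fit$probe))
  out <- cbind(delta,
               fit[c("t_mod", "df_total", "p", "s2", "zero_variance")])
  out$q <- bh_fdr(out$p)
  if (!is.null(manifest)) {
    mi <- match(out$probe, manifest$probe)
    if (anyNA(mi)) {
      stop("probe missing from manifest: ", out$probe[which(is.na(mi))[1]],
           call. = FALSE)
    }
    out$gene <- manifest$gene[mi]
    out$feature <- manifest$feature[mi]
    out$island_relation <- manifest$island_relation[mi]
  }
  attr(out, "d0") <- attr(fit, "d0")
  attr(out, "s02") <- attr(fit, "s02")
  out
}

#' Call differential methylation sites
#'
#' Keeps probes with `|delta_beta| > delta_min` (strict) and `p < p_max`
#' (strict); direction is `hyper` for positive deltaBeta (cases more
#' methylated), `hypo` otherwise. Per-direction counts and the
#' hypermethylated proportion are attached as the `direction_summary`
#' attribute.
#'
#' @param stats output of [dms_stats()] (any data.frame with `delta_beta`
#'   and `p` works).
#' @param delta_min strict threshold on `|delta_beta|`.
#' @param p_max strict threshold on `p`.
#' @return the DMS subset with a `direction` column.
#' @export
call_dms <- function(stats, delta_min = 0.1, p_max = 0.01) {
  stopifnot(all(c("delta_beta", "p") %in% names(stats)))
  keep <- abs(stats$delta_beta) > delta_min & stats$p < p_max
  out <- stats[keep, , drop = FALSE]
  out$direction <- ifelse(out$delta_beta > 0, "hyper", "hypo")
  rownames(out) <- NULL
  n_hyper <- sum(out$direction == "hyper")
  attr(out, "direction_summary") <- data.frame(
    n_dms = nrow(out), n_hyper = n_hyper, n_hypo = nrow(out) - n_hyper,
    prop_hyper = if (nrow(out)) n_hyper / nrow(out) else NA_real_)
  out
}

#' Genomic-context distribution of DMS versus background
#'
#' Cross-tabulates DMS and background probes over island relation x
#' gene-region feature, with proportions, the DMS/background enrichment
#' ratio and a per-cell Fisher enrichment p.
#'
#' @param dms DMS table (needs a `probe` column; `direction` used if
#'   present).
#' @param manifest probe manifest covering every DMS probe (hard error
#'   otherwise).
#' @param background probe ids forming the comparison universe; defaults to
#'   all manifest probes.
#' @return data.frame with one row per island-relation x feature cell.
#' @export
region_distribution <- function(dms, manifest, background = NULL) {
  probes <- dms$probe
  mi <- match(probes, manifest$probe)
  if (anyNA(mi)) {
    stop("DMS probe missing from manifest: ", probes[which(is.na(mi))[1]],
         call. = FALSE)
  }
  background <- background %||% manifest$probe
  bi <- match(background, manifest$probe)
  if (anyNA(bi)) {
    stop("background probe missing from manifest: ",
         background[which(is.na(bi))[1]], call. = FALSE)
  }
  lev_isl <- union(ISLAND_RELATIONS, unique(manifest$island_relation))
  lev_fea <- union(GENE_FEATURES, unique(manifest$feature))
  tab_d <- table(factor(manifest$island_relation[mi], lev_isl),
                 factor(manifest$feature[mi], lev_fea))
  tab_b <- table(factor(manifest$island_relation[bi], lev_isl),
                 factor(manifest$feature[bi], lev_fea))
  out <- expand.grid(island_relation = lev_isl, feature = lev_fea,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_dms <- as.vector(tab_d)
  out$n_background <- as.vector(tab_b)
  nd <- length(probes); nb <- length(background)
  out$prop_dms <- if (nd) out$n_dms / nd else 0
  out$prop_background <- if (nb) out$n_background / nb else 0
  out$ratio <- ifelse(out$prop_background > 0,
                      out$prop_dms / out$prop_background, NA_real_)
  out$p_enrich <- vapply(seq_len(nrow(out)), function(i) {
    fisher_exact_2x2(out$n_dms[i], nd - out$n_dms[i],
                     out$n_background[i], nb - out$n_background[i])$p
  }, numeric(1))
  if (!is.null(dms$direction)) {
    tab_h <- table(factor(manifest$island_relation[mi][dms$direction == "hyper"],
                          lev_isl),
                   factor(manifest$feature[mi][dms$direction == "hyper"],
                          lev_fea))
    out$n_hyper <- as.vector(tab_h)
    out$n_hypo <- out$n_dms - out$n_hyper
  }
  out
}
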