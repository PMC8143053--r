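---
title: "Methods: rare-variant / DNA-methylation cross-talk analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant / DNA-methylation cross-talk analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcrosstalk)
```

## The analysis problem

Case-control studies of congenital heart disease increasingly collect two
molecular layers on the same population: whole-exome variant calls on a
large cohort, and array methylation (beta values) on a small subgroup.
Neither layer alone is decisive — rare-variant hits at raw significance are
plentiful, and differential methylation in a handful of samples is noisy —
so the analysis strategy is convergence: a gene is interesting when its
case-enriched rare-variant signal can be *linked to the methylation layer*
by at least one of three mechanisms, and when it additionally sits next to
established disease genes in the interaction network. This package
implements that strategy as a reusable, fully tested pipeline, with a
synthetic-study generator in place of patient data.

## Statistical model, stage by stage

### Rare-variant association

Variants enter the analysis filtered to the rare, deleterious,
protein-altering set: annotated MAF < 0.05 (strict), SIFT "damaging", and
functional class in {non-synonymous SNV, stopgain, frameshift, splicing}.
Genotypes are collapsed to carrier states (dominant coding): any
non-reference allele makes the sample a carrier. Diploid dosage is not
modelled — with MAF < 0.05 homozygous carriers are rare, and carrier
counts are what this kind of study reports.

Two tests are run:

* **Per-variant Fisher scan.** For each variant, the 2×2 table
  carriers/non-carriers × case/control is tested with a two-sided Fisher
  exact test. The per-gene minimum of these p-values supplies the
  "per-variant" gene list.
* **Gene burden (CMC collapsing).** A sample is a *gene* carrier iff it
  carries at least one qualifying variant of the gene; the collapsed 2×2
  table is tested exactly. Collapsing borrows strength across variants and
  is the minimal defensible burden test when per-variant counts are tiny.

The two statistics select overlapping but distinct gene lists (the
per-variant minimum-p is sensitive to a single strong variant, the burden
test to diffuse carrier excess); the default candidate set is their union
at raw *P* < 0.05, switchable to intersection or either list alone. No
multiple-testing correction is applied at this stage by design: the
downstream integration criteria and the network filter are the error
control, and raw-threshold counts keep every stage auditable. A "top tier"
at *P* < 0.01 is labelled for reporting.

The Fisher p-value is computed by summing hypergeometric probabilities
(fixed margins) over all tables at most as probable as the observed one,
with a relative tie tolerance of 1e-7. Degenerate tables (a zero margin)
give *p* = 1; the odds ratio is the sample cross-product, `Inf` when only
the case side is occupied and `NaN` (undefined) for the all-zero table.
Monomorphic variants are retained with *p* = 1 and flagged rather than
dropped, so variant counts reconcile across stages.

### Differential methylation

Beta values — methylated signal fractions in [0, 1] — are tested on their
native scale, because the deltaBeta effect threshold is defined on that
scale; an M-value (logit) mode is available but off by default. Per probe
*g* the pipeline reports:

* `deltaBeta = mean(beta_case) − mean(beta_control)`, an exact arithmetic
  difference with no shrinkage, and
* a moderated *t*: pooled two-group variance *s²_g* on *d_g = n₁+n₂−2* df,
  shrunk toward a prior *s₀²* with *d₀* df estimated from all probes by
  matching the mean and variance of log *s²_g* to the scaled-F model
  (digamma/trigamma moment equations, trigamma inverted by Newton
  iteration). The posterior variance is
  *s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)* and the statistic is referred to
  a *t* distribution on *d₀ + d_g* df.

Degenerate situations are handled explicitly: if the observed log-variance
dispersion does not exceed its sampling noise (e.g. all *s²_g* equal), the
estimate degenerates to *d₀ = ∞* — the pooled-variance limit, where the
test ranks probes by |deltaBeta| — with a warning. A probe with zero
variance in both groups still gets a finite statistic through shrinkage and
is flagged. Forcing *d₀ = 0* recovers the classical pooled two-sample *t*
exactly; both limits are pinned by tests.

A probe is called a DMS when |deltaBeta| > 0.1 **and** *p* < 0.01, both
strict inequalities (a probe at exactly 0.1 or exactly 0.01 is excluded).
BH-adjusted q-values are emitted as an extra column for transparency but
play no role in calling. Hyper/hypomethylation is the sign of deltaBeta
(case minus control). Sample QC is a Pearson correlation matrix across
probes, with zero-variance samples flagged as undefined rather than
propagating `NaN`, and a within-group median-correlation flag (default
threshold 0.9).

Probes annotated to several genes (semicolon lists) are expanded to one row
per gene for gene-level overlap. Genomic context is summarised as DMS vs
background counts over island relation × gene-region feature with
enrichment ratios and per-cell Fisher p-values.

### Integration criteria

Candidate genes from the association stage are linked to methylation three
ways:

1. **DMS overlap** — the gene carries ≥ 1 called DMS probe; gene direction
   is hyper/hypo from the probe signs, "mixed" when both occur.
2. **CpG-island variant** — a filtered variant of the gene lies inside an
   island. Islands are BED intervals (0-based half-open), so a 1-based
   position *p* is inside `start end` iff `start < p ≤ end`; this boundary
   convention is pinned by tests at both interval ends.
3. **meQTL linkage** — a variant locus of the gene matches an meQTL SNP
   (exact chrom+pos match preferred; gene-symbol fallback with a logged
   downgrade when the pair table carries no coordinates) whose target
   probe is a called DMS. The DMS requirement on the target
   (`require_dms_target`) is on by default — a regulatory link to an
   unperturbed probe is not methylation evidence — and switchable.

Records carry per-criterion flags and supports; the exclusive Venn regions
over the three sets (optionally four, with the known-gene panel) partition
the union exactly. A reporting tier keeps genes whose collapsed case
carrier frequency exceeds the control frequency.

### Enrichment and network prioritization

Over-representation uses the one-sided hypergeometric upper tail
*P(X ≥ k)* — the enrichment question is directional — with BH FDR across
terms and a report filter at *p* ≤ 0.05 and FDR < 0.05. The background
defaults to the union of all term genes and the query set and is
configurable, since the correct universe depends on how the term map was
built.

The interaction network keeps edges with score ≥ 0.4 (the common
medium-confidence convention), deduplicates undirected edges by maximum
score, and measures unweighted hop distance from the known-gene panel
(multi-source BFS). Candidates within distance 1 — direct interactors —
are kept by default; unreachable candidates are never kept, even with
`max_distance = Inf`.

## The synthetic-study generator

The generator's defaults are the study conditions the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `n_case`, `n_control` | 216, 100 | variant-arm cohort |
| `n_genes`, `variants_per_gene` | 500, 1–4 | gene universe (desk scale) |
| `background_carrier_rate` | 0.05 | per-variant null carrier probability |
| `n_enriched`, `enriched_or` | 10, 8 | planted genes; case carrier odds × 8 |
| `maf_range` | [0.001, 0.049] | annotated MAF (fraction) |
| `meth_case_n`, `meth_control_n` | 11, 5 | methylation-arm group sizes |
| `n_probes`, `n_spiked`, `spike_delta` | 5000, 200, ±0.25 | beta matrix and planted DMS |
| `beta_modes`, `beta_dispersion` | 0.2/0.8, 0.08 | bimodal baseline; logit-scale SD |
| `island_coverage` | 0.8 | probability a planted gene's variant gets an island |
| `frac_cis`, `cis_window` | 0.7, 1 Mb | planted meQTL geometry |

Carrier states are Bernoulli draws at the background rate, with the odds
ratio applied to case samples of enriched genes (probabilities outside
(0, 1) are rejected). Beta noise is logit-normal around the probe mean:
simple, strictly inside [0, 1], and with an SD that shrinks near the
boundaries as array data does; the dispersion parameter is the logit-scale
SD. Spiked probes shift the case mean by the planted delta on the beta
scale and are started from the baseline mode that leaves room for the
shift. Islands are 51-bp intervals centred on the selected variants and
verified to cover exactly the planted set. The PPI is a
preferential-attachment (scale-free) graph over all genes plus the known
core, with one guaranteed direct edge per planted gene. All generation is
deterministic given the seed (stage-offset sub-seeds, global RNG state
restored); seeds are mandatory.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: probe-probe correlation and batch structure,
cell-composition effects, genotyping/annotation error, linkage
disequilibrium, population stratification, subtype heterogeneity within
cases, and realistic meQTL discovery noise (planted pairs are true links
by construction). Results on synthetic bundles demonstrate correctness of
the machinery and its operating characteristics under the stated model,
not performance on a real cohort.

## Numerical choices and problem sizes

* Exactness of the 2×2 test is checked against exhaustive enumeration over
  every table with total ≤ 30 (tolerance 1e-10), and against
  `stats::fisher.test` on random tables; the moderated fit is cross-checked
  against the limma reference implementation on a heterogeneous-variance
  fixture.
* Calibration and power of the burden test are measured at 200 cases /
  100 controls and 1000 genes: null false-positive fraction at
  *P* < 0.05 over 20 seeds (expected conservative, ≤ 0.06), and recovery
  of odds-ratio-8 genes over 50 seeds (≥ 90%).
* DMS operating characteristics use 5000 probes, 11 vs 5 samples, 200
  spikes at |delta| = 0.25 and logit-SD 0.08 — sensitivity ≥ 0.8 at
  false-positive rate ≤ 0.02.
* End-to-end recovery runs the full pipeline on ten default-design bundles
  and requires the final candidate list to equal the planted cross-talk
  genes exactly.

These sizes were chosen as the smallest designs at which the properties
are sharply testable; the acceptance script reuses the same designs with
fewer replicate seeds (5 null, 10 power, 3 spike-in) since it reports
point estimates rather than asserting bounds.

## Known limitations

* The burden test is unadjusted collapsing: no covariates, no weights, no
  variance-component (SKAT-type) alternative.
* The methylation model is a plain two-group comparison; paired designs,
  subtype covariates and multi-probe region calling are out of scope.
* meQTL matching trusts the supplied pair table; no attempt is made to
  assess transferability of links discovered in other tissues.
* Gene symbols are the join key throughout; harmonization of synonyms is
  the caller's responsibility.
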