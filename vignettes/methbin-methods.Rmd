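---
title: "Bin-based WGBS DMR analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based WGBS DMR analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures methbin implements, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where more than one reasonable
convention exists.

## The quantification model

Bisulfite sequencing reports, for each CpG, a number of methylated and
unmethylated calls. methbin works at near-nucleosomal resolution: fixed
200-bp bins tiled from coordinate 0 of each chromosome (0-based,
half-open coordinates everywhere internally; the Bismark coverage
dialect's 1-based positions are converted at the parser boundary). CpGs
are palindromic, so calls on the reverse-strand G at position p+1 are by
default folded into the forward-strand C record at p, doubling effective
depth.

A bin's methylation level is the percentage of methylated calls among all
calls of its CpGs. Pooling calls rather than averaging per-CpG fractions
weights each sequenced molecule equally and is robust at moderate depth.
A bin enters analysis only if it has **≥ 2 covered CpG sites** and
**≥ 10 total calls** (`min_cpgs`, `min_calls`). The coverage filter is
read on the same pooled quantity that defines the level, since that is
the number whose precision it guards. Bins with no covered CpG are
omitted entirely: absence of data is not hypomethylation.

Two global summaries are provided: *site mode* (ratio of pooled calls
over all passing bins — the default, matching a per-CpG-call average) and
*bin mode* (unweighted mean of bin levels — the scale on which the
bin-unit significance test operates). Category means (a gene's 3′ CGI,
a CGI set, ...) are unweighted means of associated passing-bin levels.

## DMR calling

Between two profiles *a* → *b*, only bins passing the filter in **both**
profiles are compared, and a bin is a DMR iff
|level~b~ − level~a~| > `dmr_threshold` (default 15 percentage points,
strict inequality, absolute — not relative — change). Direction is GAIN
iff the difference is positive. Maturation contrasts (mDMR) are oriented
early age → late age within a cell type; differentiation contrasts (dDMR)
stem cell → differentiated within an age.

No per-bin statistical test is attached. The method targets deeply
sequenced pooled-sample methylomes, where each profile is a single pooled
measurement and a replicate-aware dispersion model has nothing to
estimate; calling is therefore the transparent threshold rule. Adjacent
same-direction DMR bins are *not* merged by default (counts are at bin
resolution); `merge_adjacent = TRUE` is available where region-level
counting is wanted.

## Gene-region classification and the eight groups

Gene models (refFlat) are collapsed per gene symbol by the union of
isoform exons before classification; "first" and "last" exons are taken
on the collapsed model in transcription orientation. This is
deterministic and avoids privileging an arbitrary isoform. Three
footprints are computed per gene:

* **THREE_PRIME** — last exon ∪ exonic 3′ UTR;
* **FIVE_PRIME** — `promoter_span` bases upstream of the TSS ∪ first exon
  ∪ exonic 5′ UTR;
* **GENE_BODY** — the remaining transcript span (introns + internal
  exons).

A bin overlapping a gene (or its promoter extension) receives exactly one
category per gene, with precedence THREE_PRIME > FIVE_PRIME > GENE_BODY
when it straddles sub-regions. The precedence is a design choice: the
biological signal of interest concentrates at 3′ ends, so 3′ assignments
must not be diluted into the body by boundary bins. A bin overlapping
several genes is assigned to each (the group tables count
bin-gene assignments, not unique bins), and single-exon genes resolve to
THREE_PRIME by the same precedence. `promoter_span` defaults to 2000 bp —
a common promoter convention — and is exposed (0 disables the upstream
extension) because the 5′ category's upstream extent is genuinely
ambiguous.

CGI status is a ≥ 1-bp overlap with any island from the user-supplied,
merge-normalised CGI list; the package deliberately consumes published
interval lists rather than detecting islands de novo.

Gene-associated DMRs are then partitioned into the eight groups
{gain, loss} × {CGI, non-CGI} × {5′, gene body or 3′}; intergenic DMRs
contribute to no group.

## The statistical layer

**Bin-unit proportion test.** The phrase "a test for proportions with the
bin as the unit" admits two readings; both ship. The default scores each
mutually passing bin as one Bernoulli observation (success =
level~a~ > level~b~, exact ties dropped) and tests p = ½ — exact binomial
up to 1000 informative bins, a normal approximation with continuity
correction beyond. This respects the bin as the observation unit. The
alternative (`variant = "pooled"`) is a two-proportion test on pooled
calls; it is more powerful but treats the call, not the bin, as the unit.

**Enrichment.** Each term is a 2×2 table (in term / not) × (DMR gene /
other universe gene); p is the two-sided Fisher exact probability by the
minimum-likelihood rule (sum of hypergeometric probabilities of tables no
more likely than observed — the convention of `stats::fisher.test`,
stated explicitly here because two-sided Fisher conventions differ), and
the correction is Bonferroni over the terms actually tested. Gene sets
arrive as GMT files; there is no web dependency and no GO-hierarchy
propagation.

**Regression.** Expression ~ methylation + age, ordinary least squares,
with age in days as a continuous covariate (log(age+1) by option; the
parameterisation is not canonical, so both are exposed). The reported
quantity is the methylation partial coefficient, its two-sided p, and
sign; BH FDR is applied across genes. Designs with methylation collinear
with age are refused via a rank and condition-number guard rather than
silently returning an unstable estimate.

**t tests.** Two-tailed pooled-variance Student by default (Welch by
flag), used for per-site condition comparisons.

**Clustering.** Agglomerative, Euclidean distance, average linkage —
unremarkable defaults chosen because the panel's between-age separation
is large relative to any metric subtlety; both are configurable and
recorded in the output metadata. Leaf order is deterministic
(`stats::hclust` tie-breaks by original index). Rows may optionally be
z-scored; the default is the raw percent scale, since percent methylation
is already a common scale across sites. In the panel comparison the
baseline age (chronologically earliest, parsed from labels such as E18.5
/ P0 / P21) is excluded: conditions coincide at birth by design, and the
question is whether post-colonization changes occurred.

## What the synthetic generator emulates

The default configuration is a desk-scale miniature: 2 chromosomes ×
2 Mb, 200 genes in regular slots, ~300 CGIs preferentially placed at gene
5′ and 3′ ends, 20× mean coverage — minutes of compute on one CPU. It
emulates the statistical structure the analysis assumes:

* **Compartmental baselines** — non-CGI CpGs at 75 % methylation, CGI
  CpGs at 10 %, matching the genome-wide-high / island-low organisation
  of vertebrate methylomes.
* **Planted DMRs** — bins inside 5′/body/3′ CGIs or non-CGI CGI-shore
  flanks, with exact |Δ| (default 30 points) between the appropriate
  samples. Where a full ± Δ step would leave the percent scale, the
  pre-level is shifted into [2, 98] so the planted effect size is always
  exact. The default composition mirrors the developmental signature
  under study: CGI maturation gains concentrated at gene body/3′, non-CGI
  maturation losses at shores, and a smaller differentiation axis.
* **Counting noise** — per CpG and sample, depth ~ Poisson(coverage) and
  methylated calls ~ beta-binomial around the true level.
* **Expression coupling** — genes with planted 3′ CGI maturation gains
  get expression = intercept + coupling × true 3′ CGI methylation + age
  trend + Gaussian noise (coupling 0.02 expression units per percentage
  point by default), relative to a constant reference gene; matched
  uncoupled genes share the age trend only.
* **Developmental panels** — CpG-site × sample percent matrices with
  within-age noise (sd 2 points) far below between-age steps (20–35
  points), two constant high-methylation repeat-element rows, and a
  germ-free condition in which the developmental-gain block fails to rise
  after the first age.

Two generator parameters deserve explicit justification, because the
miniature genome is a compression, not a copy, of a mammalian genome:

* **CpG density** (`cpg_spacing` 20 bp outside CGIs, 8 bp inside). Real
  genome-wide spacing is nearer 100 bp, but at 20× coverage a 200-bp bin
  with 2–3 CpGs carries ~40–60 calls, and the binomial noise floor of a
  level difference at that depth is ±8–10 points — threshold-scale noise
  that would swamp a 20k-bin miniature with false calls regardless of
  implementation quality. The miniature instead reproduces the per-bin
  call depths of the CpG-dense regulatory territory (CGIs, shores, gene
  ends) where the analysis' planted signal lives, which is what makes
  recall/false-positive properties of the *caller* measurable at desk
  scale.
* **Overdispersion** (`dispersion` 0.01). Beta-binomial noise is kept
  (real WGBS is overdispersed; `dispersion = 0` recovers pure binomial
  for analytic checks), but the default is low because the emulated
  measurements are pooled over many individuals, and pooling averages
  away inter-individual variance. Per-CpG dispersion contributes
  p(1−p)·d/m to a bin's level variance (m CpGs per bin), i.e. a
  level-difference sd of ~3–5 points at d = 0.05 for CpG-sparse bins —
  again threshold-scale — while d = 0.01 keeps the planted Δ = 30 at
  > 4 sd from the 15-point threshold.

What the generator does **not** emulate: read-level artefacts (no FASTQ,
no M-bias, no conversion-efficiency error), sequence content, copy-number
or CpG-destroying variation, biological replicate structure for the
methylomes, chromosome-scale features (telomeres, imprinted megabase
domains), or realistic gene-length and CGI-length distributions. Passing
tests therefore demonstrate correctness of the pipeline's arithmetic and
its operating characteristics under the stated noise model — not
performance on real libraries with alignment artefacts.

## Numerical choices

* Two-sided Fisher p sums probabilities ≤ observed × (1 + 10⁻⁷) to absorb
  floating-point ties, and is clamped to ≤ 1 (the sum of all table
  probabilities can exceed 1 by rounding when the observed table is the
  mode).
* The sign test switches from exact binomial to the continuity-corrected
  normal approximation above 1000 informative bins.
* Division by zero never arises in binning: uncovered bins are omitted,
  and the filter guarantees total calls ≥ 10 before any level is used.
* Degenerate t tests (zero pooled variance) and degenerate regression
  designs error out rather than returning NaN.
* Clustering of a constant matrix (all distances zero) proceeds with the
  index tie-break rather than erroring.
* BH-adjusted p values satisfy monotonicity and never fall below the raw
  p; note that the step-up adjustment is not idempotent on its own output
  (re-adjusting adjusted values inflates them), which is a property of
  the standard definition, not an implementation artefact.

## Problem sizes used in validation

The test suite validates interval and binning arithmetic against
per-base brute-force oracles on 200 random 10-kb toy genomes, Fisher p
values against explicit table enumeration for every universe size up to
60, DMR recall and false-positive rates on five full default miniatures
(~195k CpGs × 4 samples each), regression calibration on > 1000 planted
expression series, and panel clustering on 20 seeded panels. These sizes
were chosen to exercise every code path at full statistical resolution
while keeping the whole suite around a minute or two of CPU.

## Known limitations

* DMR calling has no replicate-aware dispersion model and no
  smoothing/HMM machinery; it is intentionally the transparent
  threshold rule and should not be applied to shallow single-replicate
  libraries, where binomial noise alone crosses the threshold.
* The proportion test's two variants bracket, but cannot resolve, the
  ambiguity in "test for proportions with the bin as the unit".
* Enrichment treats gene sets as flat; hierarchical (parent–child aware)
  GO analysis is out of scope.
* Normality screening ahead of the t tests is not performed; the input
  scale is trusted.
* The CLI wrapper covers the simulate/analyse loop; bespoke analyses are
  expected to go through the R functions.
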