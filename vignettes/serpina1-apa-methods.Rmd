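---
title: "Quantifying SERPINA1 3'UTR alternative polyadenylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SERPINA1 3'UTR alternative polyadenylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apa3utr)
```

## The biological problem

The SERPINA1 mRNA, which encodes the neutrophil elastase inhibitor
alpha-1-antitrypsin (A1AT), carries two cleavage/polyadenylation sites in
its 3'UTR: a proximal site shortly after the stop codon and a distal site
roughly 1.6 kb further 3'. Transcripts ending at the distal site carry a
long 3'UTR that strongly represses translation, so the *fraction of
transcripts using the distal site* — not overall mRNA abundance — becomes a
lever on A1AT protein output. This package implements the full quantitative
toolkit around that observation: estimating distal-site usage from
coverage, comparing it across cohorts (e.g. COPD cases vs controls), PI
genotypes, GOLD stages, subcellular fractions and single-cell clusters;
annotating the cleavage sites and the RNA-binding-protein (RBP) motifs
around them; modelling which 3'UTR regions carry the repression; scoring
RBPs for their predicted effect on site usage in disease; and summarizing
chemical structure-probing data for the same transcript.

## The distal ratio

For a per-base coverage track, let $P$ and $D$ be the summed read depths
over the proximal-specific and distal-specific segments, with lengths
$L_p$ and $L_d$. The distal ratio is

$$ r \;=\; \frac{D/L_d}{\,D/L_d + P/L_p\,}. $$

It lies in $[0,1]$, is exactly invariant to rescaling all depths, and is
set to missing when both segments have zero coverage (such samples are
excluded listwise from comparisons).

**The estimand is bounded below 0.5.** Both isoforms cover the proximal
segment, so with short-isoform abundance $S$ and long-isoform abundance
$L$ the ratio converges to $L/(S + 2L) < 1/2$ as depth grows
(`true_distal_ratio()`). Published per-tissue ratios near or above 0.5
therefore imply either region definitions that are not strictly
isoform-specific or proximal-coverage depletion; worth keeping in mind
when comparing absolute values across studies.

**Region definitions.** The packaged default (`serpina1_region_spec()`)
derives all genomic intervals from the published *transcript* coordinates
of the proximal segment and distal Regions 1–4, anchored at transcript
position 1519 = chr14:94378451 on the minus strand. We use the transcript
coordinates because the published genomic spans are internally
inconsistent (Region 1 spans 398 transcript nt but 399 genomic nt as
printed, and the printed Region 1/2 genomic spans overlap by 2 nt);
`check_table_coordinates()` reports these mismatches rather than silently
correcting the published values. Derived this way the proximal segment is
79 bp and Regions 1–4 tile a 1602 bp distal segment exactly. Any
alternative definition can be supplied as BED.

**Statistical choices.** The cohort comparison reports the fold change of
group medians and a two-sided Mann–Whitney U p-value — distribution-free
and consistent with the median framing; exact for groups of at most 8
untied values, normal approximation with tie correction otherwise. The
disease-stage trend uses Spearman rank correlation. These procedures were
chosen because the source analyses name none; both are the field-standard
defaults for skewed ratio distributions.

**Single cells.** The same formula applies per cell to region read
counts; cells with fewer than `min_total_reads = 3` region reads are
dropped (a ratio from one or two reads is almost binary). Because
per-cell ratios are noisy, the per-cluster output reports both the median
of per-cell ratios and a pooled ratio (counts summed across the cluster
before normalization); the two agree for deep clusters and the pooled
form is more stable for sparse ones.

## Cleavage-site calling and motif annotation

3'-end sequencing yields per-base counts of read 3' ends.
`call_end_peaks()` clusters non-zero positions greedily in transcript
direction: successive end positions at most `merge_window = 8` nt apart
join one cluster, clusters with fewer than `min_count = 10` reads are
dropped (reads conserved via the `discarded_count` attribute), and the
summit is the maximum-count position with ties broken 3'-ward — matching
the sharp 3' cliff expected at a genuine cleavage site. The procedure is
deliberately simple because the signal is two well-separated single-
nucleotide peaks, not a genome-wide atlas.

Around each summit, `scan_pas()` reports every hexamer within 40 nt
upstream at Hamming distance at most 1 from the canonical
polyadenylation signal `AAUAAA` (so the known weaker proximal signal
`AUUAAA` is a variant hit, and the engineered proximal mutation `AUCAAG`,
at distance 2, is correctly not a hit). We scan all Hamming-1 neighbours
rather than a curated variant list because only those two hexamers are
documented for this transcript. `scan_gu_rich()` slides 10-nt windows
across 40 nt downstream and calls a G/U-rich element when some window
reaches 60% G/U — conventional values, configurable, since no numeric
criterion is published.

The bipartite QKI motif `5'-NACUAAY-N(1,20)-UAAY-3'` is scanned by
`scan_qki_motif()`. Because the consensus does not define multiplicity,
the default pairs each 7-nt half-site with its nearest valid downstream
closer (shortest spacer) without reusing half-sites; an exhaustive mode
reports every valid pairing and is the form checked against a brute-force
enumeration oracle in the tests. DNA input is treated as RNA throughout.

## The deletion-construct translation model

Reporter constructs delete subsets of distal Regions 1–4; normalized
luminescence $y$ is modelled with no intercept as

$$ y \;=\; t_1 x_1 + t_2 x_2 + t_3 x_3 + t_4 x_4, $$

where $x_i = 1$ when Region $i$ is **absent** from the construct. Under
this parameterization the Long construct (nothing deleted) predicts 0 and
the Short construct predicts $\sum_i t_i \approx 0.96$ — the only reading
under which a no-intercept model is consistent with Short being the
brightest construct. Each $t_i$ is the translation gained by removing
region $i$, i.e. that region's share of the repression.

**Construct composition.** The deletion series is published only
graphically, so composition is an explicit input. The packaged default
(`serpina1_deletion_design()`) uses Del1 = {2,3,4}, Del2 = {1},
Del3 = {2}, Del4 = {3}, Del5 = {1,2}, Del6 = {2}. This satisfies the
stated constraints (Deletion 1 removes Regions 2–4; Deletions 5 and 6
both retain Regions 3 and 4) and — crucially — has full column rank. A
composition in which Regions 3 and 4 are only ever deleted together makes
$t_3$ and $t_4$ unidentifiable (their design columns coincide), and
`fit_region_coefficients()` refuses such designs by name rather than
returning an arbitrary solution.

**Fitting.** Replicates are individual observations in an unweighted
no-intercept OLS (`lm(y ~ 0 + X)`); construct means enter only the
reported $R^2$, computed as the squared correlation between per-construct
predicted and mean observed expression. Normalization divides each batch
by its Short-construct mean and clips to $[0,1]$ (min–max normalization
is available as an option); the 0–1 normalization procedure is not
detailed in the source, so the Short-referenced form was chosen as the
one that gives the reference construct a defined value of 1 in every
batch. Whether the original fit used replicate-level or mean-level
observations is unknown; the coefficient estimates are identical either
way, but standard-error scales need not be comparable.

With the published coefficients $t = (0.34, 0.08, 0.22, 0.32)$, Regions
1, 3 and 4 carry $0.88/0.96 = 91.7\%$ of the repression:

```{r}
t_pub <- serpina1_translation_coefficients()
variance_attribution(t_pub, c("Region1", "Region3", "Region4"))
```

## The RBP two-dimensional volcano

For each RBP with shRNA knockdown data, place it at
$(\mathrm{d}x, \mathrm{d}y)$ where $\mathrm{d}x$ is its log2 fold change
in disease and $\mathrm{d}y$ is its knockdown distal ratio minus the
empty-vector control ratio. Knockdown shows what *less* protein does, so
when the protein is down in disease ($\mathrm{d}x < 0$) the disease
effect has $\mathrm{d}y$'s sign, and the opposite otherwise: the RBP is
predicted to *increase* the disease distal ratio when
$\mathrm{d}x\,\mathrm{d}y < 0$ and to *decrease* it when
$\mathrm{d}x\,\mathrm{d}y > 0$. The effect size is the Euclidean distance
$d$ from the center on the raw axes (no standardization, matching the raw
plotting convention; a z-scored mode exists for sensitivity analysis),
scored as $s \cdot \log_2 d$ with $s = \pm 1$ by direction. Note that for
$d < 1$ the log is negative, so the *sign* of the score inverts relative
to the color semantics; selection and ranking therefore use $|\log_2 d|$
only, which is unaffected. Candidates require both adjusted p-values
(knockdown ratio change, differential expression) below 0.05 and
$|\log_2 d| > 1$; raw knockdown p-values are Benjamini–Hochberg adjusted
across the record set first. The control ratio is a required input — its
numeric value is not published — and 0.07 is used as the working default
in examples and simulations, consistent with lung-scale ratios sitting
below the QKI knockdown value's published control.

## Structure metrics

SHAPE reactivities are classified with the standard color thresholds
(high $\ge 0.85$, intermediate $\ge 0.4$), configurable. Per-nucleotide
Shannon entropy is computed from a base-pairing probability matrix as
$H_i = -\sum_j P_{ij}\log_{10} P_{ij}$ over pairing partners only — the
common convention for structure-entropy tracks; since the upstream
folding toolchain's exact convention (base, unpaired term, windowing) is
not restated in the source, absolute entropies are convention-dependent
and an `include_unpaired` variant is provided. Motif accessibility is the
median reactivity over the site's non-missing nucleotides (at least half
must have data), called accessible at the intermediate boundary 0.4.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the analysis stages consume, with
planted truth:

* `simulate_coverage()` — two-isoform coverage: per-base depth is
  negative binomial with mean `mean_depth * (S + L)` in the proximal
  segment and `mean_depth * L` everywhere 3' of it. Dispersion defaults
  to 0.1 (variance $\mu + 0.1\mu^2$) to emulate RNA-seq overdispersion;
  0 degrades to Poisson.
* `simulate_cohort()` — control ratios drawn from Beta(5, 95) (median
  ≈ 0.047, CV ≈ 0.43: lung-scale ratios with the marked inter-individual
  spread the cohort data show), case ratios from the same Beta scaled by
  the planted fold; each ratio is inverted to abundances via
  $L/S = r/(1-2r)$ and capped at 0.45 because the estimand cannot exceed
  0.5. Default `mean_depth = 50` reads/base per abundance unit: at that
  depth measurement error contributes well under 5% of the
  between-subject variance, so cohort-level conclusions are insensitive
  to it while simulations stay light.
* `simulate_end_seq()` — multinomial site assignment with rounded
  Gaussian position jitter (sd 2 nt); read counts conserved.
* `simulate_luminescence()` — linear predictor plus Gaussian noise
  (sd 0.03, four replicates), truncated at zero.
* `simulate_rbp_table()` — 216 null records scattered tightly around the
  volcano center with uniform p-values, plus planted effects (default six
  decreasers and two increasers at $|\log_2 d| > 1$ with vanishing
  p-values, mirroring the scale of the strongest observed knockdown
  effects).

All generators take explicit seeds and restore the global RNG state.
What they deliberately do **not** emulate: positional coverage bias and
exon structure, between-region correlation within a sample, 5'UTR isoform
complexity, fragment-level reads, mapping artifacts, and cell-type
composition shifts. Passing recovery tests on these generators therefore
validates the estimators and the pipeline plumbing — not robustness to
alignment or library-preparation pathologies in real data.

## Numerical behaviour and known limitations

* **Single-sample ratio precision under overdispersion.** With per-base
  NB noise (dispersion 0.1) the proximal segment is only 79 bp, so at
  S = L and proximal depth 2000x the mean proximal depth has CV ≈ 3.6%
  and the single-sample ratio a standard deviation of ≈ 0.008 — per-sample
  estimates land within ±0.01 of the asymptotic 1/3 only about 80% of the
  time, and no finite depth removes the overdispersed per-base variance's
  contribution through such a short segment. The estimator is unbiased
  (mean across seeds ≈ 1/3 to three decimals), and under Poisson noise the
  sd drops to ≈ 6×10⁻⁴. Cohort comparisons are unaffected in practice:
  between-subject spread dominates at the default simulation settings.
* **Rank-test calibration.** At the discovery-cohort sizes (82 vs 64) the
  normal-approximation Mann–Whitney test holds its 5% size to within
  binomial noise over 1000 simulated null cohorts.
* **Problem sizes used in the packaged checks** (chosen to make the
  test suite quick to run routinely): 200 seeded deletion-series
  experiments, 500 calibration samples, 1000 null and 200 alternative
  cohorts, 1000 random sequences against the scanner oracles.
* **Degenerate inputs.** Constant ratios give a flagged zero trend;
  a zero control median switches the cohort estimate to a median
  difference; empty end-count tracks yield empty site lists; rank-
  deficient designs and non-symmetric probability matrices error rather
  than warn.
* The packaged analyses do not reproduce controlled-access cohort
  results: those require the original restricted data sets, and the
  recovery/calibration simulations here stand in for them.
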