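# apa3utr

Quantitative analysis of alternative polyadenylation (APA) in the
**SERPINA1** 3'UTR.

The SERPINA1 mRNA (encoding alpha-1-antitrypsin, A1AT) has two
cleavage/polyadenylation sites in its 3'UTR. Transcripts using the distal
site carry a ~1.6 kb longer 3'UTR that strongly represses translation, so
the fraction of transcripts ending at the distal site controls A1AT protein
output independently of mRNA abundance. This package is for researchers who
want to measure and model that event: compute distal-site usage from
RNA-seq coverage, compare it between disease cohorts, genotypes, disease
stages, subcellular fractions and single-cell clusters, annotate cleavage
sites and RBP motifs, attribute the translational repression to 3'UTR
regions, and score RNA-binding proteins for their predicted effect on site
usage in disease.

## The statistics at its core

**Distal ratio.** With `D`, `P` the summed depths over the distal and
proximal 3'UTR segments and `Ld`, `Lp` their lengths:

    r = (D/Ld) / (D/Ld + P/Lp)

Cohorts are compared by the fold change of group medians with a two-sided
Mann–Whitney U test; stage trends by Spearman correlation.

**Translation model.** Normalized reporter luminescence `y` of deletion
constructs follows a no-intercept linear model

    y = t1*x1 + t2*x2 + t3*x3 + t4*x4,   xi = 1 if Region i deleted,

so each coefficient `ti` is Region i's share of the translational
repression; the fraction carried by a region subset is `sum(t_sub)/sum(t)`.

**RBP effect score.** Each RNA-binding protein sits at
`(dx, dy) = (log2 DE fold change, knockdown ratio − control ratio)`; it is
predicted to increase the disease distal ratio when `dx*dy < 0`, decrease
it when `dx*dy > 0`, with effect size `log2 sqrt(dx^2 + dy^2)` and
candidates filtered at `|log2 d| > 1` with both adjusted p-values < 0.05.

Also included: cleavage-site peak calling from 3'-end counts, PAS hexamer
(`AAUAAA` ± 1 mismatch) and G/U-rich element scanning, the bipartite QKI
motif `NACUAAY-N(1,20)-UAAY`, SHAPE reactivity classes, pairing-probability
Shannon entropy, and seeded synthetic-data generators with planted truth
for every stage.

## Worked example

```r
library(apa3utr)

spec <- serpina1_region_spec()
spec
#> <region_spec> SERPINA1 (- strand)
#>   proximal: chr14:94378372-94378451 (79 bp)
#>   distal:   chr14:94376749-94378351 (1602 bp)
#>   subregions: Region1, Region2, Region3, Region4

# a synthetic case/control cohort with a planted 2-fold median shift
sim <- simulate_cohort(n_case = 82, n_control = 64, fold = 2, seed = 20)
ratios <- vapply(sim$tracks,
                 function(tr) compute_distal_ratio(tr, sim$spec)$ratio,
                 numeric(1))
compare_cohorts(ratios[sim$truth$group == "case"],
                ratios[sim$truth$group == "control"])
#> <cohort_comparison> fold change 2.209, p = 6.63e-15 (n = 82 vs 64)

# deletion-series translation coefficients from simulated luminescence
des <- serpina1_deletion_design()
lum <- simulate_luminescence(des, serpina1_translation_coefficients(),
                             sigma = 0.03, n_replicates = 4, seed = 20)
fit <- fit_region_coefficients(des, lum)
fit
#> <translation_coefficients>
#>   Region1: 0.33±0.01
#>   Region2: 0.07±0.01
#>   Region3: 0.23±0.01
#>   Region4: 0.34±0.02
#>   R-squared (construct means): 0.999
variance_attribution(fit, c("Region1", "Region3", "Region4"))
#> [1] 0.9292536

# the bipartite QKI motif
scan_qki_motif("GGAACUAACGGGGGUAAUGG")
#> # A tibble: 1 × 5
#>   half1_start spacer_len half2_start half1_seq half2_seq
#> 1           3          5          15 AACUAAC   UAAU
```

The cohort comparison recovers the planted 2-fold shift (estimate 2.21)
with overwhelming significance at these sample sizes; the fitted
coefficients land within ±0.02 of the generating truth
(0.34, 0.08, 0.22, 0.32), and Regions 1, 3 and 4 together carry ~93% of
the repression in this replicate. The QKI scan reports the 7-nt half-site
at position 3, a 5-nt spacer, and the `UAAU` closer.

## Package layout

* `R/` — interval types and I/O, the distal-ratio statistic and
  comparisons, cleavage-site and motif annotation, the translation model,
  RBP effect scoring, structure metrics, synthetic-data generators.
* `vignettes/serpina1-apa-methods.Rmd` — the models, parameter choices and
  their rationale, and known limitations.
* `tests/testthat/` — unit, property (oracle-checked) and end-to-end
  acceptance tests.
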