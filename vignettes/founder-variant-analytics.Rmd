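---
title: "Founder-variant analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder-variant analytics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
library(dplyr)
```

`founderhap` covers the computational chain used to characterise a founder
copy-number variant in a clinically ascertained cohort: detecting the CNV
from targeted-panel read depth, delineating the shared haplotype around it,
dating the founder event from linkage-disequilibrium decay, quantifying how
unlikely the shared haplotype is to arise by chance, scoring the CNV on the
ClinGen point scale, and summarising penetrance and outcomes in the cascade-
screened families. This vignette explains each model, its assumptions and
tunable parameters, and the design decisions taken where more than one
reasonable convention exists.

## Read-depth CNV detection

On a targeted panel, the read count of each region of interest (ROI,
typically an exon) is proportional to its copy number, its capture
efficiency, and the sample's sequencing depth. `normalize_depth()` removes
the latter two factors in sequence:

1. **within-sample**: each sample's counts are divided by the median count
   over its *control ROIs* — regions assumed diploid in every sample of the
   run. The median (rather than the sum) keeps one aberrant control from
   skewing the factor.
2. **across samples**: each ROI's normalised values are divided by their
   median across all samples of the run, cancelling per-ROI capture
   efficiency.

The resulting dosage ratio is exactly 1 for a clean diploid matrix, ~0.5
over a heterozygous deletion and ~1.5 over a heterozygous duplication.
`call_cnv()` thresholds these ratios at `del_max = 0.65` and
`dup_min = 1.35` and reports maximal contiguous runs. The "approximately
50% / 150%" dosage signals have no canonical hard cut-offs; 0.65/1.35 sit
midway between the heterozygous signals and the diploid baseline, leaving
symmetric guard bands of width 0.35 on either side, and are exposed as
arguments. At depth 500 and above, Poisson counting noise (sd of the ratio
roughly `1/sqrt(500)` = 0.045) is far inside these bands, which is why
recovery of a planted multi-exon deletion is essentially deterministic —
the test suite demands 100 exact recoveries in 100 seeded replicates and
zero calls on null runs.

Normalisation requires at least two samples (the cross-sample reference is
otherwise undefined) and fails loudly for a sample with no reads over the
control regions. GC-content and mappability corrections, useful at genome
scale, are deliberately out of scope for a small targeted panel.

`deletion_span()` uses the coordinate-difference convention
`|start - end|`, which reproduces the published span of the exon 23–26
deletion (Chr11:g.47360721–47357175, GRCh37) as 3546 bp. An inclusive
1-based closed count would give 3547; the difference convention is stated
in the function's documentation. Breakpoints may be supplied in either
order, including the descending order of HGVS `g.` deletion notation.

## Shared-haplotype delineation

Carrier chromosomes descending from a common founder share the marker
alleles flanking the variant until recombination erodes the segment.
`infer_founder_alleles()` takes the founder allele at each microsatellite
to be the modal non-missing allele among carrier haplotypes, with ties
broken towards the smallest allele id so results are reproducible.

`concordant_interval()` finds, per haplotype, the maximal contiguous marker
run containing the variant on which the haplotype carries the founder
allele. The run must include both markers immediately flanking the variant;
a haplotype discordant at either flank is flagged as non-founder-like
(empty interval). Missing microsatellite calls (coded 0) are common
dropouts, so the default `"permissive"` policy lets them bridge a run; the
`"strict"` policy breaks on them instead.

`shared_core()` intersects all per-haplotype intervals. The reported span
is the physical distance between the outermost jointly concordant markers —
a conservative lower bound, since the true recombination breakpoints lie
somewhere between the last concordant and first discordant markers. The
recombinant-exclusion ladder then removes one haplotype at a time, greedily
choosing the haplotype whose removal maximally widens the intersection
(ties towards the earlier row), recording `(n remaining, span)` at each
step. This makes statements like "all 24 share 1.19 Mb; 19 of 24 share
13.8 Mb" a well-defined, deterministic output. The implementation is
checked against a brute-force scan of every contiguous marker interval on
hundreds of random instances.

`synthetic_proband_haplotypes()` ships a constructed 24-haplotype panel
over a 13-marker, 26.4 Mb map whose ladder contains exactly those two
rungs. It reproduces the *sharing structure* of the real proband panel;
the marker coordinates and alleles are synthetic, since the original
genotypes are not public.

```{r replica}
replica <- synthetic_proband_haplotypes()
core <- shared_core(replica$haps, replica$map, replica$variant_bp)
glance(core)
tidy(core) |> filter(n %in% c(24, 19))
```

## Dating the founder event

For a marker at recombination fraction `r` from the variant, the founder
allele survives `t` generations of meiosis on a carrier chromosome with
probability `(1 - r)^t`; chromosomes that recombined carry the background
allele distribution, where the founder allele has frequency `Pn2`. The
expected founder-allele frequency among carriers is therefore

$$P_{d1} = (1-r)^t + \left(1 - (1-r)^t\right) P_{n2},$$

which inverts to the moment estimator implemented in `marker_age()`:

$$t = \frac{\ln\left((P_{d1} - P_{n2})/(1 - P_{n2})\right)}{\ln(1-r)}.$$

Map distances are converted to recombination fractions with the Haldane
(no-interference) function `r = (1 - e^{-2d})/2`, and genetic positions
default to the human-genome rule of thumb 1 Mb ≈ 1 cM unless a measured
`pos_cm` column is supplied (`d` is then `|cM difference|/100` Morgans).

Markers are treated marginally and the per-marker estimates averaged with
equal weights (`estimate_age()`). Two degeneracies are excluded rather than
imputed, with reasons recorded per marker: `Pd1 = 1` (a fully preserved
allele carries no decay information; the formula would return 0 regardless
of `r`) and `Pd1 <= Pn2` (no excess sharing; the log argument is
non-positive). If every marker is excluded the estimate fails loudly.

`to_calendar()` converts generations to years as
`years_ago = t * span + anchor` with a 25-year generation span and the
anchor at the present carriers' mean age (default 63), so `t = 5` dates the
event 188 years back:

```{r calendar}
to_calendar(5, span_years = 25, anchor_age_years = 63, reference_year = 2023)
```

### Numerical behaviour

The inversion is exact in exact arithmetic: the test suite verifies
`marker_age()` recovers `g` to 1e-9 across the full realistic regime. In
double precision the recoverable precision is bounded by the conditioning
of the subtraction `Pd1 - Pn2`: the founder excess `(1-r)^g (1-Pn2)`
shrinks geometrically in `g` and, for distant markers and many generations
(say `r > 0.3, g > 30`), drops toward the rounding resolution of `Pd1`
itself, at which point no algorithm can recover the age from those inputs.
The property tests therefore apply a conditioning-aware tolerance floor of
`eps / (signal * (1 - Pn2) * |ln(1-r)|)` in that corner. For the study-like
regime (`g ≈ 5`, `d ≤ 0.14` Morgans) the identity holds with enormous
margin.

### The descent simulator as validation harness

`simulate_descent()` draws carrier haplotypes under exactly the marginal
model the estimator assumes: per marker, the founder allele is retained
with probability `(1 - r)^g`, otherwise redrawn from the background, with
no marker mutation. This is a deliberate design choice — recombination is
*not* simulated as a crossover process along the chromosome — because it
makes parameter recovery an algebraic identity and so separates estimator
correctness from model mis-specification. A chromosome-level crossover
simulation would introduce correlated retention between linked markers; the
marginal estimator is unbiased under it too, but with larger Monte-Carlo
variance. Background alleles are drawn with the founder allele at frequency
`pop_freqs` and the remaining probability spread uniformly over the other
allele ids (`n_alleles = 6` by default, a typical microsatellite allele
count).

At 100,000 carrier haplotypes and fourteen markers at 1–14 cM, the
five-generation simulation is dated back to 5 ± 0.2 generations; this is
the scale used in the acceptance script (it runs in a few seconds).

## Haplotype-by-chance probability

Independently of the microsatellites, the intragenic SNP configuration
shared by all probands argues for common descent. Under
linkage-equilibrium independence, the probability that one random
chromosome carries the configuration is the product over SNPs of the
population allele frequency (founder state "present") or its complement
("absent"); the probability that all `n = 24` unrelated probands carry it
by chance is that product to the 24th power, computed in log space
(`haplotype_match_probability()`). With the packaged gnomAD v4 non-Finnish
European frequencies the per-haplotype probability is ~0.0359 and the
cohort probability ~2.07e-35 (2.15e-37 with the all-population
frequencies). The corresponding published table prints the same mantissas
with positive two-digit exponents (10^25, 10^27), which are inconsistent
with a probability below one and with the printed per-SNP frequencies; the
exponents appear garbled in typesetting, so this package reports the
computed values.

## ACMG/ClinGen copy-number-loss scoring

`classify_cnv()` is a transparent point adder over an evidence table, with
the five-class thresholds of the ClinGen CNV standard (pathogenic at
+0.99, likely pathogenic at +0.90, benign at −0.99) loaded from an
editable JSON file, so revised versions of the standard can be dropped in.
`segregation_points()` maps observed segregation counts onto the
co-segregation tiers (0.15 / 0.30 / 0.45 points at 3 / 5 / 7 segregations,
saturating at 0.45). Only the loss pathway is implemented. The
segregation evidence in the motivating analysis combines the detailed-
evaluation criteria into a single item at 0.45 points; the engine treats
it the same way, as one evidence row, but any alternative split can be
expressed in the evidence table. `count_segregations()` defines an
observed segregation as a phenotype-positive relative who carries the
variant, excluding probands as ascertainment events.

```{r acmg}
ev <- tibble::tibble(
  criterion = c("1A", "2E", "3A", "4F/5D"),
  points = c(0, 0.9, 0, segregation_points(19))
)
glance(classify_cnv(ev))
```

## Cohort analytics and the canonical fixture

`build_cohort_fixture()` generates the 83-individual synthetic cohort whose
integer structure matches the published counts exactly: group sizes, sex
splits, phenotype counts, symptomatic counts, the age-50 penetrance
numerators and denominators, risk-factor sub-blocks, outcome component
counts and follow-up denominators. The printed marginals do not pin down
the joint sex × age × phenotype distribution of the 37 G+ relatives, so
one internally consistent cross-tabulation was fixed (males: 7/8 affected
at ≥50, 4/6 below; females: 4/6 and 4/17) and is documented in the
function's help page. Ages, BMI and follow-up are the only seeded columns:
sorted normal deviates truncated to the printed ranges, so that the ≥50
counts hold exactly for every seed while group means and ranges stay
plausible. The fixture reproduces the count structure of the real cohort,
not its correlations beyond those constraints — passing tests certify the
analytics and the published count arithmetic, not any new clinical claim.

The analytics themselves are thin, explicit layers over base R tests:

- `penetrance()` and `sex_stratified_penetrance()` — affected fractions
  with optional age thresholds; the 2×2 sex comparison uses the chi-square
  **without** Yates continuity correction by default, which reproduces the
  published p-values (0.010 for the sex split, 0.002 for the symptomatic
  comparison) on the reconstructed tables; the corrected form is a flag
  away.
- `outcome_summary()` — component and composite outcome counts over the
  individuals with outcome follow-up; the composite is death,
  transplantation, life-threatening arrhythmia, heart-failure
  hospitalisation or septal reduction (device implantation is reported but
  excluded).
- `compare_groups()` — categorical variables by chi-square with a Fisher
  fallback when any expected cell is below 5; continuous variables by
  unpaired t-test when both groups pass Shapiro normality at α = 0.05,
  otherwise Mann–Whitney. The normality gate is a documented default (the
  motivating analysis does not state one) and can be overridden per
  variable with `force_test`.
- `match_by_age()` — greedy nearest-age matching without replacement, for
  age-matched proband/relative comparisons; the matching algorithm in the
  original analysis is unstated, so results on the fixture are indicative
  rather than exact reproductions.
- `bsa_index()` — body-surface-area indexing of echocardiographic
  measures.

```{r cohort}
cohort <- build_cohort_fixture(seed = 1)
penetrance(cohort, role = "relative", genotype = "G+", min_age = 50)
outcome_summary(cohort, genotype = "G+") |> filter(outcome == "composite")
```

## File formats

Readers and writers (`read_marker_map()`, `read_haplotypes()`,
`read_counts()`, `read_cohort()` and matching writers) use plain TSV/CSV
with 1-based fully-closed genomic coordinates, allele 0 for a missing
microsatellite call (linkage-format convention) and empty fields for
missing cohort values. Each reader validates its schema and reports the
offending line; write-then-read round-trips are identity and are tested as
such.

## Known limitations

- The descent simulator is marginal per marker; it does not model crossover
  interference, marker mutation or genealogy (all carriers descend
  independently from the founder). It validates the estimator under its own
  assumptions, which is its purpose.
- The age estimator provides no confidence interval beyond seed resampling
  of the simulation; likelihood-based dating is out of scope.
- The shared-core span is a conservative outer-marker bound; spans quoted
  to the first discordant marker would be systematically larger.
- The cohort fixture encodes printed counts, not patient-level reality;
  continuous comparisons on it (echo measures, ages) are plausible but not
  reproductions.
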