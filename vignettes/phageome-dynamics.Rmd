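---
title: "Phageome dynamics after faecal filtrate transplantation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phageome dynamics after faecal filtrate transplantation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagedyn)
```

# What this package computes

`phagedyn` re-implements, as a tested and reusable pipeline, the phageome
analysis of a small randomised trial of faecal filtrate transplantation
(FFT): recipients with metabolic syndrome receive a 0.2-µm-filtered,
bacteria-depleted faecal suspension from a healthy donor, and bulk (WGS)
and virus-like-particle (VLP) metagenomes are followed over a month. The
package does **not** run assemblers, viral classifiers, binners or
aligners; it consumes their tabular outputs (annotation summaries, ANI
tables, read counts with coverage breadths, MAG tables, CRISPR-spacer
hits) and implements everything downstream:

1. **Viral triage** — a contig of at least 5 kb is called viral when at
   least one of four evidence criteria holds: ≥ 1 annotated viral gene, a
   classifier score ≥ 0.95, ≥ 2 viral hallmark genes, or no viral *and*
   no bacterial genes at all. A missing score fails only the score
   criterion: an unscored contig cannot pass a score cut.
2. **Viral populations (VPs)** — exact duplicates (100% identity, shorter
   member fully aligned) are collapsed to the longest representative;
   survivors are clustered at an average-nucleotide-identity threshold
   into VPs, the species-rank unit of all downstream analyses.
3. **Quantification** — per contig and sample, read counts are zeroed
   when coverage breadth is below 75%; counts and lengths are summed per
   VP and converted to RPKM; low-signal VPs (total RPKM < 100, or > 20
   RPKM in fewer than 10% of samples) are removed before ordination.
4. **Host linkage** — MAGs passing `completeness − 5 × contamination ≥
   50` are linked to VPs by prophage containment (a VP member contig
   binned into the MAG) and by CRISPR-spacer hits (spacer length 20–30
   bp, ≤ 2 mismatches against the full spacer).
5. **Dynamics** — per recipient and day: the share of abundance on VPs
   detected in the assigned donor (engraftment), and on VPs absent at the
   recipient's baseline (novelty); per species and recipient, mean VP and
   MAG abundance changes between day pairs, correlated by Spearman's rank
   within treatment arms (negative: lytic/antagonistic; positive:
   lysogenic/protagonistic).
6. **Enrichment** — over-representation of host species among
   differentially abundant VPs by a one-sided hypergeometric test with
   Benjamini–Hochberg correction.
7. **Clinical** — two-sided Fisher exact tests for adverse-event counts,
   continuous-glucose-monitor time in range (3.9–10 mmol/L), OGTT
   glucose area under the curve (trapezoid over 0–120 min), and HOMA-IR.

# Statistical choices and their rationale

## The clustering threshold

The source analyses state both 90% and 95% ANI for VP clustering in
different places. The threshold is therefore a configuration value
(`ani_threshold_pct`, default 95, the common viral-population
convention); the discrepancy is surfaced rather than silently resolved.
Clustering itself is greedy length-sorted centroid clustering: contigs
are visited longest-first and join the first VP whose *representative*
they match at or above the threshold. This is deterministic, matches
common practice, and differs from single linkage on chains (A–B and B–C
similar, A–C not: centroid yields {A, B}, {C}). Single linkage is
available behind `method = "single"`. Directed ANI values from
asymmetric all-vs-all searches are reconciled by taking the maximum.

## Mismatch counting for spacer hits

Short-alignment BLAST output frequently contains partial local
alignments. Mismatches are counted against the full spacer,
`spacer_len − n_identical`, so unaligned spacer ends and gap columns all
count as mismatches. This is the strictest defensible reading and
minimises spurious host assignments; it subsumes the looser
"alignment-internal mismatches only" reading.

## PERMANOVA

`permanova()` implements the pseudo-F partition of squared
inter-sample distances directly (between/within sums of squares via the
Gower-centred inner-product matrix), with the permutation p-value
`(1 + #{F_perm ≥ F_obs}) / (1 + n_perm)` at 1000 permutations by
default. It is verified in the test suite against a brute-force
all-permutations oracle at N ≤ 6 and against `vegan::adonis2` as an
independent implementation. Covariate control ("age and sex") is a
sequential two-term partition with the group term last — an approximation
of the reference sequential-SS implementation, documented as such. The
distance is configurable because the source does not name one: Euclidean
on clr-transformed abundances (Aitchison, default) or Bray–Curtis on
proportions.

## Compositional handling

Richness and Shannon diversity are computed on RPKM; ordination-type
analyses use the centred log-ratio transform. The clr pseudocount
defaults to half the smallest positive value of the table, the standard
compositional fallback when zeros are present (the source is silent on
this). Columns of a clr table sum to zero by construction and the
package validates this within 1e-9.

## The enrichment universe

The hypergeometric parameterisation follows the stated `phyper(q − 1, m,
n, k, lower.tail = FALSE)` convention, with one documented
interpretation: the universe is restricted to VPs with at least one host
link, and differentially abundant VPs without any host are excluded from
`k`. A VP linked to several species contributes to each species' counts
(multi-membership). Species with no differentially abundant VP are not
tested.

## Spearman p-values

Average ranks handle ties; the two-sided p-value uses exact enumeration
over rank permutations for n ≤ 8 and the t-approximation
`t = ρ√((n−2)/(1−ρ²))` above. (The exact cut-off sits at 8 rather than
10 because full enumeration at n = 10 costs 3.6 M permutations for no
practical gain — every interaction analysis in this package involves
hundreds of points.)

## Fisher's exact test

Two-sided p by the sum-of-small-probabilities rule with a 1e-7 relative
slack — the convention that reproduces the trial's printed values (0.19
for 6/12 vs 2/12 subjects with related adverse events; 0.11 for 8 vs 2
related events) and agrees with an explicit `choose()` enumeration
oracle in the tests. Mid-p corrections are not used.

# The synthetic world

All tests run offline on data from `generate_community()`, which emits
every input table with planted truth. Its defaults are a *stated world*,
chosen once and not tuned against test outcomes:

* **Design**: 12 participants per arm, sampling days 0, 2, 4, 7, 14, 28
  (the trial's grid), 80 VPs, 40 MAGs in 20 species, 4 donors.
* **Trajectories**: log-abundances follow Gaussian random walks between
  sampling days (MAG step sd 0.8, VP noise sd 0.6), exponentiated,
  composed on the proportion scale and multinomially sampled to integer
  counts at log-normal library sizes (median 3 × 10⁵ reads). Generating
  on the log scale and closing to proportions gives realistic
  compositional noise; heavier-tailed noise is out of scope.
* **Coupling**: for host-linked species, the VP log-step equals
  `coupling_beta` times the mean MAG log-step plus noise. The source
  reports only a weak correlation (ρ ≈ −0.13) and no effect size, so the
  default |beta| was calibrated once by Monte-Carlo *before* the
  acceptance suite existed: beta = ±0.3 realises a Spearman ρ of about
  ∓0.19 (sd 0.04) at ~480 species-sample points, weak but
  sign-recoverable; beta = 0 realises a 4.5% type-I rate at nominal 5%.
* **Donors**: one pre-intervention sample per donor, over a donor-specific
  VP pool disjoint from recipient baselines. In FFT recipients the
  donor's VPs carry exactly `engraftment_fraction` (default 0.10) of
  post-baseline relative abundance, and a novel pool absent at day 0
  carries `novelty_rate` (default 0.15) in both arms — percentages in
  the range the trial reports for donor-shared and new phages.
  Consequently the expected "new phage" share in the FFT arm is
  `engraftment + novelty` (donor VPs are themselves absent at baseline),
  the closed form the end-to-end test checks. The price of this clean
  closed form is zero donor-recipient overlap at baseline, which real
  viromes do not have.
* **Adversaries**: the fixture plants non-viral decoy contigs (fail all
  four triage criteria), a low-quality MAG that contains a viral contig
  and must be removed by the quality gate before it fabricates a
  prophage link, spacer decoys that each violate exactly one filter, and
  a 2% rate of low-breadth coverage records.

A green test therefore establishes that the *rules* are implemented
exactly (filters, closed forms, partitions, test statistics) and that
planted signals of realistic size are recovered at trial-scale sample
sizes. It does not establish robustness to features the generator lacks:
sequence-level artefacts, uneven VP detectability between VLP and WGS
fractions, donor-recipient baseline overlap, or non-Gaussian abundance
dynamics.

# Numerical and degenerate-input conventions

* Boundary semantics follow the stated rules everywhere: breadth 0.75 is
  kept, quality score 50 is kept, total RPKM exactly 100 is kept,
  prevalence exactly 10% is kept, spacer lengths 20 and 30 are kept,
  time-in-range bounds are inclusive.
* All-zero samples: richness 0, Shannon 0 by convention; proportion
  closure leaves the column at zero rather than NaN.
* Duplicate ties in `dedup_exact` and clustering are broken by length
  descending, then lexicographically smallest id — every output is
  deterministic and invariant to input row order.
* Every stochastic function takes an explicit integer seed and restores
  the caller's RNG state; derived seeds stay below 2³¹.
* The pipeline's tables are written with fixed column order and 6
  significant digits; reruns with identical inputs and seed are
  byte-identical (verified in the tests).
* The CLI accepts a JSON configuration (a YAML reader is deliberately
  not a dependency); single-stage subcommands re-run the deterministic
  pipeline through the requested stage, which is idempotent and
  byte-stable, rather than maintaining partial state.

# Known limitations

* Differential abundance estimation itself (ANCOM-BC) is out of scope;
  the DA-VP list is an input.
* The covariate-adjusted PERMANOVA is a sequential approximation, not a
  re-implementation of the reference marginal tests.
* HOMA-IR requires an explicit insulin unit; printed summary tables with
  ambiguous unit labels cannot be reproduced from group means (means of
  ratios are not ratios of means).
* Protein-sharing (VC-level) clustering, principal response curves,
  mixed models and CGM metrics beyond time-in-range are out of scope.
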