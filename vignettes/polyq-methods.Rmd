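---
title: "Hinge-anchored polyQ quantification and vocalization-frequency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hinge-anchored polyQ quantification and vocalization-frequency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqvoc)
```

## The problem

The transcription factors FOXP2 and FOXP1 carry two long polyglutamine
(polyQ) repeats, Q1 and Q2, separated by a short conserved "hinge"
peptide (`HPGKQAKE` in FOXP2, `ALQVARQLLL` in FOXP1). Across mammals
these repeats vary widely in length, and the variation tracks
vocalization phenotypes: species vocalizing at high (ultrasonic)
frequencies tend to have a low Q1/Q2 length ratio, species vocalizing at
low or infrasonic frequencies a high one. `polyqvoc` implements the
quantitative machinery needed to study this association: a rule-based
repeat caller anchored on the hinge, threshold classifiers of
vocalization classes, binned group-mean correlation statistics, and the
normalization/fitting formulas of the accompanying molecular assays
(circular dichroism, FRAP, dual-luciferase, condensate areas, cochlear
landmarks).

## Repeat calling

The caller never aligns sequences. It anchors on the hinge:

1. **Hinge search** (`find_hinge()`): every window of anchor length is
   scored by Hamming distance (substitutions only, no indels); the
   minimum-distance window wins, leftmost on ties. The default mismatch
   tolerance is 2 — the hinge is strongly conserved, but distant
   orthologs occasionally carry a substitution (one bat species
   substitutes a proline into the hinge). Tolerance, anchor, and windows
   are all exposed in `hinge_config()` rather than hard-coded. Indels
   are excluded deliberately: the one known insertion case sits
   *between* the hinge and Q2 and is handled as an extension, below.
2. **Q run grammar**: a Q run is a maximal substring of glutamines
   permitting at most one interior histidine, which counts toward the
   run length. Histidine is treated as part of the polar stretch because
   it occurs embedded within otherwise uninterrupted Q1 repeats in a few
   species; restricting it to interior positions keeps runs maximal and
   unambiguous (an H at a run boundary is just flanking sequence).
3. **Q2** is the longest run starting within `downstream_window`
   (default 60) residues after the hinge end. Up to
   `extension_allowance` (default 4) intervening residues are canonical
   spacing; a larger gap is reported as `extension_len` and flagged
   `hinge_extension`. This captures the 22-residue insertion
   (`VGSGRLTHAEEGEAGRGPRRPG`) present in a few predicted cetacean
   sequences — likely a splice-prediction artifact — while leaving Q2
   itself unchanged, so such sequences remain usable.
4. **Q1**: within `upstream_window` (default 100) residues before the
   hinge, the repeat region runs from the first Q run of length
   `min_run` (default 2) to the hinge start. Several species shorten Q1
   by proline insertion; since proline is a structural breaker, Q1 is
   the run immediately N-terminal to the *first* proline in the region,
   and the fragmented runs between that proline and the hinge are
   ignored (`q1_truncated_by_proline`). Without a proline, Q1 is simply
   the longest run in the region.
5. The sum S = Q1+Q2 and ratio R = Q1/Q2 are stored at full double
   precision; tables print the ratio to two decimals (half-even). When a
   species has several isoforms, `select_longest_isoform()` keeps the
   one maximizing S, the stated convention for multi-isoform accessions;
   ties keep input order and are flagged.

The window defaults keep the search inside the Q-rich N-terminal ~300
residues and away from distal Q runs; they matter only for unusually
divergent sequences and are config-exposed.

```{r}
call_repeats(paste0("M", "QQQQQQ", "P", "QQ", "P", "QQ",
                    "HPGKQAKE", "QQQ"))
```

Degenerate inputs never produce silent numbers: a sequence without a
findable hinge, or without a qualifying run on either side, yields a
*flagged* call (`no_hinge`, `no_q1`, `no_q2`) with undefined sum and
ratio, and flagged species are excluded from classification and
correlation with the reason logged.

## Classification

The published vocalization classes are threshold regions, not fitted
clusters, and the classifiers implement exactly those regions. For bats:
non-echolocating species (NE) have S > 60; ultrasound emitters split by
ratio into constant-frequency callers (CF, R < 1), multi-harmonic
frequency-modulated callers (FM2, 1 ≤ R ≤ 2.1), and single-harmonic FM
callers (FM1, 2.1 < R ≤ 3.5). Mammal-wide FOXP2 bands are low (R ≤ 3.5,
ultrasonic specialists), intermediate (3.5–4.5, human-like), and high
(> 4.5, infrasonic specialists); FOXP1 bands are extreme-low (< 0.2),
low (0.2–0.5), mid, and high (≥ 2). Boundary membership is not printed
for every edge in the source descriptions; the package fixes one
consistent convention — S = 60 is not NE, FM2 owns both its printed
endpoints, FOXP2 bands are left-open/right-closed — and every threshold
lives in `classifier_config()`, so any other convention is one argument
away. Ratios outside a scheme's range return `UNASSIGNED` rather than
erroring, because mammal-wide panels legitimately contain them.

## Binned group-mean correlations

Species are grouped either by fixed bins of a parameter or by ranking
into equal-size groups, and the Pearson correlation is computed over the
group means. The built-in schemes are the published ones: characteristic
frequency (≤30, 30–90 kHz by 10, >90), minimum frequency (≤20, 20–80 by
10, >80), bandwidth (≤5, 5–40 by 5, >40), Q1/Q2 in ten bins (≤1, 1–5 by
0.5, >5) or six bins (≤3, 3–5 by 0.5, >5), and ranked CW/BW groups of 5
species. The interval convention follows the printed first-bin
inequality ("≤30"): first bin closed at its upper edge, interior bins
left-open/right-closed, last bin open above. Edge-sitting values are
therefore assigned downward; the sources do not state their tie
handling, so this is a package convention. Rank grouping requires the
species count to divide evenly — an error, not silent truncation,
because unequal trailing groups would bias the group means.

p-values for group-mean correlations use the two-sided t approximation
with n−2 degrees of freedom. With 8–10 groups this is an approximation;
it is reported alongside r and never used to filter anything. With
exactly two groups r is ±1 by construction and the p-value is undefined
(`NA`).

Ratio-band comparisons use fixed-effects one-way ANOVA with a
Student–Newman–Keuls stepdown on the ordered group means: stretches of p
ordered means are tested against the studentized range distribution
(`stats::ptukey`) with the within-group degrees of freedom, widest
stretch first; a non-significant stretch blocks everything nested inside
it. Unbalanced groups use the harmonic mean of the two group sizes in
each comparison — the classical recipe, though the sources do not state
their choice. The post hoc runs only when the omnibus F test is
significant, which keeps the family-wise error of the whole procedure
near the nominal level (verified at ~0.04 under the complete null in the
test suite).

## Assay formulas

* **CD**: mean residue ellipticity is
  θ·mw / (10·(n−1)·c·pl) with concentration in mg/mL and path in cm.
  Spectral features are the low-minus-high-temperature subtraction
  spectrum, the 222/208 nm ellipticity ratio (a ratio > 1 in the
  subtraction spectrum is the coiled-coil signature), and the melt curve
  of the 222 nm signal normalized to the lowest temperature. The
  208/222 nm lookup takes the nearest grid point within 1 nm (spectra
  are collected every 0.5–1 nm) and errors beyond that.
* **FRAP**: each region is first normalized to its own pre-bleach mean,
  then the bleached region is divided pointwise by the mean of the
  normalized controls, cancelling acquisition photobleaching shared by
  all regions (the fit is provably invariant to any common
  multiplicative drift). Post-bleach points are fitted to the
  single-exponential recovery F(t) = F0 + (P − F0)(1 − e^(−t/τ)) by
  bounded Levenberg–Marquardt least squares (F0 ∈ [0,1], P ∈ [0,1.5],
  τ > 0), initialized from the first post-bleach value, the mean of the
  last 10 points, and the observed time to half recovery. A single
  exponential is used because the reported quantities — half-time
  t½ = τ·ln 2 and mobile fraction (P − F0)/(1 − F0) — are exactly what
  it determines; a plateau below the post-bleach floor flags
  `no_recovery` instead of reporting a negative mobile fraction.
* **Dual-luciferase**: firefly/Renilla per well, then division by the
  control-group mean ratio, making the control mean exactly 1 on every
  plate by construction.
* **Condensates**: the relative area is condensate area over
  cell/nuclear area; an optional control mean rescales conditions to a
  control of 1.
* **Cochlear landmarks**: CW/BW and height/width are Euclidean distance
  ratios between labelled landmark pairs, each required exactly twice.

## What the synthetic data emulates — and what it does not

`gen_ortholog()` composes flank + Q1 block + proline blocks + hinge +
optional extension + Q2 + flank, with flanks drawn from an alphabet
excluding Q, P and H so the programmed repeat structure is provably the
only one present. `gen_panel_with_phenotypes()` draws ratios uniformly,
quantizes them to integer (Q1, Q2) with Q2 ≤ 20 and Q1 ≤ 60 (the
observed mammalian range; quantization error ≤ 0.05 for ratios in
[0.3, 6]), and programs log10 frequency and log10 body mass as linear
functions of the ratio plus Gaussian noise. The defaults — 200 species,
slope −0.35 log10(kHz) per ratio unit, intercept 2.2, noise sd 0.15 —
span roughly 100 kHz calls at ratio 0.5 down to low-kHz calls at ratio
6, with body mass rising over ~4 orders of magnitude, the magnitude of
the published mammal-wide trend. At these defaults the model-implied
group-level correlation over the ten ratio bins is −0.998 (computed by
an independent Monte Carlo from the model definition), and the test
suite requires the full pipeline to recover it within ±0.1 in ≥ 90% of
20 seeds.

The generator deliberately does **not** emulate: phylogenetic
autocorrelation (species are i.i.d., so tests say nothing about
pseudo-replication in real panels), alignment ambiguity or sequencing
error, non-linear ratio–phenotype relationships, or realistic CD
physics — the two CD basis shapes are synthetic curves sharing an
isodichroic crossing at 203 nm, useful for testing the feature
arithmetic, not for interpreting real spectra. Passing tests therefore
demonstrate the correctness of the calling rules and statistics, not the
biological claim itself.

All generators are deterministic given a seed and return truth tables
sufficient to assert every downstream call exactly; the test suite's
round-trip oracle exercises Q1 ∈ {2..60}, Q2 ∈ {2..20}, 0–3 prolines,
optional histidine, and the 22-residue extension on over a thousand
generated sequences.

## Problem sizes and numerical choices

The shipped analyses and tests use a 200-species panel, 20 panel seeds
for the recovery check, 200 noisy FRAP traces, and 2,000 null
simulations for the SNK error-rate check — sizes at which the Monte
Carlo error of each checked quantity is comfortably below its test
tolerance. Ratios are compared exactly where the arithmetic is exact
(the stored ratio is the IEEE quotient Q1/Q2; note that the rounded
product `ratio * q2` need not bit-equal `q1` for all integer pairs) and
with explicit tolerances elsewhere. Ties are broken deterministically
throughout: leftmost hinge window, first-in-input isoform, smallest q2
in ratio quantization, stable rank binning.

## Limitations

The package consumes protein sequences only (no CAG/CAA codon
analysis), calls exactly the two hinge-flanking repeats (minor distal Q
runs are out of scope), and performs ordinary correlations without
phylogenetic correction, matching the procedure it implements. The
optional accession helper (`scripts/fetch_orthologs.R`) requires network
access and is never run by the test suite; offline validation uses
synthetic sequences that reproduce the human ortholog architectures
(FOXP2 40/10, FOXP1 6/7) and are labelled as synthetic.
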