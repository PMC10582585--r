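# polyqvoc

Quantifying FOXP2/FOXP1 polyglutamine repeat lengths and their
association with mammalian vocalization frequency.

## The problem

The transcription factors FOXP2 and its paralog FOXP1 each carry two
long polyglutamine (polyQ) repeats, **Q1** and **Q2**, separated by a
short conserved hinge peptide (`HPGKQAKE` in FOXP2, `ALQVARQLLL` in
FOXP1). Across mammals the repeat lengths vary widely, and the variation
tracks vocalization phenotypes: ultrasonic specialists (echolocating
bats, many rodents) converge on a low Q1/Q2 ratio, while low-frequency
and infrasonic vocalizers (whales, elephants, rhinos) converge on a high
one. Comparative analyses of this association need a reproducible,
rule-based way to measure the repeats and relate them to phenotypes —
that is what this package provides, for anyone working on comparative
molecular evolution of repeat-containing proteins.

## What it computes

* **Hinge-anchored repeat calling** (`find_hinge()`, `call_repeats()`,
  `select_longest_isoform()`): the hinge is located by a
  minimum-Hamming sliding-window scan; Q2 is the longest Q run starting
  within a window after the hinge (with the 22-residue cetacean hinge
  insertion detected and excluded); Q1 is called upstream with the
  proline-interruption rule (Q1 ends at the first proline; fragments
  between it and the hinge are ignored) and single-interior-histidine
  tolerance. Reports S = Q1+Q2 and R = Q1/Q2 at full precision, with
  explicit quality flags instead of silent failures.
* **Threshold classification** (`classify_usv_type()`,
  `classify_ratio_band()`, `call_type_from_collen()`): bat call-type
  regions — NE (S > 60), CF (R < 1), FM2 (1 ≤ R ≤ 2.1), FM1
  (2.1 < R ≤ 3.5) — plus the mammal-wide FOXP2 ratio bands
  (≤3.5 / 3.5–4.5 / >4.5) and FOXP1 bands (<0.2 / 0.2–0.5 / ≥2).
* **Binned group-mean correlations** (`assign_bins()`,
  `correlate_group_means()`, `compare_groups()`): the published bin
  schemes, Pearson r over group means with a t-distribution p-value,
  and one-way ANOVA with a Student–Newman–Keuls stepdown for ratio-band
  comparisons.
* **Assay quantification** (`mean_residue_ellipticity()`,
  `cd_features()`, `frap_normalize_fit()`, `luciferase_normalize()`,
  `condensate_relative_area()`, `cochlear_ratios()`): CD mean residue
  ellipticity θ·mw/(10·(n−1)·c·pl) and spectral features, FRAP double
  normalization with bounded single-exponential recovery fitting,
  dual-luciferase normalization, condensate relative areas, and
  cochlear landmark ratios.
* **Synthetic data with ground truth** (`gen_ortholog()`,
  `gen_panel_with_phenotypes()`, `gen_frap_trace()`, `gen_cd_spectra()`,
  `gen_luc_plate()`): deterministic generators for every input the
  pipeline consumes, each returning a truth table for exact oracle
  testing.
* **End-to-end pipeline** (`run_pipeline()`): FASTA + phenotype table
  in, repeat-call/classification/correlation tables out, driven by a
  config list or YAML file.

## Worked example

```r
library(polyqvoc)

# proline-interrupted Q1: the repeat ends at the first proline
call_repeats(paste0("M", "QQQQQQ", "P", "QQ", "P", "QQ", "HPGKQAKE", "QQQ"))
#> <repeat_call> Q1=6 Q2=3 sum=9 ratio=2.00 extension=0

recs <- read_fasta("results/simulated/worked_examples.fasta", gene = "FOXP2")
tab <- repeat_call_table(recs)
tab[, c("species", "q1", "q2", "sum", "ratio", "extension_len", "flags")]
#>               species q1 q2 sum ratio extension_len           flags
#> 1               plain 12  5  17   2.4             0
#> 2 proline_interrupted  6  3   9   2.0             0
#> 3  histidine_tolerant  8  2  10   4.0             0
#> 4      cetacean_style 20 10  30   2.0            22 hinge_extension

classify_usv_type(tab$sum, tab$ratio)
#> [1] "FM1" "FM2" "UNASSIGNED" "FM2"
```

Reading the output: Q1 of the second sequence is 6 because the run is
truncated at the first proline (the two downstream QQ fragments are
ignored); the fourth sequence carries the 22-residue insertion between
hinge and Q2, reported as `extension_len` and flagged, with Q2 itself
unaffected. The third sequence (ratio 4.0) falls outside the chiropteran
ratio range, hence `UNASSIGNED` for the bat call-type scheme — it would
be `INTERMEDIATE` (human-like) in the mammal-wide bands.

## Analysis workflow

The numbered scripts under `analysis/` run the study end to end on
synthetic data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R         # panel + worked constructions, with truth
Rscript analysis/02_extract_repeats.R  # repeat calls, checked against truth
Rscript analysis/03_classify.R         # call-type and ratio-band tables
Rscript analysis/04_correlate.R        # binned correlations, ANOVA + SNK
Rscript analysis/05_assays.R           # FRAP / CD / luciferase / landmarks
```

On the default 200-species panel (programmed slope −0.35 log10(kHz) per
ratio unit, noise sd 0.15), step 4 reports a ten-bin group-mean
correlation of r = −0.999 between ratio and log10 frequency and a
significant separation of all three FOXP2 ratio bands
(F(2,197) = 271.85, SNK p < 0.05 for every pair); step 5 recovers the
programmed FRAP kinetics (median t-half 16.83 s, mobile fraction 0.78)
and the programmed luciferase repression (0.796 vs a programmed 0.79).

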