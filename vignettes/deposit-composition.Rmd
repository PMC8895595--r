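---
title: "Identifying deposit proteins from hydrolysate amino-acid composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying deposit proteins from hydrolysate amino-acid composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depositcomp)
```

## The problem

Insoluble intracellular protein deposits — intranuclear inclusions in
polyglutamine disease or in neuronal intranuclear inclusion disease (NIID),
amyloid aggregates more generally — resist the standard proteomics route.
Their cores solubilize poorly, and the proteins that form them are often
dominated by low-complexity regions (LCRs) and compositionally biased
regions (CBRs) that yield few informative tryptic peptides, so LC–MS/MS can
miss exactly the protein that makes up the deposit. A polyglutamine tract,
for instance, produces essentially no unique peptides.

Bulk amino-acid analysis sidesteps this: hydrolyze the insoluble fraction to
free amino acids, quantify each detection channel, and ask which amino acid
is *over-represented* in the deposit-rich (case) fraction relative to a
matched control fraction. The enriched channel is then a fingerprint to rank
candidate proteins (e.g., an LC–MS/MS identification list) by their content
of that amino acid computed directly from sequence. `depositcomp`
implements this inference chain as a tested pipeline:

1. model the hydrolysis chemistry and compute channel compositions of
   proteins and mixtures from sequence;
2. detect the enriched channel (case vs. control fold change);
3. rank candidates by their content of that channel;
4. compare composition profiles (Pearson correlation, Jensen–Shannon
   divergence);
5. estimate the candidate's mixture fraction in the measurement;
6. annotate LCRs/CBRs in the top candidate.

## The hydrolysis model

An amino-acid analyzer does not see residues; it sees hydrolysate channels.
Two chemistry facts drive the model:

* **Deamidation pooling.** Acid hydrolysis converts Gln to Glu and Asn to
  Asp, so the analyzer reports pooled channels, conventionally written
  **Glx** (Gln + Glu) and **Asx** (Asn + Asp). Quantification is unaffected
  because the free acids and amides have nearly equal molecular weights
  (Glu 147.13 g/mol; Gln 146.15 g/mol computed from C5H10N2O3 — note that
  two-decimal literature citations of this constant vary by a hundredth or
  two).
* **Tryptophan loss.** 6 M HCl hydrolysis destroys Trp (recovery 0);
  4 N methanesulfonic acid (MSA) hydrolysis preserves it (recovery 1).
  Analyses that need the Trp channel therefore use MSA.

A `hydrolysis_scheme` packages a residue-to-channel map and per-residue
recovery factors. Three schemes are built in: `intact` (identity map, the
in-silico composition of a sequence), `hcl` and `msa`. Composition is
**mole-fraction (residue-count) based** throughout — "percentage of amino
acid numbers", not mass percentage — because that is what both sequence
counting and ninhydrin channel areas approximate. Recovery is applied
before normalization and the result renormalized, modelling an analyzer
that reports relative content of the channels it detects. Cysteine recovery
defaults to 1 under both acid schemes but is configurable
(`hydrolysis_scheme("hcl", recovery = c(C = 0.5))`), since real acid
hydrolysis degrades Cys to a protocol-dependent degree.

Ambiguity codes are resolved by channel semantics: `B` (Asn/Asp) feeds the
Asx channel and `Z` (Gln/Glu) the Glx channel under a pooled scheme — the
codes *are* those channels — while under `intact` they are dropped with a
warning because their residue identity is undetermined. `U` counts as Cys;
`X` is excluded from counts and from the length denominator.

```{r}
sch <- hydrolysis_scheme("hcl")
protein_composition(protein_record("demo", "WQQEEGGGG"), sch)
```

## The positive control: a polyglutamine construct

The package carries a reconstruction of the classic positive control: the
N-terminal huntingtin exon-1 fragment (17-residue head, polyglutamine
tract, proline-rich tail) fused to EGFP, as expressed in the HD190QG mouse.
`construct_nhtt_egfp(n)` varies only the tract, so composition differences
between tract lengths are attributable to the expansion alone. The printed
figure sequence is an image in the source publication; the construct here
is assembled from the canonical huntingtin exon-1 and EGFP sequences, which
reproduces the published fold change:

```{r}
glx <- function(n)
  protein_composition(construct_nhtt_egfp(n), sch)$fractions[["Glx"]]
glx(190) / glx(21)   # ~2.7x, the expanded vs normal tract
```

The `hcl` scheme is used for this check because HCl was the chemistry
applied to the mouse fractions; under `msa` the ratio differs only through
the single EGFP tryptophan.

## Enrichment calling and ranking

`fold_change()` divides case channel fractions by control fractions.
Control channels below `epsilon` (default 1e-4, logged when used) are
floored to keep ratios finite. The default target-calling rule is the
**unique maximum fold change, provided it exceeds 1** — matching the
empirical situation where one amino acid rises in the deposit fraction
while every other falls. A `threshold` mode calls all channels with fold
change at or above a cutoff, for dipeptide-repeat-like double biases.

`rank_by_channel()` scores candidates by `protein_composition()` and sorts
by descending channel fraction; ties share the smaller rank and are ordered
by id, so rankings are deterministic and permutation-invariant. Candidates
with no recoverable residues under the scheme (an all-Trp sequence under
`hcl`) are excluded with a warning rather than silently scored 0.

`profile_similarity()` reports Pearson correlation and base-2
Jensen–Shannon divergence side by side. The underlying comparison in this
field is visual ("the patterns look alike"); neither metric is privileged
in any pass/fail logic, they are complementary summaries.

## Mixture-fraction estimation

`estimate_mixture_fraction()` models the measurement as
`f * candidate + (1 - f) * background` and minimizes Euclidean distance
over `f` in [0, 1]. The objective is a quadratic in `f`, so the minimizer
is computed in closed form (the unconstrained projection
`<m - b, c - b> / ||c - b||^2` clamped to the unit interval) rather than by
golden-section or grid search; the tests nevertheless verify agreement with
a 1e-3 grid oracle. The estimate is a *recovered-residue molar* fraction —
the scale on which hydrolysate measurements live — not a chain-molar or
mass fraction; the synthetic generator stores the matching ground truth.
When candidate and background coincide the fraction is unidentifiable and
returned as `NA` with a flag, never silently as 0 or 1.

## Low-complexity and bias scanning

Because deposit-forming proteins are typically LCR/CBR-rich, the pipeline
annotates the top candidate:

* `scan_low_complexity()` is a SEG-like two-threshold entropy scan:
  length-25 windows at or below 2.2 bits seed segments, which extend
  through overlapping windows at or below 2.5 bits; segments separated by
  at most 10 residues merge. The two-threshold design (strict seed, looser
  extension) keeps isolated borderline windows from fragmenting one
  biological region.
* `scan_residue_bias()` asks a sharper question — bias toward a *chosen*
  residue set (e.g. `"GS"` for a glycine/serine-rich repeat protein): the
  upper binomial tail of the observed in-set count per window against the
  background mass of the set, windows at or below `p_threshold = 1e-6`
  kept and merged as above. Tails are computed in log space so extreme
  enrichment does not underflow. These tails are descriptive window
  diagnostics, not hypothesis tests; no multiple-testing correction is
  applied or appropriate.

The defaults (window 25, 2.2/2.5 bits, 1e-6, merge gap 10, uniform 1/20
background; a database-average background is available via
`aa_frequencies("database")`) are package choices — no specific scan
algorithm is prescribed by the underlying analysis — and every parameter is
exposed in `scan_params()`. Coordinates are 0-based half-open everywhere in
code and converted to 1-based closed only in the human-readable report
tables. `coverage()` reports the fraction of the sequence under merged
segments; for a hornerin-like glycine/serine quasi-repeat protein this is
the quantity corresponding to the "~95% tandem quasi-repeating domains"
description of that protein family.

## The synthetic generator

`generate_bundle()` produces seeded case/control experiments with known
ground truth, emulating the deposit-analysis design:

* a background proteome (default 50 proteins) with residue frequencies from
  the curated-database average and lognormal lengths (median 400 aa,
  sdlog 0.6 — proteome-typical);
* one spiked tandem-repeat protein: a 50-residue random head plus 140
  copies of a 20-mer unit that is 60% Ser / 25% Gly (a hornerin-like
  glycine/serine quasi-repeat at hornerin scale, ~2850 aa);
* the control measured composition is the background-only mixture, the case
  adds the spike at chain-molar fraction 0.4; both pass through the chosen
  scheme (default `msa`) and receive independent multiplicative lognormal
  per-channel noise (CV 3%), then renormalize.

Multiplicative lognormal noise followed by renormalization keeps fractions
positive and mimics the relative-quantitation error of ninhydrin detection.
All draws flow from one seed via an isolated RNG (`withr::with_seed`), so
bundles are byte-reproducible and global RNG state is untouched. The truth
record stores both the chain-molar spike weight and the derived
recovered-residue fraction, which is what `estimate_mixture_fraction()`
sees (a long spike contributes more residues per chain).

What the generator does **not** model, and what passing tests therefore do
not establish about real data: chromatographic peak shapes and retention,
co-eluting contaminants, non-protein material in real fractions (lipofuscin
and other autofluorescent debris), correlated channel errors, partial
hydrolysis, and false candidates beyond plain background proteins. The
synthetic checks validate the inference machinery, not the wet-lab assay.

## Numerical and degenerate-input choices

* Composition vectors always carry the full channel set of their scheme,
  in a fixed analyzer-like order, and are renormalized to sum to 1 within
  1e-9; measured tables keep their raw (pre-normalization) sum as metadata
  because chromatograms are not necessarily normalized.
* Ranking ties break lexicographically by id; rankings are therefore
  deterministic under input permutation.
* Correlation of a constant profile is reported as `NA`, never coerced.
* An empty target-channel set short-circuits the pipeline into a
  `no-enrichment` report (CLI exit code 3) with ranking skipped.
* Sequences shorter than the scan window produce an empty segment set with
  a warning, not an error.

## Problem sizes used in the checks

The packaged test-suite runs the full property set on sequences up to 400
residues, brute-force scanner equivalence up to 200 residues, and the
parameter-recovery study on 100 seeded default bundles (50 background
proteins each); the whole suite completes in well under a minute on a
single CPU. The accession-dependent checks (ranking the 19 real candidate
proteins and hornerin's G/S coverage) require a one-time
`scripts/fetch_table1.R` download of the UniProt sequences, which are not
redistributed with the package.

## Limitations

* The enrichment step compares single measurements per fraction, as in the
  motivating experiments; no replicate-level statistics are offered.
* Mixture estimation is two-component (candidate vs. everything else); no
  simultaneous multi-candidate deconvolution.
* The scanner does not predict disorder or infer repeat periods; it
  quantifies composition only.
* Reconstructed fixtures (the polyglutamine construct) are assembled from
  canonical component sequences, not transcribed from the original figure
  image.
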