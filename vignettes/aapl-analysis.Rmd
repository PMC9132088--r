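---
title: "AAPL quantification and interaction scoring: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AAPL quantification and interaction scoring: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
quantities, the statistical choices, what the synthetic-data generator does
and does not emulate, and where the design was genuinely open.

## The measurement model

Antigen–antibody proximity labeling (AAPL) couples an Fe(III) catalytic
probe to an antigen-specific antibody. After the antibody binds its target
on intact cells, peroxide addition generates hydroxyl radicals locally, so
proteins near the epitope are oxidized more than the bulk membrane
proteome. The raw observable, after digestion and label-free MS
quantification, is a table of peptidoform intensities and spectral counts:
for each tryptic peptide, an unmodified form and zero or more oxidized
forms (`ox:<residue>`), per condition and replicate.

Two ratios summarize oxidation:

* **site degree** — for one peptide in one condition, the oxidized
  intensity at a site over the summed unmodified + modified intensity of
  that peptide;
* **EPO (extent of protein oxidation)** — summed oxidized intensity over
  summed total intensity of the protein.

Both are intensity fractions in [0, 1]. The underlying assumptions are the
usual ones of modification stoichiometry by MS1 intensity: oxidized and
unmodified forms of a peptide ionize comparably, and intensities are
additive across peptidoforms. Neither holds exactly in real data
(oxidation can shift retention and ionization); the ratios are
nevertheless the field's standard readout.

### Replicate aggregation

Point estimates of degree and EPO sum intensities across replicates before
forming ratios (a pooled estimator, more stable for low-intensity oxidized
forms than averaging per-replicate ratios). Per-replicate EPO values are
computed separately and used only for inference. This split is a package
decision; nothing in the measurement definition forces it.

### Inference against controls

For each treatment condition, each protein's replicate EPO values are
compared with its pooled control replicates (all control conditions
combined) by a one-sided Welch *t*-test (treatment greater), then
Benjamini–Hochberg adjusted across proteins within the condition. The test
choice is deliberate but unforced: replicate EPO values are approximately
normal on the scale observed here, group variances differ (treatment
oxidation adds variance), and one-sided is the only direction of interest.
With fewer than two usable replicates on a side the result is `NA` rather
than a guess. A property test verifies the null calibration of the
unadjusted p-values (fraction below 0.05 close to 5% on a 400–1000 protein
null simulation); note that under a *complete* null the BH-adjusted
q-values reject essentially nothing — that is the intended behavior of
FDR control, not a defect.

### Fold changes and floors

EPO fold change divides a condition's EPO by the mean control EPO with a
floor of 1e-4 on the denominator; proteins whose controls are entirely
unoxidized therefore report a large but finite fold change and a
`fc_capped` flag instead of an infinity. The floor value is arbitrary by
necessity; it only matters for proteins with literally zero control
oxidation, where any finite fold change is a convention.

## The AAPL score

The score adapts the topological score (TopS) of AP-MS interaction
analysis to oxidation data. A proteins × conditions matrix is built with
entries `v = oxidized spectral count × EPO` — combining the two
protein-level readouts so that a protein scores high only when both its
oxidized evidence (spectra) and its oxidized fraction (intensity) are
elevated. With row sums `R`, column sums `C`, grand total `T`, and
expectation `E = R·C/T`, the transform is `v · ln(v/E)` for `v > 0` and 0
otherwise (`0·ln 0` defined as 0). The score read in the selected
(optimal) treatment condition is the AAPL score; control columns
discipline the expectation.

Properties relied on downstream, all property-tested: the score is
positive iff observed exceeds expected; permuting proteins permutes
scores; scaling the whole matrix by *k* scales scores by *k*. The last
property means raw scores grow with acquisition depth, so the conventional
0/1 thresholds are meaningful on data of comparable depth; `aapl_scores()`
offers `rescale_total` to pin the grand total when comparing across depths
(off by default, honoring the printed thresholds as-is).

The exact functional combination of spectral counts and EPO is the one
genuinely open design point in this pipeline; the composition rule is
therefore a single switch (`mode`): `"spc_epo"` (default), `"spc"`
(counts only), or `"tops_epo"` (TopS of counts, multiplied by EPO after
the transform). All downstream stages are agnostic to the choice.

## Classification rules and boundary conventions

* **L1**: AAPL score strictly above 1.
* **L2**: score in (0, 1] *and* EPO fold change strictly above 1.5.
* "Above" is read as strict everywhere; score exactly 1 is an L2
  candidate, fold change exactly 1.5 fails L2, score exactly 0 is not L2.
* STRING typing: T1 needs a direct bait edge with combined score strictly
  above 0.7; T2 a direct edge in [0.4, 0.7] (both endpoints included); T3
  no qualifying direct edge but an edge of at least 0.4 to some T1/T2
  protein (the 0.4 floor on the secondary edge is a package convention);
  T4 the remainder. The typed universe is the set of scored (oxidized)
  proteins, not the whole detected proteome.
* Score-bin summaries use (1, ∞), (0, 1], (−∞, 0], assigning score 0 to
  the lowest bin.

The bait is excluded from interactor lists by definition. Cross-reactivity
reporting inverts the logic: an unrelated antigen analyzed under another
antibody's data should sit near fold change 1 with a non-positive score,
and is flagged if it would classify L1/L2.

## Networks

The single-bait graph contains the bait, all L1/L2 interactors, and those
oxidized non-interactors that share an evidence edge with the bait or an
interactor ("grey" nodes); edges among grey nodes enter only when both
endpoints are already in the graph. Edge attributes encode the figure
conventions: solid for edges among bait/T1/T2 nodes, dashed when a T3
protein is involved, backslash for T4 (the "worst endpoint" rule), and an
opacity band from the combined score at the conventional 0.4/0.7/0.9
confidence tiers. Node fill is exported as the numeric `epo_fc` attribute
— rendering (e.g. a white-to-red ramp over fold change) is the consumer's
job. Merged two-bait graphs keep per-bait attribute pairs on shared nodes
and the maximum score on duplicated edges.

## Glycan typing

The five-type vocabulary (CH, F, FS, HM, S) is formalized as a rule table
over composition counts: high mannose is unsubstituted HexNAc≤2/Hex≥4;
fucosyl-sialylated takes precedence over fucosylated and sialylated;
neutral complex/hybrid is the remainder. The boundaries follow standard
N-glycan nomenclature; they are configurable in the sense that the rule
function is pure and total (exhaustively enumerated in tests). Per-protein
percentages are intensity-weighted by default with a count-weighted
alternative, since either convention appears in glycoproteomics practice.
Inhibitor comparisons (kifunensine; sialyltransferase inhibitor) flag an
interactor as decreased when its EPO ratio to the untreated AAPL condition
drops below 0.8 (δ = 0.2) — a default chosen to sit well outside the
replicate noise of the EPO estimates at desk scale.

## The synthetic-data generator

The generator exists so that every downstream stage has ground truth. It
emulates:

* a proteome of random sequences at average amino-acid composition
  (lognormal lengths, mean 350);
* tryptic digestion (cleave after K/R except before P, configurable
  missed cleavages, detectability window 6–50 residues);
* proximity structure as three classes — bait, proximal, background —
  with oxidation multipliers (defaults 10×, 8×, 1×);
* per-residue oxidation probability `p_background × weight(residue) ×
  multiplier(protein, condition)`, with susceptibility weights in the
  hydroxyl-radical reactivity order (M > W > Y > F > H ≈ C ≫ others) and
  `p_background = 0.01` for the most reactive class, giving background
  EPO near 1.5% and bait EPO near 15–20% — the regime where both controls
  and treatments are informative;
* condition structure M1–M6 vs C1–C3: controls always at multiplier 1;
  non-selected treatments get labeling efficiencies ramped over
  [0.3, 0.8] (selected = 1), emulating sub-optimal antibody:probe ratios
  so that condition selection is non-trivial;
* noise: lognormal base intensities (meanlog 14, sdlog 1), lognormal
  replicate noise (sdlog 0.2), binomial realized oxidation fractions over
  200 pseudo-molecules, Poisson spectral counts at 3e-6 counts per
  intensity unit;
* a known-interaction edge list overlapping the true proximal set by a
  configurable fraction (default 50%, matching the observed partial
  agreement between proximity labeling and literature databases), plus
  decoy edges among background proteins.

Intensity is conserved exactly: unmodified + oxidized intensities of a
peptide observation sum to its realized base intensity.

It does **not** emulate: peptide ionization efficiency differences,
missing values from data-dependent acquisition, retention-time or
charge-state effects, search-engine FDR, shared peptides between
proteins, antibody binding kinetics, or any continuous geometry of
distance (distance is abstracted to the three classes). Passing the
recovery tests therefore shows the scoring logic is sound under the
stated noise model — not that any particular real dataset will reach the
same sensitivity.

Only mono-oxidation is simulated by default (`di_oxidation` adds second
hits behind a flag); the analysis side accepts `ox:`/`ox2:` tokens either
way.

## Numerical and degenerate-input choices

* All residue coordinates are 1-based inclusive; `ox:0` is a parse error.
* Zero-intensity/zero-count rows are dropped on read, with a logged count;
  malformed rows are hard errors, never warnings.
* EPO with zero total intensity is `NA` (excluded downstream), not 0.
* All-zero proteins normalize to 0 rather than 0/0.
* Condition clustering uses correlation distance (1 − Pearson r) with
  average linkage; constant profiles correlate as 0 by convention.
* The TopS transform is exact at `v = 0` by the `0·ln 0 := 0` rule; a
  zero grand total is an error, not a zero matrix.
* Score matrices drop all-zero protein rows (logged) before the
  transform, since such rows would otherwise make expectations
  undefined for retained columns.

## Problem sizes in the test suite

The shipped tests run entirely on generated data: oracle-equivalence
checks on 1000 random peptide tables (≤ 20 peptides each) and 500 random
matrices (≤ 20 × 9); recovery on the default study conditions
(200 proteins, 10 proximal, 8× enrichment, 3 replicates) over seeds 1–5;
cross-reactivity on 100-protein two-antigen simulations; null calibration
on 400–1000 protein simulations with all multipliers at 1. These sizes
were chosen as the smallest at which the binomial/Poisson noise averages
out enough for the recovery and calibration statements to be stable.

## Known limitations

* AAPL scores scale with acquisition depth (documented above); comparing
  absolute scores across experiments of very different depth requires the
  `rescale_total` option and then re-anchoring the L1 threshold.
* Shared peptides are credited to every matching protein, which slightly
  double-counts evidence in closely related protein families.
* The Welch test needs ≥ 2 replicates per side; designs with single
  replicates get no inference, only point estimates.
* Whether the published percentages for glycan types are intensity- or
  count-weighted is not determinable from figure captions alone; both are
  implemented, intensity-weighted is the default.
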