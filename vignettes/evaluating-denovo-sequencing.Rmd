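---
title: "Evaluating de novo peptide sequencing: accuracy metrics and target-decoy FDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating de novo peptide sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovoeval)
```

## The problem

De novo peptide sequencing infers a peptide's amino acid sequence directly
from a tandem mass (MS/MS) spectrum, with no protein database. Evaluating
such tools is harder than evaluating database search: per-study accuracy
definitions drift, and — unlike database search with its decoy databases —
there has been no standard way to estimate the false discovery rate (FDR)
of de novo peptide-spectrum matches (PSMs). This package implements a
complete evaluation framework: three accuracy metrics computed against
ground-truth peptides, decoy *spectrum* generation, target-decoy FDR
estimation, a fragment-ion-coverage "true FDR" for validating the
estimate, and a mutated-peptide benchmark simulator. Everything runs
offline on synthetic data generated in code, and equally on any real MGF
file plus delimited PSM tables.

## Accuracy metrics

All three metrics are micro-averages: numerators and denominators are
summed over all PSMs first, then divided. A scan where the tool returned
no peptide contributes zeros to every numerator and its full denominators
— abstention is never rewarded.

**Fragment-ion accuracy.** For each PSM, the theoretical ions of the
ground-truth and the de novo peptide are computed — twelve categories per
fragmentation site: b and y series, each plain or with an H2O or NH3
neutral loss, at charge 1 and 2 — and matched against the spectrum peaks
at 0.02 Da (inclusive). The metric is the summed count of *shared*
matched peaks over the summed count of ground-truth matched peaks. We
count distinct peaks rather than ion labels (a peak satisfying both a b
and a y ion counts once); the spectrum evidences peaks, not labels, and
the peak-level intersection is what both peptides can jointly explain. A
switch (`count = "ions"`) provides label-level counting for comparison.

**Amino-acid accuracy.** Residues are aligned by mass, not by string
position: two cursors walk both peptides from the N terminus, and
residues are matched when their masses differ by less than 0.1 Da while
their cumulative masses agree within 0.5 Da; otherwise the cursor with
the smaller cumulative mass advances. This deliberately approximate match
absorbs isobaric pairs (I/L, N(Deamidation)/D, K/Q, Q(Deamidation)/E,
M(Oxidation)/F) that high-resolution instruments cannot separate. The
greedy cursor rule follows the established reference implementations of
this metric; because the printed descriptions of the rule are loose, the
test suite checks the cursor walk against a dynamic-programming oracle
that maximizes matched pairs under the same tolerances.

**Peptide accuracy.** A peptide counts as recovered when every de novo
residue matched in the alignment; the denominator is the number of
ground-truth PSMs.

`stratify_by_length()` repeats the micro-average within user-defined
peptide-length bins, since performance depends strongly on length.

## Decoy spectra and FDR estimation

Decoy *peptides* are useless against a de novo engine, which will happily
find the best sequence for any spectrum. The framework instead builds
decoy *spectra*: for each target spectrum a fraction X of its peaks is
removed and replaced by the same number of "noise" peaks drawn from the
pool of real peaks across the whole dataset, so every decoy keeps its
target's peak count and precursor line, and decoy peaks follow the target
peak distribution. Two removal strategies are implemented:

* **random** — peaks removed uniformly; noise sampled from the all-peaks
  pool;
* **intensity/peptide-mass** — the removal count is derived from the
  precursor neutral mass M: estimated length `L = round(M / 123)` (123 Da
  being roughly the average residue mass), expected b/y ion count
  `(L - 1) * 2`, removal count that times X. The top-count
  highest-intensity peaks are removed (ties toward lower m/z, so results
  are deterministic), and noise is drawn from the pool of *removed* peaks
  only.

Numerical choices frozen here: halves round away from zero in every
count; noise is sampled with replacement (the pool is large, and
without-replacement bookkeeping fails on small pools); a spectrum may
re-receive one of its own removed peaks; duplicate m/z values are
allowed, as MGF permits them.

The engine is then run on targets and decoys alike, and PSMs compete:
either per scan (`scan_specific`, higher score wins, ties to the target)
or with both PSMs kept (`keep_both`), which lets every decoy compete
against the whole dataset and yields the more stringent estimate. At a
score cutoff with D decoy and T target PSMs above it, the estimated FDR
is D/(D+T) (the proportion of decoy PSMs, the default) or the classical
D/T behind `denominator = "targets"`. No monotonization or q-value
transform is applied by default; raw proportions are reported, with
cutoffs taken at 200 evenly spaced score quantiles.

## True FDR and validation

With ground truth available, the estimate can be validated against a
"false peptide rate". A de novo peptide is *correct* when the peaks its
theoretical ions match (set 2) cover strictly more than Y% (default 90%)
of the peaks matched by the ground-truth peptide's ions (set 1). This is
deliberately weaker than sequence identity: when a spectrum lacks the
fragment ions that would distinguish two sequences, a de novo tool cannot
be blamed for choosing the wrong one. PSMs whose ground truth matches no
peak at all are excluded from the true FDR entirely, for the same reason.

`validate_fdr()` reports the signed gap between the estimated and true
curves and the maximum absolute gap over the region with true FDR at most
0.2, labelling each sweep point as an under-estimation, over-estimation
or accurate. `fdr_calibration_sweep()` runs the whole workflow over both
strategies and a grid of X values and reports the best-calibrated
configuration. One subtlety matters when validating: the true FDR is a
rate among *target* PSMs, so the estimator on the same scale is D/T. The
default D/(D+T) answers "what fraction of accepted PSMs are decoys" and
is systematically below D/T by the factor 1/(1 + D/T) — about 3 points at
an FDR of 20% — so the sweep validates with `denominator = "targets"`.

## The synthetic benchmark

Because the framework must be testable without external engines or
repository downloads, the package ships its own data generator and a
controllable mock engine. These emulate the *statistical structure* the
framework assumes, not real spectra:

* `generate_fixture_dataset()` draws tryptic-like peptides (length 7–20,
  C-terminal K/R) and predicts spectra containing exactly the singly
  charged b/y ions with rank-based synthetic intensities (y brighter than
  b, mid-sequence brighter than termini). Defaults: 10% per-ion dropout,
  10 uniform noise peaks per spectrum, 0.005 Da m/z jitter (a quarter of
  the matching tolerance) — a clean but not sterile high-resolution
  spectrum. An optional terminal-site dropout removes ions near the
  peptide ends to reproduce the missing-terminal-fragment phenomenon.
* `mock_denovo()` corrupts the ground truth in spectrum-aware ways:
  fragmentation sites with no matched b/y ion trigger adjacent-residue
  swaps (exactly the ambiguity a real engine faces at a missing site),
  plus independent residue substitutions and transpositions; an optional
  "recall" bias toward a supplied reference peptide models training-data
  memorization. The score is the percentage of the prediction's b/y ions
  found in the spectrum, plus bounded Gaussian noise — origin-blind, so
  decoy spectra are scored exactly like targets.
* `mutate_peptide()` / `generate_mutation_datasets()` build the
  mutated-peptide benchmark: one dataset per substitution count k
  (default 1–10), each peptide mutated at exactly k distinct positions
  (substitutes never equal the original residue; isobaric substitutions
  are allowed and will still align under the 0.1 Da rule), positions
  recorded so positional accuracy needs no re-inference.

What passing tests on these fixtures do **not** show: behaviour on real
noise structure (the generator's noise is uniform, not fragment-like),
on co-eluting peptides, low-resolution data, or real engines' score
scales. The framework's contracts (count conservation, micro-averaging,
competition rules, coverage classification) are what the tests establish.

## Study conditions used by the test suite and acceptance script

Problem sizes are chosen to exercise the statistics without waste:
pipeline-closure on 500 noise-free spectra with a zero-error engine
(all three accuracies exactly 1, true FDR identically 0); decoy
conservation over X in {0.1, ..., 0.9} under both strategies on 100
spectra; FDR calibration on a 2,000-scan fixture with a 5% per-residue
engine error, sweeping both strategies over the X grid (under these
conditions the best configuration tracks the true FDR within 5 points,
and whole-dataset competition is uniformly at least as stringent as
scan-specific competition); the mutation benchmark on 1,000 peptides of
length 10–20 (so every k in 1..10 applies to every peptide), where
peptide accuracy declines monotonically in k when the engine is biased
toward the unmutated references, and terminal-site dropout of 0.5
depresses mutated-position accuracy in the first-3 and last-3 position
classes relative to the middle-3 class (classes defined only for length
at least 9, where they are disjoint).

## Positional classes and other decisions

* Position classes: first three, last three, and middle three (positions
  `ceiling(L/2) - 1 .. ceiling(L/2) + 1`); peptides too short for the
  classes to be disjoint (L < 9) are excluded and counted.
* Charge-2 fragment ions are enumerated regardless of precursor charge;
  restrict with the `charges` argument if desired.
* Matching is many-ions-to-one-peak with a nearest-peak tie-break; the
  alternative (greedy one-to-one) is not what the spectrum evidences and
  is not implemented.
* The mass table is monoisotopic, frozen at five decimals, and shipped
  both in code and as a plain-text resource that a test compares
  bit-exactly.
* Peptide strings use the Letter(ModName) dialect;
  `convert_mass_delta_notation()` maps "+57.02"-style annotations onto
  the registry within 0.01 Da.

## Known limitations

The simulator emits only singly charged b/y ions, so the twelve-category
matcher is exercised against real variety only through the loss/charge
arithmetic itself; intensity models are synthetic ranks, not learned
spectra; and the mock engine's score is a fragment-coverage percentage,
which real engines only approximate. Calibration results on the fixtures
(which removal percentage is best, how large the gap is) characterize the
fixtures, not any particular real engine: on real data the best
percentage must be re-selected per tool, which is precisely the workflow
`fdr_calibration_sweep()` automates.
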