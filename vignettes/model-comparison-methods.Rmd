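---
title: "Statistical comparison of crystallographic model pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical comparison of crystallographic model pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalcmp)
```

## The problem

Automated re-refinement and rebuilding of a deposited crystal structure
produces a second model of the same data, and the question every user asks
is: *is the new model actually better, and where?* Most quality indicators
are noisy, and their noise depends on the data (test-set size, resolution,
residue size), so raw differences mislead. xtalcmp implements the decision
layer for that comparison: calibrated significance rules for global
indicators, a clash-severity score, percentile ranks against a reference
databank, a paired-refinement rule for choosing a resolution cutoff, k-fold
cross-validation of the free R factor, occupancy sanitization, and
per-residue change detection with Coot script output.

## Significance rules for global indicators

**Free R factor.** The precision of R\_free is limited by the test-set size;
we use the standard estimate σ(R\_free) = R\_free / √N\_test, computed from
the *initial* model, which defines the null hypothesis. A change is called
significant when |ΔR\_free| > 2.6 σ, the two-sided standard-normal threshold
for p = 0.01 (`round(qnorm(1 - 0.01/2), 1)` = 2.6). The boundary itself is
insignificant: the rule is strict inequality, so "2.6 σ exactly" does not
fire. Work R gets no verdict — it can be lowered by overfitting, and no
calibrated rule exists for it.

**Free correlation coefficient.** Correlations are variance-stabilized with
the Fisher transformation z = atanh(cc); the change statistic is

Z = (z(cc\_f) − z(cc\_i)) / √(1/(N\_i − 3) + 1/(N\_f − 3)),

the standard two-sample form, with |Z| > 2.6 significant. The 1/(N − 3)
variance is what makes Z undefined for N ≤ 3, which is exactly the
behaviour needed per-residue (below): tiny compounds at low resolution have
too few independent map points for any verdict.

**Restraint r.m.s. Z-scores.** Bond and angle r.m.s.Z have no distributional
test, only the convention that values should not exceed 1.0. The rule scheme
is: from above 1.0, any strict decrease is an improvement and any strict
increase a deterioration; crossing upward through 1.0 is always a
deterioration; everything else is insignificant.

**Percentile ranks.** Geometry scores (Ramachandran, rotamer, fine packing,
bump severity) are reported as percentile ranks against the reference
databank. With a databank of ~70 000 entries one percentile point spans ~700
entries, so a change of one point or more is treated as significant.
Percentiles use strictly-worse counting (worst score → 0, better than all →
100, ties share a rank); the convention is stated because implementations
differ and plots must match.

Verdict colours are fixed: improvement = green, deterioration = red,
insignificant = grey, undefined = white.

```{r verdict-example}
initial <- quality_scores(r = 0.22, r_free = 0.25, n_test = 1200,
                          cc_free = 0.90, n_free_obs = 1200,
                          bond_rmsz = 0.7, angle_rmsz = 1.2)
final <- quality_scores(r = 0.19, r_free = 0.21, n_test = 1200,
                        cc_free = 0.94, n_free_obs = 1200,
                        bond_rmsz = 0.7, angle_rmsz = 1.0)
build_comparison(initial, final)[, c("metric", "initial", "final", "label")]
```

## Weighted bump severity

Clashes are unordered atom pairs whose separation falls short of the sum of
their van der Waals radii (Bondi-type defaults: C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80, H 1.20 Å; unknown elements 1.70 Å) by more than a minimum
overlap, default 0.10 Å — small enough to catch real errors, large enough to
suppress contacts attributable to liberal restraint settings. Excluded:
pairs within a residue, main-chain contacts of sequence-adjacent residues
(bonded geometry), and pairs in different alternate conformations; models
with alternates are first reduced to the highest-occupancy conformer.
Detection uses a spatial grid (near-linear cost) and considers no
crystallographic symmetry mates — a documented narrowing relative to full
validation practice that keeps the module map- and symmetry-free.

The score is BS\_w = 100 · Σ overlap² / N\_residues. The quadratic weight is
chosen so that severe clashes dominate: one 0.8 Å clash counts as much as
sixteen 0.2 Å clashes. The functional form is isolated behind
`weighted_bump_severity()` so an alternative published normalization can be
swapped in without touching detection.

## Paired refinement and the resolution cutoff

When the data extend beyond the resolution previously used, the cutoff is
extended step by step. Bins beyond the previous cutoff have *equal
reflection counts* (`binliner`), not equal resolution width, so each further
step adds a predictably noisier but equally sized packet of data;
reflections with identical d never straddle a bin edge. At each step two
models are refined — one at the current, one at the extended cutoff — and
compared on the *common* lower-resolution test reflections using four
metrics: R\_free, weighted R\_free (w = 1/σ²), the free correlation
coefficient, and a free log-likelihood (Gaussian surrogate; an engine
supplying its own likelihood takes precedence). A single least-squares scale
between Fo and Fc is applied per model before metric computation — the
minimal scaling choice. The extension is rejected as soon as two or more
metrics show strict numeric deterioration ("equally well or better" always
passes); ties are not deteriorations.

Real reciprocal-space refinement is out of scope. The `RefinementEngine`
contract — `(model, reflections, d_cutoff) → (model, f_calc)` — carries mock
engines: an identity engine (perfect fit), a fixed-truth engine, and
`engine_mock_noise()`, whose error level falls with the amount of data used
and rises with the noise of the included high-resolution shells. The mock
draws one seeded error direction shared by all cutoffs, so the accept/reject
sequence is deterministic: extension continues exactly while the error level
falls, and worsening the noise profile can only stop it earlier. This makes
the decision-procedure tests exact rather than statistical.

## k-fold cross-validation of R_free

With fewer than 500 test reflections a single R\_free is unreliable
(test-set selection alone moves it by whole percentage points), so k-fold
cross-validation is used: k = round(1/test fraction) alternative disjoint
test sets (k = 20 for a 5% set, minimum 2). Fold assignment is a seeded
random permutation within thin resolution shells (blocks of k reflections in
descending-d order), so every fold samples all resolutions, as free sets
conventionally do; a deposited multi-valued free flag covering 0..k−1 is
reused instead of regenerating folds. Before each fold the model is
perturbed to make the alternative sets "free": either every B factor is
reset to a fixed value (default: the median input B, rounded — a
scale-appropriate surrogate that needs no map access), or, for refinement
regimes without individual B factors, coordinates are jiggled with an
isotropic Gaussian of 0.2 Å per axis — large enough to decorrelate the model
from a previous test-set choice, small enough to preserve the structure. The
choice between modes is the caller's, since the package cannot see the
B-factor model. Per fold, work R and free R are computed after a
least-squares scale fitted on the work reflections; means and standard
deviations across folds summarize the result.

## Occupancy sanitization

Residues whose occupancies encode "not there" (0.00 or 0.01) or that carry
three or more distinct occupancy values (at the 2-decimal precision of the
PDB format) are flagged as implausible. Genuine alternate conformations —
internally uniform conformer groups summing to ~1 — are exempt from the
three-value rule, and only non-standard residues (ligands, modified
residues) are examined by default, because that is where the pattern
occurs; `only_nonstandard = FALSE` widens the net. Flagged residues receive
one occupancy per residue: the value held by most atoms, ties towards the
larger value, clamped to [0.01, 1]. The assigned value is an initializer
for downstream occupancy refinement, so the least-surprising rule was
preferred over any attempt at estimation, and it is isolated in
`assign_single_occupancy()`.

## Per-residue density fit and model changes

Per-residue real-space correlation (RSCC) changes reuse the Fisher-Z
statistic with N = the number of independent map grid points behind each
RSCC value, so significance depends on residue size and map resolution, not
only on the magnitude of the change: |Z| > 2.6 is green/red, defined but
smaller is grey, undefined (N ≤ 3) is white. Fit tables are preferentially
read from an external density-statistics program's output; when absent,
`estimate_grid_points()` counts nodes of a d/3 lattice within 2.0 Å of the
residue's atoms — a documented approximation to "independent" grid points,
which the package does not attempt to define crystallographically.

Discrete rebuilding events are detected from the coordinates: deleted
waters; completed side chains (atoms beyond CB appearing); rotamer changes
(any χ dihedral moved > 30°, with the 180° terminal equivalences of
Phe/Tyr/Asp/Glu folded out); His/Asn/Gln flips (the swapped terminal
assignment matches better than the direct one); and peptide flips (carbonyl
O moved > 2.0 Å while both flanking Cα stay within 0.5 Å). The χ threshold
and flip thresholds are not prescribed anywhere; 30°/2.0 Å/0.5 Å separate
rotamer-well moves and plane flips from refinement jitter and are function
arguments, not constants. Precedence when several detectors fire is
peptide-flip > hnq-flip > rotamer. All detectors depend only on internal
geometry, so a common rigid-body motion of both models changes nothing.
Changes are exported as Scheme and Python scripts that open a Coot button
list recentring on each change site.

## Reference databank and synthetic data

Percentiles and box plots are computed against the ~1000 entries nearest in
resolution (all exact ties with the 1000th distance included). Box plots use
linearly interpolated quartiles and 1.5·IQR whiskers with Tukey outlier
flagging.

No real databank ships with the package. `generate_synthetic_databank()`
draws resolutions log-normally (meanlog = log 2.0, sdlog = 0.25) and scores
from resolution-dependent distributions: r\_free ~ N(0.05 + 0.07·d, 0.03)
floored at 0.01, Ramachandran Z ~ N(1.0 − 1.2·d, 1.5), rotamer Z ~
N(0.8 − 1.0·d, 1.5), packing Z ~ N(0.5 − 0.8·d, 1.2), bump severity ~
logN(log(0.5 + 1.5·d), 0.8). The trends (quality degrades with resolution)
are realistic; the *correlation structure is not* — real scores co-vary
strongly within an entry, resolutions cluster at data-collection sweet
spots, and score distributions have heavier tails. Passing tests against
this databank therefore demonstrate correct ranking, neighbourhood and
box-plot mechanics, not calibrated percentiles for real structures.
Similarly, `generate_synthetic_reflections()` produces Wilson-like
amplitudes with proportional sigmas and a random test set; it emulates
counting statistics, not anisotropy, twinning, ice rings or incompleteness.

## Numerical choices and degenerate inputs

* d-spacings use the general triclinic reciprocal-metric formula; tested to
  1e-9 relative against direct metric-tensor inversion.
* Significance thresholds are strict (`>`), so boundary values are
  insignificant; rmsZ rules are also strict, so no-change is never a verdict.
* `sigma_rfree` with an empty test set, and Z with N ≤ 3, propagate to
  "undefined" (white) rather than erroring, because both occur in real
  input.
* `binliner` puts remainders in the leading (low-resolution) bins and grows
  a bin rather than splitting reflections of identical d.
* Intensity-only reflection files are accepted as F = √max(I, 0) with a
  warning; no French–Wilson conversion is attempted, which keeps scope on
  the decision layer. Binary MTZ is not read — the documented CSV dialect
  (h,k,l,F,SIGF,FREE plus a `# cell` line) is the interchange format, and
  the free-flag column is recognized as the most-populated integer column
  whose minority fraction is below 50%, the minority value marking the test
  set.
* Duplicate Miller indices (unmerged data) and residues sharing an
  identifier with conflicting names are hard errors, named in the message.

## Problem sizes

The shipped tests and the acceptance script run on: a 70 000-entry synthetic
databank for percentile equivalence; 10 000 reflections for fold tiling;
2 000 reflections × 20 folds × 5 seeds for the k-fold recovery check;
3 000 reflections and 5 extension steps for paired refinement; 200-atom
random models against the all-pairs clash oracle; and the 3-residue demo
pair for end-to-end determinism. These sizes were chosen as the smallest at
which each statistical claim is cleanly visible.

## Known limitations

* No symmetry-related clash detection, no hydrogens placed, no per-atom
  energies.
* No mmCIF, no anisotropic B factors, no map I/O.
* The refinement engines are mocks; every conclusion about real refinement
  behaviour requires plugging in a real engine behind the contract.
* The grid-point estimator approximates map independence by masking only.
* Synthetic data limitations as described above.
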