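---
title: "Methods: middle-down quantification of H3 tail proteoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: middle-down quantification of H3 tail proteoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midtail)
```

## The measurement model

`midtail` quantifies combinatorially modified histone H3 N-terminal tail
proteoforms from multiplexed middle-down MS2 data. The analyte is the
sortase-released tail: residues 1–32 of H3.1 or H3.3 fused to a GGGH tag,
giving the 36-residue surrogates

```
H3.1  ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGGH
H3.3  ARTKQTARKSTGGKAPRKQLATKAARKSAPSTGGGH
```

which differ only at position 31 (A vs S). Because the sortase motif sits at
residues 29–33, information C-terminal of T32 (notably K36) is lost by
construction. Two fixed chemical moieties travel with every peptide: a TMT
6-plex label on the single histidine (+229.162932 Da, computed here from its
elemental composition with two heavy isotopes, 4 x 13C + 1 x 15N) and a
C-terminal ligation scar of +76.1001 Da, defined as the mass difference
between His and Lys + 2,3-diaminopropionamide left by the tag chemistry.
That offset is a defined constant of the labelling scheme, not an elemental
formula, and is stored as printed.

The variable search space is the registry returned by
`default_modifications()`: the methyl series on K/R (max 3 each; trimethyl K
only), phospho on S/T (max 2), acetyl on K (max 5), and rare propionyl on K
(max 1), with at most 6 common + 1 rare marks per peptide. All compositional
deltas are computed from IUPAC monoisotopic atomic masses, so e.g. acetyl is
42.0105646 Da, distinct from trimethyl at 42.0469502 Da — a 0.036 Da split
that the 15 ppm fragment tolerance (±0.02 Da at m/z 1300, charge 1) can
resolve on most fragments; disambiguation is the search engine's job, and
the package consumes its assignments.

## Fragment chemistry

`fragment_ladder()` generates a/b/c/y/z ions with the conventions

- `b_i` = sum of (modified) residues 1..i; `a_i = b_i − CO`;
  `c_i = b_i + NH3`
- `y_j` = sum of residues n−j+1..n + H2O + the C-terminal offset;
  `z_j = y_j − (NH3 − H)` (radical z-dot, the ETD default; plain z via
  `z_radical = FALSE`)
- m/z = (neutral + z x 1.00727646677)/z; the 13C−12C spacing is
  1.0033548 Da.

Modifications localize to the ladder side containing their residue, so
complementary neutral b/y pairs sum exactly to the proteoform neutral mass —
an identity the test suite checks to < 1e−9 relative error on random
proteoforms. Neutral losses default to NH3 and H2O on all series (including
a ions; removable via the `losses` argument), and fragment charges run from
1 to min(4, precursor charge − 1). The precursor side of the chemistry is
`proteoform_neutral_mass()`, verified in the tests against an independent
mass calculator on the printed sequences.

## Annotation and attribution

Each peak of a PSM-bearing scan is matched, per PSM, to the theoretical
fragment minimizing |ppm error| within tolerance (default 15 ppm). Exact
ties — which arise systematically, e.g. `c_i − NH3` coincides with `b_i` to
machine precision — are broken deterministically: candidates whose +1
isotope companion is present at the candidate's charge win first
(charge-state disambiguation by isotope spacing, standard practice), then
lowest index, series order a<b<c<y<z, lowest charge, and no-loss before NH3
before H2O. A peak carries at most one match per PSM; a peak explained by
several co-isolated PSMs lists all of them.

A match is *confirmed* when a peak of positive intensity sits at
m/z + 1.003355/z within the same ppm tolerance. Only confirmed matches carry
intensity: the peak's intensity is credited to its PSM, an equal 1/k split
for peaks confirmed for k PSMs. Equal split is a deliberate choice where the
underlying procedure is underdetermined; a proportional-to-unique-evidence
split is available via `share = "proportional"`. With equal split the
attributed intensity per scan equals the summed intensity of its confirmed
peaks exactly — the conservation invariant the acceptance checks enforce.
Proteoform abundance is then the attributed-intensity fraction, pooled over
scans within one run (abundances are not pooled across runs; a second
6-plex is a second fit).

Peaks below 133 m/z are excluded from fragment matching. The TMT 6-plex
reporter region lies there, and the reporter channels are spaced almost
exactly one 13C unit apart, so reporters would otherwise be matchable as
"isotope-confirmed fragments" of low-mass ions and double-counted. The
floor is configurable (`min_fragment_mz`).

## Reporter quantification

Reporters are extracted as the nearest peak within tolerance of each
channel's m/z (standard TMT6 values, editable in the run design); a missing
or zero-intensity channel counts as missing. Label isotopic impurities are
corrected by solving `M x = raw` for the design's mixing matrix M (column j
= distribution of label j across channels; identity by default), clipping
negative solutions at zero with a warning. A constrained solve was chosen
over ignoring impurities because the simulator can apply M forward, giving
the exact-inversion acceptance check; what "processed separately" should
mean beyond this is not specified anywhere, so identity is the shipped
default.

Channel normalization multiplies every channel by max(S)/S_c, where S_c is
the channel's mean (default) or median intensity over all PSM-bearing
scans. This removes loading imbalance while preserving within-scan ratios.
Scans with at least `min_reporters = 2` non-missing reporters per treatment
condition, and whose accepted PSMs all share one proteoform, contribute
their log2-transformed normalized intensities to that proteoform's
grouping; zeros are excluded rather than imputed, since an imputation model
would add assumptions the data cannot check. Chimeric scans with two
different proteoforms contribute to abundance but not to reporter grouping,
because their reporter signal is a mixture.

## Differential statistics

Per proteoform, log2 signals pool by condition across eligible scans;
log2FC = mean(treated) − mean(vehicle), tested two-sided. Welch's unequal
variance t-test is the default — the safer choice when per-condition
variances differ and nothing in the procedure promises homoscedasticity —
with the pooled-variance variant behind `var_equal = TRUE`. Significance is
flagged at raw p < 0.05 (strict inequality); Benjamini–Hochberg q-values are
reported as an extra column for transparency but deliberately do not drive
the flag, matching the underlying procedure. Proteoforms with fewer than 2
observations in either condition are reported as quantified-but-not-tested.
The `vehicle` condition defaults to the condition of the design's first
channel (TMT-126 in the shipped design).

Site-level marginals (`marginalize_sites()`) sum proteoform abundances
carrying each positioned mark; the unmodified fraction of a site is one
minus the sum of marks there. `compare_bottom_up()` computes Pearson r over
the site labels shared with an external bottom-up table (≥ 3 required),
per condition when both tables carry one.

## What the simulator emulates — and what it does not

`simulate_dataset()` reproduces the acquisition geometry of the assay:
charge-8 precursors isolated in 480–540 m/z, chimeric scans (default rate
0.2, i.e. a fifth of scans carry a second co-isolated PSM), fragment peaks
from the charge 1–2 b/c/y/z ladders with Gaussian m/z jitter (σ = 3 ppm,
matching a 15 ppm matching tolerance at 5σ), +1 isotope companions at 0.45
of the monoisotopic intensity (the approximate +1/mono ratio of a ~4 kDa
peptide), log-normal fragment intensities (median 2000, sdlog 0.7), 30
uniform noise peaks per scan, TMT reporters with per-channel loading
imbalance, log-normal multiplicative noise (CV 0.3) and forward impurity
mixing, and a PSM table in which 15% of rows are generated to fail the
score filters (the filter-bookkeeping tests count them exactly).

Two generator conventions matter for interpretation:

- *Scan allocation is deterministic* (largest-remainder apportionment
  proportional to the across-channel mean fractions). Scans are drawn
  proportionally to the mixture without multinomial sampling noise, so
  recovery error measures the pipeline, not the draw. The default
  five-proteoform mixture (fractions 0.35/0.25/0.20/0.12/0.08) makes the
  default 200-scan allocation exact.
- *Condition effects are true fraction fold changes.* A configured log2
  shift scales the proteoform's fraction in the treated channels, and the
  unshifted proteoforms renormalize so each channel's fractions sum to 1 —
  total tail amount per channel is constant, as in balanced 1:1:1:1:1:1
  channel mixing. Reporter intensities scale with the per-condition
  fraction relative to its across-channel mean. This makes "injected shift
  recovered without bias" well-posed: the injected value is exactly the
  quantity the pipeline estimates. The default configuration shifts
  H3K9acK14acK23acK27me2 by log2(2.55) ≈ 1.35, the hallmark
  deacetylase-inhibition response this assay is designed to detect.

The simulator does not model chromatography, MS1 survey scans, full isotope
envelopes (truncated at +1, sufficient for the confirmation rule),
co-isolation of unidentified species, or a calibrated relationship between
PEP and the true error rate. Passing tests therefore demonstrate
correctness of the computation under the stated noise model — not
robustness to retention-time-dependent interference or search-engine error
patterns in real data.

## Numerical choices and degenerate inputs

- The noiseless-limit check runs the annotator at 0.01 ppm tolerance: with
  zero simulated jitter the tolerance should track the (perfect) mass
  accuracy. At 15 ppm, accidental coincidences between +1 isotope peaks and
  unrelated theoretical ions — e.g. the +1 peak of an NH3-loss y ion lies
  4.5 ppm from the z-dot ion — contribute ~1e−3 level cross-attribution,
  which is a property of the idealized data, not an implementation error.
  Default-noise runs use 15 ppm throughout.
- All-zero attribution yields an empty abundance table with a warning;
  channels with no signal are excluded from the normalization maximum and
  left unscaled; a singular impurity matrix is an error naming the design;
  empty result tables are written as headers-only files; and output tables
  are byte-deterministic (fixed sort, fixed number formatting).
- Problem sizes in the shipped checks — 200 scans for default-noise
  recovery, 100 for the noiseless limit, 400 for shift recovery, 1000
  proteoforms at 6 observations per condition for the null calibration of
  the t-test — were chosen to make sampling error a small fraction of each
  check's tolerance.

## Limitations

PEP and delta-mod scores are consumed, never computed: the package trusts
the upstream search. There is no FDR estimation, no PTM re-localization, no
MS1-level quantification, and no moderated (limma-style) test — raw
per-proteoform t-tests match the underlying procedure, at the cost of power
for sparsely observed proteoforms. K36 and everything C-terminal of the
sortase motif are invisible to the assay. mzML support (via mzR) writes
numeric native scan ids; the package's TSV peak-list dialect preserves ids
verbatim.
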