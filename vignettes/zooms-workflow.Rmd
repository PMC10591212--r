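---
title: "ZooMS biomarker discovery and species identification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ZooMS biomarker discovery and species identification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoomsr)
```

## The problem and the model

Collagen type I survives in bone for millennia.  Its sequence differs
slightly between species, so the masses of its tryptic peptides — read as
singly protonated ions from a MALDI-TOF spectrum — form a taxonomic
fingerprint.  In teleost fish, COL1 comprises three distinct chains (α1a,
α2, α1b), roughly tripling the supply of potentially discriminating sites
relative to mammals.  This package implements the full desk workflow:
derive candidate biomarkers from reference COL1 sequences, match them
against spectra, and call taxa per sample, with every stage validated
against synthetic ground truth.

The mass model is deliberately minimal.  A peptide's singly protonated
monoisotopic mass is

$$[M+H]^+ = \sum_i m_{\mathrm{res}}(a_i) + m_{H_2O} + m_{H^+}
  + n_{OH}\,\delta_{OH} + n_{deam}\,\delta_{deam} + n_{ox}\,\delta_{ox}$$

with $\delta_{OH} = 15.994915$ (hydroxylation of Pro/Lys),
$\delta_{deam} = 0.984016$ (deamidation of Asn/Gln, common in ancient
proteins) and $\delta_{ox} = 15.994915$ (Met oxidation).  Modifications are
*counted*, never site-localised: MALDI-TOF reads whole-peptide masses and
cannot localise them.  Collagen peptides therefore appear as ~16 Da ladders
of hydroxylation states, which is how the package reports them.  Multiply
charged ions and adducts are out of scope (MALDI collagen work reads the
singly charged peaks).

## Digestion

Trypsin cleaves C-terminal to K/R; the classical rule suppresses cleavage
when proline follows.  That rule is the default, with
`cleave_before_proline = TRUE` available because observed collagen panels
contain proline-initial peptides implying an R–P cleavage.  Defaults
`max_missed_cleavages = 2`, `min_length = 6`, `max_length = 60` span
published fish ZooMS markers (12–33 residues, some with an internal K/R)
with margin.  Peptides are indexed by 1-based start position in the
*mature* chain, which makes the positional name (`COL1a2 568`) identical
for homologous peptides across species — the hinge on which cross-species
pairing turns.  Mature-region bounds are explicit annotations supplied with
the sequences; predicting propeptide cleavage is not attempted.

## Marker discovery and diagnosticity

`discover_markers()` digests every species, pairs peptides by (chain,
mature start, missed cleavages) — valid because the chains are treated as
gap-free and length-matched, with `X`-padding and a warning where lengths
differ — and emits a marker wherever sequences differ between at least two
species or a peptide is present in some species only.  A species' variant
is *specific* when no other species shares its sequence; the marker is
flagged for a single species only when exactly one species carries a unique
variant.

Being sequence-specific is not enough to be *usable*: MALDI only sees
masses.  Each variant state is therefore flagged MALDI-diagnostic only if
its m/z is separated by more than the tolerance (default 0.2 Da, an
external-calibration MALDI scale; ppm matching is available) from every
mass any other species can produce.  The collision background is the *full*
digest of the other species — including invariant peptides, and with
hydroxylation enumerated to the residue cap rather than the reporting cap —
because a shared peptide peak that happens to be isobaric with a
species-specific variant would otherwise fake cross-species evidence.
`isobaric_conflicts()` reports all within-panel collisions explicitly, the
classic example being a serine/proline versus proline/alanine pair whose
masses coincide exactly when the second carries one extra hydroxylation.

The bundled grouper panel (`grouper_panel()`) is a verbatim transcription
of a published four-species reference table: printed observed masses are
stored as strings and never forced to agree with computed masses; footnoted
entries (comber-shared mass, isobaric peak, LC-MS/MS-only evidence) are
demoted from diagnostic use; and one row whose printed mass is ~17 Da below
its printed sequence's computed mass is carried as an annotated anomaly.

## Spectra

The published processing chain for such data runs through a GUI tool's
"default settings", which are not recoverable; this module instead fixes an
explicit, documented contract, with every value a config knob
(`preprocess_params()`):

* baseline: rolling minimum in windows of 5% of the m/z span, linearly
  interpolated and subtracted, floored at zero;
* smoothing: Savitzky–Golay, 7 points, order 2;
* noise: $1.4826 \times$ MAD of (intensity − block median) in 100 Da
  blocks, interpolated; blocks are anchored at the spectrum's lowest m/z so
  all estimates are invariant under a global mass shift, and a trailing
  partial block is merged into its neighbour so no estimate is starved of
  points;
* peaks: local maxima with S/N ≥ threshold (default 3.0; the conventional
  working range is 3.0–5.0), apex refined by three-point parabolic
  interpolation — on log intensities when all three points are positive,
  which is exact for Gaussian profiles and recovers centres to well under
  0.05 Da at ~3 points per FWHM.

S/N is defined as (intensity − local median) / local noise, so a pure-noise
spectrum yields false positives at roughly the Gaussian 3σ tail rate —
bounded explicitly in the tests.  Centroided input (auto-detected from
point density) bypasses baseline, smoothing and refinement.  Manual peak
inspection, used in practice on real spectra, is replaced by this machine
rule; there is no hidden curation step.

## Identification

`predict()` on a fitted panel matches every MALDI-visible variant against
the picked peaks (best absolute delta per variant, deltas reported signed)
and applies deliberately conservative rules: a species call needs at least
`min_specific` (default 1) distinct specific, diagnostic markers for
exactly one species and none for any other; specific evidence for two
species is a recorded conflict and forces `indeterminate` — never a
majority vote.  With shared-marker support only (default ≥ 2 distinct
markers) the call is `genus_level`.  LC-MS/MS-only markers are excluded
from matching by default; `include_lcms_only` exposes the relaxation some
studies apply to borderline spectra as an explicit flag rather than a
guess.  Demoted (non-diagnostic) variants still match and count as shared
support, mirroring the "use only in combination" guidance attached to
ambiguous published markers.

## Phylogeny stand-in

The tree module is a sanity check that species in a profile set are
separable, not a phylogenetic method: pairwise p-distance over concatenated
mature chains (positions with `X` in either sequence excluded pair-wise),
neighbour joining via `ape`, and column-resampling bootstrap (support = %
of replicates containing each split; default B = 100, a knob).  Negative NJ
branch lengths are clamped to zero.  Maximum-likelihood trees under
substitution models are explicitly out of scope; on additive matrices NJ
provably recovers the generating topology, which is what the tests assert.

## The synthetic generator

`make_species()` builds an ancestral Gly-X-Y repeat protein per chain
(glycine every third residue, proline-rich X/Y draws, K/R at a frequency
giving realistic tryptic fragment lengths) and derives each species by
planting substitutions that are recorded position-by-position in a truth
manifest.  Substitutions avoid G/K/R positions, positions directly after
K/R, and never introduce P/K/R — so tryptic boundaries are identical across
species and the positional pairing assumption holds *by construction*.
This emulates what matters for the pipeline — variant peptides with shifted
masses inside a conserved digest frame — and deliberately not real collagen
biology: no indels, no hotspots, no biased substitution matrix, no
chain-specific composition.  Passing tests therefore demonstrate algorithmic
correctness on in-model data, not robustness to alignment error or
sequencing noise in real reference sequences.

`simulate_spectrum()` renders each non-dropped peptide as a Gaussian of
configurable FWHM (default 0.35 Da, reflector-mode scale) at its `[M+H]+`
for a hydroxylation state drawn binomially over its prolines (p = 0.2 per
proline), with log-normal intensities, an exponential chemical baseline,
additive detector noise, Poisson-rate spurious peaks, a global ppm
calibration shift and per-peak jitter.  `clean_noise_model()` is the exact
noise-free limit (only the hydroxylation mixture remains); dropout emulates
the degradation that drives real samples towards genus-level or
indeterminate calls.

Defaults fixed for the validation study: 4 species, 340 triplets per chain
(~1020-residue mature chains), substitution rate 0.008 per eligible X/Y
position, cleavage density 0.06 (mean fragment ≈ 25 residues), proline
fraction 0.30, seed 42.  Panel construction for simulations uses one missed
cleavage and a reporting cap of 3 hydroxylations; the collision background
uses the full residue-capped ladder as described above.

## Validation strategy and problem sizes

The test suite pins every computational claim to an independent oracle:
digestion against exhaustive substring enumeration (100 random 200-residue
chains at 0–2 missed cleavages); masses against independently computed
monoisotopic values and against a published panel at its printed precision
(±0.25 Da, printed values mix theoretical and calibrated-observed masses);
marker discovery against the generator's manifest (exact set equality of
markers and specific flags); matching against brute-force enumeration; NJ
against generating topologies of random additive matrices.  The end-to-end
study classifies 400 clean synthetic spectra (100 per species, seed 42),
requiring ≥ 95% correct species calls with all errors conservative, and a
dropout grid (0, 0.4, 0.8; common random numbers across levels) with
monotonically degrading accuracy.  These sizes were chosen as the smallest
that exercise every code path with stable statistics.

## Known limitations

* Homology pairing is positional; real indels would shift frames and are
  only handled by exclusion-with-warning, not alignment.
* Hydroxylation is counted, not localised; isomeric peptides with equal
  modification counts are indistinguishable, as in the instrument.
* Evidence levels (MALDI-visible vs LC-MS/MS-only) are input annotations on
  imported panels, not predicted.
* The printed masses of published panels are observed values; agreement
  beyond ~0.1–0.25 Da should not be expected, and one known anomalous row
  is carried as an annotation rather than reconciled.
* The NJ tree is a separability check; do not report it as a phylogeny.
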