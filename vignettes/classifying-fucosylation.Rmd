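---
title: "Classifying core and outer fucosylation of N-glycopeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying core and outer fucosylation of N-glycopeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fucotyper)
```

## The problem

A fucose on an N-glycan can sit in two structurally and biologically
distinct places: on the innermost (reducing-end) GlcNAc of the trimannosyl
core (alpha-1,6, "core" fucosylation, the FUT8 product) or on an antenna
GlcNAc/Gal (alpha-1,3/4 Lewis-type, "outer" fucosylation). Both isoforms
have the same mass, so an intact-mass glycopeptide identification cannot
distinguish them. Their CID MS/MS spectra can: a core fucose travels with
the peptide-bearing Y fragments, so fucosylated Y ions (Y1F..Y4F) appear
alongside their parents, while an outer fucose stays on the released glycan
and shows up in fucosylated oxonium B ions (B2F, B3F, B3SF). `fucotyper`
turns that pairing logic into an automated four-class decision — `none`,
`core`, `outer`, `dual` — for glycopeptide-spectrum matches (GSMs) that
have already been identified by upstream software.

## The feature model

For each GSM the package extracts the relative intensities of a fixed
14-ion panel, in a fixed order:

```{r}
fragment_specs()
```

Peak matching uses an absolute tolerance of ±0.02 Da and a signal-to-noise
gate of 3, with the noise level estimated as the median intensity of the
spectrum's nonzero peaks. Two details are deliberate design choices rather
than givens:

* **Normalisation.** "Relative intensity" is taken relative to the
  spectrum's base peak. This yields bounded, scale-free features in
  [0, 1]; an alternative (normalising over the 14 matched intensities
  only) couples the features to each other and was rejected for that
  reason. The choice is configurable at extraction time.
* **Noise estimate.** The median of nonzero peak intensities is robust and
  parameter-free. A fixed absolute noise threshold would be meaningless
  across instruments and across the synthetic generator's arbitrary
  intensity units. For a spectrum with *no* noise bed (the noiseless
  synthetic templates used in closure tests) an S/N gate is ill-posed —
  the "noise" would be the median of the true diagnostic peaks, and
  `intensity >= 3 * median` would discard most genuine ions by
  construction — so such spectra are extracted with `snr_min = 0`.

Isotope-envelope verification of the monoisotopic peak is not implemented;
a peak within tolerance that passes the S/N gate is accepted. With
high-resolution data and a ±0.02 Da window this is rarely wrong, but it is
a known limitation.

## The two model families

Both families map the 14 features to a probability simplex over the four
classes (fixed order `none`, `core`, `outer`, `dual`; argmax ties break to
the earlier class).

**Network family.** A fully connected net, 14 inputs → `n_layers` hidden
layers of `n_nodes` rectified linear units → 4-way softmax, trained by
full-batch gradient descent on the cross-entropy at a learning rate of
0.02, with Xavier-initialised weights and inverted dropout (keep
probability 0.75) on the hidden activations during training. The search
grid crosses nodes {8, 16, 32, 64, 128}, hidden layers {3, 4, 5} and
epochs {10, 100, 500, 1000, 2000, 5000, 10000, 20000}, with 10 seeded
replicates per architecture — 1,200 candidates. A softmax output (rather
than an independent per-class sigmoid) is required for a categorical
distribution and for the Pscore below. The dropout parameter 0.75 is
interpreted as the *keep* probability, the convention of the
TensorFlow-1-era tooling this family mirrors; training is full-batch
because no mini-batch size is part of the design. Everything is
deterministic given the spec's seed.

**Margin family.** A linear soft-margin SVM (C-classification, one-vs-one
with pairwise-coupled Platt probability calibration, via e1071). The cost
grid is the union of four successively narrower stages — powers of two
from 2^-5 to 2^15, then 2^0..2^6, then the integers 4..16, then 8.0..11.0
in 0.1 steps — 52 distinct values, crossed with 20 seeds (the seed drives
the calibration's internal cross-validation split): 1,040 candidates.

## Decoy scoring, FDR and model selection

Each prediction is summarised by the **Pscore**,

$$\mathrm{Pscore} = -\ln\bigl(1 - (P_1 - P_2)\bigr),$$

where $P_1$ and $P_2$ are the top two class probabilities. The gap is
clamped at $1 - 10^{-12}$, capping the score at $-\ln 10^{-12} \approx
27.6$; a flat top pair scores 0.

Decoy GSMs calibrate what an uninformative Pscore looks like. Two
constructions are provided:

* `make_spectrum_decoys()` (pipeline default) randomly rearranges the
  intensity values among the peaks of each spectrum and re-extracts the
  features. Diagnostic windows then mostly inherit noise-level
  intensities, so decoy vectors are sparse and incoherent while each
  spectrum's intensity multiset, noise estimate and base peak are
  conserved.
* `make_decoys()` permutes the 14 already-extracted feature values within
  each vector, conserving the value multiset per GSM exactly.

The two differ materially for discriminative models. A permuted *feature*
vector of a typical (densely populated) GSM carries strong intensities in
both the fucosylated-B and fucosylated-Y slots at once — precisely the
`dual` signature — and a margin model is *more* confident the farther a
point sits from its hyperplane, so such decoys can score higher than
targets and invert the target-decoy comparison. Spectrum-level
rearrangement does not manufacture coherent class evidence and is
therefore the default everywhere the score distributions feed FDR
estimation. The feature-level permutation remains available
(`decoy_method = "features"`) and is the construction whose conservation
property is unit-tested.

Decoy Pscores are averaged over 5 independent replicates per GSM. The
estimated FDR at threshold $t$ is
$\#\{decoy \ge t\} / \max(1, \#\{target \ge t\})$ (no $\pi_0$
correction), and the reported cutoff is the smallest observed target score
with FDR below the requested level (default 1%). Targets and decoys are
compared by the Mann–Whitney AUC of a ROC curve. Candidate models are
ranked by the **Euclidean length** $\sqrt{\mathrm{accuracy}^2 +
\mathrm{AUC}^2}$ of their test-set accuracy and target-decoy AUC, ties to
the first candidate.

The **consensus** layer accepts a GSM when it passes the Pscore filter in
at least one family (the union rule; a strict intersection is available)
*and* both families predict the same class. Decoys are always drawn from
the same GSM set being filtered, so each set (train/test/unknown) gets its
own cutoff. In evaluation, accuracy counts an unclassified GSM as a miss
over the whole set, while sensitivity is TP/(TP+FN) over classified GSMs
only.

## The synthetic generator

No public raw data accompany the method this package implements, so the
generator is a first-class module: it emulates the class-conditional
structure of curated CID spectra of standard glycoproteins well enough to
exercise every pipeline stage, with a hidden true label per GSM and an
independent rule-based oracle (`oracle_classify()`) encoding the B/Y
pairing logic directly.

Per GSM the generator places the template's present ions at their
theoretical m/z with truncated Gaussian jitter (sd 0.005 Da, capped at
half the matching tolerance), draws log-normal intensities (sd 0.4 on the
log scale) around ion-specific medians (Y ions dominant, oxonium ions
moderate), and adds 60 noise peaks at uniform m/z with intensities kept
below the S/N gate. Three structural features matter:

* **Per-ion dropout.** Detectability is ion-specific: the Y1 anchor is
  essentially always present (1%), minor species like B3/B3F are flaky
  (15%). Rates are mild overall because the emulated population is
  *curated* — spectra a human could classify by eye; heavily degraded
  spectra would not have survived manual classification into a training
  set.
* **Fucose intensity splitting.** When an ion and its fucosylated partner
  co-occur, they share the fragment population: a Beta-distributed
  fraction (mean 0.35) of the pair total moves to the fucosylated ion.
  Fucosylation therefore also *changes* the parent-ion intensities, as it
  does in real spectra.
* **Antenna-dependent yields.** Oxonium (B-ion) intensity scales with the
  number of LacNAc antennae and the small Y ions inversely, so
  tri/tetra-antennary spectra (outer-enriched, AGP-like) have a different
  overall shape from bi-antennary ones (core-enriched, IgG-like). Class
  membership is thus correlated with the whole profile, not only with the
  fucose slots — as it is in plasma data, where the classes come from
  different proteins.

Dataset-level defaults: class mix 39/25/21/16% (none/core/outer/dual),
echoing the manual class proportions of a curated standard-protein
training set; compositions drawn so that outer/dual GSMs are
tri/tetra-antennary with probability 0.8 and none/core mono/bi/hybrid;
fucose counts 0/1/1/2 by class. All generation is reproducible from one
seed.

What the generator does **not** model: isotope envelopes, multiply charged
fragments, chimeric spectra, retention time, and in-source fucose
migration (which can place weak fucosylated-ion signals in spectra of
non-fucosylated precursors). Passing tests on synthetic data therefore
demonstrate the pipeline's internal correctness and its behaviour under
controlled noise — not instrument-grade performance on plasma data.

## Worked example

```{r, eval = FALSE}
ds <- generate_dataset(n = 400, seed = 101, test_fraction = 0.35)
cfg <- pipeline_config(
  spectra = ds$spectra, gsm = ds$gsm,
  network = network_grid(nodes = 64, layers = 4, epochs = 2000,
                         replicates = 1, base_seed = 11),
  margin = margin_grid(costs = c(1, 8.7), seeds = 20),
  seed = 5
)
bundle <- run_train(cfg)

unknown <- generate_dataset(n = 200, seed = 202)
cls <- run_classify(
  pipeline_config(spectra = unknown$spectra, gsm = unknown$gsm, seed = 6),
  bundle
)
run_evaluate(cls, unknown$gsm)
```

The reduced grid above (one network architecture, two costs) is the
problem size used throughout the package's own end-to-end checks: it keeps
a full train–select–classify–filter cycle at a few hundred GSMs within a
couple of minutes on one CPU while exercising every stage. The full
1,200 + 1,040 candidate grids are the defaults of `pipeline_config()` and
enumerate (and train) completely if requested.

## Known limitations

* The 2,000-epoch budget in the example undertrains the dropout-regularised
  network family; architectures in the full grid with 10,000+ epochs
  converge further. Accuracy figures from reduced grids are conservative.
* Margin-family probabilities are Platt-calibrated and plateau well below
  saturation, so margin Pscores have a practical ceiling around 2–5;
  cutoffs for this family are correspondingly small.
* Target-decoy AUC on synthetic data is sensitive to how a model
  extrapolates to near-empty feature vectors, which is untrained
  behaviour; across seeds it typically ranges 0.6–0.95 rather than the
  near-1 values attainable with strongly stereotyped curated real data.
* Sensitivity of the consensus output is high (incorrect consensus calls
  are rare) but its coverage depends directly on the Pscore cutoffs; with
  weak target-decoy separation the union filter can exclude a substantial
  fraction of GSMs.
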