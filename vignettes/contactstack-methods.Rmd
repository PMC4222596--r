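---
title: "Stacked receptive-field refinement of contact maps: models and methods"
author: "contactstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked receptive-field refinement of contact maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Coevolution-based contact predictors (sparse inverse covariance, direct
coupling analysis, mutual information) score each residue pair of a protein
independently. True contacts are anything but independent: a hydrogen-bonded
strand pair puts a contact at $(i{+}1, j{-}1)$ next to one at $(i, j)$,
helices contact their partners in periodic patches, and isolated single-cell
"contacts" are almost always artefacts. `contactstack` exploits this by
training a feed-forward cascade of classifiers. Layer 0 scores every
residue pair from its *ordinary features* alone:

* the scores of the $k$ base prediction maps at $(i, j)$,
* the sequence separation $j - i$,
* the profile (PSSM) rows of $i$ and $j$ (21 log-ratio values each),
* predicted secondary-structure probabilities in a 9-residue window
  around $i$ and around $j$ (3 classes per residue),
* predicted relative surface accessibility rows (5 values per residue)
  in the same windows.

Every later layer $t$ re-scores the pair from the ordinary features
concatenated with the *receptive field*: the $(2h{+}1) \times (2h{+}1)$
square of layer-$(t{-}1)$ contact probabilities centred on $(i, j)$. A pair
whose neighbourhood supports it (a ladder, a stripe) is promoted; an
isolated spike loses its support and sinks. The final layer's map is the
refined prediction.

Each layer's learner is a random forest — 100 bagged trees with at least
500 samples in any leaf. The deliberately coarse leaves regularise a
heavily unbalanced problem: contact density falls roughly as $1/L$, so
positive pairs are a few percent of the training vectors.

## Contact definition and evaluation

A contact is a residue pair whose C$\beta$–C$\beta$ distance (C$\alpha$
for glycine) is at most 8 Å, the CASP convention; the boundary value
counts as a contact. Residues unresolved in a structure are masked, not
imputed, and masked pairs never enter numerators or denominators.

Precision is reported as top-$\alpha L$ PPV: rank all pairs with
separation $\ge 5$ by score, keep the top $\lceil \alpha L \rceil$, and
report the fraction that are true contacts. Score ties are broken by
larger separation, then smaller $i$, then smaller $j$ — an arbitrary but
frozen rule, because exact reproducibility matters more than any
particular tie order. Breakdowns follow the common conventions: separation
ranges short (6–12), medium (13–24), long (25+) with boundary separations
12 and 24 assigned to the lower range, ranked within each range at
$\lceil L/10 \rceil$ predictions; secondary-structure categories assign
each global top-$L$ pair to the unordered class pair of its residues.

## Alignment statistics

`effective_sequences()` single-linkage clusters alignment rows on the
pairwise-identity graph and reports the number of clusters (equivalently,
the sum of per-row weights $1/|\mathrm{cluster}|$). The identity threshold
is an explicit parameter, default 0.62 fractional identity, with a
`threshold_fun` hook for schemes that derive the threshold from the mean
pairwise identity of the alignment; we deliberately do not hard-code any
particular derived formula. Identity between two rows compares all columns
not gapped in both rows; a column gapped in exactly one row counts as a
mismatch.

Profiles use a background-proportional pseudo-frequency,
$f = (f_{\mathrm{obs}} + c \cdot b)/(1 + c)$ with $c = 1$ by default. Two
properties drove this choice over a plain additive (uniform Laplace)
count: the profile is exactly zero wherever the observed frequencies equal
the background, and it is invariant under duplicating or permuting rows.
The default background is a Swiss-Prot-like amino-acid composition plus a
small constant gap frequency, renormalised.

Mutual information uses the 21-state alphabet with an additive pseudocount
of $1/441$ per joint cell (one pseudo-observation in total), configurable
down to the plug-in estimator at 0. The average product correction
subtracts $\bar r_i \bar r_j / \bar r$ with the diagonal excluded from all
means. Gap-heavy rows (more than 20% gaps) are removed before MI, with the
query always retained.

## Training protocol

Training pools the eligible pairs ($i < j$, separation $\ge 5$, truth
unmasked) of all training families; only the unordered orientation is
encoded and predictions are mirrored, which halves the work on a
symmetric problem. Pairs below the separation floor are excluded from
training and returned as probability 0 — trivially local contacts would
otherwise dominate the positive class.

Receptive fields seen during training come, by default, from out-of-fold
maps: families are split into 3 folds, and each family's layer-$t$ map is
predicted by a model trained on the other folds, so no layer consumes
fields produced by a model that saw those same pairs. This is the standard
stacked-generalisation guard; three folds (models trained on two-thirds of
the families) proved a good accuracy/cost point on one CPU, and the fold
count is configurable. An `"infold"` mode that reuses the full model's own
training predictions is available for comparison; it is cheaper and lets a
controlled amount of optimism into the fields. Per-layer top-L PPV is
logged both in-sample and out-of-fold, and training warns when the
out-of-fold value drops between layers — with too many layers the cascade
starts reproducing secondary-structure texture instead of refining
contacts, so the depth (default 5) should not be raised casually. No
automatic early stop is performed.

### The learner backend

The default backend (`"rf_hist"`) is a random forest with histogram-based
split finding, run through xgboost in random-forest mode: one round of 100
parallel trees, per-tree row subsampling of 0.632 without replacement,
$\sqrt{p}$ features sampled per node, squared-error leaves with at least
500 samples each. With squared error on 0/1 labels and no shrinkage or
regularisation, every leaf stores exactly the contact fraction of its
samples, so the ensemble output is a bagged class frequency in $[0, 1]$ —
the same estimand as a classification forest's probability vote.
Candidate splits come from 32 feature quantiles; with leaves forced to
hold hundreds of samples the trees are shallow and insensitive to split
resolution beyond that, while training is an order of magnitude faster
than exact-split search, which is what makes five-layer stacks with
out-of-fold fields practical on a single CPU. An exact-split backend
(`"rf_exact"`, via ranger) is provided and is interchangeable through the
same learner contract; any model that fits labelled vectors and returns a
contact probability can be plugged in.

All randomness — fold assignment, per-layer and per-fold learner seeds,
and every generator draw — derives deterministically from configuration
seeds, so training and prediction are bit-reproducible. Stack archives
store every layer model plus the predictions on a small deterministic
probe family; `load_stack()` re-predicts the probe and refuses archives
it cannot reproduce exactly.

## The synthetic family generator

The generator exists so the whole pipeline — features, training,
receptive fields, evaluation — runs end to end with no external data,
under conditions that mimic what matters statistically about real
families:

* **Topology.** Helix/strand/coil segments alternate with coil linkers;
  element types are drawn to approximate a requested composition
  (default H/E/C ≈ 0.35/0.30/0.35 with per-family jitter). Strands group
  into sheets of 2–4; paired strands contribute contiguous ladders
  (anti-parallel along anti-diagonals, parallel along diagonals) widened
  to a band, as C$\beta$ contacts in real sheets are. Helix pairs
  contribute *intermittent* anti-diagonal patches recurring with the
  helical period — ridge-into-groove interfaces touch every few residues,
  not continuously — and are markedly sparser than sheet ladders. Helices
  also carry local $i, i{+}3/4$ contacts, some helices pack against
  strands, and a few short tertiary arcs are sprinkled in. At $L = 80$
  this yields on the order of 40–90 contacts at separation $\ge 5$,
  comparable to real 8 Å maps.
* **Base maps.** Each of $k$ maps scores a pair as
  $\mathrm{signal} \cdot \mathrm{truth} + \mathcal{N}(0, 1)$, rectified at
  zero — chosen because the zero-signal chance level is then analytic
  (PPV equals the eligible contact density). False positives come in two
  kinds, controlled separately so the isolated-spike filtering behaviour
  is directly testable: clustered 3-cell ladders (plausible-looking
  artefacts) and isolated single cells. A configurable fraction
  (default 0.6) of false-positive sites is shared across the $k$ maps,
  mimicking systematic artefacts that hit all coevolution methods alike
  and therefore survive naive averaging — that shared part is exactly
  what a flat combiner cannot remove but a receptive field can.
* **Surrogate per-residue features.** SS/RSA/profile tables are derived
  from the true secondary-structure string with a fidelity that grows
  with the family's signal strength and collapses to pure noise at signal
  zero. Their only job is to carry recoverable signal with the right
  dependence structure; they make no claim to biological realism, and
  nothing downstream depends on more than that.
* **Meff surrogate.** A lognormal draw whose scale grows with signal,
  standing in for the effective alignment depth that governs coevolution
  quality in real data.

What passing tests on this generator do show: the cascade exploits spatial
clustering, removes isolated artefacts, gains most where contacts form
dense regular patterns (sheets), and degrades gracefully to chance on
uninformative input. What they cannot show: performance on real coupling
matrices, whose artefact structure (phylogenetic bias, entropic effects)
is richer than this noise model.

## Numerical choices and degenerate inputs

* Receptive fields and feature windows are zero-padded outside the chain;
  zero reads as "no predicted contact", and mirroring would invent
  structure at the termini.
* The feature order is frozen and documented so serialised models stay
  valid; encoding is deterministic to the bit.
* Separation enters raw; a `separation_transform` hook allows binned or
  squashed variants.
* A cutoff of exactly the contact distance counts as contact; a dense
  external map asymmetric beyond $10^{-6}$ relative is rejected rather
  than silently symmetrised.
* Degenerate cases error loudly: no eligible pairs, empty positive class,
  unknown secondary-structure symbols, out-of-range triplet indices.
  Single-row alignments give a zero MI map with a warning; an all-zero
  map passes through APC unchanged with a warning.

## Problem sizes

The package's reference benchmark — used by the test suite and the
acceptance script — trains on 40 synthetic families and evaluates on 20
held-out families of length 70–90 at the generator's default signal
spread, with $k = 4$ base maps. These sizes give stable layer-wise
statistics while keeping a full five-layer out-of-fold training run in the
minutes range on one CPU. The field-width comparison (11×11 vs 3×3 vs
1×1) is made at matched depth using three-layer cascades; because training
is sequential and seeded, a deeper stack's early layers coincide exactly
with a shallower stack's, so the shared five-layer run is reused. The
analytic limit checks (noiseless ⇒ perfect precision; zero signal ⇒
chance) use base-map-only feature configurations, since profile and
structure surrogates would otherwise contribute legitimate signal of
their own; the noiseless check evaluates at $\alpha = 0.3$, safely below
the contact density of the strand-rich families it generates.

## Known limitations

* The synthetic noise model is Gaussian-rectified with planted false
  positives; real coupling matrices deviate in both tail shape and
  artefact geometry.
* Secondary-structure and accessibility inputs are consumed as given
  (files or surrogates); the package does not run predictors.
* Only intra-chain contacts are modelled; inter-chain interfaces and
  biological assemblies are out of scope.
* The identity threshold for effective-sequence counting is a parameter,
  not a derived quantity; alignment-adaptive schemes must be supplied via
  the hook.
* mmCIF structures are not parsed; convert to PDB first.
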