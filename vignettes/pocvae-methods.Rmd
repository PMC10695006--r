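---
title: "Generative design of shape-persistent organic cages: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative design of shape-persistent organic cages: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `pocvae`, the choices
made where the design was genuinely open, and what the synthetic-data
experiments do and do not demonstrate.

## The disassembled cage representation

A Tri⁴Di⁶ porous organic cage assembles four tri-topic vertex precursors
(BB1) with six di-topic edge precursors (BB2) under one dynamic covalent
reaction. Because the full cage SMILES is long and highly redundant, the
package never models it: a cage is the triple (BB1 ordinal, BB2 skeleton
SMILES, reaction ordinal). Only BB2 is modelled as a sequence — edge
precursors are short and nearly linear, so a sequence model generates
them with high validity, while BB1 and reaction stay categorical and can
never leave their catalogs. The two reactive end groups of a BB2 are
replaced by the placeholder token `[Lr]` (a heavy-element symbol no real
edge precursor uses), which makes site counting and graph-symmetry
checking purely structural operations.

Tokenisation is character-level. Multi-character tokens (`Br`, `Cl`,
`[nH]`, `@@`, `%nn` ring closures, and `[Lr]` itself) are remapped to
single-character surrogates through a fixed, versioned table before
indexing; the vocabulary is the four specials `[pad]`, `[sos]`, `[eos]`,
`[Lr]` followed by the sorted corpus characters, and sequences are padded
to the longest corpus tokenisation plus two. The surrogate table is a
reconstruction — its exact inventory is an implementation constant of
this package, fixed so that encodings are stable across versions.

## Model

* **Sequence encoder** — bidirectional GRU over the embedded token
  sequence (hidden 256 per direction at reference scale). The padded tail
  is processed like any other input; the `[pad]` embedding is learned.
* **Categorical encoder** — one-hot BB1 and reaction through a one-hidden-
  layer MLP.
* **Fusion** — how the components are jointly encoded is an open design
  point; the package concatenates the two final directional hidden states with
  the categorical summary and applies two affine maps to obtain the
  posterior mean and log-variance (128-d latent at reference scale).
  Log-variances are clamped to [-12, 12] for numerical safety; the clamp
  is inactive in ordinary training.
* **Sequence decoder** — single-direction GRU (hidden 384). The latent z
  initialises the hidden state through a tanh affine map *and* is
  concatenated to every input embedding, the common conditioning for
  recurrent VAE decoders; teacher forcing during training, greedy or
  multinomial decoding at inference.
* **Categorical decoder** — MLP head with independent softmax outputs
  for BB1 and reaction; arg-max at inference.
* **Predictor** — MLP from z to P(collapse|z) (label 1 = collapse).
  During training the predictor sees the *sampled* z (the same draw the
  decoders consume); at evaluation it sees the posterior mean. Whether to
  use samples or means during joint training was open; sampling keeps a
  single reparameterised pathway per batch.

The loss is the weighted sum of the per-token BB2 cross-entropy (summed
over unpadded positions, averaged over the batch), the BB1 and reaction
cross-entropies, β times the closed-form diagonal-Gaussian KL to the
standard-normal prior, and γ times the binary cross-entropy of the
predictor computed over labeled records only — an all-unlabeled batch
contributes exactly zero predictor loss, which is what makes the ~1.2
million unlabeled augmented cages usable. The relative weights inside the
reconstruction sum are not dictated by anything in the training protocol;
both default to 1.

## Training protocol

Reference settings: 100 epochs, batch 64, Adam with learning rate 1e-4,
β annealed cyclically over five cycles from 0 to 0.0025 (the package
ramps linearly over the first half of each cycle, then holds the
plateau — `ramp_fraction = 0.5`, the convention of the cyclic-annealing
scheme this follows), and a linear 0→1 warm-up applied to both the
categorical reconstruction component and the predictor term so early
training concentrates on sequence reconstruction. Both schedulers are
indexed by epoch and constant within one. The split is greedy: floor(90.0%
of the original records) and floor(99.8% of the augmented records) train
the model; the complements are the two held-out sets (on 35 802 originals
this is exactly 32 221 / 3581). Unlabeled augmented records are mixed
into batches uniformly at random. Training aborts with a diagnostic on a
non-finite loss.

All layers, backpropagation through time and Adam are base-R matrix code.
The analytic gradients are checked against central finite differences in
the test suite (every parameter tensor, random entries, absolute
tolerance 1e-6 + 1e-4·|g|).

## Generation and the filter cascade

*Random sampling* draws z ~ N(0, I). *Interpolation* uses spherical
linear interpolation between posterior means (means, not samples — the
deterministic choice makes paths reproducible), decodes every path point
and keeps those whose predicted persistence probability (1 − P(collapse))
reaches the threshold, 0.8 by default; the start point must itself pass
the threshold, which is only enforceable for thresholds ≤ 1.
*Bayesian optimisation* minimises

    a(z) = −log p(y = 0 | z) + ω ||z||² / 2

inside the per-dimension min/max box of the training latents. The
regulariser is the negative log standard-normal density with its constant
dropped; the predictor probability is clamped to [1e-6, 1 − 1e-6] so the
acquisition is finite everywhere; ω defaults to 0.1 (the balance between
exploitation and staying on the learnt manifold — no canonical value
exists, and results are reported with the value used). The surrogate is
the package's own choice: a squared-exponential GP with median-heuristic
lengthscale and expected-improvement proposals (Latin-hypercube initial
design, EI maximised over a random cloud plus bounded L-BFGS-B), with a
final bounded local polish of the incumbent on the true acquisition —
the acquisition is cheap to evaluate, so the polish costs little and
makes the optimiser's output insensitive to GP misfit.

Every decoded candidate passes the filter in a fixed order — validity,
novelty, precursor validity, reaction-site count, symmetry — and the
first failing stage is recorded; a failure triggers resampling until the
quota or the attempt budget is reached. Validity combines a syntactic
screen (token inventory, balanced branches, paired ring closures) with an
OpenBabel parse, because OpenBabel alone silently repairs some malformed
strings. Novelty inside the filter uses the combined original+augmented
key set; the metric report computes both variants. Uniqueness counts
canonically identical cages once (keys are BB1 ordinal + canonical BB2
SMILES + reaction ordinal).

**Symmetry.** C₂ molecular symmetry of an edge precursor is approximated
by graph symmetry: both `[Lr]` atoms must lie in the same automorphism
orbit of the canonical form's heavy-atom molecular graph, with element
vertex colours and bond-order edge colours. Bonds between aromatic atoms
on a cycle get their own colour so that an arbitrary Kekulé assignment
cannot break a symmetry it should not. Edge colours are encoded for the
BLISS solver by subdividing each bond with a coloured auxiliary vertex.
The test suite checks the predicate against an independent brute-force
enumeration of colour-preserving permutations on 200 generated
precursors.

## Synthetic data: what it emulates and what it does not

The generator emulates the *shape* of the cage dataset: small BB1 and
reaction catalogs, a pool of grammar-assembled BB2 skeletons (arene,
heteroarene and chain cores with mirror-paired linker arms) that are
always parseable with exactly two sites, a controllable symmetric
fraction (symmetric products place the same arm on mirror-equivalent
attachment points, so the symmetry predicate holds by construction), and
a deterministic label rule: a cage is collapsed iff its BB2 has fewer
than a threshold number of heavy atoms or no ring, unless the reaction is
the designated rigid type (echoing the empirical robustness of alkyne
metathesis). Default conditions: 4 BB1 skeletons, 3 reactions, 60 BB2
skeletons, 500 cages, 30% unlabeled, 80% symmetric — a predominantly
symmetric pool like the real Tri⁴Di⁶ precursors, with an asymmetric
minority so the symmetry filter is exercised.

Because the label rule is a deterministic function of the disassembled
representation, a successful joint training can in principle reach
accuracy 1.0, which makes predictor-recovery tests meaningful. What the
fixtures do *not* emulate: MD-derived labels with their noise and
reaction-dependent error structure, the scale (~1.2 M cages) and token
diversity (vocabulary of 30) of the real corpus, or realistic BB1
chemistry. Passing the desk-scale suites shows the machinery is correct
and can recover a learnable structure; it does not certify the headline
rates achievable only at full scale.

## Desk-scale configuration

The scaled-down experiments in the tests and the acceptance script use
500 cages, latent 16, encoder/decoder hidden 64/96, embedding 32, 30
epochs, batch 32 and Adam lr 4e-3. The learning rate and batch size
differ from the reference protocol deliberately: 30 epochs over 450
training records is ~420 gradient steps, versus millions at full scale,
so the optimiser must move faster per step; 4e-3 with batch 32 was chosen
from loss-curve behaviour on fixtures. Dropout stays at the reference
0.25/0.5.

## Known limitations

* OpenBabel canonicalisation defines molecular identity; a different
  backend would partition a few edge cases differently.
* The GRU stack is plain R; at reference scale (1.2 M records, 100
  epochs) it is impractical — the package's full-scale settings are
  documented defaults, not a demonstrated run.
* The filter's symmetry stage rejects asymmetric precursors outright;
  cages from asymmetric precursors exist but are out of scope.
* 3-D assembly, MD validation of generated cages and SELFIES encodings
  are out of scope.
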