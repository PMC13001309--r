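---
title: "Benchmarking natural-language odor descriptions: models and methods"
author: "odieu package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking natural-language odor descriptions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odieu)
```

## The problem

Free-form sentences written by human observers about the smell of a molecule
("sweet, fruity, with a green apple nuance") carry more perceptual information
than binary semantic labels, but two trained observers never write the same
sentence about the same molecule. Any structure-to-text (S2T) or
neural-to-text (N2T) predictor therefore has a natural performance ceiling:
the inter-observer consensus. The benchmark implemented here formalizes that
idea. If `S_hh` is the average similarity between two humans' descriptions of
the same molecule, and `S_mh` the average similarity between a machine's
description and a human's, a predictor passes the "olfactory Turing test"
when `S_mh` approaches `S_hh`. Everything in this package — the catalogue
model, the lexical metrics, the embedding benchmark, the odor-space
comparisons, the prefix-tuned generator, and the Procrustes neural decoder —
exists to compute, compare or close that gap.

The package is built around a catalogue of multi-source descriptions: each
molecule may be described by up to three independent human sources, and the
cross-source same-molecule pairs are the currency of the benchmark. A
reference catalogue profile with 1,762 molecules described by exactly two
sources and 854 by all three yields `1762 + 3*854 = 4324` pairwise
comparisons; `crossSourcePairs()` reproduces this count exactly and
`overlapSummary()` the underlying multiplicities.

## The synthetic study system

Licensed description catalogues cannot be redistributed, so the package ships
a seeded generator (`generateCatalog()`) whose outputs exercise every method
on data with *known* latent structure:

* each molecule belongs to one of `n_families` perceptual families (fruity,
  sulfurous, floral, ...), with disjoint built-in vocabularies;
* each present source writes one templated sentence ("This molecule has a
  `<token>`, `<token>` odor with `<token>` notes."); each token comes from the
  molecule's true family with probability `alpha` (the inter-observer
  agreement), otherwise from a uniformly random family;
* a per-molecule Gaussian latent (family centre + jitter) is mapped through
  seeded full-rank linear maps, plus Gaussian noise of s.d. `noise_sigma`,
  into molecular descriptors (`generateDescriptors()`) and 30-dimensional
  neural response vectors (`generateNeuralResponses()`), emulating geometry
  embeddings / fingerprint panels and glomerular population responses.

Defaults are `n_sources = 3` (the catalogue the benchmark targets has three
human sources), `neural_dim = 30` (the dimensionality of the neural
response embedding the N2T module consumes), `alpha = 0.8` (high but
imperfect agreement — same-family tokens dominate yet two sources rarely
coincide exactly, which is what real inter-observer data look like),
`latent_dim = 8`, `descriptor_dim = 32` and `noise_sigma = 0.1` (clearly
structured but not noiseless). The generator's `SyntheticTruth` (latents,
family ids, linear maps) is kept only for recovery tests; no method under
test reads it.

What the generator does *not* emulate: chemically realistic descriptor
distributions, correlated noise across sources, vocabulary that varies in
register or length, or polysemous odor terms. Passing tests therefore show
that the algorithms recover known structure under controlled conditions, not
that any particular score would be attained on real catalogues.

## Lexical metrics

`bleu()`, `rougeL()`, `meteor()` and `bertScore()` follow the original metric
definitions, on a 0-100 scale, over one shared tokenizer (Unicode NFC,
lowercase, split on non-alphanumerics). Where a definition leaves latitude,
the choice is documented and fixed:

* **BLEU** — modified n-gram precision with brevity penalty, geometric mean
  over orders 1..4 (or 1). Unsmoothed by default: any zero higher-order
  precision gives 0, as in the original formulation; an `add1` smoothing flag
  exists for corpora of very short sentences.
* **ROUGE-L** — LCS-based F-measure with the harmonic mean (beta = 1).
* **METEOR** — two matching stages (exact, then a lightweight suffix
  stemmer), greedy left-to-right alignment, `F = 10PR/(R + 9P)`, fragmentation
  penalty `0.5 (chunks/m)^3`. The greedy alignment is deterministic and
  hand-checkable; it does not guarantee the minimal chunk count of the
  original implementation, a deliberate simplification.
* **BERTScore** — greedy cosine matching F1 with a pluggable token embedder;
  baseline rescaling is off.

`consensusGap()` aggregates any of these into the `S_hh` vs `S_mh` statistic;
human-human pairs are scored in both directions and averaged, since a pair of
observers has no privileged "candidate" side.

## The model-based benchmark

Sentence embedders implement a small contract: unit-normalized rows, pure
function of (state, text). Two backends ship with the package: the
deterministic hashed bag-of-content-words `toyEmbedder()` (stopwords removed,
tokens hashed into buckets, counts L2-normalized) and the trainable
`linearTextEmbedder()` (a projection matrix over the same hashed features).
The benchmark itself (`benchmarkReport()`) computes:

* the paired cosine-similarity (CS) sample over cross-source same-molecule
  pairs, against a **derangement null** — the pairing is shuffled with no
  fixed points and no accidental same-molecule matches, seeded;
* the 1-Wasserstein distance (`emd1d()`) between the paired and null CS
  samples — for equal sizes the mean absolute difference of sorted samples
  (the monotone coupling is optimal in 1-D), otherwise the exact CDF-integral
  form;
* top-k retrieval accuracy (`topkRetrieval()`): queries are one kind's
  embeddings, the gallery is the cross-source description embeddings, the
  query record itself is excluded, ties break by stable gallery order;
* a Welch t-test of the machine-human CS sample against the human-human one
  (`compareToConsensus()`); Welch rather than pooled because the two samples
  have no reason to share a variance.

`averageEmbeddings()` implements the dataset-averaged description embedding
and its leave-source-out variant. The full average contains the source it is
later compared with and is therefore optimistically biased; the
leave-source-out average removes that self-inclusion. Averaged vectors are
renormalized to unit length before any CS.

## Contrastive fine-tuning

`finetuneEmbedder()` trains the projection with molecule-level k-fold
cross-validation (default 5): folds partition *molecules*, not descriptions,
so no text of a held-out molecule can leak into training, and every reported
similarity uses the fold model that never saw the molecule
(`heldOutEmbed()`). Positives are all cross-source same-molecule pairs;
negatives are uniformly sampled different-molecule pairs at a 1:1 ratio,
seeded.

The default loss is AnglE-style: a logistic contrast on the cosine
similarity around a margin (default 0.5, temperature 0.05) plus a logistic
contrast on the complex-phase angle distance. For the angle term the
embedding's first and second halves are read as real and imaginary parts;
the per-coordinate phase difference is summarized as
`a = mean((1 - cos(phase_u - phase_v)) / 2)`, which is 0 for identical
phases and 0.5 at chance, and positives are pushed below a margin of 0.4.
The angle term targets the saturation of the cosine at the top of its range,
which is its purpose in the cited objective; the plain cosine term alone is
available as `loss = "cosine"`. All gradients are analytic (verified against
finite differences in the test suite) and optimized with full-batch Adam.

An earlier listwise ranking formulation of the same objective (softmax over
all positive-negative pairs) minimized training loss but generalized
erratically on held-out folds; the per-pair logistic form was adopted for
that reason and is the package's design choice.

## Odor-space geometry

`reduceMDS()` performs metric MDS: classical scaling initialization followed
by SMACOF majorization steps (each step provably does not increase stress),
reporting Kruskal stress-1. High-dimensional embedding spaces are reduced
this way (e.g. to 50 dimensions) before comparison, mirroring how
sentence-embedding spaces of hundreds of dimensions are brought to a common
footing with latent spaces of structure-based models.

`ccaSharedDims()` computes canonical correlations between two spaces on their
overlapping molecules and reports the sum of squared correlations — an
effective count of shared dimensions, weighted by alignment strength. A
space compared with itself gives exactly its dimensionality. Numerical
choices: inputs are centered; rank-deficient or n < d inputs are first
projected onto their top min(d, n-1) principal components; a relative ridge
(1e-8) is added to a covariance block *only* when it is ill-conditioned
(smallest eigenvalue below 1e-9 of the largest), so that well-posed
comparisons remain exactly invariant under invertible linear transforms of
either space — an identity the test suite checks.

`linearMapPredict()` fits the pseudoinverse linear map from a base space to a
target space on a seeded 80% molecule split, centering both spaces with
**training-set means only** (the test suite verifies that shifting held-out
molecules cannot change the fit), and reports the mean per-coordinate Pearson
correlation on the held-out 20%. The unweighted mean over coordinates is the
aggregation choice; the map is directional, and both directions are obtained
by swapping arguments. Under an exact linear link the held-out R exceeds
0.999; with equal per-coordinate signal and noise s.d. it concentrates at
1/sqrt(2), the closed-form attenuation, both verified in the tests.

## Structure-to-text by prefix tuning

The S2T generator conditions a **frozen** causal language model on molecular
structure: a trainable 4-layer tanh multilayer perceptron (`prefixEncoder()`)
maps a descriptor vector (z-scored with training statistics) to `k = 10`
prefix slots of the model's token-embedding width, and only the encoder's
parameters receive gradients (`trainEncoder()`). The teacher-forced
next-token negative log-likelihood is computed over the target text (plus
end-of-sequence) only; prefix positions condition every step but contribute
no loss. The freeze contract is enforced mechanically: the language model's
weight fingerprint (an FNV-1a hash of a canonical text rendering of its
tensors) must be identical before and after training, or training aborts.

Tests and the command-line workflow run against `tinyCausalLM()`, a
word-level causal model of a few thousand parameters designed so that the
whole training loop runs in seconds on one CPU: its context state mixes the
prefix mean (fixed weight 0.5, so conditioning persists across the entire
generation) with a recency-decayed mean (decay 0.6) of the preceding token
embeddings, followed by a tanh layer and a projection to vocabulary logits.
Large pretrained backbones satisfy the same contract (differentiable
token-level loss given prefix embeddings) and can be substituted behind it;
they are deliberately not a test dependency.

Decoding (`generateDescription()`) is greedy by default and deterministic.
Two standard mitigations for the degeneracies of very small frozen models are
applied: a no-repeat constraint (a fixed point of the context recursion would
otherwise repeat one token forever) and a minimum length before
end-of-sequence is admissible (default 4 tokens). Sampling decoding is
seeded. On the two-cluster synthetic corpus (descriptor clusters tied to
disjoint vocabularies), held-out generations prefer their own cluster's
ground-truth texts by toy-embedder cosine similarity — the package's
qualitative analogue of "the generator encodes perceptual content from
structure alone".

## Neural-to-text

`fitProcrustes()` aligns neural response vectors (Q-vectors) with sentence
embeddings by a similarity transform — translation, isotropic scale and an
orthogonal matrix (reflections admitted), solved in closed form by SVD of the
centered cross-covariance. `loocvProcrustes()` evaluates it by leave-one-out
cross-validation: the map is fitted on n-1 odorants and applied to the
left-out one, and the per-odorant CS between predicted and true embeddings is
compared with a seeded derangement null run through the identical protocol.
When the embedding dimension exceeds the neural one, both sides are reduced
to the common rank min(d_q, d_E, n_train - 1) by PCA fitted on the training
odorants only, and predictions return to the original embedding space through
the transposed loadings. Zero-padding the neural side is the rejected
alternative: it would make the orthogonality constraint act on directions
that carry no data.

Decoding goes through an invertible embedder contract: `invertibleEmbedder()`
ships a toy backend whose embedding is the token-count vector over a fixed
vocabulary and whose inverse rounds counts back to a token multiset, so
`invDecode(inv, invEmbed(inv, t))` reproduces the tokens of any in-vocabulary
text exactly. Real invertible sentence embedders implement the same two
functions.

## Augmentation

`completeDescription()` turns raw human descriptions (HD) into completed
sentences (CHD), label sets (HL) into completed label sentences (CHL), and
machine-predicted labels into CDL records, through a pluggable completion
backend. The deterministic template backend used in tests fills the
catalogue's sentence template with the input's content words and never drops
one (a validator warns if a backend does). `fewshotSmilesPrompt()` assembles
zero- or few-shot prompts from SMILES-description example pools with a
leakage guard: the query molecule must not appear among the examples.
Augmented records are appended next to their originals, never in place of
them. The shipped prompt texts are plain-text reconstructions, exposed as
configuration.

## Problem sizes and numerical conventions

The test suite and the acceptance script run on one CPU in a few minutes
total. Chosen sizes: benchmark corpora of 200 molecules x 3 sources;
fine-tuning with 5 folds x 20 epochs on ~1,200 labeled pairs; CCA/MDS on
40-250 molecules; LOOCV at the 59-odorant overlap the N2T analysis targets;
prefix tuning on 24 training molecules x 150 epochs with a ~20-token
vocabulary. Degenerate inputs error early and explicitly: zero-norm vectors
in cosine similarity, constant samples in the Welch test, zero-variance
Procrustes inputs, dimension mismatches everywhere. All stochastic steps
(negative sampling, fold assignment, derangements, splits, training order,
sampling decoders) take explicit seeds, and every CLI run writes a manifest
from which a deterministic stage can be reproduced bit for bit.

## Known limitations

* The toy embedders are bags of content words: they ignore word order, so
  the package's own demonstrations cannot show syntax effects — only a
  trainable sentence embedder with real texts can (the benchmark machinery
  is agnostic to which embedder is plugged in).
* METEOR uses a lightweight stemmer and greedy alignment, not the reference
  implementation's resources.
* The tiny causal LM is a contract fixture; its generations demonstrate
  conditioning, not fluent language.
* `canonicalSmilesMerge()` is intentionally off by default: molecule identity
  is the caller's key, and merging by canonical SMILES can silently conflate
  stereoisomers.
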