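---
title: "Adversarially trained SMILES triage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarially trained SMILES triage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep generative models propose molecules by the million, but standard
drug-likeness filters (rule of five, QED, synthetic accessibility) do a poor
job of separating compounds that resemble known drugs and bioactives from
the kind of material a generative model or a purchasable-compound catalog
produces. This package trains a *discriminative triage score* for that
separation, as the byproduct of a sequence GAN over SMILES strings: a
generator learns to imitate a "catalog-like" corpus and is then pushed,
adversarially and by direct fine-tuning on drug-like molecules, to produce
ever more confusable negatives; the discriminator that survives this
curriculum outputs, for any molecule, the probability that it belongs to the
positive (drug/bioactive-like) set. That probability — `scoreMolecules()` —
is the product the package exists for.

## Data model and preprocessing

Molecules enter and leave the package as SMILES strings; internally a
molecule is a `TokenSequence` of integer ids under a closed
`TokenVocabulary`. Every corpus passes a six-step cleaning pipeline
(`preprocessSmiles()`) before tokenization:

1. only H, C, N, O, F, P, S, Cl, Br, I;
2. no isotope labels;
3. no duplicates (first occurrence kept, detected on the canonical form);
4. structural sanity: no aliphatic carbon run longer than 4, at most 10
   hydroxyl groups, average molecular weight at most 750 Da, at least 10
   atoms;
5. canonical SMILES with stereo descriptors (OpenBabel canonical form);
6. optionally, removal of molecules whose token stream leaves the
   vocabulary.

Where the rules leave room, the package commits to one reading and exposes
it as a parameter: "atom number" counts heavy atoms (hydrogens are implicit
in SMILES; `countHydrogens` flips this), the aliphatic-chain rule is an
overridable recursive SMARTS (a path of five acyclic sp³ carbons whose
heavy neighbours are all carbon — a run *longer than four* exists exactly
when this pattern matches), hydroxyls are `[OX2H1]`, thresholds are strict
inequalities as stated, and unparseable records get their own rejection
reason rather than an error. Chemistry (parsing, canonicalization,
descriptors, SMARTS) is delegated to OpenBabel via ChemmineOB; the QED and
SA comparators are delegated to RDKit's published implementations through
the system `python` (`qedSa()` — an optional capability, not a package
dependency).

## Tokenization

SMILES are tokenized greedily left to right: the eight multi-character
bracket atoms `[C@H] [C@@H] [nH] [C@@] [C@] [S@] [S@@] [H]` are single
tokens, the halogen digraphs become single letters (`Cl` → `L`, `Br` →
`R`), `%nn` ring labels are one token, everything else is one character.
Any other bracket atom is out-of-vocabulary by design — it is rejected in
cleaning rather than split into meaningless characters. Three control
tokens (`<pad>`, `<start>`, `<end>`) are prepended to the corpus-derived
body tokens; the vocabulary orders body tokens lexicographically (C locale)
so it is identical across runs and corpus orderings. Token ids are dense
1..|V| (R indexing). Round-trip exactness — `detokenize(tokenize(s)) == s`
— is property-tested over the full fixture grammars.

## The generator

The policy G(w_{t+1} | w_1..w_t) is a stacked-LSTM language model: an
embedding table, three LSTM layers (the reference depth; configurable), and
a linear-softmax head. Sampling is ancestral from `<start>` until the first
`<end>` or the capacity `maxLen`. Training minimizes mean per-token negative
log-likelihood with Adam, inter-layer dropout (default 0.1), gradient-norm
clipping at 5, and early stopping on mean validation loss (patience 1 epoch
by default); the best-validation parameters are returned.

A deliberate semantic point: sampling draws from the *full* softmax over
the vocabulary, control tokens included. Trained models assign control
tokens negligible mass mid-sequence, but the enumeration oracles in the
test suite cover the full space, so sequence length is defined everywhere
as "position of the first `<end>`, else capacity" rather than by counting
pad entries.

## The discriminator

D(W) embeds an encoded sequence as a T × k matrix and applies a bank of
convolution kernels of window sizes l (default 1..10 at 100 filters each;
the desk-scale study uses 1..4 at 12), each feature being the ReLU of the
summed element-wise product of the kernel with an l-row window plus bias.
Each kernel's feature map is max-pooled over the windows that fit inside
the token stream — windows overlapping trailing padding are excluded, so
scores are exactly invariant to padding — then pooled features are
concatenated and mapped by a linear layer and logistic function to a
probability in (0,1). Supervised training merges the positive and negative
corpora, splits each class 8:1:1 into train/validation/internal-test,
minimizes the two-term cross-entropy (mean over reals of −log D plus mean
over fakes of −log(1−D)) on balanced batches with Adam (batch 128, learning
rate 1e-4, patience 1), and reports internal-test accuracy and AUC.

## Adversarial coupling

The generator is treated as a reinforcement-learning policy whose reward
for a *finished* sequence is the discriminator probability. Intermediate
actions are valued by Monte-Carlo rollouts: Q(s_t, a) is the mean
discriminator score of N policy completions of the action-extended prefix
(default N = 16), and exactly the discriminator score of the finished
sequence when the action terminates it. The policy gradient is the
score-function estimator — the average over sampled sequences of
Σ_t ∇log G(a_{t+1}|s_t)·Q(s_t, a_{t+1}) — ascended with Adam. The
per-sequence sum is normalized by the fixed generation horizon (the
capacity's action count), not by each sequence's own length: with variable
lengths a per-sequence 1/T makes the estimator biased for ∇E[D(W)] and
gives it a nonzero mean under constant reward, whereas the fixed-horizon
normalization keeps it proportional-unbiased and exactly zero-mean under
constant reward — properties the test suite verifies against exhaustive
enumeration on a toy world.

Each adversarial step is: one policy-gradient update (64 sampled
sequences); one likelihood step on 64 molecules drawn from the real
(positive) pool — the *progressive augmentation* that steadily drags the
generator's output distribution toward the drug-like set, so the "fake"
examples the discriminator sees keep getting harder and more diverse; and
one discriminator update on a balanced 64 fake + 64 real batch under the
two-term loss. Both learning rates default to 1e-4. Optional early
stopping monitors the window-smoothed discriminator loss after a burn-in
(default 100 steps, window 50) — the monitored loss begins "after
stabilization", since raw adversarial losses oscillate; runs of a fixed
step count disable it. No reward baseline is used by default (plain
REINFORCE); a moving-average baseline is available behind a flag.

## Synthetic fixtures and what they do (and do not) show

Everything is testable offline through two hand-written stochastic
grammars. The negative grammar emits acyclic alkane/ether/amine molecules
(10–16 heavy atoms, aliphatic runs capped at 4 by construction): simple,
catalog-like material. The positive grammar emits aromatic molecules with
amide/ester linkers, a stereocenter, optional halogens and short
aliphatic/ether/amine tails — exercising the aromatic, stereo and halogen
tokens, with higher molecular weight (roughly 180–310 Da vs 130–250). Both grammars are
seed-deterministic, emit unique molecules (by canonical form by default)
and survive the cleaning pipeline in full. They are *separable by
construction* (the aromatic-carbon token alone classifies ≥ 90% correctly),
which makes the GAN task learnable at desk scale; they do not imitate real
drug chemistry's property distributions, so passing tests demonstrate the
machinery — not performance on real libraries, which depends on the corpora
a user trains on.

A fully enumerable toy world (two body tokens, three-token bodies, a small
seeded generator and a hand-set detector discriminator whose scores spread
over (0.1, 0.9)) supports exact oracles: complete enumeration of the
sequence distribution (probabilities summing to 1), exact conditional
action values with variances, the exact objective J = E[D(W)] and its
gradient. The analytic backward pass is validated against central finite
differences; Monte-Carlo Q values are checked inside 3σ enumeration bands
at N = 10,000; the sampled policy gradient at 5,000 draws must reach cosine
≥ 0.95 against the enumerated exact gradient.

## Study conditions at desk scale

The bundled study (tests and the acceptance script) runs with: 2,200
negative-grammar molecules for generator pretraining (1,800 train / 200
validation / 200 held out), 1,000 positive-grammar molecules as the real
pool, both grammars capped at 26 tokens (encoded capacity 28 — rollout
cost grows with the square of the horizon, so fixture length is the main
runtime dial), generator with embedding 32 / hidden 32 / 3 layers,
discriminator with embedding 32, windows 1..4, 12 filters; desk
pretraining uses batch 256 at learning rate 2e-3 (patience 2) and
discriminator pretraining batch 128 at 1e-3 — scaled-up corpora would use
the reference settings that remain the function defaults (batch 512 / 128
at 1e-4, patience 1). Adversarial training runs 400 steps with the
reference batch sizes (64; 64+64) and learning rates (1e-4) and N = 16
rollouts. Under these conditions the discriminator reaches internal-test
AUC ≈ 1 on the separable grammars, and after adversarial training the mean
discriminator score of generator samples rises by well over 0.1 while the
molecular-weight spread of late samples widens beyond the pretraining
corpus's — the desk-scale analogue of progressive augmentation's effect.

## Numerical choices

* Parameters initialize Gaussian (sd 0.08; the toy world uses larger scales
  for contrast), forget-gate biases at +1.
* Adam uses the conventional moments (0.9, 0.999, eps 1e-8) with bias
  correction; gradient clipping applies to the global norm.
* Softmax and log-softmax are max-shifted; discriminator probabilities are
  clamped at 1e-12 inside the loss logs.
* Sampling uses inverse-CDF draws against pre-drawn uniforms; every
  stochastic entry point takes a `seed` and restores the caller's RNG
  state, and compiled kernels receive their uniforms from R, so a seeded
  run is bitwise reproducible.
* Ties in ranking break by input order; selection thresholds are inclusive.
* Degenerate inputs are contracts, not crashes: empty corpora produce empty
  results and zero ledgers, unparseable or out-of-vocabulary molecules get
  reasons and NA scores, a window larger than the sequence contributes zero
  features.
* Hot paths (teacher-forced weighted gradient, batched sampling
  continuation with compaction of finished rows, forward scoring) are
  RcppArmadillo kernels; the R single-step path is kept for enumeration and
  inspection and is tested for exact agreement.

## Known limitations

* The discriminator score is only as meaningful as the corpora it was
  trained against; the bundled grammars demonstrate mechanism, not
  real-library performance.
* OpenBabel's canonical SMILES, logP and H-bond-donor/acceptor conventions
  differ in detail from other toolkits'; canonical forms are internally
  consistent but not interchangeable with RDKit's.
* Sequences the policy truncates at capacity are scored as token streams
  (the discriminator does not parse chemistry); invalid SMILES among
  samples are reported at decode time, not repaired.
* The rollout estimator is plain REINFORCE; long sequences make its
  variance felt, which is why rollout counts and the optional baseline are
  exposed.
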