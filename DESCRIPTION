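Package: MolTriageGAN
Title: Adversarially Trained SMILES Discriminator for Triaging De Novo Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a sequence generative adversarial network over SMILES
    strings and uses its discriminator as a molecule-triage score. A
    three-layer LSTM policy generates molecules token by token; a multiscale
    convolutional classifier scores token sequences as drug/bioactive-like
    versus generative/catalog-like; the two are coupled by REINFORCE policy
    gradients with Monte-Carlo rollout action values and a progressive
    augmentation schedule that fine-tunes the generator on drug-like samples
    during adversarial training. Includes the six-step SMILES cleaning
    pipeline, the tokenizer with multi-character bracket-atom tokens,
    rule-of-five / Fsp3 descriptor baselines, and deterministic synthetic
    SMILES grammars for end-to-end desk-scale training and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    ChemmineOB,
    pROC
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
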