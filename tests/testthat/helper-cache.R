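# Shared, seed-deterministic fixtures built once per test session. The
# desk-scale study conditions: a 2200-molecule negative-grammar corpus
# (1800 train / 200 validation / 200 held out), a 1000-molecule positive
# pool, encoded at a common capacity, a generator pretrained on the
# negative grammar and a discriminator trained on positives vs negatives.

.fixtureCache <- new.env(parent = emptyenv())

studyFixtures <- function() {
  if (is.null(.fixtureCache$fx)) {
    neg <- makeNegativeGrammar(2200, seed = 21)
    pos <- makePositiveGrammar(1000, seed = 22)
    vocab <- buildVocabulary(c(neg, pos))
    maxLen <- 28L
    .fixtureCache$fx <- list(
      neg = neg, pos = pos, vocab = vocab, maxLen = maxLen,
      negIds = encodeSmiles(neg, vocab, maxLen = maxLen),
      posIds = encodeSmiles(pos, vocab, maxLen = maxLen))
  }
  .fixtureCache$fx
}

studyGenerator <- function() {
  if (is.null(.fixtureCache$gen)) {
    fx <- studyFixtures()
    gen <- newGenerator(fx$vocab, embeddingDim = 32L, hiddenDim = 32L,
                        nLayers = 3L, dropout = 0.1, maxLen = fx$maxLen,
                        seed = 5)
    fit <- mlePretrain(gen, fx$negIds[1:1800, ], fx$negIds[1801:2000, ],
                       batchSize = 256L, lr = 2e-3, patience = 2L,
                       maxEpochs = 12L, seed = 6)
    .fixtureCache$gen <- fit
  }
  .fixtureCache$gen
}

studyDiscriminator <- function() {
  if (is.null(.fixtureCache$disc)) {
    fx <- studyFixtures()
    disc <- newDiscriminator(fx$vocab, embeddingDim = 32L, windows = 1:4,
                             nFilters = 12L, dropout = 0.1, seed = 3)
    tr <- trainDiscriminator(disc, fx$posIds, fx$negIds[1:1000, ],
                             batchSize = 128L, lr = 1e-3, patience = 1L,
                             maxEpochs = 8L, seed = 4)
    .fixtureCache$disc <- tr
  }
  .fixtureCache$disc
}

# cosine between two parameter structures
paramCosine <- function(a, b) {
  va <- unlist(a, use.names = FALSE)
  vb <- unlist(b, use.names = FALSE)
  sum(va * vb) / sqrt(sum(va * va) * sum(vb * vb))
}

paramNorm <- function(a) sqrt(sum(unlist(a, use.names = FALSE)^2))

# average molecular weights for a SMILES vector (NA where unparseable)
molWeights <- function(smiles) {
  vapply(smiles, function(s) {
    f <- MolTriageGAN:::.molFacts(s)
    if (is.null(f)) NA_real_ else f$prop$MW
  }, 0, USE.NAMES = FALSE)
}
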