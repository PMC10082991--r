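# Deterministic synthetic-SMILES generators. Two structurally distinct
# grammars provide a separable positive/negative task and a pretraining
# corpus with no external downloads: the negative grammar emits plain
# acyclic alkane/ether/amine molecules, the positive grammar emits
# aromatic amide/ester molecules with stereocenters and halogens.
# Both are built so every emitted molecule passes the cleaning pipeline
# (>= 10 heavy atoms, aliphatic runs capped at 4, MW well under 750).
# A hand-sized, fully enumerable toy world supports exact oracles for
# rollout values and policy gradients.

.uniqueDraws <- function(n, drawFun) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    batch <- vapply(seq_len(max(n, 64L)), function(i) drawFun(), "")
    out <- unique(c(out, batch))
    tries <- tries + 1L
    if (tries > 200L) stop("grammar space too small for ", n, " unique draws")
  }
  out[seq_len(n)]
}

# One acyclic alkane/ether/amine: alternating short carbon runs (1-3, with
# occasional single-carbon branches) and O/N linkers. Runs capped so no
# aliphatic chain exceeds 4 even across a branch.
.drawNegative <- function(minHeavy = 10L, maxHeavy = 16L, maxTokens = 26L) {
  repeat {
    target <- sample(minHeavy:maxHeavy, 1L)
    run <- function() {
      len <- sample(1:3, 1L)
      branch <- len >= 2L && stats::runif(1) < 0.3
      s <- strrep("C", len)
      if (branch) s <- paste0(substr(s, 1L, 1L), "(C)",
                              substr(s, 2L, len))
      list(s = s, n = len + as.integer(branch))
    }
    r <- run(); parts <- r$s; heavy <- r$n
    while (heavy < target) {
      het <- sample(c("O", "N"), 1L)
      r <- run()
      parts <- paste0(parts, het, r$s)
      heavy <- heavy + 1L + r$n
    }
    if (nchar(parts) <= maxTokens) return(parts)  # single-char tokens only
  }
}

# One aromatic drug-motif molecule: optionally substituted benzene, an
# amide/sulfonamide/ester linker, a stereocenter, and a short aliphatic /
# ether / amine tail. Exercises the tokens c, =, [C@H]/[C@@H], L and R.
# Draws are capped at 26 tokens so the whole corpus fits a short capacity,
# which keeps rollout horizons (and hence adversarial training cost) small.
.drawPositive <- function(maxTokens = 26L) {
  repeat {
    halo <- sample(c("Cl", "Br", "F", "C", "OC", "N", ""), 1L,
                   prob = c(.18, .13, .13, .13, .13, .1, .2))
    ringSub <- sample(c("", "C", "F"), 1L, prob = c(.7, .15, .15))
    core <- if (nzchar(halo) && nzchar(ringSub))
      paste0(halo, "c1cc(", ringSub, ")cc(%s)c1")
    else if (nzchar(halo)) paste0(halo, "c1ccc(%s)cc1")
    else if (nzchar(ringSub)) paste0(ringSub, "c1ccc(%s)cc1")
    else "c1ccc(%s)cc1"
    linker <- sample(c("C(=O)N", "C(=O)O", "NC(=O)", "OC(=O)"), 1L)
    chiral <- sample(c("[C@H]", "[C@@H]"), 1L)
    # when the linker attaches its carbonyl carbon to the stereocenter, an
    # all-carbon branch + tail would form an aliphatic run longer than 4;
    # keep one heteroatom within reach of the center in that case
    carbonylSide <- linker %in% c("NC(=O)", "OC(=O)")
    branch <- if (carbonylSide) sample(c("C", "CO", "CN"), 1L)
              else sample(c("C", "CC", "CO", "CN"), 1L)
    run1 <- if (carbonylSide) sample(c("C", "CO", "CN", "OC", "NC"), 1L)
            else sample(c("C", "CC", "CO", "CN", "OC", "NC"), 1L)
    ext <- sample(c("", "OC", "NC", "OCC", "NCC"), 1L,
                  prob = c(.4, .15, .15, .15, .15))
    mid <- paste0(linker, chiral, "(", branch, ")", run1, ext)
    smi <- sprintf(core, mid)
    if (length(tokenizeSmiles(smi)) <= maxTokens) return(smi)
  }
}

#' Synthetic negative-set grammar (plain alkane/ether/amine molecules)
#'
#' Deterministic per seed; draws are unique. With
#' \code{unique = "canonical"} (default) draws are additionally
#' deduplicated on their canonical form so the whole corpus survives the
#' duplicate rule of the cleaning pipeline; \code{"string"} skips the
#' chemistry round and deduplicates on the raw string only (faster, used
#' for large string-level corpora).
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @param unique deduplication level: \code{"canonical"} or \code{"string"}.
#' @return character vector of n SMILES strings.
#' @export
makeNegativeGrammar <- function(n, seed = NULL,
                                unique = c("canonical", "string")) {
  unique <- match.arg(unique)
  .withSeed(seed, {
    out <- .uniqueDraws(n, .drawNegative)
    if (unique == "canonical") out <- .dedupeCanonical(out, n, .drawNegative)
    out
  })
}

#' Synthetic positive-set grammar (aromatic drug-motif molecules)
#'
#' @inheritParams makeNegativeGrammar
#' @return character vector of n SMILES strings.
#' @export
makePositiveGrammar <- function(n, seed = NULL,
                                unique = c("canonical", "string")) {
  unique <- match.arg(unique)
  .withSeed(seed, {
    out <- .uniqueDraws(n, .drawPositive)
    if (unique == "canonical") out <- .dedupeCanonical(out, n, .drawPositive)
    out
  })
}

# Keep draws whose canonical forms are unique, topping up until n remain.
.dedupeCanonical <- function(draws, n, drawFun) {
  canon <- canonicalizeSmiles(draws)
  keep <- !is.na(canon) & !duplicated(canon)
  out <- draws[keep]
  seen <- canon[keep]
  guard <- 0L
  while (length(out) < n) {
    extra <- vapply(seq_len(64L), function(i) drawFun(), "")
    extra <- setdiff(unique(extra), out)
    cx <- canonicalizeSmiles(extra)
    ok <- !is.na(cx) & !(cx %in% seen) & !duplicated(cx)
    out <- c(out, extra[ok])
    seen <- c(seen, cx[ok])
    guard <- guard + 1L
    if (guard > 200L) stop("could not reach ", n, " canonical-unique draws")
  }
  out[seq_len(n)]
}

#' Hand-sized enumerable toy world
#'
#' A five-token vocabulary (three control tokens plus the body tokens
#' \code{C} and \code{O}), sequence capacity of three body tokens, and a
#' small seeded generator/discriminator pair. Every sequence the policy can
#' emit, its probability, every action value and the exact policy gradient
#' are computable by exhaustive enumeration, which the tests use as an
#' oracle for the Monte-Carlo machinery.
#'
#' @param hiddenDim,embeddingDim,nLayers toy generator sizes.
#' @param seed seed fixing the hand-set parameters.
#' @return list: \code{vocab}, \code{gen}, \code{disc}, \code{maxLen}.
#' @export
makeToyWorld <- function(hiddenDim = 8L, embeddingDim = 4L, nLayers = 1L,
                         seed = 7L) {
  vocab <- newVocabulary(c("C", "O"))
  maxLen <- 5L  # start + up to 3 body tokens + end
  gen <- newGenerator(vocab, embeddingDim = embeddingDim,
                      hiddenDim = hiddenDim, nLayers = nLayers,
                      dropout = 0, maxLen = maxLen, seed = seed,
                      initScale = 0.4)
  # Hand-set discriminator: window-1 filters detect the tokens C / O / <end>,
  # window-2 filters detect the bigrams CC / CO / OO; the head mixes the
  # max-pooled presence indicators with both signs, giving scores spread
  # across (0.1, 0.9) — enough reward contrast for gradient oracles.
  disc <- newDiscriminator(vocab, embeddingDim = 4L,
                           windows = c(1L, 2L), nFilters = 3L,
                           dropout = 0, seed = seed + 1L)
  E <- matrix(0, 5, 4)
  E[vocab@endId, 3] <- 1
  E[tokenToId(vocab, "C"), 1] <- 1
  E[tokenToId(vocab, "O"), 2] <- 1
  W1 <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  W2 <- cbind(c(1, 0, 0, 0, 1, 0, 0, 0),   # CC
              c(1, 0, 0, 0, 0, 1, 0, 0),   # CO
              c(0, 1, 0, 0, 0, 1, 0, 0))   # OO
  disc@params <- list(
    E = E,
    conv = list(list(W = W1, b = c(0, 0, 0)),
                list(W = W2, b = c(-1, -1, -1))),
    head = list(w = c(1.2, -0.8, 0.3, 1.0, -1.2, 0.6), b = -0.4))
  list(vocab = vocab, gen = gen, disc = disc, maxLen = maxLen)
}

#' Enumerate every sequence of a small policy
#'
#' Walks the complete tree of token choices up to the capacity: sequences
#' terminate at \code{<end>} or truncate at \code{maxLen} columns. The
#' probabilities of the enumerated sequences sum to one.
#'
#' @param gen a small \linkS4class{SmilesGenerator}.
#' @param maxLen encoded capacity (keep tiny: the tree is |V|^length).
#' @return list: \code{ids} (matrix, one row per sequence), \code{logProb},
#'   \code{prob}, \code{Tacts} (actions per sequence).
#' @export
enumerateSequences <- function(gen, maxLen = NULL) {
  vocab <- gen@vocab
  if (is.null(maxLen)) maxLen <- gen@config$maxLen
  V <- vocabSize(vocab)
  rows <- list()
  walk <- function(prefix, logp) {
    col <- length(prefix) + 1L
    st <- .zeroState(gen, 1L)
    for (tok in prefix) st <- .stepState(gen, st, tok)
    probs <- drop(.softmax(.stateLogits(gen, st)))
    for (a in seq_len(V)) {
      lp <- logp + log(probs[a])
      seqIds <- c(prefix, a)
      if (a == vocab@endId || col == maxLen) {
        row <- rep(vocab@padId, maxLen)
        row[seq_along(seqIds)] <- seqIds
        rows[[length(rows) + 1L]] <<- list(row = row, lp = lp)
      } else {
        walk(seqIds, lp)
      }
    }
  }
  walk(vocab@startId, 0)
  ids <- do.call(rbind, lapply(rows, `[[`, "row"))
  logProb <- vapply(rows, `[[`, 0, "lp")
  list(ids = ids, logProb = logProb, prob = exp(logProb),
       Tacts = .seqLengths(ids, vocab) - 1L)
}

#' Exact action value by enumeration
#'
#' Q(prefix, action) as the conditional expectation of the discriminator
#' score over all completions of the action-extended prefix, computed from
#' the full sequence enumeration. Also returns the conditional variance
#' (for sizing Monte-Carlo error bars).
#'
#' @param enum result of [enumerateSequences()].
#' @param disc a \linkS4class{SmilesDiscriminator}.
#' @param gen the enumerated generator (for control ids and capacity).
#' @param prefixIds encoded prefix starting with \code{<start>}.
#' @param action candidate token id.
#' @return list: \code{value}, \code{var}, \code{pPrefix} (mass of the
#'   extended prefix).
#' @export
exactQValue <- function(enum, disc, gen, prefixIds, action) {
  scores <- discriminatorScore(disc, enum$ids)
  ext <- c(prefixIds, action)
  m <- length(ext)
  match <- apply(enum$ids[, seq_len(m), drop = FALSE], 1L,
                 function(r) all(r == ext))
  # a terminated enumeration row equals ext exactly when ext is complete
  p <- enum$prob[match]
  if (!sum(p) > 0) stop("extended prefix has zero probability mass")
  w <- p / sum(p)
  mu <- sum(w * scores[match])
  list(value = mu, var = sum(w * (scores[match] - mu)^2),
       pPrefix = sum(p))
}

#' Exact policy objective and its gradient by enumeration
#'
#' \code{exactExpectedReward}: J = E[D(W)] over the enumerated sequence
#' distribution. \code{exactPolicyGradient}: the exact score-function
#' gradient \eqn{\sum_W p(W) D(W) \nabla \log p(W)} scaled by the same
#' fixed 1/T horizon normalization the sampled REINFORCE estimator uses, so
#' the two quantities agree in expectation (not just direction). Computed
#' without any action values or rollouts — an independent oracle for the
#' Monte-Carlo path.
#'
#' @param gen small generator.
#' @param disc discriminator.
#' @param maxLen capacity.
#' @return \code{exactExpectedReward}: scalar. \code{exactPolicyGradient}:
#'   parameter-shaped list (ascent direction).
#' @export
exactExpectedReward <- function(gen, disc, maxLen = NULL) {
  enum <- enumerateSequences(gen, maxLen)
  sum(enum$prob * discriminatorScore(disc, enum$ids))
}

#' @rdname exactExpectedReward
#' @export
exactPolicyGradient <- function(gen, disc, maxLen = NULL) {
  if (is.null(maxLen)) maxLen <- gen@config$maxLen
  enum <- enumerateSequences(gen, maxLen)
  scores <- discriminatorScore(disc, enum$ids)
  Tmax <- maxLen - 1L
  total <- NULL
  for (s in seq_len(nrow(enum$ids))) {
    ids <- matrix(enum$ids[s, ], nrow = 1L)
    Tb <- enum$Tacts[s]
    w <- numeric(ncol(ids) - 1L)
    w[seq_len(Tb)] <- enum$prob[s] * scores[s] / Tmax
    g <- .weightedGrad(gen, ids, matrix(w, nrow = 1L))$grads
    g <- .paramsScale(g, -1)  # the pass returns -d(w . logp)
    total <- if (is.null(total)) g else .paramsAdd(total, g)
  }
  total
}
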