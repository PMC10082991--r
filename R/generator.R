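# The autoregressive SMILES policy: a stacked-LSTM language model over token
# ids. Single steps and enumeration run in R; the teacher-forced weighted
# gradient and batched sampling continuation run in compiled kernels
# (src/nnkernels.cpp) with all randomness drawn from the R RNG, so seeded
# runs are reproducible end to end. The weighted-gradient pass serves both
# maximum-likelihood training (uniform weights over real targets) and
# REINFORCE (weights = action values).

#' Create a SMILES generator
#'
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param embeddingDim token embedding size.
#' @param hiddenDim LSTM hidden size per layer.
#' @param nLayers number of stacked LSTM layers (3 mirrors the reference
#'   architecture).
#' @param dropout inter-layer dropout rate used during likelihood training.
#' @param maxLen encoded sequence capacity (start + body + end, padded).
#' @param seed RNG seed for parameter initialization.
#' @param initScale standard deviation of the Gaussian initializer.
#' @return a \linkS4class{SmilesGenerator}. Forget-gate biases start at +1.
#' @export
newGenerator <- function(vocab, embeddingDim = 128L, hiddenDim = 512L,
                         nLayers = 3L, dropout = 0.1, maxLen = 100L,
                         seed = NULL, initScale = 0.08) {
  V <- vocabSize(vocab)
  .withSeed(seed, {
    E <- matrix(stats::rnorm(V * embeddingDim, sd = initScale), V, embeddingDim)
    layers <- lapply(seq_len(nLayers), function(l) {
      din <- if (l == 1L) embeddingDim else hiddenDim
      b <- numeric(4L * hiddenDim)
      b[hiddenDim + seq_len(hiddenDim)] <- 1  # forget gate bias
      list(W = matrix(stats::rnorm(din * 4L * hiddenDim, sd = initScale),
                      din, 4L * hiddenDim),
           U = matrix(stats::rnorm(hiddenDim * 4L * hiddenDim, sd = initScale),
                      hiddenDim, 4L * hiddenDim),
           b = b)
    })
    M <- matrix(stats::rnorm(hiddenDim * V, sd = initScale), hiddenDim, V)
    params <- list(E = E, layers = layers, M = M, cvec = numeric(V))
    new("SmilesGenerator", params = params,
        config = list(embeddingDim = as.integer(embeddingDim),
                      hiddenDim = as.integer(hiddenDim),
                      nLayers = as.integer(nLayers),
                      dropout = dropout, maxLen = as.integer(maxLen)),
        vocab = vocab)
  })
}

# One batched LSTM cell step. x: B x din, h/c: B x H. Gate order i,f,g,o.
.lstmCell <- function(layer, x, h, c) {
  H <- ncol(h)
  z <- x %*% layer$W + h %*% layer$U
  z <- z + rep(layer$b, each = nrow(z))
  i <- .sigmoid(z[, seq_len(H), drop = FALSE])
  f <- .sigmoid(z[, H + seq_len(H), drop = FALSE])
  g <- tanh(z[, 2L * H + seq_len(H), drop = FALSE])
  o <- .sigmoid(z[, 3L * H + seq_len(H), drop = FALSE])
  cn <- f * c + i * g
  list(h = o * tanh(cn), c = cn)
}

# Length of each encoded row: the column of the first <end>, or the last
# column when a row truncates without one. Counting non-pad entries would be
# wrong for raw policy samples, where control tokens can be drawn mid-body.
.seqLengths <- function(ids, vocab) {
  e <- (ids == vocab@endId) + 0L
  has <- rowSums(e) > 0L
  fe <- max.col(e, ties.method = "first")
  as.integer(ifelse(has, fe, ncol(ids)))
}

# Per-target action mask: positions up to and including the first <end>.
.actionMask <- function(targets, vocab) {
  Tin <- ncol(targets)
  fe <- .seqLengths(targets, vocab)
  matrix(seq_len(Tin), nrow(targets), Tin, byrow = TRUE) <=
    matrix(fe, nrow(targets), Tin)
}

# Hidden state as B x H x L arrays (h and c), matching the kernel layout.
.zeroState <- function(gen, B) {
  H <- gen@config$hiddenDim
  L <- gen@config$nLayers
  list(h = array(0, c(B, H, L)), c = array(0, c(B, H, L)))
}

# Consume one column of token ids, returning the updated state.
.stepState <- function(gen, state, tokenIds) {
  B <- dim(state$h)[1L]
  H <- dim(state$h)[2L]
  x <- gen@params$E[tokenIds, , drop = FALSE]
  for (l in seq_len(gen@config$nLayers)) {
    cell <- .lstmCell(gen@params$layers[[l]], x,
                      matrix(state$h[, , l], B, H),
                      matrix(state$c[, , l], B, H))
    state$h[, , l] <- cell$h
    state$c[, , l] <- cell$c
    x <- cell$h
  }
  state
}

.stateLogits <- function(gen, state) {
  B <- dim(state$h)[1L]
  hTop <- matrix(state$h[, , gen@config$nLayers], B)
  logits <- hTop %*% gen@params$M
  logits + rep(gen@params$cvec, each = B)
}

#' Next-token distribution from a hidden state
#'
#' Consumes one token per batch row and applies the softmax output layer to
#' the resulting top hidden state. The single-step workhorse behind
#' sampling; exposed for inspection and testing.
#'
#' @param gen a \linkS4class{SmilesGenerator}.
#' @param state list with \code{h} and \code{c} arrays of dimension
#'   B x hidden x layers (use \code{NULL} for the zero initial state).
#' @param tokenIds integer vector of token ids to consume (one per batch row).
#' @return list with the updated \code{state} and \code{probs}, a B x |V|
#'   matrix of next-token probabilities (rows sum to one).
#' @export
generatorStep <- function(gen, state, tokenIds) {
  if (is.null(state)) state <- .zeroState(gen, length(tokenIds))
  state <- .stepState(gen, state, tokenIds)
  list(state = state, probs = .softmax(.stateLogits(gen, state)))
}

# Batched ancestral continuation from a state (compiled kernel); uniforms
# are drawn here so the ambient R RNG governs the draw sequence.
.continueFrom <- function(gen, state, nSteps, keepStates = FALSE,
                          limits = NULL) {
  B <- dim(state$h)[1L]
  if (is.null(limits)) limits <- rep.int(nSteps, B)
  U <- matrix(stats::runif(B * nSteps), B, nSteps)
  .cppLstmContinue(gen@params$E, gen@params$layers, gen@params$M,
                   gen@params$cvec, state$h, state$c, U, nSteps,
                   gen@vocab@endId, gen@vocab@padId, keepStates,
                   as.integer(limits))
}

#' Sample token sequences from the policy
#'
#' Ancestral sampling: start from \code{<start>}, draw each next token from
#' the per-step softmax distribution, stop a row at its first \code{<end>}
#' or truncate at \code{maxLen} columns.
#'
#' @param gen a \linkS4class{SmilesGenerator}.
#' @param n number of sequences.
#' @param maxLen encoded capacity (default: the generator's configured one).
#' @param seed RNG seed (local to the call).
#' @param keepStates also return the per-step hidden states (used by
#'   Monte-Carlo rollouts to resume sampling mid-sequence).
#' @return list: \code{ids} (n x maxLen id matrix), \code{lengths} (column
#'   of each row's \code{<end>}, or maxLen if truncated), \code{terminated}
#'   (logical), and, if requested, \code{states[[t]]} = state after
#'   consuming column t.
#' @export
sampleSequences <- function(gen, n, maxLen = NULL, seed = NULL,
                            keepStates = FALSE) {
  vocab <- gen@vocab
  if (is.null(maxLen)) maxLen <- gen@config$maxLen
  ids <- matrix(vocab@padId, n, maxLen)
  if (n == 0L)
    return(list(ids = ids, lengths = integer(), terminated = logical()))
  .withSeed(seed, {
    ids[, 1L] <- vocab@startId
    state <- .stepState(gen, .zeroState(gen, n), ids[, 1L])
    cont <- .continueFrom(gen, state, maxLen - 1L, keepStates = keepStates)
    ids[, 2L:maxLen] <- cont$tokens
    lengths <- .seqLengths(ids, vocab)
    terminated <- apply(ids == vocab@endId, 1L, any)
    out <- list(ids = ids, lengths = as.integer(lengths),
                terminated = terminated)
    if (keepStates) {
      states <- vector("list", maxLen)
      states[[1L]] <- state
      for (s in seq_len(cont$emitted)) states[[s + 1L]] <- cont$states[[s]]
      out$states <- states
    }
    out
  })
}

#' Log-probability of encoded sequences under the policy
#'
#' Sum over the chain of per-step log-probabilities of the body tokens and
#' the terminating \code{<end>} token; positions after the first
#' \code{<end>} contribute nothing, so the value is invariant to padding.
#'
#' @param gen a \linkS4class{SmilesGenerator}.
#' @param ids encoded id matrix (rows start with \code{<start>}).
#' @return numeric vector of per-sequence log-probabilities.
#' @export
sequenceLogProb <- function(gen, ids) {
  if (is.null(dim(ids))) ids <- matrix(ids, nrow = 1L)
  fw <- .weightedGrad(gen, ids, matrix(0, nrow(ids), ncol(ids) - 1L))
  mask <- .actionMask(ids[, -1L, drop = FALSE], gen@vocab)
  lp <- fw$logProbTargets
  lp[!mask] <- 0
  rowSums(lp)
}

# Teacher-forced pass: per-position target log-probabilities and the
# gradient of -sum weights * log p(target). Dropout masks (inverted, per
# layer output) are drawn here when requested.
.weightedGrad <- function(gen, ids, weights, train = FALSE) {
  cfg <- gen@config
  dropMasks <- NULL
  if (train && cfg$dropout > 0) {
    B <- nrow(ids)
    Tin <- ncol(ids) - 1L
    HL <- cfg$hiddenDim * cfg$nLayers
    dropMasks <- array(
      stats::rbinom(B * HL * Tin, 1L, 1 - cfg$dropout) / (1 - cfg$dropout),
      c(B, HL, Tin))
  }
  .cppLstmGrad(gen@params$E, gen@params$layers, gen@params$M,
               gen@params$cvec, ids, weights, dropMasks)
}

# Mean negative log-likelihood per real target token.
.batchNll <- function(gen, ids) {
  fw <- .weightedGrad(gen, ids, matrix(0, nrow(ids), ncol(ids) - 1L))
  mask <- .actionMask(ids[, -1L, drop = FALSE], gen@vocab)
  -sum(fw$logProbTargets[mask]) / sum(mask)
}

#' One likelihood (MLE) update step
#'
#' A single Adam step on the mean per-token negative log-likelihood of a
#' batch. Also the progressive-augmentation move of adversarial training:
#' fine-tuning the generator on a batch of real (drug-like) sequences.
#'
#' @param gen a \linkS4class{SmilesGenerator}.
#' @param ids encoded batch.
#' @param lr learning rate (0 leaves parameters unchanged).
#' @param opt Adam state (created fresh when \code{NULL}).
#' @param clip global gradient-norm clip (\code{Inf} disables).
#' @param train apply dropout during the forward pass.
#' @return list: updated \code{gen}, \code{opt}, batch \code{loss} (mean NLL
#'   per token, computed before the update).
#' @export
mleStep <- function(gen, ids, lr, opt = NULL, clip = 5, train = TRUE) {
  if (is.null(opt)) opt <- adamInit(gen@params)
  mask <- .actionMask(ids[, -1L, drop = FALSE], gen@vocab)
  nTok <- sum(mask)
  fw <- .weightedGrad(gen, ids, mask / nTok, train = train)
  loss <- -sum(fw$logProbTargets[mask]) / nTok
  if (lr > 0) {
    grads <- .clipGrads(fw$grads, clip)
    upd <- adamStep(gen@params, grads, opt, lr)
    gen@params <- upd$params
    opt <- upd$opt
  }
  list(gen = gen, opt = opt, loss = loss)
}

#' Maximum-likelihood pretraining with validation early stopping
#'
#' Minimizes mean per-token negative log-likelihood with Adam; after each
#' epoch the mean validation loss is computed, and training stops when it
#' has not decreased for \code{patience} consecutive epochs. The state with
#' the best validation loss is returned.
#'
#' @param gen a \linkS4class{SmilesGenerator}.
#' @param corpusIds,valIds encoded training and validation sets (validation
#'   must be non-empty).
#' @param batchSize sequences per Adam step.
#' @param lr learning rate.
#' @param patience epochs without validation improvement before stopping.
#' @param maxEpochs hard epoch cap.
#' @param clip global gradient-norm clip.
#' @param seed RNG seed (shuffling, dropout).
#' @param verbose print per-epoch losses.
#' @return list: best \code{gen}, \code{history} data.frame (epoch,
#'   trainLoss, valLoss), \code{bestEpoch}.
#' @export
mlePretrain <- function(gen, corpusIds, valIds, batchSize = 512L, lr = 1e-4,
                        patience = 1L, maxEpochs = 30L, clip = 5,
                        seed = NULL, verbose = FALSE) {
  stopifnot(nrow(corpusIds) > 0L)
  if (is.null(valIds) || nrow(valIds) == 0L)
    stop("a non-empty validation set is required for early stopping")
  .withSeed(seed, {
    opt <- adamInit(gen@params)
    best <- list(gen = gen, loss = .batchNll(gen, valIds), epoch = 0L)
    history <- data.frame(epoch = 0L, trainLoss = NA_real_,
                          valLoss = best$loss)
    bad <- 0L
    for (epoch in seq_len(maxEpochs)) {
      ord <- sample.int(nrow(corpusIds))
      lossSum <- 0; lossN <- 0L
      for (start in seq(1L, length(ord), by = batchSize)) {
        take <- ord[start:min(start + batchSize - 1L, length(ord))]
        st <- mleStep(gen, corpusIds[take, , drop = FALSE], lr, opt,
                      clip = clip)
        gen <- st$gen; opt <- st$opt
        lossSum <- lossSum + st$loss * length(take)
        lossN <- lossN + length(take)
      }
      valLoss <- .batchNll(gen, valIds)
      history <- rbind(history, data.frame(
        epoch = epoch, trainLoss = lossSum / lossN, valLoss = valLoss))
      if (verbose)
        message(sprintf("epoch %d train %.4f val %.4f", epoch,
                        lossSum / lossN, valLoss))
      if (valLoss < best$loss) {
        best <- list(gen = gen, loss = valLoss, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    list(gen = best$gen, history = history, bestEpoch = best$epoch)
  })
}
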