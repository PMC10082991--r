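# Adversarial coupling of policy and discriminator: Monte-Carlo rollout
# action values, the REINFORCE policy-gradient update, the two-term
# discriminator update, and the alternating loop with progressive
# augmentation (one likelihood step on real samples per generator update).

#' Monte-Carlo rollouts completing a partial sequence
#'
#' Keeps the prefix fixed and samples the remaining positions ancestrally
#' from the current policy, N times.
#'
#' @param gen a \linkS4class{SmilesGenerator}.
#' @param prefixIds integer vector: encoded prefix starting with
#'   \code{<start>} (no pads).
#' @param n number N of rollouts.
#' @param maxLen encoded capacity (default: generator's configured).
#' @param seed RNG seed.
#' @return n x maxLen id matrix of completed sequences; if the prefix is
#'   already complete (ends with \code{<end>} or fills \code{maxLen}), n
#'   padded copies of it.
#' @export
mcRollout <- function(gen, prefixIds, n, maxLen = NULL, seed = NULL) {
  vocab <- gen@vocab
  if (is.null(maxLen)) maxLen <- gen@config$maxLen
  prefixIds <- as.integer(prefixIds)
  stopifnot(length(prefixIds) >= 1L, prefixIds[1L] == vocab@startId,
            length(prefixIds) <= maxLen)
  ids <- matrix(vocab@padId, n, maxLen)
  ids[, seq_along(prefixIds)] <- rep(prefixIds, each = n)
  complete <- prefixIds[length(prefixIds)] == vocab@endId ||
    length(prefixIds) == maxLen
  if (complete || n == 0L) return(ids)
  .withSeed(seed, {
    state <- .zeroState(gen, n)
    for (tok in prefixIds) state <- .stepState(gen, state, rep(tok, n))
    cont <- .continueFrom(gen, state, maxLen - length(prefixIds))
    ids[, (length(prefixIds) + 1L):maxLen] <- cont$tokens
    ids
  })
}

#' Rollout-estimated action value
#'
#' Q(prefix, action): if appending \code{action} completes the sequence
#' (action is \code{<end>} or capacity is reached), exactly the
#' discriminator probability of the completed sequence — no rollout.
#' Otherwise the mean discriminator probability over N policy rollouts of
#' the action-extended prefix. Always inside [0, 1].
#'
#' @param gen a \linkS4class{SmilesGenerator}.
#' @param disc a \linkS4class{SmilesDiscriminator} sharing the vocabulary.
#' @param prefixIds encoded prefix (starts with \code{<start>}).
#' @param action token id of the candidate next token.
#' @param nRollouts N.
#' @param maxLen encoded capacity.
#' @param seed RNG seed.
#' @return list: \code{value}, \code{terminal} (logical), \code{rollouts}
#'   (id matrix, absent for terminal actions).
#' @export
qValue <- function(gen, disc, prefixIds, action, nRollouts = 16L,
                   maxLen = NULL, seed = NULL) {
  vocab <- gen@vocab
  if (is.null(maxLen)) maxLen <- gen@config$maxLen
  ext <- c(as.integer(prefixIds), as.integer(action))
  stopifnot(length(ext) <= maxLen)
  terminal <- action == vocab@endId || length(ext) == maxLen
  if (terminal) {
    ids <- matrix(vocab@padId, 1L, maxLen)
    ids[1L, seq_along(ext)] <- ext
    return(list(value = discriminatorScore(disc, ids)[1L],
                terminal = TRUE))
  }
  ro <- mcRollout(gen, ext, nRollouts, maxLen = maxLen, seed = seed)
  list(value = mean(discriminatorScore(disc, ro)), terminal = FALSE,
       rollouts = ro)
}

# Batched rollout action values for a sampled batch, reusing the hidden
# states cached during sampling. For each cut position t (action at encoded
# column t+1) every still-active sequence is replicated N times and
# completed from its cached state; completions are scored in one
# discriminator call. Terminal actions take the score of the full sequence.
.rolloutQMatrix <- function(gen, disc, sampled, nRollouts, maxLen) {
  vocab <- gen@vocab
  ids <- sampled$ids
  B <- nrow(ids)
  lens <- .seqLengths(ids, vocab) # column of first <end>, else maxLen
  fullScore <- discriminatorScore(disc, ids)
  Tacts <- lens - 1L              # actions per sequence
  Q <- matrix(0, B, max(Tacts))
  for (t in seq_len(max(Tacts))) {
    col <- t + 1L                 # encoded column holding action t
    hasAction <- Tacts >= t
    termHere <- hasAction & (ids[, col] == vocab@endId | col == maxLen)
    Q[termHere, t] <- fullScore[termHere]
    act <- which(hasAction & !termHere)
    if (!length(act)) next
    n <- length(act) * nRollouts
    roll <- matrix(vocab@padId, n, maxLen)
    roll[, seq_len(col)] <- rep(ids[act, seq_len(col), drop = FALSE],
                                each = nRollouts)
    st <- sampled$states[[col]]
    takeRows <- rep(act, each = nRollouts)
    state <- list(h = st$h[takeRows, , , drop = FALSE],
                  c = st$c[takeRows, , , drop = FALSE])
    cont <- .continueFrom(gen, state, maxLen - col)
    roll[, (col + 1L):maxLen] <- cont$tokens
    sc <- matrix(discriminatorScore(disc, roll), nrow = nRollouts)
    Q[act, t] <- colMeans(sc)
  }
  list(Q = Q, Tacts = Tacts, fullScore = fullScore)
}

#' One REINFORCE policy-gradient update of the generator
#'
#' Samples \code{genBatch} sequences from the policy, estimates the action
#' value of every emitted token by Monte-Carlo rollouts (terminal actions
#' scored exactly), accumulates the score-function gradient
#' \eqn{(1/T) \sum_t \nabla \log G(a_{t+1}|W_{1:t}) Q(W_{1:t}, a_{t+1})}
#' averaged over the batch, and ascends it with Adam.
#'
#' @param gen a \linkS4class{SmilesGenerator}.
#' @param disc the current \linkS4class{SmilesDiscriminator}.
#' @param genBatch sequences sampled per update.
#' @param nRollouts rollouts N per action value.
#' @param lr learning rate (0: estimate only, no parameter change).
#' @param opt Adam state.
#' @param maxLen encoded capacity for sampling and rollouts.
#' @param baseline optional scalar subtracted from all Q values (moving
#'   average variance reduction; off when \code{NULL}, plain REINFORCE).
#' @param seed RNG seed.
#' @return list: updated \code{gen}, \code{opt}, \code{meanReward} (mean
#'   discriminator score of the sampled sequences), \code{meanQ},
#'   \code{gradient} (the raw batch gradient estimate, ascent direction).
#' @export
policyGradientStep <- function(gen, disc, genBatch = 64L, nRollouts = 16L,
                               lr = 1e-4, opt = NULL, maxLen = NULL,
                               baseline = NULL, seed = NULL) {
  if (is.null(opt)) opt <- adamInit(gen@params)
  if (is.null(maxLen)) maxLen <- gen@config$maxLen
  .withSeed(seed, {
    sampled <- sampleSequences(gen, genBatch, maxLen = maxLen,
                               keepStates = TRUE)
    qm <- .rolloutQMatrix(gen, disc, sampled, nRollouts, maxLen)
    B <- genBatch
    Tin <- ncol(sampled$ids) - 1L
    Tmax <- maxLen - 1L   # generation horizon: fixed 1/T normalization so
                          # the estimator stays proportional-unbiased for
                          # the expected-reward gradient under variable
                          # sequence lengths (and exactly zero-mean when
                          # the reward is constant)
    weights <- matrix(0, B, Tin)
    for (b in seq_len(B)) {
      Tb <- qm$Tacts[b]
      qb <- qm$Q[b, seq_len(Tb)]
      if (!is.null(baseline)) qb <- qb - baseline
      weights[b, seq_len(Tb)] <- qb / Tmax
    }
    # ascend J: minimize -J, i.e. take the gradient of the weighted NLL
    # with positive weights Q/T and negate into the descent convention
    grads <- .weightedGrad(gen, sampled$ids, weights / B)$grads
    ascent <- .paramsScale(grads, -1)   # gradient of +J
    if (lr > 0) {
      upd <- adamStep(gen@params, grads, opt, lr)
      gen@params <- upd$params
      opt <- upd$opt
    }
    list(gen = gen, opt = opt,
         meanReward = mean(qm$fullScore),
         meanQ = mean(qm$Q[cbind(seq_len(B), pmax(qm$Tacts, 1L))]),
         gradient = ascent)
  })
}

#' Alternating adversarial training with progressive augmentation
#'
#' Each step: one policy-gradient update of the generator, one likelihood
#' fine-tuning step of the generator on real samples (progressive
#' augmentation: the generated "fake" pool drifts toward the drug-like set,
#' steadily hardening the discriminator's task), then one discriminator
#' update on a balanced fake/real batch. Optionally stops early when the
#' window-smoothed discriminator loss no longer decreases after a burn-in
#' ("after stabilization").
#'
#' @param gen pretrained \linkS4class{SmilesGenerator}.
#' @param disc pretrained \linkS4class{SmilesDiscriminator}.
#' @param realIds encoded pool of real (positive) sequences.
#' @param nSteps maximum adversarial steps (0 returns the models unchanged).
#' @param genBatch sequences sampled per generator update.
#' @param nRollouts rollouts per action value.
#' @param genLr,discLr learning rates.
#' @param discHalfBatch real and fake sequences per discriminator update
#'   (the batch is discHalfBatch + discHalfBatch).
#' @param augment enable the progressive-augmentation likelihood step.
#' @param augmentBatch real samples per augmentation step.
#' @param earlyStop monitor the smoothed discriminator loss.
#' @param burnIn steps before monitoring starts.
#' @param windowSize smoothing window ("epoch-sized") for the monitor.
#' @param maxLen encoded capacity (default: generator's; real sequences are
#'   padded or must fit).
#' @param baselineDecay when non-NULL, maintain a moving-average reward
#'   baseline with this decay (off by default: plain REINFORCE).
#' @param checkpointEvery write generator/discriminator checkpoints every
#'   this many steps into \code{checkpointDir} (NULL: never).
#' @param checkpointDir directory for checkpoints.
#' @param seed RNG seed governing the whole run.
#' @param verbose print progress every 25 steps.
#' @return list: final \code{gen}, \code{disc}, and \code{history} — a
#'   data.frame with one row per executed step (step, genReward, discLoss,
#'   meanQ).
#' @export
adversarialTrain <- function(gen, disc, realIds, nSteps = 400L,
                             genBatch = 64L, nRollouts = 16L,
                             genLr = 1e-4, discLr = 1e-4,
                             discHalfBatch = 64L,
                             augment = TRUE, augmentBatch = 64L,
                             earlyStop = TRUE, burnIn = 100L,
                             windowSize = 50L, maxLen = NULL,
                             baselineDecay = NULL,
                             checkpointEvery = NULL, checkpointDir = NULL,
                             seed = NULL, verbose = FALSE) {
  if (is.null(maxLen)) maxLen <- gen@config$maxLen
  stopifnot(ncol(realIds) <= maxLen)
  if (ncol(realIds) < maxLen)
    realIds <- cbind(realIds,
                     matrix(gen@vocab@padId, nrow(realIds),
                            maxLen - ncol(realIds)))
  history <- data.frame(step = integer(), genReward = numeric(),
                        discLoss = numeric(), meanQ = numeric())
  if (nSteps == 0L)
    return(list(gen = gen, disc = disc, history = history))
  .withSeed(seed, {
    genOpt <- adamInit(gen@params)
    mleOpt <- adamInit(gen@params)
    discOpt <- adamInit(disc@params)
    baseline <- NULL
    bestSmooth <- Inf
    smoothHist <- numeric()
    for (step in seq_len(nSteps)) {
      pg <- policyGradientStep(gen, disc, genBatch = genBatch,
                               nRollouts = nRollouts, lr = genLr,
                               opt = genOpt, maxLen = maxLen,
                               baseline = baseline)
      gen <- pg$gen; genOpt <- pg$opt
      if (!is.null(baselineDecay)) {
        baseline <- if (is.null(baseline)) pg$meanReward
                    else baselineDecay * baseline +
                      (1 - baselineDecay) * pg$meanReward
      }
      if (augment) {
        take <- sample.int(nrow(realIds), min(augmentBatch, nrow(realIds)))
        ms <- mleStep(gen, realIds[take, , drop = FALSE], lr = genLr,
                      opt = mleOpt, train = FALSE)
        gen <- ms$gen; mleOpt <- ms$opt
      }
      fake <- sampleSequences(gen, discHalfBatch, maxLen = maxLen)
      takeR <- sample.int(nrow(realIds), min(discHalfBatch, nrow(realIds)))
      ds <- discriminatorStep(disc, fakeIds = fake$ids,
                              realIds = realIds[takeR, , drop = FALSE],
                              lr = discLr, opt = discOpt)
      disc <- ds$disc; discOpt <- ds$opt
      history <- rbind(history, data.frame(
        step = step, genReward = pg$meanReward, discLoss = ds$loss,
        meanQ = pg$meanQ))
      if (verbose && step %% 25L == 0L)
        message(sprintf("step %d reward %.3f discLoss %.3f", step,
                        pg$meanReward, ds$loss))
      if (!is.null(checkpointEvery) && step %% checkpointEvery == 0L &&
          !is.null(checkpointDir)) {
        saveModel(gen, file.path(checkpointDir,
                                 sprintf("generator_step%04d.rds", step)))
        saveModel(disc, file.path(checkpointDir,
                                  sprintf("discriminator_step%04d.rds", step)))
      }
      if (earlyStop && step > burnIn && step >= windowSize) {
        smooth <- mean(utils::tail(history$discLoss, windowSize))
        smoothHist <- c(smoothHist, smooth)
        if (smooth < bestSmooth) {
          bestSmooth <- smooth
        } else if (length(smoothHist) > windowSize) {
          recent <- utils::tail(smoothHist, windowSize)
          if (all(recent >= bestSmooth)) break
        }
      }
    }
    list(gen = gen, disc = disc, history = history)
  })
}
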