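# Convolutional sequence classifier: token embeddings -> multiscale 1-D
# convolutions -> ReLU -> pad-masked max-pooling -> concatenation -> linear
# head -> logistic probability. Windows overlapping pad positions are
# excluded from pooling so the score is invariant to trailing padding.

#' Create a SMILES discriminator
#'
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param embeddingDim embedding size k (rows of the T x k input matrix).
#' @param windows integer window sizes of the kernel bank (sorted
#'   internally; scores do not depend on the order given).
#' @param nFilters filters per window size (scalar or one per window).
#' @param dropout dropout on the pooled feature vector during training.
#' @param seed RNG seed for initialization.
#' @param initScale Gaussian initializer scale.
#' @return a \linkS4class{SmilesDiscriminator}.
#' @export
newDiscriminator <- function(vocab, embeddingDim = 128L, windows = 1:10,
                             nFilters = 100L, dropout = 0.1, seed = NULL,
                             initScale = 0.08) {
  V <- vocabSize(vocab)
  windows <- sort(as.integer(windows))
  nFilters <- rep_len(as.integer(nFilters), length(windows))
  .withSeed(seed, {
    E <- matrix(stats::rnorm(V * embeddingDim, sd = initScale), V, embeddingDim)
    conv <- Map(function(l, f)
      list(W = matrix(stats::rnorm(l * embeddingDim * f, sd = initScale),
                      l * embeddingDim, f),
           b = numeric(f)),
      windows, nFilters)
    head <- list(w = stats::rnorm(sum(nFilters), sd = initScale), b = 0)
    new("SmilesDiscriminator",
        params = list(E = E, conv = conv, head = head),
        config = list(embeddingDim = as.integer(embeddingDim),
                      windows = windows, nFilters = nFilters,
                      dropout = dropout),
        vocab = vocab)
  })
}

#' Embed an encoded sequence as a T x k matrix
#'
#' Row t is the embedding row of token w_t; pad positions get the pad
#' embedding row.
#'
#' @param disc a \linkS4class{SmilesDiscriminator}.
#' @param ids integer vector of token ids (one sequence).
#' @return numeric matrix with \code{length(ids)} rows.
#' @export
discEmbed <- function(disc, ids) {
  disc@params$E[as.integer(ids), , drop = FALSE]
}

#' Convolutional feature map for one window size
#'
#' Slides a window of \code{l} rows over the embedded sequence; feature i is
#' \code{act(sum(kernel * emb[i:(i+l-1), ]) + bias)} — the summed
#' element-wise product of the kernel with the window, plus bias, through
#' the nonlinearity.
#'
#' @param emb T x k embedding matrix.
#' @param kernel l x k kernel matrix.
#' @param bias scalar bias.
#' @param act nonlinearity (default ReLU).
#' @return numeric vector of length T - l + 1.
#' @export
featureMap <- function(emb, kernel, bias, act = function(x) pmax(x, 0)) {
  l <- nrow(kernel)
  Tlen <- nrow(emb)
  if (l > Tlen) stop("window size exceeds sequence length")
  vapply(seq_len(Tlen - l + 1L), function(i)
    act(sum(kernel * emb[i:(i + l - 1L), , drop = FALSE]) + bias), 0)
}

# Batched forward. ids: B x T. Returns probabilities and, optionally, the
# cache needed for backward. Pooling is over valid windows only (those not
# extending past the last non-pad position); a window size with no valid
# position contributes zero features.
.discForward <- function(disc, ids, train = FALSE, cache = FALSE) {
  p <- disc@params
  cfg <- disc@config
  B <- nrow(ids)
  Tlen <- ncol(ids)
  k <- cfg$embeddingDim
  lens <- .seqLengths(ids, disc@vocab)
  A <- array(p$E[as.vector(ids), ], dim = c(B, Tlen, k))
  pooled <- NULL
  caches <- if (cache) vector("list", length(cfg$windows)) else NULL
  for (wi in seq_along(cfg$windows)) {
    l <- cfg$windows[[wi]]
    P <- Tlen - l + 1L
    if (P < 1L) {
      f <- cfg$nFilters[[wi]]
      pooled <- cbind(pooled, matrix(0, B, f))
      if (cache) caches[[wi]] <- list(skip = TRUE, f = f)
      next
    }
    Z <- matrix(0, B * P, l * k)
    for (j in seq_len(l))
      Z[, (j - 1L) * k + seq_len(k)] <-
        matrix(A[, j:(j + P - 1L), , drop = FALSE], B * P, k)
    C <- Z %*% p$conv[[wi]]$W
    C <- C + rep(p$conv[[wi]]$b, each = B * P)
    C <- pmax(C, 0)
    # valid window: position + l - 1 <= length  (col-major rows are (b, pos))
    pos <- rep(seq_len(P), each = B)
    valid <- pos + l - 1L <= rep(lens, P)
    C[!valid, ] <- -Inf
    Ca <- array(C, dim = c(B, P, ncol(C)))
    pool <- matrix(0, B, ncol(C))
    arg <- matrix(1L, B, ncol(C))
    for (pp in seq_len(P)) {
      slice <- Ca[, pp, , drop = TRUE]
      if (is.null(dim(slice))) slice <- matrix(slice, B, ncol(C))
      better <- slice > pool | (pp == 1L)
      take <- better & is.finite(slice)
      pool[take] <- slice[take]
      arg[take] <- pp
    }
    pool[!is.finite(pool)] <- 0
    anyValid <- lens >= l
    pool[!anyValid, ] <- 0
    pooled <- cbind(pooled, pool)
    if (cache)
      caches[[wi]] <- list(skip = FALSE, Z = Z, C = Ca, arg = arg,
                           anyValid = anyValid, P = P, l = l)
  }
  mask <- NULL
  feat <- pooled
  if (train && cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(pooled), 1L, 1 - cfg$dropout) /
                     (1 - cfg$dropout), B, ncol(pooled))
    feat <- pooled * mask
  }
  logit <- drop(feat %*% p$head$w) + p$head$b
  prob <- .sigmoid(logit)
  out <- list(prob = prob, logit = logit)
  if (cache)
    out$cache <- list(ids = ids, A = A, caches = caches, pooled = pooled,
                      feat = feat, mask = mask, lens = lens)
  out
}

#' Discriminator probability for encoded sequences
#'
#' Max-pooled multiscale convolution features through the linear head and
#' logistic squashing: the probability that each sequence belongs to the
#' positive (drug/bioactive-like) set. Deterministic (no dropout) and
#' invariant to trailing padding.
#'
#' @param disc a \linkS4class{SmilesDiscriminator}.
#' @param ids encoded id matrix (or vector for one sequence).
#' @return numeric vector of probabilities strictly inside (0, 1).
#' @export
discriminatorScore <- function(disc, ids) {
  if (is.null(dim(ids))) ids <- matrix(ids, nrow = 1L)
  storage.mode(ids) <- "integer"
  # trailing all-pad columns cannot affect the score; trim them for speed
  keep <- max(.seqLengths(ids, disc@vocab))
  if (keep < ncol(ids)) ids <- ids[, seq_len(keep), drop = FALSE]
  p <- disc@params
  scoreBlock <- function(m)
    .cppDiscScore(p$E, p$conv, as.integer(disc@config$windows),
                  p$head$w, p$head$b, m, disc@vocab@endId)
  n <- nrow(ids)
  block <- 4096L   # bound the im2col workspace
  if (n <= block) return(drop(scoreBlock(ids)))
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    take <- start:min(start + block - 1L, n)
    out[take] <- scoreBlock(ids[take, , drop = FALSE])
  }
  out
}

# Backward pass of dLoss/dlogit -> parameter gradients.
.discBackward <- function(disc, fwCache, dlogit) {
  p <- disc@params
  cfg <- disc@config
  cc <- fwCache$cache
  B <- length(dlogit)
  k <- cfg$embeddingDim
  Tlen <- ncol(cc$ids)
  dfeat <- outer(dlogit, p$head$w)
  gHw <- colSums(cc$feat * dlogit)
  gHb <- sum(dlogit)
  if (!is.null(cc$mask)) dfeat <- dfeat * cc$mask
  dA <- array(0, dim = dim(cc$A))
  gConv <- vector("list", length(cfg$windows))
  off <- 0L
  for (wi in seq_along(cfg$windows)) {
    f <- cfg$nFilters[[wi]]
    cols <- off + seq_len(f)
    off <- off + f
    wc <- cc$caches[[wi]]
    if (isTRUE(wc$skip)) {
      gConv[[wi]] <- .zerosLike(p$conv[[wi]])
      next
    }
    dpool <- dfeat[, cols, drop = FALSE]
    dpool[!wc$anyValid, ] <- 0
    P <- wc$P; l <- wc$l
    # route pooled gradients to their argmax positions; ReLU gate via C > 0
    dC <- matrix(0, B * P, f)
    rowIdx <- matrix(seq_len(B), B, f) + (wc$arg - 1L) * B
    Cact <- matrix(wc$C, B * P, f)
    sel <- cbind(as.vector(rowIdx), as.vector(col(dpool)))
    vals <- as.vector(dpool)
    keep <- vals != 0
    if (any(keep)) {
      sel <- sel[keep, , drop = FALSE]
      vals <- vals[keep]
      gate <- Cact[sel] > 0
      dC[sel[gate, , drop = FALSE]] <- dC[sel[gate, , drop = FALSE]] +
        vals[gate]
    }
    gW <- crossprod(wc$Z, dC)
    gb <- colSums(dC)
    dZ <- dC %*% t(p$conv[[wi]]$W)
    for (j in seq_len(l)) {
      dSlice <- array(dZ[, (j - 1L) * k + seq_len(k)], dim = c(B, P, k))
      dA[, j:(j + P - 1L), ] <- dA[, j:(j + P - 1L), , drop = FALSE] + dSlice
    }
    gConv[[wi]] <- list(W = gW, b = gb)
  }
  gE <- matrix(0, nrow(p$E), k)
  dAmat <- matrix(dA, B * Tlen, k)
  rs <- rowsum(dAmat, group = as.vector(cc$ids))
  tid <- as.integer(rownames(rs))
  gE[tid, ] <- gE[tid, , drop = FALSE] + rs
  list(E = gE, conv = gConv, head = list(w = gHw, b = gHb))
}

#' Adversarial discriminator loss (closed two-term form)
#'
#' \code{mean(-log p_real) + mean(-log(1 - p_fake))}: the sum of the
#' positive-set and generated-set cross-entropy terms. A perfect
#' discriminator scores 0; one stuck at 0.5 scores \code{2 log 2}.
#'
#' @param pReal probabilities assigned to real (positive) sequences.
#' @param pFake probabilities assigned to generated sequences.
#' @return scalar loss.
#' @export
discriminatorLoss <- function(pReal, pFake) {
  eps <- 1e-12
  mean(-log(pmax(pReal, eps))) + mean(-log(pmax(1 - pFake, eps)))
}

#' One adversarial discriminator update
#'
#' A single Adam step on [discriminatorLoss()] over a batch of real and
#' generated (fake) encoded sequences.
#'
#' @param disc a \linkS4class{SmilesDiscriminator}.
#' @param fakeIds,realIds encoded batches (typically 64 + 64).
#' @param lr learning rate.
#' @param opt Adam state (fresh when \code{NULL}).
#' @param train apply feature dropout.
#' @return list: updated \code{disc}, \code{opt}, pre-update \code{loss}.
#' @export
discriminatorStep <- function(disc, fakeIds, realIds, lr, opt = NULL,
                              train = TRUE) {
  stopifnot(nrow(fakeIds) > 0L, nrow(realIds) > 0L)
  if (is.null(opt)) opt <- adamInit(disc@params)
  Tlen <- max(ncol(fakeIds), ncol(realIds))
  padTo <- function(m) {
    if (ncol(m) < Tlen)
      m <- cbind(m, matrix(disc@vocab@padId, nrow(m), Tlen - ncol(m)))
    m
  }
  ids <- rbind(padTo(realIds), padTo(fakeIds))
  y <- c(rep(1, nrow(realIds)), rep(0, nrow(fakeIds)))
  fw <- .discForward(disc, ids, train = train, cache = TRUE)
  loss <- discriminatorLoss(fw$prob[y == 1], fw$prob[y == 0])
  # d loss / d logit with per-class 1/n weights
  wgt <- ifelse(y == 1, 1 / sum(y == 1), 1 / sum(y == 0))
  dlogit <- (fw$prob - y) * wgt
  grads <- .discBackward(disc, fw, dlogit)
  upd <- adamStep(disc@params, grads, opt, lr)
  disc@params <- upd$params
  list(disc = disc, opt = upd$opt, loss = loss)
}

#' Supervised pretraining of the discriminator
#'
#' Merges positive and negative corpora, splits them stratified 8:1:1 into
#' train / validation / internal-test, and minimizes the two-term
#' cross-entropy with Adam on balanced batches. Stops when the validation
#' loss has not decreased for \code{patience} epochs; the best-validation
#' state is returned together with internal-test accuracy and AUC.
#'
#' @param disc a \linkS4class{SmilesDiscriminator}.
#' @param posIds,negIds encoded positive and negative corpora (non-empty).
#' @param batchSize total sequences per step (half from each class).
#' @param lr learning rate.
#' @param split train/validation/test fractions, summing to 1.
#' @param patience epochs without validation improvement before stopping.
#' @param maxEpochs hard cap.
#' @param seed RNG seed (split, shuffling, dropout).
#' @param verbose print per-epoch losses.
#' @return list: best \code{disc}, \code{history}, \code{testAUC},
#'   \code{testAccuracy}, \code{splitIdx} (per-class index lists).
#' @export
trainDiscriminator <- function(disc, posIds, negIds, batchSize = 128L,
                               lr = 1e-4, split = c(0.8, 0.1, 0.1),
                               patience = 1L, maxEpochs = 20L, seed = NULL,
                               verbose = FALSE) {
  stopifnot(nrow(posIds) > 0L, nrow(negIds) > 0L,
            abs(sum(split) - 1) < 1e-8)
  Tlen <- max(ncol(posIds), ncol(negIds))
  padTo <- function(m) {
    if (ncol(m) < Tlen)
      m <- cbind(m, matrix(disc@vocab@padId, nrow(m), Tlen - ncol(m)))
    m
  }
  posIds <- padTo(posIds); negIds <- padTo(negIds)
  .withSeed(seed, {
    mkSplit <- function(n) {
      ord <- sample.int(n)
      nTr <- round(split[1] * n)
      nVa <- round(split[2] * n)
      list(train = ord[seq_len(nTr)],
           val = ord[nTr + seq_len(nVa)],
           test = ord[(nTr + nVa + 1L):n])
    }
    sp <- mkSplit(nrow(posIds)); sn <- mkSplit(nrow(negIds))
    valLoss <- function(d) {
      pr <- discriminatorScore(d, posIds[sp$val, , drop = FALSE])
      pf <- discriminatorScore(d, negIds[sn$val, , drop = FALSE])
      discriminatorLoss(pr, pf)
    }
    opt <- adamInit(disc@params)
    best <- list(disc = disc, loss = valLoss(disc), epoch = 0L)
    history <- data.frame(epoch = 0L, trainLoss = NA_real_,
                          valLoss = best$loss)
    half <- max(1L, batchSize %/% 2L)
    bad <- 0L
    for (epoch in seq_len(maxEpochs)) {
      po <- sample(sp$train); no <- sample(sn$train)
      nBatch <- max(1L, ceiling(max(length(po), length(no)) / half))
      lossSum <- 0
      for (bi in seq_len(nBatch)) {
        pTake <- po[((bi - 1L) * half) %% length(po) + seq_len(half)]
        nTake <- no[((bi - 1L) * half) %% length(no) + seq_len(half)]
        pTake <- pTake[!is.na(pTake)]; nTake <- nTake[!is.na(nTake)]
        st <- discriminatorStep(disc,
                                fakeIds = negIds[nTake, , drop = FALSE],
                                realIds = posIds[pTake, , drop = FALSE],
                                lr = lr, opt = opt)
        disc <- st$disc; opt <- st$opt
        lossSum <- lossSum + st$loss
      }
      vl <- valLoss(disc)
      history <- rbind(history, data.frame(
        epoch = epoch, trainLoss = lossSum / nBatch, valLoss = vl))
      if (verbose)
        message(sprintf("epoch %d train %.4f val %.4f", epoch,
                        lossSum / nBatch, vl))
      if (vl < best$loss) {
        best <- list(disc = disc, loss = vl, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    disc <- best$disc
    prT <- discriminatorScore(disc, posIds[sp$test, , drop = FALSE])
    pfT <- discriminatorScore(disc, negIds[sn$test, , drop = FALSE])
    auc <- .binaryAuc(c(prT, pfT),
                      c(rep(1L, length(prT)), rep(0L, length(pfT))))
    acc <- mean(c(prT > 0.5, pfT <= 0.5))
    list(disc = disc, history = history, bestEpoch = best$epoch,
         testAUC = auc, testAccuracy = acc,
         splitIdx = list(pos = sp, neg = sn))
  })
}

# AUC via pROC (direction fixed so that larger scores mean positive).
.binaryAuc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}
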