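test_that("embedding matrix has one row per position and shares token rows", {
  tw <- makeToyWorld()
  v <- tw$vocab
  ids <- c(v@startId, tokenToId(v, c("C", "O", "C")), v@endId, v@padId)
  emb <- discEmbed(tw$disc, ids)
  expect_identical(nrow(emb), length(ids))
  expect_identical(emb[2, ], emb[4, ])                      # shared token row
  expect_identical(emb[6, ], tw$disc@params$E[v@padId, ])   # pad row
})

test_that("feature maps match hand arithmetic and degenerate windows", {
  emb <- rbind(c(1, 2), c(3, -1), c(0.5, 0))     # T = 3, k = 2
  kernel <- rbind(c(1, -1), c(0.5, 2))           # l = 2
  fm <- featureMap(emb, kernel, bias = 0.25)
  # window 1: 1*1 + 2*(-1) + 3*0.5 + (-1)*2 + 0.25 = -1.25 -> ReLU 0
  # window 2: 3*1 + (-1)*(-1) + 0.5*0.5 + 0*2 + 0.25 = 4.5
  expect_equal(fm, c(0, 4.5), tolerance = 1e-12)
  expect_length(featureMap(emb, matrix(1, 3, 2), 0), 1L)   # l = T
  expect_identical(featureMap(emb, matrix(0, 2, 2), 0), c(0, 0))
  expect_error(featureMap(emb, matrix(0, 4, 2), 0), "window")
})

test_that("scores live strictly inside (0,1) and ignore trailing pads", {
  fx <- studyFixtures()
  disc <- newDiscriminator(fx$vocab, embeddingDim = 16L, windows = 1:4,
                           nFilters = 8L, seed = 19)
  ids <- fx$negIds[1:20, ]
  p <- discriminatorScore(disc, ids)
  expect_true(all(p > 0 & p < 1))
  more <- cbind(ids, matrix(fx$vocab@padId, nrow(ids), 7L))
  expect_identical(discriminatorScore(disc, more), p)
})

test_that("window order in the configuration does not change scores", {
  fx <- studyFixtures()
  d1 <- newDiscriminator(fx$vocab, embeddingDim = 8L, windows = c(1, 2, 3),
                         nFilters = 4L, seed = 20)
  d2 <- newDiscriminator(fx$vocab, embeddingDim = 8L, windows = c(3, 1, 2),
                         nFilters = 4L, seed = 20)
  ids <- fx$negIds[1:10, ]
  expect_identical(discriminatorScore(d1, ids), discriminatorScore(d2, ids))
})

test_that("discriminator gradients match finite differences", {
  tw <- makeToyWorld()
  disc <- newDiscriminator(tw$vocab, embeddingDim = 4L, windows = c(1L, 2L),
                           nFilters = 3L, dropout = 0, seed = 21,
                           initScale = 0.4)
  ids <- sampleSequences(tw$gen, 6, seed = 22)$ids
  y <- c(1, 0, 1, 0, 1, 0)
  lossOf <- function(params) {
    d2 <- disc; d2@params <- params
    p <- discriminatorScore(d2, ids)
    discriminatorLoss(p[y == 1], p[y == 0])
  }
  fw <- MolTriageGAN:::.discForward(disc, ids, cache = TRUE)
  wgt <- ifelse(y == 1, 1 / sum(y == 1), 1 / sum(y == 0))
  g <- MolTriageGAN:::.discBackward(disc, fw, (fw$prob - y) * wgt)
  p0 <- disc@params
  eps <- 1e-6
  set.seed(23)
  for (probe in 1:8) {
    part <- sample(c("E", "head", "conv1", "conv2"), 1L)
    get <- switch(part, E = function(q) q$E, head = function(q) q$head$w,
                  conv1 = function(q) q$conv[[1]]$W,
                  conv2 = function(q) q$conv[[2]]$W)
    set <- switch(part,
      E = function(q, i, e) { q$E[i] <- q$E[i] + e; q },
      head = function(q, i, e) { q$head$w[i] <- q$head$w[i] + e; q },
      conv1 = function(q, i, e) { q$conv[[1]]$W[i] <- q$conv[[1]]$W[i] + e; q },
      conv2 = function(q, i, e) { q$conv[[2]]$W[i] <- q$conv[[2]]$W[i] + e; q })
    garr <- switch(part, E = g$E, head = g$head$w,
                   conv1 = g$conv[[1]]$W, conv2 = g$conv[[2]]$W)
    i <- sample(length(get(p0)), 1L)
    fd <- (lossOf(set(p0, i, eps)) - lossOf(set(p0, i, -eps))) / (2 * eps)
    expect_equal(garr[i], fd, tolerance = 1e-4)
  }
})

test_that("the two-term loss has its closed forms", {
  expect_equal(discriminatorLoss(rep(1, 4), rep(0, 4)), 0, tolerance = 1e-9)
  expect_equal(discriminatorLoss(rep(0.5, 4), rep(0.5, 4)), 2 * log(2),
               tolerance = 1e-9)
})

test_that("training separates the two grammars at high AUC", {
  tr <- studyDiscriminator()
  expect_gte(tr$testAUC, 0.95)
  expect_gte(tr$testAccuracy, 0.9)
  fx <- studyFixtures()
  pr <- discriminatorScore(tr$disc, fx$posIds[1:100, ])
  pf <- discriminatorScore(tr$disc, fx$negIds[1:100, ])
  expect_gt(mean(pr), mean(pf))
})

test_that("shuffled labels give chance-level internal-test AUC", {
  fx <- studyFixtures()
  pool <- rbind(fx$posIds[1:250, ], fx$negIds[1:250, ])
  set.seed(24)
  ord <- sample.int(500L)
  shamPos <- pool[ord[1:250], ]
  shamNeg <- pool[ord[251:500], ]
  disc <- newDiscriminator(fx$vocab, embeddingDim = 16L, windows = 1:3,
                           nFilters = 8L, seed = 25)
  tr <- trainDiscriminator(disc, shamPos, shamNeg, batchSize = 128L,
                           lr = 1e-3, patience = 1L, maxEpochs = 3L,
                           seed = 26)
  expect_lt(abs(tr$testAUC - 0.5), 0.12)
})

test_that("doubling every record leaves the split proportions intact", {
  fx <- studyFixtures()
  disc <- newDiscriminator(fx$vocab, embeddingDim = 8L, windows = 1:2,
                           nFilters = 4L, seed = 27)
  tr1 <- trainDiscriminator(disc, fx$posIds[1:100, ], fx$negIds[1:100, ],
                            maxEpochs = 1L, seed = 28)
  tr2 <- trainDiscriminator(disc, fx$posIds[rep(1:100, 2L), ],
                            fx$negIds[rep(1:100, 2L), ],
                            maxEpochs = 1L, seed = 28)
  for (cls in c("pos", "neg")) {
    n1 <- lengths(tr1$splitIdx[[cls]])
    n2 <- lengths(tr2$splitIdx[[cls]])
    expect_identical(unname(n2), unname(2L * n1))
  }
})
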