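test_that("rollouts of a complete prefix are N padded copies", {
  tw <- makeToyWorld()
  v <- tw$vocab
  full <- c(v@startId, tokenToId(v, c("C", "O")), v@endId)
  ro <- mcRollout(tw$gen, full, 5L)
  expect_identical(nrow(ro), 5L)
  expect_true(all(apply(ro, 1L, function(r)
    all(r == c(full, v@padId)))))
})

test_that("a deterministic policy gives identical completions", {
  tw <- makeToyWorld()
  gen <- tw$gen
  v <- tw$vocab
  # one-hot-ish policy: always emit C then end is unreachable until cap
  gen@params$M[] <- 0
  gen@params$cvec[] <- -60
  gen@params$cvec[tokenToId(v, "C")] <- 60
  ro <- mcRollout(gen, c(v@startId, tokenToId(v, "C")), 7L, seed = 30)
  expect_identical(nrow(unique(ro)), 1L)
})

test_that("action values of terminal actions equal the score bitwise", {
  tw <- makeToyWorld()
  v <- tw$vocab
  prefix <- c(v@startId, tokenToId(v, c("C", "O")))
  qv <- qValue(tw$gen, tw$disc, prefix, v@endId)
  full <- matrix(c(prefix, v@endId, v@padId), 1L)
  expect_identical(qv$value, discriminatorScore(tw$disc, full)[1L])
  expect_true(qv$terminal)
  # capacity-reaching action is terminal too
  prefix3 <- c(v@startId, tokenToId(v, c("C", "O", "C")))
  qv3 <- qValue(tw$gen, tw$disc, prefix3, tokenToId(v, "C"))
  expect_true(qv3$terminal)
})

test_that("a constant discriminator yields Q = 0.5 everywhere", {
  tw <- makeToyWorld()
  d0 <- tw$disc
  d0@params$head$w[] <- 0
  d0@params$head$b <- 0
  v <- tw$vocab
  for (prefix in list(v@startId, c(v@startId, tokenToId(v, "C")))) {
    for (a in seq_len(vocabSize(v))) {
      qv <- qValue(tw$gen, d0, prefix, a, nRollouts = 3L, seed = 31)
      expect_identical(qv$value, 0.5)
    }
  }
})

test_that("policy-gradient step with lr = 0 changes nothing but reports", {
  tw <- makeToyWorld()
  pg <- policyGradientStep(tw$gen, tw$disc, genBatch = 16L, nRollouts = 4L,
                           lr = 0, seed = 32)
  expect_identical(pg$gen@params, tw$gen@params)
  expect_true(pg$meanReward > 0 && pg$meanReward < 1)
  expect_gt(paramNorm(pg$gradient), 0)
})

test_that("one discriminator update lowers the loss on a fixed batch", {
  tw <- makeToyWorld()
  disc <- newDiscriminator(tw$vocab, embeddingDim = 4L, windows = c(1L, 2L),
                           nFilters = 3L, dropout = 0, seed = 33,
                           initScale = 0.3)
  real <- sampleSequences(tw$gen, 32L, seed = 34)$ids
  fake <- sampleSequences(tw$gen, 32L, seed = 35)$ids
  st1 <- discriminatorStep(disc, fake, real, lr = 0.05)
  st2 <- discriminatorStep(st1$disc, fake, real, lr = 0.05, opt = st1$opt)
  expect_lt(st2$loss, st1$loss)
})

test_that("zero adversarial steps return the models unchanged", {
  tw <- makeToyWorld()
  real <- sampleSequences(tw$gen, 8L, seed = 36)$ids
  out <- adversarialTrain(tw$gen, tw$disc, real, nSteps = 0L)
  expect_identical(out$gen@params, tw$gen@params)
  expect_identical(out$disc@params, tw$disc@params)
  expect_identical(nrow(out$history), 0L)
})

test_that("history tracks every step and checkpoints reload identically", {
  tw <- makeToyWorld()
  real <- sampleSequences(tw$gen, 32L, seed = 37)$ids
  dir <- tempfile(); dir.create(dir)
  out <- adversarialTrain(tw$gen, tw$disc, real, nSteps = 6L,
                          genBatch = 8L, nRollouts = 2L,
                          discHalfBatch = 8L, earlyStop = FALSE,
                          checkpointEvery = 3L, checkpointDir = dir,
                          seed = 38)
  expect_identical(nrow(out$history), 6L)
  expect_identical(out$history$step, 1:6)
  gfile <- file.path(dir, "generator_step0006.rds")
  dfile <- file.path(dir, "discriminator_step0006.rds")
  expect_true(file.exists(gfile) && file.exists(dfile))
  g2 <- loadModel(gfile)
  d2 <- loadModel(dfile)
  probe <- sampleSequences(out$gen, 10L, seed = 39)
  probe2 <- sampleSequences(g2, 10L, seed = 39)
  expect_identical(probe$ids, probe2$ids)
  expect_identical(discriminatorScore(out$disc, probe$ids),
                   discriminatorScore(d2, probe$ids))
})

test_that("action values stay within [0, 1] during a short run", {
  tw <- makeToyWorld()
  pg <- policyGradientStep(tw$gen, tw$disc, genBatch = 32L, nRollouts = 4L,
                           lr = 1e-3, seed = 40)
  expect_true(pg$meanQ >= 0 && pg$meanQ <= 1)
  expect_true(pg$meanReward >= 0 && pg$meanReward <= 1)
})
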