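test_that("per-step distributions normalize and are deterministic", {
  tw <- makeToyWorld()
  out <- generatorStep(tw$gen, NULL, rep(tw$vocab@startId, 4L))
  expect_equal(rowSums(out$probs), rep(1, 4), tolerance = 1e-6)
  out2 <- generatorStep(tw$gen, NULL, rep(tw$vocab@startId, 4L))
  expect_identical(out$probs, out2$probs)   # bitwise, dropout off
})

test_that("zero output layer gives the uniform distribution", {
  tw <- makeToyWorld()
  gen <- tw$gen
  gen@params$M[] <- 0
  gen@params$cvec[] <- 0
  out <- generatorStep(gen, NULL, tw$vocab@startId)
  expect_equal(unname(drop(out$probs)), rep(1 / 5, 5), tolerance = 1e-12)
})

test_that("sampling respects n = 0, seeds, and forced termination", {
  tw <- makeToyWorld()
  expect_identical(nrow(sampleSequences(tw$gen, 0L)$ids), 0L)
  s1 <- sampleSequences(tw$gen, 50, seed = 11)
  s2 <- sampleSequences(tw$gen, 50, seed = 11)
  expect_identical(s1$ids, s2$ids)
  # forcing p(end | start) ~ 1 gives empty bodies everywhere
  gen <- tw$gen
  gen@params$M[] <- 0
  gen@params$cvec[] <- -50
  gen@params$cvec[tw$vocab@endId] <- 50
  s <- sampleSequences(gen, 20, seed = 12)
  expect_true(all(s$ids[, 2] == tw$vocab@endId))
  expect_true(all(s$terminated))
})

test_that("log-probability has the uniform-policy closed form and ignores pads", {
  tw <- makeToyWorld()
  gen <- tw$gen
  gen@params$M[] <- 0
  gen@params$cvec[] <- 0
  v <- tw$vocab
  ids <- matrix(c(v@startId, tokenToId(v, c("C", "O", "C")), v@endId), 1L)
  expect_equal(sequenceLogProb(gen, ids), 4 * log(1 / 5), tolerance = 1e-12)
  padded <- cbind(ids, matrix(v@padId, 1L, 5L))
  expect_identical(sequenceLogProb(tw$gen, ids),
                   sequenceLogProb(tw$gen, padded))
})

test_that("enumerated sequence probabilities are complete and consistent", {
  tw <- makeToyWorld()
  enum <- enumerateSequences(tw$gen)
  expect_equal(sum(enum$prob), 1, tolerance = 1e-9)
  lp <- sequenceLogProb(tw$gen, enum$ids)
  expect_equal(lp, enum$logProb, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  tw <- makeToyWorld()
  gen <- tw$gen
  ids <- sampleSequences(gen, 4, seed = 13)$ids
  set.seed(14)
  W <- matrix(runif(nrow(ids) * (ncol(ids) - 1L)), nrow(ids))
  g <- MolTriageGAN:::.weightedGrad(gen, ids, W)$grads
  lossOf <- function(params) {
    g2 <- gen; g2@params <- params
    fw2 <- MolTriageGAN:::.weightedGrad(g2, ids, W * 0)
    -sum(W * fw2$logProbTargets)
  }
  p <- gen@params
  eps <- 1e-6
  for (nm in c("E", "M", "cvec")) {
    for (r in 1:3) {
      i <- sample(length(p[[nm]]), 1L)
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
    }
  }
  for (nm in c("W", "U", "b")) {
    i <- sample(length(p$layers[[1]][[nm]]), 1L)
    pp <- p; pp$layers[[1]][[nm]][i] <- pp$layers[[1]][[nm]][i] + eps
    pm <- p; pm$layers[[1]][[nm]][i] <- pm$layers[[1]][[nm]][i] - eps
    fd <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
    expect_equal(g$layers[[1]][[nm]][i], fd, tolerance = 1e-4)
  }
})

test_that("a likelihood step with lr = 0 leaves parameters unchanged", {
  tw <- makeToyWorld()
  ids <- sampleSequences(tw$gen, 8, seed = 15)$ids
  st <- mleStep(tw$gen, ids, lr = 0)
  expect_identical(st$gen@params, tw$gen@params)
})

test_that("repeated likelihood steps on one batch decrease its loss", {
  tw <- makeToyWorld()
  gen <- tw$gen
  ids <- sampleSequences(gen, 16, seed = 16)$ids
  opt <- NULL
  losses <- numeric(6)
  for (k in 1:6) {
    st <- mleStep(gen, ids, lr = 0.02, opt = opt, train = FALSE)
    gen <- st$gen; opt <- st$opt
    losses[k] <- st$loss
  }
  expect_lt(losses[6], losses[1])
  expect_true(all(diff(losses) < 1e-8))  # monotone over the first steps
})

test_that("overfitting a single repeated sequence drives its NLL below 0.1", {
  vocab <- newVocabulary(c("C", "O", "N"))
  gen <- newGenerator(vocab, embeddingDim = 8L, hiddenDim = 24L,
                      nLayers = 2L, dropout = 0, maxLen = 10L, seed = 17)
  ids <- encodeSmiles("CONOC", vocab, maxLen = 10L)
  batch <- ids[rep(1L, 16L), ]
  opt <- NULL
  for (k in 1:120) {
    st <- mleStep(gen, batch, lr = 0.02, opt = opt, train = FALSE)
    gen <- st$gen; opt <- st$opt
  }
  expect_lt(st$loss, 0.1)
})

test_that("pretraining early-stops and never returns worse than it started", {
  fit <- studyGenerator()
  h <- fit$history
  expect_lte(min(h$valLoss[-1]), h$valLoss[1])
  expect_identical(min(h$valLoss), h$valLoss[fit$bestEpoch + 1L])
  expect_error(
    mlePretrain(studyGenerator()$gen, studyFixtures()$negIds[1:10, ],
                studyFixtures()$negIds[0, , drop = FALSE]),
    "validation")
})

test_that("the pretrained policy separates its grammar from the other one", {
  fx <- studyFixtures()
  gen <- studyGenerator()$gen
  heldOut <- fx$negIds[2001:2200, ]
  outGrammar <- fx$posIds[1:200, ]
  expect_gt(mean(sequenceLogProb(gen, heldOut)),
            mean(sequenceLogProb(gen, outGrammar)))
})

test_that("sample frequencies match enumerated probabilities (50k draws)", {
  tw <- makeToyWorld()
  enum <- enumerateSequences(tw$gen)
  n <- 50000L
  s <- sampleSequences(tw$gen, n, seed = 18)
  key <- apply(s$ids, 1L, paste, collapse = ",")
  ekey <- apply(enum$ids, 1L, paste, collapse = ",")
  counts <- table(key)
  expect_true(all(names(counts) %in% ekey))  # every sample is enumerated
  # 3-sigma multinomial band for the non-negligible outcomes
  big <- which(enum$prob > 2e-3)
  for (i in big) {
    obs <- if (ekey[i] %in% names(counts)) counts[[ekey[i]]] else 0L
    sigma <- sqrt(n * enum$prob[i] * (1 - enum$prob[i]))
    expect_lt(abs(obs - n * enum$prob[i]), 3 * sigma + 1e-9)
  }
})
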