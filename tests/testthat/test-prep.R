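test_that("element whitelist accepts organic subset and rejects others", {
  expect_true(checkElements("c1ccccc1"))
  expect_false(checkElements("C[Si](C)C"))
  expect_true(checkElements("ClCCBr"))
  expect_true(is.na(checkElements("not_a_smiles(((")))
})

test_that("isotope labels are detected", {
  expect_true(checkIsotopes("CCO"))
  expect_false(checkIsotopes("[13CH4]"))
  expect_false(checkIsotopes("[2H]OC"))
})

test_that("size rules fire in order with strict thresholds", {
  expect_identical(checkSizeRules("CO"), "atoms")
  expect_identical(checkSizeRules("CCCCCC"), "chain")  # run of 6 > 4
  expect_identical(checkSizeRules("CCCC", minAtoms = 1L), "none")  # run of 4
  # strict molecular-weight boundary, probed via the threshold knob on a
  # molecule of known weight (ethanol, 46.06844 Da)
  mw <- molWeights("CCO")
  expect_identical(checkSizeRules("CCO", minAtoms = 1L, maxMw = mw), "none")
  expect_identical(checkSizeRules("CCO", minAtoms = 1L, maxMw = mw - 1e-3),
                   "mw")
  # hydroxyl counting: glycerol has 3, under the default threshold
  expect_identical(checkSizeRules("OCC(O)CO", minAtoms = 1L), "none")
  expect_identical(checkSizeRules("OCC(O)CO", minAtoms = 1L,
                                  maxHydroxyls = 2L), "hydroxyl")
  # hydrogens count only when asked
  expect_identical(checkSizeRules("CCO"), "atoms")          # 3 heavy
  expect_identical(checkSizeRules("CCO", countHydrogens = TRUE,
                                  minAtoms = 9L), "none")   # 9 atoms with H
})

test_that("canonicalization unifies spellings, keeps stereo, is idempotent", {
  expect_identical(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  can <- canonicalizeSmiles("C[C@H](N)O")
  expect_match(can, "@")
  expect_identical(canonicalizeSmiles(can), can)
  expect_true(is.na(canonicalizeSmiles("garbage(((")))
})

test_that("corpus preprocessing keeps order, conserves counts, is idempotent", {
  base <- makeNegativeGrammar(20, seed = 41)
  corpus <- c(base[1:10], base[1], "CO", base[11:20])  # a duplicate + tiny
  res <- preprocessSmiles(corpus)
  expect_identical(sum(res$report), length(corpus))
  expect_identical(unname(res$report["duplicate"]), 1L)
  expect_identical(unname(res$report["atoms"]), 1L)
  expect_identical(unname(res$report["survivors"]), 20L)
  # order stability: survivors appear in input order
  expect_identical(res$survivors,
                   res$records$canonical_smiles[
                     res$records$rejection_reason == "none"])
  # idempotence
  res2 <- preprocessSmiles(res$survivors)
  expect_identical(res2$survivors, res$survivors)
  expect_identical(unname(res2$report["survivors"]), 20L)
  expect_true(all(res2$records$rejection_reason == "none"))
  # survivors round-trip through canonicalization unchanged
  expect_identical(canonicalizeSmiles(res$survivors), res$survivors)
})

test_that("empty input yields empty output and an all-zero ledger", {
  res <- preprocessSmiles(character())
  expect_identical(length(res$survivors), 0L)
  expect_identical(sum(res$report), 0L)
})

test_that("out-of-vocabulary removal works when a vocabulary is supplied", {
  vocab <- buildVocabulary(c("CCCCOCCC", "CCOCCNCC"))
  res <- preprocessSmiles(c("CCCOCCCOCC", "ClCCCOCCCOCC"), vocab = vocab)
  expect_identical(unname(res$report["survivors"]), 1L)
  expect_identical(unname(res$report["oov"]), 1L)
  expect_identical(as.character(res$records$rejection_reason[2]), "oov")
})

test_that("smiles files round-trip with optional ids", {
  path <- tempfile(fileext = ".smi")
  writeSmilesFile(c("CCO", "c1ccccc1"), path, ids = c("a", "b"))
  df <- readSmilesFile(path)
  expect_identical(df$smiles, c("CCO", "c1ccccc1"))
  expect_identical(df$id, c("a", "b"))
})
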