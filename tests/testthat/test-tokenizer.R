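test_that("tokenization follows the halogen digraph and bracket-atom rules", {
  expect_identical(tokenizeSmiles("ClCBr"), c("L", "C", "R"))
  expect_identical(tokenizeSmiles("C[C@H](N)O"),
                   c("C", "[C@H]", "(", "N", ")", "O"))
  expect_identical(tokenizeSmiles("O=C(O)c1ccccc1"),
                   c("O", "=", "C", "(", "O", ")", "c", "1",
                     "c", "c", "c", "c", "c", "1"))
  # all eight multi-character bracket atoms are single tokens
  brackets <- c("[C@H]", "[C@@H]", "[nH]", "[C@@]", "[C@]",
                "[S@]", "[S@@]", "[H]")
  for (b in brackets)
    expect_identical(tokenizeSmiles(paste0("C", b))[2], b)
})

test_that("unknown bracket atoms raise an out-of-vocabulary error naming the span", {
  err <- tryCatch(tokenizeSmiles("C[Si](C)C"), error = identity)
  expect_s3_class(err, "oov_token_error")
  expect_match(conditionMessage(err), "\\[Si\\]")
  expect_error(tokenizeSmiles("C[unclosed"), class = "oov_token_error")
})

test_that("detokenize inverts tokenize, including on empty input", {
  expect_identical(detokenizeSmiles(c("L", "C", "R")), "ClCBr")
  expect_identical(detokenizeSmiles(character()), "")
  expect_error(detokenizeSmiles(c("C", "[Xx]")), "unknown token")
  smis <- c(makeNegativeGrammar(100, seed = 31, unique = "string"),
            makePositiveGrammar(100, seed = 32, unique = "string"))
  for (s in smis)
    expect_identical(detokenizeSmiles(tokenizeSmiles(s)), s)
})

test_that("vocabulary construction is deterministic and minimal", {
  v <- buildVocabulary(c("CC", "CO"))
  expect_identical(sort(vocabTokens(v)),
                   sort(c("<pad>", "<start>", "<end>", "C", "O")))
  corpus <- makePositiveGrammar(50, seed = 33, unique = "string")
  v1 <- buildVocabulary(corpus)
  v2 <- buildVocabulary(rev(corpus))
  expect_identical(vocabTokens(v1), vocabTokens(v2))
  # independent token census: scan with a second implementation of the rules
  oracleTokens <- function(s) {
    out <- character(0)
    while (nzchar(s)) {
      m <- regmatches(s, regexpr(
        "^(\\[[^]]*\\]|Cl|Br|%[0-9][0-9]|.)", s))[[1]]
      out <- c(out, switch(m, Cl = "L", Br = "R", m))
      s <- substr(s, nchar(m) + 1L, nchar(s))
    }
    out
  }
  census <- sort(unique(unlist(lapply(corpus, oracleTokens))))
  expect_identical(setdiff(vocabTokens(v1), c("<pad>", "<start>", "<end>")),
                   census)
})

test_that("encode adds control tokens, pads, round-trips, and checks lengths", {
  v <- buildVocabulary(c("CCO", "C[C@H](N)O"))
  ids <- encodeSmiles("CCO", v, maxLen = 8)
  expect_identical(ncol(ids), 8L)
  expect_identical(unname(ids[1, 1:5]),
                   c(v@startId, tokenToId(v, c("C", "C", "O")), v@endId))
  expect_true(all(ids[1, 6:8] == v@padId))
  expect_identical(decodeSmiles(encodeSmiles("C[C@H](N)O", v), v),
                   "C[C@H](N)O")
  expect_error(encodeSmiles("CCO", v, maxLen = 4), "maxLen")
  expect_error(encodeSmiles("[Se]CC", v), class = "oov_token_error")
})

test_that("vocabulary JSON serialization round-trips", {
  v <- buildVocabulary(makePositiveGrammar(20, seed = 35, unique = "string"))
  path <- tempfile(fileext = ".json")
  writeVocabulary(v, path)
  v2 <- readVocabulary(path)
  expect_identical(vocabTokens(v2), vocabTokens(v))
  expect_identical(controlIds(v2), controlIds(v))
})
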