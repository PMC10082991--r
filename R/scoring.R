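# User-facing triage: score SMILES lists with a trained discriminator,
# rank, and select.

#' Score molecules with a trained discriminator
#'
#' Optionally cleans the input through the preprocessing pipeline (so
#' scoring matches the training distribution), then tokenizes, encodes and
#' scores each molecule. Records that fail (unparseable, rule-rejected,
#' out-of-vocabulary, too long) receive an \code{NA} score and a reason —
#' never a silent drop. Ranks are dense over the scored records, descending
#' by score with ties broken by input order.
#'
#' @param disc a trained \linkS4class{SmilesDiscriminator}.
#' @param smiles character vector of SMILES strings.
#' @param prepFirst run [preprocessSmiles()] first (default TRUE).
#' @param maxLen encoded capacity (default: fit the longest scored record).
#' @return data.frame: \code{input_smiles}, \code{canonical_smiles},
#'   \code{score}, \code{rank}, \code{reason}.
#' @export
scoreMolecules <- function(disc, smiles, prepFirst = TRUE, maxLen = NULL) {
  n <- length(smiles)
  vocab <- disc@vocab
  canon <- smiles
  reason <- rep("none", n)
  if (prepFirst) {
    prep <- preprocessSmiles(smiles, vocab = vocab)
    canon <- prep$records$canonical_smiles
    reason <- as.character(prep$records$rejection_reason)
  }
  score <- rep(NA_real_, n)
  tokLists <- vector("list", n)
  for (i in seq_len(n)) {
    if (reason[i] != "none") next
    toks <- tryCatch(tokenizeSmiles(canon[i]), error = function(e) NULL)
    if (is.null(toks) || !all(toks %in% vocab@tokens)) {
      reason[i] <- "oov"; next
    }
    tokLists[[i]] <- toks
  }
  ok <- which(reason == "none")
  if (length(ok)) {
    need <- max(vapply(tokLists[ok], length, 1L)) + 2L
    if (is.null(maxLen)) maxLen <- need
    tooLong <- ok[vapply(tokLists[ok], length, 1L) + 2L > maxLen]
    reason[tooLong] <- "too_long"
    ok <- setdiff(ok, tooLong)
  }
  if (length(ok)) {
    ids <- encodeTokenLists(tokLists[ok], vocab, maxLen)
    score[ok] <- discriminatorScore(disc, ids)
  }
  rank <- rep(NA_integer_, n)
  if (length(ok)) {
    ord <- ok[order(-score[ok], ok)]   # stable: ties keep input order
    rank[ord] <- seq_along(ord)
  }
  data.frame(input_smiles = smiles, canonical_smiles = canon,
             score = score, rank = rank, reason = reason,
             stringsAsFactors = FALSE)
}

#' Select top-ranked or above-threshold molecules
#'
#' Stable descending sort by score; exactly one of \code{topK} or
#' \code{minScore} must be given.
#'
#' @param scored data.frame from [scoreMolecules()].
#' @param topK keep the K best-scoring records.
#' @param minScore keep records with score at or above the threshold.
#' @return the selected rows, best first.
#' @export
rankAndSelect <- function(scored, topK = NULL, minScore = NULL) {
  stopifnot(nrow(scored) > 0L)
  if (is.null(topK) == is.null(minScore))
    stop("give exactly one of topK or minScore")
  ok <- which(!is.na(scored$score))
  ord <- ok[order(-scored$score[ok], ok)]
  sel <- scored[ord, , drop = FALSE]
  if (!is.null(topK)) utils::head(sel, topK)
  else sel[sel$score >= minScore, , drop = FALSE]
}
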