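# SMILES tokenization. Single characters are tokens except for: the eight
# multi-character bracket atoms treated atomically, the halogen digraphs
# Cl -> L and Br -> R, and %nn ring-closure labels.

.BRACKET_ATOMS <- c("[C@H]", "[C@@H]", "[nH]", "[C@@]", "[C@]",
                    "[S@]", "[S@@]", "[H]")

.oovError <- function(span, smiles) {
  stop(structure(class = c("oov_token_error", "error", "condition"),
                 list(message = sprintf(
                   "out-of-vocabulary span '%s' in SMILES '%s'", span, smiles),
                   call = sys.call(-1), span = span)))
}

#' Tokenize a SMILES string
#'
#' Greedy left-to-right segmentation: the eight bracket atoms
#' \code{[C@@H] [C@@@@H] [nH] [C@@@@] [C@@] [S@@] [S@@@@] [H]} are single
#' tokens, \code{Cl} becomes \code{L} and \code{Br} becomes \code{R},
#' \code{\%nn} ring labels are single tokens, and every other character is
#' its own token. Concatenating the tokens (with L/R mapped back) reproduces
#' the input exactly.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @seealso [detokenizeSmiles()] for the inverse.
#' @examples
#' tokenizeSmiles("ClCBr")        # "L" "C" "R"
#' tokenizeSmiles("C[C@@H](N)O")
#' @export
tokenizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .oovError(substr(smiles, i, n), smiles)
      span <- substr(smiles, i, j)
      if (!(span %in% .BRACKET_ATOMS)) .oovError(span, smiles)
      k <- k + 1L; out[k] <- span
      i <- j + 1L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      k <- k + 1L; out[k] <- "L"; i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      k <- k + 1L; out[k] <- "R"; i <- i + 2L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]", substr(smiles, i + 1L, i + 2L)))
        .oovError(substr(smiles, i, min(n, i + 2L)), smiles)
      k <- k + 1L; out[k] <- substr(smiles, i, i + 2L); i <- i + 3L
    } else {
      k <- k + 1L; out[k] <- ch; i <- i + 1L
    }
  }
  out[seq_len(k)]
}

# Tokens detokenizeSmiles accepts besides the bracket atoms and %nn labels.
.SINGLE_CHARS <- c(LETTERS, letters, 0:9, "(", ")", "=", "#", "-", "+",
                   "/", "\\", ".", ":", "*", "$", "@")

#' Reassemble a SMILES string from tokens
#'
#' Inverse of [tokenizeSmiles()]: maps \code{L} back to \code{Cl} and
#' \code{R} back to \code{Br}, skips control tokens, and concatenates.
#'
#' @param tokens character vector of tokens (control tokens allowed, skipped).
#' @return the SMILES string.
#' @export
detokenizeSmiles <- function(tokens) {
  if (length(tokens) == 0L) return("")
  tokens <- tokens[!(tokens %in% c(.PAD, .START, .END))]
  ok <- tokens %in% .BRACKET_ATOMS | tokens %in% .SINGLE_CHARS |
    grepl("^%[0-9][0-9]$", tokens)
  if (!all(ok)) stop("unknown token(s): ", paste(tokens[!ok], collapse = " "))
  tokens[tokens == "L"] <- "Cl"
  tokens[tokens == "R"] <- "Br"
  paste(tokens, collapse = "")
}

#' Build a token vocabulary from a corpus
#'
#' The vocabulary is the three control tokens followed by every token
#' observed in the corpus, ordered lexicographically in the C locale so the
#' result is identical across runs and corpus orderings.
#'
#' @param corpus character vector of SMILES strings.
#' @return a \linkS4class{TokenVocabulary}.
#' @export
buildVocabulary <- function(corpus) {
  stopifnot(length(corpus) > 0L)
  toks <- unique(unlist(lapply(corpus, tokenizeSmiles), use.names = FALSE))
  toks <- sort(toks, method = "radix")
  newVocabulary(toks)
}

#' Construct a vocabulary from an explicit body-token set
#'
#' @param bodyTokens character vector of body tokens (control tokens are
#'   prepended automatically).
#' @return a \linkS4class{TokenVocabulary}.
#' @export
newVocabulary <- function(bodyTokens) {
  tokens <- c(.PAD, .START, .END, bodyTokens)
  new("TokenVocabulary", tokens = tokens,
      padId = 1L, startId = 2L, endId = 3L)
}

#' Map tokens to ids and back
#'
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param tokens character vector of tokens.
#' @param ids integer vector of token ids.
#' @return integer ids / character tokens.
#' @export
tokenToId <- function(vocab, tokens) {
  ids <- match(tokens, vocab@tokens)
  if (anyNA(ids))
    stop("token(s) not in vocabulary: ",
         paste(unique(tokens[is.na(ids)]), collapse = " "))
  ids
}

#' @rdname tokenToId
#' @export
idToToken <- function(vocab, ids) vocab@tokens[ids]

#' Encode SMILES strings into a padded id matrix
#'
#' Each row is \code{<start>}, the body tokens, \code{<end>}, then
#' \code{<pad>} up to \code{maxLen} columns. Token count + 2 must fit in
#' \code{maxLen}.
#'
#' @param smiles character vector of SMILES strings.
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param maxLen total encoded length (default: longest string + 2).
#' @return integer matrix (n x maxLen) with attribute \code{lengths}, the
#'   per-row count of non-pad positions.
#' @export
encodeSmiles <- function(smiles, vocab, maxLen = NULL) {
  tokLists <- lapply(smiles, tokenizeSmiles)
  encodeTokenLists(tokLists, vocab, maxLen)
}

#' @rdname encodeSmiles
#' @param tokLists list of token character vectors.
#' @export
encodeTokenLists <- function(tokLists, vocab, maxLen = NULL) {
  need <- vapply(tokLists, length, 1L) + 2L
  if (is.null(maxLen)) maxLen <- max(need)
  if (any(need > maxLen))
    stop(sprintf("sequence needs %d positions but maxLen is %d",
                 max(need), maxLen))
  n <- length(tokLists)
  ids <- matrix(vocab@padId, n, maxLen)
  ids[, 1L] <- vocab@startId
  for (i in seq_len(n)) {
    ti <- tokenToId(vocab, tokLists[[i]])
    if (length(ti)) ids[i, 1L + seq_along(ti)] <- ti
    ids[i, length(ti) + 2L] <- vocab@endId
  }
  structure(ids, lengths = need)
}

#' Decode an encoded id matrix back to SMILES
#'
#' Strips control tokens and detokenizes each row.
#'
#' @param ids integer matrix (or vector for one sequence) of token ids.
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @return character vector of SMILES strings.
#' @export
decodeSmiles <- function(ids, vocab) {
  if (is.null(dim(ids))) ids <- matrix(ids, nrow = 1L)
  apply(ids, 1L, function(row) detokenizeSmiles(vocab@tokens[row]))
}

#' Serialize / read a vocabulary as JSON
#'
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param path file path.
#' @export
writeVocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(tokens = vocab@tokens,
         control = list(pad = .PAD, start = .START, end = .END)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tokens <- obj$tokens
  new("TokenVocabulary", tokens = tokens,
      padId = match(.PAD, tokens), startId = match(.START, tokens),
      endId = match(.END, tokens))
}
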