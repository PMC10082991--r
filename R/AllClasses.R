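#' @import methods
NULL

# Reserved control tokens. They are not legal SMILES substrings, so tokenizing
# a molecule can never produce them.
.PAD <- "<pad>"
.START <- "<start>"
.END <- "<end>"

#' Closed token vocabulary for SMILES sequence models
#'
#' Holds the ordered token set shared by the generator and the discriminator:
#' the three control tokens (pad, start, end) followed by the body tokens in
#' a deterministic lexicographic (C-locale) order. Token ids are the 1-based
#' positions in \code{tokens} and are dense \code{1..length(tokens)}.
#'
#' @slot tokens ordered character vector of all tokens, control tokens first.
#' @slot padId,startId,endId integer ids of the control tokens.
#' @export
setClass("TokenVocabulary",
  representation(tokens = "character",
                 padId = "integer", startId = "integer", endId = "integer"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@tokens)) msg <- c(msg, "tokens must be unique")
    sp <- c(object@padId, object@startId, object@endId)
    if (length(unique(sp)) != 3L || any(sp < 1L) || any(sp > length(object@tokens)))
      msg <- c(msg, "control token ids must be three distinct in-range ids")
    if (!all(object@tokens[sp] == c(.PAD, .START, .END)))
      msg <- c(msg, "control ids must point at <pad>, <start>, <end>")
    if (length(msg)) msg else TRUE
  })

#' Autoregressive SMILES policy (stacked-LSTM language model)
#'
#' The theta-parameterized policy G(w_{t+1} | w_1..w_t): an embedding table,
#' a stack of LSTM layers implementing the recurrent update, and a linear
#' softmax head mapping the top hidden state to a distribution over the
#' vocabulary.
#'
#' @slot params list with elements \code{E} (|V| x e embedding), \code{layers}
#'   (list of per-layer lists \code{W}, \code{U}, \code{b}), \code{M}
#'   (H x |V| output weights) and \code{cvec} (length-|V| output bias).
#' @slot config list: \code{embeddingDim}, \code{hiddenDim}, \code{nLayers},
#'   \code{dropout}, \code{maxLen} (encoded length incl. start/end/pad).
#' @slot vocab the \linkS4class{TokenVocabulary} the model is bound to.
#' @export
setClass("SmilesGenerator",
  representation(params = "list", config = "list", vocab = "TokenVocabulary"),
  validity = function(object) {
    p <- object@params; cfg <- object@config
    V <- length(object@vocab@tokens)
    msg <- character()
    if (!identical(dim(p$E), c(V, cfg$embeddingDim)))
      msg <- c(msg, "embedding table must be |V| x embeddingDim")
    if (length(p$layers) != cfg$nLayers)
      msg <- c(msg, "layer count must match config")
    if (!identical(dim(p$M), c(cfg$hiddenDim, V)) || length(p$cvec) != V)
      msg <- c(msg, "output layer must map hiddenDim -> |V|")
    if (length(msg)) msg else TRUE
  })

#' Convolutional SMILES discriminator
#'
#' The phi-parameterized classifier D(W): token embeddings are concatenated
#' into a T x k matrix, convolved with a bank of kernels of several window
#' sizes, ReLU-activated, max-pooled per kernel over pad-free windows,
#' concatenated, and mapped by a linear layer + logistic function to the
#' probability that the sequence belongs to the positive set.
#'
#' @slot params list with \code{E} (|V| x k), \code{conv} (per window size a
#'   list \code{W} ((l*k) x F), \code{b} (F)) and \code{head} (list \code{w},
#'   \code{b}).
#' @slot config list: \code{embeddingDim}, \code{windows} (sorted integer
#'   window sizes), \code{nFilters}, \code{dropout}.
#' @slot vocab the shared \linkS4class{TokenVocabulary}.
#' @export
setClass("SmilesDiscriminator",
  representation(params = "list", config = "list", vocab = "TokenVocabulary"),
  validity = function(object) {
    cfg <- object@config
    msg <- character()
    if (is.unsorted(cfg$windows)) msg <- c(msg, "windows must be sorted")
    if (length(object@params$conv) != length(cfg$windows))
      msg <- c(msg, "one kernel bank per window size")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "TokenVocabulary", function(object) {
  body <- setdiff(object@tokens, c(.PAD, .START, .END))
  cat("TokenVocabulary of", length(object@tokens), "tokens",
      sprintf("(%d body + 3 control)\n", length(body)))
  cat(" body:", paste(body, collapse = " "), "\n")
})

setMethod("show", "SmilesGenerator", function(object) {
  cfg <- object@config
  cat("SmilesGenerator:", sprintf(
    "|V|=%d, embedding %d, %d LSTM layer(s) x %d hidden, dropout %.2f, maxLen %d\n",
    length(object@vocab@tokens), cfg$embeddingDim, cfg$nLayers,
    cfg$hiddenDim, cfg$dropout, cfg$maxLen))
})

setMethod("show", "SmilesDiscriminator", function(object) {
  cfg <- object@config
  cat("SmilesDiscriminator:", sprintf(
    "|V|=%d, embedding %d, windows {%s} x %s filters, dropout %.2f\n",
    length(object@vocab@tokens), cfg$embeddingDim,
    paste(cfg$windows, collapse = ","),
    paste(unique(cfg$nFilters), collapse = "/"), cfg$dropout))
})

#' Accessors
#'
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @return \code{vocabSize} the number of tokens; \code{vocabTokens} the
#'   ordered token vector; \code{controlIds} a named integer vector with the
#'   pad/start/end ids.
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' @rdname vocabSize
#' @export
vocabTokens <- function(vocab) vocab@tokens

#' @rdname vocabSize
#' @export
controlIds <- function(vocab)
  c(pad = vocab@padId, start = vocab@startId, end = vocab@endId)

#' @rdname vocabSize
#' @param x a generator or discriminator.
#' @export
modelVocab <- function(x) x@vocab
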