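# Model persistence: a versioned container holding parameters, config and
# the vocabulary, written with saveRDS. Reloaded models reproduce scores
# and samples bitwise.

.CHECKPOINT_VERSION <- 1L

#' Save / load generator and discriminator checkpoints
#'
#' @param model a \linkS4class{SmilesGenerator} or
#'   \linkS4class{SmilesDiscriminator}.
#' @param path file path (conventionally \code{.rds}).
#' @export
saveModel <- function(model, path) {
  type <- if (is(model, "SmilesGenerator")) "generator"
          else if (is(model, "SmilesDiscriminator")) "discriminator"
          else stop("not a generator or discriminator")
  saveRDS(list(version = .CHECKPOINT_VERSION, type = type,
               params = model@params, config = model@config,
               tokens = model@vocab@tokens), path)
  invisible(path)
}

#' @rdname saveModel
#' @return \code{loadModel}: the restored model object.
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  stopifnot(obj$version == .CHECKPOINT_VERSION)
  vocab <- new("TokenVocabulary", tokens = obj$tokens,
               padId = match(.PAD, obj$tokens),
               startId = match(.START, obj$tokens),
               endId = match(.END, obj$tokens))
  cls <- if (obj$type == "generator") "SmilesGenerator"
         else "SmilesDiscriminator"
  new(cls, params = obj$params, config = obj$config, vocab = vocab)
}
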