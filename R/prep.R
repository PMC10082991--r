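# Six-step corpus cleaning pipeline applied to every corpus before
# tokenization: (1) element whitelist, (2) no isotopes, (3) no duplicates,
# (4) size/composition rules, (5) canonicalization with stereo, (6) optional
# out-of-vocabulary removal.

.REJECTION_LEVELS <- c("none", "parse", "element", "isotope", "duplicate",
                       "chain", "hydroxyl", "mw", "atoms", "oov")

#' Clean a SMILES corpus
#'
#' Applies, in order: element whitelist (H, C, N, O, F, P, S, Cl, Br, I),
#' isotope removal, duplicate removal (on the canonical form, first
#' occurrence kept), size rules (aliphatic chain > 4, hydroxyls > 10,
#' MW > 750 Da, atoms < 10), canonicalization with stereo retained, and —
#' when \code{vocab} is given — removal of molecules whose token stream
#' leaves the vocabulary. Unparseable records get reason \code{parse}.
#' Per-record failures are recorded, never raised; survivors keep their
#' input order.
#'
#' @param smiles character vector of SMILES strings (one molecule each).
#' @param ids optional character vector of record ids.
#' @param vocab optional \linkS4class{TokenVocabulary} for the
#'   out-of-vocabulary rule.
#' @param countHydrogens,chainSmarts,hydroxylSmarts,maxMw,minAtoms,maxHydroxyls
#'   rule knobs, see [checkSizeRules()].
#' @return list with \code{records}, a data.frame (\code{input_smiles},
#'   \code{source_id}, \code{canonical_smiles}, \code{mol_weight},
#'   \code{heavy_atoms}, \code{rejection_reason}); \code{survivors}, the
#'   canonical SMILES that passed; and \code{report}, a named integer vector
#'   of per-reason counts plus \code{survivors}, summing to the input size.
#' @export
preprocessSmiles <- function(smiles, ids = NULL, vocab = NULL,
                             countHydrogens = FALSE,
                             chainSmarts = .DEFAULT_CHAIN_SMARTS,
                             hydroxylSmarts = .DEFAULT_HYDROXYL_SMARTS,
                             maxMw = 750, minAtoms = 10L, maxHydroxyls = 10L) {
  n <- length(smiles)
  if (is.null(ids)) ids <- rep(NA_character_, n)
  reason <- rep("none", n)
  canon <- rep(NA_character_, n)
  mw <- rep(NA_real_, n)
  heavy <- rep(NA_integer_, n)

  sizeReason <- rep("none", n)
  for (i in seq_len(n)) {
    facts <- .molFacts(smiles[i])
    if (is.null(facts)) { reason[i] <- "parse"; next }
    mw[i] <- facts$prop$MW
    heavy[i] <- facts$heavyAtoms
    canon[i] <- facts$prop$cansmi
    if (!all(facts$elements %in% .ALLOWED_ELEMENTS)) {
      reason[i] <- "element"; next
    }
    if (grepl("\\[[0-9]", smiles[i])) { reason[i] <- "isotope"; next }
    mol <- facts$mol
    sizeReason[i] <-
      if (ChemmineOB::smartsSearch_OB(mol, chainSmarts) > 0) "chain"
      else if (ChemmineOB::smartsSearch_OB(mol, hydroxylSmarts) > maxHydroxyls)
        "hydroxyl"
      else if (mw[i] > maxMw) "mw"
      else if ((if (countHydrogens) facts$allAtoms else facts$heavyAtoms)
               < minAtoms) "atoms"
      else "none"
  }

  # step (3): duplicates on the canonical form among records that passed
  # steps (1)-(2), first occurrence kept
  alive <- reason == "none"
  dup <- alive & duplicated(ifelse(alive, canon, NA), incomparables = NA)
  reason[dup] <- "duplicate"

  # step (4): size/composition rules on what remains
  takeSize <- reason == "none" & sizeReason != "none"
  reason[takeSize] <- sizeReason[takeSize]

  # step (6): out-of-vocabulary tokens
  if (!is.null(vocab)) {
    alive <- which(reason == "none")
    for (i in alive) {
      toks <- tryCatch(tokenizeSmiles(canon[i]), error = function(e) NULL)
      if (is.null(toks) || !all(toks %in% vocab@tokens)) reason[i] <- "oov"
    }
  }

  reason <- factor(reason, levels = .REJECTION_LEVELS)
  records <- data.frame(input_smiles = smiles, source_id = ids,
                        canonical_smiles = canon, mol_weight = mw,
                        heavy_atoms = heavy, rejection_reason = reason,
                        stringsAsFactors = FALSE)
  counts <- table(reason)
  report <- c(survivors = unname(counts["none"]),
              counts[setdiff(names(counts), "none")])
  list(records = records,
       survivors = canon[reason == "none"],
       report = report)
}

#' Read / write one-molecule-per-line SMILES files
#'
#' Lines hold a SMILES string and an optional whitespace-separated id.
#'
#' @param path file path.
#' @return \code{readSmilesFile}: data.frame with \code{smiles} and
#'   \code{id} columns.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  data.frame(smiles = vapply(parts, `[`, "", 1L),
             id = vapply(parts, function(p)
               if (length(p) > 1L) p[2L] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' @rdname readSmilesFile
#' @param smiles character vector of SMILES strings.
#' @param ids optional ids written as a second column.
#' @export
writeSmilesFile <- function(smiles, path, ids = NULL) {
  lines <- if (is.null(ids)) smiles else paste(smiles, ids)
  writeLines(lines, path)
  invisible(path)
}
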