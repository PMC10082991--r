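# Thin wrappers around OpenBabel (ChemmineOB). Molecules are parsed once per
# record; invalid SMILES yield NA/NULL rather than errors so corpus-level
# callers can record per-record diagnostics.

.parseMol <- function(smiles) {
  m <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                error = function(e) NULL)
  if (is.null(m) || length(m) != 1L) NULL else m
}

# Element symbols from a Hill-order molecular formula such as "C13H18ClNO2+".
.formulaElements <- function(formula) {
  m <- gregexpr("[A-Z][a-z]?", formula)[[1]]
  if (m[1] == -1L) return(character())
  substring(formula, m, m + attr(m, "match.length") - 1L)
}

.formulaCounts <- function(formula) {
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- substring(formula, m, m + attr(m, "match.length") - 1L)
  el <- sub("[0-9]+$", "", parts)
  ct <- as.integer(sub("^[A-Za-z]+", "", parts))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

.ALLOWED_ELEMENTS <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# Path of five consecutive acyclic sp3 carbons whose heavy neighbours are all
# carbon: matches iff the longest such run exceeds four atoms.
.CHAIN_ATOM <- "[CX4;!R;!$([#6][!#6;!#1])]"
.DEFAULT_CHAIN_SMARTS <- paste(rep(.CHAIN_ATOM, 5L), collapse = "-")
.DEFAULT_HYDROXYL_SMARTS <- "[OX2H1]"

#' Element whitelist check
#'
#' TRUE iff every atom of the molecule is one of H, C, N, O, F, P, S, Cl,
#' Br, I.
#'
#' @param smiles one SMILES string.
#' @return logical; NA if the SMILES does not parse.
#' @export
checkElements <- function(smiles) {
  mol <- .parseMol(smiles)
  if (is.null(mol)) return(NA)
  els <- .formulaElements(ChemmineOB::prop_OB(mol)$formula)
  all(els %in% .ALLOWED_ELEMENTS)
}

#' Isotope-label check
#'
#' TRUE iff no atom carries an explicit isotope label. Isotope labels only
#' occur as digits directly after an opening bracket in SMILES, so the check
#' is textual on the parsed-validated string.
#'
#' @param smiles one SMILES string.
#' @return logical; NA if the SMILES does not parse.
#' @export
checkIsotopes <- function(smiles) {
  mol <- .parseMol(smiles)
  if (is.null(mol)) return(NA)
  !grepl("\\[[0-9]", smiles)
}

#' Size/composition rules
#'
#' Returns the first triggered rejection among \code{chain} (a run of more
#' than 4 consecutive acyclic aliphatic carbons bonded only to C/H),
#' \code{hydroxyl} (more than 10 hydroxyl groups), \code{mw} (average
#' molecular weight strictly above 750 Da) and \code{atoms} (fewer than 10
#' atoms, heavy atoms by default), else \code{"none"}.
#'
#' @param smiles one SMILES string.
#' @param countHydrogens count hydrogens in the atom-number rule (default
#'   FALSE: heavy atoms only, the usual cheminformatics reading since
#'   hydrogens are implicit in SMILES).
#' @param chainSmarts,hydroxylSmarts overridable SMARTS patterns behind the
#'   chain and hydroxyl rules.
#' @param maxMw,minAtoms rule thresholds (strict \code{> maxMw}, strict
#'   \code{< minAtoms}).
#' @param maxHydroxyls hydroxyl-count threshold (strict \code{>}).
#' @return one of \code{"none" "chain" "hydroxyl" "mw" "atoms"}; NA if the
#'   SMILES does not parse.
#' @export
checkSizeRules <- function(smiles, countHydrogens = FALSE,
                           chainSmarts = .DEFAULT_CHAIN_SMARTS,
                           hydroxylSmarts = .DEFAULT_HYDROXYL_SMARTS,
                           maxMw = 750, minAtoms = 10L, maxHydroxyls = 10L) {
  mol <- .parseMol(smiles)
  if (is.null(mol)) return(NA_character_)
  p <- ChemmineOB::prop_OB(mol)
  if (ChemmineOB::smartsSearch_OB(mol, chainSmarts) > 0) return("chain")
  if (ChemmineOB::smartsSearch_OB(mol, hydroxylSmarts) > maxHydroxyls)
    return("hydroxyl")
  if (p$MW > maxMw) return("mw")
  counts <- .formulaCounts(p$formula)
  nAtoms <- if (countHydrogens) sum(counts)
            else sum(counts[names(counts) != "H"])
  if (nAtoms < minAtoms) return("atoms")
  "none"
}

#' Canonical SMILES with stereo descriptors
#'
#' OpenBabel canonical form, chiral and cis/trans information retained.
#' Idempotent: canonicalizing a canonical string returns it unchanged.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector; NA where a string does not parse.
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- strsplit(out, "[\t\n]")[[1]][1]
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Molecular properties for one parsed molecule; NULL if unparseable.
.molFacts <- function(smiles, countHydrogens = FALSE) {
  mol <- .parseMol(smiles)
  if (is.null(mol)) return(NULL)
  p <- ChemmineOB::prop_OB(mol)
  counts <- .formulaCounts(p$formula)
  list(mol = mol, prop = p,
       elements = names(counts),
       heavyAtoms = sum(counts[names(counts) != "H"]),
       allAtoms = sum(counts))
}
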