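# Simple comparator metrics: the rule-of-five descriptor panel, Fsp3, and
# wrappers routing QED / SA to RDKit's published implementations.

#' Descriptor panel for the rule-of-five comparison
#'
#' Molecular weight (average), logP, Lipinski hydrogen-bond donors and
#' acceptors, rotatable bonds, and Fsp3 — the fraction of carbon atoms that
#' are sp3-hybridized. Descriptors are computed by OpenBabel; Fsp3 is the
#' SMARTS count of \code{[CX4]} over all carbons.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame: \code{smiles}, \code{mw}, \code{logp}, \code{hbd},
#'   \code{hba}, \code{rotatable_bonds}, \code{fsp3} (NA for carbon-free
#'   molecules), with NA rows where a SMILES does not parse.
#' @export
propertyPanel <- function(smiles) {
  out <- data.frame(smiles = smiles, mw = NA_real_, logp = NA_real_,
                    hbd = NA_integer_, hba = NA_integer_,
                    rotatable_bonds = NA_integer_, fsp3 = NA_real_,
                    stringsAsFactors = FALSE)
  rotSmarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
  for (i in seq_along(smiles)) {
    mol <- .parseMol(smiles[i])
    if (is.null(mol)) next
    p <- ChemmineOB::prop_OB(mol)
    out$mw[i] <- p$MW
    out$logp[i] <- p$logP
    out$hbd[i] <- as.integer(p$HBD)
    out$hba[i] <- as.integer(p$HBA1)
    # the symmetric bond pattern matches each rotatable bond twice
    out$rotatable_bonds[i] <-
      ChemmineOB::smartsSearch_OB(mol, rotSmarts, uniqueMatches = FALSE) %/% 2L
    nC <- ChemmineOB::smartsSearch_OB(mol, "[#6]")
    out$fsp3[i] <- if (nC > 0)
      ChemmineOB::smartsSearch_OB(mol, "[CX4]") / nC else NA_real_
  }
  out
}

#' Count rule-of-five violations
#'
#' Violations of MW > 500, logP > 5, donors > 5, acceptors > 10 (strict
#' inequalities: a molecule exactly at a boundary does not violate it).
#'
#' @param panel data.frame from [propertyPanel()] (or with columns
#'   \code{mw}, \code{logp}, \code{hbd}, \code{hba}).
#' @return integer vector, 0-4 per molecule.
#' @export
ro5Violations <- function(panel) {
  as.integer((panel$mw > 500) + (panel$logp > 5) +
             (panel$hbd > 5) + (panel$hba > 10))
}

#' QED and synthetic-accessibility scores via RDKit
#'
#' Delegates to RDKit's published implementations of the quantitative
#' estimate of drug-likeness (0-1, larger is more drug-like) and the
#' fragment-contribution synthetic-accessibility score (1 easy - 10 hard),
#' run through the system \code{python}. Requires a python interpreter with
#' the \code{rdkit} package on the PATH; errors otherwise.
#'
#' @param smiles character vector of SMILES strings.
#' @param python python executable to use.
#' @return data.frame: \code{smiles}, \code{qed}, \code{sa} (NA where a
#'   SMILES does not parse).
#' @export
qedSa <- function(smiles, python = "python") {
  if (Sys.which(python) == "")
    stop("no '", python, "' executable on the PATH")
  script <- 'import sys, csv, os
from rdkit import Chem, RDLogger, RDConfig
from rdkit.Chem import QED
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer
RDLogger.DisableLog("rdApp.*")
w = csv.writer(sys.stdout)
for line in sys.stdin:
    smi = line.strip()
    if not smi:
        continue
    m = Chem.MolFromSmiles(smi)
    if m is None:
        w.writerow(["NA", "NA"])
    else:
        w.writerow([QED.qed(m), sascorer.calculateScore(m)])
'
  inFile <- tempfile(fileext = ".smi")
  on.exit(unlink(inFile))
  writeLines(smiles, inFile)
  res <- suppressWarnings(
    system2(python, c("-c", shQuote(script)),
            stdin = inFile, stdout = TRUE, stderr = FALSE))
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0)
    stop("python/rdkit call failed")
  vals <- utils::read.csv(text = paste(res, collapse = "\n"),
                          header = FALSE, na.strings = "NA")
  data.frame(smiles = smiles, qed = as.numeric(vals$V1),
             sa = as.numeric(vals$V2), stringsAsFactors = FALSE)
}
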