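#' Invalid-molecule error condition
#'
#' Structured condition raised when a SMILES string cannot be parsed. Carries
#' the offending id and string so batch callers can report rejected records.
#'
#' @param id compound id (may be NA).
#' @param smiles the offending string.
#' @param reason parser message.
#' @keywords internal
invalidMoleculeError <- function(id, smiles, reason = "unparseable SMILES") {
  structure(
    class = c("invalidMoleculeError", "error", "condition"),
    list(message = sprintf("invalid molecule%s: %s (%s)",
      if (is.na(id) || !nzchar(id)) "" else paste0(" '", id, "'"),
      smiles, reason),
      call = NULL, id = id, smiles = smiles))
}

# OpenBabel writes parse diagnostics to stderr; capture quietly.
.quietly <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}

#' Parse one SMILES into an OpenBabel molecule handle plus graph structure
#'
#' Returns the pieces every downstream computation needs: the OBMol reference
#' (for property, SMARTS and fingerprint calls), element symbols, the bond list
#' with orders, and the molecular-formula hydrogen count. Bond-less molecules
#' (single atoms, noble gases) are valid input.
#'
#' @param smiles single SMILES string.
#' @param id optional compound id used in error reporting.
#' @return list with elements \code{mol} (OBMol ref), \code{atoms} (character
#'   element symbols), \code{bonds} (integer matrix from,to,order; 0 rows if
#'   none), \code{nH} (total hydrogen count from the formula), \code{formula}.
#' @export
parseMolecule <- function(smiles, id = NA_character_) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    stop(invalidMoleculeError(id, as.character(smiles)[1L], "empty SMILES"))
  smiles <- trimws(smiles)
  mol <- tryCatch(
    .quietly(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) stop(invalidMoleculeError(id, smiles, conditionMessage(e))))
  sdfText <- tryCatch(
    .quietly(ChemmineOB::convertFormat("SMI", "SDF", source = smiles)),
    error = function(e) stop(invalidMoleculeError(id, smiles, conditionMessage(e))))
  sdf <- .quietly(ChemmineR::read.SDFset(strsplit(sdfText, "\n", fixed = TRUE)[[1L]]))[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L)
    stop(invalidMoleculeError(id, smiles, "no atoms"))
  atoms <- gsub("_[0-9]+$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  # ChemmineR returns a degenerate 2-column block when the molecule has no bonds
  if (is.null(bb) || ncol(bb) < 3L || nrow(bb) == 0L || all(bb[, 1L] == 0)) {
    bonds <- matrix(integer(0), 0L, 3L)
  } else {
    bonds <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]), as.integer(bb[, 3L]))
  }
  colnames(bonds) <- c("from", "to", "order")
  props <- .quietly(ChemmineOB::prop_OB(mol))
  formula <- as.character(props$formula[1L])
  nH <- .formulaHydrogens(formula)
  list(mol = mol, atoms = atoms, bonds = bonds, nH = nH,
    formula = formula, props = props, smiles = smiles, id = id)
}

# Hydrogen count from a Hill-order molecular formula string, e.g. "C9H8O4" -> 8.
.formulaHydrogens <- function(formula) {
  m <- regmatches(formula, regexec("H([0-9]*)([A-Z]|$)", formula))[[1L]]
  if (length(m) == 0L || m[1L] == "") return(0L)
  # guard against He/Hf/Hg: the H must not be followed by a lowercase letter
  m2 <- regmatches(formula, regexec("H(?![a-z])([0-9]*)", formula, perl = TRUE))[[1L]]
  if (length(m2) == 0L) return(0L)
  if (m2[2L] == "") 1L else as.integer(m2[2L])
}

# Count of unique SMARTS matches on a parsed molecule.
.smartsCount <- function(parsed, pattern) {
  as.numeric(.quietly(
    ChemmineOB::smartsSearch_OB(parsed$mol, pattern, uniqueMatches = TRUE)))
}
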