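# Per-element constants used by the descriptor engine: atomic number Z, valence
# electrons Zv, standard (organic subset) valence, atomic mass, Pauling
# electronegativity, covalent radius (Angstrom), static dipole polarizability
# (Angstrom^3). Standard physical-chemistry reference values.
.ELEMENTS <- data.frame(
  symbol  = c("H",   "He",  "B",   "C",   "N",   "O",   "F",   "Si",  "P",   "S",   "Cl",  "Br",  "I",   "Se",  "As"),
  Z       = c(1,     2,     5,     6,     7,     8,     9,     14,    15,    16,    17,    35,    53,    34,    33),
  Zv      = c(1,     2,     3,     4,     5,     6,     7,     4,     5,     6,     7,     7,     7,     6,     5),
  valence = c(1,     0,     3,     4,     3,     2,     1,     4,     3,     2,     1,     1,     1,     2,     3),
  mass    = c(1.008, 4.003, 10.81, 12.011, 14.007, 15.999, 18.998, 28.086, 30.974, 32.06, 35.45, 79.904, 126.904, 78.971, 74.922),
  en      = c(2.20,  0.00,  2.04,  2.55,  3.04,  3.44,  3.98,  1.90,  2.19,  2.58,  3.16,  2.96,  2.66,  2.55,  2.18),
  rcov    = c(0.31,  0.28,  0.84,  0.76,  0.71,  0.66,  0.57,  1.11,  1.07,  1.05,  1.02,  1.20,  1.39,  1.20,  1.19),
  polar   = c(0.667, 0.205, 3.03,  1.76,  1.10,  0.802, 0.557, 5.38,  3.63,  2.90,  2.18,  3.05,  5.35,  3.77,  4.31),
  stringsAsFactors = FALSE
)

# Fallback constants for elements outside the table (rare in drug-like input):
# carbon-like graph behaviour, generic heavy-atom physics.
.ELEMENT_FALLBACK <- list(Z = 6, Zv = 4, valence = 4, mass = 12.011,
  en = 2.0, rcov = 1.2, polar = 3.0)

.elementProps <- function(symbols) {
  idx <- match(symbols, .ELEMENTS$symbol)
  out <- .ELEMENTS[ifelse(is.na(idx), 1L, idx), c("Z", "Zv", "valence", "mass", "en", "rcov", "polar")]
  miss <- is.na(idx)
  if (any(miss)) {
    for (col in names(.ELEMENT_FALLBACK)) out[[col]][miss] <- .ELEMENT_FALLBACK[[col]]
  }
  rownames(out) <- NULL
  out
}
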