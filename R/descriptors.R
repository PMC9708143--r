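# The 208-descriptor engine. Classical 2D descriptors computed from the
# hydrogen-depleted molecular graph plus OpenBabel whole-molecule properties
# and SMARTS pattern counts. The manifest (inst/extdata) freezes name set and
# order so the feature dimension stays pinned at 208 regardless of toolkit
# version drift.

# SMARTS fragment dictionary: 44 functional-group / environment counts.
.FRAGMENT_SMARTS <- c(
  fr_carboxylic_acid = "[CX3](=O)[OX2H1]",
  fr_ester           = "[CX3](=O)[OX2H0][#6]",
  fr_amide           = "[CX3](=O)[NX3]",
  fr_aldehyde        = "[CX3H1]=O",
  fr_ketone          = "[#6][CX3](=O)[#6]",
  fr_ether           = "[OD2]([#6])[#6]",
  fr_phenol          = "[OX2H][c]",
  fr_aliphatic_alcohol = "[OX2H][CX4]",
  fr_primary_amine   = "[NX3;H2;!$(NC=O)]",
  fr_secondary_amine = "[NX3;H1;!$(NC=O)]([#6])[#6]",
  fr_tertiary_amine  = "[NX3;H0;!$(NC=O)]([#6])([#6])[#6]",
  fr_nitro           = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
  fr_nitrile         = "[CX2]#[NX1]",
  fr_azo             = "[NX2]=[NX2]",
  fr_hydrazine       = "[NX3][NX3]",
  fr_imine           = "[CX3]=[NX2]",
  fr_guanidine       = "[NX3][CX3](=[NX2])[NX3]",
  fr_urea            = "[NX3][CX3](=[OX1])[NX3]",
  fr_carbamate       = "[OX2][CX3](=[OX1])[NX3]",
  fr_thiol           = "[SX2H]",
  fr_sulfide         = "[SX2]([#6])[#6]",
  fr_disulfide       = "[SX2][SX2]",
  fr_sulfoxide       = "[SX3]=[OX1]",
  fr_sulfone         = "[SX4](=[OX1])=[OX1]",
  fr_sulfonamide     = "[SX4](=[OX1])(=[OX1])[NX3]",
  fr_phosphoryl      = "[PX4]=[OX1]",
  fr_aliphatic_halide = "[CX4][F,Cl,Br,I]",
  fr_aromatic_halide = "c[F,Cl,Br,I]",
  fr_alkene          = "[CX3]=[CX3]",
  fr_alkyne          = "[CX2]#[CX2]",
  fr_benzene         = "c1ccccc1",
  fr_aromatic_N      = "[n]",
  fr_aromatic_O      = "[o]",
  fr_aromatic_S      = "[s]",
  fr_NH_aromatic     = "[nH]",
  fr_epoxide         = "[CX4]1[OX2][CX4]1",
  fr_lactone         = "[CX3;R](=[OX1])[OX2;R]",
  fr_lactam          = "[CX3;R](=[OX1])[NX3;R]",
  fr_acyl_halide     = "[CX3](=[OX1])[F,Cl,Br,I]",
  fr_anhydride       = "[CX3](=[OX1])[OX2][CX3](=[OX1])",
  fr_methyl          = "[CX4H3]",
  fr_methylene       = "[CX4H2]",
  fr_quaternary_C    = "[CX4H0]",
  fr_sp2_carbon      = "[CX3]"
)

.ELEMENT_COUNT_SYMBOLS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si")
.AUTOCORR_PROPS <- c(m = "mass", en = "en", r = "rcov", p = "polar")
.AUTOCORR_LAGS <- 1:8

# Canonical descriptor order; the shipped manifest equals this.
.descriptorNames <- function() {
  c(
    c("MW", "ExactMass", "LogP", "MolarRefractivity", "TPSA",
      "HBondAcceptors1", "HBondAcceptors2", "HBondDonors"),
    paste0("nAtom", .ELEMENT_COUNT_SYMBOLS), "nAtomOther", "nHeavyAtoms", "nHydrogens",
    c("nHeteroAtoms", "nHalogens", "fracHeteroAtoms",
      "nPosCharge", "nNegCharge", "netFormalCharge"),
    c("nBonds", "nSingleBonds", "nDoubleBonds", "nTripleBonds",
      "nAromaticBonds", "nRotatableBonds", "nRingBonds"),
    c("nRingsCyclomatic", "nRingAtoms", "nAromaticAtoms",
      paste0("nAtomsRing", 3:8), "fracAromaticAtoms"),
    c("Chi0", "Chi1", "Chi2", "Chi3", "Chi4",
      "Chi0v", "Chi1v", "Chi2v", "Chi3v", "Chi4v",
      "Kappa1", "Kappa2", "Kappa3",
      "WienerIndex", "BalabanJ", "ZagrebM1", "ZagrebM2", "PlattF",
      "GraphRadius", "GraphDiameter", "EccentricConnectivity",
      "PetitjeanShape", "HararyIndex"),
    as.vector(t(outer(c("ATS", "Moran", "Geary"),
      as.vector(outer(names(.AUTOCORR_PROPS), .AUTOCORR_LAGS, paste, sep = "_")),
      paste, sep = "_"))),
    names(.FRAGMENT_SMARTS)
  )
}

#' The frozen 208-name descriptor manifest
#'
#' Loads the descriptor manifest shipped with the package (or a user file, one
#' name per line). The manifest fixes which descriptors are computed and in
#' what order, pinning the descriptor block at exactly 208 columns.
#'
#' @param file optional path to a manifest file; default is the shipped one.
#' @return character vector of 208 descriptor names.
#' @export
descriptorManifest <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "descriptor_manifest_208.txt",
      package = "forgeNet", mustWork = TRUE)
  names <- readLines(file)
  names <- names[nzchar(trimws(names)) & !startsWith(trimws(names), "#")]
  names <- trimws(names)
  if (length(names) != 208L)
    stop("descriptor manifest must contain exactly 208 names, got ", length(names))
  unknown <- setdiff(names, .descriptorNames())
  if (length(unknown))
    stop("manifest names not computable by this engine: ",
      paste(utils::head(unknown, 5L), collapse = ", "))
  if (anyDuplicated(names)) stop("descriptor manifest contains duplicates")
  names
}

# Distance matrix of the hydrogen-depleted graph (Inf across components),
# via breadth-first search from every atom.
.graphDistances <- function(nAtoms, bonds) {
  D <- matrix(Inf, nAtoms, nAtoms)
  diag(D) <- 0
  if (nrow(bonds) == 0L || nAtoms < 2L) return(D)
  adj <- vector("list", nAtoms)
  for (i in seq_len(nrow(bonds))) {
    u <- bonds[i, 1L]; v <- bonds[i, 2L]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  for (s in seq_len(nAtoms)) {
    dist <- rep(Inf, nAtoms); dist[s] <- 0
    frontier <- s; level <- 0
    while (length(frontier)) {
      level <- level + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- level
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# Simple-path sums for Kier-Hall chi: for k = 2,3,4 returns the number of
# simple paths of k edges and the sum over paths of prod(delta)^(-1/2).
.pathStatistics <- function(adj, delta) {
  counts <- c(`2` = 0, `3` = 0, `4` = 0)
  sums <- c(`2` = 0, `3` = 0, `4` = 0)
  n <- length(adj)
  if (n == 0L) return(list(counts = counts, sums = sums))
  recurse <- function(path, prodDelta) {
    k <- length(path) - 1L
    if (k >= 2L) {
      key <- as.character(k)
      counts[key] <<- counts[key] + 1
      sums[key] <<- sums[key] + 1 / sqrt(prodDelta)
    }
    if (k == 4L) return(invisible())
    for (w in adj[[path[length(path)]]]) {
      if (!(w %in% path)) recurse(c(path, w), prodDelta * delta[w])
    }
  }
  for (s in seq_len(n)) {
    if (length(adj[[s]]) == 0L) next
    recurse(s, delta[s])
  }
  # every path is enumerated from both ends
  list(counts = counts / 2, sums = sums / 2)
}

.finite0 <- function(x) if (length(x) == 0L || !is.finite(x)) 0 else x

# Full canonical descriptor vector for one parsed molecule.
.allDescriptors <- function(parsed) {
  out <- stats::setNames(numeric(length(.descriptorNames())), .descriptorNames())
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  nA <- length(atoms)
  ep <- .elementProps(atoms)

  p <- parsed$props
  out["MW"] <- as.numeric(p$MW[1L])
  out["ExactMass"] <- tryCatch(
    as.numeric(.quietly(ChemmineOB::exactMass_OB(parsed$mol))),
    error = function(e) as.numeric(p$MW[1L]))
  out["LogP"] <- as.numeric(p$logP[1L])
  out["MolarRefractivity"] <- as.numeric(p$MR[1L])
  out["TPSA"] <- as.numeric(p$TPSA[1L])
  out["HBondAcceptors1"] <- as.numeric(p$HBA1[1L])
  out["HBondAcceptors2"] <- as.numeric(p$HBA2[1L])
  out["HBondDonors"] <- as.numeric(p$HBD[1L])

  for (sym in .ELEMENT_COUNT_SYMBOLS)
    out[paste0("nAtom", sym)] <- sum(atoms == sym)
  out["nAtomOther"] <- sum(!atoms %in% c(.ELEMENT_COUNT_SYMBOLS, "H"))
  out["nHeavyAtoms"] <- sum(atoms != "H")
  out["nHydrogens"] <- parsed$nH + sum(atoms == "H")

  out["nHeteroAtoms"] <- sum(!atoms %in% c("C", "H"))
  out["nHalogens"] <- sum(atoms %in% c("F", "Cl", "Br", "I"))
  out["fracHeteroAtoms"] <- if (nA > 0) out["nHeteroAtoms"] / nA else 0
  posC <- vapply(c("[*+]", "[*+2]", "[*+3]"), function(s) .smartsCount(parsed, s), 0)
  negC <- vapply(c("[*-]", "[*-2]", "[*-3]"), function(s) .smartsCount(parsed, s), 0)
  out["nPosCharge"] <- sum(posC)
  out["nNegCharge"] <- sum(negC)
  out["netFormalCharge"] <- sum(posC * 1:3) - sum(negC * 1:3)

  out["nBonds"] <- nrow(bonds)
  out["nSingleBonds"] <- .smartsCount(parsed, "[*]-[*]")
  out["nDoubleBonds"] <- .smartsCount(parsed, "[*]=[*]")
  out["nTripleBonds"] <- .smartsCount(parsed, "[*]#[*]")
  out["nAromaticBonds"] <- .smartsCount(parsed, "[a]:[a]")
  out["nRotatableBonds"] <- .smartsCount(parsed, "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]")
  out["nRingBonds"] <- .smartsCount(parsed, "[*]@[*]")

  # ring block
  deg <- rep(0L, nA)
  if (nrow(bonds)) {
    tab <- table(factor(c(bonds[, 1L], bonds[, 2L]), levels = seq_len(nA)))
    deg <- as.integer(tab)
  }
  D <- .graphDistances(nA, bonds)
  nComp <- if (nA == 0L) 0L else {
    # components = number of BFS trees: count via finite-distance blocks
    comp <- rep(NA_integer_, nA); cid <- 0L
    for (s in seq_len(nA)) if (is.na(comp[s])) { cid <- cid + 1L; comp[is.finite(D[s, ])] <- cid }
    cid
  }
  out["nRingsCyclomatic"] <- max(0L, nrow(bonds) - nA + nComp)
  out["nRingAtoms"] <- .smartsCount(parsed, "[R]")
  out["nAromaticAtoms"] <- .smartsCount(parsed, "[a]")
  for (r in 3:8)
    out[paste0("nAtomsRing", r)] <- .smartsCount(parsed, sprintf("[r%d]", r))
  out["fracAromaticAtoms"] <- if (nA > 0) out["nAromaticAtoms"] / nA else 0

  # Kier-Hall connectivity: simple delta = heavy degree; valence delta from
  # valence electrons, implicit hydrogens and atomic number.
  ordNum <- ifelse(bonds[, 3L] == 4L, 1.5, bonds[, 3L])  # aromatic written as 4
  bosum <- rep(0, nA)
  if (nrow(bonds)) for (i in seq_len(nrow(bonds))) {
    bosum[bonds[i, 1L]] <- bosum[bonds[i, 1L]] + ordNum[i]
    bosum[bonds[i, 2L]] <- bosum[bonds[i, 2L]] + ordNum[i]
  }
  hOnAtom <- pmax(0, ep$valence - bosum)
  deltaV <- ifelse(ep$Z > 10,
    (ep$Zv - hOnAtom) / pmax(ep$Z - ep$Zv - 1, 1),
    ep$Zv - hOnAtom)
  adj <- vector("list", nA)
  if (nrow(bonds)) for (i in seq_len(nrow(bonds))) {
    u <- bonds[i, 1L]; v <- bonds[i, 2L]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  chiTerm <- function(x) ifelse(x > 0, 1 / sqrt(x), 0)
  out["Chi0"] <- sum(chiTerm(deg))
  out["Chi0v"] <- sum(chiTerm(deltaV))
  if (nrow(bonds)) {
    du <- deg[bonds[, 1L]]; dv <- deg[bonds[, 2L]]
    ok <- du > 0 & dv > 0
    out["Chi1"] <- sum(1 / sqrt(du[ok] * dv[ok]))
    dvu <- deltaV[bonds[, 1L]]; dvv <- deltaV[bonds[, 2L]]
    okv <- dvu > 0 & dvv > 0
    out["Chi1v"] <- sum(1 / sqrt(dvu[okv] * dvv[okv]))
    out["ZagrebM1"] <- sum(deg^2)
    out["ZagrebM2"] <- sum(du * dv)
    out["PlattF"] <- sum(du + dv - 2)
  }
  psSimple <- .pathStatistics(adj, pmax(deg, 0))
  psValence <- .pathStatistics(adj, pmax(deltaV, 0))
  out["Chi2"] <- psSimple$sums["2"]; out["Chi3"] <- psSimple$sums["3"]
  out["Chi4"] <- psSimple$sums["4"]
  out["Chi2v"] <- psValence$sums["2"]; out["Chi3v"] <- psValence$sums["3"]
  out["Chi4v"] <- psValence$sums["4"]

  P1 <- nrow(bonds); P2 <- psSimple$counts["2"]; P3 <- psSimple$counts["3"]
  A <- nA
  out["Kappa1"] <- if (P1 > 0) A * (A - 1)^2 / P1^2 else 0
  out["Kappa2"] <- if (P2 > 0 && A >= 2) (A - 1) * (A - 2)^2 / P2^2 else 0
  out["Kappa3"] <- if (P3 > 0 && A >= 3) {
    if (A %% 2 == 1) (A - 1) * (A - 3)^2 / P3^2 else (A - 3) * (A - 2)^2 / P3^2
  } else 0

  Dfin <- D[is.finite(D) & D > 0]
  out["WienerIndex"] <- sum(Dfin) / 2
  out["HararyIndex"] <- sum(1 / Dfin) / 2
  ecc <- apply(D, 1L, function(r) { f <- r[is.finite(r)]; if (length(f)) max(f) else 0 })
  out["GraphRadius"] <- .finite0(min(ecc))
  out["GraphDiameter"] <- .finite0(max(ecc))
  out["EccentricConnectivity"] <- sum(deg * ecc)
  out["PetitjeanShape"] <- if (out["GraphRadius"] > 0)
    (out["GraphDiameter"] - out["GraphRadius"]) / out["GraphRadius"] else 0
  if (nrow(bonds)) {
    s <- apply(D, 1L, function(r) sum(r[is.finite(r)]))
    su <- s[bonds[, 1L]]; sv <- s[bonds[, 2L]]
    ok <- su > 0 & sv > 0
    mu <- out["nRingsCyclomatic"]
    out["BalabanJ"] <- P1 / (mu + 1) * sum(1 / sqrt(su[ok] * sv[ok]))
  }

  # spatial autocorrelation over topological distance
  for (pk in names(.AUTOCORR_PROPS)) {
    w <- ep[[.AUTOCORR_PROPS[[pk]]]]
    wbar <- mean(w); wc <- w - wbar; ssq <- sum(wc^2)
    for (lag in .AUTOCORR_LAGS) {
      pairs <- which(D == lag, arr.ind = TRUE)
      pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
      np <- nrow(pairs)
      ats <- if (np) sum(w[pairs[, 1L]] * w[pairs[, 2L]]) else 0
      out[sprintf("ATS_%s_%d", pk, lag)] <- ats
      if (np && ssq > 0) {
        out[sprintf("Moran_%s_%d", pk, lag)] <-
          (nA / (2 * np)) * sum(wc[pairs[, 1L]] * wc[pairs[, 2L]]) / ssq
        out[sprintf("Geary_%s_%d", pk, lag)] <-
          ((nA - 1) / (2 * 2 * np)) * sum((w[pairs[, 1L]] - w[pairs[, 2L]])^2) / ssq
      }
    }
  }

  for (fn in names(.FRAGMENT_SMARTS))
    out[fn] <- .smartsCount(parsed, .FRAGMENT_SMARTS[[fn]])

  out
}

#' Compute the 208 molecular descriptors for one SMILES
#'
#' Descriptors are returned in manifest order. The set covers whole-molecule
#' OpenBabel properties (molecular weight, logP, molar refractivity, TPSA,
#' hydrogen-bond donor/acceptor counts), element/bond/ring counts, Kier-Hall
#' connectivity (chi) and shape (kappa) indices, distance-based indices
#' (Wiener, Balaban J, Harary, eccentric connectivity), Moreau-Broto / Moran /
#' Geary autocorrelations over mass, electronegativity, covalent radius and
#' polarizability, and 44 SMARTS fragment counts.
#'
#' @param smiles single SMILES string.
#' @param manifest descriptor manifest (default: the shipped 208-name file).
#' @param id optional compound id for error reporting.
#' @return named numeric vector of length 208 in manifest order.
#' @examples
#' \dontrun{
#' v <- computeDescriptors("CCO")
#' v["TPSA"]  # 20.23
#' }
#' @export
computeDescriptors <- function(smiles, manifest = descriptorManifest(),
                               id = NA_character_) {
  parsed <- parseMolecule(smiles, id = id)
  full <- .allDescriptors(parsed)
  full[manifest]
}
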