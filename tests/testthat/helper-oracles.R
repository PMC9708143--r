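# Independent oracle values and small utilities shared across tests.

# MACCS key sets (keys 1..166 that are ON) computed for the fixture molecules
# with an independent cheminformatics toolkit (RDKit 2024.09) and frozen here
# before the implementation was written.
RDKIT_MACCS_ONBITS <- list(
  ethanol     = c(82, 109, 114, 139, 153, 155, 157, 160, 164),
  aspirin     = c(89, 113, 123, 126, 127, 136, 139, 140, 143, 144, 146, 150,
                  152, 154, 157, 159, 160, 162, 163, 164, 165),
  paracetamol = c(92, 110, 113, 117, 127, 131, 133, 135, 139, 143, 151, 152,
                  154, 156, 157, 158, 159, 160, 161, 162, 163, 164, 165),
  ibuprofen   = c(74, 115, 123, 139, 141, 149, 154, 155, 157, 159, 160, 162,
                  163, 164, 165),
  benzene     = c(162, 163, 165),
  glycine     = c(54, 82, 84, 95, 100, 104, 123, 131, 132, 139, 151, 153, 154,
                  155, 157, 158, 159, 161, 164),
  helium      = c(44)
)

# Caffeine reference on-bits (same independent toolkit); compared with a
# one-bit allowance because aromaticity perception of the fused dicarbonyl
# ring differs between toolkits (key 125, "more than one aromatic ring").
RDKIT_MACCS_ONBITS_CAFFEINE <- c(37, 38, 65, 75, 77, 79, 80, 83, 85, 89, 92,
  93, 95, 96, 97, 98, 101, 105, 106, 110, 113, 117, 120, 121, 122, 125, 127,
  136, 137, 141, 142, 143, 144, 148, 149, 150, 154, 156, 158, 159, 160, 161,
  162, 163, 164, 165)

# TPSA of ethanol from an independent toolkit call (checked before the build).
ETHANOL_TPSA <- 20.23

# Brute-force ROC AUC: exhaustive concordant-pair counting (ties count 1/2).
concordanceAUC <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Random confusion table with all counts >= 0 and n > 0.
randomConfusion <- function() {
  repeat {
    counts <- c(TP = rpois(1, 8), FP = rpois(1, 5), TN = rpois(1, 12),
      FN = rpois(1, 4))
    if (sum(counts) > 0) return(counts)
  }
}

# Expand a confusion table into (truth, predicted) vectors for oracle
# computations that work on raw labels.
expandConfusion <- function(counts) {
  truth <- c(rep(1, counts["TP"]), rep(0, counts["FP"]),
    rep(0, counts["TN"]), rep(1, counts["FN"]))
  pred <- c(rep(1, counts["TP"]), rep(1, counts["FP"]),
    rep(0, counts["TN"]), rep(0, counts["FN"]))
  list(truth = truth, pred = pred)
}

# Random small tree in the treeStructures() format: recursively split nodes up
# to a depth limit, drawing split features from 1..d.
randomTree <- function(d, maxDepth = 4, pSplit = 0.7) {
  rows <- data.frame(node = 1L, left = 0L, right = 0L,
    splitFeature = NA_integer_)
  grow <- function(node, depth) {
    if (depth < maxDepth && runif(1) < pSplit) {
      rows$splitFeature[node] <<- sample.int(d, 1L)
      l <- nrow(rows) + 1L; r <- nrow(rows) + 2L
      rows[l, ] <<- data.frame(node = l, left = 0L, right = 0L,
        splitFeature = NA_integer_)
      rows[r, ] <<- data.frame(node = r, left = 0L, right = 0L,
        splitFeature = NA_integer_)
      rows$left[node] <<- l; rows$right[node] <<- r
      grow(l, depth + 1L); grow(r, depth + 1L)
    }
  }
  grow(1L, 0L)
  rows
}

# Brute-force edge enumeration for a tree in treeStructures() format.
bruteForceTreeEdges <- function(tree) {
  edges <- matrix(integer(0), 0, 2)
  for (u in seq_len(nrow(tree))) {
    if (is.na(tree$splitFeature[u])) next
    for (ch in c(tree$left[u], tree$right[u])) {
      if (ch > 0 && !is.na(tree$splitFeature[ch]))
        edges <- rbind(edges, c(tree$splitFeature[u], tree$splitFeature[ch]))
    }
  }
  unique(edges)
}

# Canonical string form of an edge set for set comparisons.
edgeKey <- function(edges) sort(paste(edges[, 1], edges[, 2], sep = "->"))

# Separable two-feature toy classification data.
separableToy <- function(n = 200, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(rnorm(n, mean = ifelse(y == 1, 3, -3), sd = 0.5),
    rnorm(n, mean = ifelse(y == 1, -2, 2), sd = 0.5))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = y)
}

# Minimal hand-built network whose active-class probability is a monotone
# function of a single input feature (identity mask, no hidden layer noise).
monotoneStubModel <- function() {
  mask <- new("MaskMatrix", m = diag(1), symmetrized = TRUE, selfLoops = TRUE)
  new("ForgeNetModel", forest = NULL, mask = mask,
    weights = list(matrix(1, 1, 1), matrix(c(-1, 1), 1, 2)),
    biases = list(0, c(0, 0)),
    standardization = list(mean = 0, sd = 1),
    config = netConfig(hidden = integer(0), seed = 1L),
    featureSetTag = "custom")
}
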