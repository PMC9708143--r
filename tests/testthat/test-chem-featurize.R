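test_that("descriptor vector has the manifest's 208 entries in order and is deterministic", {
  man <- descriptorManifest()
  expect_length(man, 208L)
  v1 <- computeDescriptors("CCO")
  v2 <- computeDescriptors("CCO")
  expect_length(v1, 208L)
  expect_identical(names(v1), man)
  expect_identical(v1, v2)
})

test_that("ethanol TPSA matches the independent-toolkit value", {
  v <- computeDescriptors("CCO")
  expect_equal(unname(v["TPSA"]), ETHANOL_TPSA, tolerance = 1e-8)
})

test_that("hand-checkable graph descriptors are exact on ethanol", {
  v <- computeDescriptors("CCO")
  # path graph C-C-O: distances (1,1,2)
  expect_equal(unname(v["WienerIndex"]), 4)
  expect_equal(unname(v["Chi1"]), 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(v["nHeavyAtoms"]), 3)
  expect_equal(unname(v["nHydrogens"]), 6)
  expect_equal(unname(v["nBonds"]), 2)
  expect_equal(unname(v["nRotatableBonds"]), 0)  # both bonds are terminal
  expect_equal(unname(v["GraphDiameter"]), 2)
})

test_that("MACCS keys equal the frozen independent-toolkit bit sets", {
  fx <- fixtureSmiles()
  for (nm in names(RDKIT_MACCS_ONBITS)) {
    smi <- fx$smiles[fx$id == nm]
    bits <- computeMACCS(smi)
    expect_length(bits, 166L)
    expect_true(all(bits %in% c(0L, 1L)))
    expect_identical(unname(which(bits == 1L)), as.integer(RDKIT_MACCS_ONBITS[[nm]]),
      label = paste("MACCS on-bits for", nm))
  }
  # Fused heteroaromatics are where aromaticity models differ between
  # toolkits: on caffeine the backend disagrees with the reference set only on
  # key 125 ("more than one aromatic ring"), whose truth depends on whether
  # the dicarbonyl six-ring is perceived aromatic.
  fx <- fixtureSmiles()
  caffeineBits <- computeMACCS(fx$smiles[fx$id == "caffeine"])
  diffs <- union(
    setdiff(which(caffeineBits == 1L), RDKIT_MACCS_ONBITS_CAFFEINE),
    setdiff(RDKIT_MACCS_ONBITS_CAFFEINE, which(caffeineBits == 1L)))
  expect_lte(length(diffs), 1L)
})

test_that("the degenerate single-atom molecule featurizes with a near-empty fingerprint", {
  bits <- computeMACCS("[He]")
  expect_lte(sum(bits), 2L)
  v <- computeDescriptors("[He]")
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["nBonds"]), 0)
})

test_that("full feature vectors concatenate descriptors and MACCS to 374", {
  fx <- fixtureSmiles()
  res <- featurizeTable(fx, featureSet = "full")
  m <- featureValues(res$features)
  expect_identical(dim(m), c(12L, 374L))
  expect_identical(featureSetTag(res$features), "full")
  expect_identical(nrow(res$rejected), 0L)
  resD <- featurizeTable(fx[1:3, ], featureSet = "descriptors_only")
  expect_identical(dim(featureValues(resD$features)), c(3L, 208L))
  expect_identical(featureSetTag(resD$features), "descriptors_only")
})

test_that("batch featurization rows equal the single-molecule path", {
  fx <- fixtureSmiles()[c(2, 5, 7), ]
  res <- featurizeTable(fx, featureSet = "full")
  m <- featureValues(res$features)
  for (i in seq_len(nrow(fx))) {
    single <- c(computeDescriptors(fx$smiles[i]), computeMACCS(fx$smiles[i]))
    expect_equal(unname(m[i, ]), unname(single), tolerance = 1e-12,
      label = paste("row", fx$id[i]))
  }
})

test_that("invalid SMILES raise structured errors singly and are dropped in batches", {
  expect_error(computeDescriptors("not_a_smiles"), class = "invalidMoleculeError")
  expect_error(computeMACCS("C1CC"), class = "invalidMoleculeError")
  expect_error(parseMolecule(""), class = "invalidMoleculeError")
  res <- featurizeTable(
    data.frame(id = c("a", "b", "c"), smiles = c("CCO", "not_a_smiles", "c1ccccc1")))
  expect_identical(rownames(featureValues(res$features)), c("a", "c"))
  expect_identical(res$rejected$id, "b")
  expect_error(
    featurizeTable(data.frame(id = "z", smiles = "not_a_smiles")),
    "all records failed")
})

test_that("record validation enforces non-empty unique ids", {
  expect_error(featurizeTable(data.frame(id = c("a", "a"), smiles = c("C", "C"))),
    "unique")
  expect_error(featurizeTable(data.frame(id = c("a", ""), smiles = c("C", "C"))),
    "non-empty")
  expect_error(featurizeTable(data.frame()), "non-empty")
})

test_that("a truncated manifest is rejected", {
  tmp <- tempfile()
  writeLines(descriptorManifest()[1:100], tmp)
  expect_error(descriptorManifest(tmp), "exactly 208")
  writeLines(c(descriptorManifest()[1:207], "NotADescriptor"), tmp)
  expect_error(descriptorManifest(tmp), "not computable")
})

test_that("cleanMatrix imputes by column median, zeroes dead columns, and is idempotent", {
  m <- matrix(c(1, 2, 3, NaN, 2, Inf, NaN, NaN, NaN), 3,
    dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
  res <- cleanMatrix(m)
  expect_identical(res$cleaned[, "c1"], m[, "c1"])
  expect_equal(unname(res$cleaned[1, "c2"]), 2)   # median of finite {2}
  expect_equal(unname(res$cleaned[3, "c2"]), 2)
  expect_equal(unname(res$cleaned[, "c3"]), c(0, 0, 0))
  expect_true(res$report$allNonFinite[res$report$column == "c3"])
  again <- cleanMatrix(res$cleaned)
  expect_identical(again$cleaned, res$cleaned)
  expect_identical(nrow(again$report), 0L)
  # no-op case returns the input unchanged
  clean <- cleanMatrix(matrix(1:4, 2, dimnames = list(NULL, c("a", "b"))))
  expect_identical(nrow(clean$report), 0L)
})

test_that("labelActives uses a strict threshold and accounts for every record", {
  tab <- data.frame(id = paste0("c", 1:4), ic50_nM = c(100, 4999.9, 5000, 12000))
  res <- labelActives(tab)
  expect_identical(res$actives$id, c("c1", "c2"))
  expect_true(all(res$actives$label == 1L))
  expect_identical(nrow(res$actives) + nrow(res$excluded), nrow(tab))
  empty <- labelActives(data.frame(id = character(0), ic50_nM = numeric(0)))
  expect_identical(nrow(empty$actives), 0L)
  bad <- labelActives(data.frame(id = c("x", "y"), ic50_nM = c(NA, -5)))
  expect_identical(nrow(bad$actives), 0L)
  expect_match(bad$excluded$reason, "non-positive", all = TRUE)
})

test_that("labelActives equals a brute-force potency scan on random tables", {
  set.seed(7)
  for (rep in 1:5) {
    pot <- runif(50, 0, 10000)
    tab <- data.frame(id = paste0("c", 1:50), ic50_nM = pot)
    res <- labelActives(tab, threshold = 5000)
    expect_identical(nrow(res$actives), sum(pot < 5000))
    expect_setequal(res$actives$id, tab$id[pot < 5000])
  }
})

test_that("compound tables round-trip through CSV and SDF readers", {
  fx <- fixtureSmiles()[1:3, ]
  csv <- tempfile(fileext = ".csv")
  write.csv(fx, csv, row.names = FALSE)
  back <- readCompounds(csv)
  expect_identical(back$id, fx$id)
  expect_identical(back$smiles, fx$smiles)
  # SDF round-trip via OpenBabel conversion
  sdf <- tempfile(fileext = ".sdf")
  txt <- ChemmineOB::convertFormat("SMI", "SDF",
    source = paste(paste(fx$smiles, fx$id, sep = "\t"), collapse = "\n"))
  writeLines(txt, sdf)
  back2 <- readCompounds(sdf)
  expect_identical(back2$id, fx$id)
  feats <- featurizeTable(back2)
  expect_identical(nrow(res <- featureValues(feats$features)), 3L)
})

test_that("feature matrices round-trip through CSV", {
  fx <- featurizeTable(fixtureSmiles()[1:3, ])$features
  path <- tempfile(fileext = ".csv")
  writeFeatureMatrix(fx, path)
  back <- readFeatureMatrix(path)
  expect_identical(featureSetTag(back), "full")
  expect_identical(compoundIds(back), compoundIds(fx))
  expect_equal(featureValues(back), featureValues(fx), tolerance = 1e-9)
})
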