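#' Featurize a compound table into a FeatureMatrix
#'
#' Converts SMILES records into the model's feature vectors: the full set is
#' the concatenation of 208 descriptors and the 166 MACCS keys (374 features);
#' \code{descriptors_only} is the 208-descriptor control set. Rows follow input
#' order; records whose SMILES cannot be parsed are dropped and reported rather
#' than aborting the batch. No scaling is applied here — training-fold
#' standardization is owned by the network trainer, which prevents
#' cross-validation leakage.
#'
#' @param records data.frame of compound records with columns \code{id} and
#'   \code{smiles} (ids non-empty and unique).
#' @param featureSet \code{"full"} (374 features) or \code{"descriptors_only"}
#'   (208).
#' @param manifest descriptor manifest (default: the shipped 208-name file).
#' @return list with \code{features} (a \linkS4class{FeatureMatrix}) and
#'   \code{rejected} (data.frame id, smiles, reason; zero rows if none).
#' @export
featurizeTable <- function(records,
                           featureSet = c("full", "descriptors_only"),
                           manifest = descriptorManifest()) {
  featureSet <- match.arg(featureSet)
  records <- .validateRecords(records)
  rows <- vector("list", nrow(records))
  rejected <- list()
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    v <- tryCatch({
      d <- computeDescriptors(records$smiles[i], manifest = manifest, id = id)
      if (featureSet == "full") c(d, computeMACCS(records$smiles[i], id = id)) else d
    }, invalidMoleculeError = function(e) e)
    if (inherits(v, "invalidMoleculeError")) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(id = id, smiles = records$smiles[i],
          reason = conditionMessage(v), stringsAsFactors = FALSE)
      rows[[i]] <- NULL
    } else rows[[i]] <- v
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep))
    stop("all records failed to featurize; no valid molecules in input")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- records$id[keep]
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(id = character(0), smiles = character(0), reason = character(0))
  list(features = FeatureMatrix(m, featureSetTag = featureSet),
    rejected = rejected)
}

.validateRecords <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  if (!all(c("id", "smiles") %in% names(records)))
    stop("records must have columns 'id' and 'smiles'")
  records$id <- as.character(records$id)
  records$smiles <- as.character(records$smiles)
  if (any(is.na(records$id) | !nzchar(records$id)))
    stop("compound ids must be non-empty")
  if (anyDuplicated(records$id))
    stop("compound ids must be unique within a table")
  records
}

#' Replace non-finite feature values
#'
#' Cleaning policy for descriptor matrices: every NaN/Inf entry is replaced by
#' the column median of the finite values; a column with no finite values
#' becomes all zero and is flagged. Idempotent.
#'
#' @param x a \linkS4class{FeatureMatrix} or plain numeric matrix.
#' @param allNonFiniteValue replacement for columns with no finite entries.
#' @return list with \code{cleaned} (same type as input) and \code{report}
#'   (data.frame: column, nReplaced, replacement, allNonFinite).
#' @export
cleanMatrix <- function(x, allNonFiniteValue = 0) {
  m <- if (is(x, "FeatureMatrix")) featureValues(x) else x
  report <- list()
  for (j in seq_len(ncol(m))) {
    bad <- !is.finite(m[, j])
    if (!any(bad)) next
    fin <- m[!bad, j]
    repl <- if (length(fin)) stats::median(fin) else allNonFiniteValue
    m[bad, j] <- repl
    report[[length(report) + 1L]] <- data.frame(
      column = colnames(m)[j], nReplaced = sum(bad), replacement = repl,
      allNonFinite = !length(fin), stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(column = character(0), nReplaced = integer(0),
      replacement = numeric(0), allNonFinite = logical(0))
  cleaned <- if (is(x, "FeatureMatrix"))
    FeatureMatrix(m, featureSetTag = featureSetTag(x)) else m
  list(cleaned = cleaned, report = report)
}

#' Label active compounds from a bioactivity table
#'
#' Applies the activity rule: records whose potency (IC50, nmol/L) is strictly
#' below the threshold are labelled active (label = 1) and returned; all other
#' records — at or above threshold, or with missing/non-positive potency — are
#' excluded and reported. Input potencies must already be in nmol/L.
#'
#' @param records data.frame with columns \code{id}, \code{smiles} (optional)
#'   and \code{ic50_nM}.
#' @param threshold activity threshold in nmol/L (default 5000).
#' @return list with \code{actives} (input rows with \code{label = 1}) and
#'   \code{excluded} (data.frame id, ic50_nM, reason). The row counts of the
#'   two parts always sum to the input row count.
#' @export
labelActives <- function(records, threshold = 5000) {
  if (!is.data.frame(records))
    stop("records must be a data.frame")
  if (nrow(records) == 0L) {
    return(list(actives = cbind(records, label = integer(0)),
      excluded = data.frame(id = character(0), ic50_nM = numeric(0),
        reason = character(0))))
  }
  if (!"ic50_nM" %in% names(records))
    stop("records must have a potency column 'ic50_nM'")
  pot <- as.numeric(records$ic50_nM)
  invalid <- is.na(pot) | pot <= 0
  active <- !invalid & pot < threshold
  excludedIdx <- which(!active)
  reason <- ifelse(invalid[excludedIdx], "missing or non-positive potency",
    sprintf("IC50 >= %g nmol/L", threshold))
  actives <- records[active, , drop = FALSE]
  if (nrow(actives)) actives$label <- 1L else actives$label <- integer(0)
  list(actives = actives,
    excluded = data.frame(id = as.character(records$id[excludedIdx]),
      ic50_nM = pot[excludedIdx], reason = reason, stringsAsFactors = FALSE))
}

#' Read a compound table from CSV or SDF
#'
#' CSV input needs columns \code{id} and \code{smiles}; optional columns
#' \code{label} and \code{ic50_nM} are carried through. SDF input uses the
#' molecule title as id and converts structures to SMILES.
#'
#' @param path file path (.csv/.tsv or .sdf).
#' @return data.frame of compound records.
#' @export
readCompounds <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".smi")
    .quietly(ChemmineOB::convertFormatFile("SDF", "SMI", path, tmp))
    lines <- readLines(tmp)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t| +")
    data.frame(
      id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, ""),
      smiles = vapply(parts, `[`, "", 1L), stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
      comment.char = "")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a FeatureMatrix as CSV
#'
#' The CSV carries the compound id in the first column and named feature
#' columns; the feature-set tag is stored in a header comment line.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output path.
#' @export
writeFeatureMatrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# feature_set: %s", featureSetTag(x)), con)
  df <- data.frame(id = compoundIds(x), featureValues(x),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  tag <- if (startsWith(first, "# feature_set:"))
    trimws(sub("# feature_set:", "", first)) else "custom"
  df <- utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  FeatureMatrix(m, featureSetTag = tag)
}
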