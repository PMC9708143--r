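#' Rank candidate compounds by predicted activity
#'
#' Scores each candidate with the fitted model and assigns ranks 1..n in
#' descending probability order; rank 1 is the most active-looking candidate.
#' Probability ties are broken by input order (stable sort), so ranks are
#' reproducible.
#'
#' @param model a \linkS4class{ForgeNetModel}.
#' @param candidates \linkS4class{FeatureMatrix} of featurized candidates whose
#'   feature-set tag matches the model's.
#' @param modelTag label for the training set / target behind the model.
#' @return a \linkS4class{RankTable}.
#' @export
screenCompounds <- function(model, candidates, modelTag = "model") {
  if (is(candidates, "FeatureMatrix") && nrow(featureValues(candidates)) == 0L)
    stop("empty candidate set")
  if (is.matrix(candidates) && nrow(candidates) == 0L)
    stop("empty candidate set")
  p <- predictProba(model, candidates)
  ids <- if (is(candidates, "FeatureMatrix")) compoundIds(candidates)
    else rownames(candidates) %||% as.character(seq_along(p))
  ord <- order(-p)  # stable: ties keep input order
  rank <- integer(length(p))
  rank[ord] <- seq_along(p)
  new("RankTable",
    rows = data.frame(id = ids, probability = unname(p), rank = rank,
      stringsAsFactors = FALSE),
    modelTag = modelTag)
}

#' Aggregate ranks across models
#'
#' Combines per-model rank tables over an identical candidate set into mean
#' ranks (arithmetic mean), ordered ascending — the candidate that "ranks last
#' on average" has the maximum mean rank. Permutation-invariant in the list
#' order.
#'
#' @param rankTables list of \linkS4class{RankTable} objects over the same ids.
#' @return data.frame with columns id, one \code{rank_<modelTag>} per input
#'   table, and \code{mean_rank}, sorted by mean_rank ascending (stable).
#' @export
aggregateRanks <- function(rankTables) {
  stopifnot(length(rankTables) >= 1L,
    all(vapply(rankTables, is, logical(1), "RankTable")))
  ids <- rankRows(rankTables[[1L]])$id
  for (t in rankTables[-1L]) {
    if (!setequal(rankRows(t)$id, ids))
      stop("all rank tables must cover the identical candidate id set")
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(rankTables)) {
    rows <- rankRows(rankTables[[i]])
    tag <- rankTables[[i]]@modelTag
    col <- paste0("rank_", if (nzchar(tag)) tag else i)
    while (col %in% names(out)) col <- paste0(col, ".", i)
    out[[col]] <- rows$rank[match(ids, rows$id)]
  }
  rankCols <- grep("^rank_", names(out), value = TRUE)
  out$mean_rank <- rowMeans(as.matrix(out[, rankCols, drop = FALSE]))
  out[order(out$mean_rank), , drop = FALSE]
}

#' Write a rank table as CSV
#'
#' @param x a \linkS4class{RankTable} or the data.frame from
#'   \code{\link{aggregateRanks}}.
#' @param path output path.
#' @export
writeRankTable <- function(x, path) {
  df <- if (is(x, "RankTable")) rankRows(x) else x
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' The screening candidate fixture: 19 decoction constituents plus the control
#'
#' Loads the shipped candidate list: the 19 constituents of the Erhuang
#' decoction plus dexamethasone as control drug. Curated structures for these
#' natural products are not bundled: the \code{smiles} column is empty by
#' default (user-suppliable), and a \code{synthetic_smiles} column carries
#' clearly-labelled synthetic stand-in structures used by examples and tests.
#'
#' @param useSyntheticSmiles if TRUE, the synthetic stand-ins are returned in
#'   the \code{smiles} column.
#' @return data.frame with columns id, name, smiles.
#' @export
ehdCandidates <- function(useSyntheticSmiles = FALSE) {
  path <- system.file("extdata", "ehd_candidates.csv", package = "forgeNet",
    mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
    colClasses = c(smiles = "character"))
  df$smiles[is.na(df$smiles)] <- ""
  if (useSyntheticSmiles) df$smiles <- df$synthetic_smiles
  df[, c("id", "name", "smiles")]
}
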