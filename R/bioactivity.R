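#' Bioactivity score per compound
#'
#' For each compound, \deqn{B = \frac{1}{n} \sum_{i=1}^{n} a(i)\,g(i)} with
#' `n` the number of accessions, `a(i)` the compound's relative peak area
#' (percent) in accession `i`'s oil and `g(i)` the germination inhibition
#' (percent) observed for that oil. With `a` and `g` both on 0-100, the
#' score lives on 0-10,000: a hypothetical oil made of a single fully
#' inhibitory compound scores exactly 10,000. The score increases both with
#' a compound's abundance and with its source oils' bioactivity, which is
#' what makes it a filter for activity-guided fractionation.
#'
#' Mildly negative inhibitions (sampling noise around an inactive oil) are
#' clamped to 0 inside the score with a warning — the formula presumes
#' inhibition, and a negative `g` would otherwise reward absence.
#'
#' @param am an [abundance_matrix()] (accessions x compounds).
#' @param g named numeric vector of inhibition percentages, one per
#'   accession of `am`.
#' @return data.frame of class `bioactivity_table` with columns `compound`,
#'   `score`; attributes `terms` (the accession x compound matrix of
#'   `a(i) * g(i)` contributions) and `n`.
#' @examples
#' am <- abundance_matrix(matrix(c(30, 50), 2, 1,
#'                        dimnames = list(c("a1", "a2"), "menthone")))
#' bioactivity_score(am, c(a1 = 80, a2 = 40))
#' @export
bioactivity_score <- function(am, g) {
  stopifnot(inherits(am, "abundance_matrix"))
  missing <- setdiff(rownames(am), names(g))
  if (length(missing))
    mint_error(sprintf("no inhibition value for accession '%s'", missing[1]),
               "mint_score_error")
  g <- as.numeric(g[rownames(am)])
  if (any(g < 0)) {
    warning(sprintf(
      "%d negative inhibition value(s) clamped to 0 for scoring",
      sum(g < 0)))
    g <- pmax(g, 0)
  }
  n <- nrow(am)
  terms <- unclass(am) * g          # row-wise a(i) * g(i)
  scores <- colSums(terms) / n
  structure(data.frame(compound = colnames(am), score = unname(scores),
                       stringsAsFactors = FALSE),
            terms = terms, n = n,
            class = c("bioactivity_table", "data.frame"))
}

#' Rank candidate allelochemicals by bioactivity score
#'
#' Orders compounds by descending score, breaking ties by compound name
#' (tied scores are reported as tied). Compounds in `exclude` — typically a
#' positive control whose activity is already established, such as citral —
#' are listed separately rather than dropped silently.
#'
#' @param bt a [bioactivity_score()] table.
#' @param exclude character vector of compounds to set aside.
#' @return list of class `candidate_ranking` with `ranked` (columns
#'   `rank`, `compound`, `score`, `tied`) and `excluded`.
#' @export
rank_candidates <- function(bt, exclude = character()) {
  stopifnot(inherits(bt, "bioactivity_table"), nrow(bt) >= 1)
  excl <- bt[bt$compound %in% exclude, , drop = FALSE]
  keep <- bt[!bt$compound %in% exclude, , drop = FALSE]
  ord <- order(-keep$score, keep$compound)
  ranked <- keep[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  ranked$tied <- duplicated(ranked$score) |
    duplicated(ranked$score, fromLast = TRUE)
  rownames(ranked) <- NULL
  rownames(excl) <- NULL
  structure(list(ranked = ranked[, c("rank", "compound", "score", "tied")],
                 excluded = excl),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, n = 5, ...) {
  cat("Candidate ranking by bioactivity score\n")
  top <- utils::head(x$ranked, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %2d. %-24s B = %8.1f%s\n", top$rank[i], top$compound[i],
                top$score[i], if (top$tied[i]) " (tied)" else ""))
  if (nrow(x$ranked) > n)
    cat(sprintf("  ... %d more\n", nrow(x$ranked) - n))
  if (nrow(x$excluded))
    cat(sprintf("  excluded (positive controls): %s\n",
                paste(x$excluded$compound, collapse = ", ")))
  invisible(x)
}

#' Heat-map display matrix of abundances with appended scores
#'
#' Rows are compounds ordered by descending bioactivity score, columns the
#' accessions plus a final `score` column. Abundance values are copied
#' bit-identically from the abundance matrix; nothing is normalized.
#'
#' @param am an [abundance_matrix()].
#' @param bt the matching [bioactivity_score()] table.
#' @return numeric matrix of dimension (compounds, accessions + 1).
#' @export
heatmap_matrix <- function(am, bt) {
  stopifnot(inherits(am, "abundance_matrix"),
            inherits(bt, "bioactivity_table"))
  if (!setequal(colnames(am), bt$compound))
    mint_error("abundance matrix and score table disagree on compounds",
               "mint_score_error")
  ord <- order(-bt$score, bt$compound)
  compounds <- bt$compound[ord]
  out <- cbind(t(unclass(am))[compounds, , drop = FALSE],
               score = bt$score[ord])
  out
}
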