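#' Construct / validate a peak table
#'
#' A peak table holds one accession's GC profile as (compound, relative peak
#' area in percent of total ion signal). Areas must be non-negative, compound
#' names unique after whitespace normalization, and the total area at most
#' 100 (plus a 1e-6 tolerance for rounded inputs).
#'
#' @param compound character vector of compound names.
#' @param area numeric vector of relative peak areas (percent).
#' @param accession accession id the table belongs to.
#' @return data.frame of class `peak_table` with attribute `accession`.
#' @export
peak_table <- function(compound, area, accession) {
  compound <- normalize_compound(compound)
  area <- as.numeric(area)
  if (length(compound) != length(area))
    mint_error("compound and area lengths differ", "mint_peak_error")
  bad <- which(is.na(area) | area < 0)
  if (length(bad))
    mint_error(sprintf("negative or missing area in row %d", bad[1]),
               "mint_peak_error")
  dup <- compound[duplicated(compound)]
  if (length(dup))
    mint_error(sprintf(
      "duplicate compound '%s'; pre-sum or pool it explicitly", dup[1]),
      "mint_peak_error")
  if (sum(area) > 100 + 1e-6)
    mint_error(sprintf("areas sum to %.6f > 100", sum(area)),
               "mint_peak_error")
  structure(data.frame(compound = compound, area = area,
                       stringsAsFactors = FALSE),
            accession = accession, class = c("peak_table", "data.frame"))
}

# Trim and collapse internal whitespace; case is preserved (matching is
# exact after normalization — synonyms are a data problem, not fuzzy code).
normalize_compound <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

#' Load a GC peak table from CSV
#'
#' Expects header columns `compound` and `area` (UTF-8). The accession id
#' defaults to the file name without extension.
#'
#' @param path CSV file path.
#' @param accession accession id (default: file name stem).
#' @return a [peak_table()].
#' @export
load_peak_table <- function(path, accession = NULL) {
  accession <- accession %||% sub("\\.[^.]*$", "", basename(path))
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("compound", "area") %in% names(df)))
    mint_error(sprintf("'%s' lacks compound/area columns", path),
               "mint_peak_error")
  peak_table(df$compound, df$area, accession)
}

#' Default isomer pooling map
#'
#' Members that interconvert (menthone/isomenthone by enolization) or are
#' isomeric (alpha-/beta-citral) are pooled before scoring.
#'
#' @return named character vector, member name -> pooled name.
#' @export
default_pooling <- function() {
  c("menthone" = "menthone/isomenthone",
    "isomenthone" = "menthone/isomenthone",
    "alpha-citral" = "citral",
    "beta-citral" = "citral")
}

#' Pool interconverting isomers in a peak table or abundance matrix
#'
#' Replaces each group of member compounds with a single pooled compound
#' whose area is the exact sum of the member areas; total area is preserved.
#' Pooling is idempotent: pooled names are not themselves members, so
#' applying the same map twice is the identity.
#'
#' @param x a [peak_table()] or [abundance_matrix()].
#' @param pooling named character vector member -> pooled name
#'   (default [default_pooling()]).
#' @return object of the same class with members replaced by pooled rows or
#'   columns.
#' @export
pool_isomers <- function(x, pooling = default_pooling()) {
  UseMethod("pool_isomers")
}

check_pooling <- function(present, pooling) {
  if (anyDuplicated(names(pooling)))
    mint_error("pooling keys must be distinct", "mint_pool_error")
  # Merging members into a name that already exists as a distinct compound
  # would conflate the two; a pooled name with no members present is just a
  # previously pooled table, which must stay legal (idempotence).
  active_targets <- unique(unname(pooling[intersect(present,
                                                    names(pooling))]))
  clash <- intersect(active_targets, setdiff(present, names(pooling)))
  if (length(clash))
    mint_error(sprintf(
      "pooled name '%s' collides with an unpooled compound", clash[1]),
      "mint_pool_error")
}

#' @export
pool_isomers.peak_table <- function(x, pooling = default_pooling()) {
  check_pooling(x$compound, pooling)
  hit <- x$compound %in% names(pooling)
  if (!any(hit)) return(x)
  pooled_name <- unname(pooling[x$compound[hit]])
  sums <- tapply(x$area[hit], pooled_name, sum)
  first_pos <- tapply(which(hit), pooled_name, min)
  keep <- x[!hit, , drop = FALSE]
  add <- data.frame(compound = names(sums), area = as.numeric(sums),
                    stringsAsFactors = FALSE)
  out <- rbind(keep, add)
  out <- out[order(c(which(!hit), as.integer(first_pos))), , drop = FALSE]
  rownames(out) <- NULL
  peak_table(out$compound, out$area, attr(x, "accession"))
}

#' @export
pool_isomers.abundance_matrix <- function(x, pooling = default_pooling()) {
  check_pooling(colnames(x), pooling)
  hit <- colnames(x) %in% names(pooling)
  if (!any(hit)) return(x)
  pooled_name <- unname(pooling[colnames(x)[hit]])
  groups <- split(which(hit), pooled_name)
  first_pos <- vapply(groups, min, numeric(1))
  pooled_cols <- vapply(groups, function(idx)
    rowSums(x[, idx, drop = FALSE]), numeric(nrow(x)))
  if (nrow(x) == 1L) pooled_cols <- matrix(pooled_cols, nrow = 1,
                                           dimnames = list(rownames(x),
                                                           names(groups)))
  out <- cbind(x[, !hit, drop = FALSE], pooled_cols)
  colnames(out) <- c(colnames(x)[!hit], names(groups))
  out <- out[, order(c(which(!hit), first_pos)), drop = FALSE]
  abundance_matrix(out)
}

#' Construct / validate an abundance matrix
#'
#' The accession-by-compound matrix of relative peak areas (percent) that
#' houses the `a(i)` terms of the bioactivity score. Entries are
#' non-negative and each row sums to at most 100 (+1e-6). Values are never
#' renormalized: the score is defined on raw relative peak areas.
#'
#' @param m numeric matrix with accession rownames and compound colnames.
#' @return matrix of class `abundance_matrix`.
#' @export
abundance_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    mint_error("abundance matrix needs accession and compound names",
               "mint_matrix_error")
  if (any(m < 0))
    mint_error("abundance matrix entries must be non-negative",
               "mint_matrix_error")
  if (any(rowSums(m) > 100 + 1e-6))
    mint_error("abundance matrix rows must sum to <= 100",
               "mint_matrix_error")
  class(m) <- c("abundance_matrix", class(m))
  m
}

#' Assemble peak tables into an abundance matrix
#'
#' Takes the union of compound names across tables (first-seen order); a
#' compound absent from a table gets area 0. Row order follows the input
#' order of tables. Assembly only places values, it never changes them.
#'
#' @param tables list of [peak_table()] objects with distinct accessions.
#' @return an [abundance_matrix()].
#' @export
build_abundance_matrix <- function(tables) {
  stopifnot(length(tables) >= 1)
  accs <- vapply(tables, function(t) as.character(attr(t, "accession")),
                 character(1))
  if (anyDuplicated(accs))
    mint_error(sprintf("duplicate accession id '%s'",
                       accs[duplicated(accs)][1]), "mint_matrix_error")
  compounds <- unique(unlist(lapply(tables, `[[`, "compound")))
  m <- matrix(0, nrow = length(accs), ncol = length(compounds),
              dimnames = list(accs, compounds))
  for (k in seq_along(tables)) {
    t <- tables[[k]]
    m[k, t$compound] <- t$area
  }
  abundance_matrix(m)
}

#' Read/write an abundance matrix as wide CSV
#'
#' @param m an [abundance_matrix()].
#' @param path CSV path (first column `accession`, then compounds).
#' @return `path` invisibly (write) or an [abundance_matrix()] (read).
#' @export
write_abundance_matrix <- function(m, path) {
  df <- data.frame(accession = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  abundance_matrix(m)
}
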