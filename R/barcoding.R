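#' Merge a forward and reverse sequencing read into a consensus
#'
#' Aligns the forward read against the reverse-complemented reverse read by
#' an exhaustive ungapped offset scan, picks the offset maximizing the
#' number of matching bases (ties: longer overlap, then smaller shift), and
#' returns the consensus over the union of the two reads. Positions where
#' the reads disagree become `N` (no quality scores are available to pick a
#' winner); an `N` in one read defers to the other.
#'
#' @param forward,reverse character scalars (nucleotide strings). `reverse`
#'   is given in sequencing orientation and is reverse-complemented here.
#' @param min_overlap minimum acceptable overlap length; a best alignment
#'   with a shorter overlap raises a merge failure (`mint_merge_error`).
#' @return the consensus sequence as a character scalar.
#' @examples
#' merge_reads("ACGTACGTACGTACGTACGT", revcomp("ACGTACGTACGTACGTACGT"),
#'             min_overlap = 10)
#' @export
merge_reads <- function(forward, reverse, min_overlap = 10) {
  stopifnot(is.character(forward), is.character(reverse),
            nzchar(forward), nzchar(reverse), min_overlap >= 1)
  fv <- strsplit(toupper(forward), "", fixed = TRUE)[[1]]
  rv <- strsplit(revcomp(toupper(reverse)), "", fixed = TRUE)[[1]]
  n1 <- length(fv)
  n2 <- length(rv)
  acgt <- c("A", "C", "G", "T")
  best <- list(score = -1L, ov = 0L, s = NA_integer_)
  for (s in seq(-(n2 - 1L), n1 - 1L)) {
    i1 <- max(1L, s + 1L)
    i2 <- min(n1, s + n2)
    ov <- i2 - i1 + 1L
    if (ov <= 0L) next
    fi <- i1:i2
    fseg <- fv[fi]
    rseg <- rv[fi - s]
    score <- sum(fseg == rseg & fseg %in% acgt)
    if (score < 0.75 * ov) next  # spurious overlap, not a real alignment
    if (score > best$score ||
        (score == best$score && ov > best$ov) ||
        (score == best$score && ov == best$ov && abs(s) < abs(best$s))) {
      best <- list(score = score, ov = ov, s = s)
    }
  }
  if (best$ov < min_overlap)
    mint_error(sprintf(
      "merge failure: best overlap (%d nt) is shorter than min_overlap (%d)",
      best$ov, as.integer(min_overlap)), "mint_merge_error")
  s <- best$s
  span <- seq(min(1L, s + 1L), max(n1, s + n2))
  cons <- vapply(span, function(p) {
    fb <- if (p >= 1L && p <= n1) fv[p] else NA_character_
    rp <- p - s
    rb <- if (rp >= 1L && rp <= n2) rv[rp] else NA_character_
    if (is.na(fb)) return(rb)
    if (is.na(rb)) return(fb)
    if (fb == rb) return(fb)
    if (fb == "N") return(rb)
    if (rb == "N") return(fb)
    "N"
  }, character(1))
  paste(cons, collapse = "")
}

# Leftmost (or rightmost) start of an approximate occurrence of `pattern`
# in `subject`, Hamming distance <= max_mismatch; NA if absent.
find_primer <- function(subject, pattern, max_mismatch, from_right = FALSE) {
  sv <- strsplit(subject, "", fixed = TRUE)[[1]]
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  k <- length(pv)
  n <- length(sv)
  if (k > n) return(NA_integer_)
  starts <- seq_len(n - k + 1L)
  if (from_right) starts <- rev(starts)
  for (i in starts) {
    if (hamming(sv[i:(i + k - 1L)], pv) <= max_mismatch) return(i)
  }
  NA_integer_
}

#' Trim a merged amplicon to the barcode region between its primers
#'
#' Locates the forward primer (leftmost approximate match) and the
#' reverse-complemented reverse primer (rightmost approximate match) and
#' returns the subsequence strictly between them: from the first nucleotide
#' downstream of the forward primer to the nucleotide preceding the reverse
#' primer site. Matching is ungapped with at most `max_mismatch` Hamming
#' mismatches.
#'
#' @param seq character scalar, the merged amplicon.
#' @param fwd_primer,rev_primer primer sequences, 5'->3' as ordered.
#' @param max_mismatch maximum mismatches tolerated per primer (default 0).
#' @return the trimmed barcode sequence (possibly empty).
#' @export
trim_to_primers <- function(seq, fwd_primer, rev_primer, max_mismatch = 0) {
  stopifnot(nzchar(fwd_primer), nzchar(rev_primer), max_mismatch >= 0)
  s <- toupper(seq)
  fp <- toupper(fwd_primer)
  rp <- revcomp(toupper(rev_primer))
  i <- find_primer(s, fp, max_mismatch)
  if (is.na(i))
    mint_error(sprintf("forward primer not found within %d mismatches",
                       as.integer(max_mismatch)),
               "mint_trim_error", primer = "forward")
  j <- find_primer(s, rp, max_mismatch, from_right = TRUE)
  if (is.na(j))
    mint_error(sprintf("reverse primer not found within %d mismatches",
                       as.integer(max_mismatch)),
               "mint_trim_error", primer = "reverse")
  start <- i + nchar(fp)    # first base downstream of the forward primer
  end <- j - 1L             # base preceding the reverse primer site
  if (end < start - 1L)
    mint_error("primer sites overlap or are out of order", "mint_trim_error")
  if (end < start) return("")
  substr(s, start, end)
}

#' Pairwise distances from an alignment
#'
#' Computes a symmetric distance matrix under pairwise deletion: for each
#' sequence pair only sites where both sequences have an unambiguous base
#' (A/C/G/T) are compared; gaps and `N` are excluded pair-by-pair.
#' `p-distance` is mismatches over comparable sites. `K2P` is the Kimura
#' two-parameter distance
#' \eqn{d = -\frac{1}{2}\log\{(1-2P-Q)\sqrt{1-2Q}\}} with `P` the transition
#' and `Q` the transversion proportion.
#'
#' @param aln character matrix (sequences x sites) with rownames.
#' @param model `"p-distance"` (default) or `"K2P"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln, model = c("p-distance", "K2P")) {
  model <- match.arg(model)
  stopifnot(is.matrix(aln), !is.null(rownames(aln)), ncol(aln) >= 1)
  labs <- rownames(aln)
  n <- length(labs)
  acgt <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  ok <- matrix(aln %in% acgt, nrow = n)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      m <- sum(comp)
      if (m == 0)
        mint_error(sprintf("no comparable sites between '%s' and '%s'",
                           labs[i], labs[j]), "mint_distance_error")
      a <- aln[i, comp]
      b <- aln[j, comp]
      if (model == "p-distance") {
        d <- sum(a != b) / m
      } else {
        diff <- a != b
        ts <- sum(diff & ((a %in% purine) == (b %in% purine)))
        P <- ts / m
        Q <- (sum(diff) - ts) / m
        w1 <- 1 - 2 * P - Q
        w2 <- 1 - 2 * Q
        if (w1 <= 0 || w2 <= 0)
          mint_error(sprintf(
            "K2P distance undefined for '%s' vs '%s' (sequences too divergent)",
            labs[i], labs[j]), "mint_distance_error")
        d <- -0.5 * log(w1 * sqrt(w2))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

validate_dist_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm)
  if (is.null(rownames(dm)))
    mint_error("distance matrix needs labels", "mint_distance_error")
  colnames(dm) <- rownames(dm)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-9))
    mint_error("asymmetric distance matrix", "mint_distance_error")
  if (any(diag(dm) != 0))
    mint_error("distance matrix diagonal must be zero", "mint_distance_error")
  if (any(dm < 0))
    mint_error("negative distances", "mint_distance_error")
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: at each step the pair minimizing
#' \eqn{Q(i,j) = (n-2) d(i,j) - R_i - R_j} is joined, with branch lengths
#' from the standard three-point formulas. Two deterministic conventions are
#' imposed so that results are reproducible and testable: (i) ties in Q are
#' broken by the lexicographically smallest pair of cluster labels (a
#' cluster is labelled by its smallest leaf), and (ii) a negative estimated
#' branch length is clamped to zero with the excess transferred to its
#' sister branch, preserving the joined pair's distance.
#'
#' @param dm symmetric numeric matrix with labels (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(dm) {
  D <- validate_dist_matrix(dm)
  n <- nrow(D)
  if (n < 3)
    mint_error("neighbor joining needs at least 3 taxa", "mint_tree_error")
  sub <- rownames(D)   # newick fragment per active cluster
  key <- rownames(D)   # smallest contained leaf label (tie-breaking)
  while (n > 3) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    k1 <- pmin(key[cand[, 1]], key[cand[, 2]])
    k2 <- pmax(key[cand[, 1]], key[cand[, 2]])
    pick <- cand[order(k1, k2)[1], ]
    i <- pick[1]
    j <- pick[2]
    d_ij <- D[i, j]
    bi <- d_ij / 2 + (R[i] - R[j]) / (2 * (n - 2))
    bj <- d_ij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(0, bi + bj); bj <- 0 }
    new_sub <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], bi, sub[j], bj)
    new_key <- min(key[i], key[j])
    d_new <- pmax((D[i, ] + D[j, ] - d_ij) / 2, 0)
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    labs <- c(rownames(D)[seq_along(keep)], paste0(".joined", n))
    dimnames(D) <- list(labs, labs)
    sub <- c(sub[keep], new_sub)
    key <- c(key[keep], new_key)
    n <- n - 1
  }
  b <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
         (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
         (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  b <- pmax(b, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 sub[1], b[1], sub[2], b[2], sub[3], b[3])
  ape::read.tree(text = nwk)
}

# Canonical key for a bipartition given one side's labels: the side not
# containing the alphabetically first taxon, sorted and joined. NA for
# trivial splits.
bipartition_key <- function(side, all_labels) {
  n <- length(all_labels)
  if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
  anchor <- min(all_labels)
  if (anchor %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' @param tree an `ape::phylo`.
#' @return character vector of canonical bipartition keys (each key lists
#'   the side not containing the alphabetically first taxon).
#' @export
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) bipartition_key(labs[idx], labs),
                 character(1))
  unique(keys[!is.na(keys)])
}

#' Neighbor-joining tree with bootstrap support, rooted on an outgroup
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' neighbor-joining tree for each replicate, and scores each bipartition of
#' the full-alignment tree by the percentage of replicates containing it.
#' The returned tree is rooted on the outgroup branch; supports are stored
#' as internal node labels (empty for the root and for nodes whose split is
#' trivial) and in `tree$node.support`.
#'
#' @param aln character matrix (sequences x sites).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param rng_seed integer seed; the same seed reproduces the same supports.
#' @param model distance model, see [pairwise_distance()].
#' @param outgroup accession id to root on (must be in the alignment).
#' @return rooted `ape::phylo` with node labels carrying support
#'   percentages and a `support` attribute (data.frame bipartition/support).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, rng_seed = 1L,
                              model = "p-distance", outgroup) {
  stopifnot(is.matrix(aln), n_reps >= 1)
  if (!outgroup %in% rownames(aln))
    mint_error(sprintf("outgroup '%s' absent from the alignment", outgroup),
               "mint_tree_error")
  base <- neighbor_joining(pairwise_distance(aln, model))
  rooted <- ape::root(base, outgroup = outgroup, resolve.root = TRUE)
  counts <- new.env(parent = emptyenv())
  n_ok <- 0L
  with_stream(rng_seed, "bootstrap", {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      keys <- tryCatch(
        tree_bipartitions(neighbor_joining(
          pairwise_distance(aln[, cols, drop = FALSE], model))),
        mint_error = function(e) NULL)
      if (is.null(keys)) next
      n_ok <- n_ok + 1L
      for (k in keys)
        assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L,
               counts)
    }
  })
  if (n_ok == 0L)
    mint_error("all bootstrap replicates failed", "mint_tree_error")
  labs <- rooted$tip.label
  n_tip <- length(labs)
  support <- rep(NA_real_, rooted$Nnode)
  parts <- ape::prop.part(rooted)   # clade tip sets per internal node
  for (nd in seq_len(rooted$Nnode)) {
    k <- bipartition_key(labs[parts[[nd]]], labs)
    if (is.na(k)) next
    cnt <- if (exists(k, counts)) get(k, counts) else 0L
    support[nd] <- 100 * cnt / n_ok
  }
  rooted$node.label <- ifelse(is.na(support), "",
                              formatC(support, format = "g", digits = 6))
  rooted$node.support <- support
  keys <- tree_bipartitions(rooted)
  attr(rooted, "support") <- data.frame(
    bipartition = keys,
    support = vapply(keys, function(k) {
      100 * (if (exists(k, counts)) get(k, counts) else 0L) / n_ok
    }, numeric(1)),
    row.names = NULL)
  attr(rooted, "n_replicates") <- n_ok
  rooted
}

#' Flag accessions whose declared species conflicts with their placement
#'
#' For each accession, walks rootward to the nearest well-supported clade
#' (bootstrap support >= `min_support`) containing at least one other
#' accession, and compares the accession's declared species with the strict
#' majority of declared species among the clade's other members. Status per
#' accession: `"ok"` (majority agrees), `"mislabelled"` (majority is a
#' different species — `inferred_species` gives it), `"unresolved"` (no
#' supported informative clade, or no strict majority, as happens for
#' species a marker cannot separate), or `"untestable"` (no other accession
#' declares the same species, so there is no reference to test against).
#'
#' @param tree rooted `ape::phylo` from [bootstrap_support()] (node labels
#'   or `node.support` carry support percentages).
#' @param declared named character vector, accession -> declared species.
#' @param min_support support threshold in percent (default 65, the weakest
#'   support still worth interpreting in small barcode panels).
#' @return data.frame with columns `accession`, `declared`, `status`,
#'   `inferred_species`, `support`.
#' @export
flag_mislabels <- function(tree, declared, min_support = 65) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (!all(labs %in% names(declared)))
    mint_error("every leaf needs a declared species", "mint_label_error")
  declared <- declared[labs]
  if (length(unique(declared)) < 2)
    mint_error("at least two declared species are required",
               "mint_label_error")
  n_tip <- length(labs)
  support <- tree$node.support
  if (is.null(support)) {
    support <- suppressWarnings(as.numeric(tree$node.label))
    if (is.null(tree$node.label)) support <- rep(NA_real_, tree$Nnode)
  }
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  clade_tips <- ape::prop.part(tree)

  out <- lapply(seq_len(n_tip), function(tip) {
    acc <- labs[tip]
    row <- data.frame(accession = acc, declared = unname(declared[acc]),
                      status = NA_character_,
                      inferred_species = NA_character_,
                      support = NA_real_, stringsAsFactors = FALSE)
    if (sum(declared == declared[acc]) < 2) {
      row$status <- "untestable"
      return(row)
    }
    nd <- parent[tip]
    while (nd != 0L) {
      idx <- nd - n_tip
      supp <- if (nd == root) NA_real_ else support[idx]
      if (!is.na(supp) && supp >= min_support) {
        others <- setdiff(labs[clade_tips[[idx]]], acc)
        # one neighbour is no reference majority: keep walking rootward
        if (length(others) >= 2) {
          tab <- table(declared[others])
          top <- names(tab)[which.max(tab)]
          if (max(tab) * 2 > length(others) &&
              sum(tab == max(tab)) == 1) {
            row$support <- supp
            if (top == declared[acc]) {
              row$status <- "ok"
            } else {
              row$status <- "mislabelled"
              row$inferred_species <- top
            }
            return(row)
          }
          # supported but uninformative clade (species not separated here)
          row$status <- "unresolved"
          row$support <- supp
          return(row)
        }
      }
      if (nd == root) break
      nd <- parent[nd]
    }
    row$status <- "unresolved"
    row
  })
  do.call(rbind, out)
}

#' Authenticate an accession panel from files
#'
#' Convenience wrapper: reads an aligned FASTA and a declared-labels CSV
#' (columns `accession`, `declared_taxon`), builds the bootstrap
#' neighbor-joining tree rooted on `outgroup`, and flags label conflicts.
#'
#' @param fasta path to the aligned FASTA.
#' @param labels path to the labels CSV.
#' @param outgroup accession id used to root the tree.
#' @param n_reps bootstrap replicates.
#' @param rng_seed integer seed.
#' @param model distance model.
#' @param min_support flagging threshold (percent).
#' @return list with elements `tree`, `flags`, `alignment`, `declared`.
#' @export
authenticate_panel <- function(fasta, labels, outgroup, n_reps = 1000L,
                               rng_seed = 1L, model = "p-distance",
                               min_support = 65) {
  aln <- read_fasta_alignment(fasta)
  lab <- read.csv(labels, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "declared_taxon") %in% names(lab)))
  declared <- setNames(lab$declared_taxon, lab$accession)
  tree <- bootstrap_support(aln, n_reps = n_reps, rng_seed = rng_seed,
                            model = model, outgroup = outgroup)
  flags <- flag_mislabels(tree, declared, min_support = min_support)
  list(tree = tree, flags = flags, alignment = aln, declared = declared)
}
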