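# Independent oracles and fixture builders used across test files.

# Random tree with strictly positive branch lengths; its cophenetic matrix
# is an additive distance matrix by construction.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
  tree <- ape::unroot(tree)
  list(tree = tree, dist = ape::cophenetic.phylo(tree))
}

# Least-squares branch lengths of a fixed topology for a distance matrix:
# solve ||A b - d|| over the edge-incidence design matrix A (rows = taxon
# pairs, columns = edges, 1 if the edge lies on the path between the pair).
ls_rss_for_topology <- function(topo, D) {
  labs <- topo$tip.label
  n <- length(labs)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(topo$edge))
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    nodes <- ape::nodepath(topo, i, j)
    on_path <- (topo$edge[, 1] %in% nodes) & (topo$edge[, 2] %in% nodes)
    A[r, on_path] <- 1
    d[r] <- D[labs[i], labs[j]]
  }
  fit <- lm.fit(A, d)
  sum(fit$residuals^2)
}

# Brute force: the unrooted topology (over all of them) whose least-squares
# fit to D has minimal RSS. Independent of the neighbor-joining code path.
best_ls_topology <- function(D) {
  labs <- rownames(D)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(topos, ls_rss_for_topology, numeric(1), D = D)
  topos[[which.min(rss)]]
}

sorted_bipartitions <- function(tree) sort(tree_bipartitions(tree))

# Canonical bipartition key, re-derived for tests: the side not containing
# the alphabetically first taxon, sorted and joined with "|".
bipartition_key_for_test <- function(side, all_labels) {
  if (min(all_labels) %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

# Small three-species scenario with two accessions per species and a
# well-separated tree (inter-species distance >> intra-species).
mini_scenario <- function(mislabel_pairs = list(), n_per_species = 2,
                          intra = 0.004, inter = 0.12) {
  species_names <- c("species A", "species B", "species C")
  accessions <- character()
  species <- character()
  clades <- character(3)
  for (s in seq_along(species_names)) {
    ids <- paste0("ACC", s, seq_len(n_per_species))
    accessions <- c(accessions, ids)
    species[ids] <- species_names[s]
    tips <- paste0(ids, ":", intra / 2, collapse = ",")
    clades[s] <- paste0("(", tips, ")")
  }
  tree <- sprintf("(%s:%g,%s:%g,%s:%g);", clades[1], inter / 2,
                  clades[2], inter / 2, clades[3], inter / 2)
  compounds <- c("alpha", "beta", "gamma")
  m <- matrix(5, length(accessions), 3,
              dimnames = list(accessions, compounds))
  m[species == "species A", "alpha"] <- 40   # active compound rich here
  inh <- data.frame(
    treatment = c(accessions, "n-hexane"),
    dose = 0.1,
    inhibition = c(ifelse(species[accessions] == "species A", 0.8, 0.15), 0))
  scenario_config(
    accessions = accessions, species = species, compounds = compounds,
    active_compound = "alpha", mislabel_pairs = mislabel_pairs,
    oil_profile_means = m, true_inhibition = inh, true_tree = tree,
    seq_length = 500L)
}

# Random peak table on a fixed compound alphabet (areas scaled to sum
# below 100).
random_peak_table <- function(seed, accession = paste0("acc", seed),
                              alphabet = c("menthone", "isomenthone",
                                           "menthol", "limonene",
                                           "alpha-citral", "beta-citral",
                                           "carvone")) {
  set.seed(seed)
  k <- sample(2:length(alphabet), 1)
  compounds <- sample(alphabet, k)
  areas <- runif(k)
  areas <- areas / sum(areas) * runif(1, 50, 99.9)
  peak_table(compounds, areas, accession)
}
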