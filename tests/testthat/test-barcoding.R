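psba_fwd <- "GTTATGCATGAACGTAATGCTC"
trnh_rev <- "CGCGCATGGTGGATTCACAATCC"

test_that("read merging returns the consensus over the best overlap", {
  read <- "ACGTTGCAGGTCCATAGGCTA"
  expect_identical(merge_reads(read, revcomp(read), min_overlap = 10), read)

  # 20 nt overlap with one disagreement -> exactly one N at that position
  left <- "GATTACAGATTACAGGATCCTTAGACCA"       # ends with ...CCTTAGACCA
  rev_template <- "CCTTAGACCAGGTTCCAATGCA"      # starts with that overlap
  # full amplicon: left + tail of rev_template after the 10 nt junction
  amplicon <- paste0(left, substr(rev_template, 11, nchar(rev_template)))
  f_read <- substr(amplicon, 1, 24)
  r_read_fwd <- substr(amplicon, 5, nchar(amplicon))   # 20 nt overlap
  # plant a disagreement inside the overlap region of the reverse read
  ch <- strsplit(r_read_fwd, "")[[1]]
  ch[8] <- setdiff(c("A", "C", "G", "T"), ch[8])[1]
  r_read_fwd_mut <- paste(ch, collapse = "")
  merged <- merge_reads(f_read, revcomp(r_read_fwd_mut), min_overlap = 15)
  expect_equal(nchar(merged), nchar(amplicon))
  expect_equal(sum(strsplit(merged, "")[[1]] == "N"), 1)

  expect_error(merge_reads("AAAAAAAAAA", "CCCCCCCCCC", min_overlap = 10),
               class = "mint_merge_error")

  # an N in one read defers to the other
  expect_identical(merge_reads("ACGTACGTACNT", revcomp("ACGTACGTACGT"),
                               min_overlap = 10), "ACGTACGTACGT")
})

test_that("primer trimming extracts the insert between the barcode primers", {
  insert <- "ACGTACGT"
  seq <- paste0(psba_fwd, insert, revcomp(trnh_rev))
  expect_identical(trim_to_primers(seq, psba_fwd, trnh_rev, 0), insert)

  # primer with one mismatch still found when allowed
  fwd_mut <- psba_fwd
  substr(fwd_mut, 5, 5) <- "A"
  seq2 <- paste0(fwd_mut, insert, revcomp(trnh_rev))
  expect_error(trim_to_primers(seq2, psba_fwd, trnh_rev, 0),
               class = "mint_trim_error")
  expect_identical(trim_to_primers(seq2, psba_fwd, trnh_rev, 1), insert)

  err <- tryCatch(trim_to_primers(insert, psba_fwd, trnh_rev, 0),
                  mint_trim_error = function(e) e)
  expect_s3_class(err, "mint_trim_error")
  expect_identical(err$primer, "forward")
})

test_that("p-distance uses pairwise deletion; K2P matches the reference", {
  aln <- rbind(a = c("A", "C", "G", "T"),
               b = c("A", "C", "G", "T"),
               c = c("A", "C", "G", "A"),
               d = c("A", "C", "-", "T"))
  D <- pairwise_distance(aln)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.25)          # 1 mismatch / 4 sites
  expect_equal(D["a", "d"], 0)             # gap site excluded: 3 comparable
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))

  # cross-check both models against ape::dist.dna on a simulated alignment
  sc <- mini_scenario()
  panel <- generate_accession_panel(sc)
  sim <- generate_marker_sequences(panel, sc$true_tree, rng_seed = 13)
  bin <- ape::as.DNAbin(sim)
  D_p <- pairwise_distance(sim, "p-distance")
  ref_p <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
  expect_equal(D_p, ref_p[rownames(D_p), colnames(D_p)], tolerance = 1e-12)
  D_k <- pairwise_distance(sim, "K2P")
  ref_k <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(D_k, ref_k[rownames(D_k), colnames(D_k)], tolerance = 1e-12)

  no_sites <- rbind(x = c("A", "-"), y = c("-", "T"))
  err <- tryCatch(pairwise_distance(no_sites),
                  mint_distance_error = function(e) e)
  expect_match(conditionMessage(err), "x.*y")
})

test_that("neighbor joining: closed form for 3 taxa, exact recovery when additive", {
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(D3)
  got <- ape::cophenetic.phylo(tr3)[rownames(D3), colnames(D3)]
  expect_equal(got, D3)   # 3-point formulas reproduce the input exactly
  b <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(b[c("A", "B", "C")]), c(1, 2, 4))

  # 4-taxon tree ((A:1,B:2):1,(C:3,D:4)): additive matrix recovered exactly
  D4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D4["A", "B"] <- D4["B", "A"] <- 3
  D4["A", "C"] <- D4["C", "A"] <- 5
  D4["A", "D"] <- D4["D", "A"] <- 6
  D4["B", "C"] <- D4["C", "B"] <- 6
  D4["B", "D"] <- D4["D", "B"] <- 7
  D4["C", "D"] <- D4["D", "C"] <- 7
  tr4 <- neighbor_joining(D4)
  expect_identical(sorted_bipartitions(tr4), "C|D")
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(D4), colnames(D4)], D4)
  # oracle: least-squares over all 3 unrooted 4-taxon topologies agrees
  expect_identical(sorted_bipartitions(best_ls_topology(D4)),
                   sorted_bipartitions(tr4))

  expect_error(neighbor_joining(D4[1:2, 1:2]), class = "mint_tree_error")
  D_asym <- D4
  D_asym[1, 2] <- 99
  expect_error(neighbor_joining(D_asym), class = "mint_distance_error")
})

test_that("neighbor joining equals the brute-force least-squares topology on additive matrices", {
  for (n in 4:6) {
    for (seed in 1:8) {
      gen <- random_additive_matrix(n, seed = 100 * n + seed)
      nj <- neighbor_joining(gen$dist)
      expect_identical(sorted_bipartitions(nj),
                       sorted_bipartitions(gen$tree),
                       label = sprintf("n=%d seed=%d vs source", n, seed))
      expect_identical(sorted_bipartitions(nj),
                       sorted_bipartitions(best_ls_topology(gen$dist)),
                       label = sprintf("n=%d seed=%d vs LS oracle", n, seed))
      # additive input is reproduced exactly (tree metric)
      expect_equal(
        ape::cophenetic.phylo(nj)[rownames(gen$dist), colnames(gen$dist)],
        gen$dist, tolerance = 1e-8)
    }
  }
})

test_that("neighbor joining matches ape::nj topologies on noisy matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    gen <- random_additive_matrix(7, seed = seed)
    D <- gen$dist
    noise <- matrix(runif(49, 0, 0.05), 7)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    D <- D + noise
    expect_identical(sorted_bipartitions(neighbor_joining(D)),
                     sorted_bipartitions(ape::nj(as.dist(D))))
  }
})

test_that("bootstrap support: bounds, concordant blocks, determinism, order invariance", {
  # two divergent blocks: every informative column supports the same split
  block1 <- c("a1", "a2", "a3")
  block2 <- c("b1", "b2", "b3")
  n_sites <- 60
  aln <- rbind(
    matrix("A", 3, n_sites, dimnames = list(block1, NULL)),
    matrix("A", 3, n_sites, dimnames = list(block2, NULL)))
  aln[block2, seq(1, n_sites, by = 2)] <- "T"   # half informative, half constant
  tr <- bootstrap_support(aln, n_reps = 100, rng_seed = 5, outgroup = "b1")
  supp <- attr(tr, "support")
  expect_true(all(supp$support >= 0 & supp$support <= 100))
  key <- bipartition_key_for_test(block2, rownames(aln))
  expect_equal(supp$support[supp$bipartition == key], 100)

  tr2 <- bootstrap_support(aln, n_reps = 100, rng_seed = 5, outgroup = "b1")
  expect_identical(attr(tr, "support"), attr(tr2, "support"))

  # permuting the row order of the alignment leaves supports unchanged
  perm <- aln[c(4, 2, 6, 1, 3, 5), ]
  tr3 <- bootstrap_support(perm, n_reps = 100, rng_seed = 5, outgroup = "b1")
  s1 <- attr(tr, "support")
  s3 <- attr(tr3, "support")
  expect_identical(s1[order(s1$bipartition), ],
                   s3[order(s3$bipartition), ],
                   ignore_attr = TRUE)

  expect_error(bootstrap_support(aln, n_reps = 0, rng_seed = 1,
                                 outgroup = "b1"))
  expect_error(bootstrap_support(aln, n_reps = 10, rng_seed = 1,
                                 outgroup = "zz"), class = "mint_tree_error")
})

test_that("mislabel flagging recovers planted swaps and respects support", {
  sc <- mini_scenario(mislabel_pairs = list(c("ACC12", "ACC21")),
                      n_per_species = 3)
  panel <- generate_accession_panel(sc)
  aln <- generate_marker_sequences(panel, sc$true_tree, rng_seed = 17)
  tree <- bootstrap_support(aln, n_reps = 100, rng_seed = 2,
                            outgroup = "ACC31")
  declared <- setNames(panel$declared_species, panel$accession)
  flags <- flag_mislabels(tree, declared)
  expect_setequal(flags$accession[flags$status == "mislabelled"],
                  c("ACC12", "ACC21"))

  # consistent labels on the same tree -> nothing flagged
  truth <- setNames(panel$true_species, panel$accession)
  flags_ok <- flag_mislabels(tree, truth)
  expect_identical(flags_ok$accession[flags_ok$status == "mislabelled"],
                   character(0))

  # unreachable threshold -> everything unresolved
  flags_unres <- flag_mislabels(tree, declared, min_support = 101)
  expect_true(all(flags_unres$status == "unresolved"))

  # an accession whose declared species has no second member is untestable
  declared2 <- declared
  declared2["ACC11"] <- "species X"
  flags2 <- flag_mislabels(tree, declared2)
  expect_identical(flags2$status[flags2$accession == "ACC11"], "untestable")
})

test_that("planted mislabels are recovered with zero false positives on separated panels", {
  for (seed in 1:5) {
    sc <- mini_scenario(mislabel_pairs = list(c("ACC13", "ACC22")),
                        n_per_species = 3, intra = 0.004, inter = 0.1)
    panel <- generate_accession_panel(sc)
    aln <- generate_marker_sequences(panel, sc$true_tree, rng_seed = seed)
    tree <- bootstrap_support(aln, n_reps = 100, rng_seed = seed,
                              outgroup = "ACC31")
    flags <- flag_mislabels(tree, setNames(panel$declared_species,
                                           panel$accession))
    expect_setequal(flags$accession[flags$status == "mislabelled"],
                    c("ACC13", "ACC22"))
  }
})
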