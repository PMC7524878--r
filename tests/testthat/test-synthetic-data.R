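test_that("accession panel applies exactly the planted label swaps", {
  sc <- mini_scenario()
  panel <- generate_accession_panel(sc)
  expect_identical(panel$declared_species, panel$true_species)

  sc2 <- mini_scenario(mislabel_pairs = list(c("ACC11", "ACC21")))
  panel2 <- generate_accession_panel(sc2)
  differs <- panel2$accession[panel2$declared_species != panel2$true_species]
  expect_setequal(differs, c("ACC11", "ACC21"))
  # swapped, not scrambled
  expect_identical(
    panel2$declared_species[panel2$accession == "ACC11"],
    panel2$true_species[panel2$accession == "ACC21"])
  # deterministic: same config -> identical panel
  expect_identical(panel2, generate_accession_panel(sc2))
})

test_that("a mislabel pair naming an unknown accession is rejected", {
  expect_error(mini_scenario(mislabel_pairs = list(c("ACC11", "nope"))),
               class = "mint_config_error")
})

test_that("marker sequences follow the tree: zero rate, determinism, distances", {
  sc <- mini_scenario()
  panel <- generate_accession_panel(sc)
  a0 <- generate_marker_sequences(panel, sc$true_tree, seq_length = 200,
                                  mutation_rate = 0, rng_seed = 5)
  expect_true(all(apply(a0, 2, function(col) length(unique(col)) == 1)))

  a1 <- generate_marker_sequences(panel, sc$true_tree, rng_seed = 11)
  a2 <- generate_marker_sequences(panel, sc$true_tree, rng_seed = 11)
  expect_identical(a1, a2)

  # expected p-distance increases with path length on the true tree
  # (checked on the shipped tree, whose path lengths span many levels)
  psc <- paper_scenario()
  ppanel <- generate_accession_panel(psc)
  paln <- generate_marker_sequences(ppanel, psc$true_tree, rng_seed = 11)
  D <- pairwise_distance(paln)
  path <- ape::cophenetic.phylo(ape::read.tree(text = psc$true_tree))
  path <- path[rownames(D), colnames(D)]
  lower <- lower.tri(D)
  expect_gt(cor(D[lower], path[lower], method = "spearman"), 0.8)
  # same species (short path) vs different species
  D1 <- pairwise_distance(a1)
  expect_lt(D1["ACC11", "ACC12"], min(D1["ACC11", c("ACC21", "ACC31")]))

  expect_error(generate_marker_sequences(panel, "(X:1,Y:1,Z:1);"),
               class = "mint_config_error")
})

test_that("neighbor joining on simulated sequences recovers the generating topology", {
  # 6-leaf tree, rate scaled so the largest p-distance is ~0.15
  tree <- "((A:0.02,B:0.02):0.03,(C:0.02,D:0.02):0.03,(E:0.05,F:0.05):0.02);"
  truth <- sorted_bipartitions(ape::read.tree(text = tree))
  panel <- data.frame(accession = LETTERS[1:6])
  hits <- 0L
  for (s in 1:100) {
    aln <- generate_marker_sequences(panel, tree, seq_length = 600,
                                     rng_seed = s)
    nj <- neighbor_joining(pairwise_distance(aln))
    if (identical(sorted_bipartitions(nj), truth)) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("oil profiles are compositional with the active compound enriched", {
  sc <- mini_scenario()
  panel <- generate_accession_panel(sc)
  study <- panel[panel$role == "study", ]

  # degenerate simplex: a single compound whose mean saturates the row
  one <- scenario_config(
    accessions = c("x1", "x2"), species = c(x1 = "s", x2 = "t"),
    compounds = "only", active_compound = "only",
    oil_profile_means = matrix(100, 2, 1,
                               dimnames = list(c("x1", "x2"), "only")),
    true_inhibition = data.frame(treatment = "only", dose = 1,
                                 inhibition = 0.5))
  prof1 <- generate_oil_profiles(generate_accession_panel(one), one)
  expect_equal(unname(prof1[, "only"]), c(100, 100))

  am <- generate_oil_profiles(study, sc, rng_seed = 3)
  rich <- rownames(am)[sc$species[rownames(am)] == "species A"]
  poor <- setdiff(rownames(am), rich)
  expect_gt(mean(am[rich, "alpha"]), mean(am[poor, "alpha"]))

  # row sums stay below 100 over 1,000 seeded accession draws
  sums <- unlist(lapply(1:167, function(s)
    rowSums(generate_oil_profiles(study, sc, rng_seed = s))))
  expect_gte(length(sums), 1000)
  expect_true(all(sums <= 100 + 1e-9))
  expect_true(all(sums >= 0))
})

test_that("germination counts follow the binomial model", {
  base <- mini_scenario()
  # inhibition 1 -> nothing germinates; inhibition 0 -> control-like
  sc <- scenario_config(
    accessions = base$accessions, species = base$species,
    compounds = base$compounds, active_compound = "alpha",
    oil_profile_means = base$oil_profile_means,
    true_inhibition = data.frame(
      treatment = c("dead", "none", "half"), dose = 1,
      inhibition = c(1, 0, 0.5)),
    replicates = 10000L)
  g <- generate_germination_counts(sc, rng_seed = 4)
  expect_true(all(g$germinated[g$treatment == "dead"] == 0))
  expect_true(all(g$germinated <= g$sown))
  m_none <- mean(g$germinated[g$treatment == "none"])
  m_half <- mean(g$germinated[g$treatment == "half"])
  expect_equal(m_none, 100 * 0.95, tolerance = 0.01)
  # law of large numbers: treated/control ratio -> 1 - inhibition
  expect_equal(m_half / m_none, 0.5, tolerance = 0.02)
})

test_that("cytotoxicity counts follow the binomial model", {
  base <- mini_scenario()
  sc <- scenario_config(
    accessions = base$accessions, species = base$species,
    compounds = base$compounds, active_compound = "alpha",
    oil_profile_means = base$oil_profile_means,
    true_inhibition = base$true_inhibition,
    true_mortality = data.frame(
      compound = c("none", "hot"), line = "WT", dose = 0.2, time = 15,
      mortality = c(0, 0.9)),
    replicates = 10000L)
  m <- generate_cytotoxicity_counts(sc, rng_seed = 9)
  expect_true(all(m$stained[m$compound == "none"] == 0))
  expect_true(all(m$stained <= m$scored))
  expect_equal(mean(m$stained[m$compound == "hot"]) / 600, 0.9,
               tolerance = 0.005 / 0.9)
})

test_that("marker-line mortality exceeds wild type at the WT EC50 when shifted", {
  sc <- paper_scenario()
  tab <- sc$true_mortality
  wt_ec50 <- sc$line_ec50$ec50[sc$line_ec50$line == "WT"]
  # at every shared dose-response dose, tubulin-line truth >= WT truth
  dr <- tab[tab$compound == "menthone/isomenthone" & tab$time == 15 &
              tab$dose != 0.2, ]
  wt <- dr[dr$line == "WT", ]
  tub <- dr[dr$line == "tubulin-marker", ]
  wt <- wt[order(wt$dose), ]
  tub <- tub[order(tub$dose), ]
  expect_true(all(tub$mortality > wt$mortality))
  # the 4-fold divisor pins the EC50s
  expect_equal(wt_ec50 / sc$line_ec50$ec50[sc$line_ec50$line ==
                                             "tubulin-marker"], 4)
})

test_that("nucleus intensities shift from green to red with dose", {
  base <- mini_scenario()
  sc <- scenario_config(
    accessions = base$accessions, species = base$species,
    compounds = base$compounds, active_compound = "alpha",
    oil_profile_means = base$oil_profile_means,
    true_inhibition = base$true_inhibition,
    nucleus_response = data.frame(compound = "perm", ec50 = 0.1, slope = 2.5),
    nuclei_per_series = 5000L)
  doses <- c(0, 0.05, 0.1, 0.2, 1.6)
  nuc <- generate_nucleus_intensities(sc, doses = doses, rng_seed = 21)
  expect_true(all(nuc$green >= 0 & nuc$red >= 0))
  cls0 <- classify_nucleus(nuc$green[nuc$dose == 0], nuc$red[nuc$dose == 0])
  expect_gte(mean(cls0 == "green", na.rm = TRUE), 0.9)
  top <- max(doses)
  clsT <- classify_nucleus(nuc$green[nuc$dose == top],
                           nuc$red[nuc$dose == top])
  expect_gte(mean(clsT == "red", na.rm = TRUE), 0.9)
  ratio_by_dose <- vapply(doses, function(d) {
    sub <- nuc[nuc$dose == d, ]
    mean(sub$red / (sub$red + sub$green))
  }, numeric(1))
  expect_true(all(diff(ratio_by_dose) >= 0))
})

test_that("generators are deterministic and per-table streams are independent", {
  sc <- paper_scenario()
  expect_identical(generate_germination_counts(sc, rng_seed = 7),
                   generate_germination_counts(sc, rng_seed = 7))
  expect_identical(generate_cytotoxicity_counts(sc, rng_seed = 7),
                   generate_cytotoxicity_counts(sc, rng_seed = 7))
  # drawing one table does not perturb another (separate streams per tag)
  g1 <- generate_germination_counts(sc, rng_seed = 7)
  invisible(generate_cytotoxicity_counts(sc, rng_seed = 123))
  expect_identical(g1, generate_germination_counts(sc, rng_seed = 7))
})

test_that("simulate_study writes a complete, re-loadable bundle", {
  sc <- mini_scenario(mislabel_pairs = list(c("ACC11", "ACC21")))
  dir <- withr::local_tempdir()
  bundle <- simulate_study(sc, rng_seed = 2, dir = dir)
  expect_true(all(file.exists(bundle$sequences, bundle$labels,
                              bundle$germination, bundle$ground_truth)))
  aln <- read_fasta_alignment(bundle$sequences)
  expect_equal(sort(rownames(aln)), sort(bundle$panel$accession))
  truth <- jsonlite::read_json(bundle$ground_truth)
  expect_setequal(unlist(truth$planted_mislabels), c("ACC11", "ACC21"))
})
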