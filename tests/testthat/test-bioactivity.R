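make_am <- function(values, accessions, compounds) {
  abundance_matrix(matrix(values, nrow = length(accessions),
                          dimnames = list(accessions, compounds)))
}

test_that("bioactivity score: ceiling, zero case, and hand arithmetic", {
  # single pure compound, fully inhibitory everywhere -> exactly 10,000
  am <- make_am(100, c("a1", "a2", "a3"), "solo")
  bt <- bioactivity_score(am, c(a1 = 100, a2 = 100, a3 = 100))
  expect_identical(bt$score, 10000)

  am0 <- make_am(c(0, 0, 50, 60), c("a1", "a2"), c("absent", "present"))
  bt0 <- bioactivity_score(am0, c(a1 = 80, a2 = 40))
  expect_identical(bt0$score[bt0$compound == "absent"], 0)
  # (1/2)(30*80 + 50*40) = 2200
  am2 <- make_am(c(30, 50), c("a1", "a2"), "cmp")
  expect_equal(bioactivity_score(am2, c(a1 = 80, a2 = 40))$score, 2200)

  expect_error(bioactivity_score(am2, c(a1 = 80)),
               regexp = "a2", class = "mint_score_error")
  expect_warning(bioactivity_score(am2, c(a1 = -3, a2 = 40)),
                 regexp = "clamped")
})

test_that("score identities: linearity, accession scaling, normalization, order", {
  set.seed(31)
  am <- make_am(runif(12, 0, 8), paste0("a", 1:4), c("x", "y", "z"))
  g <- setNames(runif(4, 0, 100), paste0("a", 1:4))
  B <- bioactivity_score(am, g)$score

  # scaling all inhibitions by c scales every score by c
  expect_equal(bioactivity_score(am, g * 0.5)$score, B * 0.5)

  # scaling one accession's areas by c changes B by (c-1) * a * g / n
  c_fac <- 3
  am_s <- unclass(am)
  am_s["a2", ] <- am_s["a2", ] * c_fac
  B_s <- bioactivity_score(abundance_matrix(am_s), g)$score
  expect_equal(B_s - B,
               (c_fac - 1) * unclass(am)["a2", ] * g["a2"] / 4,
               ignore_attr = TRUE)

  # adding an all-zero accession rescales every score by n/(n+1)
  am_plus <- abundance_matrix(rbind(unclass(am), a5 = 0))
  B_plus <- bioactivity_score(am_plus, c(g, a5 = 50))$score
  expect_equal(B_plus, B * 4 / 5)

  # invariant to accession ordering
  perm <- c("a3", "a1", "a4", "a2")
  B_perm <- bioactivity_score(abundance_matrix(unclass(am)[perm, ]),
                              g[perm])$score
  expect_equal(B_perm, B)
})

test_that("ranking orders by score with lexicographic ties and explicit exclusions", {
  am <- make_am(c(12, 12,  12, 12,  5, 5,  20, 20),
                c("a1", "a2"), c("bravo", "alpha", "citral", "delta"))
  bt <- bioactivity_score(am, c(a1 = 60, a2 = 60))
  rk <- rank_candidates(bt, exclude = "citral")
  expect_identical(rk$ranked$compound[1], "delta")        # highest score
  expect_identical(rk$ranked$compound[2:3], c("alpha", "bravo"))  # tie, lexicographic
  expect_true(all(rk$ranked$tied[2:3]))
  expect_identical(rk$excluded$compound, "citral")        # listed, not dropped
  expect_identical(rk$ranked$rank, seq_len(nrow(rk$ranked)))

  single <- bioactivity_score(make_am(10, "a1", "only"), c(a1 = 50))
  expect_identical(rank_candidates(single)$ranked$rank, 1L)
})

test_that("heat-map matrix mirrors the ranking and copies values bit-identically", {
  set.seed(8)
  am <- make_am(runif(12, 0, 8), paste0("a", 1:3), c("x", "y", "z", "w"))
  bt <- bioactivity_score(am, setNames(runif(3, 20, 90), paste0("a", 1:3)))
  hm <- heatmap_matrix(am, bt)
  expect_equal(dim(hm), c(4, 3 + 1))
  expect_identical(rownames(hm), rank_candidates(bt)$ranked$compound)
  for (cmp in colnames(am))
    expect_identical(unname(hm[cmp, rownames(am)]), unname(am[, cmp]))
  expect_equal(unname(hm[, "score"]),
               bt$score[match(rownames(hm), bt$compound)])
})

test_that("the planted active compound ranks first in >= 95/100 synthetic studies", {
  sc <- paper_scenario()
  panel <- generate_accession_panel(sc)
  hits <- 0L
  for (seed in 1:100) {
    am <- pool_isomers(generate_oil_profiles(panel, sc, rng_seed = seed))
    germ <- generate_germination_counts(sc, rng_seed = seed)
    ctl <- germ$germinated[germ$treatment == "n-hexane"]
    g <- vapply(rownames(am), function(acc) {
      inhibition_percent(
        germ$germinated[germ$treatment == acc & germ$dose == 0.1],
        ctl)$inhibition
    }, numeric(1))
    g <- pmax(g, 0)
    rk <- rank_candidates(bioactivity_score(am, g), exclude = "citral")
    if (rk$ranked$compound[1] == "menthone/isomenthone") hits <- hits + 1L
  }
  expect_gte(hits, 95)
})
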