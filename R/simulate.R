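#' Generate the accession panel with true and declared species labels
#'
#' Declared labels equal the true species except for accessions named in the
#' scenario's `mislabel_pairs`, whose declared labels are swapped. This
#' emulates botanical-garden panels in which some plants turn out to be
#' mis-assigned when barcoded.
#'
#' Reference sequences (curated database anchors) are appended with
#' `role = "reference"` and can never be mislabelled.
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns `accession`, `true_species`,
#'   `declared_species`, `role` (`"study"` or `"reference"`).
#' @examples
#' panel <- generate_accession_panel(paper_scenario())
#' subset(panel, true_species != declared_species)
#' @export
generate_accession_panel <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  panel <- data.frame(
    accession = config$accessions,
    true_species = unname(config$species),
    declared_species = unname(config$species),
    role = "study",
    stringsAsFactors = FALSE)
  for (pair in config$mislabel_pairs) {
    i <- match(pair[1], panel$accession)
    j <- match(pair[2], panel$accession)
    if (is.na(i) || is.na(j))
      mint_error(sprintf("mislabel pair (%s) references an unknown accession",
                         paste(pair, collapse = ", ")), "mint_config_error")
    tmp <- panel$declared_species[i]
    panel$declared_species[i] <- panel$declared_species[j]
    panel$declared_species[j] <- tmp
  }
  if (length(config$references)) {
    panel <- rbind(panel, data.frame(
      accession = names(config$references),
      true_species = unname(config$references),
      declared_species = unname(config$references),
      role = "reference",
      stringsAsFactors = FALSE))
  }
  panel
}

#' Simulate an aligned barcode sequence set along a true tree
#'
#' Evolves a random root sequence along the tree under Jukes-Cantor site
#' substitution: on a branch of length `t` (expected substitutions/site,
#' scaled by `mutation_rate`) each site differs from its parent with
#' probability \eqn{3/4 (1 - e^{-4t/3})}, the substituted base drawn
#' uniformly from the other three. Leaves of `true_tree` must be exactly the
#' panel accessions. Since sites never gain or lose positions, the output is
#' an alignment by construction.
#'
#' @param panel data.frame from [generate_accession_panel()].
#' @param true_tree an `ape::phylo` tree or a Newick string.
#' @param seq_length number of alignment columns.
#' @param mutation_rate multiplier applied to branch lengths.
#' @param rng_seed integer seed.
#' @return character matrix (accessions x sites) over A/C/G/T.
#' @export
generate_marker_sequences <- function(panel, true_tree, seq_length = 600L,
                                      mutation_rate = 1, rng_seed = 1L) {
  if (is.character(true_tree))
    true_tree <- ape::read.tree(text = true_tree)
  stopifnot(inherits(true_tree, "phylo"), seq_length >= 1)
  if (!setequal(true_tree$tip.label, panel$accession))
    mint_error("tree leaves do not match the accession panel",
               "mint_config_error")
  bases <- c("A", "C", "G", "T")
  with_stream(rng_seed, "marker_sequences", {
    tree <- ape::reorder.phylo(true_tree, "cladewise")  # parent before child
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample(bases, seq_length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      t_len <- tree$edge.length[e] * mutation_rate
      p_sub <- 0.75 * (1 - exp(-4 * t_len / 3))
      s <- seqs[[parent]]
      hit <- which(runif(seq_length) < p_sub)
      if (length(hit)) {
        # uniform over the three non-identical bases
        shift <- sample.int(3L, length(hit), replace = TRUE)
        cur <- match(s[hit], bases)
        s[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      }
      seqs[[child]] <- s
    }
    aln <- do.call(rbind, seqs[seq_len(n_tip)])
    rownames(aln) <- tree$tip.label
    aln[panel$accession, , drop = FALSE]
  })
}

#' Simulate per-accession oil composition profiles
#'
#' Draws each accession's relative peak areas from a scaled Dirichlet
#' distribution centred on the scenario's mean profile. The simplex includes
#' an implicit "unidentified" component equal to the shortfall of the mean
#' row sum below 100, so realized rows also sum to at most 100 (mirroring GC
#' tables in which not every peak is identified). Compounds with mean zero
#' stay exactly zero.
#'
#' @param panel data.frame from [generate_accession_panel()].
#' @param config a [scenario_config()].
#' @param rng_seed integer seed (default: scenario seed).
#' @return an [abundance_matrix()] (accessions x compounds, percent).
#' @export
generate_oil_profiles <- function(panel, config, rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "scenario_config"))
  if ("role" %in% names(panel))
    panel <- panel[panel$role == "study", , drop = FALSE]  # references have no oils
  means <- config$oil_profile_means[panel$accession, , drop = FALSE]
  conc <- config$dirichlet_conc
  with_stream(rng_seed, "oil_profiles", {
    rows <- lapply(seq_len(nrow(means)), function(i) {
      mu <- means[i, ]
      unidentified <- max(0, 100 - sum(mu))
      alpha <- conc * c(mu, unidentified) / 100
      g <- numeric(length(alpha))
      pos <- alpha > 0
      g[pos] <- rgamma(sum(pos), shape = alpha[pos], rate = 1)
      if (sum(g) == 0) g[length(g)] <- 1  # degenerate all-zero guard
      x <- 100 * g / sum(g)
      x[-length(x)]
    })
    out <- do.call(rbind, rows)
    dimnames(out) <- dimnames(means)
    abundance_matrix(out)
  })
}

#' Simulate germination count tables
#'
#' For every (treatment, dose) row of the scenario's true-inhibition table,
#' draws `replicates` boxes of `seeds_per_box` seeds with germination
#' probability `p_control * (1 - inhibition)`. Inhibition acts
#' multiplicatively on the control germination probability, so a treatment
#' with zero inhibition is distributed exactly like a control.
#'
#' @param config a [scenario_config()].
#' @param rng_seed integer seed (default: scenario seed).
#' @return data.frame with columns `treatment`, `dose`, `replicate`, `sown`,
#'   `germinated`.
#' @export
generate_germination_counts <- function(config, rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "scenario_config"))
  tab <- config$true_inhibition
  p <- config$p_control * (1 - tab$inhibition)
  if (any(p < 0 | p > 1))
    mint_error("germination probability outside [0, 1]", "mint_config_error")
  with_stream(rng_seed, "germination", {
    reps <- config$replicates
    out <- tab[rep(seq_len(nrow(tab)), each = reps), c("treatment", "dose")]
    out$replicate <- rep(seq_len(reps), nrow(tab))
    out$sown <- config$seeds_per_box
    out$germinated <- rbinom(nrow(out), config$seeds_per_box,
                             rep(p, each = reps))
    rownames(out) <- NULL
    out
  })
}

#' Simulate Evans Blue mortality count tables
#'
#' For every (compound, line, dose, time) row of the scenario's
#' true-mortality table, draws `replicates` populations of `cells_scored`
#' cells, with the stained (dead) count binomial at the true mortality.
#'
#' @param config a [scenario_config()].
#' @param rng_seed integer seed (default: scenario seed).
#' @return data.frame with columns `compound`, `line`, `dose`, `time`,
#'   `replicate`, `scored`, `stained`.
#' @export
generate_cytotoxicity_counts <- function(config, rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "scenario_config"))
  tab <- config$true_mortality
  if (is.null(tab))
    mint_error("scenario has no true_mortality table", "mint_config_error")
  with_stream(rng_seed, "cytotoxicity", {
    reps <- config$replicates
    out <- tab[rep(seq_len(nrow(tab)), each = reps),
               c("compound", "line", "dose", "time")]
    out$replicate <- rep(seq_len(reps), nrow(tab))
    out$scored <- config$cells_scored
    out$stained <- rbinom(nrow(out), config$cells_scored,
                          rep(tab$mortality, each = reps))
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-nucleus AO/EB intensity tables
#'
#' For each compound/dose in the scenario's nucleus-response table, draws two
#' experimental series of `nuclei_per_series` nuclei. The red fraction
#' r = red/(red+green) of each nucleus is beta-distributed with mean
#' `baseline + (max - baseline) * pi(dose)`, where `pi` is a 2-parameter
#' log-logistic permeabilization curve; total intensity is log-normal. The
#' mean red fraction is therefore non-decreasing in dose by construction.
#'
#' @param config a [scenario_config()].
#' @param doses dose grid (default `c(0, 0.0625, 0.125, 0.25, 0.5)` % v/v).
#' @param rng_seed integer seed (default: scenario seed).
#' @return data.frame with columns `compound`, `dose`, `series`, `nucleus`,
#'   `green`, `red`.
#' @export
generate_nucleus_intensities <- function(config,
                                         doses = c(0, 0.0625, 0.125, 0.25, 0.5),
                                         rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "scenario_config"), length(doses) >= 1)
  resp <- config$nucleus_response
  if (is.null(resp))
    mint_error("scenario has no nucleus_response table", "mint_config_error")
  with_stream(rng_seed, "nuclei", {
    n <- config$nuclei_per_series
    rows <- list()
    for (i in seq_len(nrow(resp))) {
      for (d in doses) {
        perm <- ll2_prob(d, resp$ec50[i], resp$slope[i])
        mu <- config$nucleus_baseline +
          (config$nucleus_max - config$nucleus_baseline) * perm
        for (series in 1:2) {
          r <- rbeta(n, mu * config$nucleus_shape,
                     (1 - mu) * config$nucleus_shape)
          total <- rlnorm(n, meanlog = log(500), sdlog = 0.3)
          rows[[length(rows) + 1L]] <- data.frame(
            compound = resp$compound[i], dose = d, series = series,
            nucleus = seq_len(n), green = (1 - r) * total, red = r * total)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic study on disk
#'
#' Runs every generator of the scenario and writes the resulting study
#' directory: an aligned FASTA of barcode sequences, a declared-labels CSV,
#' per-accession GC peak-table CSVs, germination / mortality / nucleus CSVs,
#' the true tree (Newick) and a ground-truth JSON sidecar (true labels,
#' planted swaps, true inhibition and mortality, line EC50s).
#'
#' @param config a [scenario_config()].
#' @param rng_seed integer seed for all generators.
#' @param dir output directory (created if needed).
#' @return a `study_bundle`: named list of file paths plus the panel, usable
#'   by [run_screen()].
#' @examples
#' \donttest{
#' bundle <- simulate_study(paper_scenario(), rng_seed = 1,
#'                          dir = tempfile("study"))
#' list.files(bundle$dir)
#' }
#' @export
simulate_study <- function(config, rng_seed = config$rng_seed, dir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)

  panel <- generate_accession_panel(config)
  aln <- generate_marker_sequences(panel, config$true_tree,
                                   seq_length = config$seq_length,
                                   mutation_rate = config$mutation_rate,
                                   rng_seed = rng_seed)
  fasta <- file.path(dir, "sequences.fasta")
  write_fasta(aln, fasta)
  labels <- file.path(dir, "labels.csv")
  write.csv(data.frame(accession = panel$accession,
                       declared_taxon = panel$declared_species),
            labels, row.names = FALSE)

  am <- generate_oil_profiles(panel, config, rng_seed = rng_seed)
  for (acc in rownames(am)) {
    pt <- data.frame(compound = colnames(am), area = am[acc, ])
    pt <- pt[pt$area > 0, ]
    write.csv(pt, file.path(dir, "peaks", paste0(acc, ".csv")),
              row.names = FALSE)
  }

  germ <- generate_germination_counts(config, rng_seed = rng_seed)
  germ_path <- file.path(dir, "germination.csv")
  write.csv(germ, germ_path, row.names = FALSE)

  mort_path <- nuc_path <- NULL
  if (!is.null(config$true_mortality)) {
    mort <- generate_cytotoxicity_counts(config, rng_seed = rng_seed)
    mort_path <- file.path(dir, "mortality.csv")
    write.csv(mort, mort_path, row.names = FALSE)
  }
  if (!is.null(config$nucleus_response)) {
    nuc <- generate_nucleus_intensities(config, rng_seed = rng_seed)
    nuc_path <- file.path(dir, "nuclei.csv")
    write.csv(nuc, nuc_path, row.names = FALSE)
  }

  tree_path <- file.path(dir, "true_tree.nwk")
  writeLines(config$true_tree, tree_path)

  planted <- unique(unlist(config$mislabel_pairs))
  truth <- list(
    true_labels = as.list(config$species),
    planted_mislabels = planted,
    active_compound = config$active_compound,
    true_inhibition = config$true_inhibition,
    line_ec50 = config$line_ec50,
    rng_seed = rng_seed)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  structure(list(
    dir = dir,
    sequences = fasta,
    labels = labels,
    peaks = file.path(dir, "peaks"),
    germination = germ_path,
    mortality = mort_path,
    nuclei = nuc_path,
    true_tree = tree_path,
    ground_truth = truth_path,
    panel = panel,
    rng_seed = rng_seed
  ), class = "study_bundle")
}

#' Write an alignment to FASTA
#'
#' @param aln character matrix (sequences x sites) with rownames as ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  ape::write.FASTA(ape::as.DNAbin(aln), path)
  invisible(path)
}

#' Read an aligned FASTA into a character matrix
#'
#' All sequences must have equal length (the file is expected to be an
#' alignment); bases are uppercased.
#'
#' @param path FASTA file.
#' @return character matrix (sequences x sites).
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    mint_error("sequences are not aligned (unequal lengths)",
               "mint_alignment_error")
  aln <- toupper(do.call(rbind, as.character(dna)))
  rownames(aln) <- names(dna)
  aln
}
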