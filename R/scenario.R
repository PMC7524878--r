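#' Define a synthetic study scenario
#'
#' A scenario bundles everything the synthetic-data generators need: the
#' accession panel with true species labels and planted label swaps, the
#' compound list with per-accession mean oil composition, the true
#' germination-inhibition and cell-mortality probabilities, line-specific
#' EC50s for the dose-response block, and the assay dimensions (seeds per
#' box, replicates, cells scored, nuclei per series).
#'
#' Probabilities are on \[0, 1\]; assay readouts derived from them are
#' reported in percent. Mean oil compositions are relative peak areas in
#' percent; the shortfall of a row sum below 100 is the unidentified
#' fraction of that oil (real GC tables rarely assign every peak).
#'
#' @param accessions character vector of accession ids (length >= 2).
#' @param species named character vector mapping accession -> true species.
#' @param compounds character vector of compound names emitted by the oil
#'   profile generator (unpooled; isomers are pooled downstream).
#' @param active_compound name of the planted active compound (must be in
#'   `compounds`).
#' @param mislabel_pairs list of length-2 character vectors; each pair of
#'   accessions has its *declared* species labels swapped.
#' @param references named character vector mapping reference sequence ids
#'   to species. References emulate curated database entries: they appear in
#'   the true tree and the simulated alignment with declared = true species,
#'   but have no oils or assays.
#' @param oil_profile_means numeric matrix (accession x compound) of mean
#'   relative peak areas in percent; row sums must be <= 100.
#' @param true_inhibition data.frame with columns `treatment`, `dose`,
#'   `inhibition` (probability). Treatments may be accession ids (their oils)
#'   or compound/control names.
#' @param true_mortality data.frame with columns `compound`, `line`, `dose`,
#'   `time`, `mortality` (probability).
#' @param line_ec50 data.frame with columns `compound`, `line`, `ec50`,
#'   `slope` describing the true mortality dose-response per cell line
#'   (2-parameter log-logistic, 0-100%). Used for documentation/ground truth;
#'   the mortality table itself drives the generator.
#' @param nucleus_response data.frame with columns `compound`, `ec50`,
#'   `slope`: the dose dependence of membrane permeabilization in the AO/EB
#'   assay.
#' @param true_tree Newick string for the true accession tree (branch lengths
#'   in expected substitutions per site).
#' @param seeds_per_box seeds sown per germination box (default 100).
#' @param replicates replicate count for count-based assays (default 3).
#' @param p_control control germination probability (default 0.95).
#' @param cells_scored cells scored per mortality replicate (default 600).
#' @param nuclei_per_series nuclei per AO/EB experimental series
#'   (default 275, i.e. the middle of 250-300); two series are generated.
#' @param nucleus_baseline,nucleus_max mean red/(red+green) ratio of fully
#'   intact and fully permeabilized populations.
#' @param nucleus_shape beta precision of per-nucleus ratios.
#' @param dirichlet_conc Dirichlet concentration for oil-composition noise
#'   (larger = tighter profiles).
#' @param seq_length barcode alignment length used by [simulate_study()].
#' @param mutation_rate multiplier on tree branch lengths for sequence
#'   simulation (1 = branch lengths are substitutions/site).
#' @param rng_seed default seed for generators.
#' @return object of class `scenario_config`.
#' @seealso [paper_scenario()] for the shipped default scenario.
#' @export
scenario_config <- function(accessions, species, compounds, active_compound,
                            mislabel_pairs = list(),
                            references = character(),
                            oil_profile_means,
                            true_inhibition,
                            true_mortality = NULL,
                            line_ec50 = NULL,
                            nucleus_response = NULL,
                            true_tree = NULL,
                            seeds_per_box = 100L,
                            replicates = 3L,
                            p_control = 0.95,
                            cells_scored = 600L,
                            nuclei_per_series = 275L,
                            nucleus_baseline = 0.06,
                            nucleus_max = 0.97,
                            nucleus_shape = 25,
                            dirichlet_conc = 250,
                            seq_length = 600L,
                            mutation_rate = 1,
                            rng_seed = 1L) {
  accessions <- as.character(accessions)
  if (length(accessions) < 2L)
    mint_error("a scenario needs at least 2 accessions", "mint_config_error")
  if (anyDuplicated(accessions))
    mint_error("duplicate accession ids", "mint_config_error")
  if (!all(accessions %in% names(species)))
    mint_error("every accession needs a true species label", "mint_config_error")
  compounds <- as.character(compounds)
  if (!length(compounds))
    mint_error("compound list must be non-empty", "mint_config_error")
  if (!active_compound %in% compounds)
    mint_error(sprintf("active compound '%s' is not in the compound list",
                       active_compound), "mint_config_error")
  for (pair in mislabel_pairs) {
    if (length(pair) != 2L || !all(pair %in% accessions))
      mint_error(sprintf(
        "mislabel pair (%s) references an unknown accession",
        paste(pair, collapse = ", ")), "mint_config_error")
  }
  if (length(references) &&
      (is.null(names(references)) || any(names(references) %in% accessions)))
    mint_error("references must be named ids distinct from accessions",
               "mint_config_error")
  oil_profile_means <- as.matrix(oil_profile_means)
  if (!setequal(rownames(oil_profile_means), accessions))
    mint_error("oil_profile_means rows must match the accession panel",
               "mint_config_error")
  oil_profile_means <- oil_profile_means[accessions, compounds, drop = FALSE]
  if (any(oil_profile_means < 0))
    mint_error("mean peak areas must be non-negative", "mint_config_error")
  if (any(rowSums(oil_profile_means) > 100 + 1e-9))
    mint_error("mean peak areas must sum to <= 100 per accession",
               "mint_config_error")
  check_prob <- function(x, what) {
    if (any(x < 0 | x > 1))
      mint_error(sprintf("%s probabilities must lie in [0, 1]", what),
                 "mint_config_error")
  }
  true_inhibition <- as.data.frame(true_inhibition)
  stopifnot(all(c("treatment", "dose", "inhibition") %in% names(true_inhibition)))
  check_prob(true_inhibition$inhibition, "inhibition")
  if (!is.null(true_mortality)) {
    true_mortality <- as.data.frame(true_mortality)
    stopifnot(all(c("compound", "line", "dose", "time", "mortality") %in%
                    names(true_mortality)))
    check_prob(true_mortality$mortality, "mortality")
  }
  check_prob(p_control, "control germination")
  stopifnot(is_count(seeds_per_box), seeds_per_box >= 1,
            is_count(replicates), replicates >= 1,
            is_count(cells_scored), cells_scored >= 1,
            is_count(nuclei_per_series), nuclei_per_series >= 1)
  structure(list(
    accessions = accessions,
    species = species[accessions],
    compounds = compounds,
    active_compound = active_compound,
    mislabel_pairs = mislabel_pairs,
    references = references,
    oil_profile_means = oil_profile_means,
    true_inhibition = true_inhibition,
    true_mortality = true_mortality,
    line_ec50 = line_ec50,
    nucleus_response = nucleus_response,
    true_tree = true_tree,
    seeds_per_box = as.integer(seeds_per_box),
    replicates = as.integer(replicates),
    p_control = p_control,
    cells_scored = as.integer(cells_scored),
    nuclei_per_series = as.integer(nuclei_per_series),
    nucleus_baseline = nucleus_baseline,
    nucleus_max = nucleus_max,
    nucleus_shape = nucleus_shape,
    dirichlet_conc = dirichlet_conc,
    seq_length = as.integer(seq_length),
    mutation_rate = mutation_rate,
    rng_seed = as.integer(rng_seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic study scenario\n")
  cat(sprintf("  accessions: %d (%d species)\n", length(x$accessions),
              length(unique(x$species))))
  cat(sprintf("  compounds: %d (active: %s)\n", length(x$compounds),
              x$active_compound))
  cat(sprintf("  planted label swaps: %d\n", length(x$mislabel_pairs)))
  cat(sprintf("  germination: %d seeds x %d replicates, control p = %.2f\n",
              x$seeds_per_box, x$replicates, x$p_control))
  cat(sprintf("  mortality: %d cells x %d replicates\n",
              x$cells_scored, x$replicates))
  invisible(x)
}

# 2-parameter log-logistic (0..1 scale) used when building scenario truth.
ll2_prob <- function(dose, ec50, slope) {
  ifelse(dose <= 0, 0, 1 / (1 + (ec50 / dose)^slope))
}

#' The shipped default scenario
#'
#' A reconstruction of a ten-accession mint screen: a panel of *Mentha*
#' accessions plus *Nepeta cataria*, *Agastache rugosa* and the outgroup
#' *Melissa officinalis*; per-accession oil compositions in which pooled
#' menthone/isomenthone is concentrated (~30%) in *M. longifolia* and
#' *A. rugosa*; one planted declared-label swap; germination-inhibition
#' truths for the compound dose series (menthone/isomenthone 70/80/99% at
#' 0.01/0.1/1 ppm; menthol and linalool mild below 1 ppm; limonene 20% even
#' at 1 ppm); Evans Blue mortality time courses at 0.2% v/v (menthone/
#' isomenthone >90% already at 15 min in the wild type; menthol 25% at
#' 15 min rising above 60% at 30 min, amplified to ~90% in the tubulin
#' marker line; limonene ~20% at 30 min); and a mortality dose-response
#' block in which the tubulin marker line reaches half-maximal mortality at
#' 4-fold lower menthone/isomenthone doses than the wild type (the actin
#' line at 1.5-fold).
#'
#' The oil-composition means are synthetic: they encode the narrated
#' chemotypes, not a published table. Doses are nominal labels (ppm for
#' germination, % v/v for cytotoxicity) and are never converted.
#'
#' @param rng_seed default seed stored in the scenario.
#' @return a [scenario_config()] object.
#' @examples
#' sc <- paper_scenario()
#' sc
#' @export
paper_scenario <- function(rng_seed = 1L) {
  accessions <- c("MH753570", "MH753576", "MH753578", "MH753577",
                  "MH753572", "MH753571", "MH753574", "MH753573",
                  "MH781964", "MH753575")
  species <- c(
    MH753570 = "Mentha spicata",
    MH753576 = "Mentha spicata",
    MH753578 = "Mentha aquatica",
    MH753577 = "Mentha arvensis",
    MH753572 = "Mentha longifolia",
    MH753571 = "Mentha x piperita",
    MH753574 = "Mentha suaveolens",
    MH753573 = "Nepeta cataria",
    MH781964 = "Melissa officinalis",
    MH753575 = "Agastache rugosa")
  compounds <- c("menthone", "isomenthone", "menthol", "limonene",
                 "pulegone", "carvone", "linalool", "1,8-cineole",
                 "alpha-citral", "beta-citral", "nepetalactone",
                 "piperitenone oxide", "citronellal")
  m <- matrix(0, nrow = length(accessions), ncol = length(compounds),
              dimnames = list(accessions, compounds))
  set_row <- function(acc, ...) {
    v <- c(...)
    m[acc, names(v)] <<- v
  }
  # Chemotype means (% relative peak area); row shortfall below 100 is the
  # unidentified fraction.
  set_row("MH753570", carvone = 45, limonene = 18, menthone = 2,
          isomenthone = 0.5, menthol = 0.5, pulegone = 0.5, linalool = 2,
          "1,8-cineole" = 8)
  set_row("MH753576", carvone = 45, limonene = 15, menthone = 2,
          isomenthone = 0.5, menthol = 1, linalool = 2, "1,8-cineole" = 7)
  set_row("MH753578", menthone = 8, isomenthone = 2, menthol = 2,
          limonene = 6, linalool = 5, "1,8-cineole" = 30)
  set_row("MH753577", menthol = 30, menthone = 5, isomenthone = 1.5,
          limonene = 5, "1,8-cineole" = 2)
  set_row("MH753572", menthol = 35, menthone = 28, isomenthone = 9,
          limonene = 3, pulegone = 1, "1,8-cineole" = 4)
  set_row("MH753571", menthol = 40, menthone = 15, isomenthone = 4,
          limonene = 3, linalool = 0.5, "1,8-cineole" = 6)
  set_row("MH753574", "piperitenone oxide" = 55, limonene = 8,
          "1,8-cineole" = 4, linalool = 3, menthone = 1)
  set_row("MH753573", nepetalactone = 45, "beta-citral" = 15,
          "alpha-citral" = 10, linalool = 3, limonene = 2)
  set_row("MH781964", citronellal = 25, "beta-citral" = 12,
          "alpha-citral" = 9, linalool = 5, limonene = 3)
  set_row("MH753575", menthone = 23, isomenthone = 8, pulegone = 14,
          limonene = 12, menthol = 0.5, linalool = 2)

  # Oil bioactivity at the 0.1 ppm screening dose (probability of
  # germination inhibition).
  oil_inh <- c(MH753570 = 0.60, MH753576 = 0.55, MH753578 = 0.40,
               MH753577 = 0.35, MH753572 = 0.80, MH753571 = 0.20,
               MH753574 = 0.15, MH753573 = 0.70, MH781964 = 0.10,
               MH753575 = 0.75)
  doses_g <- c(0.01, 0.1, 1)
  compound_inh <- rbind(
    data.frame(treatment = "menthone/isomenthone", dose = doses_g,
               inhibition = c(0.70, 0.80, 0.99)),
    data.frame(treatment = "menthol", dose = doses_g,
               inhibition = c(0.30, 0.40, 0.95)),
    data.frame(treatment = "linalool", dose = doses_g,
               inhibition = c(0.30, 0.38, 0.93)),
    data.frame(treatment = "limonene", dose = doses_g,
               inhibition = c(0.05, 0.10, 0.20)),
    data.frame(treatment = "n-hexane", dose = doses_g, inhibition = 0),
    data.frame(treatment = "ethanol", dose = doses_g, inhibition = 0))
  true_inhibition <- rbind(
    data.frame(treatment = names(oil_inh), dose = 0.1,
               inhibition = unname(oil_inh)),
    compound_inh)

  lines <- c("WT", "actin-marker", "tubulin-marker")
  # Time-course block at 0.2% v/v (times in minutes).
  tc <- function(compound, line, m15, m30) {
    data.frame(compound = compound, line = line, dose = 0.2,
               time = c(15, 30), mortality = c(m15, m30))
  }
  time_course <- rbind(
    tc("menthone/isomenthone", "WT", 0.93, 0.96),
    tc("menthone/isomenthone", "actin-marker", 0.93, 0.96),
    tc("menthone/isomenthone", "tubulin-marker", 0.95, 0.97),
    tc("menthol", "WT", 0.25, 0.65),
    tc("menthol", "actin-marker", 0.27, 0.68),
    tc("menthol", "tubulin-marker", 0.45, 0.90),
    tc("limonene", "WT", 0.10, 0.20),
    tc("limonene", "actin-marker", 0.10, 0.22),
    tc("limonene", "tubulin-marker", 0.10, 0.20),
    tc("ethanol", "WT", 0.03, 0.05),
    tc("ethanol", "actin-marker", 0.03, 0.05),
    tc("ethanol", "tubulin-marker", 0.03, 0.05),
    tc("n-hexane", "WT", 0.03, 0.05),
    tc("n-hexane", "actin-marker", 0.03, 0.05),
    tc("n-hexane", "tubulin-marker", 0.03, 0.05))
  # Dose-response block at 15 min: the tubulin marker line saturates at
  # 4-fold lower menthone/isomenthone doses than the wild type.
  line_ec50 <- data.frame(
    compound = "menthone/isomenthone",
    line = lines,
    ec50 = c(0.06, 0.06 / 1.5, 0.06 / 4),
    slope = 2)
  doses_m <- c(0.00625, 0.0125, 0.025, 0.05, 0.1, 0.4)
  dose_response <- do.call(rbind, lapply(seq_len(nrow(line_ec50)), function(i) {
    data.frame(compound = line_ec50$compound[i], line = line_ec50$line[i],
               dose = doses_m, time = 15,
               mortality = ll2_prob(doses_m, line_ec50$ec50[i],
                                    line_ec50$slope[i]))
  }))
  true_mortality <- rbind(time_course, dose_response)

  nucleus_response <- data.frame(
    compound = c("menthone/isomenthone", "limonene", "A. rugosa oil"),
    ec50 = c(0.12, 0.9, 0.3),
    slope = c(2.5, 2, 2))

  # Curated reference sequences, two per species (the real screen anchored
  # its tree with curated database homologues); short tags keep Newick tidy.
  ref_tags <- c("Mentha spicata" = "Mspi", "Mentha aquatica" = "Maqu",
                "Mentha arvensis" = "Marv", "Mentha longifolia" = "Mlon",
                "Mentha x piperita" = "Mpip", "Mentha suaveolens" = "Msua",
                "Nepeta cataria" = "Ncat", "Melissa officinalis" = "Moff",
                "Agastache rugosa" = "Arug")
  references <- character()
  for (sp in names(ref_tags)) {
    ids <- paste0("REF", ref_tags[[sp]], 1:2)
    references[ids] <- sp
  }
  clade <- function(sp, study) {
    refs <- names(references)[references == sp]
    ref_part <- sprintf("(%s:0.002,%s:0.002)", refs[1], refs[2])
    if (length(study) == 2) {
      sprintf("((%s:0.002,%s:0.002):0.003,%s:0.003)",
              study[1], study[2], ref_part)
    } else {
      sprintf("(%s:0.003,%s:0.002)", study, ref_part)
    }
  }
  spi <- clade("Mentha spicata", c("MH753570", "MH753576"))
  lon <- clade("Mentha longifolia", "MH753572")
  pip <- clade("Mentha x piperita", "MH753571")
  aqu <- clade("Mentha aquatica", "MH753578")
  sua <- clade("Mentha suaveolens", "MH753574")
  arv <- clade("Mentha arvensis", "MH753577")
  cat_ <- clade("Nepeta cataria", "MH753573")
  rug <- clade("Agastache rugosa", "MH753575")
  mel <- clade("Melissa officinalis", "MH781964")
  true_tree <- sprintf(
    "(((%s:0.015,(%s:0.014,%s:0.014):0.008):0.005,((%s:0.01,%s:0.01):0.008,%s:0.018):0.005):0.035,(%s:0.028,%s:0.028):0.025,%s:0.09);",
    spi, lon, pip, aqu, sua, arv, cat_, rug, mel)

  scenario_config(
    accessions = accessions,
    species = species,
    compounds = compounds,
    active_compound = "menthone",
    mislabel_pairs = list(c("MH753576", "MH753572")),
    references = references,
    oil_profile_means = m,
    true_inhibition = true_inhibition,
    true_mortality = true_mortality,
    line_ec50 = line_ec50,
    nucleus_response = nucleus_response,
    true_tree = true_tree,
    rng_seed = rng_seed)
}
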