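#' Run the full activity-guided screen on a study bundle
#'
#' Orchestrates the stages in order — authenticate the panel, assemble the
#' pooled abundance matrix, estimate per-oil germination inhibition, score
#' and rank candidate compounds, fit compound dose-response curves, and
#' summarize cytotoxicity (including the wild-type vs tubulin-marker
#' sensitivity comparison and, when a nucleus table is present, the AO/EB
#' class distributions). Optional inputs that are absent produce a section
#' marked `"skipped"`; missing required inputs stop with the stage name.
#'
#' Oils are identified as treatments whose name matches an accession id of
#' the panel; their inhibition at `screening_dose` supplies the `g(i)`
#' vector of the bioactivity score. Each compound is referenced against its
#' solvent control (`solvent_map`, falling back to `default_control`).
#'
#' @param bundle a `study_bundle` from [simulate_study()], or a named list
#'   of paths (`sequences`, `labels`, `peaks`, `germination`, optionally
#'   `mortality`, `nuclei`).
#' @param outgroup accession to root the barcode tree on (default: last
#'   panel accession, the conventional outgroup position of the shipped
#'   scenario — `MH781964`, *Melissa officinalis*).
#' @param n_boot bootstrap replicates for the authentication stage.
#' @param rng_seed seed for the bootstrap stage.
#' @param min_support bootstrap threshold for mislabel flagging.
#' @param screening_dose dose at which oils were assayed (default 0.1 ppm).
#' @param exclude compounds set aside as positive controls in the ranking.
#' @param solvent_map named character vector compound -> control treatment.
#' @param default_control control treatment for compounds not in
#'   `solvent_map`.
#' @param pooling isomer pooling map (default [default_pooling()]).
#' @param sensitivity_lines two cell lines compared for the EC50 shift.
#' @return nested list of class `screen_report`.
#' @examples
#' \donttest{
#' bundle <- simulate_study(paper_scenario(), rng_seed = 1,
#'                          dir = tempfile("study"))
#' rep <- run_screen(bundle, n_boot = 100)
#' rep$bioactivity$top_candidate
#' }
#' @export
run_screen <- function(bundle,
                       outgroup = NULL,
                       n_boot = 1000L,
                       rng_seed = 1L,
                       min_support = 65,
                       screening_dose = 0.1,
                       exclude = "citral",
                       solvent_map = c(menthol = "ethanol"),
                       default_control = "n-hexane",
                       pooling = default_pooling(),
                       sensitivity_lines = c("WT", "tubulin-marker")) {
  need <- function(name) {
    path <- bundle[[name]]
    if (is.null(path) || !file.exists(path))
      mint_error(sprintf("stage '%s': required input '%s' is missing",
                         name, path %||% name), "mint_pipeline_error")
    path
  }

  # --- authentication ------------------------------------------------------
  labels_path <- need("labels")
  lab <- read.csv(labels_path, stringsAsFactors = FALSE)
  if (is.null(outgroup)) outgroup <- lab$accession[nrow(lab)]
  auth <- authenticate_panel(need("sequences"), labels_path,
                             outgroup = outgroup, n_reps = n_boot,
                             rng_seed = rng_seed, min_support = min_support)
  auth_report <- list(
    newick = ape::write.tree(auth$tree),
    flags = auth$flags,
    flagged = auth$flags$accession[auth$flags$status == "mislabelled"],
    outgroup = outgroup,
    n_replicates = attr(auth$tree, "n_replicates"),
    rng_seed = rng_seed)

  # --- chemistry -----------------------------------------------------------
  peaks_dir <- need("peaks")
  files <- sort(list.files(peaks_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    mint_error("stage 'chemistry': no peak tables found",
               "mint_pipeline_error")
  tables <- lapply(lapply(files, load_peak_table), pool_isomers,
                   pooling = pooling)
  am <- build_abundance_matrix(tables)

  # --- germination ---------------------------------------------------------
  germ <- read.csv(need("germination"), stringsAsFactors = FALSE)
  stopifnot(all(c("treatment", "dose", "replicate", "sown", "germinated")
                %in% names(germ)))
  control_counts <- function(control) {
    counts <- germ$germinated[germ$treatment == control]
    if (!length(counts))
      mint_error(sprintf("stage 'germination': control '%s' absent",
                         control), "mint_pipeline_error")
    counts
  }
  oil_treatments <- intersect(unique(germ$treatment), rownames(am))
  g <- vapply(oil_treatments, function(acc) {
    treated <- germ$germinated[germ$treatment == acc &
                                 germ$dose == screening_dose]
    inhibition_percent(treated, control_counts(default_control))$inhibition
  }, numeric(1))

  compound_treatments <- setdiff(
    unique(germ$treatment),
    c(oil_treatments, default_control, unname(solvent_map), "water"))
  dose_tables <- lapply(compound_treatments, function(cmp) {
    ctl <- unname(solvent_map[cmp])
    if (is.na(ctl) || is.null(ctl)) ctl <- default_control
    mc <- mean(control_counts(ctl))
    sub <- germ[germ$treatment == cmp, , drop = FALSE]
    per_dose <- lapply(sort(unique(sub$dose)), function(d) {
      est <- inhibition_percent(sub$germinated[sub$dose == d],
                                control_counts(ctl))
      data.frame(dose = d, inhibition = est$inhibition, se = est$se)
    })
    points <- data.frame(dose = sub$dose,
                         response = 100 * (1 - sub$germinated / mc))
    fit <- tryCatch(fit_dose_response(points$dose, points$response),
                    mint_error = function(e) NULL)
    list(compound = cmp, control = ctl,
         inhibition = do.call(rbind, per_dose),
         fit = if (is.null(fit)) NULL else
           fit[c("lower", "upper", "ec50", "slope", "model", "converged",
                 "rss")])
  })
  names(dose_tables) <- compound_treatments

  germ_report <- list(
    oil_inhibition = data.frame(accession = oil_treatments,
                                inhibition = unname(g)),
    screening_dose = screening_dose,
    control = default_control,
    compounds = dose_tables)

  # --- bioactivity ---------------------------------------------------------
  bt <- bioactivity_score(am, g)
  ranking <- rank_candidates(bt, exclude = exclude)
  hm <- heatmap_matrix(am, bt)
  bio_report <- list(
    scores = as.data.frame(bt),
    ranking = ranking$ranked,
    excluded = ranking$excluded,
    top_candidate = ranking$ranked$compound[1],
    heatmap = as.data.frame(hm))

  # --- cytotoxicity --------------------------------------------------------
  cyto_report <- "skipped"
  if (!is.null(bundle$mortality) && file.exists(bundle$mortality)) {
    mort <- read.csv(bundle$mortality, stringsAsFactors = FALSE)
    mort_summary <- summarize_mortality(mort)
    sens <- tryCatch({
      ls <- line_sensitivity(mort, compound = bio_report$top_candidate,
                             line_a = sensitivity_lines[1],
                             line_b = sensitivity_lines[2])
      list(compound = ls$compound, line_a = ls$line_a, line_b = ls$line_b,
           fold = ls$fold$fold, ci_lower = ls$fold$ci_lower,
           ci_upper = ls$fold$ci_upper,
           ec50_a = ls$fit_a$ec50, ec50_b = ls$fit_b$ec50)
    }, mint_error = function(e) paste("skipped:", conditionMessage(e)))
    nuclei_report <- "skipped"
    if (!is.null(bundle$nuclei) && file.exists(bundle$nuclei)) {
      nuc <- read.csv(bundle$nuclei, stringsAsFactors = FALSE)
      nuclei_report <- class_frequency_distribution(nuc)
    }
    cyto_report <- list(mortality = mort_summary, line_sensitivity = sens,
                        nuclei = nuclei_report)
  }

  structure(list(
    authentication = auth_report,
    chemistry = list(abundance = as.data.frame(unclass(am)),
                     accessions = rownames(am),
                     compounds = colnames(am)),
    germination = germ_report,
    bioactivity = bio_report,
    cytotoxicity = cyto_report,
    seeds = list(bootstrap = rng_seed)
  ), class = "screen_report")
}

#' Write a screen report to disk
#'
#' JSON (machine-readable, deterministic serialization) and/or a short
#' human-readable text summary with one line per ranked compound.
#'
#' @param report a `screen_report` from [run_screen()].
#' @param dir output directory (created if needed).
#' @param formats subset of `c("json", "text")`.
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "text")) {
  stopifnot(inherits(report, "screen_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    out["json"] <- path
  }
  if ("text" %in% formats) {
    path <- file.path(dir, "report.txt")
    lines <- c("Activity-guided screen report",
               "=============================",
               "",
               sprintf("Authentication: %d accession(s) flagged as mislabelled%s",
                       length(report$authentication$flagged),
                       if (length(report$authentication$flagged))
                         paste0(" (", paste(report$authentication$flagged,
                                            collapse = ", "), ")") else ""),
               "",
               "Candidates by bioactivity score:")
    rk <- report$bioactivity$ranking
    if (nrow(rk)) {
      lines <- c(lines, sprintf("  %2d. %-24s B = %8.1f", rk$rank,
                                rk$compound, rk$score))
    } else {
      lines <- c(lines, "  no candidates")
    }
    if (nrow(report$bioactivity$excluded))
      lines <- c(lines, sprintf("  excluded: %s",
                                paste(report$bioactivity$excluded$compound,
                                      collapse = ", ")))
    sens <- report$cytotoxicity
    if (is.list(sens) && is.list(sens$line_sensitivity))
      lines <- c(lines, "",
                 sprintf("Line sensitivity (%s): EC50 %s/%s = %.2f",
                         sens$line_sensitivity$compound,
                         sens$line_sensitivity$line_a,
                         sens$line_sensitivity$line_b,
                         sens$line_sensitivity$fold))
    writeLines(lines, path)
    out["text"] <- path
  }
  invisible(out)
}

# Strip S3 classes so jsonlite serializes plain lists/frames predictably.
unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    class(x) <- "data.frame"
    return(x)
  }
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}
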