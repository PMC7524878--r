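#' Percent mortality from dye-exclusion counts
#'
#' Evans Blue is excluded by intact cells; stained cells are dead or dying.
#' Per replicate, mortality is `100 * stained / scored`; the condition
#' estimate is the replicate mean with its standard error (viability is the
#' complement, so mortality + viability = 100 on every record).
#'
#' @param stained integer vector of stained-cell counts per replicate.
#' @param scored integer vector (or scalar) of cells scored per replicate.
#' @return list of class `mortality_estimate` with `mortality`, `se`,
#'   `per_replicate`, `n`.
#' @examples
#' mortality_percent(c(540, 551, 536), 600)
#' @export
mortality_percent <- function(stained, scored) {
  stained <- as.numeric(stained)
  scored <- as.numeric(scored)
  if (length(scored) == 1L) scored <- rep(scored, length(stained))
  stopifnot(length(stained) >= 1, length(stained) == length(scored))
  if (any(scored < 1))
    mint_error("zero cells scored", "mint_mortality_error")
  if (any(stained < 0 | stained > scored))
    mint_error("stained count outside [0, scored]", "mint_mortality_error")
  pct <- 100 * stained / scored
  se <- if (length(pct) > 1) sd(pct) / sqrt(length(pct)) else NA_real_
  structure(list(mortality = mean(pct), se = se, per_replicate = pct,
                 n = length(pct)),
            class = "mortality_estimate")
}

#' @export
print.mortality_estimate <- function(x, ...) {
  cat(sprintf("mortality: %.1f%%", x$mortality))
  if (!is.na(x$se)) cat(sprintf(" (SE %.2f, n = %d)", x$se, x$n))
  cat("\n")
  invisible(x)
}

#' Summarize a mortality count table by condition
#'
#' @param records data.frame with columns `stained`, `scored` and the
#'   grouping columns in `by`.
#' @param by grouping columns (default compound/line/dose/time).
#' @return data.frame with one row per condition: grouping columns plus
#'   `mortality`, `se`, `n_replicates`.
#' @export
summarize_mortality <- function(records,
                                by = c("compound", "line", "dose", "time")) {
  by <- intersect(by, names(records))
  stopifnot(all(c("stained", "scored") %in% names(records)), length(by) >= 1)
  keys <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(records, keys), function(grp) {
    est <- mortality_percent(grp$stained, grp$scored)
    cbind(grp[1, by, drop = FALSE],
          data.frame(mortality = est$mortality, se = est$se,
                     n_replicates = est$n))
  }))
  rownames(out) <- NULL
  out
}

#' Classify nuclei by their red fraction in the AO/EB assay
#'
#' Acridine Orange permeates all cells (green nuclei); Ethidium Bromide
#' enters only after membrane permeabilization, shifting nuclei over orange
#' to red. The classification rule is a threshold on the red fraction
#' `r = red / (red + green)`: green if `r < t_low`, orange if
#' `t_low <= r < t_high`, red if `r >= t_high` (half-open intervals, so a
#' ratio exactly at `t_low` is orange). A nucleus with both intensities zero
#' is unclassifiable and returned as `NA`.
#'
#' @param green,red non-negative intensity vectors.
#' @param t_low,t_high ratio thresholds, `0 <= t_low < t_high <= 1`
#'   (defaults 1/3 and 2/3, splitting the ratio range evenly).
#' @return factor with levels `green`, `orange`, `red` (`NA` =
#'   unclassifiable).
#' @examples
#' classify_nucleus(green = c(100, 30, 0), red = c(0, 70, 50))
#' @export
classify_nucleus <- function(green, red, t_low = 1 / 3, t_high = 2 / 3) {
  stopifnot(t_low >= 0, t_low < t_high, t_high <= 1)
  green <- as.numeric(green)
  red <- as.numeric(red)
  stopifnot(length(green) == length(red))
  if (any(green < 0 | red < 0, na.rm = TRUE))
    mint_error("intensities must be non-negative", "mint_nucleus_error")
  total <- green + red
  r <- ifelse(total > 0, red / total, NA_real_)
  cls <- ifelse(is.na(r), NA_character_,
                ifelse(r < t_low, "green",
                       ifelse(r < t_high, "orange", "red")))
  factor(cls, levels = c("green", "orange", "red"))
}

#' Class frequency distribution of nuclei per condition
#'
#' Classifies every nucleus and tabulates counts and frequencies of
#' green/orange/red per (compound, dose). Unclassifiable nuclei are tallied
#' but excluded from the frequencies, which therefore sum to 1 in every
#' condition with at least one classifiable nucleus.
#'
#' @param records data.frame with columns `compound`, `dose`, `green`,
#'   `red`.
#' @param t_low,t_high thresholds passed to [classify_nucleus()].
#' @return data.frame with one row per condition and class: `compound`,
#'   `dose`, `class`, `count`, `frequency`, `n_unclassifiable`.
#' @export
class_frequency_distribution <- function(records, t_low = 1 / 3,
                                         t_high = 2 / 3) {
  stopifnot(all(c("compound", "dose", "green", "red") %in% names(records)))
  keys <- interaction(records$compound, records$dose, drop = TRUE,
                      lex.order = TRUE)
  out <- do.call(rbind, lapply(split(records, keys), function(grp) {
    cls <- classify_nucleus(grp$green, grp$red, t_low, t_high)
    n_un <- sum(is.na(cls))
    counts <- table(cls)
    total <- sum(counts)
    if (total == 0)
      mint_error(sprintf(
        "no classifiable nuclei for %s at dose %g",
        grp$compound[1], grp$dose[1]), "mint_nucleus_error")
    data.frame(compound = grp$compound[1], dose = grp$dose[1],
               class = names(counts), count = as.integer(counts),
               frequency = as.numeric(counts) / total,
               n_unclassifiable = n_un)
  }))
  rownames(out) <- NULL
  out
}

#' EC50 fold difference in sensitivity between two cell lines
#'
#' Fits a log-logistic mortality dose-response for each line (responses are
#' replicate-level mortality percentages) and returns the EC50 fold change
#' `line_a / line_b`. A fold above 1 means line B reaches half-maximal
#' mortality at lower doses, i.e. line B is the more sensitive.
#'
#' @param records mortality count table (columns `compound`, `line`,
#'   `dose`, `time`, `stained`, `scored`).
#' @param compound compound to compare.
#' @param line_a,line_b cell line names.
#' @param time optional time point (minutes) to subset to.
#' @param model dose-response model (default `"LL2"`: mortality runs
#'   0-100%).
#' @return list of class `line_sensitivity` with `fold` (an
#'   [ec50_fold_change()] result), `fit_a`, `fit_b`.
#' @export
line_sensitivity <- function(records, compound, line_a, line_b,
                             time = NULL, model = "LL2") {
  stopifnot(all(c("compound", "line", "dose", "stained", "scored") %in%
                  names(records)))
  sel <- records$compound == compound & records$line %in% c(line_a, line_b)
  if (!is.null(time)) sel <- sel & records$time == time
  records <- records[sel, , drop = FALSE]
  fit_line <- function(line) {
    grp <- records[records$line == line, , drop = FALSE]
    if (length(unique(grp$dose)) < 4)
      mint_error(sprintf(
        "line '%s' needs >= 4 dose points for a sensitivity fit", line),
        "mint_fit_error")
    fit_dose_response(grp$dose, 100 * grp$stained / grp$scored,
                      model = model)
  }
  fit_a <- fit_line(line_a)
  fit_b <- fit_line(line_b)
  structure(list(fold = ec50_fold_change(fit_a, fit_b),
                 fit_a = fit_a, fit_b = fit_b,
                 line_a = line_a, line_b = line_b, compound = compound),
            class = "line_sensitivity")
}

#' @export
print.line_sensitivity <- function(x, ...) {
  cat(sprintf("%s: EC50(%s) / EC50(%s) = %.3g\n", x$compound, x$line_a,
              x$line_b, x$fold$fold))
  invisible(x)
}
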