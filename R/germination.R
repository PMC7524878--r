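#' Percent inhibition of germination relative to a control
#'
#' \eqn{g = 100 (1 - \bar{t} / \bar{c})} with \eqn{\bar{t}, \bar{c}} the
#' mean germinated counts of treated and control replicates. The standard
#' error is propagated from the replicate variances by the delta method for
#' a ratio of means. Values live on \eqn{(-\infty, 100]}: a treatment that
#' germinates better than the control yields a negative inhibition, which is
#' reported as observed (clamping, where required, happens at scoring time).
#'
#' @param treated,control numeric vectors of germinated counts per
#'   replicate (>= 1 replicate each).
#' @return list of class `inhibition_estimate` with elements `inhibition`
#'   (percent), `se`, `mean_treated`, `mean_control`, `n_treated`,
#'   `n_control`.
#' @examples
#' inhibition_percent(c(28, 29, 28), c(95, 96, 94))
#' @export
inhibition_percent <- function(treated, control) {
  treated <- as.numeric(treated)
  control <- as.numeric(control)
  stopifnot(length(treated) >= 1, length(control) >= 1,
            all(!is.na(treated)), all(!is.na(control)))
  mc <- mean(control)
  if (mc <= 0)
    mint_error("control mean germination is zero; inhibition undefined",
               "mint_inhibition_error")
  mt <- mean(treated)
  g <- 100 * (1 - mt / mc)
  vt <- if (length(treated) > 1) var(treated) / length(treated) else NA_real_
  vc <- if (length(control) > 1) var(control) / length(control) else NA_real_
  se <- if (is.na(vt) || is.na(vc)) NA_real_ else
    100 * sqrt(vt / mc^2 + mt^2 * vc / mc^4)
  structure(list(inhibition = g, se = se, mean_treated = mt,
                 mean_control = mc, n_treated = length(treated),
                 n_control = length(control)),
            class = "inhibition_estimate")
}

#' @export
print.inhibition_estimate <- function(x, ...) {
  cat(sprintf("inhibition: %.2f%%", x$inhibition))
  if (!is.na(x$se)) cat(sprintf(" (SE %.2f)", x$se))
  cat(sprintf("  [treated %.1f vs control %.1f germinated]\n",
              x$mean_treated, x$mean_control))
  invisible(x)
}

ll4 <- function(dose, lower, upper, ec50, slope) {
  lower + (upper - lower) / (1 + (ec50 / dose)^slope)
}

#' Fit a log-logistic dose-response curve
#'
#' Least-squares fit of the four-parameter log-logistic
#' \deqn{f(d) = lower + \frac{upper - lower}{1 + (ec50/d)^{slope}}}
#' by Levenberg-Marquardt with a multi-start grid (EC50 spanning the dose
#' range geometrically, slopes 0.5/1/2/4). With fewer than 4 points or
#' fewer than 3 distinct doses, a 2-parameter model with `lower = 0`,
#' `upper = 100` is fitted instead (this is also the natural model for
#' mortality and inhibition percentages, selectable via `model = "LL2"`).
#' The response is assumed increasing in dose (use inhibition or mortality,
#' not viability); `slope` is constrained positive, so the fitted curve is
#' monotone. Doses must be positive — a zero-dose control belongs in the
#' response definition (the 0% anchor), not in the log-logistic.
#'
#' A fit that cannot be obtained returns `converged = FALSE` with `NA`
#' parameters rather than raising.
#'
#' @param dose positive numeric vector.
#' @param response numeric vector (percent scale).
#' @param se optional standard errors; when given and all positive, points
#'   are weighted by `1/se^2`.
#' @param model `"auto"` (default), `"LL4"` or `"LL2"`.
#' @return object of class `dose_response_fit`: list with `lower`, `upper`,
#'   `ec50`, `slope`, `se` (named vector of parameter standard errors),
#'   `rss`, `converged`, `model`, `n`, `data`.
#' @examples
#' d <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
#' fit <- fit_dose_response(d, ll4(d, 0, 100, 0.4, 2))
#' fit$ec50
#' @export
fit_dose_response <- function(dose, response, se = NULL,
                              model = c("auto", "LL4", "LL2")) {
  model <- match.arg(model)
  dose <- as.numeric(dose)
  response <- as.numeric(response)
  stopifnot(length(dose) == length(response), length(dose) >= 2)
  if (any(dose <= 0))
    mint_error("doses must be positive for the log-logistic model",
               "mint_fit_error")
  if (length(unique(response)) == 1L)
    mint_error(
      "all responses identical; fit a flat model instead of a sigmoid",
      "mint_fit_error")
  n_distinct <- length(unique(dose))
  if (model == "auto")
    model <- if (length(dose) >= 4 && n_distinct >= 3) "LL4" else "LL2"
  if (model == "LL4" && (length(dose) < 4 || n_distinct < 3))
    mint_error("LL4 needs >= 4 points with >= 3 distinct doses",
               "mint_fit_error")
  if (n_distinct < 2)
    mint_error("need >= 2 distinct doses", "mint_fit_error")

  weights <- NULL
  if (!is.null(se) && all(se > 0) && !anyNA(se)) weights <- 1 / se^2
  df <- data.frame(dose = dose, response = response)
  ec50_grid <- exp(seq(log(min(dose)), log(max(dose)), length.out = 7))
  slope_grid <- c(0.5, 1, 2, 4)
  lo0 <- min(response)
  up0 <- max(response)

  best <- NULL
  for (e0 in ec50_grid) {
    for (s0 in slope_grid) {
      args <- if (model == "LL4") {
        list(response ~ lower + (upper - lower) / (1 + (ec50 / dose)^slope),
             data = df,
             start = list(lower = lo0, upper = up0, ec50 = e0, slope = s0),
             lower = c(lower = -1e3, upper = -1e3, ec50 = 1e-12,
                       slope = 1e-6),
             upper = c(lower = 1e3, upper = 1e3, ec50 = 1e12, slope = 50),
             control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        list(response ~ 100 / (1 + (ec50 / dose)^slope),
             data = df,
             start = list(ec50 = e0, slope = s0),
             lower = c(ec50 = 1e-12, slope = 1e-6),
             upper = c(ec50 = 1e12, slope = 50),
             control = minpack.lm::nls.lm.control(maxiter = 200))
      }
      if (!is.null(weights)) args$weights <- weights
      fit <- tryCatch(suppressWarnings(do.call(minpack.lm::nlsLM, args)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(resid(fit)^2 * (weights %||% 1))
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    return(structure(list(lower = NA_real_, upper = NA_real_,
                          ec50 = NA_real_, slope = NA_real_,
                          se = NULL, rss = NA_real_, converged = FALSE,
                          model = model, n = length(dose), data = df),
                     class = "dose_response_fit"))
  }
  cf <- coef(best$fit)
  par_se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                     error = function(e) setNames(rep(NA_real_, length(cf)),
                                                  names(cf)))
  lower <- if (model == "LL4") unname(cf["lower"]) else 0
  upper <- if (model == "LL4") unname(cf["upper"]) else 100
  converged <- is.finite(cf["ec50"]) && cf["ec50"] > 0 && lower <= upper
  structure(list(lower = lower, upper = upper,
                 ec50 = unname(cf["ec50"]), slope = unname(cf["slope"]),
                 se = par_se, rss = best$rss, converged = converged,
                 model = model, n = length(dose), data = df),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("%s log-logistic fit (%d points)%s\n", x$model, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  lower %.3g  upper %.3g  ec50 %.4g  slope %.3g  rss %.4g\n",
              x$lower, x$upper, x$ec50, x$slope, x$rss))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, dose = NULL, ...) {
  dose <- dose %||% object$data$dose
  ll4(dose, object$lower, object$upper, object$ec50, object$slope)
}

#' EC50 fold change between two dose-response fits
#'
#' Ratio `ec50_a / ec50_b` with its uncertainty propagated on the log
#' scale: \eqn{SE(\log ratio) = \sqrt{(SE_a/ec50_a)^2 + (SE_b/ec50_b)^2}}.
#'
#' @param fit_a,fit_b converged [fit_dose_response()] objects.
#' @return list of class `ec50_fold` with `fold`, `log_se`, `ci_lower`,
#'   `ci_upper` (95%).
#' @export
ec50_fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    mint_error("fold change requires two converged fits", "mint_fit_error")
  fold <- fit_a$ec50 / fit_b$ec50
  rel_a <- unname(fit_a$se["ec50"]) / fit_a$ec50
  rel_b <- unname(fit_b$se["ec50"]) / fit_b$ec50
  log_se <- sqrt(rel_a^2 + rel_b^2)
  structure(list(fold = fold, log_se = log_se,
                 ci_lower = fold * exp(-1.96 * log_se),
                 ci_upper = fold * exp(1.96 * log_se)),
            class = "ec50_fold")
}

#' @export
print.ec50_fold <- function(x, ...) {
  cat(sprintf("EC50 fold change: %.3g", x$fold))
  if (is.finite(x$log_se))
    cat(sprintf(" (95%% CI %.3g-%.3g)", x$ci_lower, x$ci_upper))
  cat("\n")
  invisible(x)
}
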