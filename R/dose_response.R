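#' Construct a dose series
#'
#' @param doses Inhibitor concentrations (unit recorded in `dose_unit`).
#' @param responses Responses per dose: Tm shifts (degrees Celsius) or
#'   percent inhibition, per `response_kind`.
#' @param response_kind `"tm_shift"` or `"stabilization_fraction"`.
#' @param n_per_dose,sd_per_dose Optional replicate counts and dispersions.
#' @param dose_unit Unit label, default `"uM"`.
#' @return A list of class `dose_series`.
#' @export
dose_series <- function(doses, responses,
                        response_kind = c("tm_shift",
                                          "stabilization_fraction"),
                        n_per_dose = NULL, sd_per_dose = NULL,
                        dose_unit = "uM") {
  response_kind <- match.arg(response_kind)
  doses <- as.numeric(doses)
  responses <- as.numeric(responses)
  if (length(doses) != length(responses)) {
    stop("doses and responses differ in length", call. = FALSE)
  }
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  structure(list(doses = doses, responses = responses,
                 response_kind = response_kind, n_per_dose = n_per_dose,
                 sd_per_dose = sd_per_dose, dose_unit = dose_unit),
            class = "dose_series")
}

#' @export
print.dose_series <- function(x, ...) {
  cat("Dose series (", x$response_kind, ", doses in ", x$dose_unit, "):\n",
      sep = "")
  print(data.frame(dose = x$doses, response = x$responses))
  invisible(x)
}

mean_tm <- function(x) {
  if (is.numeric(x)) return(x)
  ests <- if (inherits(x, "tm_estimate")) list(x) else x
  ok <- !vapply(ests, function(e) "no_transition" %in% e$flags, logical(1))
  vapply(ests[ok], `[[`, numeric(1), "tm")
}

#' Inhibitor destabilization profile
#'
#' Mean Tm change of the probe alone at each inhibitor dose relative to the
#' untreated probe; negative values mean destabilization (direct compound
#' binding or covalent modification).
#'
#' @param tm_by_dose Named list: one numeric Tm vector (or list of
#'   [estimate_tm()] results) per dose; names are the doses.
#' @param reference Tm values of the untreated probe.
#' @param dose_unit Unit label.
#' @return A [dose_series()] with `response_kind = "tm_shift"`.
#' @export
destabilization_profile <- function(tm_by_dose, reference, dose_unit = "uM") {
  ref <- mean_tm(reference)
  if (!length(ref)) stop("empty reference group", call. = FALSE)
  doses <- as.numeric(names(tm_by_dose))
  if (anyNA(doses)) {
    stop("tm_by_dose must be named by numeric doses", call. = FALSE)
  }
  grp <- lapply(tm_by_dose, mean_tm)
  if (any(lengths(grp) < 1L)) {
    stop("every dose group needs at least one usable estimate", call. = FALSE)
  }
  dose_series(doses,
              vapply(grp, mean, numeric(1)) - mean(ref),
              response_kind = "tm_shift",
              n_per_dose = lengths(grp),
              sd_per_dose = vapply(grp, function(v) {
                if (length(v) > 1) stats::sd(v) else 0
              }, numeric(1)),
              dose_unit = dose_unit)
}

#' Suppression of ligand-induced stabilization
#'
#' Percent inhibition of the DNA-induced Tm shift at each inhibitor dose:
#' `100 * (1 - dTm(DNA, dose) / dTm(DNA, 0))`, where each shift is taken
#' against the probe-alone Tm at the same dose, so direct destabilization by
#' the compound does not masquerade as binding inhibition. Values can exceed
#' 100 (shift reversed) and fall below 0 (shift enhanced); they are reported
#' raw.
#'
#' @param tm_probe Named list (by dose, `"0"` required or supplied via
#'   `reference_probe`) of probe-alone Tm values.
#' @param tm_probe_dna Named list by dose of probe+DNA Tm values; the dose-0
#'   entry is the uninhibited reference shift.
#' @param dose_unit Unit label.
#' @return A [dose_series()] with `response_kind = "stabilization_fraction"`
#'   covering the nonzero doses.
#' @export
stabilization_suppression <- function(tm_probe, tm_probe_dna,
                                      dose_unit = "uM") {
  d_probe <- as.numeric(names(tm_probe))
  d_dna <- as.numeric(names(tm_probe_dna))
  if (anyNA(d_probe) || anyNA(d_dna)) {
    stop("groups must be named by numeric doses", call. = FALSE)
  }
  if (!(0 %in% d_probe) || !(0 %in% d_dna)) {
    stop("dose-0 (uninhibited) groups are required", call. = FALSE)
  }
  shift_at <- function(dose) {
    p <- tm_probe[[as.character(if (dose %in% d_probe) dose else 0)]]
    q <- tm_probe_dna[[as.character(dose)]]
    mean(mean_tm(q)) - mean(mean_tm(p))
  }
  ref_shift <- shift_at(0)
  if (!is.finite(ref_shift) || ref_shift <= 0) {
    stop("no stabilization to suppress: uninhibited DNA shift is ",
         signif(ref_shift, 4), " °C", call. = FALSE)
  }
  doses <- sort(setdiff(d_dna, 0))
  resp <- vapply(doses, function(dose) {
    100 * (1 - shift_at(dose) / ref_shift)
  }, numeric(1))
  dose_series(doses, resp, response_kind = "stabilization_fraction",
              dose_unit = dose_unit)
}

four_pl <- function(dose, bottom, top, ic50, hill) {
  # limit at dose = 0 is `bottom` for hill > 0
  ifelse(dose == 0, bottom, bottom + (top - bottom) / (1 + (ic50 / dose)^hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (ic50/dose)^hill)`
#' on the linear dose axis with an explicit IC50 parameter. Default starting
#' values: `bottom`/`top` from the response extremes, `ic50` from the dose
#' nearest the half-maximal response, `hill = 1`.
#'
#' @param series A [dose_series()], or a numeric dose vector (then
#'   `responses` must be given). At least 4 distinct doses, of which 3
#'   nonzero, are required.
#' @param responses Responses when `series` is a bare dose vector.
#' @param init Optional named vector/list of starting values.
#' @param fix_bottom,fix_top Optionally pin the asymptotes (e.g. 0 and 100
#'   for percent-inhibition responses).
#' @param ... Passed to [dose_series()] when building one on the fly.
#' @return An object of class `dose_response_fit` with components `ic50`,
#'   `hill`, `top`, `bottom`, `sse`, `converged`, `series`. Methods:
#'   `print`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' d <- 10^seq(0, 2, length.out = 8)
#' fit <- fit_4pl(d, 100 / (1 + 16.4 / d))
#' coef(fit)
#' @export
fit_4pl <- function(series, responses = NULL, init = NULL,
                    fix_bottom = NULL, fix_top = NULL, ...) {
  if (!inherits(series, "dose_series")) {
    series <- dose_series(series, responses, ...)
  }
  dose <- series$doses
  y <- series$responses
  if (length(unique(dose)) < 4L) {
    stop("4PL fit needs at least 4 distinct doses", call. = FALSE)
  }
  if (length(unique(dose[dose > 0])) < 3L) {
    stop("4PL fit needs at least 3 distinct nonzero doses", call. = FALSE)
  }
  asc <- suppressWarnings(stats::cor(dose, y))
  asc <- is.na(asc) || asc >= 0
  b0 <- fix_bottom %||% if (asc) min(y) else max(y)
  t0 <- fix_top %||% if (asc) max(y) else min(y)
  half <- (b0 + t0) / 2
  pos <- dose > 0
  i0 <- dose[pos][which.min(abs(y[pos] - half))]
  start <- list(bottom = b0, top = t0, ic50 = max(i0, min(dose[pos])),
                hill = 1)
  if (!is.null(init)) start[names(init)] <- as.list(init)
  fixed <- c(if (!is.null(fix_bottom)) "bottom",
             if (!is.null(fix_top)) "top")
  free <- setdiff(names(start), fixed)
  form <- stats::as.formula(paste(
    "y ~ four_pl(dose,",
    if ("bottom" %in% fixed) b0 else "bottom", ",",
    if ("top" %in% fixed) t0 else "top", ", ic50, hill)"))
  lower <- c(bottom = -Inf, top = -Inf, ic50 = .Machine$double.eps,
             hill = 1e-3)[free]
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(dose = dose, y = y),
                      start = start[free], lower = unname(lower),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, sse = NA_real_,
                          converged = FALSE,
                          message = conditionMessage(fit), series = series),
                     class = "dose_response_fit"))
  }
  cf <- as.list(stats::coef(fit))
  cf$bottom <- cf$bottom %||% b0
  cf$top <- cf$top %||% t0
  fitted <- four_pl(dose, cf$bottom, cf$top, cf$ic50, cf$hill)
  converged <- fit$convInfo$isConv
  msg <- fit$convInfo$stopMessage
  # an IC50 far outside the tested doses means the data carry no midpoint
  # information (e.g. an inactive compound); report as an ambiguous fit
  pos <- dose[dose > 0]
  if (converged && (cf$ic50 > 100 * max(pos) || cf$ic50 < min(pos) / 100)) {
    converged <- FALSE
    msg <- sprintf("ambiguous fit: IC50 (%.3g) far outside the dose range",
                   cf$ic50)
  }
  structure(list(ic50 = cf$ic50, hill = cf$hill, top = cf$top,
                 bottom = cf$bottom, sse = sum((y - fitted)^2),
                 converged = converged,
                 message = msg, series = series,
                 fitted = fitted, residuals = y - fitted),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  if (!isTRUE(x$converged)) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  IC50 = %.4g %s, hill = %.3g, bottom = %.4g, top = %.4g (SSE %.3g)\n",
              x$ic50, x$series$dose_unit, x$hill, x$bottom, x$top, x$sse))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$series$doses
       else if (is.list(newdata)) newdata$dose else as.numeric(newdata)
  four_pl(d, object$bottom, object$top, object$ic50, object$hill)
}

#' @export
residuals.dose_response_fit <- function(object, ...) object$residuals

#' @export
plot.dose_response_fit <- function(x, ...) {
  d <- x$series$doses
  graphics::plot(d, x$series$responses, log = if (all(d > 0)) "x" else "",
                 xlab = paste0("dose (", x$series$dose_unit, ")"),
                 ylab = x$series$response_kind, ...)
  if (isTRUE(x$converged)) {
    dd <- exp(seq(log(min(d[d > 0])), log(max(d)), length.out = 200))
    graphics::lines(dd, four_pl(dd, x$bottom, x$top, x$ic50, x$hill))
  }
  invisible(x)
}

#' Two-sample Student t comparison of Tm groups
#'
#' Classic pooled-variance, two-tailed two-sample t test with significance
#' stars at 0.05 / 0.01 / 0.001. When both groups have zero variance and
#' equal means the comparison is reported as `t = 0`, `p = 1` by convention.
#' A Welch (unequal-variance) variant is available via `var_equal = FALSE`.
#'
#' @param a,b Numeric Tm vectors (n >= 2 each).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A list of class `group_comparison` with means, sds, ns, `t_stat`,
#'   `df`, `p_value` and `stars` (`ns`, `*`, `**`, `***`).
#' @export
compare_tm_groups <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  dm <- mean(a) - mean(b)
  if (se == 0) {
    t_stat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
    if (dm == 0) df <- na + nb - 2
  } else {
    t_stat <- dm / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = na, n_b = nb, t_stat = t_stat, df = df,
                 p_value = p, stars = stars, var_equal = var_equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("t(%.3g) = %.4g, p = %.3g %s  (means %.3f vs %.3f, n = %d/%d)\n",
              x$df, x$t_stat, x$p_value, x$stars, x$mean_a, x$mean_b,
              x$n_a, x$n_b))
  invisible(x)
}
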