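#' Ligand-depletion model of the melting-temperature shift
#'
#' The quadratic (ligand-depletion) isotherm used to relate the observed
#' melting-temperature shift to total ligand concentration:
#' \deqn{\Delta T_m = \frac{(\Delta T_{max} + D + K_D) -
#'   \sqrt{(\Delta T_{max} + D + K_D)^2 - 4\,\Delta T_{max} D}}{2}}
#' where `D` is the total ligand (dsDNA) concentration and `K_D` the
#' apparent dissociation constant. The expression mixes a temperature
#' (`delta_t_max`, degrees Celsius) with concentrations, so the fitted `kd`
#' is tied to the concentration unit; this package fixes micromolar as the
#' fitting unit (see the vignette).
#'
#' @param delta_t_max Maximal shift at saturation (degrees Celsius), > 0.
#' @param kd Apparent dissociation constant (same unit as `d`), >= 0.
#' @param d Total ligand concentration(s), >= 0 (vectorised).
#' @return Predicted shift(s), in `[0, delta_t_max]`.
#' @examples
#' predict_delta_tm(1.678, 2.228, 10)  # ~1.335 degrees
#' @export
predict_delta_tm <- function(delta_t_max, kd, d) {
  if (delta_t_max <= 0) stop("delta_t_max must be > 0", call. = FALSE)
  if (kd < 0) stop("kd must be >= 0", call. = FALSE)
  if (any(d < 0)) stop("concentrations must be >= 0", call. = FALSE)
  a <- delta_t_max + d + kd
  rad <- a^2 - 4 * delta_t_max * d
  # algebraically rad = (d + kd - delta_t_max)^2 + 4*kd*delta_t_max >= 0;
  # clamp rounding error
  rad[rad < 0] <- 0
  (a - sqrt(rad)) / 2
}

#' Construct a binding series
#'
#' One ΔTm titration: melting-temperature shifts measured over a ligand
#' concentration series.
#'
#' @param ligand_concs Total ligand concentrations (micromolar), length >= 3
#'   with at least two distinct values.
#' @param delta_tms Observed shifts (degrees Celsius), same length.
#' @param site_multiplicity Binding sites per ligand molecule used to form
#'   the effective concentration (default 1 = duplex concentration; 2 counts
#'   each site of a tandem-site duplex separately).
#' @param probe,ligand Labels.
#' @param sd Optional per-point dispersions (kept for reporting only; the
#'   fit is unweighted).
#' @return A list of class `binding_series`.
#' @export
binding_series <- function(ligand_concs, delta_tms, site_multiplicity = 1L,
                           probe = "probe", ligand = "ligand", sd = NULL) {
  ligand_concs <- as.numeric(ligand_concs)
  delta_tms <- as.numeric(delta_tms)
  if (length(ligand_concs) != length(delta_tms)) {
    stop("concentration and shift vectors differ in length", call. = FALSE)
  }
  if (length(ligand_concs) < 3L) {
    stop("a binding series needs at least 3 points", call. = FALSE)
  }
  if (any(ligand_concs < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (length(unique(ligand_concs)) < 2L) {
    stop("need at least two distinct concentrations", call. = FALSE)
  }
  if (site_multiplicity < 1) {
    stop("site_multiplicity must be a positive integer", call. = FALSE)
  }
  structure(list(ligand_concs = ligand_concs, delta_tms = delta_tms,
                 site_multiplicity = as.integer(site_multiplicity),
                 probe = probe, ligand = ligand, sd = sd),
            class = "binding_series")
}

#' Fit the ligand-depletion isotherm to a ΔTm titration
#'
#' Unweighted least-squares fit of [predict_delta_tm()] to a
#' [binding_series()], estimating the saturating shift `delta_t_max`
#' (degrees Celsius) and the apparent dissociation constant `kd`
#' (micromolar). The fit uses bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]); default starting values are
#' `delta_t_max = max(delta_tms)` and `kd` = the concentration whose
#' observed shift is nearest half-maximum.
#'
#' @param series A [binding_series()], or a numeric concentration vector
#'   (then `delta_tms` must be given).
#' @param delta_tms Shifts when `series` is a bare concentration vector.
#' @param init Optional named list/vector with `delta_t_max` and `kd`.
#' @param lower Lower bounds for `(delta_t_max, kd)`.
#' @param ... Passed to [binding_series()] when building one on the fly.
#' @return An object of class `binding_fit`: components `delta_t_max`, `kd`,
#'   `sse`, `converged`, `n_points`, `series`, `ci_delta_t_max`, `ci_kd`
#'   (filled by [bootstrap_ci()]), plus fitted values and residuals.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`, `plot`,
#'   `confint`.
#' @examples
#' d <- c(0.5, 1, 2, 4, 6, 8, 10)
#' fit <- fit_binding(binding_series(d, predict_delta_tm(1.678, 2.228, d)))
#' coef(fit)
#' @export
fit_binding <- function(series, delta_tms = NULL, init = NULL,
                        lower = c(1e-8, 0), ...) {
  if (!inherits(series, "binding_series")) {
    series <- binding_series(series, delta_tms, ...)
  }
  d_eff <- series$ligand_concs * series$site_multiplicity
  y <- series$delta_tms
  if (all(abs(y) < .Machine$double.eps^0.5)) {
    stop("degenerate fit: all shifts are zero", call. = FALSE)
  }
  if (is.null(init)) {
    dt0 <- max(y)
    half <- dt0 / 2
    kd0 <- d_eff[which.min(abs(y - half))]
    if (kd0 <= 0) kd0 <- stats::median(d_eff[d_eff > 0])
    init <- c(delta_t_max = dt0, kd = kd0)
  }
  dat <- data.frame(d = d_eff, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ predict_delta_tm(delta_t_max, kd, d),
                      data = dat,
                      start = list(delta_t_max = init[["delta_t_max"]],
                                   kd = init[["kd"]]),
                      lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(delta_t_max = NA_real_, kd = NA_real_,
                          sse = NA_real_, converged = FALSE,
                          message = conditionMessage(fit),
                          n_points = length(y), series = series,
                          ci_delta_t_max = NULL, ci_kd = NULL,
                          fitted = rep(NA_real_, length(y)),
                          residuals = rep(NA_real_, length(y))),
                     class = "binding_fit"))
  }
  cf <- stats::coef(fit)
  fitted <- predict_delta_tm(cf[["delta_t_max"]], cf[["kd"]], d_eff)
  structure(list(delta_t_max = cf[["delta_t_max"]], kd = cf[["kd"]],
                 sse = sum((y - fitted)^2),
                 converged = fit$convInfo$isConv,
                 message = fit$convInfo$stopMessage,
                 n_points = length(y), series = series,
                 ci_delta_t_max = NULL, ci_kd = NULL,
                 fitted = fitted, residuals = y - fitted),
            class = "binding_fit")
}

binding_leverage <- function(fit) {
  d <- fit$series$ligand_concs * fit$series$site_multiplicity
  eps <- 1e-6
  J <- cbind(
    (predict_delta_tm(fit$delta_t_max + eps, fit$kd, d) - fit$fitted) / eps,
    (predict_delta_tm(fit$delta_t_max, fit$kd + eps, d) - fit$fitted) / eps)
  h <- try(diag(J %*% solve(crossprod(J)) %*% t(J)), silent = TRUE)
  if (inherits(h, "try-error")) rep(0, length(d)) else pmin(h, 0.95)
}

#' Residual-resampling bootstrap intervals for a binding fit
#'
#' Percentile (2.5/97.5) confidence intervals for `delta_t_max` and `kd`
#' obtained by resampling fit residuals with replacement, rebuilding
#' pseudo-series and refitting. Residuals are leverage-adjusted
#' (`r / sqrt(1 - h)`, the usual modified residuals) and centred before
#' resampling, which corrects the downward bias of raw least-squares
#' residuals at small n. Deterministic for a given seed.
#'
#' @param fit A converged [fit_binding()] result with >= 4 points.
#' @param n_boot Bootstrap replicates (>= 100; default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return `fit`, with `ci_delta_t_max`, `ci_kd` (length-2 vectors) and a
#'   `boot` matrix of replicate estimates attached.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "binding_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (fit$n_points < 4L) {
    stop("bootstrap needs at least 4 points", call. = FALSE)
  }
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  series <- fit$series
  res <- fit$residuals / sqrt(1 - binding_leverage(fit))
  res <- res - mean(res)
  init <- c(delta_t_max = fit$delta_t_max, kd = fit$kd)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  est <- matrix(NA_real_, n_boot, 2,
                dimnames = list(NULL, c("delta_t_max", "kd")))
  for (b in seq_len(n_boot)) {
    y_b <- fit$fitted + sample(res, replace = TRUE)
    s_b <- series
    s_b$delta_tms <- y_b
    f_b <- tryCatch(suppressWarnings(fit_binding(s_b, init = init)),
                    error = function(e) NULL)
    if (!is.null(f_b) && isTRUE(f_b$converged)) {
      est[b, ] <- c(f_b$delta_t_max, f_b$kd)
    }
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ok <- stats::complete.cases(est)
  fit$ci_delta_t_max <- unname(stats::quantile(est[ok, 1], probs))
  fit$ci_kd <- unname(stats::quantile(est[ok, 2], probs))
  fit$boot <- est
  fit$boot_level <- level
  fit
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Ligand-depletion binding fit",
      sprintf("(%s + %s, site multiplicity %d)\n",
              x$series$probe, x$series$ligand, x$series$site_multiplicity))
  if (!isTRUE(x$converged)) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  delta_t_max = %.4g °C, KD(app) = %.4g µM  (SSE %.3g, n = %d)\n",
              x$delta_t_max, x$kd, x$sse, x$n_points))
  if (!is.null(x$ci_kd)) {
    cat(sprintf("  bootstrap %d%% CI: delta_t_max [%.4g, %.4g], KD [%.4g, %.4g]\n",
                round(100 * x$boot_level), x$ci_delta_t_max[1],
                x$ci_delta_t_max[2], x$ci_kd[1], x$ci_kd[2]))
  }
  cat("  note: KD is unit-bound -- concentrations and KD are micromolar\n")
  invisible(x)
}

#' @export
summary.binding_fit <- function(object, ...) {
  print(object)
  if (isTRUE(object$converged)) {
    cat("  residuals (°C):\n")
    print(summary(object$residuals))
  }
  invisible(object)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(delta_t_max = object$delta_t_max, kd = object$kd)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) {
    object$series$ligand_concs * object$series$site_multiplicity
  } else if (is.list(newdata)) {
    newdata$d
  } else {
    as.numeric(newdata)
  }
  predict_delta_tm(object$delta_t_max, object$kd, d)
}

#' @export
residuals.binding_fit <- function(object, ...) object$residuals

#' @export
plot.binding_fit <- function(x, ...) {
  d <- x$series$ligand_concs * x$series$site_multiplicity
  graphics::plot(d, x$series$delta_tms, xlab = "[ligand] (µM)",
                 ylab = expression(Delta * T[m] ~ (degree * C)), ...)
  if (isTRUE(x$converged)) {
    dd <- seq(0, max(d), length.out = 200)
    graphics::lines(dd, predict_delta_tm(x$delta_t_max, x$kd, dd))
  }
  invisible(x)
}

#' @export
confint.binding_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$ci_kd) || !identical(object$boot_level, level)) {
    object <- bootstrap_ci(object, level = level, ...)
  }
  out <- rbind(delta_t_max = object$ci_delta_t_max, kd = object$ci_kd)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}
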