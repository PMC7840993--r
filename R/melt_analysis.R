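#' Smoothing specification for melt curves
#'
#' @param method One of `"savitzky_golay"` (default), `"moving_average"`,
#'   `"none"`.
#' @param window Odd window length in grid points (>= 3). Default 7, which on
#'   the usual 0.2 degree grid spans 1.2 degrees and preserves derivative
#'   peak position.
#' @param polyorder Polynomial order for Savitzky-Golay (must be < window).
#' @return A list of class `smoothing_spec`.
#' @export
smoothing_spec <- function(method = c("savitzky_golay", "moving_average",
                                      "none"),
                           window = 7L, polyorder = 3L) {
  method <- match.arg(method)
  window <- as.integer(window)
  if (method != "none") {
    if (window < 3L || window %% 2L == 0L) {
      stop("smoothing window must be odd and >= 3", call. = FALSE)
    }
    if (method == "savitzky_golay" && polyorder >= window) {
      stop("polyorder must be smaller than the window", call. = FALSE)
    }
  }
  structure(list(method = method, window = window,
                 polyorder = as.integer(polyorder)),
            class = "smoothing_spec")
}

#' Smooth a fluorescence curve
#'
#' @param curve Numeric RFU vector on the plate's temperature grid.
#' @param spec A [smoothing_spec()].
#' @return Smoothed vector of the same length. `method = "none"` returns the
#'   input unchanged.
#' @export
smooth_curve <- function(curve, spec = smoothing_spec()) {
  stopifnot(inherits(spec, "smoothing_spec"))
  if (spec$method == "none") return(curve)
  if (length(curve) < spec$window) {
    stop("curve shorter than the smoothing window", call. = FALSE)
  }
  switch(spec$method,
    moving_average = {
      k <- spec$window
      half <- (k - 1L) %/% 2L
      n <- length(curve)
      # centred mean; the window shrinks symmetrically near the edges so the
      # output keeps the input length and a linear ramp stays linear
      vapply(seq_len(n), function(i) {
        h <- min(half, i - 1L, n - i)
        mean(curve[(i - h):(i + h)])
      }, numeric(1))
    },
    savitzky_golay = as.numeric(
      signal::sgolayfilt(curve, p = spec$polyorder, n = spec$window)
    )
  )
}

#' Positive-derivative curve d(RFU)/dT
#'
#' Central differences at interior points, one-sided differences at the two
#' ends; supports non-uniform strictly increasing grids.
#'
#' @param grid Temperatures (degrees Celsius), strictly increasing,
#'   length >= 3.
#' @param curve RFU vector of the same length.
#' @return Numeric vector of d(RFU)/dT, same length as the input.
#' @export
derivative_curve <- function(grid, curve) {
  n <- length(grid)
  if (length(curve) != n) stop("grid/curve length mismatch", call. = FALSE)
  if (n < 3L) stop("need at least 3 points to differentiate", call. = FALSE)
  if (any(diff(grid) <= 0)) {
    stop("temperature grid must be strictly increasing", call. = FALSE)
  }
  d <- numeric(n)
  d[1] <- (curve[2] - curve[1]) / (grid[2] - grid[1])
  d[n] <- (curve[n] - curve[n - 1]) / (grid[n] - grid[n - 1])
  i <- 2:(n - 1)
  d[i] <- (curve[i + 1] - curve[i - 1]) / (grid[i + 1] - grid[i - 1])
  d
}

#' Quality-control thresholds for melt curves
#'
#' @param background_fraction Flag `high_background` when the initial RFU
#'   exceeds this fraction of the curve's maximum. Dye binding to natively
#'   exposed hydrophobic surface (disordered probes) shows up this way.
#'   Default 0.5.
#' @param min_dynamic_range Flag `low_signal` when max - min RFU falls below
#'   this (RFU units). Default 1.
#' @param prominence_fraction Flag `no_transition` when the derivative peak
#'   rises less than this fraction of the dynamic range per degree above the
#'   lowest derivative in the search range. Default 0.1.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(background_fraction = 0.5, min_dynamic_range = 1,
                          prominence_fraction = 0.1) {
  structure(list(background_fraction = background_fraction,
                 min_dynamic_range = min_dynamic_range,
                 prominence_fraction = prominence_fraction),
            class = "qc_thresholds")
}

#' Flag melt curves unusable for Tm estimation
#'
#' Flags: `high_background` (initial fluorescence already a large fraction of
#' the signal span, the failure mode of partially disordered probes),
#' `low_signal` (dynamic range below threshold), `no_transition` (no
#' sufficiently prominent derivative peak), `edge_peak` (derivative maximum
#' sits on a search-range boundary).
#'
#' @param grid Temperatures.
#' @param curve RFU vector.
#' @param thresholds A [qc_thresholds()].
#' @param search_range Length-2 numeric range (degrees Celsius) used for the
#'   peak checks; defaults to the full grid.
#' @param spec Smoothing applied before differentiating.
#' @return Character vector of flags (possibly empty).
#' @export
qc_curve <- function(grid, curve, thresholds = qc_thresholds(),
                     search_range = range(grid), spec = smoothing_spec()) {
  flags <- character(0)
  rng <- max(curve) - min(curve)
  low_signal <- rng < thresholds$min_dynamic_range
  if (low_signal) flags <- c(flags, "low_signal")
  if (curve[1] > thresholds$background_fraction * max(curve)) {
    flags <- c(flags, "high_background")
  }
  sm <- if (length(curve) >= spec$window) smooth_curve(curve, spec) else curve
  d <- derivative_curve(grid, sm)
  in_rng <- grid >= search_range[1] & grid <= search_range[2]
  if (sum(in_rng) >= 3L) {
    drng <- d[in_rng]
    prom <- max(drng) - min(drng)
    if (low_signal || rng <= 0 ||
        prom < thresholds$prominence_fraction * rng) {
      flags <- c(flags, "no_transition")
    }
    peak_at <- which(in_rng)[which.max(drng)]
    if (peak_at == min(which(in_rng)) || peak_at == max(which(in_rng))) {
      flags <- c(flags, "edge_peak")
    }
  } else {
    flags <- c(flags, "no_transition")
  }
  unique(flags)
}

#' Estimate the melting temperature of one well
#'
#' Tm is located as the maximum of the smoothed positive derivative
#' d(RFU)/dT within `search_range`, then refined to sub-grid resolution by
#' the vertex of the parabola through the peak sample and its two
#' neighbours. By default the search excludes 2 grid points at each end of
#' the grid and everything above the quench cutoff (90 degrees Celsius),
#' where dye-signal decay dominates.
#'
#' @param grid Temperatures (degrees Celsius), strictly increasing.
#' @param curve RFU vector.
#' @param spec A [smoothing_spec()].
#' @param search_range Length-2 numeric range; `NULL` for the default
#'   described above.
#' @param quench_cutoff Upper limit applied to the default search range.
#' @param thresholds A [qc_thresholds()].
#' @param well_id Label stored in the result.
#' @return A list of class `tm_estimate` with components `well_id`, `tm`,
#'   `peak_height`, `search_range` and `flags`. `tm` is `NA` when the curve
#'   carries `no_transition`.
#' @export
estimate_tm <- function(grid, curve, spec = smoothing_spec(),
                        search_range = NULL, quench_cutoff = 90,
                        thresholds = qc_thresholds(), well_id = "well") {
  n <- length(grid)
  if (length(curve) != n) stop("grid/curve length mismatch", call. = FALSE)
  if (is.null(search_range)) {
    search_range <- c(grid[min(3L, n)], min(grid[max(1L, n - 2L)],
                                            quench_cutoff))
  }
  if (search_range[1] < grid[1] || search_range[2] > grid[n]) {
    stop("search_range outside the temperature grid", call. = FALSE)
  }
  idx <- which(grid >= search_range[1] & grid <= search_range[2])
  if (length(idx) < 3L) {
    stop("fewer than 3 grid points in the search range", call. = FALSE)
  }
  flags <- qc_curve(grid, curve, thresholds, search_range, spec)
  sm <- smooth_curve(curve, spec)
  d <- derivative_curve(grid, sm)
  k <- idx[which.max(d[idx])]
  tm <- grid[k]
  peak_height <- d[k]
  # parabolic vertex through the peak and its neighbours (uniform-grid form
  # with the local step); skipped on a boundary peak
  if (k > min(idx) && k < max(idx)) {
    y1 <- d[k - 1]; y2 <- d[k]; y3 <- d[k + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      h <- (grid[k + 1] - grid[k - 1]) / 2
      delta <- 0.5 * (y1 - y3) / denom
      delta <- max(-0.5, min(0.5, delta))
      tm <- grid[k] + delta * h
      peak_height <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  if ("no_transition" %in% flags) {
    tm <- NA_real_
    peak_height <- NA_real_
  }
  structure(list(well_id = well_id, tm = tm, peak_height = peak_height,
                 search_range = search_range, flags = flags),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("Tm estimate [%s]: %s °C (peak %.4g RFU/°C)%s\n", x$well_id,
              if (is.na(x$tm)) "NA" else sprintf("%.2f", x$tm),
              x$peak_height,
              if (length(x$flags)) paste0(" flags: ",
                                          paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Estimate Tm for every well of a plate
#'
#' @param plate A [melt_plate()].
#' @inheritParams estimate_tm
#' @return Data frame with columns `well_id`, `tm`, `peak_height`, `flags`
#'   (comma-separated, empty when clean).
#' @export
estimate_tm_plate <- function(plate, spec = smoothing_spec(),
                              search_range = NULL, quench_cutoff = 90,
                              thresholds = qc_thresholds()) {
  stopifnot(inherits(plate, "melt_plate"))
  res <- lapply(colnames(plate$curves), function(w) {
    est <- estimate_tm(plate$temperatures, plate$curves[, w], spec,
                       search_range, quench_cutoff, thresholds, well_id = w)
    data.frame(well_id = w, tm = est$tm, peak_height = est$peak_height,
               flags = paste(est$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Ligand-induced melting-temperature shift
#'
#' Computes the mean Tm difference between a sample group and a reference
#' group (positive = stabilization), with the replicate standard deviation
#' propagated as `sqrt(sd_s^2/n_s + sd_r^2/n_r)`.
#'
#' @param samples,references Numeric Tm vectors, or lists of
#'   [estimate_tm()] results (flagged `no_transition` estimates are
#'   rejected unless `allow_flagged`).
#' @param sample_group,reference_group Labels carried into the result.
#' @param allow_flagged Set `TRUE` to tolerate flagged estimates.
#' @return A list of class `delta_tm` with `value`, `sd`, `n_sample`,
#'   `n_reference` and the group labels.
#' @export
delta_tm <- function(samples, references, sample_group = "sample",
                     reference_group = "reference", allow_flagged = FALSE) {
  pull <- function(x, side) {
    if (is.numeric(x)) return(x)
    ests <- if (inherits(x, "tm_estimate")) list(x) else x
    bad <- vapply(ests, function(e) "no_transition" %in% e$flags, logical(1))
    if (any(bad) && !allow_flagged) {
      stop("flagged Tm estimate(s) in ", side, " group: ",
           paste(vapply(ests[bad], `[[`, "", "well_id"), collapse = ", "),
           call. = FALSE)
    }
    vapply(ests[!bad], `[[`, numeric(1), "tm")
  }
  s <- pull(samples, "sample")
  r <- pull(references, "reference")
  if (length(s) < 1L || length(r) < 1L) {
    stop("need at least one usable estimate per group", call. = FALSE)
  }
  sd_of <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(value = mean(s) - mean(r),
                 sd = sqrt(sd_of(s)^2 / length(s) + sd_of(r)^2 / length(r)),
                 sample_group = sample_group,
                 reference_group = reference_group,
                 n_sample = length(s), n_reference = length(r)),
            class = "delta_tm")
}

#' @export
print.delta_tm <- function(x, ...) {
  cat(sprintf("dTm(%s - %s) = %+.3f °C (sd %.3f, n = %d/%d)\n",
              x$sample_group, x$reference_group, x$value, x$sd,
              x$n_sample, x$n_reference))
  invisible(x)
}
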