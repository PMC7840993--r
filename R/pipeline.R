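#' Workflow configuration
#'
#' @param smoothing A [smoothing_spec()].
#' @param search_range Length-2 Tm search range (degrees Celsius) or `NULL`
#'   for the default (grid minus edges, capped at `quench_cutoff`).
#' @param quench_cutoff Upper Tm search limit, degrees Celsius.
#' @param thresholds A [qc_thresholds()].
#' @param site_multiplicity Sites per ligand molecule for the binding fit.
#' @param n_boot Bootstrap replicates for the binding-fit CI.
#' @param seed Integer seed for the bootstrap.
#' @param response_kind Response fitted in the IC50 workflow:
#'   `"stabilization_fraction"` (percent inhibition, default) or
#'   `"tm_shift"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(smoothing = smoothing_spec(), search_range = NULL,
                       quench_cutoff = 90, thresholds = qc_thresholds(),
                       site_multiplicity = 1L, n_boot = 1000L, seed = 1L,
                       response_kind = c("stabilization_fraction",
                                         "tm_shift")) {
  structure(list(smoothing = smoothing, search_range = search_range,
                 quench_cutoff = quench_cutoff, thresholds = thresholds,
                 site_multiplicity = as.integer(site_multiplicity),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 response_kind = match.arg(response_kind)),
            class = "run_config")
}

# replicate-level (case) bootstrap for the workflow CI: resamples the Tm
# replicates within every group, with the deviation of each resampled group
# mean inflated by sqrt(n/(n-1)) to undo the bootstrap's small-n downward
# bias of the variance of a mean; the shared reference error is thereby
# propagated into the interval, which a residual bootstrap on the fitted
# series cannot see
bootstrap_ci_wells <- function(fit, refs, groups, n_boot = 1000L, seed = 1L,
                               level = 0.95) {
  series <- fit$series
  init <- c(delta_t_max = fit$delta_t_max, kd = fit$kd)
  bmean <- function(g) {
    n <- length(g)
    if (n == 1L) return(g)
    mean(g) + (mean(sample(g, replace = TRUE)) - mean(g)) * sqrt(n / (n - 1))
  }
  est <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("delta_t_max", "kd")))
    for (b in seq_len(n_boot)) {
      s_b <- series
      s_b$delta_tms <- vapply(groups, bmean, numeric(1)) - bmean(refs)
      f_b <- tryCatch(suppressWarnings(fit_binding(s_b, init = init)),
                      error = function(e) NULL)
      if (!is.null(f_b) && isTRUE(f_b$converged)) {
        out[b, ] <- c(f_b$delta_t_max, f_b$kd)
      }
    }
    out
  })
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ok <- stats::complete.cases(est)
  fit$ci_delta_t_max <- unname(stats::quantile(est[ok, 1], probs))
  fit$ci_kd <- unname(stats::quantile(est[ok, 2], probs))
  fit$boot <- est
  fit$boot_level <- level
  fit
}

check_plate_layout <- function(plate, layout) {
  stopifnot(inherits(plate, "melt_plate"), inherits(layout, "plate_layout"))
  miss <- setdiff(layout$well_id, colnames(plate$curves))
  if (length(miss)) {
    stop("layout well(s) absent from plate: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

tm_table_for <- function(plate, layout, config) {
  tab <- estimate_tm_plate(plate, config$smoothing, config$search_range,
                           config$quench_cutoff, config$thresholds)
  tab <- merge(layout, tab, by = "well_id", sort = FALSE)
  tab$excluded <- tab$flags != ""
  tab
}

exclusion_lines <- function(tab) {
  ex <- tab[tab$excluded, , drop = FALSE]
  if (!nrow(ex)) return(character(0))
  sprintf("excluded well %s (%s): %s", ex$well_id, ex$replicate_group,
          ex$flags)
}

#' Run the dsDNA-titration (KD) workflow
#'
#' Curves to Tm to ΔTm to the ligand-depletion fit: estimates a Tm for every
#' well, excludes QC-flagged wells with a logged reason, aggregates ΔTm per
#' ligand concentration against the reference wells, fits
#' (`delta_t_max`, `kd`) and attaches bootstrap confidence intervals.
#'
#' @param plate A [melt_plate()].
#' @param layout A [plate_layout()] with at least one reference well and at
#'   least three ligand concentrations.
#' @param config A [run_config()].
#' @return A list of class `kd_workflow`: `tm_table` (per-well estimates and
#'   QC), `delta_tms` (per-concentration shifts with replicate sd), `fit`
#'   (a [fit_binding()] result with CIs), `excluded`, `report` (character
#'   lines).
#' @export
run_kd_workflow <- function(plate, layout, config = run_config()) {
  check_plate_layout(plate, layout)
  tab <- tm_table_for(plate, layout, config)
  usable <- tab[!tab$excluded, , drop = FALSE]
  if (!nrow(usable)) {
    stop("all wells failed QC:\n",
         paste(exclusion_lines(tab), collapse = "\n"), call. = FALSE)
  }
  refs <- usable$tm[usable$role == "reference"]
  if (!length(refs)) stop("no usable reference wells", call. = FALSE)
  lig <- usable[usable$role == "sample" & !is.na(usable$ligand_conc), ,
                drop = FALSE]
  concs <- sort(unique(lig$ligand_conc))
  if (length(concs) < 3L) {
    stop("need at least 3 ligand concentrations", call. = FALSE)
  }
  dts <- lapply(concs, function(cc) {
    delta_tm(lig$tm[lig$ligand_conc == cc], refs,
             sample_group = sprintf("%g uM", cc))
  })
  series <- binding_series(concs, vapply(dts, `[[`, numeric(1), "value"),
                           site_multiplicity = config$site_multiplicity,
                           probe = layout$probe[1],
                           ligand = stats::na.omit(layout$ligand)[1],
                           sd = vapply(dts, `[[`, numeric(1), "sd"))
  fit <- fit_binding(series)
  if (isTRUE(fit$converged) && fit$n_points >= 4L) {
    fit <- bootstrap_ci_wells(fit, refs,
                              lapply(concs, function(cc) {
                                lig$tm[lig$ligand_conc == cc]
                              }),
                              n_boot = config$n_boot, seed = config$seed)
  }
  delta_df <- data.frame(
    ligand_conc = concs,
    delta_tm = series$delta_tms,
    sd = series$sd,
    n = vapply(dts, `[[`, integer(1), "n_sample"))
  report <- c(
    sprintf("KD workflow: %d wells, %d usable, %d reference", nrow(tab),
            nrow(usable), length(refs)),
    exclusion_lines(tab),
    sprintf("reference Tm = %.3f °C (n = %d)", mean(refs), length(refs)),
    if (isTRUE(fit$converged)) {
      c(sprintf("fit: delta_t_max = %.4g °C, KD(app) = %.4g µM, SSE = %.3g",
                fit$delta_t_max, fit$kd, fit$sse),
        if (!is.null(fit$ci_kd)) {
          sprintf("bootstrap 95%% CI: KD [%.4g, %.4g] µM", fit$ci_kd[1],
                  fit$ci_kd[2])
        })
    } else sprintf("fit did not converge: %s", fit$message),
    paste("note: KD is tied to the micromolar concentration scale;",
          "the model adds delta_t_max (°C) to concentrations"))
  structure(list(tm_table = tab, delta_tms = delta_df, fit = fit,
                 excluded = tab$well_id[tab$excluded], report = report),
            class = "kd_workflow")
}

#' @export
print.kd_workflow <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

#' Run the inhibitor (IC50) workflow
#'
#' Estimates per-well Tm, builds the destabilization profile (probe +
#' inhibitor vs untreated probe), the suppression profile (percent
#' inhibition of the ligand-induced shift), fits a 4PL on the configured
#' response and reports treated-vs-untreated group comparisons.
#'
#' @param plate A [melt_plate()].
#' @param layout A [plate_layout()] whose wells cover, per dose, probe-alone
#'   / probe+inhibitor and probe+DNA(+inhibitor) classes, with uninhibited
#'   groups at dose 0.
#' @param config A [run_config()].
#' @return A list of class `ic50_workflow`: `tm_table`, `destabilization`
#'   and `suppression` ([dose_series()]), `fit` (a [fit_4pl()] result),
#'   `comparisons` (per-dose [compare_tm_groups()] on the DNA wells),
#'   `excluded`, `report`.
#' @export
run_ic50_workflow <- function(plate, layout, config = run_config()) {
  check_plate_layout(plate, layout)
  tab <- tm_table_for(plate, layout, config)
  usable <- tab[!tab$excluded, , drop = FALSE]
  if (!nrow(usable)) {
    stop("all wells failed QC:\n",
         paste(exclusion_lines(tab), collapse = "\n"), call. = FALSE)
  }
  has_dna <- !is.na(usable$ligand)
  dose <- ifelse(is.na(usable$inhibitor_conc), 0, usable$inhibitor_conc)
  split_tm <- function(rows) {
    split(usable$tm[rows], dose[rows])
  }
  probe_groups <- split_tm(!has_dna)
  dna_groups <- split_tm(has_dna)
  if (!"0" %in% names(dna_groups)) {
    stop("missing uninhibited probe+DNA reference wells", call. = FALSE)
  }
  if (!"0" %in% names(probe_groups)) {
    stop("missing untreated probe wells", call. = FALSE)
  }
  inh_doses <- sort(unique(dose[dose > 0]))
  destab <- if (length(intersect(as.character(inh_doses),
                                 names(probe_groups)))) {
    destabilization_profile(
      probe_groups[names(probe_groups) %in% as.character(inh_doses)],
      probe_groups[["0"]])
  }
  supp <- stabilization_suppression(probe_groups, dna_groups)
  resp <- if (config$response_kind == "stabilization_fraction") supp else {
    dose_series(supp$doses, vapply(supp$doses, function(d) {
      mean(dna_groups[[as.character(d)]]) - mean(dna_groups[["0"]])
    }, numeric(1)), response_kind = "tm_shift")
  }
  fit <- tryCatch(
    if (config$response_kind == "stabilization_fraction") {
      fit_4pl(resp, fix_bottom = 0, fix_top = 100)
    } else fit_4pl(resp),
    error = function(e) {
      structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                     bottom = NA_real_, sse = NA_real_, converged = FALSE,
                     message = conditionMessage(e), series = resp),
                class = "dose_response_fit")
    })
  comparisons <- lapply(as.character(inh_doses), function(d) {
    if (!d %in% names(dna_groups)) return(NULL)
    if (length(dna_groups[[d]]) < 2L || length(dna_groups[["0"]]) < 2L) {
      return(NULL)
    }
    compare_tm_groups(dna_groups[[d]], dna_groups[["0"]])
  })
  names(comparisons) <- as.character(inh_doses)
  comparisons <- Filter(Negate(is.null), comparisons)
  report <- c(
    sprintf("IC50 workflow: %d wells, %d usable", nrow(tab), nrow(usable)),
    exclusion_lines(tab),
    sprintf("uninhibited DNA shift = %.3f °C",
            mean(dna_groups[["0"]]) - mean(probe_groups[["0"]])),
    if (isTRUE(fit$converged)) {
      sprintf("4PL fit: IC50 = %.4g %s (hill %.3g)", fit$ic50,
              resp$dose_unit, fit$hill)
    } else sprintf("4PL fit did not converge: %s", fit$message),
    vapply(names(comparisons), function(d) {
      cmp <- comparisons[[d]]
      sprintf("dose %s vs 0: t = %.3g, p = %.3g %s", d, cmp$t_stat,
              cmp$p_value, cmp$stars)
    }, character(1)))
  structure(list(tm_table = tab, destabilization = destab,
                 suppression = supp, fit = fit, comparisons = comparisons,
                 excluded = tab$well_id[tab$excluded], report = report),
            class = "ic50_workflow")
}

#' @export
print.ic50_workflow <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}
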