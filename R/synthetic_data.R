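GAS_CONSTANT_KJ <- 0.008314462618  # kJ mol^-1 K^-1
KELVIN <- 273.15

#' Two-state fraction unfolded
#'
#' Van't Hoff two-state unfolding: the fraction unfolded at temperature `t`
#' is `1 / (1 + exp(dG / (R T)))` with `dG = dh_vh (1 - T/Tm)` (absolute
#' temperatures), so the fraction is exactly 1/2 at `t = tm` and the
#' transition sharpens as the van't Hoff enthalpy grows.
#'
#' @param t Temperature(s), degrees Celsius (vectorised).
#' @param tm Melting temperature, degrees Celsius.
#' @param dh_vh Van't Hoff enthalpy, kJ/mol (> 0).
#' @return Fraction unfolded in `[0, 1]`.
#' @export
two_state_fraction_unfolded <- function(t, tm, dh_vh) {
  if (dh_vh <= 0) stop("dh_vh must be > 0", call. = FALSE)
  tk <- t + KELVIN
  tmk <- tm + KELVIN
  dg <- dh_vh * (1 - tk / tmk)
  1 / (1 + exp(dg / (GAS_CONSTANT_KJ * tk)))
}

#' Simulation parameters for one melt curve
#'
#' Generative parameters of a SYPRO-Orange-type two-state melt curve:
#' sloped native and unfolded baselines, a van't Hoff transition, an
#' exponential post-transition quench of the dye signal, and additive
#' Gaussian RFU noise on the instrument's 25-95 degree, 0.2-degree grid.
#'
#' @param tm0 Apo melting temperature, degrees Celsius (default 42.5, the
#'   behaviour of a well-folded Rel-homology-domain probe).
#' @param dh_vh Van't Hoff enthalpy, kJ/mol (default 400, giving a
#'   transition a few degrees wide).
#' @param native_baseline,unfolded_baseline Length-2 `(intercept, slope)` in
#'   RFU and RFU per degree.
#' @param amplitude Transition amplitude, RFU (> 0).
#' @param quench_onset Temperature where dye-signal decay starts (must
#'   exceed `tm0`; default `tm0 + 8`).
#' @param quench_rate Exponential decay rate above the onset, 1/degree.
#' @param noise_sd Gaussian RFU noise sd.
#' @param grid Length-3 `(start, end, step)` in degrees Celsius.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(tm0 = 42.5, dh_vh = 400,
                     native_baseline = c(100, 1),
                     unfolded_baseline = c(150, -2),
                     amplitude = 1000,
                     quench_onset = tm0 + 8, quench_rate = 0.05,
                     noise_sd = 0, grid = c(25, 95, 0.2)) {
  if (dh_vh <= 0) stop("dh_vh must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (grid[3] <= 0) stop("grid step must be > 0", call. = FALSE)
  if (quench_onset <= tm0) stop("quench_onset must exceed tm0", call. = FALSE)
  structure(list(tm0 = tm0, dh_vh = dh_vh,
                 native_baseline = native_baseline,
                 unfolded_baseline = unfolded_baseline,
                 amplitude = amplitude, quench_onset = quench_onset,
                 quench_rate = quench_rate, noise_sd = noise_sd,
                 grid = grid),
            class = "sim_spec")
}

sim_grid <- function(spec) seq(spec$grid[1], spec$grid[2], by = spec$grid[3])

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-well stream: fold (seed, key) into a 31-bit sub-seed
well_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Simulate one melt curve
#'
#' `RFU(T) = [native(T) (1 - f) + (unfolded(T) + amplitude) f] *
#' exp(-quench_rate * max(0, T - quench_onset)) + noise`, with `f` the
#' two-state fraction unfolded. Deterministic for a given seed.
#'
#' @param spec A [sim_spec()].
#' @param tm_override Use this Tm instead of `spec$tm0` (the quench onset
#'   shifts with it).
#' @param seed Integer seed for the noise stream.
#' @return A list with `temperatures`, `rfu` and the generating `tm`.
#' @export
simulate_melt_curve <- function(spec = sim_spec(), tm_override = NULL,
                                seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  tm <- tm_override %||% spec$tm0
  onset <- spec$quench_onset + (tm - spec$tm0)
  t <- sim_grid(spec)
  f <- two_state_fraction_unfolded(t, tm, spec$dh_vh)
  native <- spec$native_baseline[1] + spec$native_baseline[2] * (t - t[1])
  unfolded <- spec$unfolded_baseline[1] +
    spec$unfolded_baseline[2] * (t - t[1])
  rfu <- (native * (1 - f) + (unfolded + spec$amplitude) * f) *
    exp(-spec$quench_rate * pmax(0, t - onset))
  if (spec$noise_sd > 0) {
    rfu <- rfu + with_seed(seed, stats::rnorm(length(t), 0, spec$noise_sd))
  }
  list(temperatures = t, rfu = rfu, tm = tm)
}

#' Plate-level simulation parameters
#'
#' @param probe A [sim_spec()] for the apo probe.
#' @param delta_t_max,kd,site_multiplicity Ligand-binding truth: saturating
#'   shift (degrees Celsius), apparent dissociation constant (micromolar)
#'   and sites per duplex, fed through [predict_delta_tm()].
#' @param ligand_concs Ligand (dsDNA) concentrations, micromolar.
#' @param destab_map Named numeric vector, dose to Tm change (degrees,
#'   negative = destabilization) of the probe alone, or a function of dose.
#' @param suppression Length-2 `(ic50, hill)` of the 4PL (bottom 0, top 100,
#'   percent) suppression of the ligand-induced shift.
#' @param replicates Replicate wells per condition.
#' @param tm_noise_sd Between-replicate Tm noise sd, degrees Celsius.
#' @param probe_name,ligand_name,inhibitor_name Labels for the layout.
#' @return A list of class `plate_sim_spec`.
#' @export
plate_sim_spec <- function(probe = sim_spec(),
                           delta_t_max = 1.678, kd = 2.228,
                           site_multiplicity = 1L,
                           ligand_concs = c(0.5, 1, 2, 4, 6, 8, 10),
                           destab_map = NULL,
                           suppression = c(ic50 = 16.4, hill = 1),
                           replicates = 3L, tm_noise_sd = 0,
                           probe_name = "probe", ligand_name = "dsDNA",
                           inhibitor_name = "inhibitor") {
  stopifnot(inherits(probe, "sim_spec"))
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (any(ligand_concs < 0)) {
    stop("ligand concentrations must be >= 0", call. = FALSE)
  }
  structure(list(probe = probe, delta_t_max = delta_t_max, kd = kd,
                 site_multiplicity = as.integer(site_multiplicity),
                 ligand_concs = ligand_concs, destab_map = destab_map,
                 suppression = suppression,
                 replicates = as.integer(replicates),
                 tm_noise_sd = tm_noise_sd, probe_name = probe_name,
                 ligand_name = ligand_name,
                 inhibitor_name = inhibitor_name),
            class = "plate_sim_spec")
}

sim_well <- function(spec, tm_true, seed, key) {
  s <- well_seed(seed, key)
  tm <- tm_true
  if (spec$tm_noise_sd > 0) {
    tm <- tm + with_seed(s, stats::rnorm(1, 0, spec$tm_noise_sd))
  }
  curve <- simulate_melt_curve(spec$probe, tm_override = tm, seed = s + 1L)
  list(tm = tm, curve = curve$rfu)
}

#' Simulate a dsDNA-titration binding experiment
#'
#' Builds a full plate mirroring a ΔTm titration design: `replicates`
#' reference wells (probe alone at `tm0`) and `replicates` wells per ligand
#' concentration whose generating Tm is `tm0 + predict_delta_tm(delta_t_max,
#' kd, conc * site_multiplicity)` plus per-well Gaussian Tm noise. All
#' randomness derives deterministically from `(seed, well)`.
#'
#' @param spec A [plate_sim_spec()].
#' @param seed Integer seed.
#' @return A list with `plate` ([melt_plate()]), `layout`
#'   ([plate_layout()]) and `truth` (the generating parameters and per-well
#'   true Tm values).
#' @export
simulate_binding_experiment <- function(spec = plate_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  grid <- sim_grid(spec$probe)
  shifts <- predict_delta_tm(spec$delta_t_max, spec$kd,
                             spec$ligand_concs * spec$site_multiplicity)
  conds <- data.frame(
    ligand_conc = c(NA_real_, spec$ligand_concs),
    shift = c(0, shifts),
    group = c("reference", sprintf("D%02d", seq_along(spec$ligand_concs)))
  )
  curves <- list(); rows <- list(); tm_true <- c()
  for (i in seq_len(nrow(conds))) {
    for (r in seq_len(spec$replicates)) {
      well <- sprintf("%s%02d", LETTERS[r], i)
      w <- sim_well(spec, spec$probe$tm0 + conds$shift[i], seed, well)
      curves[[well]] <- w$curve
      tm_true[well] <- w$tm
      is_ref <- is.na(conds$ligand_conc[i])
      rows[[well]] <- as_layout_row(
        well_id = well, probe = spec$probe_name, probe_conc = 1.5,
        ligand = if (is_ref) NA_character_ else spec$ligand_name,
        ligand_conc = conds$ligand_conc[i],
        inhibitor = NA_character_, inhibitor_conc = NA_real_,
        inhibitor_conc_unit = "uM",
        replicate_group = conds$group[i],
        role = if (is_ref) "reference" else "sample")
    }
  }
  list(plate = melt_plate(grid, curves,
                          metadata = list(source = "tmshift simulator",
                                          scenario = "binding", seed = seed)),
       layout = plate_layout(do.call(rbind, rows)),
       truth = list(delta_t_max = spec$delta_t_max, kd = spec$kd,
                    site_multiplicity = spec$site_multiplicity,
                    tm0 = spec$probe$tm0, shifts = shifts,
                    ligand_concs = spec$ligand_concs, tm_true = tm_true,
                    seed = seed))
}

destab_at <- function(spec, dose) {
  if (dose == 0 || is.null(spec$destab_map)) return(0)
  m <- spec$destab_map
  if (is.function(m)) return(m(dose))
  key <- as.character(dose)
  if (!key %in% names(m)) {
    stop("destab_map has no entry for dose ", dose, call. = FALSE)
  }
  unname(m[key])
}

suppression_at <- function(spec, dose) {
  if (dose == 0) return(0)
  p <- spec$suppression
  100 / (1 + (p[["ic50"]] / dose)^p[["hill"]])
}

#' Simulate an inhibitor dose-response experiment
#'
#' For each dose (including 0) three well classes are generated: probe
#' alone, probe + inhibitor (the probe Tm moved by the destabilization
#' truth) and probe + inhibitor + ligand at `dna_conc` (the ligand-induced
#' shift scaled by `1 - suppression(dose)/100` per the 4PL suppression
#' truth). Dose 0 carries no inhibitor.
#'
#' @param spec A [plate_sim_spec()].
#' @param doses Inhibitor doses (micromolar), nonzero.
#' @param dna_conc Ligand concentration used in the DNA wells (micromolar,
#'   default 10).
#' @param seed Integer seed.
#' @return A list with `plate`, `layout` and `truth` (including the
#'   suppression 4PL and per-dose destabilization used).
#' @export
simulate_inhibition_experiment <- function(spec = plate_sim_spec(),
                                           doses = c(3, 10, 30, 100),
                                           dna_conc = 10, seed = 1L) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  grid <- sim_grid(spec$probe)
  dna_shift <- predict_delta_tm(spec$delta_t_max, spec$kd,
                                dna_conc * spec$site_multiplicity)
  all_doses <- c(0, sort(doses))
  curves <- list(); rows <- list(); tm_true <- c()
  col <- 0L
  for (dose in all_doses) {
    destab <- destab_at(spec, dose)
    supp <- suppression_at(spec, dose)
    classes <- list(
      probe = list(tm = spec$probe$tm0 + destab, ligand = FALSE),
      probe_dna = list(tm = spec$probe$tm0 + destab +
                         dna_shift * (1 - supp / 100), ligand = TRUE)
    )
    for (cls in names(classes)) {
      col <- col + 1L
      for (r in seq_len(spec$replicates)) {
        well <- sprintf("%s%02d", LETTERS[r], col)
        w <- sim_well(spec, classes[[cls]]$tm, seed, well)
        curves[[well]] <- w$curve
        tm_true[well] <- w$tm
        has_inh <- dose > 0
        rows[[well]] <- as_layout_row(
          well_id = well, probe = spec$probe_name, probe_conc = 1.5,
          ligand = if (classes[[cls]]$ligand) spec$ligand_name
                   else NA_character_,
          ligand_conc = if (classes[[cls]]$ligand) dna_conc else NA_real_,
          inhibitor = if (has_inh) spec$inhibitor_name else NA_character_,
          inhibitor_conc = if (has_inh) dose else NA_real_,
          inhibitor_conc_unit = "uM",
          replicate_group = sprintf("%s_d%g", cls, dose),
          role = if (!has_inh && !classes[[cls]]$ligand) "reference"
                 else "sample")
      }
    }
  }
  list(plate = melt_plate(grid, curves,
                          metadata = list(source = "tmshift simulator",
                                          scenario = "inhibition",
                                          seed = seed)),
       layout = plate_layout(do.call(rbind, rows)),
       truth = list(suppression = spec$suppression,
                    destab = vapply(all_doses, function(d) destab_at(spec, d),
                                    numeric(1)),
                    doses = all_doses, dna_conc = dna_conc,
                    dna_shift = dna_shift, tm0 = spec$probe$tm0,
                    tm_true = tm_true, seed = seed))
}
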