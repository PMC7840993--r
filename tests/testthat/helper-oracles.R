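# brute-force grid-search oracles and small fixture builders, independent of
# the optimizers they check

grid_search_binding <- function(concs, y, dt_range, kd_range, n = 80L) {
  dts <- seq(dt_range[1], dt_range[2], length.out = n)
  kds <- seq(kd_range[1], kd_range[2], length.out = n)
  best <- list(sse = Inf)
  for (dt in dts) {
    pred <- vapply(kds, function(k) {
      sum((y - predict_delta_tm(dt, k, concs))^2)
    }, numeric(1))
    i <- which.min(pred)
    if (pred[i] < best$sse) {
      best <- list(sse = pred[i], delta_t_max = dt, kd = kds[i])
    }
  }
  best
}

grid_search_4pl <- function(dose, y, bottom, top, ic50_range, hill_range,
                            n = 80L) {
  ic50s <- exp(seq(log(ic50_range[1]), log(ic50_range[2]), length.out = n))
  hills <- seq(hill_range[1], hill_range[2], length.out = n)
  f <- function(d, i, h) bottom + (top - bottom) / (1 + (i / d)^h)
  best <- list(sse = Inf)
  for (i in ic50s) {
    sses <- vapply(hills, function(h) sum((y - f(dose, i, h))^2), numeric(1))
    k <- which.min(sses)
    if (sses[k] < best$sse) best <- list(sse = sses[k], ic50 = i,
                                         hill = hills[k])
  }
  best
}

# a clean noiseless two-state curve with flat baselines
flat_sim <- function(tm0 = 42.5, ...) {
  sim_spec(tm0 = tm0, native_baseline = c(100, 0),
           unfolded_baseline = c(100, 0), ...)
}

wide_csv_text <- function() {
  paste("Temperature,A1,A2",
        "25,10,20",
        "26,11,21",
        "27,12,22", sep = "\n")
}

long_csv_text <- function() {
  paste("well,temperature,rfu",
        "A1,25,10", "A1,26,11", "A1,27,12",
        "A2,25,20", "A2,26,21", "A2,27,22", sep = "\n")
}

layout_yaml_text <- function() {
  paste("wells:",
        "  A1: {probe: p65, probe_conc: 1.5, role: reference}",
        "  A2: {probe: p65, probe_conc: 1.5, ligand: dsDNA, ligand_conc: 10,",
        "       replicate_group: g1}", sep = "\n")
}
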