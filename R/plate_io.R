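#' Construct a melt plate
#'
#' A `melt_plate` holds the melt curves of one run: a shared, strictly
#' increasing temperature grid (degrees Celsius) and one relative-fluorescence
#' (RFU) trace per well.
#'
#' @param temperatures Numeric vector of temperatures in degrees Celsius,
#'   strictly increasing.
#' @param curves Numeric matrix with `length(temperatures)` rows and one named
#'   column per well, or a named list of numeric vectors of matching length.
#' @param metadata Optional free-text metadata (instrument, run id, ...).
#' @return An object of class `melt_plate` with components `temperatures`
#'   (numeric), `curves` (numeric matrix, wells in columns) and `metadata`.
#' @seealso [read_melt_csv()], [simulate_melt_curve()]
#' @export
melt_plate <- function(temperatures, curves, metadata = list()) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 2L) {
    stop("a melt plate needs at least 2 temperature points", call. = FALSE)
  }
  if (anyNA(temperatures) || any(diff(temperatures) <= 0)) {
    stop("temperature grid must be strictly increasing and free of NA",
         call. = FALSE)
  }
  if (is.list(curves) && !is.data.frame(curves)) {
    lens <- lengths(curves)
    if (any(lens != length(temperatures))) {
      stop("curve length mismatch for well(s): ",
           paste(names(curves)[lens != length(temperatures)], collapse = ", "),
           call. = FALSE)
    }
    curves <- do.call(cbind, lapply(curves, as.numeric))
    # do.call drops names when a single curve is given
    if (is.null(colnames(curves))) colnames(curves) <- names(lens)
  }
  curves <- as.matrix(curves)
  storage.mode(curves) <- "double"
  rownames(curves) <- NULL
  if (nrow(curves) != length(temperatures)) {
    stop("curves must have one row per temperature", call. = FALSE)
  }
  if (is.null(colnames(curves)) || anyDuplicated(colnames(curves))) {
    stop("wells must be uniquely named", call. = FALSE)
  }
  structure(
    list(temperatures = temperatures, curves = curves, metadata = metadata),
    class = "melt_plate"
  )
}

#' @export
print.melt_plate <- function(x, ...) {
  cat("Melt plate:", ncol(x$curves), "wells,",
      length(x$temperatures), "temperatures",
      sprintf("(%.1f-%.1f °C, step %.2g °C)\n",
              min(x$temperatures), max(x$temperatures),
              stats::median(diff(x$temperatures))))
  cat("Wells:", paste(utils::head(colnames(x$curves), 8), collapse = ", "),
      if (ncol(x$curves) > 8) "...", "\n")
  invisible(x)
}

#' @export
plot.melt_plate <- function(x, wells = colnames(x$curves), derivative = FALSE,
                            ...) {
  wells <- match.arg(wells, colnames(x$curves), several.ok = TRUE)
  y <- x$curves[, wells, drop = FALSE]
  if (derivative) {
    y <- apply(y, 2, function(v) derivative_curve(x$temperatures, v))
  }
  graphics::matplot(x$temperatures, y, type = "l", lty = 1,
                    xlab = "Temperature (°C)",
                    ylab = if (derivative) "d(RFU)/dT" else "RFU", ...)
  invisible(x)
}

#' Read a melt-curve plate from CSV
#'
#' Two dialects are supported. The wide dialect (canonical, mirroring common
#' qPCR melt exports) has a first column `Temperature` and one column per
#' well. The long dialect has columns `well`, `temperature`, `rfu`. Both
#' parse to the same in-memory representation.
#'
#' @param file Path to a CSV file, or a connection.
#' @param format `"wide"` or `"long"`.
#' @return A [melt_plate()].
#' @export
read_melt_csv <- function(file, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- utils::read.csv(file, check.names = FALSE, strip.white = TRUE)
  if (format == "wide") {
    if (ncol(df) < 2L || tolower(names(df)[1]) != "temperature") {
      stop("wide melt CSV must start with a 'Temperature' column",
           call. = FALSE)
    }
    if (anyDuplicated(names(df)[-1])) {
      stop("duplicate well column(s): ",
           paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
                 collapse = ", "), call. = FALSE)
    }
    num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
    bad <- names(df)[vapply(num, anyNA, logical(1))]
    if (length(bad)) {
      stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    df[] <- num
    ord <- order(df[[1]])
    df <- df[ord, , drop = FALSE]
    if (any(diff(df[[1]]) <= 0)) {
      stop("temperature grid is not strictly increasing (duplicate row near T=",
           df[[1]][which(diff(df[[1]]) <= 0)[1]], ")", call. = FALSE)
    }
    melt_plate(df[[1]], as.matrix(df[-1]))
  } else {
    names(df) <- tolower(names(df))
    need <- c("well", "temperature", "rfu")
    if (!all(need %in% names(df))) {
      stop("long melt CSV needs columns well, temperature, rfu", call. = FALSE)
    }
    df$temperature <- suppressWarnings(as.numeric(df$temperature))
    df$rfu <- suppressWarnings(as.numeric(df$rfu))
    if (anyNA(df$temperature) || anyNA(df$rfu)) {
      stop("non-numeric temperature/rfu cell in long melt CSV", call. = FALSE)
    }
    grid <- sort(unique(df$temperature))
    wells <- unique(df$well)
    curves <- lapply(wells, function(w) {
      sub <- df[df$well == w, , drop = FALSE]
      if (nrow(sub) != length(grid) || anyDuplicated(sub$temperature) ||
          !all(sort(sub$temperature) == grid)) {
        stop("well ", w, " does not cover the shared temperature grid exactly",
             call. = FALSE)
      }
      sub$rfu[order(sub$temperature)]
    })
    names(curves) <- wells
    melt_plate(grid, curves)
  }
}

#' Write a melt plate to CSV (wide dialect)
#'
#' Numeric values are written with 6 significant digits, so a write/read
#' round trip reproduces the plate to that precision.
#'
#' @param plate A [melt_plate()].
#' @param file Path or connection to write to.
#' @export
write_melt_csv <- function(plate, file) {
  stopifnot(inherits(plate, "melt_plate"))
  df <- data.frame(Temperature = signif(plate$temperatures, 6),
                   signif(plate$curves, 6), check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(plate)
}

#' Read a plate layout
#'
#' The layout maps wells to experimental conditions. It is a YAML document
#' with a top-level `wells` mapping; each entry may declare `probe`,
#' `probe_conc` (micromolar), `ligand`, `ligand_conc`, `inhibitor`,
#' `inhibitor_conc`, `inhibitor_conc_unit`, `replicate_group` and `role`
#' (one of `sample`, `reference`, `blank`; default `sample`). A missing
#' `replicate_group` defaults to the well id. Reference wells must carry no
#' ligand and no inhibitor; concentrations must be non-negative.
#'
#' @param file Path to a YAML layout file, or a YAML string.
#' @return A data frame of class `plate_layout`, one row per well.
#' @export
read_layout <- function(file) {
  doc <- if (is.character(file) && length(file) == 1L && !file.exists(file) &&
             grepl("\n", file)) {
    yaml::yaml.load(file)
  } else {
    yaml::read_yaml(file)
  }
  if (is.null(doc$wells) || !length(doc$wells)) {
    stop("layout must declare a non-empty 'wells' mapping", call. = FALSE)
  }
  rows <- lapply(names(doc$wells), function(w) {
    e <- doc$wells[[w]]
    as_layout_row(well_id = w,
                  probe = e$probe %||% NA_character_,
                  probe_conc = e$probe_conc %||% NA_real_,
                  ligand = e$ligand %||% NA_character_,
                  ligand_conc = e$ligand_conc %||% NA_real_,
                  inhibitor = e$inhibitor %||% NA_character_,
                  inhibitor_conc = e$inhibitor_conc %||% NA_real_,
                  inhibitor_conc_unit = e$inhibitor_conc_unit %||% "uM",
                  replicate_group = e$replicate_group %||% w,
                  role = e$role %||% "sample")
  })
  plate_layout(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_layout_row <- function(well_id, probe, probe_conc, ligand, ligand_conc,
                          inhibitor, inhibitor_conc, inhibitor_conc_unit,
                          replicate_group, role) {
  data.frame(well_id = as.character(well_id),
             probe = as.character(probe),
             probe_conc = as.numeric(probe_conc),
             ligand = as.character(ligand),
             ligand_conc = as.numeric(ligand_conc),
             inhibitor = as.character(inhibitor),
             inhibitor_conc = as.numeric(inhibitor_conc),
             inhibitor_conc_unit = as.character(inhibitor_conc_unit),
             replicate_group = as.character(replicate_group),
             role = as.character(role),
             stringsAsFactors = FALSE)
}

#' Validate and class a plate-layout data frame
#'
#' @param df Data frame with the columns documented in [read_layout()].
#' @return `df`, validated, with class `plate_layout` prepended.
#' @export
plate_layout <- function(df) {
  need <- c("well_id", "probe", "probe_conc", "ligand", "ligand_conc",
            "inhibitor", "inhibitor_conc", "inhibitor_conc_unit",
            "replicate_group", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("layout is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$well_id)) {
    stop("duplicate well id(s): ",
         paste(unique(df$well_id[duplicated(df$well_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$role %in% c("sample", "reference", "blank"))) {
    stop("unknown role(s): ",
         paste(setdiff(unique(df$role), c("sample", "reference", "blank")),
               collapse = ", "), call. = FALSE)
  }
  concs <- c(df$probe_conc, df$ligand_conc, df$inhibitor_conc)
  if (any(concs < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  ref <- df$role == "reference"
  has_lig <- !is.na(df$ligand) & !(!is.na(df$ligand_conc) & df$ligand_conc == 0)
  has_inh <- !is.na(df$inhibitor) &
    !(!is.na(df$inhibitor_conc) & df$inhibitor_conc == 0)
  if (any(ref & (has_lig | has_inh))) {
    stop("reference wells must carry no ligand and no inhibitor: ",
         paste(df$well_id[ref & (has_lig | has_inh)], collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Write a result table as TSV
#'
#' Writes any result data frame (Tm table, binding fit, dose-response fit)
#' with a header row, the column order of the input, and numeric columns
#' rounded to 6 significant digits, so identical records always produce
#' byte-identical files.
#'
#' @param records A data frame.
#' @param file Path or connection.
#' @export
write_results <- function(records, file) {
  stopifnot(is.data.frame(records))
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    formatC(signif(x, 6), format = "g", digits = 6)
  })
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(records)
}
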