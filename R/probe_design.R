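#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values for the 20 standard amino acids
#' (one-letter codes). Positive = hydrophobic.
#'
#' @format Named numeric vector of length 20.
#' @export
kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

check_residues <- function(seq, permissive = FALSE, id = "sequence") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), names(kyte_doolittle))
  if (length(bad) && !permissive) {
    stop("non-standard residue(s) in ", id, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [seqinr::read.fasta()] returning upper-case residue
#' strings named by record id, in file order. Sequences containing
#' characters outside the 20 standard residues are rejected unless
#' `permissive = TRUE`.
#'
#' @param file FASTA file path.
#' @param permissive Allow non-standard residue letters.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file, permissive = FALSE) {
  recs <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  if (!length(recs)) stop("no FASTA records found", call. = FALSE)
  out <- vapply(recs, function(r) {
    toupper(gsub("[[:space:]*]", "", as.character(r)[1]))
  }, character(1))
  names(out) <- vapply(recs, function(r) attr(r, "name"), character(1))
  for (i in seq_along(out)) check_residues(out[[i]], permissive, names(out)[i])
  out
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle values over all residues. The
#' window-independent summary used to judge overall probe hydrophilicity.
#'
#' @param seq Residue string (one-letter codes).
#' @param permissive Score unknown residues as 0 instead of erroring.
#' @return GRAVY value in `[-4.5, 4.5]`.
#' @examples
#' gravy("AAAA")  # 1.8
#' @export
gravy <- function(seq, permissive = FALSE) {
  seq <- toupper(seq)
  check_residues(seq, permissive)
  chars <- strsplit(seq, "")[[1]]
  if (!length(chars)) stop("empty sequence", call. = FALSE)
  vals <- kyte_doolittle[chars]
  vals[is.na(vals)] <- 0
  mean(vals)
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Unweighted mean hydropathy over a sliding window, without edge padding,
#' so the profile has `length(seq) - window + 1` scores. Positions are
#' 1-based window centres, matching protein residue numbering.
#'
#' @param seq Residue string.
#' @param window Odd window size (default 9).
#' @param permissive Score unknown residues as 0.
#' @return A list of class `hydropathy_profile`: `positions`, `scores`,
#'   `window`, `gravy`, `length`.
#' @export
hydropathy_profile <- function(seq, window = 9L, permissive = FALSE) {
  seq <- toupper(seq)
  check_residues(seq, permissive)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (window > n) stop("window longer than the sequence", call. = FALSE)
  vals <- unname(kyte_doolittle[chars])
  vals[is.na(vals)] <- 0
  cs <- cumsum(c(0, vals))
  scores <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  half <- (window - 1L) %/% 2L
  structure(list(positions = (1L + half):(n - half), scores = scores,
                 window = window, gravy = mean(vals), length = n),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("Hydropathy profile: %d residues, window %d, GRAVY %.3f\n",
              x$length, x$window, x$gravy))
  cat(sprintf("  scores: %d windows in [%.2f, %.2f]\n", length(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
plot.hydropathy_profile <- function(x, threshold = NULL, ...) {
  graphics::plot(x$positions, x$scores, type = "l", xlab = "residue",
                 ylab = "Kyte-Doolittle hydropathy", ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Low-hydropathy segments of a profile
#'
#' Maximal runs of consecutive window scores below a threshold that reach a
#' minimum length. Such segments mark hydrophilic / flexible stretches
#' (e.g. domain boundaries and disordered linkers) that make poor
#' dye-binding probes.
#'
#' @param profile A [hydropathy_profile()].
#' @param threshold Score threshold (scores strictly below count).
#' @param min_length Minimum run length in windows (default 10).
#' @return Data frame with 1-based inclusive `start`, `end` (window-centre
#'   residue positions), `length` and `mean_score`; zero rows when no run
#'   qualifies.
#' @export
low_hydropathy_segments <- function(profile, threshold = -1.5,
                                    min_length = 10L) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  below <- profile$scores < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  out <- data.frame(start = profile$positions[starts[keep]],
                    end = profile$positions[ends[keep]],
                    length = r$lengths[keep],
                    mean_score = vapply(which(keep), function(i) {
                      mean(profile$scores[starts[i]:ends[i]])
                    }, numeric(1)))
  out[order(out$start), , drop = FALSE]
}

#' Path to the bundled canonical human RelA (p65) sequence
#'
#' FASTA fixture with the 551-residue canonical human RelA/p65 sequence
#' (UniProt Q04206), used for hydropathy-based probe-design examples and
#' checks.
#'
#' @return File path.
#' @export
rela_fasta <- function() {
  system.file("extdata", "RELA_HUMAN_Q04206.fasta", package = "tmshift",
              mustWork = TRUE)
}
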