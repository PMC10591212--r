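# Monoisotopic mass arithmetic for singly protonated ([M+H]+) collagen
# peptides, as read from MALDI-TOF spectra.

# Standard monoisotopic residue masses (Da).  'X' (unresolved position) has
# no mass and is rejected by the mass engine.
.AA_MONO <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)

#' Mass constants used by the peptide mass engine
#'
#' Monoisotopic masses (Da) of water and the proton, and the mass deltas of
#' the three modifications relevant to collagen ZooMS: hydroxylation of
#' proline/lysine (+15.994915), deamidation of asparagine/glutamine
#' (+0.984016) and oxidation of methionine (+15.994915).
#'
#' @format Named numeric vector.
#' @export
mass_constants <- c(
  water         = 18.010565,
  proton        = 1.007276,
  hydroxylation = 15.994915,
  deamidation   = 0.984016,
  oxidation     = 15.994915)

.residue_counts <- function(sequence, residues) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(chars %in% residues)
}

.check_sequence <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.AA_MONO))
  if (length(bad))
    stop("unknown residue letter(s) in peptide sequence: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  chars
}

#' Monoisotopic [M+H]+ of a peptide with counted modifications
#'
#' Sums standard monoisotopic residue masses, adds water and one proton
#' (MALDI singly charged convention), then the mass deltas for the requested
#' modification counts.  Modifications are counted, not site-localised:
#' MALDI-TOF cannot localise them.
#'
#' @param sequence Character vector of peptide sequences (20 standard
#'   one-letter residues; `X` is rejected because it has no defined mass).
#' @param n_oh Hydroxylations (+15.994915 Da each), capped at the number of
#'   P plus K residues.
#' @param n_deam Deamidations (+0.984016 Da each), capped at N plus Q.
#' @param n_ox Oxidations (+15.994915 Da each), capped at M.
#' @return Numeric vector of [M+H]+ values (Da).
#' @examples
#' peptide_mh("GEAGHRGPDGNAGR")            # ~1350.63
#' peptide_mh("GFTGMQGLPGPAGAHGER", n_oh = 1)
#' @export
peptide_mh <- function(sequence, n_oh = 0L, n_deam = 0L, n_ox = 0L) {
  n <- length(sequence)
  args <- data.frame(sequence = sequence,
                     n_oh = rep_len(n_oh, n),
                     n_deam = rep_len(n_deam, n),
                     n_ox = rep_len(n_ox, n),
                     stringsAsFactors = FALSE)
  vapply(seq_len(n), function(i) {
    s <- args$sequence[i]
    chars <- .check_sequence(s)
    caps <- c(oh   = sum(chars %in% c("P", "K")),
              deam = sum(chars %in% c("N", "Q")),
              ox   = sum(chars == "M"))
    want <- c(oh = args$n_oh[i], deam = args$n_deam[i], ox = args$n_ox[i])
    if (any(want < 0))
      stop("modification counts must be nonnegative", call. = FALSE)
    if (any(want > caps))
      stop("modification count exceeds available residues for '", s, "': ",
           paste(names(want)[want > caps], collapse = ", "), call. = FALSE)
    sum(.AA_MONO[chars]) +
      mass_constants[["water"]] + mass_constants[["proton"]] +
      want[["oh"]]   * mass_constants[["hydroxylation"]] +
      want[["deam"]] * mass_constants[["deamidation"]] +
      want[["ox"]]   * mass_constants[["oxidation"]]
  }, numeric(1))
}

#' Enumerate modification-state mass variants of a peptide
#'
#' All combinations of hydroxylation, deamidation and oxidation counts within
#' the given caps (each additionally capped by the available residues),
#' sorted by ascending m/z.  Adjacent hydroxylation states differ by exactly
#' 15.994915 Da, the ~16 Da ladder spacing characteristic of collagen
#' peptides.
#'
#' @param sequence Single peptide sequence.
#' @param max_oh,max_deam,max_ox Per-modification maxima (counts).
#' @return `data.frame` with columns `n_oh`, `n_deam`, `n_ox`, `mz`.
#' @export
variant_masses <- function(sequence, max_oh = 3L, max_deam = 0L, max_ox = 0L) {
  if (length(sequence) != 1L) stop("one sequence at a time")
  if (max_oh < 0 || max_deam < 0 || max_ox < 0)
    stop("modification caps must be nonnegative")
  chars <- .check_sequence(sequence)
  oh_cap   <- min(max_oh,   sum(chars %in% c("P", "K")))
  deam_cap <- min(max_deam, sum(chars %in% c("N", "Q")))
  ox_cap   <- min(max_ox,   sum(chars == "M"))
  grid <- expand.grid(n_oh = 0:oh_cap, n_deam = 0:deam_cap, n_ox = 0:ox_cap)
  base <- peptide_mh(sequence)
  grid$mz <- base +
    grid$n_oh   * mass_constants[["hydroxylation"]] +
    grid$n_deam * mass_constants[["deamidation"]] +
    grid$n_ox   * mass_constants[["oxidation"]]
  grid <- grid[order(grid$mz), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Tolerance-based mass matching
#'
#' Tests observed against theoretical m/z under an absolute (Da) or relative
#' (ppm, converted at the theoretical mass) tolerance.  Deltas are reported
#' signed as observed minus theoretical.
#'
#' @param observed,theoretical Positive m/z values (recycled).
#' @param tol Tolerance value (> 0).
#' @param unit `"Da"` or `"ppm"`.
#' @return `data.frame` with columns `match` (logical) and `delta` (Da).
#' @export
match_mass <- function(observed, theoretical, tol = 0.2,
                       unit = c("Da", "ppm")) {
  unit <- match.arg(unit)
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("tol must be a single positive number")
  if (any(observed <= 0) || any(theoretical <= 0))
    stop("masses must be positive")
  n <- max(length(observed), length(theoretical))
  observed <- rep_len(observed, n)
  theoretical <- rep_len(theoretical, n)
  tol_da <- if (unit == "ppm") tol * 1e-6 * theoretical else rep_len(tol, n)
  delta <- observed - theoretical
  data.frame(match = abs(delta) <= tol_da, delta = delta)
}
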