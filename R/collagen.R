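# Collagen type I chain sequences.  Teleost fish COL1 has three distinct
# chains (alpha-1a, alpha-2, alpha-1b); each is a Gly-X-Y triplet-repeat
# protein whose mature region (propeptides removed) is what tryptic peptide
# positions are numbered against.

.CHAIN_IDS <- c("COL1a1a", "COL1a2", "COL1a1b")
# 20 standard residues plus 'X' for unresolved positions
.AA_ALPHABET <- strsplit("GASPVTCLINDQKEMHFRYWX", "")[[1]]

#' A collagen type I chain of one species
#'
#' @param species_id Species label.
#' @param chain_id One of `"COL1a1a"`, `"COL1a2"`, `"COL1a1b"`.
#' @param residues Amino-acid sequence over the 20 standard letters plus
#'   `X` for unresolved positions.
#' @param mature_start,mature_end 1-based inclusive bounds of the mature
#'   chain within `residues`.  Bounds are supplied explicitly (e.g. from an
#'   annotation table) rather than predicted.
#' @return Object of class `collagen_chain`.
#' @export
collagen_chain <- function(species_id, chain_id, residues,
                           mature_start = 1L,
                           mature_end = nchar(residues)) {
  if (!nzchar(residues)) stop("residues must be non-empty")
  if (!chain_id %in% .CHAIN_IDS)
    stop("unknown chain_id '", chain_id, "'; expected one of ",
         paste(.CHAIN_IDS, collapse = ", "))
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, .AA_ALPHABET)
  if (length(bad))
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  n <- nchar(residues)
  if (!(mature_start >= 1 && mature_start <= mature_end && mature_end <= n))
    stop("need 1 <= mature_start <= mature_end <= length(residues)")
  structure(list(species_id = species_id, chain_id = chain_id,
                 residues = residues,
                 mature_start = as.integer(mature_start),
                 mature_end = as.integer(mature_end)),
            class = "collagen_chain")
}

#' @export
print.collagen_chain <- function(x, ...) {
  cat(sprintf("<collagen_chain> %s %s: %d residues (mature %d..%d)\n",
              x$species_id, x$chain_id, nchar(x$residues),
              x$mature_start, x$mature_end))
  invisible(x)
}

#' The three collagen chains of one species
#'
#' @param chains List of [collagen_chain()] objects sharing one species and
#'   carrying distinct chain ids.
#' @return Object of class `species_profile`.
#' @export
species_profile <- function(chains) {
  ids <- vapply(chains, `[[`, "", "chain_id")
  sp <- unique(vapply(chains, `[[`, "", "species_id"))
  if (anyDuplicated(ids)) stop("chain ids must be distinct within a species")
  if (length(sp) != 1L) stop("all chains must share one species_id")
  names(chains) <- ids
  structure(list(species_id = sp, chains = chains),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: chains %s\n", x$species_id,
              paste(names(x$chains), collapse = ", ")))
  invisible(x)
}

#' Mature-chain sequence
#'
#' @param chain A [collagen_chain()].
#' @return The substring `residues[mature_start..mature_end]`.
#' @export
mature_sequence <- function(chain) {
  stopifnot(inherits(chain, "collagen_chain"))
  substr(chain$residues, chain$mature_start, chain$mature_end)
}

#' Read species profiles from FASTA plus a mature-bounds table
#'
#' FASTA headers must encode species and chain as `>SPECIES|CHAIN`
#' (separator configurable).  Mature bounds come from a TSV with columns
#' `species`, `chain`, `start`, `end`; chains without an annotation default
#' to the whole record.  When chain lengths differ across species the
#' shorter sequences are end-padded with `X` (warning), keeping downstream
#' positional pairing simple for these highly conserved, essentially
#' gap-free proteins.
#'
#' @param fasta Path to an amino-acid FASTA file.
#' @param bounds Path to the bounds TSV, or a data.frame, or `NULL`.
#' @param sep Header separator between species and chain (default `"|"`).
#' @param pad Pad length-mismatched chains with `X` (default `TRUE`).
#' @return Named list of [species_profile()] objects.
#' @export
read_profiles <- function(fasta, bounds = NULL, sep = "|", pad = TRUE) {
  aa <- tryCatch(Biostrings::readAAStringSet(fasta),
                 error = function(e) stop("malformed FASTA '", fasta, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(aa) == 0L) {
    warning("empty FASTA file: ", fasta)
    return(list())
  }
  hdr <- names(aa)
  parts <- strsplit(hdr, sep, fixed = TRUE)
  ok <- lengths(parts) >= 2L
  if (any(!ok))
    stop("FASTA header lacks a chain tag (expected SPECIES", sep,
         "CHAIN): '", hdr[!ok][1L], "'")
  species <- vapply(parts, `[[`, "", 1L)
  chain <- vapply(parts, function(p) trimws(p[[2L]]), "")
  bad <- !chain %in% .CHAIN_IDS
  if (any(bad))
    stop("unknown chain_id '", chain[bad][1L], "' in header '",
         hdr[bad][1L], "'")
  seqs <- unname(as.character(aa))
  if (!is.null(bounds) && !is.data.frame(bounds))
    bounds <- utils::read.delim(bounds, stringsAsFactors = FALSE)
  # per-chain length harmonisation across species
  if (pad) {
    for (cid in unique(chain)) {
      idx <- which(chain == cid)
      lens <- nchar(seqs[idx])
      if (length(unique(lens)) > 1L) {
        warning("chain ", cid, " lengths differ across species; ",
                "end-padding with 'X'")
        m <- max(lens)
        seqs[idx] <- vapply(seqs[idx], function(s)
          paste0(s, strrep("X", m - nchar(s))), "")
      }
    }
  }
  profiles <- list()
  for (sp in unique(species)) {
    idx <- which(species == sp)
    chains <- lapply(idx, function(i) {
      st <- 1L; en <- nchar(seqs[i])
      if (!is.null(bounds)) {
        row <- bounds[bounds$species == sp & bounds$chain == chain[i], ,
                      drop = FALSE]
        if (nrow(row) == 1L) { st <- row$start; en <- min(row$end, en) }
      }
      collagen_chain(sp, chain[i], seqs[i], st, en)
    })
    missing <- setdiff(.CHAIN_IDS, chain[idx])
    if (length(missing))
      warning("species ", sp, " is missing chain(s): ",
              paste(missing, collapse = ", "))
    profiles[[sp]] <- species_profile(chains)
  }
  profiles
}

#' Peptide-support sequence coverage
#'
#' Percentage of chain positions covered by at least `min_support` distinct
#' located peptides; positions covered by fewer peptides count as
#' unreconstructed.  This is the two-peptide support rule used when scoring
#' how much of a collagen chain an LC-MS/MS experiment recovered.
#'
#' @param chain A [collagen_chain()].
#' @param peptides data.frame with columns `start` (1-based, mature
#'   coordinates) and `sequence`.
#' @param min_support Minimum distinct peptides per position (default 2).
#' @param scope `"mature"` (denominator = mature chain) or `"total"`
#'   (denominator = full precursor; propeptide positions cannot be covered).
#' @return Percentage in [0, 100].
#' @export
coverage_pct <- function(chain, peptides, min_support = 2L,
                         scope = c("mature", "total")) {
  stopifnot(inherits(chain, "collagen_chain"))
  scope <- match.arg(scope)
  if (min_support < 1L) stop("min_support must be >= 1")
  mlen <- chain$mature_end - chain$mature_start + 1L
  denom <- if (scope == "mature") mlen else nchar(chain$residues)
  if (is.null(peptides) || nrow(peptides) == 0L) return(0)
  depth <- integer(mlen)
  pep <- unique(peptides[, c("start", "sequence")])
  for (i in seq_len(nrow(pep))) {
    from <- pep$start[i]
    to <- from + nchar(pep$sequence[i]) - 1L
    if (from < 1L || to > mlen)
      stop("peptide out of mature-chain bounds: start=", from,
           " end=", to, " (mature length ", mlen, ")")
    depth[from:to] <- depth[from:to] + 1L
  }
  100 * sum(depth >= min_support) / denom
}

#' Pairwise p-distance between aligned sequences
#'
#' Proportion of differing positions among compared positions; positions
#' where either sequence carries `X` (unresolved) are excluded from both
#' numerator and denominator.
#'
#' @param a,b Equal-length character sequences.
#' @return Fraction in [0, 1].
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must be equal length")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  use <- ca != "X" & cb != "X"
  if (!any(use)) stop("undefined p-distance: zero comparable positions")
  sum(ca[use] != cb[use]) / sum(use)
}
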