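# In-silico tryptic digestion of collagen chains.  Trypsin cleaves
# C-terminal to K or R; the classical rule suppresses cleavage when the next
# residue is proline.  Missed cleavages join adjacent fragments.

#' Digestion parameters
#'
#' @param max_missed_cleavages Maximum internal uncleaved K/R sites per
#'   peptide (default 2; the reference grouper panel peptides carry up to one
#'   internal K/R).
#' @param min_length,max_length Retained peptide length bounds in residues
#'   (defaults 6 and 60 span the 12-33 residue range of published fish ZooMS
#'   markers with margin).
#' @param cleave_before_proline If `FALSE` (classical trypsin), K/R followed
#'   by P is not a cleavage site.  `TRUE` permits cleavage before proline,
#'   needed to reproduce observed proline-initial collagen peptides.
#' @return List of class `digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 2L, min_length = 6L,
                          max_length = 60L, cleave_before_proline = FALSE) {
  if (max_missed_cleavages < 0) stop("max_missed_cleavages must be >= 0")
  if (min_length < 1L || min_length > max_length)
    stop("need 1 <= min_length <= max_length")
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 cleave_before_proline = isTRUE(cleave_before_proline)),
            class = "digest_params")
}

# Positions (1-based) after which trypsin cleaves.
.cleavage_sites <- function(chars, cleave_before_proline) {
  n <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n]
  if (!cleave_before_proline) sites <- sites[chars[sites + 1L] != "P"]
  sites
}

#' Tryptic peptides of a collagen chain
#'
#' Cleaves the mature chain after every K/R (suppressed before P unless
#' `cleave_before_proline`), joins up to `max_missed_cleavages` adjacent
#' fragments, and filters by length.  Start positions are 1-based within the
#' mature chain, matching the positional peptide naming convention.
#'
#' @param chain A [collagen_chain()] or a plain character sequence (then
#'   treated as an already-mature chain with no species/chain identity).
#' @param params A [digest_params()] object.
#' @return `data.frame` with columns `species`, `chain`, `name`, `start`,
#'   `sequence`, `missed_cleavages`, sorted by start then length.
#' @examples
#' tryptic_peptides("GPAGKGPAGR", digest_params(0, min_length = 1))
#' @export
tryptic_peptides <- function(chain, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  if (inherits(chain, "collagen_chain")) {
    seqc <- mature_sequence(chain)
    species <- chain$species_id
    chain_id <- chain$chain_id
  } else {
    seqc <- as.character(chain)
    species <- NA_character_
    chain_id <- NA_character_
  }
  empty <- data.frame(species = character(), chain = character(),
                      name = character(), start = integer(),
                      sequence = character(), missed_cleavages = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(seqc)) return(empty)
  chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bounds <- c(0L, .cleavage_sites(chars, params$cleave_before_proline), n)
  nfrag <- length(bounds) - 1L
  out <- vector("list", nfrag * (params$max_missed_cleavages + 1L))
  k <- 0L
  for (i in seq_len(nfrag)) {
    for (mc in 0:params$max_missed_cleavages) {
      j <- i + mc
      if (j > nfrag) break
      from <- bounds[i] + 1L
      to <- bounds[j + 1L]
      len <- to - from + 1L
      if (len < params$min_length || len > params$max_length) next
      k <- k + 1L
      out[[k]] <- data.frame(
        species = species, chain = chain_id,
        name = peptide_name(chain_id, from),
        start = from,
        sequence = substr(seqc, from, to),
        missed_cleavages = mc,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$start, nchar(res$sequence)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Positional peptide name
#'
#' Chain label plus the 1-based start position in the mature chain, e.g.
#' `"COL1a2 568"`.  Naming is purely positional, so homologous peptides of
#' different species share a name — this is what enables cross-species
#' marker pairing.
#'
#' @param chain_id Chain label (or `NA`).
#' @param start 1-based start position in the mature chain.
#' @return Character vector of names.
#' @export
peptide_name <- function(chain_id, start) {
  ifelse(is.na(chain_id), paste("peptide", start), paste(chain_id, start))
}
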