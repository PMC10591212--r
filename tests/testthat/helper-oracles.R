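# Independent oracles and small fixture builders used across the suite.

# Brute-force tryptic digest: enumerate every substring and keep the valid
# tryptic peptides (starts after a cleavage site or at the terminus, ends on
# one, internal missed-cleavage count within bound).  Independent of the
# fragment-joining algorithm in the package.
brute_digest <- function(seqc, max_mc, min_len = 6L, max_len = 60L,
                         cleave_before_proline = FALSE) {
  chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
  n <- length(chars)
  site <- chars %in% c("K", "R")
  site[n] <- FALSE
  if (!cleave_before_proline && n > 1L)
    site[which(site) [chars[which(site) + 1L] == "P"]] <- FALSE
  cs <- c(0L, cumsum(site))  # cs[i+1] = number of sites in 1..i
  out <- list()
  for (from in 1:n) {
    if (!(from == 1L || site[from - 1L])) next
    for (to in from:n) {
      len <- to - from + 1L
      if (len > max_len) break
      if (len < min_len) next
      if (!(to == n || site[to])) next
      mc <- cs[to] - cs[from]  # internal sites within from..to-1
      if (mc > max_mc) next
      out[[length(out) + 1L]] <- data.frame(
        start = from, sequence = paste(chars[from:to], collapse = ""),
        missed_cleavages = mc, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), sequence = character(),
                      missed_cleavages = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, nchar(res$sequence)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

random_protein <- function(n, include_x = FALSE) {
  pool <- c("G", "A", "S", "P", "V", "T", "L", "N", "D", "Q", "K", "E",
            "M", "H", "F", "R")
  if (include_x) pool <- c(pool, "X")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Digest parameters suited to the short chains of the tiny fixtures below.
tiny_dp <- function(max_mc = 1L) {
  digest_params(max_missed_cleavages = max_mc, min_length = 4L,
                max_length = 150L)
}

# A tiny collagen-like profile set: identical chains with substitutions
# applied at the stated mature positions of one chain.  Cleavage sites are
# denser than the full-scale default so short chains still digest into
# peptides of usable length.
tiny_profiles <- function(subs = list(), n_triplets = 30L, seed = 11L,
                          prop_len = 6L) {
  set.seed(seed)
  cfg <- synthetic_species_config(n_species = length(subs),
                                  triplets_per_chain = n_triplets,
                                  substitution_rate = 0,
                                  cleavage_density = 0.18,
                                  propeptide_length = prop_len, seed = seed)
  base <- make_species(cfg)$profiles
  species <- names(base)
  for (i in seq_along(subs)) {
    for (s in subs[[i]]) {  # s = list(chain, pos, to)
      ch <- base[[i]]$chains[[s$chain]]
      stopifnot(!is.na(s$pos), s$pos >= 1L,
                s$pos <= ch$mature_end - ch$mature_start + 1L)
      full_pos <- ch$mature_start + s$pos - 1L
      substr(ch$residues, full_pos, full_pos) <- s$to
      base[[i]]$chains[[s$chain]] <- ch
    }
  }
  base
}

# Gaussian-profile spectrum on a uniform grid.
gaussian_spectrum <- function(centers, heights, fwhm = 0.35,
                              mz = seq(980, 1020, by = 0.1),
                              floor_int = 0) {
  sigma <- fwhm / 2.354820045
  y <- rep(floor_int, length(mz))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-0.5 * ((mz - centers[i]) / sigma)^2)
  maldi_spectrum(mz, y, sample_id = "synthetic", centroided = FALSE)
}
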