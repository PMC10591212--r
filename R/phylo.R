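# Neighbour-joining sanity check over collagen sequence divergence.  This is
# deliberately a lightweight distance-based stand-in: it checks that the
# species in a profile set are separable, it is not a substitution-model
# phylogeny.

#' p-distance matrix over species profiles
#'
#' Concatenates the mature sequences of the three chains per species and
#' computes pairwise [p_distance()] (positions with `X` in either sequence
#' excluded pair-wise).
#'
#' @param profiles Named list of [species_profile()] objects, or a named
#'   character vector of aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(profiles) {
  seqs <- .concat_sequences(profiles)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- p_distance(seqs[[i]], seqs[[j]])
  d
}

.concat_sequences <- function(profiles) {
  if (is.character(profiles)) {
    if (is.null(names(profiles))) stop("sequences must be named")
    return(profiles)
  }
  out <- vapply(profiles, function(p) {
    paste(vapply(p$chains[order(names(p$chains))], mature_sequence, ""),
          collapse = "")
  }, "")
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- vapply(profiles, `[[`, "", "species_id")
  out
}

.check_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (nrow(d) < 3L) stop("need >= 3 taxa for a tree")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (via \pkg{ape}); negative branch lengths, an
#' artefact NJ can produce on noisy matrices, are clamped to zero.  On an
#' additive matrix NJ recovers the generating topology.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist`.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- .check_dist(d)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Character matrix (taxa x aligned positions) from profiles.
.char_matrix <- function(profiles) {
  seqs <- .concat_sequences(profiles)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("concatenated sequences must be equal length (pad with 'X')")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

# p-distance matrix from a character matrix; pairs with no comparable
# positions fall back to the matrix maximum (conservative, bootstrap only).
.dist_from_chars <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- x[i, ] != "X" & x[j, ] != "X"
    d[i, j] <- d[j, i] <-
      if (any(use)) sum(x[i, use] != x[j, use]) / sum(use) else NA_real_
  }
  if (anyNA(d)) d[is.na(d)] <- max(d, 0, na.rm = TRUE)
  d
}

#' Bootstrap support for the neighbour-joining tree
#'
#' Resamples aligned columns of the concatenated mature sequences `B` times,
#' rebuilds the NJ tree per replicate, and reports per-split support as the
#' percentage of replicates containing the split (stored in `node.label`).
#' Deterministic for a fixed seed.
#'
#' @param profiles As in [p_distance_matrix()].
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return `phylo` tree with `node.label` holding support percentages in
#'   [0, 100] (the root label is `NA`).
#' @export
bootstrap_support <- function(profiles, B = 100L, seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  x <- .char_matrix(profiles)
  build <- function(m) {
    tr <- ape::nj(stats::as.dist(.dist_from_chars(m)))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  }
  ref <- build(x)
  set.seed(seed)
  counts <- ape::boot.phylo(ref, x, build, B = as.integer(B),
                            rooted = FALSE, quiet = TRUE)
  ref$node.label <- round(100 * counts / B, 1)
  ref$node.label[1L] <- NA  # root of an unrooted tree carries no split
  ref
}
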