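# Discovery of species-discriminating peptide biomarkers.  Homologous
# peptides are paired positionally across species (chain + mature start +
# missed cleavages), valid because collagen chains are treated as gap-free
# and length-matched; variable pairings become markers.
#
# A discovered panel is the package's fitted object: predict() on it matches
# picked peaks and produces a taxonomic call.

#' Discover a species-discriminating marker panel
#'
#' Digests every profile, pairs peptides across species by position, and
#' emits a marker for every pairing whose sequences differ between at least
#' two species (or whose presence pattern differs).  For each species
#' variant the modification-state mass ladder is enumerated, and each state
#' is flagged MALDI-diagnostic only when its m/z is separated by more than
#' `tol` from every mass any *other* species can produce — including the
#' invariant (non-marker) peptides and hydroxylation states beyond the
#' matching cap, so a shared peptide peak can never impersonate a
#' species-specific marker.
#'
#' @param profiles Named list of [species_profile()] objects (>= 2).
#' @param dparams [digest_params()]; default allows one missed cleavage.
#' @param max_oh,max_deam,max_ox Modification caps for the reported mass
#'   variants (defaults 3, 0, 0).
#' @param tol MALDI-scale diagnosticity tolerance in Da (default 0.2).
#' @return Object of class `marker_panel` with elements `species`,
#'   `markers` (one row per marker x species), `variants` (one row per
#'   marker x species x modification state, with `specific` and
#'   `diagnostic` flags), `tol`, `caps`.
#' @export
discover_markers <- function(profiles,
                             dparams = digest_params(max_missed_cleavages = 1L),
                             max_oh = 3L, max_deam = 0L, max_ox = 0L,
                             tol = 0.2) {
  if (length(profiles) < 2L) stop("need >=2 taxa to discriminate")
  sp_names <- vapply(profiles, `[[`, "", "species_id")
  if (anyDuplicated(sp_names)) stop("duplicate species ids")
  peps <- lapply(profiles, function(p) {
    tab <- do.call(rbind, lapply(p$chains, tryptic_peptides,
                                 params = dparams))
    tab[!grepl("X", tab$sequence, fixed = TRUE), , drop = FALSE]
  })
  names(peps) <- sp_names
  caps <- list(max_oh = as.integer(max_oh), max_deam = as.integer(max_deam),
               max_ox = as.integer(max_ox))

  all_tab <- do.call(rbind, peps)
  all_tab$key <- paste(all_tab$chain, all_tab$start,
                       all_tab$missed_cleavages, sep = ":")
  keys <- unique(all_tab[, c("key", "chain", "start", "missed_cleavages",
                             "name")])
  keys <- keys[order(keys$chain, keys$start, keys$missed_cleavages), ,
               drop = FALSE]

  seq_by_key <- split(all_tab[, c("species", "sequence")], all_tab$key)

  marker_rows <- list(); mi <- 0L
  for (r in seq_len(nrow(keys))) {
    k <- keys$key[r]
    kb <- seq_by_key[[k]]
    seqs <- stats::setNames(rep(NA_character_, length(sp_names)), sp_names)
    seqs[kb$species] <- kb$sequence
    present <- !is.na(seqs)
    distinct <- unique(seqs[present])
    is_marker <- length(distinct) >= 2L || any(!present)
    if (!is_marker) next
    # a species variant is specific when no other species shares it
    specific <- vapply(sp_names, function(sp) {
      present[sp] && !seqs[sp] %in% seqs[setdiff(sp_names, sp)]
    }, logical(1))
    only_absent_specific <- sum(present) == 1L
    if (only_absent_specific) specific <- present
    ssf <- if (sum(specific) == 1L) sp_names[specific] else NA_character_
    mi <- mi + 1L
    marker_rows[[mi]] <- data.frame(
      marker_id = k, name = keys$name[r], chain = keys$chain[r],
      start = keys$start[r], missed_cleavages = keys$missed_cleavages[r],
      species = sp_names, present = unname(present),
      sequence = unname(seqs), evidence = ifelse(present, "MALDI_visible",
                                                 "absent"),
      specific = unname(specific), species_specific_for = ssf,
      mass_printed = NA_character_, footnote = "", note = "",
      stringsAsFactors = FALSE)
  }

  if (mi == 0L) {
    return(.new_marker_panel(sp_names, .empty_markers(), .empty_variants(),
                             tol, caps))
  }
  markers <- do.call(rbind, marker_rows)

  # mass variants of every present marker sequence
  pm <- markers[markers$present, , drop = FALSE]
  uniq_seq <- unique(pm$sequence)
  vm_by_seq <- lapply(uniq_seq, variant_masses, max_oh = caps$max_oh,
                      max_deam = caps$max_deam, max_ox = caps$max_ox)
  names(vm_by_seq) <- uniq_seq
  variants <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
    vm <- vm_by_seq[[pm$sequence[i]]]
    data.frame(marker_id = pm$marker_id[i], name = pm$name[i],
               species = pm$species[i], sequence = pm$sequence[i],
               vm, specific = pm$specific[i], stringsAsFactors = FALSE)
  }))

  # diagnosticity against the full digest mass background of the other
  # species, hydroxylation enumerated to the residue cap (not just the
  # matching cap) so overlooked high-hydroxylation states cannot collide
  bg <- lapply(sp_names, function(sp) {
    us <- unique(peps[[sp]]$sequence)
    sort(unlist(lapply(us, function(s)
      variant_masses(s, max_oh = 99L, max_deam = caps$max_deam,
                     max_ox = caps$max_ox)$mz), use.names = FALSE))
  })
  names(bg) <- sp_names
  variants$diagnostic <- vapply(seq_len(nrow(variants)), function(i) {
    others <- sort(unlist(bg[setdiff(sp_names, variants$species[i])],
                          use.names = FALSE))
    .min_gap(variants$mz[i], others) > tol
  }, logical(1))

  diag_by <- tapply(variants$diagnostic,
                    paste(variants$marker_id, variants$species), any)
  markers$diagnostic <- FALSE
  kk <- paste(markers$marker_id, markers$species)
  hit <- kk %in% names(diag_by)
  markers$diagnostic[hit] <- as.logical(diag_by[kk[hit]])

  variants <- variants[order(variants$mz), , drop = FALSE]
  rownames(markers) <- rownames(variants) <- NULL
  .new_marker_panel(sp_names, markers, variants, tol, caps)
}

.min_gap <- function(x, sorted) {
  if (!length(sorted)) return(Inf)
  i <- findInterval(x, sorted)
  lo <- if (i >= 1L) x - sorted[i] else Inf
  hi <- if (i < length(sorted)) sorted[i + 1L] - x else Inf
  min(lo, hi)
}

# align column types with a template (JSON drops the type of all-NA columns)
.coerce_like <- function(df, template) {
  for (col in intersect(names(df), names(template))) {
    df[[col]] <- switch(class(template[[col]])[1L],
                        character = as.character(df[[col]]),
                        integer = as.integer(df[[col]]),
                        numeric = as.numeric(df[[col]]),
                        logical = as.logical(df[[col]]),
                        df[[col]])
  }
  df
}

.empty_markers <- function() data.frame(
  marker_id = character(), name = character(), chain = character(),
  start = integer(), missed_cleavages = integer(), species = character(),
  present = logical(), sequence = character(), evidence = character(),
  specific = logical(), species_specific_for = character(),
  mass_printed = character(), footnote = character(), note = character(),
  diagnostic = logical(), stringsAsFactors = FALSE)

.empty_variants <- function() data.frame(
  marker_id = character(), name = character(), species = character(),
  sequence = character(), n_oh = integer(), n_deam = integer(),
  n_ox = integer(), mz = numeric(), specific = logical(),
  diagnostic = logical(), stringsAsFactors = FALSE)

.new_marker_panel <- function(species, markers, variants, tol, caps) {
  structure(list(species = unname(species), markers = markers,
                 variants = variants, tol = tol, caps = caps),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  nm <- length(unique(x$markers$marker_id))
  cat(sprintf("<marker_panel> %d species, %d markers, %d mass variants (tol %.3g Da)\n",
              length(x$species), nm, nrow(x$variants), x$tol))
  sp <- x$markers$species_specific_for
  sp <- unique(sp[!is.na(sp)])
  if (length(sp))
    cat("  species-specific markers for:", paste(sort(sp), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.marker_panel <- function(object, ...) {
  m <- object$markers
  per_sp <- vapply(object$species, function(sp)
    sum(!is.na(m$species_specific_for) & m$species_specific_for == sp &
        m$species == sp), integer(1))
  out <- list(n_species = length(object$species),
              n_markers = length(unique(m$marker_id)),
              n_variants = nrow(object$variants),
              specific_per_species = per_sp,
              tol = object$tol)
  class(out) <- "summary.marker_panel"
  out
}

#' @export
print.summary.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d markers over %d species (%d mass variants, tol %.3g Da)\n",
              x$n_markers, x$n_species, x$n_variants, x$tol))
  cat("Species-specific markers:\n")
  for (sp in names(x$specific_per_species))
    cat(sprintf("  %-16s %d\n", sp, x$specific_per_species[[sp]]))
  invisible(x)
}

#' Isobaric collisions within a panel
#'
#' All pairs of mass variants — across markers, species and modification
#' states — whose m/z collide within `tol` but whose sequences differ.
#' Identical sequences in different species are the same peptide, not an
#' isobaric pair, and are not reported.
#'
#' @param panel A [marker_panel()].
#' @param tol Collision tolerance in Da (default: the panel's).
#' @return `data.frame`: one row per conflicting pair with both sequences,
#'   species, hydroxylation states, masses and the shared mass.
#' @export
isobaric_conflicts <- function(panel, tol = panel$tol) {
  stopifnot(inherits(panel, "marker_panel"))
  v <- panel$variants
  if (nrow(v) == 0L) stop("panel is empty")
  v <- v[order(v$mz), , drop = FALSE]
  out <- list(); k <- 0L
  n <- nrow(v)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && v$mz[j] - v$mz[i] <= tol) {
      if (v$sequence[i] != v$sequence[j]) {
        k <- k + 1L
        out[[k]] <- data.frame(
          name1 = v$name[i], species1 = v$species[i],
          sequence1 = v$sequence[i], n_oh1 = v$n_oh[i], mz1 = v$mz[i],
          name2 = v$name[j], species2 = v$species[j],
          sequence2 = v$sequence[j], n_oh2 = v$n_oh[j], mz2 = v$mz[j],
          mz_shared = (v$mz[i] + v$mz[j]) / 2,
          stringsAsFactors = FALSE)
      }
      j <- j + 1L
    }
  }
  if (k == 0L)
    return(data.frame(name1 = character(), species1 = character(),
                      sequence1 = character(), n_oh1 = integer(),
                      mz1 = numeric(), name2 = character(),
                      species2 = character(), sequence2 = character(),
                      n_oh2 = integer(), mz2 = numeric(),
                      mz_shared = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export / import a marker panel
#'
#' JSON (`.json`) is the lossless round-trip format and serialises the full
#' panel.  TSV (`.tsv`) is the human-readable table — one row per marker and
#' species, mirroring the published panel layout — from which mass variants
#' are recomputed on import; variant-level diagnosticity is then
#' re-derived within the panel (the digest background of a discovery run is
#' not part of the table).
#'
#' @param panel A [marker_panel()].
#' @param path Output path; format chosen by extension unless `format`
#'   given.
#' @param format `"auto"`, `"json"` or `"tsv"`.
#' @return `export_panel` returns `path` invisibly; `import_panel` a
#'   [marker_panel()].
#' @export
export_panel <- function(panel, path, format = c("auto", "json", "tsv")) {
  stopifnot(inherits(panel, "marker_panel"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(
      list(species = panel$species, markers = panel$markers,
           variants = panel$variants, tol = panel$tol, caps = panel$caps),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(panel$markers, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname export_panel
#' @param max_oh,max_deam,max_ox Modification caps used to recompute mass
#'   variants on TSV import (defaults 3, 0, 0).
#' @param tol Diagnosticity tolerance for TSV import (default 0.2).
#' @export
import_panel <- function(path, format = c("auto", "json", "tsv"),
                         max_oh = 3L, max_deam = 0L, max_ox = 0L,
                         tol = 0.2) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    markers <- if (length(obj$markers)) {
      .coerce_like(as.data.frame(obj$markers, stringsAsFactors = FALSE),
                   .empty_markers())
    } else .empty_markers()
    variants <- if (length(obj$variants)) {
      .coerce_like(as.data.frame(obj$variants, stringsAsFactors = FALSE),
                   .empty_variants())
    } else .empty_variants()
    return(.new_marker_panel(obj$species, markers, variants, obj$tol,
                             as.list(obj$caps)))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = "")
  required <- c("marker_id", "name", "species", "present", "sequence",
                "evidence", "specific")
  for (col in required)
    if (!col %in% names(tab))
      stop("panel table lacks required column '", col, "'")
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$marker_id[i]) || is.na(tab$species[i]))
      stop("panel table row ", i, ": missing marker_id or species")
    if (isTRUE(tab$present[i] == "TRUE" | tab$present[i] == TRUE) &&
        (is.na(tab$sequence[i]) || !nzchar(tab$sequence[i])))
      stop("panel table row ", i, ": present marker without a sequence")
  }
  tab$present <- as.logical(tab$present)
  tab$specific <- as.logical(tab$specific)
  if (anyNA(tab$present) || anyNA(tab$specific))
    stop("panel table: unparseable present/specific flag (row ",
         which(is.na(tab$present) | is.na(tab$specific))[1L], ")")
  for (col in c("chain", "mass_printed", "footnote", "note",
                "species_specific_for"))
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  if (!"start" %in% names(tab)) tab$start <- NA_integer_
  if (!"missed_cleavages" %in% names(tab)) tab$missed_cleavages <- NA_integer_
  tab$start <- as.integer(tab$start)
  tab$missed_cleavages <- as.integer(tab$missed_cleavages)
  tab$footnote[is.na(tab$footnote)] <- ""
  tab$note[is.na(tab$note)] <- ""
  species <- unique(tab$species)

  # species_specific_for from the per-variant specific flags
  ssf <- tapply(seq_len(nrow(tab)), tab$marker_id, function(idx) {
    sp <- tab$species[idx][tab$specific[idx] & tab$present[idx]]
    if (length(unique(sp)) == 1L) unique(sp) else NA_character_
  })
  tab$species_specific_for <- as.character(ssf[tab$marker_id])

  caps <- list(max_oh = as.integer(max_oh), max_deam = as.integer(max_deam),
               max_ox = as.integer(max_ox))
  pm <- tab[tab$present, , drop = FALSE]
  variants <- if (nrow(pm)) do.call(rbind, lapply(seq_len(nrow(pm)),
    function(i) {
      vm <- variant_masses(pm$sequence[i], max_oh = caps$max_oh,
                           max_deam = caps$max_deam, max_ox = caps$max_ox)
      data.frame(marker_id = pm$marker_id[i], name = pm$name[i],
                 species = pm$species[i], sequence = pm$sequence[i], vm,
                 specific = pm$specific[i], stringsAsFactors = FALSE)
    })) else .empty_variants()

  if (nrow(variants)) {
    # within-panel diagnosticity; annotated rows (isobaric peak 'b',
    # mass shared outside the panel's taxa 'a') are demoted outright
    demoted <- paste(pm$marker_id, pm$species)[pm$footnote %in% c("a", "b") |
                                                 nzchar(pm$note)]
    variants$diagnostic <- vapply(seq_len(nrow(variants)), function(i) {
      if (paste(variants$marker_id[i], variants$species[i]) %in% demoted)
        return(FALSE)
      others <- variants$mz[variants$species != variants$species[i] &
                              variants$sequence != variants$sequence[i]]
      .min_gap(variants$mz[i], sort(others)) > tol
    }, logical(1))
    variants <- variants[order(variants$mz), , drop = FALSE]
  }

  diag_by <- if (nrow(variants))
    tapply(variants$diagnostic,
           paste(variants$marker_id, variants$species), any) else NULL
  tab$diagnostic <- FALSE
  kk <- paste(tab$marker_id, tab$species)
  hit <- kk %in% names(diag_by)
  tab$diagnostic[hit] <- as.logical(diag_by[kk[hit]])

  markers <- tab[, c("marker_id", "name", "chain", "start",
                     "missed_cleavages", "species", "present", "sequence",
                     "evidence", "specific", "species_specific_for",
                     "mass_printed", "footnote", "note", "diagnostic")]
  rownames(markers) <- rownames(variants) <- NULL
  .new_marker_panel(species, markers, variants, tol, caps)
}

#' The bundled Mediterranean grouper reference panel
#'
#' A transcription of the published 22-biomarker collagen peptide panel for
#' the four Mediterranean *Epinephelus* species (white, goldblotch, dusky
#' and dogtooth grouper), including the footnote annotations: `a` = mass
#' also observed in a comber, use only in combination; `b` = peak present
#' through an isobaric peptide; `c` = seen in LC-MS/MS only, invisible in
#' MALDI.  The COL1a2 568 variant printed at m/z 1319.6 computes to ~1336.61
#' from its printed sequence; it is carried as an annotated anomaly and its
#' printed mass is never forced.
#'
#' @param ... Passed to [import_panel()] (e.g. modification caps).
#' @return A [marker_panel()].
#' @export
grouper_panel <- function(...) {
  path <- system.file("extdata", "grouper_marker_panel.tsv",
                      package = "zoomsr", mustWork = TRUE)
  import_panel(path, format = "tsv", ...)
}
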