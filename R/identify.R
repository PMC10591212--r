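# Matching picked peaks against a marker panel and producing per-sample
# taxonomic calls, then cohort-level composition summaries.

#' Match picked peaks against a marker panel
#'
#' Every MALDI-visible panel mass variant is tested against every peak; the
#' best (smallest absolute delta) peak is retained per variant.  Markers
#' whose evidence is LC-MS/MS-only are excluded — they cannot appear in a
#' MALDI spectrum.
#'
#' @param peaks `data.frame` with an `mz` column (as from [pick_peaks()]).
#' @param panel A [marker_panel()].
#' @param tol Matching tolerance (default: the panel's).
#' @param unit `"Da"` or `"ppm"`.
#' @param include_lcms_only Also match LC-MS/MS-only variants (default
#'   `FALSE`); an explicit relaxation for borderline spectra.
#' @return `data.frame` of class `zooms_matches`: one row per variant with
#'   `mz_theoretical`, `mz_observed`, `delta` (signed, observed minus
#'   theoretical), `matched`, plus the variant's `specific`/`diagnostic`
#'   flags.
#' @export
match_markers <- function(peaks, panel, tol = panel$tol,
                          unit = c("Da", "ppm"),
                          include_lcms_only = FALSE) {
  stopifnot(inherits(panel, "marker_panel"))
  unit <- match.arg(unit)
  if (nrow(panel$variants) == 0L) stop("panel is empty")
  m <- panel$markers
  keep_ev <- c("MALDI_visible", if (include_lcms_only) "LCMSMS_only")
  ok <- paste(m$marker_id, m$species)[m$present & m$evidence %in% keep_ev]
  v <- panel$variants
  v <- v[paste(v$marker_id, v$species) %in% ok, , drop = FALSE]
  obs <- sort(peaks$mz)
  find_best <- function(x) {
    if (!length(obs)) return(NA_real_)
    i <- findInterval(x, obs)
    cands <- obs[c(max(i, 1L), min(i + 1L, length(obs)))]
    cands[which.min(abs(cands - x))]
  }
  v$mz_theoretical <- v$mz
  v$mz_observed <- vapply(v$mz, find_best, numeric(1))
  v$delta <- v$mz_observed - v$mz_theoretical
  tol_da <- if (unit == "ppm") tol * 1e-6 * v$mz_theoretical else tol
  v$matched <- !is.na(v$delta) & abs(v$delta) <= tol_da
  v$mz_observed[!v$matched] <- NA_real_
  v$delta[!v$matched] <- NA_real_
  v$mz <- NULL
  rownames(v) <- NULL
  structure(v, class = c("zooms_matches", "data.frame"), tol = tol,
            unit = unit)
}

#' Taxonomic call from marker matches
#'
#' Species call iff exactly one species has at least `min_specific` distinct
#' matched species-specific markers (diagnostic states only) and no other
#' species has any; genus-level iff the species rule fails but at least
#' `min_shared_for_genus` distinct shared markers match; otherwise
#' indeterminate.  Specific matches for two species are a conflict and
#' force indeterminate — no majority vote.
#'
#' @param matches A [match_markers()] result.
#' @param min_specific Minimum distinct specific markers for a species call
#'   (default 1, the single-diagnostic-peptide convention).
#' @param min_shared_for_genus Minimum distinct shared markers for a
#'   genus-level call (default 2).
#' @param sample_id Sample label.
#' @return Object of class `zooms_id` with elements `sample_id`, `call`
#'   (`"species"`, `"genus_level"` or `"indeterminate"`), `species`,
#'   `supporting`, `conflicts`, `n_shared`, `score`.
#' @export
call_species <- function(matches, min_specific = 1L,
                         min_shared_for_genus = 2L, sample_id = "") {
  stopifnot(inherits(matches, "zooms_matches"))
  hit <- matches[matches$matched, , drop = FALSE]
  spec_hit <- hit[hit$specific & hit$diagnostic, , drop = FALSE]
  counts <- tapply(spec_hit$marker_id, spec_hit$species,
                   function(x) length(unique(x)))
  spp <- names(counts)
  n_shared <- length(unique(hit$marker_id[!hit$specific]))
  score <- length(unique(hit$marker_id))
  conflicts <- if (length(spp) > 1L) spec_hit else
    spec_hit[0L, , drop = FALSE]
  call <- "indeterminate"; species <- NA_character_
  if (length(spp) == 1L && counts[[1L]] >= min_specific) {
    call <- "species"; species <- spp
  } else if (length(spp) <= 1L && n_shared >= min_shared_for_genus) {
    call <- "genus_level"
  } else if (length(spp) > 1L && n_shared >= min_shared_for_genus) {
    call <- "indeterminate"  # conflicting specific evidence
  }
  structure(list(sample_id = sample_id, call = call, species = species,
                 supporting = spec_hit, conflicts = conflicts,
                 n_shared = n_shared, score = score),
            class = "zooms_id")
}

#' @export
print.zooms_id <- function(x, ...) {
  cat(sprintf("<zooms_id> %s: %s (%d specific, %d shared markers)\n",
              if (nzchar(x$sample_id)) x$sample_id else "(unnamed)",
              id_label(x), nrow(x$supporting), x$n_shared))
  if (nrow(x$conflicts))
    cat("  conflicting specific markers for:",
        paste(unique(x$conflicts$species), collapse = ", "), "\n")
  invisible(x)
}

#' Call label of an identification
#'
#' `"species:<id>"`, `"genus_level"` or `"indeterminate"`.
#'
#' @param id A `zooms_id` (or list of them).
#' @return Character vector.
#' @export
id_label <- function(id) {
  if (inherits(id, "zooms_id")) id <- list(id)
  vapply(id, function(x)
    if (x$call == "species") paste0("species:", x$species) else x$call, "")
}

#' Identify one sample from a fitted marker panel
#'
#' `predict` on a [marker_panel()]: accepts a picked-peak table or a raw
#' [maldi_spectrum()] (then preprocessed and peak-picked first), matches the
#' panel and returns the taxonomic call.  An empty panel (no variable
#' peptides among the fitted species) yields an indeterminate call.
#'
#' @param object A [marker_panel()].
#' @param newdata Peak `data.frame` or [maldi_spectrum()].
#' @param pparams [preprocess_params()] used when `newdata` is a spectrum.
#' @param tol,unit,include_lcms_only Passed to [match_markers()].
#' @param min_specific,min_shared_for_genus Passed to [call_species()].
#' @param ... Unused.
#' @return A `zooms_id`.
#' @export
predict.marker_panel <- function(object, newdata,
                                 pparams = preprocess_params(),
                                 tol = object$tol, unit = "Da",
                                 include_lcms_only = FALSE,
                                 min_specific = 1L,
                                 min_shared_for_genus = 2L, ...) {
  sample_id <- ""
  if (inherits(newdata, "maldi_spectrum")) {
    sample_id <- newdata$sample_id
    newdata <- pick_peaks(preprocess_spectrum(newdata, pparams), pparams)
  }
  if (nrow(object$variants) == 0L) {
    return(structure(list(sample_id = sample_id, call = "indeterminate",
                          species = NA_character_,
                          supporting = .empty_variants()[0L, ],
                          conflicts = .empty_variants()[0L, ],
                          n_shared = 0L, score = 0L),
                     class = "zooms_id"))
  }
  mm <- match_markers(newdata, object, tol = tol, unit = unit,
                      include_lcms_only = include_lcms_only)
  call_species(mm, min_specific = min_specific,
               min_shared_for_genus = min_shared_for_genus,
               sample_id = sample_id)
}

#' Identify every spectrum of a cohort
#'
#' @param spectra List of [maldi_spectrum()] objects (or peak tables).
#' @param panel A [marker_panel()].
#' @param pparams [preprocess_params()].
#' @param ... Passed to [predict.marker_panel()].
#' @return Named list of `zooms_id`.
#' @export
identify_cohort <- function(spectra, panel, pparams = preprocess_params(),
                            ...) {
  ids <- lapply(spectra, function(s)
    predict(panel, s, pparams = pparams, ...))
  names(ids) <- vapply(ids, `[[`, "", "sample_id")
  ids
}

#' Cohort composition summary
#'
#' Counts and proportions of taxonomic calls per group (e.g. occupation
#' period).  Ungrouped samples form a single group; proportions sum to one
#' within each group.
#'
#' @param ids List of `zooms_id` objects.
#' @param groups Named character vector mapping sample ids to group labels,
#'   or `NULL` for a single group.
#' @return `data.frame` with columns `group`, `call`, `n`, `proportion`.
#' @export
summarize_cohort <- function(ids, groups = NULL) {
  if (length(ids) == 0L)
    return(data.frame(group = character(), call = character(),
                      n = integer(), proportion = numeric()))
  labels <- id_label(ids)
  sample_ids <- vapply(ids, `[[`, "", "sample_id")
  grp <- if (is.null(groups)) rep("all", length(ids)) else {
    if (!all(sample_ids %in% names(groups)))
      stop("groups must label every sample")
    unname(groups[sample_ids])
  }
  tab <- as.data.frame(table(group = grp, call = labels),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "n"
  tot <- tapply(tab$n, tab$group, sum)
  tab$proportion <- tab$n / as.numeric(tot[tab$group])
  tab <- tab[order(tab$group, -tab$n), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
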