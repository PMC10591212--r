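# Marker discovery, isobaric conflict detection, panel serialisation and
# the bundled grouper reference panel.

test_that("identical profiles give an empty panel; one profile errors", {
  prof <- tiny_profiles(list(list(), list()))
  panel <- discover_markers(prof)
  expect_equal(nrow(panel$markers), 0L)
  expect_equal(nrow(panel$variants), 0L)
  expect_error(discover_markers(prof[1]), ">=2 taxa")
})

test_that("a single planted A->G substitution yields exactly the
           overlapping peptides as markers with a -14.016 mass shift", {
  base <- tiny_profiles(list(list(), list()))
  # find an A at an X/Y position inside a tryptic peptide of sp01
  dp <- tiny_dp()
  peps <- do.call(rbind, lapply(base$sp01$chains, tryptic_peptides,
                                params = dp))
  ch <- base$sp01$chains$COL1a2
  mat <- strsplit(mature_sequence(ch), "")[[1]]
  pos <- which(mat == "A" & seq_along(mat) %% 3 != 1)[1]
  expect_false(is.na(pos))
  prof <- tiny_profiles(list(list(),
                             list(list(chain = "COL1a2", pos = pos,
                                       to = "G"))))
  panel <- discover_markers(prof, dp)
  # oracle: peptides of chain COL1a2 overlapping pos
  overl <- peps[peps$chain == "COL1a2" & peps$start <= pos &
                  peps$start + nchar(peps$sequence) - 1L >= pos, ]
  expect_setequal(unique(panel$markers$marker_id),
                  paste(overl$chain, overl$start, overl$missed_cleavages,
                        sep = ":"))
  # both species' variants present, differing by one residue
  m <- panel$markers[panel$markers$present, ]
  byid <- split(m, m$marker_id)
  for (b in byid) {
    expect_equal(nrow(b), 2L)
    d <- peptide_mh(b$sequence[b$species == "sp02"]) -
         peptide_mh(b$sequence[b$species == "sp01"])
    expect_equal(d, -14.01565, tolerance = 1e-4)
  }
  # two species both carry a unique variant: no single-species flag
  expect_true(all(is.na(panel$markers$species_specific_for)))
})

test_that("a variant unique to one of four species is flagged specific", {
  prof <- tiny_profiles(list(list(),
                             list(list(chain = "COL1a1a", pos = 11,
                                       to = "S")),
                             list(), list()))
  # position 11 must not already be S/G/K/R nor follow K/R
  mat <- strsplit(mature_sequence(prof$sp02$chains$COL1a1a), "")[[1]]
  expect_equal(mat[11], "S")
  panel <- discover_markers(prof, tiny_dp())
  expect_gte(nrow(panel$markers), 1)
  expect_true(all(panel$markers$species_specific_for == "sp02"))
  sp2 <- panel$markers[panel$markers$species == "sp02", ]
  expect_true(all(sp2$specific))
})

test_that("adding a species never rewrites existing species' variants", {
  subs3 <- list(list(),
                list(list(chain = "COL1a2", pos = 14, to = "V")),
                list(list(chain = "COL1a1b", pos = 20, to = "T")))
  subs4 <- c(subs3, list(list(list(chain = "COL1a1a", pos = 26, to = "D"))))
  p3 <- discover_markers(tiny_profiles(subs3), tiny_dp())
  p4 <- discover_markers(tiny_profiles(subs4), tiny_dp())
  m3 <- p3$markers[p3$markers$present, c("marker_id", "species", "sequence")]
  m4 <- p4$markers[p4$markers$present, c("marker_id", "species", "sequence")]
  expect_true(all(p3$markers$marker_id %in% p4$markers$marker_id))
  merged <- merge(m3, m4, by = c("marker_id", "species"))
  expect_equal(merged$sequence.x, merged$sequence.y)
})

test_that("isobaric conflicts are reported across modification states", {
  panel <- grouper_panel()
  con <- isobaric_conflicts(panel)
  pair <- con[con$name1 == "COL1a1 793" & con$name2 == "COL1a1 793" &
                con$sequence1 != con$sequence2, ]
  expect_gte(nrow(pair), 1L)
  expect_true(any(abs(pair$mz_shared - 2178.06) < 0.01))
  # hydroxylation states differ by one between the two forms
  at <- pair[abs(pair$mz_shared - 2178.06) < 0.01, ]
  expect_true(all(abs(at$n_oh1 - at$n_oh2) == 1L))
  # identical sequences in different species are never conflicts
  expect_true(all(con$sequence1 != con$sequence2))
})

test_that("well-separated panels report no conflicts", {
  prof <- tiny_profiles(list(list(),
                             list(list(chain = "COL1a2", pos = 14,
                                       to = "V"))),
                        n_triplets = 12L)
  panel <- discover_markers(prof, tiny_dp(), max_oh = 0)
  if (nrow(panel$variants) >= 2) {
    gaps <- diff(sort(panel$variants$mz))
    # this tiny fixture happens to be well separated; assert and use it
    expect_true(all(gaps[gaps > 0] > 0.2))
    expect_equal(nrow(isobaric_conflicts(panel)), 0L)
  }
})

test_that("JSON export/import round-trips a discovered panel", {
  prof <- tiny_profiles(list(list(),
                             list(list(chain = "COL1a2", pos = 14,
                                       to = "V"))))
  panel <- discover_markers(prof, tiny_dp())
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  export_panel(panel, f)
  back <- import_panel(f)
  expect_equal(back$species, panel$species)
  expect_equal(back$markers, panel$markers)
  expect_equal(back$variants, panel$variants, tolerance = 1e-12)
  expect_equal(back$tol, panel$tol)
})

test_that("TSV import/export round-trips the bundled panel", {
  panel <- grouper_panel()
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  export_panel(panel, f)
  back <- import_panel(f)
  expect_equal(back$markers, panel$markers)
  expect_equal(back$variants, panel$variants, tolerance = 1e-12)
})

test_that("the bundled grouper panel matches its published structure", {
  panel <- grouper_panel()
  expect_length(panel$species, 4L)
  expect_setequal(panel$species, c("E_aeneus", "E_costae", "E_marginatus",
                                   "E_caninus"))
  # 23 printed rows carrying >= 22 biomarker mass entries
  expect_gte(length(unique(panel$markers$marker_id)), 22L)
  # the white-grouper diagnostic peptide carries a two-state mass pair
  m586 <- panel$markers[panel$markers$name == "COL1a1 586" &
                          panel$markers$species == "E_aeneus" &
                          panel$markers$present, ]
  expect_equal(m586$mass_printed, "2855.33/2871.33")
  expect_true(m586$specific)
  expect_equal(unique(panel$markers$species_specific_for[
    panel$markers$marker_id == m586$marker_id]), "E_aeneus")
  # the 1319.6 anomaly is annotated, not forced: computed mass ~1336.61
  anom <- panel$markers[panel$markers$mass_printed == "1319.6" &
                          panel$markers$present, ]
  expect_equal(nrow(anom), 1L)
  expect_equal(anom$species, "E_caninus")
  expect_match(anom$note, "1336.61")
  expect_false(anom$diagnostic)  # demoted: combination use only
  v <- panel$variants[panel$variants$marker_id == anom$marker_id, ]
  expect_equal(min(v$mz), 1336.6101, tolerance = 1e-3)
  # LC-MS/MS-only entries are marked as such
  ev <- panel$markers[panel$markers$footnote == "c", "evidence"]
  expect_true(all(ev == "LCMSMS_only"))
  # transcribed bold flags: 3 specific markers for the goldblotch grouper
  sp_costae <- panel$markers[panel$markers$specific &
                               panel$markers$species == "E_costae", ]
  expect_equal(nrow(sp_costae), 3L)
})

test_that("malformed panel tables fail with a row reference", {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeLines(c("marker_id\tname\tspecies\tpresent\tsequence\tevidence\tspecific",
               "r01\tCOL1a2 5\tspA\tTRUE\t\tMALDI_visible\tFALSE"), f)
  expect_error(import_panel(f), "row 1")
  writeLines("name\tspecies", f)
  expect_error(import_panel(f), "required column")
})
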