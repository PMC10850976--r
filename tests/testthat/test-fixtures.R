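test_that("generation is reproducible and honors the event count", {
  t1 <- simulateGlycoproteomics(n_events = 40, seed = 42)
  t2 <- simulateGlycoproteomics(n_events = 40, seed = 42)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$events), 40L)
  t3 <- simulateGlycoproteomics(n_events = 40, seed = 43)
  expect_false(identical(t1$events, t3$events))
})

test_that("every event's peptide occurs in its protein at the stated start", {
  tr <- simulateGlycoproteomics(n_events = 60, seed = 5)
  ev <- tr$events
  found <- substr(tr$proteins[ev$accession], ev$peptide_start,
                  ev$peptide_start + nchar(ev$peptide) - 1L)
  expect_identical(unname(found), ev$peptide)
  # site residues are as labeled, N sites in genuine sequons
  expect_identical(substr(ev$peptide, ev$site, ev$site), ev$residue)
  nrows <- which(ev$residue == "N")
  expect_true(all(mapply(checkSequon, ev$peptide[nrows], ev$site[nrows])))
})

test_that("worksheet mass rounding obeys the configured mode", {
  for (mode in c("none", "2dp", "integer")) {
    tr <- simulateGlycoproteomics(n_events = 30, rounding = mode, seed = 8)
    d <- abs(tr$events$annotated_mass - tr$events$exact_mass)
    bound <- switch(mode, none = 1e-12, `2dp` = 0.005, integer = 0.5)
    expect_lte(max(d), bound)
    expect_lt(max(d), 1.0)   # valid events stay inside the match tolerance
  }
})

test_that("rendered rows carry one bracket at the event site", {
  tr <- simulateGlycoproteomics(n_events = 10, seed = 3)
  rb <- renderByonicRows(tr)
  ev_rows <- which(rb$row_info$type == "event")
  for (i in ev_rows) {
    p <- parseAnnotatedPeptide(rb$rows$peptide[i])
    e <- tr$events[rb$row_info$event[i], ]
    expect_equal(p$sequence, e$peptide)
    glyc_mod <- p$mods[which.min(abs(p$mods$mass - e$annotated_mass)), ]
    expect_equal(glyc_mod$position, e$site)
    expect_lt(abs(glyc_mod$mass - e$annotated_mass), 0.01)
  }
})

test_that("full pipeline recovers ground truth under every rounding mode", {
  for (mode in c("none", "2dp", "integer")) {
    tr <- simulateGlycoproteomics(n_events = 80, rounding = mode,
                                  dup_rate = 0.3, unglyc_rate = 0.2,
                                  seed = 100 + match(mode, c("none", "2dp",
                                                             "integer")))
    rb <- renderByonicRows(tr)
    gp <- byonicToGlycopeptides(rb$rows)
    truth <- unique(data.frame(key = tr$events$peptide,
                               position = tr$events$site,
                               glycan = tr$events$glycan))
    got <- siteTable(gp)[, c("key", "position", "glycan")]
    o <- function(d) {
      d <- d[order(d$key, d$position, d$glycan), ]
      rownames(d) <- NULL
      d
    }
    expect_identical(o(got), o(truth))
    # dedup: duplicate rows never create extra sites
    expect_equal(nrow(got), nrow(truth))
    # glycoprotein route: protein coordinates offset correctly
    prot <- byonicToGlycoproteins(rb$rows, tr$proteins)
    ptruth <- unique(data.frame(
      key = tr$events$accession,
      position = tr$events$peptide_start + tr$events$site - 1L,
      glycan = tr$events$glycan))
    pgot <- siteTable(prot)[, c("key", "position", "glycan")]
    expect_identical(o(pgot), o(ptruth))
  }
})

test_that("corrupt rows are all rejected with diagnostics in glycoprotein mode", {
  tr <- simulateGlycoproteomics(n_events = 50, corrupt_rate = 0.5, seed = 77)
  rb <- renderByonicRows(tr)
  expect_gt(sum(rb$row_info$type == "corrupt"), 0L)
  prot <- byonicToGlycoproteins(rb$rows, tr$proteins)
  # recovered entries equal ground truth despite the corrupt rows
  ptruth <- unique(data.frame(
    key = tr$events$accession,
    position = tr$events$peptide_start + tr$events$site - 1L,
    glycan = tr$events$glycan))
  pgot <- siteTable(prot)[, c("key", "position", "glycan")]
  o <- function(d) {
    d <- d[order(d$key, d$position, d$glycan), ]
    rownames(d) <- NULL
    d
  }
  expect_identical(o(pgot), o(ptruth))
  # no row silently lost: every non-event row left a diagnostic trail
  n_bad <- sum(rb$row_info$type %in% c("corrupt", "unglycosylated"))
  expect_gte(nrow(diagnostics(prot)), n_bad)
})

test_that("FASTA round trip preserves the synthetic protein database", {
  tr <- simulateGlycoproteomics(n_events = 12, seed = 9)
  fa <- tempfile(fileext = ".fasta")
  writeFastaDB(tr$proteins, fa)
  db <- readSequenceDB(fa)
  expect_identical(db[names(tr$proteins)], tr$proteins)
})
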