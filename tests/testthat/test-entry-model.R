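test_that("rows sharing a key aggregate into one entry, blank lines skipped", {
  x <- readGlycoTSV(c("PEPNK\t4\tHexNAc(2)", "", "PEPNK\t?\tHex(3)"),
                    "glycopeptide")
  expect_equal(length(x), 1L)
  st <- siteTable(x)
  expect_equal(nrow(st), 2L)
  expect_equal(st$position, c(4L, NA))   # unknown sites sort last
  expect_equal(nrow(diagnostics(x)), 0L)
})

test_that("non-contiguous repeats of a key merge; distinct keys separate", {
  x <- readGlycoTSV(c("AAAK\t1\tHex(1)", "CCCK\t1\tHex(1)",
                      "AAAK\t2\tHex(2)"), "glycopeptide")
  expect_equal(length(x), 2L)
  expect_setequal(entryKeys(x), c("AAAK", "CCCK"))
  expect_equal(sum(siteTable(x)$key == "AAAK"), 2L)
})

test_that("entry aggregation is invariant to row order", {
  lines <- randomEntryLines(30, seed = 42)
  a <- readGlycoTSV(lines, "glycopeptide")
  set.seed(1)
  b <- readGlycoTSV(sample(lines), "glycopeptide")
  expect_identical(siteTable(a), siteTable(b))
  expect_identical(canonicalForm(a), canonicalForm(b))
})

test_that("malformed rows are diagnosed, never silently dropped", {
  bad <- c("PEPNK\t9\tHex(1)",          # beyond 5-mer
           "PEPNK\t0\tHex(1)",          # position 0
           "PEPNK\tx\tHex(1)",          # non-integer
           "PEPBK\t1\tHex(1)",          # B not a standard residue
           "PEPNK\t1",                  # wrong column count
           "PEPNK\t1\tHex(1)\tnotanacc",# bad 4th column
           "PEPNK\t1\tHexNAc(2)Methyl(1)")
  x <- readGlycoTSV(bad, "glycopeptide")
  expect_equal(length(x), 0L)
  expect_equal(nrow(diagnostics(x)), length(bad))
  expect_match(diagnostics(x)$message[1], "beyond peptide length")
})

test_that("a malformed row invalidates its whole entry (all-or-nothing)", {
  x <- readGlycoTSV(c("PEPNK\t4\tHexNAc(2)", "PEPNK\t9\tHex(1)",
                      "SASK\t1\tHex(1)"), "glycopeptide")
  expect_equal(entryKeys(x), "SASK")
  dg <- diagnostics(x)
  expect_equal(sum(dg$key == "PEPNK"), 2L)  # offender + discarded sibling
  expect_match(dg$message[2], "invalidated")
})

test_that("third column auto-dispatches composition vs GlyTouCan accession", {
  x <- readGlycoTSV(c("PEPNK\t4\tG00912UN",
                      "PEPNK\t2\tNeuAc(1)HexNAc(4)Hex(7)"), "glycopeptide")
  st <- siteTable(x)
  expect_setequal(st$glycan, c("G00912UN", "HexNAc(4)Hex(7)NeuAc(1)"))
})

test_that("glycopeptide 4th column accumulates source accessions", {
  x <- readGlycoTSV(c("PEPNK\t4\tHexNAc(2)\tP05154",
                      "PEPNK\t2\tHex(3)"), "glycopeptide")
  st <- siteTable(x)
  expect_true("P05154" %in% st$source)
})

test_that("glycoprotein mode validates accession shape and positions", {
  x <- readGlycoTSV(c("P05154\t50\tHexNAc(2)", "NOTANACC\t3\tHex(1)"),
                    "glycoprotein")
  expect_equal(entryKeys(x), "P05154")
  expect_match(diagnostics(x)$message[1], "accession")
  # isoform suffixes rejected: ID stability demands base accessions
  y <- readGlycoTSV("P05154-1\t50\tHexNAc(2)", "glycoprotein")
  expect_equal(length(y), 0L)
})

test_that("glycoprotein validation checks sequence length and membership", {
  db <- readSequenceDB(tinyFasta())
  expect_named(db, c("P05154", "A2VCP3"), ignore.order = TRUE)
  ok <- readGlycoTSV("P05154\t50\tHexNAc(2)", "glycoprotein")
  v <- validateGlycoproteins(ok, db)
  expect_equal(length(v), 1L)
  expect_equal(siteTable(v)$residue, substr(db[["P05154"]], 50, 50))
  far <- readGlycoTSV(sprintf("P05154\t%d\tHexNAc(2)",
                              nchar(db[["P05154"]]) + 1L), "glycoprotein")
  vf <- validateGlycoproteins(far, db)
  expect_equal(length(vf), 0L)
  expect_match(diagnostics(vf)$message, "beyond protein sequence")
  miss <- readGlycoTSV("Q9Z1M0\t5\tHexNAc(2)", "glycoprotein")
  vm <- validateGlycoproteins(miss, db)
  expect_equal(length(vm), 0L)
  expect_match(diagnostics(vm)$message, "not present")
})

test_that("write . parse round trip is exact and canonically ordered", {
  lines <- randomEntryLines(25, seed = 7)
  x <- readGlycoTSV(lines, "glycopeptide")
  out <- writeGlycoTSV(x)
  y <- readGlycoTSV(out, "glycopeptide")
  expect_identical(siteTable(x), siteTable(y))
  expect_identical(writeGlycoTSV(y), out)
  # sites emitted position-ascending within an entry
  z <- readGlycoTSV(c("AAAK\t3\tHex(1)", "AAAK\t1\tHex(2)"), "glycopeptide")
  expect_equal(writeGlycoTSV(z),
               c("AAAK\t1\tHex(2)", "AAAK\t3\tHex(1)"))
  expect_length(writeGlycoTSV(readGlycoTSV(character(0), "glycopeptide")), 0L)
})
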