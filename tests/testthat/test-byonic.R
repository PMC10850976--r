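test_that("annotated peptides parse to bare sequence plus positioned mods", {
  p <- parseAnnotatedPeptide("R.DILTILAN[+2237.78]TTLQITCR.S")
  expect_equal(p$sequence, "DILTILANTTLQITCR")
  expect_equal(p$mods, data.frame(position = 8L, mass = 2237.78))
  expect_equal(parseAnnotatedPeptide("PEPTIDE"),
               list(sequence = "PEPTIDE",
                    mods = data.frame(position = integer(0),
                                      mass = numeric(0))))
  p2 <- parseAnnotatedPeptide("K.S[+79.97]AS[+203.08]K.L")
  expect_equal(p2$sequence, "SASK")
  expect_equal(p2$mods$position, c(1L, 3L))
  expect_equal(p2$mods$mass, c(79.97, 203.08))
  # "-" flanks at protein termini
  expect_equal(parseAnnotatedPeptide("-.MKT[+203.08]K.R")$sequence, "MKTK")
  expect_error(parseAnnotatedPeptide("K.PEP[+12.3TIDE.R"), "bracket")
  expect_error(parseAnnotatedPeptide("K.[+12.3]PEP.R"), "before any residue")
})

test_that("glycan-site matching follows the mass-tolerance rule", {
  expect_equal(matchGlycanSite(data.frame(position = 8, mass = 2237.78),
                               "HexNAc(4)Hex(7)NeuAc(1)"), 8L,
               ignore_attr = TRUE)
  # far-off mass: no match, reason reported
  res <- matchGlycanSite(data.frame(position = 1, mass = 79.97), "HexNAc(2)")
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "no modification within")
  # integer-rounded worksheet masses still match under the 1.0 Da default
  expect_equal(matchGlycanSite(data.frame(position = 3, mass = 892),
                               "HexNAc(2)Hex(3)"), 3L, ignore_attr = TRUE)
  expect_lt(abs(compositionMass("HexNAc(2)Hex(3)") - 892.3172), 1e-3)
  # several qualifying mods: smallest |delta| wins, then smallest position
  mods <- data.frame(position = c(2, 9), mass = c(892.0, 892.3))
  expect_equal(matchGlycanSite(mods, "HexNAc(2)Hex(3)"), 9L,
               ignore_attr = TRUE)
  tie <- data.frame(position = c(5, 2), mass = c(892.3, 892.3))
  m <- matchGlycanSite(tie, "HexNAc(2)Hex(3)")
  expect_equal(m, 2L, ignore_attr = TRUE)
  expect_true(attr(m, "ambiguous"))
  expect_error(matchGlycanSite(mods, "HexNAc(2)Hex(3)", tolerance = 0))
})

test_that("UniProt accessions are extracted from protein-name fields", {
  expect_equal(
    extractAccession("sp|P05154|IPSP_HUMAN Plasma serine protease inhibitor"),
    "P05154")
  expect_equal(extractAccession(">tr|A2VCP3|A2VCP3_MOUSE"), "A2VCP3")
  expect_equal(extractAccession("Mouse P2X purinoceptor Q9Z1M0"), "Q9Z1M0")
  expect_true(is.na(extractAccession("some protein without id")))
})

test_that("worksheet rows convert to deduplicated glycopeptide entries", {
  rows <- data.frame(
    peptide = c("R.DILTILAN[+2237.78]TTLQITCR.S",
                "R.DILTILAN[+2237.78]TTLQITCR.S",   # exact duplicate
                "K.S[+203.08]ASK.L",
                "K.PEPTIDEK.R"),                    # no glycan info
    glycan = c("HexNAc(4)Hex(7)NeuAc(1)", "HexNAc(4)Hex(7)NeuAc(1)",
               "HexNAc(1)", ""),
    protein = c("sp|P35918|VGFR2_MOUSE", "sp|P35918|VGFR2_MOUSE", "", ""),
    stringsAsFactors = FALSE)
  x <- byonicToGlycopeptides(rows)
  expect_equal(length(x), 2L)
  st <- siteTable(x)
  expect_equal(nrow(st), 2L)   # duplicate removed
  expect_equal(st$source[st$key == "DILTILANTTLQITCR"], "P35918")
  expect_equal(nrow(diagnostics(x)), 1L)
  expect_match(diagnostics(x)$message, "no glycosylation")
  # accounting: every input row is converted or diagnosed
  converted_rows <- 3L  # rows 1-3 yielded sites (row 2 deduplicated later)
  expect_equal(converted_rows + nrow(diagnostics(x)), nrow(rows))
})

test_that("unmatched and malformed worksheet rows drop with diagnostics", {
  rows <- data.frame(
    peptide = c("K.S[+79.97]ASK.L",      # phospho mass, not the glycan
                "K.AAAK.R",              # glycan but no modification
                "K.S[+203.08]ASK.L"),
    glycan = c("HexNAc(2)", "HexNAc(1)", "HexNAc(2)Methyl(1)"),
    stringsAsFactors = FALSE)
  x <- byonicToGlycopeptides(rows)
  expect_equal(length(x), 0L)
  expect_equal(nrow(diagnostics(x)), 3L)
  expect_match(diagnostics(x)$message[1], "no modification within")
  expect_match(diagnostics(x)$message[2], "no modifications on peptide")
  expect_match(diagnostics(x)$message[3], "Methyl")
})

test_that("comma-separated glycan cells are matched as independent candidates", {
  rows <- data.frame(
    peptide = "K.S[+203.08]AN[+1216.42]K.L",
    glycan = "HexNAc(1), HexNAc(2)Hex(5)",
    stringsAsFactors = FALSE)
  x <- byonicToGlycopeptides(rows)
  st <- siteTable(x)
  expect_equal(nrow(st), 2L)
  expect_equal(st$position[st$glycan == "HexNAc(1)"], 1L)
  expect_equal(st$position[st$glycan == "HexNAc(2)Hex(5)"], 3L)
})

test_that("glycoprotein conversion maps peptide sites onto the protein", {
  db <- c(X00001 = paste0("MAAAAAAAA", "SASK", "GGGG"))  # SASK starts at 10
  rows <- data.frame(peptide = "A.S[+79.97]AS[+203.08]K.G",
                     glycan = "HexNAc(1)", start = 10L,
                     protein = "sp|X00001|SYN", stringsAsFactors = FALSE)
  # X00001 is not a real accession shape; use a valid one
  names(db) <- "P12345"
  rows$protein <- "sp|P12345|SYN"
  x <- byonicToGlycoproteins(rows, db)
  st <- siteTable(x)
  expect_equal(st$key, "P12345")
  expect_equal(st$position, 12L)          # 10 + 3 - 1
  expect_equal(st$residue, "S")
  # stated start that contradicts the database sequence rejects the row
  bad <- rows; bad$start <- 11L
  y <- byonicToGlycoproteins(bad, db)
  expect_equal(length(y), 0L)
  expect_match(paste(diagnostics(y)$message, collapse = " "),
               "sequence inconsistency")
  # accession absent from the database
  rows2 <- rows; rows2$protein <- "sp|P99999|OTHER"
  z <- byonicToGlycoproteins(rows2, db)
  expect_equal(length(z), 0L)
  expect_match(paste(diagnostics(z)$message, collapse = " "), "absent")
})

test_that("a synthetic VEGFR2-like fixture recovers the N-linked site", {
  # place DILTILANTTLQITCR at a known offset in a synthetic P35918-like record
  offset <- 31L
  seqs <- paste0(paste(rep("G", offset - 1L), collapse = ""),
                 "DILTILANTTLQITCR", "KRR")
  db <- c(P35918 = seqs)
  rows <- data.frame(peptide = "R.DILTILAN[+2238]TTLQITCR.K",
                     glycan = "HexNAc(4)Hex(7)NeuAc(1)", start = offset,
                     protein = "sp|P35918|VGFR2_MOUSE synthetic",
                     stringsAsFactors = FALSE)
  x <- byonicToGlycoproteins(rows, db)
  st <- siteTable(x)
  expect_equal(st$position, offset + 7L)
  expect_equal(st$residue, "N")
  expect_equal(unname(classifyEntries(x)), "N_ONLY")
})
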