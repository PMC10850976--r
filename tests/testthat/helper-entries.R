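# Shared fixture builders. Everything is generated in code at test time.

GLYCAN_POOL <- c("HexNAc(2)", "HexNAc(2)Hex(5)", "HexNAc(1)Hex(1)NeuAc(1)",
                 "Hex(3)", "HexNAc(4)Hex(7)NeuAc(1)", "G00912UN",
                 "HexNAc(2)Hex(3)Fuc(1)")

# Random glycopeptide rows in long form; returns TSV lines. Peptides are
# random 8..14-mers, each entry carries 1..3 sites (possibly unknown).
randomEntryLines <- function(n_entries, seed, unknown_rate = 0.1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(8:14, n_entries, replace = TRUE)
  peps <- vapply(lens, function(l)
    paste(sample(aa, l, replace = TRUE), collapse = ""), character(1))
  n_sites <- sample(1:3, n_entries, replace = TRUE)
  key <- rep(peps, n_sites)
  len <- rep(lens, n_sites)
  pos <- as.character((sample.int(1000L, length(key), replace = TRUE) %% len) + 1L)
  pos[stats::runif(length(key)) < unknown_rate] <- "?"
  g <- sample(GLYCAN_POOL, length(key), replace = TRUE)
  paste(key, pos, g, sep = "\t")
}

# A tiny two-protein FASTA database written to a temp file.
tinyFasta <- function() {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(
    ">sp|P05154|IPSP_HUMAN Plasma serine protease inhibitor",
    paste(rep("MKLSTAILQRWD", 9), collapse = ""),
    ">tr|A2VCP3|A2VCP3_MOUSE",
    "MSASKDILTILANTTLQITCRWYHG"), fa)
  fa
}
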