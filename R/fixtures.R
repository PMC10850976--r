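## Glycan pools for synthetic events. All masses are derived from the
## composition tables at render time, never hard-coded.
.N_GLYCAN_POOL <- paste0("HexNAc(2)Hex(", 5:9, ")")
.O_GLYCAN_POOL <- c("HexNAc(1)", "HexNAc(1)Hex(1)", "HexNAc(2)Hex(1)",
                    "HexNAc(1)Hex(1)NeuAc(1)", "HexNAc(1)Hex(1)NeuAc(2)",
                    "HexNAc(2)Hex(1)NeuAc(1)")
.CMAN_GLYCAN <- "Hex(1)"

.randomPeptide <- function(len, site, residue) {
  p <- sample(setdiff(.AA20, c("N", "S", "T", "W")), len, replace = TRUE)
  p[site] <- residue
  if (residue == "N") {
    ## guarantee an N-X-S/T sequon (X != P) so synthetic N sites look real
    p[site + 1L] <- sample(setdiff(.AA20, c("P", "N", "S", "T", "W")), 1L)
    p[site + 2L] <- sample(c("S", "T"), 1L)
  }
  paste(p, collapse = "")
}

#' Generate a seeded synthetic glycoproteomics ground truth
#'
#' Builds an artificial protein database and a set of glycosylation
#' events (protein, peptide, start, site, residue, glycan) with exact and
#' worksheet-annotated glycan masses, emulating what a Byonic-style
#' summary worksheet reports. Each peptide is embedded verbatim in its
#' protein at its stated start, in its own non-overlapping slot; N-linked
#' sites are placed in genuine N-X-S/T sequons. Everything is reproducible
#' from the seed.
#'
#' @param n_events Number of glycosylation events.
#' @param residue_props Named numeric proportions for site residues over
#'   \code{N}, \code{S}, \code{T}, \code{W}, \code{other}.
#' @param rounding Worksheet mass-rounding mode: \code{"none"},
#'   \code{"2dp"} (two decimals) or \code{"integer"} (some worksheets
#'   print glycan masses as integers).
#' @param dup_rate Expected extra duplicate rows per event row.
#' @param unglyc_rate Expected unglycosylated (empty-glycan) rows per
#'   event row.
#' @param corrupt_rate Expected corrupt rows per event row.
#' @param corruption_ops Corruption operators to cycle through:
#'   \code{"shifted_start"}, \code{"peptide_mismatch"},
#'   \code{"unknown_glycan"}, \code{"bad_mass"}.
#' @param seed Integer seed.
#' @return List of class \code{glyco_truth}: \code{proteins} (named
#'   sequences), \code{events} (data.frame), and the noise configuration.
#' @export
#' @examples
#' tr <- simulateGlycoproteomics(n_events = 5, seed = 1)
#' tr$events[, c("accession", "peptide", "site", "residue", "glycan")]
simulateGlycoproteomics <- function(n_events = 100,
                                    residue_props = c(N = 0.45, S = 0.2,
                                                      T = 0.15, W = 0.05,
                                                      other = 0.15),
                                    rounding = c("none", "2dp", "integer"),
                                    dup_rate = 0, unglyc_rate = 0,
                                    corrupt_rate = 0,
                                    corruption_ops = c("shifted_start",
                                                       "peptide_mismatch",
                                                       "unknown_glycan",
                                                       "bad_mass"),
                                    seed = 1L) {
  rounding <- match.arg(rounding)
  stopifnot(n_events >= 1, all(residue_props >= 0), sum(residue_props) > 0)
  set.seed(seed)
  slots_per_protein <- 8L
  slot_width <- 30L
  n_proteins <- ceiling(n_events / slots_per_protein)
  prot_len <- slots_per_protein * slot_width + 10L
  accs <- sprintf("P%05d", seq_len(n_proteins) + 10000L)
  proteins <- vapply(accs, function(a)
    paste(sample(.AA20, prot_len, replace = TRUE), collapse = ""),
    character(1))
  residue_props <- residue_props / sum(residue_props)
  res_kind <- sample(names(residue_props), n_events, replace = TRUE,
                     prob = residue_props)
  ev <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    prot_i <- ((i - 1L) %/% slots_per_protein) + 1L
    slot <- ((i - 1L) %% slots_per_protein)
    start <- slot * slot_width + 4L
    len <- sample(10:18, 1L)
    kind <- res_kind[i]
    residue <- switch(kind, N = "N", S = "S", T = "T", W = "W",
                      other = sample(c("A", "R", "Y", "G", "V"), 1L))
    site <- sample(2:(len - 3L), 1L)
    pep <- .randomPeptide(len, site, residue)
    glycan <- switch(kind,
                     N = sample(.N_GLYCAN_POOL, 1L),
                     S = , T = sample(.O_GLYCAN_POOL, 1L),
                     W = .CMAN_GLYCAN,
                     other = sample(.O_GLYCAN_POOL, 1L))
    seqs <- proteins[[prot_i]]
    substr(seqs, start, start + len - 1L) <- pep
    proteins[[prot_i]] <- seqs
    exact <- compositionMass(glycan)
    annotated <- switch(rounding, none = exact, `2dp` = round(exact, 2),
                        integer = round(exact))
    ev[[i]] <- data.frame(accession = accs[prot_i], peptide = pep,
                          peptide_start = start, site = site,
                          residue = residue, glycan = glycan,
                          exact_mass = exact, annotated_mass = annotated,
                          stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev)
  ## random peptides can collide with truth semantics only if the same
  ## (peptide, site, glycan) tuple repeats; regenerate would be overkill —
  ## at >= 10-mer random peptides this never occurs in practice, assert it
  stopifnot(!anyDuplicated(paste(events$peptide, events$site, events$glycan)))
  structure(list(proteins = proteins, events = events, rounding = rounding,
                 dup_rate = dup_rate, unglyc_rate = unglyc_rate,
                 corrupt_rate = corrupt_rate, corruption_ops = corruption_ops,
                 seed = seed),
            class = "glyco_truth")
}

.formatMass <- function(mass, rounding) {
  switch(rounding,
         none = sprintf("%+.4f", mass),
         `2dp` = sprintf("%+.2f", mass),
         integer = sprintf("%+d", as.integer(round(mass))))
}

.annotatePeptide <- function(truth, event, mass_text) {
  prot <- truth$proteins[[event$accession]]
  s <- event$peptide_start; len <- nchar(event$peptide)
  flank_n <- if (s > 1L) substr(prot, s - 1L, s - 1L) else "-"
  flank_c <- if (s + len <= nchar(prot)) substr(prot, s + len, s + len) else "-"
  chars <- strsplit(event$peptide, "")[[1]]
  chars[event$site] <- paste0(chars[event$site], "[", mass_text, "]")
  paste0(flank_n, ".", paste(chars, collapse = ""), ".", flank_c)
}

#' Render a synthetic truth as Byonic-like worksheet rows
#'
#' The inverse of the worksheet converter: produces a row table with
#' annotated peptides (flanking residues, bracketed modification masses),
#' glycan composition strings, start positions and
#' \code{"sp|ACC|NAME"}-style protein names, plus the protein database as
#' a FASTA-ready named vector. Duplicate, unglycosylated and corrupt rows
#' are injected at the truth's configured rates and indexed in
#' \code{row_info}, so tests can verify that the converter keeps exactly
#' the valid rows. About a third of event rows also carry an unrelated
#' +15.9949 oxidation bracket, which must never win the glycan-mass match.
#'
#' @param truth A \code{glyco_truth} from
#'   \code{\link{simulateGlycoproteomics}}.
#' @return List: \code{rows} (data.frame \code{peptide}, \code{glycan},
#'   \code{modtype}, \code{start}, \code{protein}), \code{proteins},
#'   \code{row_info} (data.frame \code{type}, \code{event},
#'   \code{corruption} aligned with \code{rows}).
#' @export
renderByonicRows <- function(truth) {
  stopifnot(inherits(truth, "glyco_truth"))
  set.seed(truth$seed + 1L)
  ev <- truth$events
  rows <- list(); info <- list()
  add <- function(peptide, glycan, start, acc, type, event = NA_integer_,
                  corruption = NA_character_, modtype = "Glycan") {
    rows[[length(rows) + 1L]] <<- data.frame(
      peptide = peptide, glycan = glycan, modtype = modtype,
      start = start, protein = paste0("sp|", acc, "|SYN_", acc),
      stringsAsFactors = FALSE)
    info[[length(info) + 1L]] <<- data.frame(
      type = type, event = event, corruption = corruption,
      stringsAsFactors = FALSE)
  }
  oxid <- stats::runif(nrow(ev)) < 1 / 3
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    ann <- .annotatePeptide(truth, e, .formatMass(e$annotated_mass,
                                                  truth$rounding))
    if (oxid[i]) {
      ## bolt an oxidation bracket onto a residue other than the site
      chars <- strsplit(sub("^..", "", sub("..$", "", ann)), "")[[1]]
      pos <- setdiff(seq_len(nchar(e$peptide)), e$site)[1]
      bare <- strsplit(e$peptide, "")[[1]]
      bare[e$site] <- paste0(bare[e$site], "[",
                             .formatMass(e$annotated_mass, truth$rounding), "]")
      bare[pos] <- paste0(bare[pos], "[+15.9949]")
      ann <- paste0(substr(ann, 1, 2), paste(bare, collapse = ""),
                    substring(ann, nchar(ann) - 1L))
    }
    add(ann, e$glycan, e$peptide_start, e$accession, "event", i)
    n_dup <- stats::rpois(1L, truth$dup_rate)
    for (d in seq_len(n_dup))
      add(ann, e$glycan, e$peptide_start, e$accession, "duplicate", i)
    n_un <- stats::rpois(1L, truth$unglyc_rate)
    for (d in seq_len(n_un)) {
      plain <- paste0(substr(ann, 1, 2), e$peptide, substring(ann, nchar(ann) - 1L))
      add(plain, "", e$peptide_start, e$accession, "unglycosylated", i,
          modtype = "")
    }
    n_cor <- stats::rpois(1L, truth$corrupt_rate)
    for (d in seq_len(n_cor)) {
      op <- truth$corruption_ops[(length(rows) %% length(truth$corruption_ops)) + 1L]
      if (op == "shifted_start") {
        add(ann, e$glycan, e$peptide_start + 3L, e$accession, "corrupt", i, op)
      } else if (op == "peptide_mismatch") {
        bad <- e
        ch <- strsplit(bad$peptide, "")[[1]]
        j <- if (e$site == 1L) nchar(bad$peptide) else 1L
        ch[j] <- setdiff(.AA20, ch[j])[1]
        bad$peptide <- paste(ch, collapse = "")
        ann_bad <- .annotatePeptide(truth, bad, .formatMass(bad$annotated_mass,
                                                            truth$rounding))
        add(ann_bad, bad$glycan, bad$peptide_start, bad$accession, "corrupt",
            i, op)
      } else if (op == "unknown_glycan") {
        add(ann, "HexNAc(2)Methyl(1)", e$peptide_start, e$accession,
            "corrupt", i, op)
      } else {  # bad_mass: annotation 5 Da off any glycan in the row
        bad_ann <- .annotatePeptide(truth, e,
                                    .formatMass(e$annotated_mass + 5,
                                                truth$rounding))
        add(bad_ann, e$glycan, e$peptide_start, e$accession, "corrupt", i, op)
      }
    }
  }
  rows <- do.call(rbind, rows)
  info <- do.call(rbind, info)
  perm <- sample.int(nrow(rows))
  list(rows = rows[perm, , drop = FALSE],
       proteins = truth$proteins,
       row_info = info[perm, , drop = FALSE])
}

#' Write a protein database as FASTA
#'
#' @param proteins Named character vector (accession to sequence).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeFastaDB <- function(proteins, file) {
  aa <- Biostrings::AAStringSet(proteins)
  names(aa) <- paste0("sp|", names(proteins), "|SYN_", names(proteins))
  Biostrings::writeXStringSet(aa, file)
  invisible(file)
}
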