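#' Parse a Byonic-annotated peptide string
#'
#' Byonic summary worksheets print peptides with single flanking residues
#' (\code{"R.DILTILAN[+2237.78]TTLQITCR.S"}, \code{"-"} at protein
#' termini) and per-residue modification masses in square brackets
#' attached to the preceding residue. Flanks are stripped and bracket
#' positions are converted to 1-based coordinates in the bare sequence.
#'
#' @param text Annotated peptide string.
#' @return List with \code{sequence} (bare peptide) and \code{mods}
#'   (data.frame of \code{position}, \code{mass}, in bracket order).
#' @export
#' @examples
#' parseAnnotatedPeptide("R.DILTILAN[+2237.78]TTLQITCR.S")
parseAnnotatedPeptide <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  s <- trimws(text)
  ## strip "X." prefix / ".X" suffix where X is one residue or "-"
  s <- sub("^[A-Z-]\\.", "", s)
  s <- sub("\\.[A-Z-]$", "", s)
  if (grepl("\\[[^]]*$", s) || grepl("^[^[]*\\]", s))
    stop("unbalanced brackets in annotated peptide: ", text)
  seq_chars <- character(0)
  mods_pos <- integer(0); mods_mass <- numeric(0)
  rest <- s
  while (nzchar(rest)) {
    ch <- substr(rest, 1L, 1L)
    if (ch == "[") {
      close <- regexpr("]", rest, fixed = TRUE)
      if (close == -1L) stop("unbalanced brackets in annotated peptide: ", text)
      inner <- substr(rest, 2L, close - 1L)
      if (!grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", inner))
        stop("malformed modification mass '", inner, "' in: ", text)
      if (!length(seq_chars))
        stop("modification bracket before any residue in: ", text)
      mods_pos <- c(mods_pos, length(seq_chars))
      mods_mass <- c(mods_mass, as.numeric(inner))
      rest <- substring(rest, close + 1L)
    } else {
      if (!ch %in% .AA20)
        stop("invalid residue letter '", ch, "' in annotated peptide: ", text)
      seq_chars <- c(seq_chars, ch)
      rest <- substring(rest, 2L)
    }
  }
  list(sequence = paste(seq_chars, collapse = ""),
       mods = data.frame(position = mods_pos, mass = mods_mass))
}

#' Match a glycan composition to a modified residue by mass
#'
#' Finds the annotated modification whose mass lies within \code{tolerance}
#' Da of the glycan's monoisotopic residue-mass sum. The default tolerance
#' of 1.0 Da accommodates worksheets that print glycan masses rounded to
#' integers. When several modifications qualify, the smallest absolute
#' mass difference wins, ties broken by the smallest position (the row is
#' flagged ambiguous via attribute).
#'
#' @param mods data.frame of \code{position}, \code{mass} (from
#'   \code{\link{parseAnnotatedPeptide}}).
#' @param glycan A composition (string or parsed counts).
#' @param tolerance Mass tolerance in Da, must be positive (default 1.0).
#' @return Matched 1-based position (integer), with attribute
#'   \code{"ambiguous"} = TRUE when more than one modification qualified;
#'   \code{NA} with attribute \code{"reason"} when nothing matched.
#' @export
#' @examples
#' mods <- data.frame(position = 8, mass = 2237.78)
#' matchGlycanSite(mods, "HexNAc(4)Hex(7)NeuAc(1)")
matchGlycanSite <- function(mods, glycan, tolerance = 1.0) {
  stopifnot(is.numeric(tolerance), tolerance > 0)
  if (is.null(mods) || nrow(mods) == 0L) {
    out <- NA_integer_; attr(out, "reason") <- "no modifications on peptide"
    return(out)
  }
  target <- compositionMass(glycan)
  delta <- abs(mods$mass - target)
  ok <- delta < tolerance
  if (!any(ok)) {
    out <- NA_integer_
    attr(out, "reason") <- sprintf(
      "no modification within %g Da of glycan mass %.4f (closest |delta| %.4f)",
      tolerance, target, min(delta))
    return(out)
  }
  cand <- which(ok)
  cand <- cand[order(delta[cand], mods$position[cand])]
  out <- as.integer(mods$position[cand[1]])
  if (length(cand) > 1L) attr(out, "ambiguous") <- TRUE
  out
}

#' Extract a UniProt accession from a protein-name field
#'
#' Handles \code{"sp|P05154|IPSP_HUMAN ..."}-style headers by preferring
#' the token between pipes; otherwise the first substring matching the
#' UniProt accession pattern anywhere in the text is used.
#'
#' @param protein_name Character vector of protein-name strings.
#' @return Character vector of accessions; \code{NA} where none was found.
#' @export
#' @examples
#' extractAccession("sp|P05154|IPSP_HUMAN Plasma serine protease inhibitor")
extractAccession <- function(protein_name) {
  vapply(protein_name, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    if (grepl("|", s, fixed = TRUE)) {
      toks <- unlist(strsplit(s, "[| ]"))
      hit <- toks[.validAccession(toks)]
      if (length(hit)) return(hit[1])
    }
    m <- regmatches(s, regexpr(.UNIPROT_RE, s))
    if (length(m)) m[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read a pre-extracted Byonic summary worksheet
#'
#' Consumes a TSV/CSV export of a PMI-Byonic-style summary worksheet and
#' maps its columns onto the fields the converter needs. The mapping is
#' supplied explicitly (by header name), mirroring the
#' specify-the-columns step of worksheet ingestion.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param columns Named character vector mapping the converter fields
#'   \code{peptide}, \code{glycan}, \code{modtype} and (for glycoprotein
#'   extraction) \code{start}, \code{protein} to header names in the file.
#' @param sep Field separator; inferred from the file extension by default.
#' @return data.frame with columns \code{peptide}, \code{glycan},
#'   \code{modtype}, \code{start}, \code{protein}.
#' @export
readByonicTable <- function(path, columns, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  need <- c("peptide", "glycan")
  if (!all(need %in% names(columns)))
    stop("column mapping must name at least: ", paste(need, collapse = ", "))
  miss <- setdiff(unname(columns), colnames(raw))
  if (length(miss))
    stop("mapped column(s) absent from worksheet: ",
         paste(miss, collapse = ", "))
  get <- function(field, default = NA) {
    if (field %in% names(columns)) raw[[columns[[field]]]]
    else rep(default, nrow(raw))
  }
  data.frame(peptide = as.character(get("peptide")),
             glycan = as.character(get("glycan", "")),
             modtype = as.character(get("modtype", "")),
             start = suppressWarnings(as.integer(get("start"))),
             protein = as.character(get("protein", "")),
             stringsAsFactors = FALSE)
}

## Shared row-scan: returns per-row parse results and drop diagnostics.
.scanByonicRows <- function(rows, tolerance) {
  stopifnot(is.data.frame(rows), all(c("peptide", "glycan") %in% colnames(rows)))
  out <- vector("list", nrow(rows))
  diag <- list()
  note <- function(i, why) diag[[length(diag) + 1L]] <<-
    data.frame(line = i, key = NA_character_, message = why)
  for (i in seq_len(nrow(rows))) {
    gtxt <- rows$glycan[i]
    if (is.na(gtxt) || !nzchar(trimws(gtxt))) {
      note(i, "row has no glycosylation information"); next
    }
    pp <- tryCatch(parseAnnotatedPeptide(rows$peptide[i]), error = identity)
    if (inherits(pp, "error")) {
      note(i, paste0("unparseable peptide: ", conditionMessage(pp))); next
    }
    ## comma-separated cells hold multiple candidate glycans, matched
    ## independently; unmatched candidates are logged, not fatal
    cands <- trimws(strsplit(gtxt, ",", fixed = TRUE)[[1]])
    cands <- cands[nzchar(cands)]
    sites <- list()
    for (g in cands) {
      cg <- tryCatch(canonicalGlycanString(g), error = identity)
      if (inherits(cg, "error")) {
        note(i, paste0("glycan rejected: ", conditionMessage(cg))); next
      }
      if (isGlyTouCanAccession(cg)) {
        note(i, paste0("accession-notated glycan '", cg,
                       "' has no mass; cannot be site-matched")); next
      }
      pos <- matchGlycanSite(pp$mods, cg, tolerance)
      if (is.na(pos)) {
        note(i, paste0("glycan '", cg, "': ", attr(pos, "reason"))); next
      }
      if (isTRUE(attr(pos, "ambiguous")))
        note(i, paste0("glycan '", cg, "': multiple modifications within ",
                       "tolerance; smallest mass difference used"))
      sites[[length(sites) + 1L]] <- list(position = as.integer(pos),
                                          glycan = cg)
    }
    if (!length(sites)) next   # all candidates already logged
    out[[i]] <- list(sequence = pp$sequence, sites = sites)
  }
  diag <- if (length(diag)) do.call(rbind, diag) else
    data.frame(line = integer(0), key = character(0), message = character(0))
  list(parsed = out, diag = diag)
}

#' Convert Byonic worksheet rows to glycopeptide entries
#'
#' Implements the worksheet-to-entry extraction: each PSM row's bracketed
#' modification masses are compared with the monoisotopic mass of the
#' glycan composition in its glycan column, and the modification within
#' \code{tolerance} (default 1.0 Da, accommodating integer-rounded
#' worksheet masses) determines the glycosylated residue. Rows without
#' glycosylation information and rows whose glycan matches no modification
#' are dropped with a diagnostic; exact duplicate (peptide, site, glycan)
#' results are deduplicated; rows for the same peptide aggregate into one
#' entry. A UniProt accession extracted from the protein-name column, when
#' present, is attached as source metadata (it never enters entry
#' identity).
#'
#' @param rows data.frame with columns \code{peptide} (annotated peptide),
#'   \code{glycan} (composition string, possibly comma-separated
#'   candidates, possibly empty), and optionally \code{modtype},
#'   \code{start}, \code{protein}.
#' @param tolerance Mass tolerance in Da (default 1.0).
#' @return A glycopeptide \code{\linkS4class{GlycoconjugateSet}} with
#'   per-row drop diagnostics in \code{diagnostics()}.
#' @export
byonicToGlycopeptides <- function(rows, tolerance = 1.0) {
  sc <- .scanByonicRows(rows, tolerance)
  key <- character(0); position <- integer(0); glycan <- character(0)
  source <- character(0)
  has_protein <- "protein" %in% colnames(rows)
  for (i in seq_along(sc$parsed)) {
    p <- sc$parsed[[i]]
    if (is.null(p)) next
    src <- if (has_protein) extractAccession(rows$protein[i]) else NA_character_
    for (s in p$sites) {
      key <- c(key, p$sequence)
      position <- c(position, s$position)
      glycan <- c(glycan, s$glycan)
      source <- c(source, src)
    }
  }
  ## a peptide seen with and without a source keeps the known source
  if (length(key)) {
    tup <- paste(key, position, glycan, sep = "\r")
    src_by_tup <- tapply(source, tup, function(a) {
      a <- a[!is.na(a)]; if (length(a)) a[1] else NA_character_
    })
    keep <- !duplicated(tup)
    key <- key[keep]; position <- position[keep]; glycan <- glycan[keep]
    source <- unname(src_by_tup[tup[keep]])
  }
  GlycoconjugateSet("glycopeptide", key = key, position = position,
                    glycan = glycan, source = source,
                    metadata = list(diagnostics = sc$diag,
                                    n_input_rows = nrow(rows)))
}

#' Convert Byonic worksheet rows to glycoprotein entries
#'
#' In addition to the glycopeptide extraction, each row needs the
#' peptide's start position in the protein and a protein-name field
#' containing a UniProt accession. The protein site is
#' \code{start + peptide_site - 1}. The bare peptide is required to occur
#' verbatim in the database sequence at the stated start — rows failing
#' this consistency check are rejected with a diagnostic, as are rows
#' whose accession cannot be extracted or is absent from \code{db}.
#'
#' @inheritParams byonicToGlycopeptides
#' @param db Named sequence vector from \code{\link{readSequenceDB}}.
#' @return A glycoprotein \code{GlycoconjugateSet} (with \code{residue}
#'   recorded per site) and per-row diagnostics.
#' @export
byonicToGlycoproteins <- function(rows, db, tolerance = 1.0) {
  stopifnot(all(c("start", "protein") %in% colnames(rows)))
  sc <- .scanByonicRows(rows, tolerance)
  diag <- sc$diag
  note <- function(i, why) diag[nrow(diag) + 1L, ] <<-
    list(i, NA_character_, why)
  key <- character(0); position <- integer(0); glycan <- character(0)
  for (i in seq_along(sc$parsed)) {
    p <- sc$parsed[[i]]
    if (is.null(p)) next
    acc <- extractAccession(rows$protein[i])
    if (is.na(acc)) {
      note(i, "no UniProt accession found in protein-name field"); next
    }
    if (!acc %in% names(db)) {
      note(i, paste0("accession ", acc, " absent from sequence database"))
      next
    }
    start <- rows$start[i]
    if (is.na(start) || start < 1L) {
      note(i, "missing or invalid peptide start position"); next
    }
    ref <- substr(db[[acc]], start, start + nchar(p$sequence) - 1L)
    if (!identical(ref, p$sequence)) {
      note(i, paste0("peptide does not match ", acc, " at stated start ",
                     start, " (sequence inconsistency)"))
      next
    }
    for (s in p$sites) {
      key <- c(key, acc)
      position <- c(position, start + s$position - 1L)
      glycan <- c(glycan, s$glycan)
    }
  }
  out <- GlycoconjugateSet("glycoprotein", key = key, position = position,
                           glycan = glycan,
                           metadata = list(diagnostics = diag,
                                           n_input_rows = nrow(rows)))
  validateGlycoproteins(out, db)
}
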