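#' Read a protein sequence database from FASTA
#'
#' Loads a local FASTA file into an accession-keyed sequence database.
#' UniProt-style headers (\code{>sp|P05154|IPSP_HUMAN ...}) expose the
#' accession as the token between pipes; otherwise the first whitespace-
#' delimited header word is used.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A named character vector, accession to uppercase sequence.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P05154|IPSP_HUMAN test", "MKLS"), fa)
#' readSequenceDB(fa)
readSequenceDB <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  acc <- vapply(hdr, function(h) {
    w <- strsplit(h, "[[:space:]]+")[[1]][1]
    if (grepl("|", w, fixed = TRUE)) {
      toks <- strsplit(w, "|", fixed = TRUE)[[1]]
      hit <- toks[.validAccession(toks)]
      if (length(hit)) return(hit[1])
      if (length(toks) >= 2L) return(toks[2])
    }
    w
  }, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ", path)
  stats::setNames(seqs, acc)
}

.parsePositionToken <- function(tok) {
  tok <- trimws(tok)
  if (tok == "?") return(NA_integer_)
  if (!grepl("^[0-9]+$", tok)) return(NULL)   # signals malformed
  p <- suppressWarnings(as.integer(tok))
  if (is.na(p) || p < 1L) return(NULL)
  p
}

#' Parse glycoconjugate entries from GlyComb-dialect TSV text
#'
#' One row per (key, site, glycan) tuple: glycopeptide rows are
#' \code{peptide<TAB>site<TAB>glycan[<TAB>uniprot]}, glycoprotein rows
#' \code{uniprot<TAB>site<TAB>glycan}. \code{"?"} marks an unknown site.
#' The third column is auto-dispatched between composition notation and
#' GlyTouCan accession. Rows sharing a key aggregate into one entry even
#' when non-contiguous; blank lines are skipped; row order never affects
#' the resulting entry set.
#'
#' Error handling is all-or-nothing per entry: a malformed row invalidates
#' every row of the entry it belongs to (a partially parsed glycosylation
#' pattern would silently receive a different canonical identifier), and
#' every offending line is reported in \code{diagnostics()}.
#'
#' @param text TSV text (single string or character vector of lines), or
#'   with \code{file=}, a path.
#' @param kind \code{"glycopeptide"} or \code{"glycoprotein"}.
#' @param file Optional path read with \code{readLines}.
#' @return A \code{\linkS4class{GlycoconjugateSet}}; per-line diagnostics
#'   in \code{diagnostics()}.
#' @export
#' @examples
#' readGlycoTSV(c("PEPNK\t4\tHexNAc(2)", "PEPNK\t?\tHex(3)"), "glycopeptide")
readGlycoTSV <- function(text, kind = c("glycopeptide", "glycoprotein"),
                         file = NULL) {
  kind <- match.arg(kind)
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  diag <- list()
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    ok_cols <- if (kind == "glycopeptide") length(f) %in% c(3L, 4L)
               else length(f) == 3L
    if (!ok_cols) {
      diag[[length(diag) + 1L]] <- data.frame(
        line = i, key = if (length(f)) f[1] else NA_character_,
        message = paste0("wrong column count (", length(f), ")"))
      next
    }
    key <- f[1]; err <- NULL
    if (kind == "glycopeptide" && !.validPeptide(key))
      err <- "invalid peptide sequence (non-standard residue letters)"
    if (kind == "glycoprotein" && !.validAccession(key))
      err <- "invalid UniProt accession"
    pos <- .parsePositionToken(f[2])
    if (is.null(err) && is.null(pos))
      err <- paste0("invalid site position '", f[2], "'")
    gly <- NULL
    if (is.null(err)) {
      gly <- tryCatch(canonicalGlycanString(f[3]), error = identity)
      if (inherits(gly, "error")) {
        err <- paste0("malformed glycan: ", conditionMessage(gly))
        gly <- NULL
      }
    }
    if (is.null(err) && kind == "glycopeptide" && !is.na(pos) &&
        pos > nchar(key))
      err <- paste0("position ", pos, " beyond peptide length ", nchar(key))
    src <- NA_character_
    if (is.null(err) && kind == "glycopeptide" && length(f) == 4L) {
      if (!.validAccession(f[4]))
        err <- paste0("invalid source UniProt accession '", f[4], "'")
      else src <- f[4]
    }
    if (!is.null(err)) {
      diag[[length(diag) + 1L]] <- data.frame(line = i, key = key,
                                              message = err)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        line = i, key = key,
        position = if (is.na(pos)) NA_integer_ else pos,
        glycan = gly, source = src, stringsAsFactors = FALSE)
    }
  }
  diag <- if (length(diag)) do.call(rbind, diag) else
    data.frame(line = integer(0), key = character(0), message = character(0))
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line = integer(0), key = character(0), position = integer(0),
               glycan = character(0), source = character(0))
  ## all-or-nothing per entry: drop every row whose key had any bad line
  bad_keys <- unique(diag$key[!is.na(diag$key)])
  dropped <- rows$key %in% bad_keys
  if (any(dropped)) {
    diag <- rbind(diag, data.frame(
      line = rows$line[dropped], key = rows$key[dropped],
      message = "row discarded: entry invalidated by a malformed sibling row"))
    rows <- rows[!dropped, , drop = FALSE]
  }
  GlycoconjugateSet(kind, key = rows$key, position = rows$position,
                    glycan = rows$glycan, source = rows$source,
                    metadata = list(diagnostics = diag))
}

#' Validate glycoprotein entries against a sequence database
#'
#' Checks that each entry's accession is present in \code{db} and that
#' every known site position lies within the protein sequence; the residue
#' letter at each known position is recorded for downstream classification.
#'
#' @param x A glycoprotein \code{GlycoconjugateSet}.
#' @param db Named sequence vector from \code{\link{readSequenceDB}}.
#' @return \code{x} with a \code{residue} column added to its site table;
#'   entries failing validation are removed and reported in
#'   \code{diagnostics()}.
#' @export
validateGlycoproteins <- function(x, db) {
  stopifnot(is(x, "GlycoconjugateSet"), conjugateKind(x) == "glycoprotein")
  st <- x@sites
  msg <- rep(NA_character_, nrow(st))
  missing_acc <- !(st$key %in% names(db))
  msg[missing_acc] <- "accession not present in sequence database"
  known <- !is.na(st$position) & !missing_acc
  too_far <- known & st$position > nchar(db[st$key])
  msg[too_far] <- "site position beyond protein sequence length"
  bad_keys <- unique(st$key[!is.na(msg)])
  bad <- st$key %in% bad_keys
  diag <- data.frame(line = rep(NA_integer_, sum(!is.na(msg))),
                     key = st$key[!is.na(msg)],
                     message = msg[!is.na(msg)])
  keep <- st[!bad, , drop = FALSE]
  residue <- ifelse(is.na(keep$position), NA_character_,
                    substr(db[keep$key], keep$position, keep$position))
  keep$residue <- as.character(residue)
  md <- x@metadata
  md$diagnostics <- rbind(
    if (is.null(md$diagnostics)) NULL else
      md$diagnostics[, c("line", "key", "message"), drop = FALSE],
    diag)
  new("GlycoconjugateSet", kind = x@kind, sites = keep, metadata = md)
}

#' Serialize a GlycoconjugateSet to GlyComb-dialect TSV
#'
#' Rows are emitted in canonical order: entries sorted by key; within an
#' entry, sites by position with unknown ("?") sites last, ties broken by
#' canonical glycan string. \code{readGlycoTSV(writeGlycoTSV(x))}
#' reproduces \code{x} exactly.
#'
#' @param x A \code{GlycoconjugateSet}.
#' @param file Optional path; when given, the text is also written there.
#' @param ids Optional named character vector (per entry key) appended as a
#'   trailing ID column.
#' @return TSV text as a character vector of lines, invisibly when
#'   \code{file} is given.
#' @export
writeGlycoTSV <- function(x, file = NULL, ids = NULL) {
  st <- .orderSites(x@sites)
  pos <- ifelse(is.na(st$position), "?", as.character(st$position))
  lines <- paste(st$key, pos, st$glycan, sep = "\t")
  if (conjugateKind(x) == "glycopeptide") {
    has_src <- !is.na(st$source)
    lines[has_src] <- paste(lines[has_src], st$source[has_src], sep = "\t")
  }
  if (!is.null(ids)) lines <- paste(lines, ids[st$key], sep = "\t")
  if (nrow(st) == 0L) lines <- character(0)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
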