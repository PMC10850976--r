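#' GlycoconjugateSet: a set of glycopeptide or glycoprotein entries
#'
#' The central container of the package. A set holds rows of
#' (key, site position, glycan) triples in long form, backed by an
#' \code{\link[S4Vectors]{DataFrame}}; rows sharing a key (a peptide
#' sequence for glycopeptide sets, a UniProt accession for glycoprotein
#' sets) form one glycoconjugate entry — the unit that receives a canonical
#' identifier. A position of \code{NA} encodes an unknown ("?") site; the
#' same position may carry several distinct glycans. Glycans are stored in
#' their canonical string form (see \code{\link{canonicalGlycanString}}).
#'
#' @slot kind Either \code{"glycopeptide"} or \code{"glycoprotein"}.
#' @slot sites A \code{DataFrame} with columns \code{key} (character),
#'   \code{position} (integer, \code{NA} = unknown), \code{glycan}
#'   (canonical glycan string) and \code{source} (optional source-protein
#'   UniProt accession for glycopeptide rows, otherwise \code{NA}).
#' @slot metadata A list; parsing/conversion diagnostics live in
#'   \code{metadata(x)$diagnostics}.
#'
#' @importClassesFrom S4Vectors DataFrame
#' @exportClass GlycoconjugateSet
setClass("GlycoconjugateSet",
         representation(kind = "character",
                        sites = "DataFrame",
                        metadata = "list"))

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Standard UniProt accession pattern (6 or 10 characters, no isoform suffix)
.UNIPROT_RE <- "[OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2}"

.validPeptide <- function(x) {
  nzchar(x) & !grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), x)
}

.validAccession <- function(x) grepl(paste0("^(", .UNIPROT_RE, ")$"), x)

setValidity("GlycoconjugateSet", function(object) {
  msg <- character(0)
  if (length(object@kind) != 1L ||
      !object@kind %in% c("glycopeptide", "glycoprotein"))
    msg <- c(msg, "kind must be 'glycopeptide' or 'glycoprotein'")
  st <- object@sites
  need <- c("key", "position", "glycan", "source")
  if (!all(need %in% colnames(st)))
    return(c(msg, paste("sites must have columns:",
                        paste(need, collapse = ", "))))
  if (nrow(st)) {
    if (length(object@kind) == 1L && object@kind == "glycopeptide") {
      if (!all(.validPeptide(st$key)))
        msg <- c(msg, "peptide keys must be non-empty over the 20-letter alphabet")
      pos_ok <- is.na(st$position) |
        (st$position >= 1L & st$position <= nchar(st$key))
      if (!all(pos_ok))
        msg <- c(msg, "positions must be NA or within 1..nchar(peptide)")
    } else if (length(object@kind) == 1L) {
      if (!all(.validAccession(st$key)))
        msg <- c(msg, "glycoprotein keys must be UniProt accessions")
      if (!all(is.na(st$position) | st$position >= 1L))
        msg <- c(msg, "positions must be NA or >= 1")
    }
    if (anyDuplicated(paste(st$key, st$position, st$glycan, sep = "\r")))
      msg <- c(msg, "duplicate (key, position, glycan) rows")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GlycoconjugateSet
#'
#' @param kind \code{"glycopeptide"} or \code{"glycoprotein"}.
#' @param key Character vector of peptide sequences or UniProt accessions,
#'   one per (site, glycan) row.
#' @param position Integer vector of 1-based site positions; \code{NA}
#'   marks an unknown site.
#' @param glycan Character vector of glycan references (composition strings
#'   or GlyTouCan accessions); canonicalized on construction.
#' @param source Optional character vector of source-protein accessions
#'   (glycopeptide sets only).
#' @param metadata Optional list.
#' @return A \code{\linkS4class{GlycoconjugateSet}}.
#' @export
#' @examples
#' gp <- GlycoconjugateSet("glycopeptide",
#'                         key = c("PEPNK", "PEPNK"),
#'                         position = c(4L, NA),
#'                         glycan = c("HexNAc(2)", "Hex(3)"))
#' gp
GlycoconjugateSet <- function(kind, key = character(0),
                              position = integer(0), glycan = character(0),
                              source = NA_character_, metadata = list()) {
  n <- length(key)
  stopifnot(length(position) == n, length(glycan) == n)
  glycan <- vapply(glycan, canonicalGlycanString, character(1),
                   USE.NAMES = FALSE)
  source <- rep_len(as.character(source), n)
  st <- S4Vectors::DataFrame(key = as.character(key),
                             position = as.integer(position),
                             glycan = glycan,
                             source = source)
  st <- .orderSites(st)
  st <- st[!duplicated(paste(st$key, st$position, st$glycan, sep = "\r")), ,
           drop = FALSE]
  new("GlycoconjugateSet", kind = kind, sites = st, metadata = metadata)
}

## canonical row order: key, then known positions ascending (unknown last),
## then glycan string; C-locale radix sort so ordering is machine-invariant
.orderSites <- function(st) {
  o <- order(st$key, is.na(st$position), st$position, st$glycan,
             method = "radix")
  st[o, , drop = FALSE]
}

#' @describeIn GlycoconjugateSet-accessors Entry kind.
#' @export
conjugateKind <- function(x) x@kind

#' Accessors for GlycoconjugateSet
#'
#' \code{conjugateKind} returns \code{"glycopeptide"} or
#' \code{"glycoprotein"}; \code{entryKeys} the distinct entry keys;
#' \code{siteTable} the long-form (key, position, glycan, source) table as a
#' base data.frame; \code{diagnostics} the diagnostics accumulated while the
#' object was parsed or converted.
#'
#' @param x A \code{GlycoconjugateSet}.
#' @name GlycoconjugateSet-accessors
NULL

#' @describeIn GlycoconjugateSet-accessors Distinct entry keys, sorted.
#' @export
entryKeys <- function(x) sort(unique(x@sites$key), method = "radix")

#' @describeIn GlycoconjugateSet-accessors Long-form site table.
#' @export
siteTable <- function(x) as.data.frame(x@sites)

#' @describeIn GlycoconjugateSet-accessors Parse/conversion diagnostics
#'   (data.frame with columns \code{line}/\code{row}, \code{key},
#'   \code{message}), or \code{NULL}.
#' @export
diagnostics <- function(x) x@metadata$diagnostics

#' @importFrom S4Vectors metadata
#' @export
setMethod("metadata", "GlycoconjugateSet", function(x, ...) x@metadata)

#' Number of entries in a set
#'
#' @param x A \code{GlycoconjugateSet}.
#' @return The number of distinct entries (keys), not the number of rows.
#' @export
setMethod("length", "GlycoconjugateSet",
          function(x) length(unique(x@sites$key)))

#' @export
setMethod("show", "GlycoconjugateSet", function(object) {
  n <- length(object)
  cat("GlycoconjugateSet of kind '", object@kind, "' with ", n,
      if (n == 1L) " entry (" else " entries (",
      nrow(object@sites), " site rows)\n", sep = "")
  if (n) {
    ks <- entryKeys(object)
    shown <- utils::head(ks, 5L)
    for (k in shown) {
      rows <- object@sites[object@sites$key == k, , drop = FALSE]
      cat("  ", k, ": ",
          paste(ifelse(is.na(rows$position), "?", rows$position),
                rows$glycan, sep = ":", collapse = "; "), "\n", sep = "")
    }
    if (length(ks) > 5L) cat("  ... and ", length(ks) - 5L, " more\n", sep = "")
  }
  dg <- diagnostics(object)
  if (!is.null(dg) && nrow(dg))
    cat("  (", nrow(dg), " diagnostics; see diagnostics())\n", sep = "")
  invisible(NULL)
})
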