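#' Per-site glycosylation class from the modified residue
#'
#' Classification is a pure function of the residue letter: asparagine is
#' N-linked, serine/threonine O-linked, tryptophan C-mannosylation, any
#' other standard residue \code{OTHER}; an unknown position (\code{NA} or
#' \code{"?"}) is \code{UNDEFINED}. Sequon context never enters the class
#' (see \code{\link{checkSequon}} for the advisory N-X-S/T validator).
#'
#' @param residue Character vector of one-letter residue codes; \code{NA}
#'   or \code{"?"} for unknown sites.
#' @return Character vector over \code{N_LINKED}, \code{O_LINKED},
#'   \code{C_MAN}, \code{OTHER}, \code{UNDEFINED}.
#' @export
#' @examples
#' classifySite(c("N", "S", "T", "W", "A", NA))
classifySite <- function(residue) {
  out <- rep("OTHER", length(residue))
  out[is.na(residue) | residue == "?"] <- "UNDEFINED"
  out[!is.na(residue) & residue == "N"] <- "N_LINKED"
  out[!is.na(residue) & residue %in% c("S", "T")] <- "O_LINKED"
  out[!is.na(residue) & residue == "W"] <- "C_MAN"
  out
}

#' Advisory N-glycosylation sequon check
#'
#' Tests whether position \code{pos} of \code{sequence} sits in an
#' N-X-S/T sequon (X != P). Advisory only: entry classification counts by
#' residue identity alone, so an asparagine site outside a sequon is still
#' N-linked for bookkeeping purposes.
#'
#' @param sequence Amino-acid sequence.
#' @param pos 1-based position (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' checkSequon("DILTILANTTLQITCR", 8)  # N-T-T -> TRUE
checkSequon <- function(sequence, pos) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  vapply(pos, function(p) {
    if (is.na(p) || p < 1L || p > nchar(sequence)) return(FALSE)
    if (substr(sequence, p, p) != "N") return(FALSE)
    if (p + 2L > nchar(sequence)) return(FALSE)
    x <- substr(sequence, p + 1L, p + 1L)
    y <- substr(sequence, p + 2L, p + 2L)
    x != "P" && y %in% c("S", "T")
  }, logical(1))
}

.siteResidues <- function(x, db = NULL) {
  st <- siteTable(x)
  if (conjugateKind(x) == "glycopeptide") {
    ifelse(is.na(st$position), NA_character_,
           substr(st$key, st$position, st$position))
  } else {
    if ("residue" %in% colnames(st)) return(st$residue)
    if (is.null(db))
      stop("classifying glycoprotein entries requires a sequence database ",
           "(db) or prior validateGlycoproteins()")
    miss <- setdiff(unique(st$key), names(db))
    if (length(miss))
      stop("accession(s) absent from sequence database: ",
           paste(miss, collapse = ", "))
    ifelse(is.na(st$position), NA_character_,
           substr(db[st$key], st$position, st$position))
  }
}

#' Per-entry glycosylation class
#'
#' Partitions entries into \code{N_ONLY} (at least one N-linked site, no
#' O-linked), \code{O_ONLY}, \code{BOTH}, and \code{NEITHER} (no N- or
#' O-linked sites: all-undefined entries, and entries whose sites are only
#' C-mannosylated tryptophans or other residues). The partition is
#' exhaustive and mutually exclusive.
#'
#' @param x A \code{GlycoconjugateSet}.
#' @param db Sequence database (required for glycoprotein sets that have
#'   not been through \code{\link{validateGlycoproteins}}).
#' @return Named character vector, one class per entry key.
#' @export
#' @examples
#' gp <- readGlycoTSV("DILTILANTTLQITCR\t8\tHexNAc(4)Hex(7)NeuAc(1)",
#'                    "glycopeptide")
#' classifyEntries(gp)
classifyEntries <- function(x, db = NULL) {
  st <- siteTable(x)
  sc <- classifySite(.siteResidues(x, db))
  keys <- entryKeys(x)
  grouped <- split(sc, factor(st$key, levels = keys))
  vapply(grouped, function(cls) {
    has_n <- any(cls == "N_LINKED")
    has_o <- any(cls == "O_LINKED")
    if (has_n && has_o) "BOTH"
    else if (has_n) "N_ONLY"
    else if (has_o) "O_ONLY"
    else "NEITHER"
  }, character(1))
}

#' Glycosylation-class summary of a set
#'
#' @inheritParams classifyEntries
#' @return data.frame with one row per class (\code{N_ONLY}, \code{O_ONLY},
#'   \code{BOTH}, \code{NEITHER}) plus columns \code{count} and
#'   \code{percent}; total entry count as attribute \code{"total"}.
#' @export
classSummary <- function(x, db = NULL) {
  cls <- classifyEntries(x, db)
  lev <- c("N_ONLY", "O_ONLY", "BOTH", "NEITHER")
  counts <- vapply(lev, function(l) sum(cls == l), integer(1))
  total <- length(cls)
  out <- data.frame(class = lev, count = unname(counts),
                    percent = if (total) unname(100 * counts / total)
                              else rep(0, 4L))
  attr(out, "total") <- total
  out
}
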