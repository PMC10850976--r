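#' Cross-dataset overlap of glycoconjugate entries via canonical IDs
#'
#' Intersects the canonical-ID sets of two datasets of the same kind. The
#' ID intersection is provably identical to direct canonical-form equality
#' (IDs are content-addressed), which is what makes cross-repository
#' comparison a set operation instead of a pairwise records comparison.
#'
#' @param a,b \code{GlycoconjugateSet}s of the same kind, or entry tables
#'   from \code{\link{entryTable}}.
#' @param labels Length-2 character vector of dataset labels.
#' @param glycanMap Optional composition-to-accession normalization map
#'   applied to both sides before ID assignment.
#' @return List with \code{shared} (data.frame: \code{id}, \code{key},
#'   per-dataset membership columns, \code{accessions}), and counts
#'   \code{n_a}, \code{n_b}, \code{n_shared} for a Venn rendering.
#' @export
#' @examples
#' a <- readGlycoTSV(c("PEPNK\t4\tHexNAc(2)", "SASK\t1\tHex(1)"),
#'                   "glycopeptide")
#' b <- readGlycoTSV("PEPNK\t4\tHexNAc(2)", "glycopeptide")
#' overlapReport(a, b, labels = c("setA", "setB"))$n_shared
overlapReport <- function(a, b, labels = c("A", "B"), glycanMap = NULL) {
  ta <- if (is.data.frame(a)) a else entryTable(a, glycanMap, labels[1])
  tb <- if (is.data.frame(b)) b else entryTable(b, glycanMap, labels[2])
  if (!identical(unique(ta$kind), character(0)) &&
      !identical(unique(tb$kind), character(0)) &&
      length(unique(c(ta$kind, tb$kind))) > 1L)
    stop("cannot compare glycopeptide with glycoprotein datasets")
  shared_ids <- sort(intersect(ta$id, tb$id), method = "radix")
  shared <- do.call(rbind, lapply(shared_ids, function(id) {
    ra <- ta[ta$id == id, , drop = FALSE]
    rb <- tb[tb$id == id, , drop = FALSE]
    acc <- sort(unique(unlist(strsplit(c(ra$accessions, rb$accessions), ";"))),
                method = "radix")
    acc <- acc[nzchar(acc)]
    out <- data.frame(id = id, key = ra$key[1],
                      a = paste(unique(ra$dataset), collapse = ";"),
                      b = paste(unique(rb$dataset), collapse = ";"),
                      accessions = paste(acc, collapse = ";"),
                      stringsAsFactors = FALSE)
    names(out)[3:4] <- labels
    out
  }))
  if (is.null(shared))
    shared <- stats::setNames(
      data.frame(id = character(0), key = character(0), a = character(0),
                 b = character(0), accessions = character(0)),
      c("id", "key", labels, "accessions"))
  list(shared = shared, n_a = length(unique(ta$id)),
       n_b = length(unique(tb$id)), n_shared = length(shared_ids))
}

#' Entries sharing a key but differing in glycosylation pattern
#'
#' Finds all unordered pairs of entries that have the same key (peptide
#' sequence or accession) but different site sets, and hence different
#' canonical IDs. Within a single parsed set this is empty by construction
#' (rows aggregate per key), so the input is an entry table — typically
#' the \code{rbind} of \code{\link{entryTable}}s from several datasets.
#'
#' @param entries Entry-table data.frame (columns \code{id}, \code{key},
#'   \code{form}).
#' @return data.frame of pairs: \code{key}, \code{id_a}, \code{id_b}
#'   (deduplicated, \code{id_a < id_b}).
#' @export
sameKeyDifferentPattern <- function(entries) {
  ent <- unique(entries[, c("key", "form", "id")])
  out <- list()
  for (k in unique(ent$key)) {
    ids <- sort(unique(ent$id[ent$key == k]), method = "radix")
    if (length(ids) < 2L) next
    cmb <- utils::combn(ids, 2L)
    out[[length(out) + 1L]] <- data.frame(key = k, id_a = cmb[1, ],
                                          id_b = cmb[2, ],
                                          stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(key = character(0), id_a = character(0), id_b = character(0))
}

#' Peptide subsumption pairs
#'
#' Unordered pairs of glycopeptide entries where one bare peptide sequence
#' is a proper substring of the other — the relationship that arises when
#' protease treatment yields nested peptides covering the same
#' glycosylation region. Equal sequences are excluded.
#'
#' @param entries Entry-table data.frame (or a glycopeptide
#'   \code{GlycoconjugateSet}).
#' @return data.frame of pairs: \code{id_a}, \code{key_a}, \code{id_b},
#'   \code{key_b}, where \code{key_a} is the shorter (subsumed) peptide.
#' @export
peptideSubsumption <- function(entries) {
  if (is(entries, "GlycoconjugateSet")) entries <- entryTable(entries)
  ent <- unique(entries[, c("key", "id")])
  keys <- unique(ent$key)
  out <- list()
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (i == j) next
    a <- keys[i]; b <- keys[j]
    if (nchar(a) < nchar(b) && grepl(a, b, fixed = TRUE)) {
      ids_a <- ent$id[ent$key == a]; ids_b <- ent$id[ent$key == b]
      out[[length(out) + 1L]] <- expand.grid(id_a = ids_a, id_b = ids_b,
                                             stringsAsFactors = FALSE)
      out[[length(out)]]$key_a <- a
      out[[length(out)]]$key_b <- b
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res <- res[!duplicated(paste(res$id_a, res$id_b)), , drop = FALSE]
    rownames(res) <- NULL
    res[, c("id_a", "key_a", "id_b", "key_b")]
  } else {
    data.frame(id_a = character(0), key_a = character(0),
               id_b = character(0), key_b = character(0))
  }
}
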