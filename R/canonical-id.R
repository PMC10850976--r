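#' Canonical serialized form of each entry
#'
#' One deterministic string per entry:
#' \code{kind|key|pos1:glycan1;pos2:glycan2;...} with sites sorted by
#' position (unknown \code{"?"} sites last) then by canonical glycan
#' string, in the C locale. The form is invariant to input row order and
#' to composition-token order within each glycan. The optional
#' source-protein accession of glycopeptide entries is deliberately
#' excluded: identity is the peptide plus its glycosylation pattern.
#'
#' @param x A \code{GlycoconjugateSet}.
#' @param glycanMap Optional named character vector mapping canonical
#'   composition strings to GlyTouCan accessions, applied before
#'   serialization so that composition-notated and accession-notated forms
#'   of the same glycan compare equal.
#' @return Named character vector, one canonical form per entry key.
#' @export
#' @examples
#' gp <- readGlycoTSV("DILTILANTTLQITCR\t8\tHexNAc(4)Hex(7)NeuAc(1)",
#'                    "glycopeptide")
#' canonicalForm(gp)
canonicalForm <- function(x, glycanMap = NULL) {
  st <- .orderSites(x@sites)
  gly <- st$glycan
  if (!is.null(glycanMap)) {
    hit <- gly %in% names(glycanMap)
    gly[hit] <- unname(glycanMap[gly[hit]])
  }
  pos <- ifelse(is.na(st$position), "?", as.character(st$position))
  site_str <- paste0(pos, ":", gly)
  keys <- sort(unique(st$key), method = "radix")
  grouped <- split(site_str, factor(st$key, levels = keys))
  forms <- vapply(grouped, paste, character(1), collapse = ";")
  stats::setNames(paste0(conjugateKind(x), "|", keys, "|", forms), keys)
}

.idFromForm <- function(form) {
  h <- vapply(form, function(f)
    digest::digest(f, algo = "sha256", serialize = FALSE), character(1),
    USE.NAMES = FALSE)
  paste0("GC", toupper(substr(h, 1L, 6L)))
}

#' Assign content-addressed GlyComb-style identifiers
#'
#' Each entry receives \code{"GC"} plus the first 24 bits (6 uppercase hex
#' characters) of the SHA-256 hash of its UTF-8 canonical form. Identical
#' entries therefore receive identical IDs on any machine, with no central
#' registry; real repository accessions are not reproduced. The pairwise
#' collision probability is about 2^-24; collisions among distinct forms
#' are detected and reported via a warning.
#'
#' @inheritParams canonicalForm
#' @return Named character vector of IDs (one per entry key), with the
#'   canonical forms attached as attribute \code{"form"} and the IDs
#'   involved in any detected collision as attribute \code{"collisions"}
#'   (empty when none). At corpus sizes in the tens of thousands a 24-bit
#'   ID space is expected to produce a handful of birthday collisions;
#'   they are reported, never silently merged.
#' @export
#' @examples
#' gp <- readGlycoTSV("DILTILANTTLQITCR\t8\tHexNAc(4)Hex(7)NeuAc(1)",
#'                    "glycopeptide")
#' glycombIDs(gp)
glycombIDs <- function(x, glycanMap = NULL) {
  forms <- canonicalForm(x, glycanMap)
  ids <- .idFromForm(forms)
  names(ids) <- names(forms)
  collisions <- character(0)
  if (length(unique(ids)) != length(unique(forms))) {
    per_id <- split(unname(forms), ids)
    collisions <- names(per_id)[vapply(per_id, function(f)
      length(unique(f)) > 1L, logical(1))]
    warning("hash collision among distinct canonical forms: ",
            paste(collisions, collapse = ", "))
  }
  attr(ids, "form") <- unname(forms)
  attr(ids, "collisions") <- collisions
  ids
}

#' Flat entry table with canonical forms and identifiers
#'
#' A one-row-per-entry summary used by the overlap machinery, carrying the
#' key, canonical form, identifier and any associated source accessions.
#' Tables from several datasets can be concatenated with \code{rbind} to
#' compare entries across datasets without merging them.
#'
#' @inheritParams canonicalForm
#' @param label Optional dataset label stored in a \code{dataset} column.
#' @return data.frame with columns \code{id}, \code{kind}, \code{key},
#'   \code{form}, \code{accessions} (semicolon-collapsed), \code{dataset}.
#' @export
entryTable <- function(x, glycanMap = NULL, label = NA_character_) {
  ids <- glycombIDs(x, glycanMap)
  st <- siteTable(x)
  acc <- vapply(names(ids), function(k) {
    a <- unique(st$source[st$key == k])
    a <- a[!is.na(a)]
    if (conjugateKind(x) == "glycoprotein") a <- unique(c(k, a))
    paste(sort(a, method = "radix"), collapse = ";")
  }, character(1))
  data.frame(id = unname(ids), kind = conjugateKind(x), key = names(ids),
             form = attr(ids, "form"), accessions = unname(acc),
             dataset = label, stringsAsFactors = FALSE)
}
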