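#' Default RDF vocabulary map
#'
#' The GlycoCoO/GlycoRDF-derived predicate and class IRIs used by the RDF
#' export, loaded from the editable map shipped in
#' \code{inst/extdata/rdf_vocabulary.tsv}. The map is deliberately a
#' configuration file: the export adopts only a small subset of the
#' glycoconjugate ontology, and users can re-point terms at a revised
#' ontology release without touching code.
#'
#' @param path Optional path to an alternative two-column
#'   (\code{term}, \code{iri}) TSV.
#' @return Named character vector of IRIs.
#' @export
rdfVocabulary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rdf_vocabulary.tsv", package = "glycoconj")
  v <- read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(v$iri, v$term)
}

.escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

#' Convert entries to GlycoCoO-style RDF triples
#'
#' Follows a schema in which each entry is a typed node carrying its
#' identifier and its peptide sequence (or protein accession) as literals;
#' each distinct glycosylated position is a site node with residue-number
#' and, where resolvable, residue-name literals; and each (site, glycan)
#' pair is a saccharide node. Glycans covered by \code{glycanMap} are
#' normalized to their GlyTouCan accessions; unmapped compositions
#' serialize as composition literals carrying an explicit unverified flag
#' — never dropped.
#'
#' @param x A \code{GlycoconjugateSet}.
#' @param ids Named ID vector from \code{\link{glycombIDs}} (computed if
#'   missing).
#' @param glycanMap Optional composition-to-accession map.
#' @param vocab Vocabulary map from \code{\link{rdfVocabulary}}.
#' @param db Optional sequence database, used to resolve residue names for
#'   glycoprotein entries.
#' @return data.frame of triples: \code{subject}, \code{predicate},
#'   \code{object}, \code{object_type} (\code{"iri"} or \code{"literal"}).
#' @export
#' @examples
#' gp <- readGlycoTSV("DILTILANTTLQITCR\t8\tHexNAc(4)Hex(7)NeuAc(1)",
#'                    "glycopeptide")
#' nrow(entryTriples(gp))
entryTriples <- function(x, ids = NULL, glycanMap = NULL,
                         vocab = rdfVocabulary(), db = NULL) {
  if (is.null(ids)) ids <- glycombIDs(x, glycanMap)
  st <- siteTable(x)
  kind <- conjugateKind(x)
  res <- .siteResiduesSafe(x, db)
  subj <- character(0); pred <- character(0); obj <- character(0)
  otype <- character(0)
  emit <- function(s, p, o, t) {
    subj <<- c(subj, s); pred <<- c(pred, p); obj <<- c(obj, o)
    otype <<- c(otype, t)
  }
  for (k in entryKeys(x)) {
    if (!k %in% names(ids)) stop("no assigned ID for entry ", k)
    id <- ids[[k]]
    e <- paste0(vocab[["base_entry"]], id)
    emit(e, vocab[["rdf_type"]],
         vocab[[if (kind == "glycopeptide") "class_glycopeptide"
                else "class_glycoprotein"]], "iri")
    emit(e, vocab[["identifier"]], id, "literal")
    emit(e, vocab[[if (kind == "glycopeptide") "peptide_sequence"
                   else "protein_accession"]], k, "literal")
    rows <- which(st$key == k)
    pos_lab <- ifelse(is.na(st$position[rows]), "?",
                      as.character(st$position[rows]))
    gi <- 0L
    for (p in unique(pos_lab)) {
      s_node <- paste0(e, "#site-", p)
      emit(e, vocab[["has_site"]], s_node, "iri")
      emit(s_node, vocab[["rdf_type"]], vocab[["class_site"]], "iri")
      emit(s_node, vocab[["site_position"]], p, "literal")
      r <- res[rows[pos_lab == p][1]]
      if (!is.na(r) && p != "?")
        emit(s_node, vocab[["site_residue"]], r, "literal")
      for (j in rows[pos_lab == p]) {
        gi <- gi + 1L
        g_node <- paste0(e, "#glycan-", gi)
        gly <- st$glycan[j]
        mapped <- !is.null(glycanMap) && gly %in% names(glycanMap)
        if (mapped) gly <- unname(glycanMap[[st$glycan[j]]])
        emit(s_node, vocab[["has_glycan"]], g_node, "iri")
        emit(g_node, vocab[["rdf_type"]], vocab[["class_saccharide"]], "iri")
        if (mapped || isGlyTouCanAccession(gly)) {
          emit(g_node, vocab[["glytoucan_id"]], gly, "literal")
        } else {
          emit(g_node, vocab[["composition_literal"]], gly, "literal")
          emit(g_node, vocab[["unmapped_flag"]], "true", "literal")
        }
      }
    }
  }
  data.frame(subject = subj, predicate = pred, object = obj,
             object_type = otype, stringsAsFactors = FALSE)
}

## residue resolution that degrades to NA instead of erroring (RDF export
## must serialize entries even without a sequence database)
.siteResiduesSafe <- function(x, db) {
  if (conjugateKind(x) == "glycopeptide" || !is.null(db) ||
      "residue" %in% colnames(siteTable(x)))
    tryCatch(.siteResidues(x, db),
             error = function(e) rep(NA_character_, nrow(siteTable(x))))
  else rep(NA_character_, nrow(siteTable(x)))
}

#' Serialize RDF triples
#'
#' Writes N-Triples or Turtle text with statements in sorted order, so the
#' same graph always serializes byte-identically.
#'
#' @param triples Triple data.frame from \code{\link{entryTriples}}.
#' @param format \code{"ntriples"} or \code{"turtle"}.
#' @param file Optional output path.
#' @return Character vector of lines (invisibly when \code{file} given).
#' @export
writeGraph <- function(triples, format = c("ntriples", "turtle"),
                       file = NULL) {
  format <- match.arg(format)
  if (nrow(triples) == 0L) {
    lines <- character(0)
  } else {
    o <- order(triples$subject, triples$predicate, triples$object,
               method = "radix")
    tr <- triples[o, , drop = FALSE]
    objs <- ifelse(tr$object_type == "iri",
                   paste0("<", tr$object, ">"),
                   paste0("\"", .escapeLiteral(tr$object), "\""))
    lines <- paste0("<", tr$subject, "> <", tr$predicate, "> ", objs, " .")
    if (format == "turtle") {
      ## minimal deterministic Turtle: prefix the common namespaces, keep
      ## one statement per line
      ns <- c(glycoconjugate = "http://purl.jp/bio/12/glyco/conjugate#",
              glycan = "http://purl.jp/bio/12/glyco/glycan#",
              rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
              dcterms = "http://purl.org/dc/terms/")
      shorten <- function(s) {
        for (p in names(ns)) {
          hit <- startsWith(s, paste0("<", ns[[p]]))
          local <- sub(paste0("^<", ns[[p]]), "", s)
          ok <- hit & grepl("^[A-Za-z_][A-Za-z0-9_-]*>$", local)
          s[ok] <- paste0(p, ":", sub(">$", "", local[ok]))
        }
        s
      }
      subj_t <- shorten(paste0("<", tr$subject, ">"))
      pred_t <- shorten(paste0("<", tr$predicate, ">"))
      objs_t <- ifelse(tr$object_type == "iri", shorten(objs), objs)
      lines <- c(paste0("@prefix ", names(ns), ": <", unname(ns), "> ."),
                 "",
                 paste0(subj_t, " ", pred_t, " ", objs_t, " ."))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
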