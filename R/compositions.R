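#' @import methods
#' @importFrom utils read.delim write.table
NULL

## Canonical symbol order used for serialization. HexNAc/Hex/Fuc/NeuAc lead
## (the order conventionally printed by Byonic-style tools), remaining
## monosaccharides and the two supported substituents follow.
.CANONICAL_ORDER <- c("HexNAc", "Hex", "Fuc", "NeuAc", "NeuGc", "Pent",
                      "HexA", "Phospho", "Sulfate")

## Worksheet-dialect aliases, normalized before canonical serialization.
.SYMBOL_ALIASES <- c(dHex = "Fuc", Sulfo = "Sulfate")

.pkg_env <- new.env(parent = emptyenv())

.load_tables <- function() {
  if (!is.null(.pkg_env$mono)) return(invisible(NULL))
  mono <- read.delim(system.file("extdata", "monosaccharides.tsv",
                                 package = "glycoconj"),
                     stringsAsFactors = FALSE)
  elem <- read.delim(system.file("extdata", "elements.tsv",
                                 package = "glycoconj"),
                     stringsAsFactors = FALSE)
  .pkg_env$mono <- mono
  .pkg_env$elements <- stats::setNames(elem$monoisotopic_mass, elem$element)
  .pkg_env$residue_mass <- stats::setNames(mono$residue_mass, mono$symbol)
  invisible(NULL)
}

#' Monosaccharide and substituent symbol table
#'
#' The vocabulary of composition symbols the package accepts, with the
#' elemental formula and monoisotopic residue mass (the mass a unit adds on
#' glycosidic incorporation, i.e. free molecule minus water for
#' monosaccharides) of each. Only the substituents \code{Phospho} and
#' \code{Sulfate} are supported; any other substituent token (e.g.
#' \code{Methyl}, \code{Acetyl}) is rejected by \code{\link{parseComposition}}.
#'
#' @return A data.frame with columns \code{symbol}, \code{class}
#'   (\code{"monosaccharide"} or \code{"substituent"}), \code{formula} and
#'   \code{residue_mass} (Da).
#' @export
#' @examples
#' monosaccharideTable()
monosaccharideTable <- function() {
  .load_tables()
  .pkg_env$mono
}

#' Monoisotopic element masses used by the package
#'
#' @return Named numeric vector of monoisotopic atomic masses (Da).
#' @export
elementMasses <- function() {
  .load_tables()
  .pkg_env$elements
}

#' Compute the monoisotopic mass of an elemental formula
#'
#' @param formula A Hill-style formula string such as \code{"C8H13NO5"}.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' formulaMass("C6H10O5")  # hexose residue, 162.0528
formulaMass <- function(formula) {
  .load_tables()
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (!nzchar(gsub("([A-Z][a-z]?)([0-9]*)", "", formula)))
    total <- 0 else stop("malformed formula: ", formula)
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.pkg_env$elements))
      stop("unknown element '", el, "' in formula ", formula)
    total <- total + n * .pkg_env$elements[[el]]
  }
  total
}

#' Parse a glycan composition string
#'
#' Parses Byonic-style composition notation such as
#' \code{"HexNAc(4)Hex(7)NeuAc(1)"} into a named integer count vector.
#' Whitespace between a symbol and its parenthesized count is tolerated
#' (some tools print \code{"HexNAc (4)"}); repeated symbols are merged by
#' summing counts; dialect aliases (\code{dHex} for \code{Fuc}, \code{Sulfo}
#' for \code{Sulfate}) are normalized. Tokens outside the supported
#' vocabulary — in particular substituents other than \code{Phospho} and
#' \code{Sulfate} — raise an error.
#'
#' @param text A single composition string.
#' @return Named integer vector of counts in canonical symbol order.
#' @export
#' @examples
#' parseComposition("HexNAc(4)Hex(7)NeuAc(1)")
#' parseComposition("HexNAc (4)Hex (7)NeuAc (1)")  # same result
parseComposition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (!nzchar(s)) stop("empty composition string")
  pat <- "^\\s*([A-Za-z]+)\\s*\\(([^)]*)\\)"
  counts <- integer(0)
  while (nzchar(s)) {
    m <- regexec(pat, s)[[1]]
    if (m[1] == -1L)
      stop("malformed composition near '", s, "'")
    parts <- regmatches(s, list(regexec(pat, s)[[1]]))[[1]]
    sym <- parts[2]; cnt <- parts[3]
    if (sym %in% names(.SYMBOL_ALIASES)) sym <- .SYMBOL_ALIASES[[sym]]
    if (!sym %in% .CANONICAL_ORDER)
      stop("unsupported composition symbol '", parts[2], "'")
    if (!grepl("^[0-9]+$", cnt))
      stop("malformed count '", cnt, "' for symbol ", sym)
    n <- as.integer(cnt)
    if (n < 1L)
      stop("count for ", sym, " must be a positive integer, got ", n)
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
    s <- trimws(substring(s, attr(regexec(pat, s)[[1]], "match.length")[1] + 1L))
  }
  counts[order(match(names(counts), .CANONICAL_ORDER))]
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum over symbols of count times residue mass. An empty composition has
#' mass zero.
#'
#' @param comp Named integer vector as returned by
#'   \code{\link{parseComposition}}, or a composition string.
#' @return Mass in Da.
#' @export
#' @examples
#' compositionMass("HexNAc(4)Hex(7)NeuAc(1)")  # 2237.783
compositionMass <- function(comp) {
  .load_tables()
  if (is.character(comp)) comp <- parseComposition(comp)
  if (length(comp) == 0L) return(0)
  bad <- setdiff(names(comp), names(.pkg_env$residue_mass))
  if (length(bad)) stop("unsupported composition symbol '", bad[1], "'")
  sum(comp * .pkg_env$residue_mass[names(comp)])
}

#' Test whether a string is a GlyTouCan accession token
#'
#' The accession shape accepted is \code{"G"} followed by five digits and two
#' uppercase letters (e.g. \code{"G00912UN"}), the shape of all published
#' GlyTouCan accessions; this is a documented dialect assumption.
#'
#' @param text Character vector.
#' @return Logical vector.
#' @export
#' @examples
#' isGlyTouCanAccession(c("G00912UN", "HexNAc(2)", ""))
isGlyTouCanAccession <- function(text) {
  !is.na(text) & grepl("^G[0-9]{5}[A-Z]{2}$", text)
}

#' Canonical string form of a glycan reference
#'
#' GlyTouCan accessions pass through verbatim; composition strings (or parsed
#' count vectors) are re-serialized with symbols in the fixed canonical order
#' (HexNAc, Hex, Fuc, NeuAc, NeuGc, Pent, HexA, Phospho, Sulfate) and no
#' whitespace, so any two equal compositions serialize identically.
#'
#' @param ref A composition string, a parsed composition (named integer
#'   vector), or a GlyTouCan accession string.
#' @return Canonical single-string form.
#' @export
#' @examples
#' canonicalGlycanString("NeuAc(1)Hex(7)HexNAc(4)")  # "HexNAc(4)Hex(7)NeuAc(1)"
#' canonicalGlycanString("G00912UN")
canonicalGlycanString <- function(ref) {
  if (is.character(ref) && length(ref) == 1L) {
    if (isGlyTouCanAccession(ref)) return(ref)
    ref <- parseComposition(ref)
  }
  stopifnot(is.numeric(ref), !is.null(names(ref)))
  ref <- ref[order(match(names(ref), .CANONICAL_ORDER))]
  paste0(names(ref), "(", as.integer(ref), ")", collapse = "")
}
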