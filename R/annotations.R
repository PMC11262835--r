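## GAF parsing, evidence filtering and the protein-binding exclusion.

#' Default accepted evidence codes
#'
#' Experimental (EXP, IDA, IPI, IMP, IGI, IEP), high-throughput (HTP, HDA,
#' HMP, HGI, HEP), traceable author statement (TAS) and curator inference
#' (IC) codes; electronically inferred annotations (IEA) are excluded. This
#' is the CAFA-style filter used for both templates and test targets.
#'
#' @return Character vector of evidence codes.
#' @export
defaultEvidenceCodes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
    "HTP", "HDA", "HMP", "HGI", "HEP", "TAS", "IC")
}

.GAF_ASPECT <- c(F = "MF", P = "BP", C = "CC")

#' Parse a GAF 2.x annotation file into an AnnotationDB
#'
#' Keeps rows whose evidence code (column 7) is in `evidenceFilter`, drops
#' rows with a `NOT` qualifier (column 4), resolves alternate term ids, and
#' skips rows whose term is unknown to the graph (counted and reported as a
#' warning). Each protein's term set is ancestor-closed within its aspect
#' and the aspect roots are removed. The aspect of a term is taken from the
#' ontology graph.
#'
#' @param path path to a tab-separated GAF 2.x file (`!` comment lines
#'   ignored).
#' @param graph an [OntologyGraph-class].
#' @param evidenceFilter evidence codes to keep; defaults to
#'   [defaultEvidenceCodes()].
#' @return An [AnnotationDB-class].
#' @export
#' @examples
#' obo <- system.file("extdata", "diamond.obo", package = "homologyGO")
#' gaf <- system.file("extdata", "diamond_synthetic.gaf", package = "homologyGO")
#' parseGAF(gaf, parseOBO(obo))
parseGAF <- function(path, graph, evidenceFilter = defaultEvidenceCodes()) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L)
    return(annotationDB(evidenceKept = evidenceFilter))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("GAF rows with fewer than 9 columns (first at data row ",
         which(nf < 9L)[1L], ")")
  protein <- vapply(fields, `[[`, character(1L), 2L)
  qualifier <- vapply(fields, `[[`, character(1L), 4L)
  goId <- vapply(fields, `[[`, character(1L), 5L)
  evidence <- vapply(fields, `[[`, character(1L), 7L)

  keep <- evidence %in% evidenceFilter & !grepl("NOT", qualifier, fixed = TRUE)
  protein <- protein[keep]
  goId <- goId[keep]

  resolved <- resolveTerms(graph, goId)
  nSkipped <- sum(is.na(resolved))
  if (nSkipped > 0L)
    warning(nSkipped, " GAF row(s) skipped: term unknown to the ontology")
  ok <- !is.na(resolved)
  protein <- protein[ok]
  resolved <- resolved[ok]

  anc <- .ancestorIndex(graph)
  roots <- goRoots()
  aspect <- graph@aspect[resolved]

  out <- stats::setNames(vector("list", 3L), .GO_ASPECTS)
  for (a in .GO_ASPECTS) {
    sel <- aspect == a
    if (!any(sel)) {
      out[[a]] <- stats::setNames(list(), character(0L))
      next
    }
    sets <- split(resolved[sel], protein[sel])
    out[[a]] <- lapply(sets, function(tms) {
      tms <- unique(tms)
      setdiff(unique(c(tms, unlist(anc[tms], use.names = FALSE))), roots)
    })
  }
  annotationDB(out, evidenceKept = evidenceFilter, nSkipped = nSkipped)
}

#' Write GAF rows to a file
#'
#' Writes a 17-column GAF 2.2 file from a data.frame of rows (as produced by
#' [genToyAnnotations()]). Deterministic: rows are written in input order.
#'
#' @param gaf data.frame with (at least) columns `protein`, `qualifier`,
#'   `term`, `evidence`, `aspect` (one of F/P/C).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGAF <- function(gaf, path) {
  n <- nrow(gaf)
  cols <- list(
    rep("toyDB", n), gaf$protein, gaf$protein, gaf$qualifier, gaf$term,
    rep("REF:0000001", n), gaf$evidence, rep("", n), gaf$aspect,
    rep("", n), rep("", n), rep("protein", n), rep("taxon:0", n),
    rep("20240101", n), rep("toyDB", n), rep("", n), rep("", n))
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c("!gaf-version: 2.2", body), path)
  invisible(path)
}

#' Apply the protein-binding exclusion rule
#'
#' Removes the entire MF annotation set of any protein whose *only* MF leaf
#' term is GO:0005515 'protein binding'. Proteins with additional MF leaves,
#' or no MF annotation, and the BP/CC sets of all proteins, are untouched.
#'
#' @param db an ancestor-closed [AnnotationDB-class].
#' @param graph an [OntologyGraph-class].
#' @return A filtered [AnnotationDB-class].
#' @export
applyProteinBindingRule <- function(db, graph) {
  mf <- db@annotations$MF
  if (length(mf) == 0L) return(db)
  drop <- vapply(mf, function(tms) {
    identical(leafTerms(tms, graph), "GO:0005515")
  }, logical(1L))
  ann <- db@annotations
  ann$MF <- mf[!drop]
  annotationDB(ann, evidenceKept = db@evidenceKept, nSkipped = db@nSkipped)
}
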