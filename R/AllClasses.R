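## Central S4 containers. All aspect-indexed structures use the canonical
## order MF, BP, CC.

#' Canonical GO aspect roots
#'
#' The three Gene Ontology aspect roots: molecular_function (GO:0003674),
#' biological_process (GO:0008150) and cellular_component (GO:0005575).
#' Roots are excluded from annotation closures, predictions and evaluation.
#'
#' @return Named character vector with names `MF`, `BP`, `CC`.
#' @export
#' @examples
#' goRoots()
goRoots <- function() {
  c(MF = "GO:0003674", BP = "GO:0008150", CC = "GO:0005575")
}

.GO_ASPECTS <- c("MF", "BP", "CC")

## ---------------------------------------------------------------- ontology

#' OntologyGraph: a parsed GO DAG
#'
#' Holds the term set, direct parent edges (`is_a` and `part_of`), the aspect
#' (MF/BP/CC) of every term, alternate-id mappings and obsolete ids. Parent
#' edges must form a DAG; propagation (ancestor closure) is always restricted
#' to a term's own aspect.
#'
#' @slot terms character vector of canonical, non-obsolete term ids.
#' @slot parents named list: term id -> character vector of direct parents.
#' @slot parentRel named list parallel to `parents`: relationship type of
#'   each edge, `"is_a"` or `"part_of"`.
#' @slot aspect named character: term id -> one of `"MF"`, `"BP"`, `"CC"`.
#' @slot roots the three canonical aspect roots (see [goRoots()]).
#' @slot altIdMap named character: alternate id -> canonical id.
#' @slot obsolete character vector of obsolete term ids.
#' @slot termNames named character: term id -> human-readable name.
#'
#' @seealso [parseOBO()], [termAncestors()], [ancestorClosure()]
#' @export
setClass("OntologyGraph", representation(
  terms = "character",
  parents = "list",
  parentRel = "list",
  aspect = "character",
  roots = "character",
  altIdMap = "character",
  obsolete = "character",
  termNames = "character"
))

## Kahn topological order over the full edge set; NULL when a cycle exists.
.topoOrder <- function(terms, parents) {
  nOut <- vapply(parents, length, integer(1L))  # edges term -> parent
  kids <- vector("list", length(terms))
  names(kids) <- terms
  for (tm in terms) {
    for (p in parents[[tm]]) {
      if (p %in% terms) kids[[p]] <- c(kids[[p]], tm)
    }
  }
  queue <- terms[nOut == 0L]
  out <- character(0L)
  deg <- nOut
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in kids[[v]]) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(terms)) NULL else out
}

setValidity("OntologyGraph", function(object) {
  msgs <- character(0L)
  if (!identical(object@roots, goRoots()))
    msgs <- c(msgs, "roots must be exactly the three canonical GO aspect roots")
  if (!setequal(names(object@parents), object@terms))
    msgs <- c(msgs, "parents must be named by exactly the term set")
  if (!all(object@terms %in% names(object@aspect)))
    msgs <- c(msgs, "every term must have an aspect label")
  else if (!all(object@aspect[object@terms] %in% .GO_ASPECTS))
    msgs <- c(msgs, "aspects must be MF, BP or CC")
  if (!all(unlist(object@parents) %in% object@terms))
    msgs <- c(msgs, "parent edges must point at known terms")
  if (is.null(.topoOrder(object@terms, object@parents)))
    msgs <- c(msgs, "parent edges must form a directed acyclic graph")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OntologyGraph
#'
#' Low-level constructor; [parseOBO()] is the usual entry point. Edges whose
#' relationship type is not given default to `is_a`.
#'
#' @param terms character vector of term ids (must include the root of every
#'   aspect that occurs).
#' @param parents named list mapping each term to its direct parents
#'   (`character(0)` for roots). Terms missing from the list get no parents.
#' @param aspect named character mapping each term to `"MF"`, `"BP"` or
#'   `"CC"`.
#' @param termNames optional named character of human-readable names.
#' @param parentRel optional named list of relationship types parallel to
#'   `parents`.
#' @param altIdMap optional named character of alternate-id mappings.
#' @param obsolete optional character vector of obsolete ids.
#' @return An [OntologyGraph-class] object.
#' @export
#' @examples
#' root <- goRoots()[["MF"]]
#' g <- ontologyGraph(
#'   terms = c(root, "GO:7000001"),
#'   parents = list("GO:7000001" = root),
#'   aspect = stats::setNames(c("MF", "MF"), c(root, "GO:7000001")))
#' termAncestors(g, "GO:7000001")
ontologyGraph <- function(terms, parents = list(), aspect,
                          termNames = character(0L),
                          parentRel = list(),
                          altIdMap = character(0L),
                          obsolete = character(0L)) {
  terms <- unique(as.character(terms))
  full <- stats::setNames(vector("list", length(terms)), terms)
  rel <- full
  for (tm in terms) {
    p <- unique(as.character(parents[[tm]]))
    full[[tm]] <- p
    r <- parentRel[[tm]]
    if (is.null(r) || length(r) != length(p)) r <- rep("is_a", length(p))
    rel[[tm]] <- as.character(r)
  }
  if (length(termNames) == 0L)
    termNames <- stats::setNames(terms, terms)
  methods::new("OntologyGraph",
    terms = terms, parents = full, parentRel = rel,
    aspect = aspect[terms], roots = goRoots(),
    altIdMap = altIdMap, obsolete = obsolete,
    termNames = termNames)
}

## ------------------------------------------------------------- annotations

#' AnnotationDB: ancestor-closed protein annotation sets
#'
#' One named list of term-id vectors per aspect. Every stored set is closed
#' under the ancestor relation within its aspect and never contains the
#' aspect root. Aspects are fully independent: a protein may appear in any
#' subset of them.
#'
#' @slot annotations list with elements `MF`, `BP`, `CC`, each a named list
#'   mapping protein id -> character vector of terms.
#' @slot evidenceKept evidence codes accepted when the database was built.
#' @slot nSkipped number of input rows skipped for unknown/obsolete term ids.
#'
#' @seealso [parseGAF()], [annotationDB()], [computeIC()]
#' @export
setClass("AnnotationDB", representation(
  annotations = "list",
  evidenceKept = "character",
  nSkipped = "integer"
))

setValidity("AnnotationDB", function(object) {
  if (!identical(names(object@annotations), .GO_ASPECTS))
    return("annotations must be a list with elements MF, BP, CC")
  for (a in .GO_ASPECTS) {
    sets <- object@annotations[[a]]
    if (!is.list(sets)) return(sprintf("annotations$%s must be a list", a))
    if (length(sets) && is.null(names(sets)))
      return(sprintf("annotations$%s must be named by protein id", a))
    if (any(vapply(sets, function(x) any(x %in% goRoots()), logical(1L))))
      return("annotation sets must not contain aspect roots")
  }
  TRUE
})

#' Construct an AnnotationDB from pre-closed term sets
#'
#' Wraps already ancestor-closed annotation sets (e.g. hand-built test
#' fixtures). Use [parseGAF()] to build a database from a GAF file with
#' evidence filtering and automatic closure.
#'
#' @param annotations list with any of the elements `MF`, `BP`, `CC`; each a
#'   named list mapping protein id to a character vector of term ids.
#' @param evidenceKept evidence codes recorded as accepted.
#' @param nSkipped number of skipped rows recorded.
#' @return An [AnnotationDB-class] object.
#' @export
annotationDB <- function(annotations = list(),
                         evidenceKept = defaultEvidenceCodes(),
                         nSkipped = 0L) {
  full <- stats::setNames(vector("list", 3L), .GO_ASPECTS)
  for (a in .GO_ASPECTS) {
    x <- annotations[[a]]
    full[[a]] <- if (is.null(x)) stats::setNames(list(), character(0L)) else x
  }
  methods::new("AnnotationDB", annotations = full,
               evidenceKept = evidenceKept, nSkipped = as.integer(nSkipped))
}

#' @describeIn annotationDB Annotation sets of one aspect (or all three).
#' @param db an `AnnotationDB`.
#' @param aspect `"MF"`, `"BP"`, `"CC"`, or `NULL` for the full list.
#' @export
annotations <- function(db, aspect = NULL) {
  stopifnot(methods::is(db, "AnnotationDB"))
  if (is.null(aspect)) return(db@annotations)
  db@annotations[[match.arg(aspect, .GO_ASPECTS)]]
}

#' @describeIn annotationDB Number of annotated proteins per aspect.
#' @export
nProteins <- function(db) {
  vapply(db@annotations, length, integer(1L))
}

## ---------------------------------------------------------------------- IC

#' ICTable: information accretion per term
#'
#' Information accretion of term q is `-log2((1 + C(q)) / (1 + C(parent(q))))`
#' where `C(q)` counts database proteins annotated with q and `C(parent(q))`
#' counts proteins carrying *all* direct parents of q simultaneously. The +1
#' smoothing keeps the ratio finite for unobserved terms.
#'
#' @slot table data.frame with columns `term`, `aspect`, `count`,
#'   `parentCount`, `ic` (bits).
#' @seealso [computeIC()], [icValues()]
#' @export
setClass("ICTable", representation(table = "data.frame"))

setValidity("ICTable", function(object) {
  need <- c("term", "aspect", "count", "parentCount", "ic")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' Extract information-accretion values
#'
#' @param x an [ICTable-class] (or an already-named numeric vector, returned
#'   unchanged, so plain vectors can stand in for an ICTable in evaluation
#'   functions).
#' @return Named numeric vector, term id -> IC in bits.
#' @export
icValues <- function(x) {
  if (is.numeric(x)) {
    stopifnot(!is.null(names(x)))
    return(x)
  }
  stopifnot(methods::is(x, "ICTable"))
  stats::setNames(x@table$ic, x@table$term)
}

#' @describeIn icValues The underlying count table.
#' @export
icTable <- function(x) {
  stopifnot(methods::is(x, "ICTable"))
  x@table
}

## ------------------------------------------------------------ template sets

#' TemplateSet: the annotated hits of one query in one aspect
#'
#' All quantities the scoring functions need for a single query: per-template
#' similarity score (bit-score or a substituted score field), the four
#' sequence-identity normalisations, and each template's ancestor-closed term
#' set in the aspect. Templates without annotations in the aspect are excluded
#' before K is counted.
#'
#' @slot query query protein id.
#' @slot aspect `"MF"`, `"BP"` or `"CC"`.
#' @slot templates data.frame with columns `template`, `score`, `qID`, `tID`,
#'   `aID`, `ID`; one row per annotated template.
#' @slot termSets list parallel to the rows of `templates`: the template's
#'   term set (non-empty, ancestor-closed, roots excluded).
#' @seealso [buildTemplateSets()], [scoreTerms()]
#' @export
setClass("TemplateSet", representation(
  query = "character",
  aspect = "character",
  templates = "data.frame",
  termSets = "list"
))

setValidity("TemplateSet", function(object) {
  need <- c("template", "score", "qID", "tID", "aID", "ID")
  if (!all(need %in% names(object@templates)))
    return(paste("templates needs columns", paste(need, collapse = ", ")))
  if (nrow(object@templates) != length(object@termSets))
    return("one term set per template row required")
  if (nrow(object@templates) < 1L)
    return("a TemplateSet needs at least one template (K >= 1)")
  if (any(vapply(object@termSets, length, integer(1L)) == 0L))
    return("every template term set must be non-empty")
  TRUE
})

#' Construct a TemplateSet directly
#'
#' Mainly for tests and examples; [buildTemplateSets()] assembles template
#' sets from a hit table and an [AnnotationDB-class].
#'
#' @param query query protein id.
#' @param aspect aspect label.
#' @param templates data.frame with columns `template`, `score`, `qID`,
#'   `tID`, `aID`, `ID`.
#' @param termSets list of character vectors, one per template row.
#' @return A [TemplateSet-class].
#' @export
templateSet <- function(query, aspect, templates, termSets) {
  methods::new("TemplateSet", query = query,
               aspect = match.arg(aspect, .GO_ASPECTS),
               templates = templates, termSets = termSets)
}

#' @describeIn templateSet Number of annotated templates K.
#' @param ts a `TemplateSet`.
#' @export
nTemplates <- function(ts) nrow(ts@templates)

## -------------------------------------------------------------- predictions

#' PredictionSet: per-protein GO term scores
#'
#' Scores lie in (0, 1]; a term a protein does not carry is absent, not zero.
#' Scores produced from ancestor-closed template annotations are DAG
#' consistent (parent score >= child score); [combinePredictors()] and
#' [propagateScores()] re-enforce this after arithmetic on score maps.
#'
#' @slot scores list with elements `MF`, `BP`, `CC`; each a named list
#'   mapping protein id -> named numeric vector (term -> score).
#' @slot method label of the scoring function, e.g. `"S2"`.
#' @slot params list of provenance parameters (lambda, weights, ...).
#' @seealso [predictGO()], [writeCAFA()]
#' @export
setClass("PredictionSet", representation(
  scores = "list",
  method = "character",
  params = "list"
))

setValidity("PredictionSet", function(object) {
  if (!identical(names(object@scores), .GO_ASPECTS))
    return("scores must be a list with elements MF, BP, CC")
  for (a in .GO_ASPECTS) {
    for (v in object@scores[[a]]) {
      if (length(v) && (is.null(names(v)) || any(v <= 0) || any(v > 1)))
        return("every score vector must be term-named with values in (0, 1]")
    }
  }
  TRUE
})

#' Construct a PredictionSet from score maps
#'
#' @param scores list with any of `MF`, `BP`, `CC`; each a named list of
#'   protein -> named numeric term scores in (0, 1].
#' @param method provenance label.
#' @param params provenance parameter list.
#' @return A [PredictionSet-class].
#' @export
predictionSet <- function(scores = list(), method = "manual", params = list()) {
  full <- stats::setNames(vector("list", 3L), .GO_ASPECTS)
  for (a in .GO_ASPECTS) {
    x <- scores[[a]]
    full[[a]] <- if (is.null(x)) stats::setNames(list(), character(0L)) else x
  }
  methods::new("PredictionSet", scores = full, method = method, params = params)
}

#' @describeIn predictionSet Score maps of one aspect (named list,
#'   protein -> named numeric).
#' @param p a `PredictionSet`.
#' @param aspect aspect label.
#' @export
predictionScores <- function(p, aspect) {
  stopifnot(methods::is(p, "PredictionSet"))
  p@scores[[match.arg(aspect, .GO_ASPECTS)]]
}

## --------------------------------------------------------------- evaluation

#' EvalCurve: precision/recall across score thresholds
#'
#' The per-threshold precision, recall and coverage underlying Fmax (or
#' wFmax when `weighted`). `fmax` is the maximum harmonic mean over the
#' threshold grid, `tmax` the smallest threshold attaining it.
#'
#' @slot thresholds ascending numeric grid in (0, 1].
#' @slot precision,recall numeric vectors per threshold.
#' @slot covered integer M(t): proteins with >= 1 prediction at t.
#' @slot nProteins integer N: proteins in the ground-truth set.
#' @slot fmax,tmax the optimum and its threshold.
#' @slot weighted TRUE when information-accretion weighted.
#' @slot aspect aspect label.
#' @seealso [fmaxCurve()], [wfmaxCurve()]
#' @export
setClass("EvalCurve", representation(
  thresholds = "numeric",
  precision = "numeric",
  recall = "numeric",
  covered = "integer",
  nProteins = "integer",
  fmax = "numeric",
  tmax = "numeric",
  weighted = "logical",
  aspect = "character"
))

#' @describeIn fmaxCurve The Fmax (or wFmax) value of a curve.
#' @param curve an `EvalCurve`.
#' @export
fmaxValue <- function(curve) {
  stopifnot(methods::is(curve, "EvalCurve"))
  curve@fmax
}

#' @describeIn fmaxCurve The smallest threshold attaining the optimum.
#' @export
fmaxThreshold <- function(curve) {
  stopifnot(methods::is(curve, "EvalCurve"))
  curve@tmax
}

#' @describeIn fmaxCurve Per-threshold curve as a data.frame.
#' @export
curveTable <- function(curve) {
  stopifnot(methods::is(curve, "EvalCurve"))
  data.frame(threshold = curve@thresholds, precision = curve@precision,
             recall = curve@recall, covered = curve@covered)
}

#' MethodComparison: paired per-protein comparison of two methods
#'
#' @slot labels the two method labels.
#' @slot perProteinF list of the two aligned per-protein F vectors.
#' @slot meanF,sem per-method mean F and standard error of the mean.
#' @slot tStatistic,pValue,df two-tailed paired t-test on the differences.
#' @slot degenerate TRUE when the differences have zero variance (t and p
#'   are then NA).
#' @seealso [pairedTTest()]
#' @export
setClass("MethodComparison", representation(
  labels = "character",
  perProteinF = "list",
  meanF = "numeric",
  sem = "numeric",
  tStatistic = "numeric",
  pValue = "numeric",
  df = "integer",
  degenerate = "logical"
))

## ---------------------------------------------------------------- benchmark

#' BenchmarkSplit: a time-elapsed target/template split
#'
#' Targets are proteins first annotated in an aspect in the new release;
#' templates carry old-release annotations. A target is never annotated in
#' its evaluated aspect in the template database.
#'
#' @slot targets list per aspect of target protein ids.
#' @slot templateDb old-release [AnnotationDB-class].
#' @slot truth new-release annotations restricted to the targets.
#' @slot partition list per aspect: named character, target ->
#'   `"LK"` / `"NK-easy"` / `"NK-hard"` (empty before [partitionTargets()]).
#' @seealso [buildTimeElapsedBenchmark()]
#' @export
setClass("BenchmarkSplit", representation(
  targets = "list",
  templateDb = "AnnotationDB",
  truth = "AnnotationDB",
  partition = "list"
))

## --------------------------------------------------------------------- show

setMethod("show", "OntologyGraph", function(object) {
  tab <- table(factor(object@aspect[object@terms], levels = .GO_ASPECTS))
  cat("OntologyGraph with", length(object@terms), "terms",
      sprintf("(MF %d, BP %d, CC %d),", tab[["MF"]], tab[["BP"]], tab[["CC"]]),
      sum(lengths(object@parents)), "parent edges,",
      length(object@obsolete), "obsolete ids\n")
})

setMethod("show", "AnnotationDB", function(object) {
  np <- nProteins(object)
  cat("AnnotationDB:", sprintf("%s %d proteins", .GO_ASPECTS, np),
      sep = "\n  ")
  cat("  evidence codes kept:", paste(object@evidenceKept, collapse = ","),
      "\n")
  if (object@nSkipped > 0L)
    cat("  rows skipped (unknown terms):", object@nSkipped, "\n")
})

setMethod("show", "ICTable", function(object) {
  cat("ICTable for", nrow(object@table), "terms; IC range",
      sprintf("[%.3f, %.3f] bits\n",
              min(object@table$ic), max(object@table$ic)))
})

setMethod("show", "TemplateSet", function(object) {
  cat("TemplateSet:", object@query, sprintf("(%s),", object@aspect),
      nTemplates(object), "annotated templates,",
      length(unique(unlist(object@termSets))), "distinct terms\n")
})

setMethod("show", "PredictionSet", function(object) {
  np <- vapply(object@scores, length, integer(1L))
  cat("PredictionSet [", object@method, "]:",
      sprintf("%s %d proteins", .GO_ASPECTS, np), sep = "\n  ")
})

setMethod("show", "EvalCurve", function(object) {
  cat(sprintf("%s curve (%s): %s = %.4f at t = %.2f (N = %d)\n",
              if (object@weighted) "wFmax" else "Fmax", object@aspect,
              if (object@weighted) "wFmax" else "Fmax",
              object@fmax, object@tmax, object@nProteins))
})

setMethod("show", "MethodComparison", function(object) {
  cat(sprintf("MethodComparison %s vs %s: mean F %.4f vs %.4f, t = %s, p = %s (df = %d)\n",
              object@labels[1L], object@labels[2L],
              object@meanF[1L], object@meanF[2L],
              format(object@tStatistic, digits = 4L),
              format(object@pValue, digits = 4L), object@df))
  if (object@degenerate)
    cat("  note: zero-variance differences; t-test degenerate\n")
})

setMethod("show", "BenchmarkSplit", function(object) {
  nt <- vapply(object@targets, length, integer(1L))
  cat("BenchmarkSplit:", sprintf("%s %d targets", names(object@targets), nt),
      sep = "\n  ")
  cat("  template proteins per aspect:",
      paste(nProteins(object@templateDb), collapse = "/"), "\n")
})
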