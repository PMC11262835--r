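## The eleven template-weighting scoring functions and their combinations.
##
## Given a query's K annotated templates, with per-template similarity score
## (bit-score by default), identity normalisations qID/tID/aID/ID and
## ancestor-closed term sets, the score of term q is
##   S1  sum of bit-scores over templates with q / sum over all K
##   S2  sum of bit-score * ID over templates with q / sum over all K
##   S3..S6  as S1 with qID / tID / aID / ID as the weight
##   S7  K(q) / K, the frequency of templates carrying q
##   S8..S11 max of qID / tID / aID / ID over templates carrying q
## All scores lie in (0, 1]; terms carried by no template are absent
## (treated as 0 downstream). Because term sets are ancestor-closed, the
## templates carrying a parent are a superset of those carrying its child,
## so every function is monotone non-increasing down the DAG.

#' The eleven scoring-function labels
#'
#' @return `c("S1", ..., "S11")`.
#' @export
scoringFunctions <- function() paste0("S", 1:11)

#' Build per-query template sets for one aspect
#'
#' Joins a deduplicated hit table against the template annotation database:
#' hits to templates without annotations in the aspect are dropped, and one
#' [TemplateSet-class] is returned per query with at least one annotated
#' template.
#'
#' @param hits canonical hit data.frame (see [parseHits()]), deduplicated.
#' @param db template [AnnotationDB-class].
#' @param aspect `"MF"`, `"BP"` or `"CC"`.
#' @return Named list of [TemplateSet-class] objects (by query id).
#' @export
buildTemplateSets <- function(hits, db, aspect) {
  aspect <- match.arg(aspect, .GO_ASPECTS)
  ann <- db@annotations[[aspect]]
  hits <- hits[hits$template %in% names(ann), , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(list(), character(0L)))
  idm <- identityMetrics(hits)
  tab <- cbind(hits[c("query", "template", "score")], idm)
  out <- lapply(split(seq_len(nrow(tab)), tab$query), function(ix) {
    templateSet(query = tab$query[[ix[[1L]]]], aspect = aspect,
                templates = tab[ix, c("template", "score",
                                      "qID", "tID", "aID", "ID")],
                termSets = unname(ann[tab$template[ix]]))
  })
  out
}

#' Score GO terms for one template set
#'
#' Applies one of the eleven scoring functions (see [scoringFunctions()]).
#' Terms carried by no template receive no score. When the weighted
#' denominator is zero (e.g. every template identity is 0 under S2), the
#' query emits no predictions and a warning reports it.
#'
#' @param ts a [TemplateSet-class].
#' @param fn scoring function label, `"S1"` .. `"S11"`.
#' @return Named numeric vector term -> score in (0, 1] (empty when the
#'   denominator vanishes).
#' @export
#' @examples
#' ts <- templateSet("q1", "MF",
#'   data.frame(template = c("t1", "t2"), score = c(100, 50),
#'              qID = c(0.8, 0.5), tID = c(0.8, 0.5),
#'              aID = c(0.8, 0.5), ID = c(0.8, 0.5)),
#'   list(c("GO:7000001", "GO:7000002"), "GO:7000001"))
#' scoreTerms(ts, "S2")
scoreTerms <- function(ts, fn = "S2") {
  fn <- match.arg(fn, scoringFunctions())
  tpl <- ts@templates
  K <- nrow(tpl)
  reps <- rep(seq_len(K), lengths(ts@termSets))
  termVec <- unlist(ts@termSets, use.names = FALSE)

  if (fn %in% paste0("S", 1:7)) {
    w <- switch(fn,
      S1 = tpl$score,
      S2 = tpl$score * tpl$ID,
      S3 = tpl$qID,
      S4 = tpl$tID,
      S5 = tpl$aID,
      S6 = tpl$ID,
      S7 = rep(1, K))
    denom <- sum(w)
    if (denom <= 0) {
      warning("zero denominator under ", fn, " for query ", ts@query,
              "; no predictions emitted")
      return(stats::setNames(numeric(0L), character(0L)))
    }
    num <- rowsum(w[reps], termVec)
    sc <- stats::setNames(num[, 1L] / denom, rownames(num))
  } else {
    idcol <- switch(fn, S8 = "qID", S9 = "tID", S10 = "aID", S11 = "ID")
    v <- tapply(tpl[[idcol]][reps], termVec, max)
    sc <- stats::setNames(as.numeric(v), names(v))
  }
  sc <- pmin(sc, 1)
  sc[sc > 0]
}

#' Homology-based GO prediction from a hit table
#'
#' The main driver: deduplicates hits, builds per-query template sets per
#' aspect against the template annotation database, and scores terms with
#' the chosen scoring function.
#'
#' @param hits canonical hit data.frame (see [parseHits()]).
#' @param db template [AnnotationDB-class].
#' @param fn scoring function label (default `"S2"`, the bit-score times
#'   sequence-identity weight).
#' @param aspects aspects to predict (default all three).
#' @param excludeSelf drop self-hits before scoring.
#' @return A [PredictionSet-class].
#' @export
predictGO <- function(hits, db, fn = "S2",
                      aspects = c("MF", "BP", "CC"), excludeSelf = FALSE) {
  fn <- match.arg(fn, scoringFunctions())
  aspects <- match.arg(aspects, .GO_ASPECTS, several.ok = TRUE)
  hits <- dedupeHits(hits, excludeSelf = excludeSelf)
  scores <- list()
  for (a in aspects) {
    sets <- buildTemplateSets(hits, db, a)
    sc <- lapply(sets, scoreTerms, fn = fn)
    scores[[a]] <- sc[vapply(sc, length, integer(1L)) > 0L]
  }
  predictionSet(scores, method = fn, params = list(excludeSelf = excludeSelf))
}

#' Blend two term-score maps linearly
#'
#' Per term, `lambda * a + (1 - lambda) * b`, a term missing from either map
#' contributing 0; the result is clipped to `[0, 1]` and zero scores are
#' dropped. With `lambda = 1` (`0`) the result equals `a` (`b`) exactly.
#'
#' @param a,b named numeric term-score maps with values in `[0, 1]`.
#' @param lambda blend weight in `[0, 1]` on `a`.
#' @return Named numeric blended score map.
#' @export
blendScores <- function(a, b, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  terms <- union(names(a), names(b))
  av <- bv <- stats::setNames(numeric(length(terms)), terms)
  av[names(a)] <- a
  bv[names(b)] <- b
  out <- pmin(pmax(lambda * av + (1 - lambda) * bv, 0), 1)
  out[out > 0]
}

#' Propagate scores up the DAG by max
#'
#' Re-enforces DAG consistency of a term-score map: every ancestor of a
#' scored term receives at least that term's score. Roots stay excluded.
#'
#' @param scores named numeric term-score map.
#' @param graph an [OntologyGraph-class].
#' @return DAG-consistent named numeric score map.
#' @export
propagateScores <- function(scores, graph) {
  if (length(scores) == 0L) return(scores)
  out <- scores
  for (tm in names(scores)) {
    for (a in termAncestors(graph, tm)) {
      prev <- out[a]
      if (is.na(prev) || prev < scores[[tm]]) out[a] <- scores[[tm]]
    }
  }
  out
}

#' Combine two prediction sets
#'
#' Per protein and term, `weight * p1 + (1 - weight) * p2` with missing
#' scores treated as 0 (used e.g. to merge the predictions of two search
#' tools). DAG consistency is re-enforced afterwards by max-propagating each
#' term's score to its ancestors.
#'
#' @param p1,p2 [PredictionSet-class] objects covering the same aspects.
#' @param weight weight on `p1` in `[0, 1]` (default 0.5).
#' @param graph an [OntologyGraph-class] (for the propagation step).
#' @return A combined [PredictionSet-class].
#' @export
combinePredictors <- function(p1, p2, weight = 0.5, graph) {
  if (!is.numeric(weight) || weight < 0 || weight > 1)
    stop("weight must be in [0, 1]")
  scores <- list()
  for (a in .GO_ASPECTS) {
    s1 <- p1@scores[[a]]
    s2 <- p2@scores[[a]]
    prots <- union(names(s1), names(s2))
    if (length(prots) == 0L) next
    scores[[a]] <- stats::setNames(lapply(prots, function(pr) {
      v <- blendScores(if (is.null(s1[[pr]])) numeric(0L) else s1[[pr]],
                       if (is.null(s2[[pr]])) numeric(0L) else s2[[pr]],
                       weight)
      propagateScores(v, graph)
    }), prots)
    keep <- vapply(scores[[a]], length, integer(1L)) > 0L
    scores[[a]] <- scores[[a]][keep]
  }
  predictionSet(scores,
                method = paste0(p1@method, "+", p2@method),
                params = list(weight = weight))
}

## ----------------------------------------------------------- CAFA file I/O

#' Write predictions in CAFA tab-separated format
#'
#' One row per (protein, term) pair with the score rounded to three
#' decimals; pairs rounding to 0.000 are omitted. A leading comment line
#' records the scoring function and parameters.
#'
#' @param pred a [PredictionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCAFA <- function(pred, path) {
  hdr <- sprintf("#homologyGO method=%s %s", pred@method,
                 paste(names(pred@params), unlist(pred@params),
                       sep = "=", collapse = " "))
  rows <- character(0L)
  for (a in .GO_ASPECTS) {
    sc <- pred@scores[[a]]
    for (pr in names(sc)) {
      v <- sc[[pr]]
      v <- v[order(-v, names(v))]
      s <- sprintf("%.3f", v)
      keep <- s != "0.000"
      if (any(keep))
        rows <- c(rows, paste(pr, names(v)[keep], s[keep], sep = "\t"))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a CAFA-format prediction file
#'
#' Parses rows of (protein, GO id, score); the aspect of each term is taken
#' from the ontology graph. Terms unknown to the graph raise an error.
#'
#' @param path CAFA tab-separated prediction file (`#` comment lines
#'   ignored).
#' @param graph an [OntologyGraph-class].
#' @param method provenance label for the returned set.
#' @return A [PredictionSet-class].
#' @export
readCAFA <- function(path, graph, method = "file") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(predictionSet(method = method))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("CAFA rows must have 3 tab-separated fields")
  prot <- vapply(parts, `[[`, character(1L), 1L)
  term <- resolveTerms(graph, vapply(parts, `[[`, character(1L), 2L))
  if (anyNA(term)) stop("prediction file contains terms unknown to the ontology")
  sc <- as.numeric(vapply(parts, `[[`, character(1L), 3L))
  if (any(is.na(sc) | sc <= 0 | sc > 1))
    stop("prediction scores must be numeric in (0, 1]")
  aspect <- graph@aspect[term]
  scores <- list()
  for (a in .GO_ASPECTS) {
    sel <- aspect == a
    if (!any(sel)) next
    byProt <- split(data.frame(term = term[sel], sc = sc[sel]), prot[sel])
    scores[[a]] <- lapply(byProt, function(d) {
      v <- tapply(d$sc, d$term, max)  # duplicate pairs: keep the max
      stats::setNames(as.numeric(v), names(v))
    })
  }
  predictionSet(scores, method = method)
}
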