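## Time-elapsed benchmark construction and target difficulty partitioning.

#' Build a time-elapsed benchmark from two annotation releases
#'
#' Targets of an aspect are proteins that carry annotations in the new
#' release but none in that aspect in the old release; the template
#' database is the full old release. The protein-binding exclusion
#' ([applyProteinBindingRule()]) is applied to both releases before the
#' split, so proteins whose only MF leaf is GO:0005515 are neither MF
#' targets nor MF templates. An aspect without targets yields a warning
#' and an empty target list.
#'
#' @param oldGaf path to the old-release GAF (or an [AnnotationDB-class]).
#' @param newGaf path to the new-release GAF (or an [AnnotationDB-class]).
#' @param graph an [OntologyGraph-class].
#' @param evidenceFilter evidence codes accepted when parsing.
#' @return A [BenchmarkSplit-class] (partition empty until
#'   [partitionTargets()]).
#' @export
buildTimeElapsedBenchmark <- function(oldGaf, newGaf, graph,
                                      evidenceFilter = defaultEvidenceCodes()) {
  asDb <- function(x) {
    if (methods::is(x, "AnnotationDB")) x
    else parseGAF(x, graph, evidenceFilter)
  }
  oldDb <- applyProteinBindingRule(asDb(oldGaf), graph)
  newDb <- applyProteinBindingRule(asDb(newGaf), graph)

  targets <- stats::setNames(vector("list", 3L), .GO_ASPECTS)
  truthAnn <- stats::setNames(vector("list", 3L), .GO_ASPECTS)
  for (a in .GO_ASPECTS) {
    tg <- setdiff(names(newDb@annotations[[a]]), names(oldDb@annotations[[a]]))
    if (length(tg) == 0L)
      warning("no time-elapsed targets in aspect ", a)
    targets[[a]] <- sort(tg)
    truthAnn[[a]] <- newDb@annotations[[a]][targets[[a]]]
  }
  methods::new("BenchmarkSplit", targets = targets,
               templateDb = oldDb,
               truth = annotationDB(truthAnn,
                                    evidenceKept = evidenceFilter),
               partition = list())
}

#' Partition targets into LK / NK-easy / NK-hard
#'
#' A target evaluated in an aspect is limited-knowledge (`LK`) when the
#' old release annotates it in a *different* aspect; otherwise it is
#' `NK-easy` when its best template sequence identity
#' (`nident / max(qlen, tlen)`) exceeds 0.5, and `NK-hard` otherwise
#' (including targets with no hits at all).
#'
#' @param split a [BenchmarkSplit-class].
#' @param hits canonical hit data.frame computed against the split's
#'   template database.
#' @return The split with its `partition` slot filled: per aspect a named
#'   character vector target -> label.
#' @export
partitionTargets <- function(split, hits) {
  stopifnot(methods::is(split, "BenchmarkSplit"))
  tmplProts <- unique(unlist(lapply(split@templateDb@annotations, names),
                             use.names = FALSE))
  hits <- hits[hits$template %in% tmplProts, , drop = FALSE]
  idv <- if (nrow(hits)) hits$nident / pmax(hits$qlen, hits$tlen) else numeric(0L)
  bestId <- if (nrow(hits)) tapply(idv, hits$query, max) else numeric(0L)

  partition <- stats::setNames(vector("list", 3L), .GO_ASPECTS)
  for (a in .GO_ASPECTS) {
    tg <- split@targets[[a]]
    if (length(tg) == 0L) {
      partition[[a]] <- stats::setNames(character(0L), character(0L))
      next
    }
    others <- setdiff(.GO_ASPECTS, a)
    hasOther <- vapply(tg, function(p) {
      any(vapply(others, function(o)
        !is.null(split@templateDb@annotations[[o]][[p]]), logical(1L)))
    }, logical(1L))
    best <- unname(bestId[tg])
    best[is.na(best)] <- 0
    lab <- ifelse(hasOther, "LK", ifelse(best > 0.5, "NK-easy", "NK-hard"))
    partition[[a]] <- stats::setNames(lab, tg)
  }
  methods::initialize(split, partition = partition)
}

#' Write a benchmark manifest
#'
#' One TSV row per target: aspect, protein id and (when available)
#' difficulty partition label.
#'
#' @param split a [BenchmarkSplit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBenchmarkManifest <- function(split, path) {
  rows <- list()
  for (a in .GO_ASPECTS) {
    tg <- split@targets[[a]]
    if (length(tg) == 0L) next
    lab <- if (length(split@partition))
      unname(split@partition[[a]][tg]) else rep(NA_character_, length(tg))
    rows[[a]] <- data.frame(aspect = a, target = tg, partition = lab,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(aspect = character(0L), target = character(0L),
               partition = character(0L))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
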