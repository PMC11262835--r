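## Information accretion from database term counts.

#' Compute information accretion from an annotation database
#'
#' For every (non-obsolete) term q of the graph,
#' `IC(q) = -log2((1 + C(q)) / (1 + C(parent(q))))` in bits, where `C(q)` is
#' the number of database proteins annotated with q in q's aspect and
#' `C(parent(q))` is the number of proteins carrying *all* direct parents of
#' q simultaneously. Because annotation sets are ancestor-closed,
#' `C(q) <= C(parent(q))` and `IC(q) >= 0`. Annotated proteins implicitly
#' carry their aspect root, so a parent set consisting only of the root
#' yields `C(parent(q)) =` the number of proteins annotated in the aspect;
#' the roots themselves get `C(root) = C(parent(root)) =` that same count
#' (hence IC 0) so that a root IC is defined although roots never enter
#' scoring or evaluation.
#'
#' @param db an ancestor-closed [AnnotationDB-class] (the template database).
#' @param graph an [OntologyGraph-class].
#' @return An [ICTable-class] covering every term of the graph.
#' @export
#' @examples
#' obo <- system.file("extdata", "diamond.obo", package = "homologyGO")
#' gaf <- system.file("extdata", "diamond_synthetic.gaf", package = "homologyGO")
#' g <- parseOBO(obo)
#' computeIC(parseGAF(gaf, g), g)
computeIC <- function(db, graph) {
  roots <- goRoots()
  rows <- vector("list", 3L)
  for (ai in seq_along(.GO_ASPECTS)) {
    a <- .GO_ASPECTS[[ai]]
    sets <- db@annotations[[a]]
    nP <- length(sets)
    termsA <- graph@terms[graph@aspect[graph@terms] == a]
    if (length(termsA) == 0L) next

    ## invert: term -> sorted protein-id vector
    prot <- rep(names(sets), lengths(sets))
    byTerm <- split(prot, unlist(sets, use.names = FALSE))

    count <- integer(length(termsA))
    parentCount <- integer(length(termsA))
    for (k in seq_along(termsA)) {
      q <- termsA[[k]]
      if (q %in% roots) {
        count[[k]] <- nP
        parentCount[[k]] <- nP
        next
      }
      count[[k]] <- length(byTerm[[q]])
      par <- graph@parents[[q]]
      par <- setdiff(par[graph@aspect[par] == a], roots)
      if (length(par) == 0L) {
        parentCount[[k]] <- nP
      } else {
        joint <- byTerm[[par[[1L]]]]
        for (p in par[-1L]) {
          joint <- intersect(joint, byTerm[[p]])
          if (length(joint) == 0L) break
        }
        parentCount[[k]] <- length(joint)
      }
    }
    ic <- -log2((1 + count) / (1 + parentCount))
    rows[[ai]] <- data.frame(term = termsA, aspect = a, count = count,
                             parentCount = parentCount, ic = ic,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(tab) <- NULL
  methods::new("ICTable", table = tab)
}

#' Export an ICTable as two-column TSV
#'
#' Columns: term id, information accretion in bits.
#'
#' @param ic an [ICTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeICTable <- function(ic, path) {
  tab <- icTable(ic)
  utils::write.table(data.frame(term = tab$term, ic = sprintf("%.6f", tab$ic)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
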