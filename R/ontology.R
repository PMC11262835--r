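## OBO parsing and DAG traversal. Only is_a and relationship: part_of edges
## are treated as parent edges (CAFA propagation convention); regulates-type
## relationships are ignored.

.NAMESPACE_MAP <- c(molecular_function = "MF",
                    biological_process = "BP",
                    cellular_component = "CC")

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas and builds an [OntologyGraph-class]. `is_a` and
#' `relationship: part_of` lines become parent edges; other relationship
#' types are ignored. Obsolete terms are recorded but excluded from the term
#' set, and `alt_id` lines populate the alternate-id map. Terms in namespaces
#' other than the three GO aspects are dropped.
#'
#' @param path path to an OBO 1.2 file.
#' @return An [OntologyGraph-class].
#' @export
#' @examples
#' obo <- system.file("extdata", "diamond.obo", package = "homologyGO")
#' parseOBO(obo)
parseOBO <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  inTerm <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur) {
    if (!is.null(cur) && is.null(cur$id))
      stop("malformed OBO stanza without id line (near line ", cur$line, ")")
    if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush(cur)
      cur <- NULL
      inTerm <- identical(ln, "[Term]")
      if (inTerm) cur <- list(line = i, parents = character(0L),
                              rel = character(0L), altIds = character(0L),
                              obsolete = FALSE)
      next
    }
    if (!inTerm) next
    sep <- regexpr(": ", ln, fixed = TRUE)
    if (sep < 0L)
      stop("malformed OBO line ", i, ": '", ln, "'")
    key <- substr(ln, 1L, sep - 1L)
    val <- substr(ln, sep + 2L, nchar(ln))
    val <- sub(" *!.*$", "", val)              # strip trailing comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "alt_id") cur$altIds <- c(cur$altIds, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "is_a") {
      cur$parents <- c(cur$parents, strsplit(val, " ", fixed = TRUE)[[1L]][1L])
      cur$rel <- c(cur$rel, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(val, " ", fixed = TRUE)[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of") {
        cur$parents <- c(cur$parents, parts[[2L]])
        cur$rel <- c(cur$rel, "part_of")
      }
    }
  }
  flush(cur)
  if (length(stanzas) == 0L) stop("no [Term] stanzas found in ", path)

  ids <- vapply(stanzas, `[[`, character(1L), "id")
  obs <- vapply(stanzas, `[[`, logical(1L), "obsolete")
  ns <- vapply(stanzas, function(s)
    if (is.null(s$namespace)) NA_character_ else s$namespace, character(1L))
  aspect <- unname(.NAMESPACE_MAP[ns])
  keep <- !obs & !is.na(aspect)

  terms <- ids[keep]
  aspectVec <- stats::setNames(aspect[keep], terms)
  nm <- vapply(stanzas, function(s)
    if (is.null(s$name)) s$id else s$name, character(1L))
  termNames <- stats::setNames(nm[keep], terms)

  parents <- stats::setNames(vector("list", length(terms)), terms)
  rels <- parents
  for (j in which(keep)) {
    p <- stanzas[[j]]$parents
    r <- stanzas[[j]]$rel
    ok <- p %in% terms
    parents[[ids[[j]]]] <- p[ok]
    rels[[ids[[j]]]] <- r[ok]
  }

  altIdMap <- character(0L)
  for (j in which(keep)) {
    a <- stanzas[[j]]$altIds
    if (length(a)) altIdMap[a] <- ids[[j]]
  }

  if (is.null(.topoOrder(terms, parents)))
    stop("cyclic parent edges detected in ", path)

  ontologyGraph(terms = terms, parents = parents, aspect = aspectVec,
                termNames = termNames, parentRel = rels,
                altIdMap = altIdMap, obsolete = ids[obs])
}

#' Serialize an OntologyGraph to OBO 1.2 text
#'
#' Writes one `[Term]` stanza per term (including roots) in the order terms
#' are stored, so output is deterministic for a given graph.
#'
#' @param graph an [OntologyGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(graph, path) {
  out <- c("format-version: 1.2", "")
  nsInv <- stats::setNames(names(.NAMESPACE_MAP), .NAMESPACE_MAP)
  for (tm in graph@terms) {
    out <- c(out, "[Term]", paste0("id: ", tm),
             paste0("name: ", graph@termNames[[tm]]),
             paste0("namespace: ", nsInv[[graph@aspect[[tm]]]]))
    p <- graph@parents[[tm]]
    r <- graph@parentRel[[tm]]
    for (k in seq_along(p)) {
      out <- c(out, if (r[[k]] == "is_a") paste0("is_a: ", p[[k]])
               else paste0("relationship: part_of ", p[[k]]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Resolve a term id against a graph
#'
#' Maps alternate ids to their canonical id; returns `NA` for unknown or
#' obsolete ids.
#'
#' @param graph an [OntologyGraph-class].
#' @param ids character vector of term ids.
#' @return Character vector of canonical ids (`NA` where unresolvable).
#' @export
resolveTerms <- function(graph, ids) {
  out <- ifelse(ids %in% graph@terms, ids,
                unname(graph@altIdMap[ids]))
  out[!(out %in% graph@terms)] <- NA_character_
  out
}

## Full transitive ancestor closure for every term, restricted to the term's
## own aspect, roots excluded. Computed once per call site in topological
## order (parents before children).
.ancestorIndex <- function(graph) {
  ord <- .topoOrder(graph@terms, graph@parents)
  anc <- stats::setNames(vector("list", length(graph@terms)), graph@terms)
  roots <- goRoots()
  for (tm in ord) {
    asp <- graph@aspect[[tm]]
    p <- graph@parents[[tm]]
    p <- p[graph@aspect[p] == asp]
    a <- unique(c(p, unlist(anc[p], use.names = FALSE)))
    anc[[tm]] <- setdiff(a, roots)
  }
  anc
}

#' Transitive ancestors of a term
#'
#' All transitive parents of `term` within its own aspect, excluding the
#' aspect roots and the term itself.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a term id (alternate ids are resolved).
#' @return Character vector of ancestor term ids.
#' @export
#' @examples
#' obo <- system.file("extdata", "diamond.obo", package = "homologyGO")
#' g <- parseOBO(obo)
#' termAncestors(g, "GO:7000004")
termAncestors <- function(graph, term) {
  tm <- resolveTerms(graph, term)
  if (is.na(tm)) stop("unknown term: ", term)
  asp <- graph@aspect[[tm]]
  roots <- goRoots()
  seen <- character(0L)
  frontier <- tm
  while (length(frontier)) {
    p <- unique(unlist(graph@parents[frontier], use.names = FALSE))
    p <- p[graph@aspect[p] == asp]
    p <- setdiff(p, seen)
    seen <- c(seen, p)
    frontier <- p
  }
  setdiff(seen, c(roots, tm))
}

#' Ancestor-close a term set
#'
#' Adds all transitive ancestors (within each term's aspect) to a term set
#' and removes the three roots. Idempotent on already-closed sets. Unknown
#' ids raise an error.
#'
#' @param terms character vector of term ids.
#' @param graph an [OntologyGraph-class].
#' @return Closed character vector (roots excluded), in first-seen order.
#' @export
ancestorClosure <- function(terms, graph) {
  if (length(terms) == 0L) return(character(0L))
  res <- resolveTerms(graph, terms)
  if (anyNA(res)) stop("unknown terms: ", paste(terms[is.na(res)], collapse = ", "))
  anc <- unlist(lapply(res, termAncestors, graph = graph), use.names = FALSE)
  setdiff(unique(c(res, anc)), goRoots())
}

#' Leaf terms of an ancestor-closed set
#'
#' Members of `annots` that are not an ancestor of any other member.
#'
#' @param annots ancestor-closed character vector of term ids.
#' @param graph an [OntologyGraph-class].
#' @return Character vector of leaf term ids.
#' @export
leafTerms <- function(annots, graph) {
  if (length(annots) == 0L) return(character(0L))
  anc <- unique(unlist(lapply(annots, termAncestors, graph = graph),
                       use.names = FALSE))
  setdiff(annots, anc)
}
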