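## Deterministic synthetic fixtures: toy ontologies, annotation databases
## and hit tables with a controllable planted homology signal.
##
## Every generator is a pure function of (seed, config): it saves and
## restores the caller's RNG state and derives its own stream from the
## config seed plus a fixed per-generator offset, so individual generators
## and full pipelines are reproducible independently.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic-fixture generators
#'
#' Defaults describe a small but non-trivial homology-transfer scenario:
#' 30 terms per aspect, 100 annotated template proteins, 50 query proteins
#' with 20 candidate templates each plus 5 random noise hits, and a strong
#' planted signal (0.8) tying bit-score and identity to term sharing.
#'
#' @param seed integer RNG seed (keep below 2^31).
#' @param nTermsPerAspect terms per aspect including the root.
#' @param maxParents maximum direct parents per generated term.
#' @param nTemplateProteins annotated template proteins.
#' @param nQueryProteins query proteins.
#' @param templatesPerQuery templates retained per query (by term overlap).
#' @param meanLeafTerms mean leaf annotations per protein per aspect
#'   (counts are `1 + Poisson(meanLeafTerms - 1)`).
#' @param signalStrength in `[0, 1]`: weight of true term overlap (vs an
#'   independent uniform draw) in the latent similarity that drives
#'   bit-scores and identities.
#' @param noiseHitsPerQuery additional random templates per query.
#' @param ieaFraction fraction of annotation rows written with the
#'   electronically-inferred (IEA) evidence code, to exercise evidence
#'   filtering (those rows are decoys: the default filter drops them).
#' @return A validated `FixtureConfig` list.
#' @export
fixtureConfig <- function(seed = 1L, nTermsPerAspect = 30L, maxParents = 2L,
                          nTemplateProteins = 100L, nQueryProteins = 50L,
                          templatesPerQuery = 20L, meanLeafTerms = 3,
                          signalStrength = 0.8, noiseHitsPerQuery = 5L,
                          ieaFraction = 0.1) {
  cfg <- list(seed = as.integer(seed),
              nTermsPerAspect = as.integer(nTermsPerAspect),
              maxParents = as.integer(maxParents),
              nTemplateProteins = as.integer(nTemplateProteins),
              nQueryProteins = as.integer(nQueryProteins),
              templatesPerQuery = as.integer(templatesPerQuery),
              meanLeafTerms = meanLeafTerms,
              signalStrength = signalStrength,
              noiseHitsPerQuery = as.integer(noiseHitsPerQuery),
              ieaFraction = ieaFraction)
  counts <- c("nTermsPerAspect", "maxParents", "nTemplateProteins",
              "nQueryProteins", "templatesPerQuery")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop(nm, " must be a positive count")
  if (cfg$noiseHitsPerQuery < 0L) stop("noiseHitsPerQuery must be >= 0")
  if (cfg$signalStrength < 0 || cfg$signalStrength > 1)
    stop("signalStrength must lie in [0, 1]")
  if (cfg$ieaFraction < 0 || cfg$ieaFraction > 1)
    stop("ieaFraction must lie in [0, 1]")
  if (cfg$meanLeafTerms < 1) stop("meanLeafTerms must be >= 1")
  class(cfg) <- "FixtureConfig"
  cfg
}

#' Generate a seeded toy ontology
#'
#' Builds a random DAG per aspect rooted at the three canonical GO roots:
#' term i draws 1..`maxParents` parents among the root and earlier terms,
#' with each edge `is_a` (80%) or `part_of` (20%). Every term is reachable
#' from its root. `nTermsPerAspect = 1` yields the roots only. The same
#' config always yields the same graph; [writeOBO()] serializes it as valid
#' OBO 1.2 text that [parseOBO()] round-trips.
#'
#' @param cfg a [fixtureConfig()].
#' @return An [OntologyGraph-class].
#' @export
genToyOntology <- function(cfg) {
  stopifnot(inherits(cfg, "FixtureConfig"))
  .withSeed(cfg$seed + 101L, {
    roots <- goRoots()
    terms <- character(0L)
    parents <- list()
    rels <- list()
    aspect <- character(0L)
    nms <- character(0L)
    for (ai in seq_along(.GO_ASPECTS)) {
      a <- .GO_ASPECTS[[ai]]
      root <- roots[[a]]
      terms <- c(terms, root)
      parents[[root]] <- character(0L)
      rels[[root]] <- character(0L)
      aspect[root] <- a
      nms[root] <- c(MF = "molecular_function", BP = "biological_process",
                     CC = "cellular_component")[[a]]
      n <- cfg$nTermsPerAspect - 1L
      if (n < 1L) next
      ids <- sprintf("GO:%07d", 7000000L + ai * 100000L + seq_len(n))
      pool <- root
      for (k in seq_len(n)) {
        npar <- sample.int(min(cfg$maxParents, length(pool)), 1L)
        p <- sample(pool, npar)
        r <- ifelse(stats::runif(npar) < 0.2, "part_of", "is_a")
        tm <- ids[[k]]
        terms <- c(terms, tm)
        parents[[tm]] <- p
        rels[[tm]] <- r
        aspect[tm] <- a
        nms[tm] <- sprintf("toy %s term %d", a, k)
        pool <- c(pool, tm)
      }
    }
    ontologyGraph(terms = terms, parents = parents, aspect = aspect,
                  termNames = nms, parentRel = rels)
  })
}

#' Generate seeded toy annotations as GAF rows
#'
#' Each protein draws `1 + Poisson(meanLeafTerms - 1)` leaf terms per aspect
#' from the non-root terms of the graph (closure happens at [parseGAF()]
#' time). Evidence codes are sampled from [defaultEvidenceCodes()], except
#' that each row independently becomes an IEA decoy with probability
#' `ieaFraction` (with `ieaFraction = 1`, [parseGAF()] under the default
#' filter yields an empty database).
#'
#' @param graph an [OntologyGraph-class].
#' @param cfg a [fixtureConfig()].
#' @param n number of proteins (default `cfg$nTemplateProteins`).
#' @param prefix protein-id prefix (default `"T"`; queries use `"Q"`).
#' @param seedOffset offset added to `cfg$seed` for this generator's RNG
#'   stream (templates and queries use different offsets).
#' @return data.frame of GAF rows with columns `protein`, `qualifier`,
#'   `term`, `evidence`, `aspect`; serialize with [writeGAF()].
#' @export
genToyAnnotations <- function(graph, cfg, n = cfg$nTemplateProteins,
                              prefix = "T", seedOffset = 202L) {
  stopifnot(inherits(cfg, "FixtureConfig"))
  .withSeed(cfg$seed + seedOffset, {
    roots <- goRoots()
    aspLetter <- c(MF = "F", BP = "P", CC = "C")
    ev <- defaultEvidenceCodes()
    prot <- sprintf("%s%04d", prefix, seq_len(n))
    rows <- list()
    for (p in prot) {
      for (a in .GO_ASPECTS) {
        nonRoot <- graph@terms[graph@aspect[graph@terms] == a &
                                 !(graph@terms %in% roots)]
        if (length(nonRoot) == 0L) next
        nl <- 1L + stats::rpois(1L, max(cfg$meanLeafTerms - 1, 0))
        leaves <- sample(nonRoot, min(nl, length(nonRoot)))
        for (tm in leaves) {
          code <- if (stats::runif(1L) < cfg$ieaFraction) "IEA"
                  else sample(ev, 1L)
          rows[[length(rows) + 1L]] <-
            data.frame(protein = p, qualifier = "enables", term = tm,
                       evidence = code, aspect = aspLetter[[a]],
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0L)
      return(data.frame(protein = character(0L), qualifier = character(0L),
                        term = character(0L), evidence = character(0L),
                        aspect = character(0L)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a seeded toy hit table with planted signal
#'
#' Every query-template pair gets a latent similarity
#' `s * overlap + (1 - s) * Uniform(0,1)` with `s = signalStrength` and
#' `overlap` the fraction of the query's true terms the template shares.
#' The hit list is the top `templatesPerQuery` templates of the similarity
#' ranking -- the way a search tool reports hits: enriched for true
#' homologs but contaminated by chance high-scorers -- plus
#' `noiseHitsPerQuery` random lower-ranking templates. Bit-score
#' (`30 + 470 * latent`) and sequence identity (target fraction
#' `0.1 + 0.8 * latent` of the longer sequence) increase with the latent,
#' so with `signalStrength = 1` and no noise the top-bit-score template
#' always shares the most truth terms, and with `signalStrength = 0`
#' bit-scores are independent of term sharing. Lengths are drawn once
#' per protein from U\{100..600\}; identical-residue counts are clamped to
#' the hit invariants (`nident <= min(alnLen, qlen, tlen)`).
#'
#' @param queryDb truth [AnnotationDB-class] for the queries.
#' @param templateDb template [AnnotationDB-class].
#' @param cfg a [fixtureConfig()].
#' @return Canonical hit data.frame (see [parseHits()]).
#' @export
genToyHits <- function(queryDb, templateDb, cfg) {
  stopifnot(inherits(cfg, "FixtureConfig"))
  .withSeed(cfg$seed + 404L, {
    unionSets <- function(db) {
      prots <- sort(unique(unlist(lapply(db@annotations, names),
                                  use.names = FALSE)))
      stats::setNames(lapply(prots, function(p) {
        unique(unlist(lapply(db@annotations, function(s) s[[p]]),
                      use.names = FALSE))
      }), prots)
    }
    qSets <- unionSets(queryDb)
    tSets <- unionSets(templateDb)
    if (length(qSets) == 0L || length(tSets) == 0L)
      return(data.frame(query = character(0L), template = character(0L),
                        bitscore = numeric(0L), evalue = numeric(0L),
                        nident = numeric(0L), alnLen = numeric(0L),
                        qlen = numeric(0L), tlen = numeric(0L),
                        score = numeric(0L)))
    qlenMap <- stats::setNames(sample(100:600, length(qSets), replace = TRUE),
                               names(qSets))
    tlenMap <- stats::setNames(sample(100:600, length(tSets), replace = TRUE),
                               names(tSets))
    s <- cfg$signalStrength
    rows <- vector("list", length(qSets))
    for (qi in seq_along(qSets)) {
      q <- names(qSets)[[qi]]
      tq <- qSets[[q]]
      ov <- vapply(tSets, function(ts) length(intersect(ts, tq)), integer(1L)) /
        max(1L, length(tq))
      ## one latent similarity per template; the hit list is the top of the
      ## similarity ranking (how a search tool reports hits), plus a few
      ## random low-ranking templates that passed the search spuriously
      latentAll <- stats::setNames(
        s * ov + (1 - s) * stats::runif(length(ov)), names(tSets))
      ord <- order(-latentAll, names(tSets))
      chosen <- names(tSets)[ord][seq_len(min(cfg$templatesPerQuery,
                                              length(tSets)))]
      rest <- setdiff(names(tSets), chosen)
      if (cfg$noiseHitsPerQuery > 0L && length(rest) > 0L)
        chosen <- c(chosen, sample(rest, min(cfg$noiseHitsPerQuery,
                                             length(rest))))
      n <- length(chosen)
      latent <- unname(latentAll[chosen])
      qlen <- rep(qlenMap[[q]], n)
      tlen <- unname(tlenMap[chosen])
      alnLen <- pmax(1, round((0.5 + 0.5 * stats::runif(n)) *
                                pmin(qlen, tlen)))
      idFrac <- 0.1 + 0.8 * latent
      nident <- round(idFrac * pmax(qlen, tlen))
      nident <- pmax(0, pmin(nident, pmin(alnLen, pmin(qlen, tlen))))
      bitscore <- round(30 + 470 * latent, 1)
      evalue <- signif(qlen * tlen * 2^(-bitscore), 3)
      rows[[qi]] <- data.frame(query = q, template = chosen,
                               bitscore = bitscore, evalue = evalue,
                               nident = nident, alnLen = alnLen,
                               qlen = qlen, tlen = tlen, score = bitscore,
                               stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows)
    hits <- hits[order(hits$query, -hits$bitscore, hits$template), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    hits
  })
}

#' Simulate a complete toy benchmark
#'
#' Ontology, template annotations, query truth annotations and a planted-
#' signal hit table, generated deterministically from one config. When
#' `dir` is given, the OBO, two GAF files and the hit table are also
#' written there.
#'
#' @param cfg a [fixtureConfig()].
#' @param dir optional output directory.
#' @return List with elements `graph`, `templateGaf`, `queryGaf`
#'   (GAF row data.frames), `templateDb`, `queryDb` (parsed, filtered,
#'   closed), `hits`, and `files` (paths, when `dir` given).
#' @export
simulateBenchmark <- function(cfg = fixtureConfig(), dir = NULL) {
  graph <- genToyOntology(cfg)
  templateGaf <- genToyAnnotations(graph, cfg, n = cfg$nTemplateProteins,
                                   prefix = "T", seedOffset = 202L)
  queryGaf <- genToyAnnotations(graph, cfg, n = cfg$nQueryProteins,
                                prefix = "Q", seedOffset = 303L)
  readDb <- function(gaf) {
    path <- tempfile(fileext = ".gaf")
    on.exit(unlink(path))
    writeGAF(gaf, path)
    parseGAF(path, graph)
  }
  templateDb <- readDb(templateGaf)
  queryDb <- readDb(queryGaf)
  hits <- genToyHits(queryDb, templateDb, cfg)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(obo = file.path(dir, "toy.obo"),
               templateGaf = file.path(dir, "template.gaf"),
               queryGaf = file.path(dir, "query.gaf"),
               hits = file.path(dir, "hits.tsv"))
    writeOBO(graph, files[["obo"]])
    writeGAF(templateGaf, files[["templateGaf"]])
    writeGAF(queryGaf, files[["queryGaf"]])
    writeHits(hits, files[["hits"]])
  }
  list(graph = graph, templateGaf = templateGaf, queryGaf = queryGaf,
       templateDb = templateDb, queryDb = queryDb, hits = hits,
       files = files)
}
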