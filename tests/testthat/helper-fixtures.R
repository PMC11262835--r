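# Shared in-code fixtures and independent oracles.

mfRoot <- goRoots()[["MF"]]

# chain: c -> b -> MF root
chainGraph <- function() {
  ontologyGraph(
    terms = c(mfRoot, "GO:7000010", "GO:7000011"),
    parents = list("GO:7000010" = mfRoot, "GO:7000011" = "GO:7000010"),
    aspect = stats::setNames(rep("MF", 3L),
                             c(mfRoot, "GO:7000010", "GO:7000011")))
}

diamondOBO <- function() system.file("extdata", "diamond.obo",
                                     package = "homologyGO")
diamondGAF <- function() system.file("extdata", "diamond_synthetic.gaf",
                                     package = "homologyGO")

# minimal GAF writer: rows = list of c(protein, term, evidence[, qualifier])
writeTestGAF <- function(rows, path = tempfile(fileext = ".gaf"),
                         aspect = "F") {
  lines <- vapply(rows, function(r) {
    qual <- if (length(r) >= 4L) r[[4L]] else "enables"
    paste("db", r[[1L]], r[[1L]], qual, r[[2L]], "REF:1", r[[3L]], "",
          aspect, "", "", "protein", "taxon:0", "20240101", "db", "", "",
          sep = "\t")
  }, character(1L))
  writeLines(c("!gaf-version: 2.2", lines), path)
  path
}

# independent transitive-closure oracle: boolean reachability fixpoint on
# the explicit edge matrix, restricted to one aspect, roots excluded
bruteForceAncestors <- function(graph, term) {
  terms <- graph@terms
  n <- length(terms)
  M <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  for (tm in terms) M[tm, graph@parents[[tm]]] <- TRUE
  R <- M
  repeat {
    R2 <- R | (R %*% M > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  anc <- terms[R[term, ]]
  anc <- anc[graph@aspect[anc] == graph@aspect[[term]]]
  setdiff(anc, goRoots())
}

# naive scoring oracle: materializes every sum / max explicitly
naiveScores <- function(tpl, termSets, fn) {
  terms <- unique(unlist(termSets))
  K <- nrow(tpl)
  out <- stats::setNames(numeric(0L), character(0L))
  for (q in terms) {
    has <- vapply(seq_len(K), function(k) q %in% termSets[[k]], logical(1L))
    val <- switch(fn,
      S1 = sum(tpl$score[has]) / sum(tpl$score),
      S2 = sum((tpl$score * tpl$ID)[has]) / sum(tpl$score * tpl$ID),
      S3 = sum(tpl$qID[has]) / sum(tpl$qID),
      S4 = sum(tpl$tID[has]) / sum(tpl$tID),
      S5 = sum(tpl$aID[has]) / sum(tpl$aID),
      S6 = sum(tpl$ID[has]) / sum(tpl$ID),
      S7 = sum(has) / K,
      S8 = max(tpl$qID[has]),
      S9 = max(tpl$tID[has]),
      S10 = max(tpl$aID[has]),
      S11 = max(tpl$ID[has]))
    out[q] <- val
  }
  out[out > 0]
}

randomOracleTemplateSet <- function(seed) {
  set.seed(seed)
  K <- sample.int(10L, 1L)
  qID <- runif(K, 0.05, 1)
  tID <- runif(K, 0.05, 1)
  tpl <- data.frame(template = sprintf("T%02d", seq_len(K)),
                    score = runif(K, 10, 500),
                    qID = qID, tID = tID,
                    aID = runif(K, 0.05, 1), ID = pmin(qID, tID))
  termSets <- lapply(seq_len(K), function(i)
    sample(paste0("q", 1:8), sample.int(4L, 1L)))
  templateSet("query", "MF", tpl, termSets)
}

# template set whose term sets are ancestor-closed w.r.t. a toy graph
randomClosedTemplateSet <- function(seed) {
  graph <- genToyOntology(fixtureConfig(seed = seed, nTermsPerAspect = 15L))
  set.seed(seed + 5000L)
  nonRoot <- graph@terms[graph@aspect[graph@terms] == "MF" &
                           !(graph@terms %in% goRoots())]
  K <- sample(2:8, 1L)
  qID <- runif(K, 0.05, 1)
  tID <- runif(K, 0.05, 1)
  tpl <- data.frame(template = sprintf("T%02d", seq_len(K)),
                    score = runif(K, 10, 500),
                    qID = qID, tID = tID,
                    aID = runif(K, 0.05, 1), ID = pmin(qID, tID))
  termSets <- lapply(seq_len(K), function(i)
    ancestorClosure(sample(nonRoot, sample.int(3L, 1L)), graph))
  list(ts = templateSet("query", "MF", tpl, termSets), graph = graph)
}

# random truth + prediction maps over an abstract term universe
randomEvalInstance <- function(seed, nProteins = 6L, nTerms = 10L,
                               gridAligned = FALSE) {
  set.seed(seed)
  terms <- paste0("t", seq_len(nTerms))
  prots <- paste0("P", seq_len(nProteins))
  truth <- lapply(prots, function(p) sample(terms, sample(2:5, 1L)))
  names(truth) <- prots
  preds <- lapply(prots, function(p) {
    tm <- sample(terms, sample(1:6, 1L))
    sc <- if (gridAligned) sample(seq(0.01, 1, 0.01), length(tm), TRUE)
          else runif(length(tm), 0.01, 1)
    stats::setNames(sc, tm)
  })
  names(preds) <- prots
  list(truth = annotationDB(list(MF = truth)),
       pred = predictionSet(list(MF = preds), method = "rand"),
       terms = terms)
}
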