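test_that("generators are pure functions of seed and config", {
  cfg <- fixtureConfig(seed = 21L, nTemplateProteins = 15L,
                       nQueryProteins = 4L, templatesPerQuery = 5L)
  g1 <- genToyOntology(cfg)
  g2 <- genToyOntology(cfg)
  p1 <- tempfile(); p2 <- tempfile()
  writeOBO(g1, p1); writeOBO(g2, p2)
  expect_identical(readLines(p1), readLines(p2))

  a1 <- genToyAnnotations(g1, cfg)
  a2 <- genToyAnnotations(g2, cfg)
  expect_identical(a1, a2)

  s1 <- simulateBenchmark(cfg)
  s2 <- simulateBenchmark(cfg)
  expect_identical(s1$hits, s2$hits)
})

test_that("degenerate and constrained ontology configs are honoured", {
  rootsOnly <- genToyOntology(fixtureConfig(seed = 1L, nTermsPerAspect = 1L))
  expect_setequal(rootsOnly@terms, unname(goRoots()))

  g <- genToyOntology(fixtureConfig(seed = 2L, nTermsPerAspect = 40L,
                                    maxParents = 2L))
  expect_true(all(lengths(g@parents) <= 2L))
  ## every term reaches its aspect root: non-roots all have >= 1 parent
  nonRoot <- setdiff(g@terms, goRoots())
  expect_true(all(lengths(g@parents[nonRoot]) >= 1L))
})

test_that("an all-IEA annotation file is emptied by the default filter", {
  cfg <- fixtureConfig(seed = 3L, nTemplateProteins = 5L, ieaFraction = 1)
  g <- genToyOntology(cfg)
  gaf <- genToyAnnotations(g, cfg)
  expect_true(all(gaf$evidence == "IEA"))
  path <- tempfile()
  writeGAF(gaf, path)
  db <- parseGAF(path, g)
  expect_equal(unname(nProteins(db)), c(0L, 0L, 0L))
})

test_that("generated hits satisfy the record invariants", {
  sim <- simulateBenchmark(fixtureConfig(seed = 8L, nTemplateProteins = 25L,
                                         nQueryProteins = 6L))
  h <- sim$hits
  expect_true(all(h$nident <= h$alnLen))
  expect_true(all(h$nident <= pmin(h$qlen, h$tlen)))
  expect_true(all(h$qlen > 0 & h$tlen > 0 & h$alnLen > 0))
  expect_true(all(h$bitscore >= 0 & h$evalue >= 0))
})

test_that("full signal without noise ranks the most-sharing template first", {
  cfg <- fixtureConfig(seed = 13L, signalStrength = 1, noiseHitsPerQuery = 0L,
                       nTemplateProteins = 30L, nQueryProteins = 6L)
  sim <- simulateBenchmark(cfg)
  unionSet <- function(db, p) unique(unlist(
    lapply(annotations(db), function(s) s[[p]]), use.names = FALSE))
  for (q in unique(sim$hits$query)) {
    hq <- sim$hits[sim$hits$query == q, ]
    top <- hq$template[which.max(hq$bitscore)]
    tq <- unionSet(sim$queryDb, q)
    overlaps <- vapply(hq$template, function(tm)
      length(intersect(unionSet(sim$templateDb, tm), tq)), integer(1L))
    expect_equal(overlaps[[top]], max(overlaps))
  }
})

test_that("zero signal leaves bit-scores uncorrelated with term sharing", {
  rhos <- numeric(0L)
  for (seed in 1:100) {
    cfg <- fixtureConfig(seed = seed, signalStrength = 0,
                         nTemplateProteins = 20L, nQueryProteins = 3L,
                         templatesPerQuery = 10L, noiseHitsPerQuery = 0L)
    sim <- simulateBenchmark(cfg)
    unionSet <- function(db, p) unique(unlist(
      lapply(annotations(db), function(s) s[[p]]), use.names = FALSE))
    for (q in unique(sim$hits$query)) {
      hq <- sim$hits[sim$hits$query == q, ]
      tq <- unionSet(sim$queryDb, q)
      ov <- vapply(hq$template, function(tm)
        length(intersect(unionSet(sim$templateDb, tm), tq)), integer(1L))
      if (stats::sd(ov) > 0 && stats::sd(hq$bitscore) > 0)
        rhos <- c(rhos, suppressWarnings(
          stats::cor(hq$bitscore, ov, method = "spearman")))
    }
  }
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("time-elapsed split follows the same-aspect novelty rule", {
  g <- chainGraph()
  ccRoot <- goRoots()[["CC"]]
  gFull <- ontologyGraph(
    terms = c(g@terms, ccRoot, "GO:7000030"),
    parents = c(g@parents[setdiff(g@terms, mfRoot)],
                stats::setNames(list(ccRoot), "GO:7000030")),
    aspect = c(g@aspect[g@terms],
               stats::setNames(c("CC", "CC"), c(ccRoot, "GO:7000030"))))
  oldPath <- tempfile(); newPath <- tempfile()
  old <- c(
    paste("db", "A", "A", "enables", "GO:7000030", "R", "IDA", "", "C",
          "", "", "protein", "taxon:0", "x", "db", sep = "\t"),
    paste("db", "B", "B", "enables", "GO:7000011", "R", "IDA", "", "F",
          "", "", "protein", "taxon:0", "x", "db", sep = "\t"))
  new <- c(
    paste("db", "A", "A", "enables", "GO:7000011", "R", "IDA", "", "F",
          "", "", "protein", "taxon:0", "x", "db", sep = "\t"),
    paste("db", "A", "A", "enables", "GO:7000030", "R", "IDA", "", "C",
          "", "", "protein", "taxon:0", "x", "db", sep = "\t"),
    paste("db", "B", "B", "enables", "GO:7000010", "R", "IDA", "", "F",
          "", "", "protein", "taxon:0", "x", "db", sep = "\t"),
    paste("db", "C", "C", "enables", "GO:7000011", "R", "IDA", "", "F",
          "", "", "protein", "taxon:0", "x", "db", sep = "\t"))
  writeLines(c("!gaf-version: 2.2", old), oldPath)
  writeLines(c("!gaf-version: 2.2", new), newPath)
  warns <- testthat::capture_warnings(
    split <- buildTimeElapsedBenchmark(oldPath, newPath, gFull))
  expect_true(all(grepl("no time-elapsed targets", warns)))  # BP and CC empty
  ## A: CC in old, new MF -> MF target but not CC target
  expect_true("A" %in% split@targets$MF)
  expect_false("A" %in% split@targets$CC)
  ## B: MF in both releases -> not an MF target
  expect_false("B" %in% split@targets$MF)
  ## C: newly MF-annotated, nothing in old -> MF target
  expect_true("C" %in% split@targets$MF)
  ## truth holds new-release closed sets for targets only
  expect_setequal(names(annotations(split@truth, "MF")), c("A", "C"))
  expect_setequal(annotations(split@truth, "MF")[["A"]],
                  c("GO:7000011", "GO:7000010"))
})

test_that("targets partition into LK, NK-easy and NK-hard", {
  templateDb <- annotationDB(list(
    MF = list(T1 = "GO:7000010"),
    BP = list(A = "GO:7200001")))
  truth <- annotationDB(list(MF = list(A = "GO:7000010", B = "GO:7000010",
                                       C = "GO:7000010")))
  split <- methods::new("BenchmarkSplit",
                        targets = list(MF = c("A", "B", "C"), BP = character(0L),
                                       CC = character(0L)),
                        templateDb = templateDb, truth = truth,
                        partition = list())
  hits <- data.frame(query = "B", template = "T1", bitscore = 300,
                     evalue = 0, nident = 120, alnLen = 150, qlen = 200,
                     tlen = 180, score = 300)  # ID = 120/200 = 0.6
  part <- partitionTargets(split, hits)@partition$MF
  expect_equal(part[["A"]], "LK")       # old BP annotation, evaluated in MF
  expect_equal(part[["B"]], "NK-easy")  # best ID 0.6 > 0.5
  expect_equal(part[["C"]], "NK-hard")  # no hits at all
})

test_that("invalid fixture configs are rejected", {
  expect_error(fixtureConfig(signalStrength = 1.2), "signalStrength")
  expect_error(fixtureConfig(nTemplateProteins = 0), "positive")
  expect_error(fixtureConfig(ieaFraction = -0.1), "ieaFraction")
})
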