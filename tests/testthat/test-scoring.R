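test_that("a single annotated template gives score 1 under S1..S7", {
  ts <- templateSet("q", "MF",
    data.frame(template = "t1", score = 120, qID = 0.5, tID = 0.6,
               aID = 0.7, ID = 0.5),
    list(c("GO:7000011", "GO:7000010")))
  for (fn in paste0("S", 1:7)) {
    sc <- scoreTerms(ts, fn)
    expect_equal(unname(sc[c("GO:7000011", "GO:7000010")]), c(1, 1),
                 info = fn)
  }
})

test_that("two-template worked example matches direct summation", {
  ts <- templateSet("q", "MF",
    data.frame(template = c("T1", "T2"), score = c(100, 50),
               qID = c(0.8, 0.5), tID = c(0.8, 0.5),
               aID = c(0.8, 0.5), ID = c(0.8, 0.5)),
    list(c("qterm", "shared"), "shared"))
  expect_equal(scoreTerms(ts, "S1")[["qterm"]], 100 / 150)
  expect_equal(scoreTerms(ts, "S2")[["qterm"]], 80 / 105)
  expect_equal(scoreTerms(ts, "S7")[["qterm"]], 0.5)
  expect_equal(scoreTerms(ts, "S1")[["shared"]], 1)
})

test_that("max-identity functions take the maximum over carrying templates", {
  ts <- templateSet("q", "MF",
    data.frame(template = c("T1", "T2"), score = c(10, 20),
               qID = c(0.3, 0.7), tID = c(0.2, 0.6),
               aID = c(0.4, 0.8), ID = c(0.2, 0.6)),
    list("x", "x"))
  expect_equal(scoreTerms(ts, "S8")[["x"]], 0.7)
  expect_equal(scoreTerms(ts, "S9")[["x"]], 0.6)
  expect_equal(scoreTerms(ts, "S10")[["x"]], 0.8)
  expect_equal(scoreTerms(ts, "S11")[["x"]], 0.6)
})

test_that("all eleven functions match the naive brute-force oracle", {
  for (seed in 1:100) {
    ts <- randomOracleTemplateSet(seed)
    for (fn in scoringFunctions()) {
      got <- scoreTerms(ts, fn)
      want <- naiveScores(ts@templates, ts@termSets, fn)
      expect_equal(got[sort(names(got))], want[sort(names(want))],
                   tolerance = 1e-12, info = paste(fn, "seed", seed))
    }
  }
})

test_that("scores are DAG-monotone on ancestor-closed template annotations", {
  for (seed in 1:30) {
    x <- randomClosedTemplateSet(seed)
    for (fn in scoringFunctions()) {
      sc <- scoreTerms(x$ts, fn)
      for (tm in names(sc)) {
        for (a in termAncestors(x$graph, tm)) {
          if (a %in% names(sc))
            expect_gte(sc[[a]] + 1e-12, sc[[tm]])
        }
      }
    }
  }
})

test_that("entry order never changes a score", {
  ts <- randomOracleTemplateSet(12)
  K <- nTemplates(ts)
  set.seed(1)
  perm <- sample.int(K)
  tsPerm <- templateSet(ts@query, ts@aspect, ts@templates[perm, ],
                        ts@termSets[perm])
  for (fn in scoringFunctions()) {
    a <- scoreTerms(ts, fn)
    b <- scoreTerms(tsPerm, fn)
    expect_equal(a[sort(names(a))], b[sort(names(b))], info = fn)
  }
})

test_that("S7 scores over disjoint singleton term sets sum to one", {
  ts <- templateSet("q", "MF",
    data.frame(template = paste0("T", 1:4), score = 1:4,
               qID = rep(0.5, 4), tID = rep(0.5, 4),
               aID = rep(0.5, 4), ID = rep(0.5, 4)),
    as.list(paste0("term", 1:4)))
  expect_equal(sum(scoreTerms(ts, "S7")), 1)
})

test_that("a vanished weighted denominator emits no predictions", {
  ts <- templateSet("q", "MF",
    data.frame(template = "T1", score = 100, qID = 0, tID = 0,
               aID = 0, ID = 0),
    list("x"))
  expect_warning(sc <- scoreTerms(ts, "S2"), "zero denominator")
  expect_length(sc, 0L)
})

test_that("blendScores is the convex combination with absent terms as zero", {
  a <- c(q = 0.8, onlyA = 0.3)
  b <- c(q = 0.4, onlyB = 0.9)
  expect_equal(blendScores(a, b, 1)[names(a)], a)
  expect_equal(blendScores(a, b, 0)[names(b)], b)
  half <- blendScores(a, b, 0.5)
  expect_equal(half[["q"]], 0.6)
  expect_equal(half[["onlyA"]], 0.15)
  expect_equal(half[["onlyB"]], 0.45)
  expect_error(blendScores(a, b, 1.2), "lambda")
})

test_that("combinePredictors averages with absent-as-zero and re-propagates", {
  g <- chainGraph()
  child <- "GO:7000011"; parent <- "GO:7000010"
  p1 <- predictionSet(list(MF = list(P1 = c(0.8, 0.8) |>
    stats::setNames(c(child, parent)))), method = "A")
  pEmpty <- predictionSet(method = "B")
  halved <- combinePredictors(p1, pEmpty, 0.5, g)
  expect_equal(predictionScores(halved, "MF")[["P1"]][[child]], 0.4)
  same <- combinePredictors(p1, p1, 0.3, g)
  expect_equal(predictionScores(same, "MF")[["P1"]][sort(c(child, parent))],
               predictionScores(p1, "MF")[["P1"]][sort(c(child, parent))])
  ## disjoint single-term maps: both at half score, parents propagated
  pa <- predictionSet(list(MF = list(P1 = c(0.8) |> stats::setNames(child))))
  pb <- predictionSet(list(MF = list(P1 = c(0.6) |> stats::setNames(parent))))
  mix <- combinePredictors(pa, pb, 0.5, g)
  v <- predictionScores(mix, "MF")[["P1"]]
  expect_equal(v[[child]], 0.4)
  expect_equal(v[[parent]], 0.4)  # max(0.3, propagated 0.4)
})

test_that("predictGO drops unannotated templates and separates aspects", {
  sim <- simulateBenchmark(fixtureConfig(seed = 5L, nTemplateProteins = 20L,
                                         nQueryProteins = 4L,
                                         templatesPerQuery = 6L))
  hits <- dedupeHits(sim$hits)
  sets <- buildTemplateSets(hits, sim$templateDb, "MF")
  for (ts in sets) {
    expect_true(all(ts@templates$template %in%
                      names(annotations(sim$templateDb, "MF"))))
    expect_equal(nTemplates(ts), length(ts@termSets))
  }
  pred <- predictGO(sim$hits, sim$templateDb, fn = "S2")
  for (a in c("MF", "BP", "CC")) {
    for (v in predictionScores(pred, a)) {
      expect_true(all(v > 0 & v <= 1))
    }
  }
})

test_that("CAFA prediction files round-trip", {
  g <- chainGraph()
  pred <- predictionSet(list(MF = list(
    P1 = c(0.876, 0.9) |> stats::setNames(c("GO:7000011", "GO:7000010")),
    P2 = c(0.25) |> stats::setNames("GO:7000011"))), method = "S2")
  path <- tempfile(fileext = ".tsv")
  writeCAFA(pred, path)
  expect_true(startsWith(readLines(path, n = 1L), "#"))
  back <- readCAFA(path, g)
  expect_equal(predictionScores(back, "MF")[["P1"]][["GO:7000011"]], 0.876)
  expect_equal(predictionScores(back, "MF")[["P2"]][["GO:7000011"]], 0.25)
})
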