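## CAFA-style evaluation: Fmax, information-accretion-weighted wFmax,
## per-protein F-measures and paired method comparison.
##
## Numerical conventions: a score counts as "at or above" threshold t when
## score >= t - 1e-9, so 0.01-step grids built with seq() agree with exact
## score thresholds despite binary rounding; 0/0 harmonic means are 0.

.T_EPS <- 1e-9

#' Default CAFA threshold grid
#'
#' @return `seq(0.01, 1, by = 0.01)`.
#' @export
cafaGrid <- function() seq(0.01, 1, by = 0.01)

## weights: NULL for unweighted (all 1); otherwise named numeric IC values.
## Missing weights for encountered terms -> error listing them.
.termWeights <- function(termList, weights) {
  if (is.null(weights)) return(NULL)
  used <- unique(unlist(termList, use.names = FALSE))
  miss <- setdiff(used, names(weights))
  if (length(miss))
    stop("no information-content value for term(s): ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) " ...")
  weights
}

.wsum <- function(terms, weights) {
  if (is.null(weights)) length(terms) else sum(weights[terms])
}

#' Precision and recall at one score threshold
#'
#' Averaged per protein as in the CAFA protocol: precision over the M(t)
#' ground-truth proteins with at least one prediction scoring `>= t`, recall
#' over all N ground-truth proteins (a protein with no prediction
#' contributes 0 to recall only). Prediction and truth sets are assumed
#' ancestor-closed with roots excluded.
#'
#' @param pred a [PredictionSet-class].
#' @param truth ground-truth [AnnotationDB-class].
#' @param aspect `"MF"`, `"BP"` or `"CC"`.
#' @param t score threshold in (0, 1].
#' @param ic optional [ICTable-class] (or named numeric) for
#'   information-accretion weighting.
#' @return List with elements `pr`, `re`, `M`, `N` (and `prUndefined` flag
#'   when `M = 0`).
#' @export
precisionRecall <- function(pred, truth, aspect, t, ic = NULL) {
  aspect <- match.arg(aspect, .GO_ASPECTS)
  truthSets <- truth@annotations[[aspect]]
  N <- length(truthSets)
  if (N == 0L) stop("no ground-truth proteins in aspect ", aspect)
  predSets <- predictionScores(pred, aspect)
  weights <- .termWeights(c(truthSets, lapply(predSets, names)),
                          if (is.null(ic)) NULL else icValues(ic))
  prs <- res <- numeric(N)
  hasPred <- logical(N)
  for (i in seq_len(N)) {
    Ti <- truthSets[[i]]
    sc <- predSets[[names(truthSets)[[i]]]]
    Pi <- if (is.null(sc)) character(0L) else names(sc)[sc >= t - .T_EPS]
    hasPred[[i]] <- length(Pi) > 0L
    tp <- .wsum(intersect(Pi, Ti), weights)
    denomP <- .wsum(Pi, weights)
    denomT <- .wsum(Ti, weights)
    prs[[i]] <- if (hasPred[[i]] && denomP > 0) tp / denomP else 0
    res[[i]] <- if (denomT > 0) tp / denomT else 0
  }
  M <- sum(hasPred)
  list(pr = if (M > 0L) mean(prs[hasPred]) else 0,
       re = mean(res), M = M, N = N,
       prUndefined = M == 0L)
}

## shared Fmax/wFmax machinery
.evalCurve <- function(pred, truth, aspect, thresholds, mode, weights) {
  aspect <- match.arg(aspect, .GO_ASPECTS)
  truthSets <- truth@annotations[[aspect]]
  N <- length(truthSets)
  if (N == 0L) stop("no ground-truth proteins in aspect ", aspect)
  predSets <- predictionScores(pred, aspect)
  weights <- .termWeights(c(truthSets, lapply(predSets, names)), weights)

  if (is.null(thresholds)) {
    thresholds <- if (mode == "exact") {
      sc <- unlist(predSets[names(truthSets)], use.names = FALSE)
      sc <- sort(unique(sc[sc > 0 & sc <= 1]))
      if (length(sc) == 0L) cafaGrid() else sc
    } else cafaGrid()
  }
  if (length(thresholds) == 0L) stop("empty threshold grid")
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  thresholds <- sort(thresholds)
  nT <- length(thresholds)

  ## per protein: cumulative true-positive / predicted weight down the
  ## sorted score list, then one findInterval per protein over the grid
  prMat <- matrix(0, nrow = N, ncol = nT)
  reMat <- matrix(0, nrow = N, ncol = nT)
  hasMat <- matrix(FALSE, nrow = N, ncol = nT)
  prots <- names(truthSets)
  for (i in seq_len(N)) {
    Ti <- truthSets[[i]]
    denomT <- .wsum(Ti, weights)
    sc <- predSets[[prots[[i]]]]
    if (is.null(sc) || length(sc) == 0L) next
    ord <- order(-sc)
    sSorted <- sc[ord]
    tms <- names(sc)[ord]
    w <- if (is.null(weights)) rep(1, length(tms)) else unname(weights[tms])
    cumP <- cumsum(w)
    cumTP <- cumsum(w * (tms %in% Ti))
    ## k(t): number of predictions with score >= t
    k <- vapply(thresholds, function(th) sum(sSorted >= th - .T_EPS),
                integer(1L))
    pos <- k > 0L
    hasMat[i, ] <- pos
    kk <- pmax(k, 1L)
    denomP <- cumP[kk]
    tp <- cumTP[kk]
    prMat[i, pos] <- ifelse(denomP[pos] > 0, tp[pos] / denomP[pos], 0)
    if (denomT > 0) reMat[i, pos] <- tp[pos] / denomT
  }
  M <- as.integer(colSums(hasMat))
  pr <- ifelse(M > 0L, colSums(prMat) / pmax(M, 1L), 0)
  re <- colMeans(reMat)
  f <- ifelse(pr + re > 0, 2 * pr * re / (pr + re), 0)
  fmax <- max(f)
  tmax <- thresholds[[which(f >= fmax - 1e-15)[1L]]]
  methods::new("EvalCurve", thresholds = thresholds, precision = pr,
               recall = re, covered = M, nProteins = as.integer(N),
               fmax = fmax, tmax = tmax,
               weighted = !is.null(weights), aspect = aspect)
}

#' Fmax: maximum harmonic mean of precision and recall
#'
#' Sweeps a score threshold grid and returns the full precision/recall
#' curve together with the maximum F-measure and the smallest threshold
#' attaining it. `mode = "exact"` uses the set of distinct prediction
#' scores as the grid instead of the canonical 0.01-step CAFA grid.
#'
#' @param pred a [PredictionSet-class].
#' @param truth ground-truth [AnnotationDB-class].
#' @param aspect `"MF"`, `"BP"` or `"CC"`.
#' @param thresholds explicit grid in (0, 1], or `NULL` to use `mode`.
#' @param mode `"grid"` (0.01 steps) or `"exact"` (distinct scores).
#' @return An [EvalCurve-class].
#' @export
fmaxCurve <- function(pred, truth, aspect, thresholds = NULL,
                      mode = c("grid", "exact")) {
  .evalCurve(pred, truth, aspect, thresholds, match.arg(mode), weights = NULL)
}

#' wFmax: information-accretion-weighted Fmax
#'
#' As [fmaxCurve()], but every term indicator is weighted by the term's
#' information accretion. Terms with IC 0 contribute to neither numerator
#' nor denominator; a term without an IC entry raises an error. With a
#' constant positive IC, wFmax equals Fmax exactly.
#'
#' @inheritParams fmaxCurve
#' @param ic an [ICTable-class] or named numeric of IC values covering
#'   every truth/prediction term.
#' @return An [EvalCurve-class] with `weighted = TRUE`.
#' @export
wfmaxCurve <- function(pred, truth, aspect, ic, thresholds = NULL,
                       mode = c("grid", "exact")) {
  .evalCurve(pred, truth, aspect, thresholds, match.arg(mode),
             weights = icValues(ic))
}

#' Per-protein F-measures at a fixed threshold
#'
#' Harmonic mean of each protein's own precision and recall at threshold
#' `t`, optionally IC-weighted. Proteins with no prediction at `t` get F=0;
#' proteins with an empty truth set are excluded (with a message).
#'
#' @param pred a [PredictionSet-class].
#' @param truth ground-truth [AnnotationDB-class].
#' @param aspect aspect label.
#' @param t score threshold; a method is typically evaluated at its own
#'   Fmax-optimal threshold ([fmaxThreshold()]).
#' @param ic optional [ICTable-class] or named numeric for weighting.
#' @return Named numeric vector protein -> F.
#' @export
perProteinF <- function(pred, truth, aspect, t, ic = NULL) {
  aspect <- match.arg(aspect, .GO_ASPECTS)
  truthSets <- truth@annotations[[aspect]]
  empty <- vapply(truthSets, length, integer(1L)) == 0L
  if (any(empty)) {
    message(sum(empty), " protein(s) with empty truth set excluded")
    truthSets <- truthSets[!empty]
  }
  predSets <- predictionScores(pred, aspect)
  weights <- .termWeights(c(truthSets, lapply(predSets, names)),
                          if (is.null(ic)) NULL else icValues(ic))
  out <- vapply(names(truthSets), function(pr) {
    Ti <- truthSets[[pr]]
    sc <- predSets[[pr]]
    Pi <- if (is.null(sc)) character(0L) else names(sc)[sc >= t - .T_EPS]
    if (length(Pi) == 0L) return(0)
    tp <- .wsum(intersect(Pi, Ti), weights)
    p <- if (.wsum(Pi, weights) > 0) tp / .wsum(Pi, weights) else 0
    r <- if (.wsum(Ti, weights) > 0) tp / .wsum(Ti, weights) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1L))
  out
}

#' Paired two-tailed t-test between per-protein F vectors
#'
#' Classical paired t on the protein-aligned differences with n-1 degrees
#' of freedom, plus the per-method standard error of the mean
#' (`sd / sqrt(n)`). Zero-variance differences are flagged degenerate
#' (t and p are NA).
#'
#' @param fa,fb equal-length numeric vectors of per-protein F-measures,
#'   aligned by protein.
#' @param labels method labels for reporting.
#' @return A [MethodComparison-class].
#' @export
#' @examples
#' pairedTTest(c(0.9, 0.8, 0.7, 0.6), c(0.8, 0.6, 0.7, 0.5))
pairedTTest <- function(fa, fb, labels = c("A", "B")) {
  n <- length(fa)
  if (length(fb) != n) stop("per-protein F vectors must be aligned (equal length)")
  if (n < 2L) stop("need at least two proteins for a paired t-test")
  d <- fa - fb
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    tstat <- NA_real_
    p <- NA_real_
  } else {
    tt <- stats::t.test(fa, fb, paired = TRUE)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  methods::new("MethodComparison", labels = labels,
               perProteinF = list(fa, fb),
               meanF = c(mean(fa), mean(fb)),
               sem = stats::setNames(
                 c(stats::sd(fa), stats::sd(fb)) / sqrt(n), labels),
               tStatistic = tstat, pValue = p, df = n - 1L,
               degenerate = degenerate)
}

#' Fraction of hits annotated with a term, as a percentage
#'
#' The utility behind statements like "107 out of 344 hits are annotated
#' with the term": `100 * nAnnotated / nTotal`, rounded to `digits`
#' decimals.
#'
#' @param nAnnotated number of hits carrying the annotation.
#' @param nTotal total number of hits.
#' @param digits decimals in the reported percentage (default 1).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' annotatedHitFraction(107, 344)  # 31.1
annotatedHitFraction <- function(nAnnotated, nTotal, digits = 1L) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nAnnotated < 0 || nAnnotated > nTotal)
    stop("nAnnotated must lie in [0, nTotal]")
  round(100 * nAnnotated / nTotal, digits)
}

#' Write an evaluation report TSV
#'
#' @param rows data.frame of evaluation rows (e.g. columns aspect,
#'   scoring_function, tool_label, fmax, argmax_t, wfmax, w_argmax_t,
#'   n_targets, sem).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
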