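## Tabular hit-file parsing and sequence-identity normalisations.
##
## Canonical hit columns used throughout the package:
##   query, template, bitscore, evalue, nident, alnLen, qlen, tlen, score
## `score` is the similarity fed to the weighted scoring functions; it
## defaults to the bit-score but can be any tool-reported similarity (e.g. a
## cosine similarity for embedding-based search tools).

.OUTFMT6 <- c("query", "template", "pident", "alnLen", "mismatch", "gapopen",
              "qstart", "qend", "tstart", "tend", "evalue", "bitscore")

.HIT_DIALECTS <- list(
  blast_tab = .OUTFMT6,
  diamond_tab = .OUTFMT6,
  mmseqs_tab = .OUTFMT6,
  generic = NULL)

## round half away from zero (deterministic across platforms, unlike round())
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Parse a tabular sequence-search hit file
#'
#' Reads BLAST/DIAMOND `outfmt 6` style (or arbitrary `columnSpec`) tables
#' into the canonical hit data.frame. When only percent identity is present,
#' the identical-residue count is derived as
#' `round(pident/100 * alnLen)` (half away from zero). Query/template
#' lengths may come from `qlen`/`tlen` columns or from a separate length
#' table; rows without lengths are skipped (counted in a warning). Rows with
#' unparseable numeric fields are rejected likewise.
#'
#' @param path tab-separated hit file (no header).
#' @param dialect one of `"blast_tab"`, `"diamond_tab"`, `"mmseqs_tab"`
#'   (all the default 12-column `outfmt 6` layout) or `"generic"`
#'   (requires `columnSpec`).
#' @param columnSpec ordered character vector naming the file's columns.
#'   Recognised names: `query`, `template`, `bitscore`, `evalue`, `nident`,
#'   `pident`, `alnLen`, `qlen`, `tlen`, `score`; anything else is ignored.
#'   Mandatory: `query`, `template`, `bitscore`, `evalue`, and either
#'   `nident` or both `pident` and `alnLen`.
#' @param lengths optional sequence lengths: a named numeric vector or a
#'   two-column data.frame (id, length). Needed when the file lacks
#'   `qlen`/`tlen` columns.
#' @param scoreField which column feeds the weighted scoring functions:
#'   `"bitscore"` (default) or `"score"` (a tool-reported similarity column
#'   named `score` in `columnSpec`).
#' @return data.frame with the canonical hit columns (zero rows for an
#'   empty file).
#' @export
parseHits <- function(path,
                      dialect = c("blast_tab", "diamond_tab", "mmseqs_tab",
                                  "generic"),
                      columnSpec = NULL, lengths = NULL,
                      scoreField = c("bitscore", "score")) {
  dialect <- match.arg(dialect)
  scoreField <- match.arg(scoreField)
  if (is.null(columnSpec)) columnSpec <- .HIT_DIALECTS[[dialect]]
  if (is.null(columnSpec))
    stop("dialect 'generic' requires a columnSpec")
  for (need in c("query", "template", "bitscore", "evalue"))
    if (!need %in% columnSpec)
      stop("columnSpec is missing the mandatory column '", need, "'")
  if (!("nident" %in% columnSpec) &&
      !all(c("pident", "alnLen") %in% columnSpec))
    stop("columnSpec needs 'nident', or both 'pident' and 'alnLen'")
  if (scoreField == "score" && !("score" %in% columnSpec))
    stop("scoreField = 'score' requires a 'score' column in columnSpec")

  empty <- data.frame(query = character(0L), template = character(0L),
                      bitscore = numeric(0L), evalue = numeric(0L),
                      nident = numeric(0L), alnLen = numeric(0L),
                      qlen = numeric(0L), tlen = numeric(0L),
                      score = numeric(0L), stringsAsFactors = FALSE)
  if (!file.exists(path)) stop("hit file not found: ", path)
  if (file.size(path) == 0L) return(empty)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(empty)
  if (ncol(raw) < length(columnSpec))
    stop("hit file has ", ncol(raw), " columns but columnSpec names ",
         length(columnSpec))
  names(raw)[seq_along(columnSpec)] <- columnSpec

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  hits <- data.frame(query = raw$query, template = raw$template,
                     bitscore = num("bitscore"), evalue = num("evalue"),
                     stringsAsFactors = FALSE)
  bad <- is.na(hits$bitscore) | is.na(hits$evalue)

  if ("nident" %in% columnSpec) {
    hits$nident <- num("nident")
  } else {
    pid <- num("pident")
    al <- num("alnLen")
    hits$nident <- .roundHalfAway(pid / 100 * al)
    bad <- bad | is.na(pid)
  }
  hits$alnLen <- if ("alnLen" %in% columnSpec) num("alnLen") else NA_real_
  bad <- bad | is.na(hits$nident) | is.na(hits$alnLen)

  lookup <- NULL
  if (!is.null(lengths)) {
    if (is.data.frame(lengths))
      lengths <- stats::setNames(as.numeric(lengths[[2L]]),
                                 as.character(lengths[[1L]]))
    lookup <- lengths
  }
  getLen <- function(col, ids) {
    if (col %in% columnSpec) return(num(col))
    if (is.null(lookup)) return(rep(NA_real_, length(ids)))
    unname(lookup[ids])
  }
  hits$qlen <- getLen("qlen", hits$query)
  hits$tlen <- getLen("tlen", hits$template)

  nBad <- sum(bad)
  if (nBad > 0L)
    warning(nBad, " hit row(s) rejected: unparseable numeric fields")
  noLen <- !bad & (is.na(hits$qlen) | is.na(hits$tlen))
  if (any(noLen))
    warning(sum(noLen), " hit row(s) skipped: query/template length unavailable")
  hits <- hits[!bad & !noLen, , drop = FALSE]

  if (nrow(hits)) {
    if (any(hits$qlen <= 0 | hits$tlen <= 0 | hits$alnLen <= 0))
      stop("non-positive sequence or alignment lengths in hit file")
    ## keep the identical-residue count within its combinatorial bounds
    hits$nident <- pmin(hits$nident,
                        pmin(hits$alnLen, pmin(hits$qlen, hits$tlen)))
    hits$nident <- pmax(hits$nident, 0)
  }
  hits$score <- if (scoreField == "score") num("score")[!bad & !noLen] else
    hits$bitscore
  rownames(hits) <- NULL
  hits
}

#' Write hits in the canonical tabular layout
#'
#' Nine tab-separated columns: query, template, bitscore, evalue, nident,
#' alnLen, qlen, tlen, score. [parseHits()] with
#' `dialect = "generic", columnSpec = hitColumnSpec()` round-trips the file.
#'
#' @param hits canonical hit data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  body <- paste(hits$query, hits$template, fmt(hits$bitscore),
                format(hits$evalue, scientific = TRUE, digits = 6L),
                hits$nident, hits$alnLen, hits$qlen, hits$tlen,
                fmt(hits$score), sep = "\t")
  writeLines(body, path)
  invisible(path)
}

#' @describeIn writeHits Column spec matching the canonical layout.
#' @export
hitColumnSpec <- function() {
  c("query", "template", "bitscore", "evalue", "nident", "alnLen",
    "qlen", "tlen", "score")
}

#' Sequence-identity normalisations of hits
#'
#' Four normalisations of the identical-residue count: by query length
#' (`qID`), template length (`tID`), aligned columns (`aID`, clamped to 1
#' for dialects counting gap columns inconsistently) and the maximum of
#' query and template length (`ID`). `ID = min(qID, tID)` always.
#'
#' @param hits canonical hit data.frame (see [parseHits()]).
#' @return data.frame with columns `qID`, `tID`, `aID`, `ID` in `[0, 1]`.
#' @export
#' @examples
#' h <- data.frame(query = "q", template = "t", bitscore = 100, evalue = 0,
#'                 nident = 30, alnLen = 50, qlen = 100, tlen = 60,
#'                 score = 100)
#' identityMetrics(h)
identityMetrics <- function(hits) {
  stopifnot(all(hits$qlen > 0), all(hits$tlen > 0), all(hits$alnLen > 0))
  data.frame(qID = hits$nident / hits$qlen,
             tID = hits$nident / hits$tlen,
             aID = pmin(1, hits$nident / hits$alnLen),
             ID = hits$nident / pmax(hits$qlen, hits$tlen))
}

#' Collapse multiple HSPs per query-template pair
#'
#' Keeps one row per (query, template) pair: the highest bit-score, ties
#' broken by lowest E-value, then first occurrence. Output preserves the
#' input order of the kept rows; idempotent.
#'
#' @param hits canonical hit data.frame.
#' @param excludeSelf drop rows where query and template are the same id.
#' @return Deduplicated hit data.frame.
#' @export
dedupeHits <- function(hits, excludeSelf = FALSE) {
  if (excludeSelf) hits <- hits[hits$query != hits$template, , drop = FALSE]
  if (nrow(hits) <= 1L) {
    rownames(hits) <- NULL
    return(hits)
  }
  idx <- seq_len(nrow(hits))
  ord <- order(hits$query, hits$template, -hits$bitscore, hits$evalue, idx)
  key <- paste(hits$query, hits$template, sep = "\r")
  best <- ord[!duplicated(key[ord])]
  hits <- hits[sort(best), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
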