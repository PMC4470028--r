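#' Metaprofile: binned density of response elements around the TSS
#'
#' @slot binEdges Numeric of length B + 1: bin boundaries in nt relative
#'   to the TSS, covering exactly `[-flank, +flank]`.
#' @slot overallCounts Integer, REs per bin regardless of grade.
#' @slot overallDensity Numeric, probability mass per bin (sums to 1 when
#'   any RE was counted).
#' @slot perGradeDensity Matrix, one row per grade threshold (`ge1` ..):
#'   density of REs with grade >= threshold, each row normalized to 1
#'   (zero rows when no RE reaches the threshold).
#' @slot nRes Total REs counted.
#' @slot binWidth,flank Geometry in nt.
#' @export
setClass("Metaprofile",
  representation(
    binEdges = "numeric", overallCounts = "integer",
    overallDensity = "numeric", perGradeDensity = "matrix",
    nRes = "integer", binWidth = "integer", flank = "integer"
  )
)

setValidity("Metaprofile", function(object) {
  B <- length(object@binEdges) - 1L
  if (length(object@overallDensity) != B) return("density length must match bins")
  if (object@nRes > 0L && abs(sum(object@overallDensity) - 1) > 1e-9) {
    return("overall density must sum to 1")
  }
  if (object@binEdges[1] != -object@flank ||
      object@binEdges[length(object@binEdges)] != object@flank) {
    return("bins must cover exactly [-flank, +flank]")
  }
  TRUE
})

setMethod("show", "Metaprofile", function(object) {
  cat(sprintf("Metaprofile: %d REs in %d bins of %d nt over [%+d, %+d]\n",
              object@nRes, length(object@overallDensity), object@binWidth,
              -object@flank, object@flank))
  invisible(object)
})

#' @describeIn Metaprofile-class Long-format table: `bin_start`, `bin_end`
#'   (relative to TSS), `count`, `density`, and one `density_ge<g>` column
#'   per grade threshold.
#' @param x A `Metaprofile`.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "Metaprofile", function(x, ...) {
  B <- length(x@overallDensity)
  df <- data.frame(
    bin_start = x@binEdges[seq_len(B)],
    bin_end = x@binEdges[seq_len(B) + 1L],
    count = x@overallCounts,
    density = x@overallDensity
  )
  for (r in rownames(x@perGradeDensity)) {
    df[[paste0("density_", r)]] <- x@perGradeDensity[r, ]
  }
  df
})

#' Grade distribution of a response-element set
#'
#' @param gr A response-element [GenomicRanges::GRanges].
#' @return A data.frame with columns `grade` (1..5), `count` and
#'   `fraction` (fractions sum to 1 when any RE is present, all zero
#'   otherwise).
#' @export
gradeDistribution <- function(gr) {
  cnt <- if (length(gr)) tabulate(gr$grade, nbins = 5L) else integer(5)
  tot <- sum(cnt)
  data.frame(
    grade = 1:5,
    count = cnt,
    fraction = if (tot > 0) cnt / tot else numeric(5)
  )
}

#' TSS-centered metaprofile of response elements
#'
#' Bins the position of every RE (anchored at its interval midpoint)
#' relative to the TSS of the window it was found in.  Windows come from
#' [extractWindows()] or [buildFixture()] and carry a `tss_offset`
#' metadata column; window orientation already puts upstream at negative
#' relative positions.  Besides the overall histogram (normalized to a
#' probability distribution), one density curve per grade threshold
#' (grade >= g) is computed.
#'
#' @param gr Response elements with seqnames matching `names(windows)`.
#' @param windows A [Biostrings::DNAStringSet] with `tss_offset` metadata.
#' @param binWidth Bin width in nt (default 100); must divide `flank`.
#' @param flank Profile half-width in nt; defaults to the largest
#'   `tss_offset` rounded up to a bin multiple.
#' @param gradeThresholds Integer vector of grade thresholds (default
#'   1:5).
#' @return A [`Metaprofile-class`].  REs falling outside
#'   `[-flank, +flank)` are ignored.
#' @export
tssMetaprofile <- function(gr, windows, binWidth = 100L, flank = NULL,
                           gradeThresholds = 1:5) {
  binWidth <- as.integer(binWidth)
  stopifnot(binWidth >= 1L)
  off <- S4Vectors::mcols(windows)$tss_offset
  if (is.null(off)) stop("windows must carry a tss_offset metadata column")
  if (is.null(flank)) {
    flank <- as.integer(ceiling(max(off, 1L) / binWidth) * binWidth)
  }
  flank <- as.integer(flank)
  if (flank %% binWidth != 0L) stop("flank must be a multiple of binWidth")
  edges <- seq(-flank, flank, by = binWidth)
  B <- length(edges) - 1L

  idx <- match(as.character(GenomicRanges::seqnames(gr)), names(windows))
  if (length(gr) && anyNA(idx)) {
    stop("response elements on contigs absent from windows")
  }
  mid0 <- (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr) - 1L) %/% 2L
  rel <- mid0 - off[idx]
  inside <- rel >= -flank & rel < flank
  rel <- rel[inside]
  grades <- gr$grade[inside]

  bin <- findInterval(rel, edges, rightmost.closed = FALSE)
  countVec <- function(sel) tabulate(bin[sel], nbins = B)
  overall <- countVec(rep(TRUE, length(bin)))
  dens <- function(cnt) if (sum(cnt) > 0) cnt / sum(cnt) else numeric(B)
  perGrade <- t(vapply(gradeThresholds, function(g) dens(countVec(grades >= g)),
                       numeric(B)))
  rownames(perGrade) <- paste0("ge", gradeThresholds)

  new("Metaprofile",
    binEdges = as.numeric(edges),
    overallCounts = as.integer(overall),
    overallDensity = dens(overall),
    perGradeDensity = perGrade,
    nRes = length(rel),
    binWidth = binWidth,
    flank = flank
  )
}

#' Per-grade frequency ratio between two scanned region sets
#'
#' Compares RE frequencies (count per candidate window) between two region
#' sets scanned with the same rule table — e.g. distal open-chromatin
#' regions versus GC-matched random sequences — reusing the binomial
#' enrichment machinery of the null-model module: the second set plays the
#' role of the null.
#'
#' @param resA,resB Response-element [GenomicRanges::GRanges] of the two
#'   sets.
#' @param nA,nB Candidate-window totals of the two sets (from
#'   [countCandidateWindows()] on the underlying sequences).
#' @param labels Length-2 character, names of the sets (reporting only).
#' @return A data.frame with one row per grade: counts, frequencies, the
#'   frequency ratio A/B and the one-sided exact binomial p-value of the
#'   A count under the B frequency; `pseudocount` flags grades where B had
#'   zero REs and a 0.5 pseudocount was used.
#' @export
regionEnrichment <- function(resA, resB, nA, nB, labels = c("A", "B")) {
  stopifnot(nA > 0, nB > 0, length(labels) == 2L)
  kA <- .countByGrade(resA)
  kB <- .countByGrade(resB)
  enr <- .binomEnrichment(kA, nA, kB, nB)
  data.frame(
    grade = 1:5,
    count_a = unname(kA), freq_a = unname(kA) / nA,
    count_b = unname(kB), freq_b = unname(enr$nullFrequency),
    ratio = unname(enr$fold),
    p_value = unname(enr$pValue),
    pseudocount = unname(enr$pseudocount),
    set_a = labels[1], set_b = labels[2]
  )
}
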