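#' NullModelResult: per-grade enrichment against a sequence null model
#'
#' Holds observed and null response-element counts per grade together with
#' the number of candidate-window trials on each side, the fold enrichment
#' (observed frequency over pooled null frequency) and one-sided exact
#' binomial tail probabilities.
#'
#' @slot observed Named numeric, RE count per grade ("1".."5") in the real
#'   sequences.
#' @slot nTrials Candidate windows scanned in the real sequences.
#' @slot nullCounts Named numeric, RE count per grade pooled over all null
#'   replicates.
#' @slot nullTrials Candidate windows scanned over all null replicates.
#' @slot nullFrequency Per-grade null frequency (pseudocount-adjusted where
#'   flagged).
#' @slot foldEnrichment Observed frequency / null frequency per grade.
#' @slot pValue One-sided (greater) exact binomial tail probability per
#'   grade.
#' @slot pseudocount Logical per grade: TRUE where the null count was zero
#'   and a 0.5 pseudocount was used.
#' @slot nReplicates Number of null replicate sets.
#' @slot seed Seed used (NA if none given).
#' @slot model Label of the null generator.
#' @export
setClass("NullModelResult",
  representation(
    observed = "numeric", nTrials = "numeric",
    nullCounts = "numeric", nullTrials = "numeric",
    nullFrequency = "numeric", foldEnrichment = "numeric",
    pValue = "numeric", pseudocount = "logical",
    nReplicates = "integer", seed = "integer", model = "character"
  )
)

setValidity("NullModelResult", function(object) {
  grades <- as.character(1:5)
  for (sl in c("observed", "nullCounts", "nullFrequency", "foldEnrichment",
               "pValue", "pseudocount")) {
    if (!identical(names(slot(object, sl)), grades)) {
      return(sprintf('slot %s must be named "1".."5"', sl))
    }
  }
  if (any(object@pValue < 0 | object@pValue > 1, na.rm = TRUE)) {
    return("pValue must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "NullModelResult", function(object) {
  cat(sprintf("NullModelResult: %s null, %d replicate(s), seed %s\n",
              object@model, object@nReplicates,
              ifelse(is.na(object@seed), "none", object@seed)))
  print(as.data.frame(object), row.names = FALSE, digits = 4)
  invisible(object)
})

#' @describeIn NullModelResult-class Tabular view: one row per grade with
#'   observed/null counts and frequencies, fold enrichment and p-value.
#' @param x A `NullModelResult`.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "NullModelResult", function(x, ...) {
  data.frame(
    grade = 1:5,
    observed_count = unname(x@observed),
    observed_freq = unname(x@observed) / x@nTrials,
    null_count = unname(x@nullCounts),
    null_freq = unname(x@nullFrequency),
    fold = unname(x@foldEnrichment),
    p_value = unname(x@pValue),
    pseudocount = unname(x@pseudocount)
  )
})

#' @rdname foldEnrichment
#' @export
setGeneric("foldEnrichment", function(object) standardGeneric("foldEnrichment"))

#' @rdname pValues
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' Per-grade fold enrichment
#' @param object A [`NullModelResult-class`].
#' @return Named numeric, one value per grade.
#' @export
setMethod("foldEnrichment", "NullModelResult", function(object) object@foldEnrichment)

#' Per-grade binomial p-values
#' @param object A [`NullModelResult-class`].
#' @return Named numeric, one value per grade.
#' @export
setMethod("pValues", "NullModelResult", function(object) object@pValue)

#' Write an enrichment report as TSV
#' @param result A [`NullModelResult-class`].
#' @param path Output path.
#' @export
writeEnrichmentTsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Locally permute a sequence, preserving per-bin base composition
#'
#' Partitions the sequence into consecutive bins of `binSize` nucleotides
#' (the last bin may be shorter) and uniformly permutes the bases within
#' each bin.  Per-bin base multisets — and hence the local GC content —
#' are preserved exactly.
#'
#' @param x A single sequence (character or [Biostrings::DNAString]).
#' @param binSize Bin width in nt (default 500, minimum 2).
#' @param seed Optional integer seed for reproducibility.
#' @return The permuted sequence as a character string.
#' @export
localPermutation <- function(x, binSize = 500L, seed = NULL) {
  binSize <- as.integer(binSize)
  stopifnot(binSize >= 2L)
  s <- .prepSequence(x)
  n <- nchar(s)
  if (n < 2L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  .withSeed(seed, {
    bin <- (seq_len(n) - 1L) %/% binSize
    idx <- unlist(lapply(split(seq_len(n), bin), function(i) {
      if (length(i) > 1L) sample(i) else i
    }), use.names = FALSE)
    paste(ch[idx], collapse = "")
  })
}

#' Random sequence with fixed expected GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2.
#'
#' @param length Sequence length in nt.
#' @param gc Target GC fraction (default 0.44, the genome-wide average of
#'   human DNA).
#' @param seed Optional integer seed.
#' @return A character string.
#' @export
randomGCSequence <- function(length, gc = 0.44, seed = NULL) {
  stopifnot(gc >= 0, gc <= 1, length >= 0)
  .withSeed(seed, {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  })
}

.countByGrade <- function(gr) {
  cnt <- tabulate(gr$grade, nbins = 5L)
  names(cnt) <- as.character(1:5)
  cnt
}

.binomEnrichment <- function(k, nTrials, nullCounts, nullTrials) {
  pseudo <- nullCounts == 0
  adjCounts <- ifelse(pseudo, 0.5, nullCounts)
  p0 <- adjCounts / nullTrials
  fold <- (k / nTrials) / p0
  pv <- vapply(seq_along(k), function(i) {
    stats::pbinom(k[i] - 1, nTrials, p0[i], lower.tail = FALSE)
  }, numeric(1))
  list(nullFrequency = p0, fold = fold, pValue = pv, pseudocount = pseudo)
}

#' Per-grade enrichment of response elements against a null model
#'
#' Scans the real sequences once, generates `nReplicates` null sequence
#' sets with the chosen generator, scans each, pools the null counts, and
#' computes per-grade fold enrichments with one-sided (greater) exact
#' binomial tests.  The number of trials is the count of candidate windows
#' of the scan (all site classes, spacers and arrangements).
#'
#' @param realSeqs Character vector or [Biostrings::DNAStringSet].
#' @param nullModel `"permute"` (local permutation of the real sequences,
#'   GC-preserving), `"gc-random"` (i.i.d. sequences of the same lengths
#'   and a fixed GC content), or a function `function(seqs)` returning a
#'   character vector of null sequences.
#' @param rules A [`RuleTable-class`].
#' @param nReplicates Number of null replicate sets (default 10).
#' @param seed Optional integer seed governing all null generation.
#' @param binSize Bin size for `"permute"` (default 500 nt).
#' @param gc GC fraction for `"gc-random"` (default 0.44).
#' @param minGrade Minimum grade passed to the scanner.
#' @return A [`NullModelResult-class`].
#' @examples
#' seqs <- vapply(1:3, function(i) randomGCSequence(2000, seed = i), "")
#' enrichmentVsNull(seqs, "gc-random", nReplicates = 2, seed = 1)
#' @export
enrichmentVsNull <- function(realSeqs, nullModel = c("permute", "gc-random"),
                             rules = defaultRuleTable(), nReplicates = 10L,
                             seed = NULL, binSize = 500L, gc = 0.44,
                             minGrade = 1L) {
  if (is(realSeqs, "DNAStringSet")) realSeqs <- as.character(realSeqs)
  stopifnot(is.character(realSeqs), length(realSeqs) >= 1L)
  nReplicates <- as.integer(nReplicates)
  stopifnot(nReplicates >= 1L)
  if (is.function(nullModel)) {
    generator <- nullModel
    modelLabel <- "custom"
  } else {
    modelLabel <- match.arg(nullModel)
    generator <- switch(modelLabel,
      "permute" = function(seqs) {
        vapply(seqs, localPermutation, character(1), binSize = binSize,
               USE.NAMES = FALSE)
      },
      "gc-random" = function(seqs) {
        vapply(nchar(seqs), randomGCSequence, character(1), gc = gc,
               USE.NAMES = FALSE)
      }
    )
  }

  realSeqs <- toupper(realSeqs)
  obs <- .countByGrade(scanSet(realSeqs, rules = rules, minGrade = minGrade))
  nTrials <- countCandidateWindows(realSeqs)

  nullCounts <- stats::setNames(numeric(5), as.character(1:5))
  nullTrials <- 0
  .withSeed(seed, {
    for (r in seq_len(nReplicates)) {
      nullSeqs <- generator(realSeqs)
      nullCounts <- nullCounts +
        .countByGrade(scanSet(nullSeqs, rules = rules, minGrade = minGrade))
      nullTrials <- nullTrials + countCandidateWindows(nullSeqs)
    }
  })

  enr <- .binomEnrichment(obs, nTrials, nullCounts, nullTrials)
  new("NullModelResult",
    observed = as.numeric(obs) |> stats::setNames(as.character(1:5)),
    nTrials = nTrials,
    nullCounts = nullCounts,
    nullFrequency = stats::setNames(enr$nullFrequency, as.character(1:5)),
    foldEnrichment = stats::setNames(enr$fold, as.character(1:5)),
    pValue = stats::setNames(enr$pValue, as.character(1:5)),
    pseudocount = stats::setNames(enr$pseudocount, as.character(1:5)),
    nReplicates = nReplicates,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    model = modelLabel
  )
}
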