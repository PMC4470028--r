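# Fixture generator: backgrounds with controllable GC structure and
# response elements of requested class/grade planted at known coordinates.

.sampleConsensusSite <- function(atProb = 0.6) {
  # one consensus-conforming 20-mer (choices at every degenerate position)
  bases <- vapply(.FULL_SYMBOLS, function(sym) {
    opts <- .IUPAC[[sym]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  for (ww in list(c(5L, 6L), c(15L, 16L))) {
    if (stats::runif(1) < atProb) {
      bases[ww] <- c("A", "T")
    }
  }
  bases
}

.violatingBase <- function(fullPos) {
  opts <- setdiff(c("A", "C", "G", "T"), .IUPAC[[.FULL_SYMBOLS[fullPos]]])
  if (length(opts) == 1L) opts else sample(opts, 1L)
}

#' Sample a response element of a requested class and grade
#'
#' Rejection sampling: draw a consensus-conforming site, optionally inject
#' mismatches at randomly chosen positions and (for full sites) a spacer,
#' grade the proposal with [classifyMismatches()] + [gradeSite()], and
#' accept when the grade matches the target.  The returned sequence
#' therefore verifiably re-grades to `targetGrade` under `rules`.  Half
#' sites are proposed without label-A/B mismatches so that sampled sites
#' are reportable under the default half-site filter.
#'
#' @param siteClass `"full"`, `"3Q"` or `"half"`.
#' @param targetGrade Integer 1..5; must not exceed the class ceiling.
#' @param rules A [`RuleTable-class`].
#' @param seed Optional integer seed.
#' @param maxTries Attempts before giving up (default 10000).
#' @return A list with `sequence` (spacer bases included for full sites),
#'   `site` (spacer-free), `siteClass`, `arrangement` (3Q sites are
#'   sampled in the "left" arrangement), `spacer`, `grade` and `penalty`.
#' @examples
#' sampleREWithGrade("full", 5, seed = 1)$sequence
#' @export
sampleREWithGrade <- function(siteClass = c("full", "3Q", "half"), targetGrade,
                              rules = defaultRuleTable(), seed = NULL,
                              maxTries = 10000L) {
  siteClass <- match.arg(siteClass)
  targetGrade <- as.integer(targetGrade)
  stopifnot(targetGrade >= 1L, targetGrade <= 5L)
  ceilingG <- rules@classCeilings[[siteClass]]
  if (targetGrade > ceilingG) {
    stop(sprintf("grade %d is unreachable for class %s (ceiling %d)",
                 targetGrade, siteClass, ceilingG))
  }
  map <- .SITE_DEFS[[.siteDefKey(siteClass, "left")]]$map
  misPool <- if (siteClass == "half" && rules@dropHalfSitesWithCoreMismatch) {
    map[!(.FULL_LABELS[map] %in% c("A", "B"))]
  } else {
    map
  }
  spacerPool <- if (siteClass != "full") 0L
    else if (targetGrade >= 4L) c(0L, 0L, 0L, 1L)
    else if (targetGrade == 3L) 0:2
    else 0:.MAX_SPACER
  maxMis <- switch(as.character(targetGrade),
                   "5" = 2L, "4" = 3L, "3" = 4L, 6L)

  .withSeed(seed, {
    for (try in seq_len(maxTries)) {
      bases <- .sampleConsensusSite()
      nMis <- sample.int(maxMis + 1L, 1L) - 1L
      if (nMis > 0L) {
        pos <- sample(misPool, min(nMis, length(misPool)))
        for (p in pos) bases[p] <- .violatingBase(p)
      }
      spacer <- if (length(spacerPool) == 1L) spacerPool else sample(spacerPool, 1L)
      site <- paste(bases[map], collapse = "")
      prof <- classifyMismatches(site, siteClass, "left")
      g <- gradeSite(prof, siteClass, spacer, rules)
      if (!is.na(g$grade) && g$grade == targetGrade) {
        seqOut <- if (siteClass == "full" && spacer > 0L) {
          paste0(substr(site, 1L, 10L),
                 paste(sample(c("A", "C", "G", "T"), spacer, replace = TRUE),
                       collapse = ""),
                 substr(site, 11L, 20L))
        } else {
          site
        }
        return(list(sequence = seqOut, site = site, siteClass = siteClass,
                    arrangement = if (siteClass == "3Q") "left" else NA_character_,
                    spacer = spacer, grade = g$grade, penalty = g$penalty))
      }
    }
    stop(sprintf("could not sample a (%s, grade %d) site in %d tries",
                 siteClass, targetGrade, maxTries))
  })
}

#' REFixture: synthetic sequences with planted response elements
#'
#' @slot sequences [Biostrings::DNAStringSet] of background windows with
#'   planted sites, with `tss_offset` metadata so the set plugs directly
#'   into [tssMetaprofile()].
#' @slot truth data.frame of planted sites: `contig`, `start`, `end`
#'   (1-based inclusive), `site_class`, `spacer`, `grade`, `sequence`.
#' @slot tss data.frame (`contig`, `tss` 0-based, `strand`, `gene_id`),
#'   one TSS per window at its center.
#' @slot seed Seed used (NA if none).
#' @export
setClass("REFixture",
  representation(sequences = "DNAStringSet", truth = "data.frame",
                 tss = "data.frame", seed = "integer")
)

setMethod("show", "REFixture", function(object) {
  cat(sprintf("REFixture: %d window(s), %d planted RE(s)\n",
              length(object@sequences), nrow(object@truth)))
  if (nrow(object@truth)) {
    print(utils::head(object@truth, 5), row.names = FALSE)
    if (nrow(object@truth) > 5) cat("  ...\n")
  }
  invisible(object)
})

#' @rdname fixtureAccessors
#' @export
setGeneric("fixtureSequences", function(object) standardGeneric("fixtureSequences"))
#' @rdname fixtureAccessors
#' @export
setGeneric("fixtureTruth", function(object) standardGeneric("fixtureTruth"))
#' @rdname fixtureAccessors
#' @export
setGeneric("fixtureTss", function(object) standardGeneric("fixtureTss"))

#' Accessors for REFixture components
#'
#' @param object An [`REFixture-class`].
#' @return The planted-site sequences, truth table or TSS table.
#' @name fixtureAccessors
NULL

#' @rdname fixtureAccessors
#' @export
setMethod("fixtureSequences", "REFixture", function(object) object@sequences)
#' @rdname fixtureAccessors
#' @export
setMethod("fixtureTruth", "REFixture", function(object) object@truth)
#' @rdname fixtureAccessors
#' @export
setMethod("fixtureTss", "REFixture", function(object) object@tss)

.gcBackground <- function(n, tssPos, gcFraction, gcRamp) {
  if (is.null(gcRamp)) {
    gcv <- rep(gcFraction, n)
  } else {
    d <- abs((seq_len(n) - 1L) - tssPos)
    w <- pmax(0, 1 - d / gcRamp$halfWidth)
    gcv <- gcRamp$flankGC + (gcRamp$centerGC - gcRamp$flankGC) * w
  }
  isGC <- stats::runif(n) < gcv
  bases <- character(n)
  bases[isGC] <- sample(c("G", "C"), sum(isGC), replace = TRUE)
  bases[!isGC] <- sample(c("A", "T"), sum(!isGC), replace = TRUE)
  bases
}

#' Build a synthetic fixture with planted response elements
#'
#' Generates `nWindows` background windows (i.i.d. bases at `gcFraction`,
#' optionally with a TSS-centered GC ramp) and overwrites them with
#' response elements sampled to a requested class/grade at requested (or
#' uniform random, non-overlapping) positions.  The truth table records
#' every planted site; grading a recorded sequence with `rules`
#' reproduces its intended grade by construction, and every placement is
#' verified against the scanner in its local sequence context (background
#' bases can extend or shadow a planted site with an equally good
#' overlapping call, in which case the placement is re-drawn).  Background
#' sequence can still contain additional, incidental REs elsewhere;
#' downstream recovery checks match on truth coordinates.
#'
#' @param plantings data.frame with columns `site_class`, `grade`, `count`
#'   and optionally `position` (site start relative to the TSS;
#'   NA = uniform random placement).
#' @param nWindows Number of background windows (default 10).
#' @param windowLength Window length in nt (default 20000, emulating a
#'   -10 kb..+10 kb promoter window).
#' @param gcFraction Background GC content (default 0.44).
#' @param gcRamp Optional list `(centerGC, flankGC, halfWidth)` describing
#'   a piecewise-linear GC enrichment around the TSS.
#' @param rules Rule table used to sample and verify planted sites.
#' @param seed Optional integer seed; the fixture is byte-identical under
#'   the same seed.
#' @return An [`REFixture-class`].
#' @examples
#' fx <- buildFixture(data.frame(site_class = "full", grade = 5, count = 3),
#'                    nWindows = 2, windowLength = 2000, seed = 1)
#' fixtureTruth(fx)
#' @export
buildFixture <- function(plantings = NULL, nWindows = 10L, windowLength = 20000L,
                         gcFraction = 0.44, gcRamp = NULL,
                         rules = defaultRuleTable(), seed = NULL) {
  nWindows <- as.integer(nWindows)
  windowLength <- as.integer(windowLength)
  stopifnot(nWindows >= 1L, windowLength >= 30L)
  if (!is.null(gcRamp)) {
    stopifnot(all(c("centerGC", "flankGC", "halfWidth") %in% names(gcRamp)))
  }
  if (!is.null(plantings)) {
    stopifnot(all(c("site_class", "grade", "count") %in% names(plantings)))
    if (!"position" %in% names(plantings)) plantings$position <- NA_integer_
  }
  tssPos <- windowLength %/% 2L

  .withSeed(seed, {
    wins <- vapply(seq_len(nWindows), function(i) {
      paste(.gcBackground(windowLength, tssPos, gcFraction, gcRamp), collapse = "")
    }, character(1))
    names(wins) <- sprintf("w%03d", seq_len(nWindows))

    occupied <- lapply(seq_len(nWindows), function(i) {
      matrix(integer(0), ncol = 2)
    })

    # a planting only counts as ground truth if the scanner recovers it at
    # its coordinates in local sequence context: background bases can
    # extend or shadow a planted site (e.g. spell an equally good
    # overlapping site), so each placement is verified on the surrounding
    # slice and re-drawn if the background wins
    margin <- 40L
    locallyRecovered <- function(win, start0, L, re) {
      a <- max(0L, start0 - margin)
      b <- min(windowLength, start0 + L + margin)
      reg <- substr(win, a + 1L, b)
      hits <- scanSequence(reg, rules = rules)
      any(GenomicRanges::start(hits) == start0 - a + 1L &
            GenomicRanges::end(hits) == start0 - a + L &
            hits$site_class == re$siteClass &
            hits$grade == re$grade)
    }

    truth <- list()
    if (!is.null(plantings)) {
      for (r in seq_len(nrow(plantings))) {
        for (k in seq_len(plantings$count[r])) {
          relPos <- plantings$position[r]
          placed <- FALSE
          for (attempt in 1:200) {
            re <- sampleREWithGrade(plantings$site_class[r], plantings$grade[r],
                                    rules = rules)
            L <- nchar(re$sequence)
            w <- sample.int(nWindows, 1L)
            start0 <- if (is.na(relPos)) {
              sample.int(windowLength - L + 1L, 1L) - 1L
            } else {
              tssPos + as.integer(relPos)
            }
            if (start0 < 0L || start0 + L > windowLength) {
              stop("planting position outside window bounds")
            }
            occ <- occupied[[w]]
            clash <- nrow(occ) > 0 &&
              any(start0 <= occ[, 2] & (start0 + L - 1L) >= occ[, 1])
            if (clash) {
              if (!is.na(relPos)) stop("requested plantings overlap at a fixed position")
              next
            }
            cand <- paste0(substr(wins[w], 1L, start0),
                           re$sequence,
                           substr(wins[w], start0 + L + 1L, windowLength))
            if (!locallyRecovered(cand, start0, L, re)) next
            occupied[[w]] <- rbind(occ, c(start0, start0 + L - 1L))
            wins[w] <- cand
            truth[[length(truth) + 1L]] <- data.frame(
              contig = names(wins)[w], start = start0 + 1L, end = start0 + L,
              site_class = re$siteClass, spacer = re$spacer, grade = re$grade,
              sequence = re$sequence, stringsAsFactors = FALSE
            )
            placed <- TRUE
            break
          }
          if (!placed) {
            stop("could not place a recoverable, non-overlapping planting")
          }
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      contig = character(0), start = integer(0), end = integer(0),
      site_class = character(0), spacer = integer(0), grade = integer(0),
      sequence = character(0), stringsAsFactors = FALSE)
    truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
    rownames(truth) <- NULL

    seqs <- Biostrings::DNAStringSet(wins)
    S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
      tss_offset = rep(tssPos, nWindows),
      contig = names(wins), tss = rep(tssPos, nWindows),
      strand = rep("+", nWindows)
    )
    new("REFixture",
      sequences = seqs,
      truth = truth,
      tss = data.frame(contig = names(wins), tss = rep(tssPos, nWindows),
                       strand = "+", gene_id = names(wins),
                       stringsAsFactors = FALSE),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  })
}

#' Write a fixture to disk
#'
#' Emits `sequences.fasta`, `truth.tsv` and `tss.tsv` (TSS positions
#' 1-based, per the TSV dialect of [readTssTable()]) into a directory.
#'
#' @param fixture An [`REFixture-class`].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  stopifnot(is(fixture, "REFixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(fixture@sequences,
                              file.path(dir, "sequences.fasta"))
  utils::write.table(fixture@truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tss <- fixture@tss
  tss$tss <- tss$tss + 1L
  utils::write.table(tss, file.path(dir, "tss.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
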