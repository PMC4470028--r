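# Sliding-window pattern search for p53 response elements.
#
# The degenerate consensus is reverse-complement symmetric position by
# position (the label map of RRRCWWGYYY is palindromic, internal quarters
# map onto internal quarters, AT cores onto AT cores, and the two 3Q
# arrangements onto each other), so every reverse-strand match coincides
# with a forward-strand match over the identical interval with identical
# penalty.  The scanner therefore enumerates the forward strand only
# (including both 3Q arrangements) and reports all hits on "+": this is
# mathematically identical to scanning both strands and collapsing each
# palindromic twin pair to a single "+" record.

.deltasFor <- function(def, spacer) {
  map <- def$map
  delta <- map - map[1L]
  if (def$site_class == "full" && spacer > 0L) {
    delta <- delta + ifelse(map > 10L, spacer, 0L)
  }
  delta
}

# per-position penalty weight for one site definition under `rules`
.positionWeights <- function(def, rules) {
  key <- .siteDefKey(def$site_class,
                     if (is.na(def$arrangement)) "left" else def$arrangement)
  cst <- .SITE_CONST[[key]]
  w <- unname(rules@labelWeights[cst$labels])
  mult <- rep(1, cst$len)
  mult[cst$internal] <- rules@internalQuarterMultiplier
  if (def$site_class == "3Q") {
    mult[cst$internal] <- mult[cst$internal] * rules@threeQuarterInternalMultiplier
  }
  w * mult
}

# Vectorized scan of one integer-coded sequence for one site definition
# and spacer length.  Returns NULL or a list of parallel vectors.
.scanDef <- function(ints, csBad, def, spacer, rules, minGrade) {
  map <- def$map
  delta <- .deltasFor(def, spacer)
  L <- delta[length(delta)] + 1L
  n <- length(ints)
  nOff <- n - L + 1L
  if (nOff < 1L) return(NULL)
  off0 <- 0:(nOff - 1L)

  hasBad <- (csBad[off0 + L + 1L] - csBad[off0 + 1L]) > 0L

  P <- length(map)
  wpos <- .positionWeights(def, rules)
  lab <- .FULL_LABELS[map]
  quarter <- ((map - 1L) %/% 5L) + 1L
  quarter <- quarter - quarter[1L] + 1L
  nQ <- quarter[P]

  S0 <- numeric(nOff)
  m <- integer(nOff)
  nd <- integer(nOff)                       # non-D mismatches
  ab <- integer(nOff)                       # A/B mismatches (half-site filter)
  qhit <- matrix(FALSE, nOff, nQ)
  for (j in seq_len(P)) {
    vals <- ints[off0 + delta[j] + 1L]
    viol <- !.ALLOWED_FULL[vals + (map[j] - 1L) * 256L]
    S0 <- S0 + wpos[j] * viol
    m <- m + viol
    if (lab[j] != "D") nd <- nd + viol
    if (lab[j] %in% c("A", "B")) ab <- ab + viol
    qhit[, quarter[j]] <- qhit[, quarter[j]] | viol
  }
  nq <- as.integer(rowSums(qhit))

  key <- .siteDefKey(def$site_class,
                     if (is.na(def$arrangement)) "left" else def$arrangement)
  cores <- .CORE_WW[[key]]
  nAT <- integer(nOff)
  for (cw in cores) {
    d1 <- cw[1L] - 1L
    d2 <- cw[2L] - 1L
    if (def$site_class == "full" && spacer > 0L) {
      if (cw[1L] > 10L) d1 <- d1 + spacer
      if (cw[2L] > 10L) d2 <- d2 + spacer
    }
    nAT <- nAT + (ints[off0 + d1 + 1L] == 65L & ints[off0 + d2 + 1L] == 84L)
  }
  bonusPer <- if (def$site_class == "full") rules@atCoreBonusFull else rules@atCoreBonusNoncanonical

  S <- pmax(0, S0 + rules@scatterSurcharge * pmax(nq - 1L, 0L) +
              rules@spacerPenalties[spacer + 1L] - nAT * bonusPer)

  idx <- findInterval(S, rules@gradeThresholds, left.open = TRUE)
  g <- 5L - idx
  g[idx >= 5L] <- NA_integer_
  exc <- m <= rules@grade5MaxMismatches & nd == 0L &
    nAT == length(cores) & spacer == 0L
  g[exc] <- 5L
  g[m >= rules@noGradeMinMismatches & nq >= rules@noGradeMinQuarters] <- NA_integer_
  if (spacer > 2L) g <- pmin(g, rules@longSpacerGradeCap)
  g <- pmin(g, rules@classCeilings[[def$site_class]])

  keep <- !hasBad & !is.na(g) & g >= minGrade
  if (def$site_class == "half" && rules@dropHalfSitesWithCoreMismatch) {
    keep <- keep & ab == 0L
  }
  if (!any(keep)) return(NULL)
  list(
    start0 = off0[keep],
    width = rep(L, sum(keep)),
    site_class = rep(def$site_class, sum(keep)),
    arrangement = rep(def$arrangement, sum(keep)),
    spacer = rep(as.integer(spacer), sum(keep)),
    n_mismatches = m[keep],
    penalty = S[keep],
    grade = g[keep]
  )
}

.prepSequence <- function(x) {
  if (is(x, "DNAString")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

# spacer-free site sequence(s); vectorized over parallel inputs
.spacerFreeSite <- function(windowSeq, siteClass, spacer) {
  out <- windowSeq
  i <- siteClass == "full" & spacer > 0L
  if (any(i)) {
    out[i] <- paste0(substring(windowSeq[i], 1L, 10L),
                     substring(windowSeq[i], 11L + spacer[i], 20L + spacer[i]))
  }
  out
}

.labelString <- function(profile) {
  if (!length(profile$positions)) return("O")
  paste(sprintf("%s@%d", profile$labels, profile$positions), collapse = ";")
}

#' Scan a sequence for graded p53 response elements
#'
#' Slides the full-site search (every spacer 0..13), both 3Q arrangements
#' and the half-site search over the sequence, grades every candidate
#' window with the rule table, discards ungraded and sub-threshold hits,
#' and (optionally) resolves overlapping hits into a final call set.
#' Windows containing any non-A/C/G/T character are skipped.  Coordinates
#' follow the usual Bioconductor convention (1-based, inclusive); all hits
#' are reported on "+" because the degenerate consensus is
#' reverse-complement symmetric, making reverse-strand matches coincide
#' with forward-strand matches over the same interval.
#'
#' @param x A single sequence: character string or [Biostrings::DNAString].
#'   Lowercase (soft-masked) bases are uppercased before scanning.
#' @param rules A [`RuleTable-class`].
#' @param minGrade Minimum reported grade (1..5).
#' @param resolve When TRUE (default), apply [resolveOverlaps()]; when
#'   FALSE, return every graded candidate window (two 3Q arrangements over
#'   the same interval are still collapsed to the better-scoring one).
#' @param contig Sequence name used in the returned object.
#' @return A [GenomicRanges::GRanges] with metadata columns `site_class`
#'   (`full`/`3Q`/`half`), `spacer_length`, `sequence` (matched bases,
#'   spacer included for full sites), `n_mismatches`, `mismatch_labels`
#'   (compact, e.g. `"D@1;A@14"`, `"O"` for none), `penalty`, `grade` and
#'   `arrangement` (3Q only), sorted by start.
#' @examples
#' scanSequence("GGGCATGTCCGGGCATGTCC")
#' @seealso [scanSet()], [resolveOverlaps()], [enumerateCandidates()]
#' @export
scanSequence <- function(x, rules = defaultRuleTable(), minGrade = 1L,
                         resolve = TRUE, contig = "seq1") {
  stopifnot(is(rules, "RuleTable"))
  minGrade <- as.integer(minGrade)
  stopifnot(minGrade >= 1L, minGrade <= 5L)
  seq <- .prepSequence(x)
  n <- nchar(seq)
  empty <- .emptyREGRanges()
  if (n < 10L) return(empty)

  ints <- as.integer(charToRaw(seq))
  csBad <- c(0L, cumsum(!.IS_ACGT[ints]))

  parts <- list()
  for (def in .SITE_DEFS) {
    spacers <- if (def$site_class == "full") 0:.MAX_SPACER else 0L
    for (sp in spacers) {
      parts[[length(parts) + 1L]] <- .scanDef(ints, csBad, def, sp, rules, minGrade)
    }
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(empty)

  start0 <- unlist(lapply(parts, `[[`, "start0"))
  width <- unlist(lapply(parts, `[[`, "width"))
  hit <- S4Vectors::DataFrame(
    site_class = unlist(lapply(parts, `[[`, "site_class")),
    spacer_length = unlist(lapply(parts, `[[`, "spacer")),
    sequence = substring(seq, start0 + 1L, start0 + width),
    n_mismatches = unlist(lapply(parts, `[[`, "n_mismatches")),
    mismatch_labels = NA_character_,
    penalty = unlist(lapply(parts, `[[`, "penalty")),
    grade = unlist(lapply(parts, `[[`, "grade")),
    arrangement = unlist(lapply(parts, `[[`, "arrangement"))
  )
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = start0 + 1L, width = width),
    strand = "+"
  )
  S4Vectors::mcols(gr) <- hit

  gr <- .dedupTwinIntervals(gr)

  # annotate mismatch labels for the (few) emitted hits
  site <- .spacerFreeSite(gr$sequence, gr$site_class, gr$spacer_length)
  gr$mismatch_labels <- vapply(seq_along(gr), function(i) {
    arr <- if (is.na(gr$arrangement[i])) "left" else gr$arrangement[i]
    .labelString(classifyMismatches(site[i], gr$site_class[i], arr))
  }, character(1))

  if (resolve) gr <- resolveOverlaps(gr)
  sort(gr)
}

.emptyREGRanges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    site_class = character(0), spacer_length = integer(0),
    sequence = character(0), n_mismatches = integer(0),
    mismatch_labels = character(0), penalty = numeric(0),
    grade = integer(0), arrangement = character(0)
  )
  gr
}

# collapse records over an identical interval and class (the two 3Q
# arrangements can both match) to the better-scoring one
.dedupTwinIntervals <- function(gr) {
  if (length(gr) < 2L) return(gr)
  arrRank <- match(gr$arrangement, c("left", "right"))
  arrRank[is.na(arrRank)] <- 0L
  o <- order(as.integer(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr),
             GenomicRanges::end(gr), match(gr$site_class, .SITE_CLASSES),
             -gr$grade, gr$penalty, arrRank)
  gr <- gr[o]
  key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr),
               GenomicRanges::end(gr), gr$site_class)
  gr[!duplicated(key)]
}

#' Scan a set of sequences
#'
#' Applies [scanSequence()] to every record of a [Biostrings::DNAStringSet]
#' (or named character vector) and concatenates the results; `scanFasta()`
#' is a convenience wrapper that reads a FASTA file first.
#'
#' @param x A [Biostrings::DNAStringSet] or (optionally named) character
#'   vector of sequences.
#' @inheritParams scanSequence
#' @return A [GenomicRanges::GRanges] with one seqlevel per input record.
#' @export
scanSet <- function(x, rules = defaultRuleTable(), minGrade = 1L, resolve = TRUE) {
  if (is(x, "DNAStringSet")) x <- as.character(x)
  stopifnot(is.character(x))
  if (!length(x)) return(.emptyREGRanges())
  nms <- names(x)
  if (is.null(nms) || anyDuplicated(nms)) nms <- paste0("seq", seq_along(x))
  res <- lapply(seq_along(x), function(i) {
    scanSequence(x[[i]], rules = rules, minGrade = minGrade,
                 resolve = resolve, contig = nms[i])
  })
  ans <- suppressWarnings(do.call(c, res))
  GenomeInfoDb::seqlevels(ans) <- nms
  sort(ans)
}

#' @rdname scanSet
#' @param path Path to a (possibly gzipped) FASTA file.
#' @export
scanFasta <- function(path, rules = defaultRuleTable(), minGrade = 1L,
                      resolve = TRUE) {
  scanSet(readFasta(path), rules = rules, minGrade = minGrade, resolve = resolve)
}

#' Enumerate candidate windows for one site class
#'
#' Lists every window the scanner would evaluate for a site class: all
#' offsets for each spacer length 0..13 (full sites), both 3Q quarter
#' arrangements, or all decamer offsets (half sites).  Windows containing
#' a non-A/C/G/T character are skipped.  This is the enumeration layer the
#' brute-force oracle in the test-suite is built on.
#'
#' @inheritParams scanSequence
#' @param siteClass `"full"`, `"3Q"` or `"half"`.
#' @return A data.frame with columns `offset` (0-based window start),
#'   `spacer`, `arrangement`, `site` (spacer-free site sequence) and
#'   `window` (full matched slice, spacer included).
#' @examples
#' nrow(enumerateCandidates(strrep("A", 25), "full"))  # 21 spacer/offset pairs
#' @export
enumerateCandidates <- function(x, siteClass = c("full", "3Q", "half")) {
  siteClass <- match.arg(siteClass)
  seq <- .prepSequence(x)
  n <- nchar(seq)
  ints <- if (n) as.integer(charToRaw(seq)) else integer(0)
  csBad <- c(0L, cumsum(!.IS_ACGT[ints]))
  out <- list()
  defs <- Filter(function(d) d$site_class == siteClass, .SITE_DEFS)
  for (def in defs) {
    spacers <- if (siteClass == "full") 0:.MAX_SPACER else 0L
    for (sp in spacers) {
      delta <- .deltasFor(def, sp)
      L <- delta[length(delta)] + 1L
      nOff <- n - L + 1L
      if (nOff < 1L) next
      off0 <- 0:(nOff - 1L)
      ok <- (csBad[off0 + L + 1L] - csBad[off0 + 1L]) == 0L
      off0 <- off0[ok]
      if (!length(off0)) next
      window <- substring(seq, off0 + 1L, off0 + L)
      out[[length(out) + 1L]] <- data.frame(
        offset = off0,
        spacer = as.integer(sp),
        arrangement = def$arrangement,
        site = .spacerFreeSite(window, siteClass, sp),
        window = window,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(offset = integer(0), spacer = integer(0),
                      arrangement = character(0), site = character(0),
                      window = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Count candidate windows of a scan
#'
#' Total number of windows the scanner evaluates over a set of sequences
#' (all classes, spacers and 3Q arrangements, N-containing windows
#' excluded).  This is the number of trials used by the binomial
#' enrichment model.
#'
#' @param x Character vector or [Biostrings::DNAStringSet] of sequences.
#' @return A single number.
#' @export
countCandidateWindows <- function(x) {
  if (is(x, "DNAStringSet")) x <- as.character(x)
  stopifnot(is.character(x))
  total <- 0
  for (s in x) {
    seq <- .prepSequence(s)
    n <- nchar(seq)
    if (n < 10L) next
    ints <- as.integer(charToRaw(seq))
    csBad <- c(0L, cumsum(!.IS_ACGT[ints]))
    for (def in .SITE_DEFS) {
      spacers <- if (def$site_class == "full") 0:.MAX_SPACER else 0L
      for (sp in spacers) {
        delta <- .deltasFor(def, sp)
        L <- delta[length(delta)] + 1L
        nOff <- n - L + 1L
        if (nOff < 1L) next
        off0 <- 0:(nOff - 1L)
        total <- total + sum((csBad[off0 + L + 1L] - csBad[off0 + 1L]) == 0L)
      }
    }
  }
  total
}

#' Resolve overlapping response-element calls
#'
#' Final-call policy applied after grading: (i) records sharing an
#' identical interval and site class are collapsed to the better-scoring
#' one (this also merges palindromic twin hits, which always score
#' identically and are reported on "+"); (ii) among mutually overlapping
#' hits of the same class, the best by grade (then lowest penalty, then
#' smallest spacer, then leftmost start) is kept greedily; (iii) 3Q and
#' half-site hits wholly contained in a kept full-site call of strictly
#' higher grade are suppressed as partial views of the stronger full site
#' (a non-canonical site graded at least as high as its full-site
#' extension is kept as an interpretation in its own right).
#'
#' @param gr A response-element [GenomicRanges::GRanges] as produced by
#'   [scanSequence()] with `resolve = FALSE`.
#' @return The filtered, sorted GRanges.
#' @export
resolveOverlaps <- function(gr) {
  if (length(gr) < 2L) return(sort(gr))
  gr <- .dedupTwinIntervals(gr)

  pick <- function(g) {
    if (length(g) < 2L) return(g)
    o <- order(-g$grade, g$penalty, g$spacer_length,
               as.integer(GenomicRanges::seqnames(g)), GenomicRanges::start(g))
    g <- g[o]
    chr <- as.integer(GenomicRanges::seqnames(g))
    s <- GenomicRanges::start(g)
    e <- GenomicRanges::end(g)
    keep <- logical(length(g))
    for (i in seq_along(g)) {
      k <- which(keep)
      keep[i] <- !any(chr[k] == chr[i] & s[k] <= e[i] & e[k] >= s[i])
    }
    g[keep]
  }

  fulls <- pick(gr[gr$site_class == "full"])
  rest <- gr[gr$site_class != "full"]
  if (length(rest) && length(fulls)) {
    ov <- GenomicRanges::findOverlaps(rest, fulls, type = "within")
    bad <- unique(S4Vectors::queryHits(ov)[
      rest$grade[S4Vectors::queryHits(ov)] < fulls$grade[S4Vectors::subjectHits(ov)]
    ])
    if (length(bad)) rest <- rest[-bad]
  }
  threeQ <- pick(rest[rest$site_class == "3Q"])
  halves <- pick(rest[rest$site_class == "half"])
  sort(c(fulls, threeQ, halves))
}
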