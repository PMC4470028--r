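#' Classify consensus mismatches of a candidate site
#'
#' Compares a spacer-free candidate site against the degenerate consensus
#' and returns every violating position annotated with its penalty label
#' (A/B/C/D), its quarter site, and whether that quarter is internal.
#' Positions matching the degenerate symbol produce nothing; a mismatch-free
#' site has an empty profile (the "O" label).  The central WW dinucleotide
#' of every complete CWWG core present in the site is extracted as well.
#'
#' @param siteSequence Spacer-free site: a 20-mer (`"full"`), 15-mer
#'   (`"3Q"`) or 10-mer (`"half"`) over uppercase A/C/G/T.
#' @param siteClass `"full"`, `"3Q"` or `"half"`.
#' @param arrangement For 3Q sites only: `"left"` (half site followed by a
#'   quarter, consensus positions 1-15) or `"right"` (quarter followed by a
#'   half site, positions 6-20).  Ignored otherwise.
#' @return A list of class `"MismatchProfile"` with elements `positions`
#'   (1-based within the spacer-free site), `labels`, `quarters` (local
#'   quarter index), `internal` (logical), `observed` (violating bases),
#'   `coreWW` (observed central core dinucleotides, one per complete half
#'   site present), `nQuartersHit`, `siteClass` and `arrangement`.
#' @examples
#' classifyMismatches("GGGCATGTCCGGGCATGTCC", "full")   # perfect consensus
#' classifyMismatches("GGGAATGTCC", "half")             # core C -> A
#' @export
classifyMismatches <- function(siteSequence, siteClass = c("full", "3Q", "half"),
                               arrangement = c("left", "right")) {
  if (length(siteClass) > 1L) siteClass <- siteClass[1L]
  if (length(arrangement) > 1L) arrangement <- arrangement[1L]
  key <- .siteDefKey(siteClass, arrangement)
  cst <- .SITE_CONST[[key]]
  ints <- as.integer(charToRaw(siteSequence))
  if (length(ints) != cst$len) {
    stop(sprintf("siteSequence must be %d bases for class %s, got %d",
                 cst$len, siteClass, length(ints)))
  }
  if (!all(.IS_ACGT[ints])) {
    stop("ambiguous base: siteSequence must contain only uppercase A, C, G, T")
  }
  viol <- !.ALLOWED_FULL[ints + (cst$map - 1L) * 256L]
  pos <- which(viol)
  qs <- cst$localQ[pos]
  out <- list(
    positions = pos,
    labels = cst$labels[pos],
    quarters = qs,
    internal = cst$internal[pos],
    observed = if (length(pos)) substring(siteSequence, pos, pos) else character(0),
    coreWW = substring(siteSequence, cst$coreStart, cst$coreEnd),
    nQuartersHit = length(unique(qs)),
    siteClass = siteClass,
    arrangement = if (siteClass == "3Q") arrangement else NA_character_
  )
  class(out) <- "MismatchProfile"
  out
}

#' @export
print.MismatchProfile <- function(x, ...) {
  cat(sprintf("MismatchProfile: %s site, %d mismatch(es) over %d quarter(s)\n",
              x$siteClass, length(x$positions), x$nQuartersHit))
  if (length(x$positions)) {
    cat(sprintf("  %s@%d (%s, Q%d)\n", x$labels, x$positions, x$observed, x$quarters),
        sep = "")
  } else {
    cat("  label O (no mismatches)\n")
  }
  cat("  core WW:", paste(x$coreWW, collapse = ", "), "\n")
  invisible(x)
}

#' Grade a candidate site from its mismatch profile
#'
#' Applies the penalty system of a [`RuleTable-class`]: the total penalty is
#' the sum of label weights (times the internal-quarter multipliers where
#' applicable), plus the scatter surcharge for every distinct mismatched
#' quarter beyond the first, plus the spacer penalty, minus the AT-core
#' bonuses, floored at zero.  Hard rules are checked first: a site with
#' more than three mismatches spread over three or more quarters is
#' unscored, and a site with at most two label-D mismatches, all cores AT
#' and no spacer is grade 5 regardless of thresholds.  The thresholded
#' grade is then clamped by the long-spacer cap and the class ceiling.
#'
#' @param profile A `"MismatchProfile"` from [classifyMismatches()].
#' @param siteClass `"full"`, `"3Q"` or `"half"`; must agree with the
#'   profile.
#' @param spacer Spacer length in bp: 0..13 for full sites, exactly 0 for
#'   3Q and half sites.
#' @param rules A [`RuleTable-class`].
#' @return A list of class `"siteGrade"` with elements `grade` (integer 1..5,
#'   or `NA` for "no grade") and `penalty` (the total penalty score).
#' @examples
#' p <- classifyMismatches("GGGCATGTCCGGGCATGTCC", "full")
#' gradeSite(p, "full", 0, defaultRuleTable())
#' @export
gradeSite <- function(profile, siteClass = c("full", "3Q", "half"), spacer = 0L,
                      rules = defaultRuleTable()) {
  if (length(siteClass) > 1L) siteClass <- siteClass[1L]
  if (!inherits(profile, "MismatchProfile")) {
    stop("profile must come from classifyMismatches()")
  }
  if (profile$siteClass != siteClass) {
    stop(sprintf("profile is for a %s site, not %s", profile$siteClass, siteClass))
  }
  spacer <- as.integer(spacer)
  if (siteClass == "full") {
    if (spacer < 0L || spacer > .MAX_SPACER) {
      stop(sprintf("spacer must lie in 0..%d for full sites", .MAX_SPACER))
    }
  } else if (spacer != 0L) {
    stop("3Q and half sites admit no spacer")
  }

  labs <- profile$labels
  m <- length(labs)
  w <- rules@labelWeights[labs]
  mult <- rep(1, m)
  internal <- profile$internal
  if (siteClass == "3Q") {
    mult[internal] <- rules@internalQuarterMultiplier * rules@threeQuarterInternalMultiplier
  } else {
    mult[internal] <- rules@internalQuarterMultiplier
  }
  nq <- profile$nQuartersHit
  nAT <- sum(profile$coreWW == "AT")
  bonusPer <- if (siteClass == "full") rules@atCoreBonusFull else rules@atCoreBonusNoncanonical
  S <- sum(w * mult) +
    rules@scatterSurcharge * max(0L, nq - 1L) +
    rules@spacerPenalties[spacer + 1L] -
    nAT * bonusPer
  S <- max(0, S)

  if (m >= rules@noGradeMinMismatches && nq >= rules@noGradeMinQuarters) {
    g <- NA_integer_
  } else if (m <= rules@grade5MaxMismatches && all(labs == "D") &&
             all(profile$coreWW == "AT") && spacer == 0L) {
    g <- 5L
  } else {
    idx <- findInterval(S, rules@gradeThresholds, left.open = TRUE)
    g <- if (idx >= 5L) NA_integer_ else 5L - idx
  }
  if (!is.na(g)) {
    if (spacer > 2L) g <- min(g, rules@longSpacerGradeCap)
    g <- min(g, rules@classCeilings[[siteClass]])
  }
  structure(list(grade = as.integer(g), penalty = S), class = "siteGrade")
}

#' @export
print.siteGrade <- function(x, ...) {
  cat(sprintf("grade %s (penalty %g)\n",
              if (is.na(x$grade)) "none" else x$grade, x$penalty))
  invisible(x)
}
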