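# Property-check helpers over randomly sampled sites.  Each helper runs
# `n` sampled cases under the ambient RNG and returns the number of
# violations (0 = property holds on every sample).
#
# Grades are compared on a rank scale where "no grade" sits below grade 1.

.IUPAC_SETS <- list(R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
                    C = "C", G = "G")
.HALF_SYM <- c("R", "R", "R", "C", "W", "W", "G", "Y", "Y", "Y")
.FULL_SYM <- rep(.HALF_SYM, 2)
.FULL_LAB <- rep(c("D", "D", "C", "A", "B", "B", "A", "C", "D", "D"), 2)
.CLS_MAP <- list(full = 1:20, "3Q" = 1:15, half = 1:10)

gradeRank <- function(g) ifelse(is.na(g$grade), 0L, g$grade)

randConformingBases <- function(atCores = NA) {
  b <- vapply(.FULL_SYM, function(sym) {
    opts <- .IUPAC_SETS[[sym]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
  if (isTRUE(atCores)) {
    b[c(5, 6)] <- c("A", "T")
    b[c(15, 16)] <- c("A", "T")
  }
  b
}

violate <- function(bases, pos) {
  for (p in pos) {
    opts <- setdiff(c("A", "C", "G", "T"), .IUPAC_SETS[[.FULL_SYM[p]]])
    bases[p] <- if (length(opts) == 1L) opts else sample(opts, 1L)
  }
  bases
}

gradeOfBases <- function(bases, cls, spacer = 0L, rules = defaultRuleTable()) {
  site <- paste(bases[.CLS_MAP[[cls]]], collapse = "")
  gradeSite(classifyMismatches(site, cls, "left"), cls, spacer, rules)
}

# converting one consensus-matching base to a violating base never
# increases the grade
propMismatchMonotone <- function(n, rules = defaultRuleTable()) {
  bad <- 0L
  for (i in seq_len(n)) {
    cls <- sample(c("full", "3Q", "half"), 1L)
    map <- .CLS_MAP[[cls]]
    bases <- randConformingBases()
    nMis <- sample(0:3, 1L)
    if (nMis) bases <- violate(bases, sample(map, nMis))
    spacer <- if (cls == "full") sample(0:13, 1L) else 0L
    g1 <- gradeOfBases(bases, cls, spacer, rules)
    site <- paste(bases[map], collapse = "")
    matching <- setdiff(map, map[classifyMismatches(site, cls, "left")$positions])
    if (!length(matching)) next
    g2 <- gradeOfBases(violate(bases, sample(matching, 1L)), cls, spacer, rules)
    if (gradeRank(g2) > gradeRank(g1)) bad <- bad + 1L
  }
  bad
}

# grade is non-increasing in spacer length, and any spacer > 2 caps the
# grade at the long-spacer limit
propSpacerMonotone <- function(n, rules = defaultRuleTable()) {
  bad <- 0L
  for (i in seq_len(n)) {
    bases <- randConformingBases()
    nMis <- sample(0:2, 1L)
    if (nMis) bases <- violate(bases, sample(1:20, nMis))
    g <- vapply(0:13, function(sp) gradeRank(gradeOfBases(bases, "full", sp, rules)),
                integer(1))
    if (any(diff(g) > 0L)) bad <- bad + 1L
    if (any(g[4:14] > rules@longSpacerGradeCap)) bad <- bad + 1L
  }
  bad
}

# a single mismatch of a given label is at least as damaging in an
# internal quarter (Q2/Q3) as in an external one (Q1/Q4)
propInternalSeverity <- function(n, rules = defaultRuleTable()) {
  bad <- 0L
  internalPos <- 6:15
  externalPos <- c(1:5, 16:20)
  for (i in seq_len(n)) {
    lab <- sample(c("A", "B", "C", "D"), 1L)
    pin <- sample(internalPos[.FULL_LAB[internalPos] == lab], 1L)
    pex <- sample(externalPos[.FULL_LAB[externalPos] == lab], 1L)
    bases <- randConformingBases(atCores = sample(c(TRUE, FALSE), 1L))
    gin <- gradeOfBases(violate(bases, pin), "full", 0L, rules)
    gex <- gradeOfBases(violate(bases, pex), "full", 0L, rules)
    if (gradeRank(gin) > gradeRank(gex)) bad <- bad + 1L
  }
  bad
}

# k mismatches confined to one quarter grade at least as well as the same
# label multiset spread over k distinct quarters
propScatter <- function(n, rules = defaultRuleTable()) {
  bad <- 0L
  quarterPos <- function(cls) {
    map <- .CLS_MAP[[cls]]
    split(map, (map - map[1]) %/% 5L)
  }
  for (i in seq_len(n)) {
    cls <- sample(c("full", "3Q", "half"), 1L)
    qp <- quarterPos(cls)
    kMax <- min(length(qp), 4L)
    k <- sample(2:kMax, 1L)
    qGroup <- sample(seq_along(qp), 1L)
    grouped <- sample(qp[[qGroup]], k)
    labs <- .FULL_LAB[grouped]
    qSpread <- sample(seq_along(qp), k)
    spread <- vapply(seq_len(k), function(j) {
      cand <- qp[[qSpread[j]]]
      cand <- cand[.FULL_LAB[cand] == labs[j]]
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, integer(1))
    if (anyDuplicated(spread)) next
    bases <- randConformingBases(atCores = sample(c(TRUE, FALSE), 1L))
    gG <- gradeOfBases(violate(bases, grouped), cls, 0L, rules)
    gS <- gradeOfBases(violate(bases, spread), cls, 0L, rules)
    if (gradeRank(gG) < gradeRank(gS)) bad <- bad + 1L
  }
  bad
}

# replacing an AT core with any other WW pair never increases the grade
propATBonus <- function(n, rules = defaultRuleTable()) {
  bad <- 0L
  otherWW <- list(c("A", "A"), c("T", "T"), c("T", "A"))
  for (i in seq_len(n)) {
    cls <- sample(c("full", "3Q", "half"), 1L)
    map <- .CLS_MAP[[cls]]
    bases <- randConformingBases(atCores = TRUE)
    nMis <- sample(0:2, 1L)
    if (nMis) bases <- violate(bases, sample(setdiff(map, c(5, 6, 15, 16)), nMis))
    gAT <- gradeOfBases(bases, cls, 0L, rules)
    ww <- if (cls == "full") sample(list(c(5L, 6L), c(15L, 16L)), 1L)[[1]] else c(5L, 6L)
    bases[ww] <- otherWW[[sample(3L, 1L)]]
    gWW <- gradeOfBases(bases, cls, 0L, rules)
    if (gradeRank(gWW) > gradeRank(gAT)) bad <- bad + 1L
  }
  bad
}

# more than three mismatches scattered over three or more quarters is
# never scored
propNoGrade <- function(n, rules = defaultRuleTable()) {
  bad <- 0L
  for (i in seq_len(n)) {
    nMis <- sample(4:6, 1L)
    repeat {
      pos <- sample(1:20, nMis)
      if (length(unique((pos - 1L) %/% 5L)) >= 3L) break
    }
    g <- gradeOfBases(violate(randConformingBases(), pos), "full", 0L, rules)
    if (!is.na(g$grade)) bad <- bad + 1L
  }
  bad
}

# half sites never exceed grade 2 (random decamers, graded directly)
propHalfCeiling <- function(n, rules = defaultRuleTable()) {
  bad <- 0L
  for (i in seq_len(n)) {
    site <- paste(sample(c("A", "C", "G", "T"), 10L, replace = TRUE), collapse = "")
    g <- gradeSite(classifyMismatches(site, "half"), "half", 0L, rules)
    if (!is.na(g$grade) && g$grade > 2L) bad <- bad + 1L
  }
  bad
}
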