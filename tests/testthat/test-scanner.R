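GS <- GenomicRanges::start
GE <- GenomicRanges::end

test_that("the canonical consensus yields exactly one full-site grade-5 call", {
  gr <- scanSequence("GGGCATGTCCGGGCATGTCC")
  expect_length(gr, 1)
  expect_identical(gr$site_class, "full")
  expect_identical(gr$grade, 5L)
  expect_identical(gr$spacer_length, 0L)
  expect_identical(as.character(GenomicRanges::strand(gr)), "+")
  expect_identical(GS(gr), 1L)
  expect_identical(GE(gr), 20L)
  expect_identical(gr$mismatch_labels, "O")

  # its reverse complement maps to the identical forward-strand interval
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGGCATGTCCGGGCATGTCC")))
  gr2 <- scanSequence(rc)
  expect_length(gr2, 1)
  expect_identical(GS(gr2), GS(gr))
  expect_identical(gr2$grade, 5L)
})

test_that("candidate enumeration counts windows per class and skips N", {
  expect_identical(nrow(enumerateCandidates(strrep("A", 20), "full")), 1L)
  # 25-mer: sum over spacers s of (25 - (20+s) + 1) = 6+5+4+3+2+1
  expect_identical(nrow(enumerateCandidates(strrep("A", 25), "full")), 21L)
  expect_identical(nrow(enumerateCandidates("ACGTNACGT", "half")), 0L)
  # both 3Q arrangements are enumerated
  arr <- enumerateCandidates(strrep("A", 15), "3Q")$arrangement
  expect_setequal(arr, c("left", "right"))
  # countCandidateWindows agrees with class-wise enumeration
  s <- strrep("ACGT", 30)
  total <- sum(vapply(c("full", "3Q", "half"),
                      function(cl) nrow(enumerateCandidates(s, cl)), integer(1)))
  expect_equal(countCandidateWindows(s), total)
})

test_that("windows containing N are never scanned or reported", {
  base <- "GGGCATGTCCGGGCATGTCC"
  withN <- paste0(strrep("T", 30), sub("A", "N", base), strrep("T", 30))
  gr <- scanSequence(withN)
  expect_false(any(grepl("N", gr$sequence)))
  # the N killed the embedded consensus site
  expect_false(any(gr$grade == 5))
})

test_that("scan output equals the brute-force oracle on random sequences", {
  withr::with_seed(11, {
    for (i in 1:5) {
      seq <- randomGCSequence(1000, 0.44)
      gr <- scanSequence(seq, resolve = FALSE)
      expect_setequal(scanKeys(gr), oracleKeys(oracleScan(seq)))
    }
  })
})

test_that("scanning a reverse complement mirrors all calls (strand involution)", {
  withr::with_seed(12, {
    seq <- randomGCSequence(1500, 0.44)
    n <- nchar(seq)
    gr <- scanSequence(seq, resolve = FALSE)
    grRC <- scanSequence(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))), resolve = FALSE)
    keyFwd <- sprintf("%d:%d:%s:%d:%d:%g", GS(gr), GE(gr), gr$site_class,
                      gr$spacer_length, gr$grade, gr$penalty)
    keyMirror <- sprintf("%d:%d:%s:%d:%d:%g", n - GE(grRC) + 1L, n - GS(grRC) + 1L,
                         grRC$site_class, grRC$spacer_length, grRC$grade,
                         grRC$penalty)
    expect_setequal(keyFwd, keyMirror)
  })
})

test_that("reported sequences exactly reproduce the input slice", {
  withr::with_seed(13, {
    seq <- randomGCSequence(1500, 0.44)
    gr <- scanSequence(seq)
    expect_identical(gr$sequence, substring(seq, GS(gr), GE(gr)))
    # interval width encodes class and spacer
    width <- GE(gr) - GS(gr) + 1L
    expLen <- ifelse(gr$site_class == "full", 20L + gr$spacer_length,
                     ifelse(gr$site_class == "3Q", 15L, 10L))
    expect_identical(width, expLen)
  })
})

test_that("every emitted call is graded and minGrade filters", {
  withr::with_seed(14, {
    seq <- randomGCSequence(2000, 0.44)
    gr <- scanSequence(seq)
    expect_true(all(gr$grade %in% 1:5))
    gr2 <- scanSequence(seq, minGrade = 2)
    expect_true(all(gr2$grade >= 2))
    expect_setequal(scanKeys(gr2), scanKeys(gr[gr$grade >= 2]))
  })
})

test_that("overlap resolution keeps the strongest interpretation", {
  mk <- function(start, end, cls, grade, penalty, spacer = 0L) {
    g <- GenomicRanges::GRanges("c1", IRanges::IRanges(start, end), strand = "+")
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      site_class = cls, spacer_length = spacer, sequence = "N",
      n_mismatches = 0L, mismatch_labels = "O", penalty = penalty,
      grade = as.integer(grade), arrangement = NA_character_)
    g
  }
  # overlapping same-class: higher grade wins
  r <- resolveOverlaps(c(mk(1, 20, "full", 3, 4), mk(10, 29, "full", 2, 7)))
  expect_length(r, 1)
  expect_identical(r$grade, 3L)
  # grade tie: lower penalty wins
  r <- resolveOverlaps(c(mk(1, 20, "full", 3, 5), mk(10, 29, "full", 3, 4)))
  expect_identical(r$penalty, 4)
  # contained weaker sub-sites are suppressed by a stronger full site
  r <- resolveOverlaps(c(mk(1, 20, "full", 5, 0), mk(1, 10, "half", 2, 0),
                         mk(6, 20, "3Q", 3, 0)))
  expect_length(r, 1)
  expect_identical(r$site_class, "full")
  # a non-canonical site at least as strong as its containing full site
  # survives as an interpretation in its own right
  r <- resolveOverlaps(c(mk(1, 20, "full", 1, 12), mk(1, 15, "3Q", 3, 0)))
  expect_length(r, 2)
  r <- resolveOverlaps(c(mk(1, 20, "full", 3, 5), mk(1, 15, "3Q", 3, 0)))
  expect_length(r, 2)
  # disjoint hits are untouched
  r <- resolveOverlaps(c(mk(1, 20, "full", 2, 8), mk(100, 119, "full", 4, 1)))
  expect_length(r, 2)
})

test_that("degenerate inputs give empty results", {
  expect_length(scanSequence(""), 0)
  expect_length(scanSequence("ACGT"), 0)
  expect_length(scanSet(character(0)), 0)
})

test_that("multi-record scans keep per-record coordinates", {
  fx <- c(a = "GGGCATGTCCGGGCATGTCC",
          b = paste0(strrep("T", 40), "GGGCATGTCCGGGCATGTCC"))
  gr <- scanSet(fx)
  g5 <- gr[gr$grade == 5]
  expect_identical(as.character(GenomicRanges::seqnames(g5)), c("a", "b"))
  expect_identical(GS(g5), c(1L, 41L))
})
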