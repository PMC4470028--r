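consensusPfm <- function(strong = 50L, weak = 1L) {
  cons <- "GGGCATGTCCGGGCATGTCC"
  m <- matrix(weak, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:20) m[substr(cons, j, j), j] <- strong
  m
}

test_that("the Dirichlet posterior transform matches hand computation", {
  # uniform column: all log-ratios zero
  u <- matrix(25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pfmToPwm(u)@weights, matrix(0, 4, 3,
               dimnames = list(c("A", "C", "G", "T"), NULL)))

  # counts (100,0,0,0), prior 1, uniform background:
  # p(A) = (100 + 0.25)/101, entry = log2(p/0.25)
  pfm <- matrix(c(100, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  w <- pfmToPwm(pfm)@weights
  expect_equal(unname(w["A", 1]), log2((100.25 / 101) / 0.25), tolerance = 1e-12)
  expect_equal(unname(w["A", 1]), 1.98925, tolerance = 1e-3)

  # an overwhelming prior collapses the posterior onto the background
  wInf <- pfmToPwm(pfm, priorStrength = 1e9)@weights
  expect_lt(max(abs(wInf)), 1e-6)

  expect_error(pfmToPwm(matrix(-1, 4, 2)), "nonnegative")
  expect_error(pfmToPwm(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2)), "all-zero")
  expect_error(pfmToPwm(matrix(1, 4, 2), background = c(0.5, 0.5, 0, 0)))
})

test_that("normalized match scores span exactly [0, 1]", {
  pw <- pfmToPwm(consensusPfm())
  argmax <- paste(apply(pw@weights, 2, function(cc) names(which.max(cc))),
                  collapse = "")
  argmin <- paste(apply(pw@weights, 2, function(cc) names(which.min(cc))),
                  collapse = "")
  expect_identical(scoreMatch(pw, argmax), 1)
  expect_identical(scoreMatch(pw, argmin), 0)
  withr::with_seed(61, {
    for (i in 1:20) {
      wdw <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
      s <- scoreMatch(pw, wdw)
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  })
  expect_error(scoreMatch(pw, "ACGT"), "20 bases")
})

test_that("raising one base to a higher-weight base never lowers the score", {
  pw <- pfmToPwm(consensusPfm())
  withr::with_seed(62, {
    bad <- 0
    for (i in 1:100) {
      wdw <- sample(c("A", "C", "G", "T"), 20, TRUE)
      j <- sample(20, 1)
      better <- names(which(pw@weights[, j] >= pw@weights[wdw[j], j]))
      w2 <- wdw
      w2[j] <- sample(better, 1)
      if (scoreMatch(pw, paste(w2, collapse = "")) <
          scoreMatch(pw, paste(wdw, collapse = "")) - 1e-12) bad <- bad + 1
    }
    expect_identical(bad, 0)
  })
})

test_that("the transform and scoring agree with the Biostrings reference", {
  withr::with_seed(63, {
    pfm <- stats::rmultinom(8, 40, c(0.3, 0.2, 0.3, 0.2))
    storage.mode(pfm) <- "integer"
    rownames(pfm) <- c("A", "C", "G", "T")
    ref <- Biostrings::PWM(pfm, type = "log2probratio",
                           prior.params = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
    mine <- pfmToPwm(pfm)
    for (i in 1:10) {
      wdw <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
      expect_equal(scoreMatch(mine, wdw),
                   Biostrings::PWMscoreStartingAt(ref, Biostrings::DNAString(wdw), 1),
                   tolerance = 1e-9)
    }
  })
})

test_that("JASPAR text matrices parse in both layouts", {
  p1 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA9999.1 toy", "A [ 10  0  3 ]", "C [  0 12  3 ]",
               "G [  2  0  3 ]", "T [  0  0  3 ]"), p1)
  m1 <- readJasparPfm(p1)
  expect_identical(attr(m1, "id"), "MA9999.1")
  expect_identical(dim(m1), c(4L, 3L))
  expect_identical(unname(m1["A", 1]), 10)
  p2 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c("10 0 3", "0 12 3", "2 0 3", "0 0 3"), p2)
  m2 <- readJasparPfm(p2)
  expect_true(is.na(attr(m2, "id")))
  attr(m1, "id") <- attr(m2, "id") <- NULL
  expect_identical(m2, m1)
})

test_that("partial sites score at their best alignment but below full width", {
  pw <- pfmToPwm(consensusPfm())
  # a perfect 3Q matches its 15 columns perfectly, yet the full-width
  # normalization keeps it structurally below a perfect full site
  s3q <- scoreBestFit(pw, "GGGCATGTCCGGGCA")
  expect_gt(s3q, 0.5)
  expect_lt(s3q, 1)
  expect_equal(scoreBestFit(pw, "TGTCCGGGCATGTCC"), s3q, tolerance = 1e-9)
  sHalf <- scoreBestFit(pw, "GGGCATGTCC")
  expect_lt(sHalf, s3q)
  # a mismatching alignment scores below the perfect one
  expect_lt(scoreBestFit(pw, "AAAAATGTCCGGGCA"), s3q)
  expect_error(scoreBestFit(pw, strrep("A", 25)), "wider")
})

test_that("grade-vs-PWM tables separate full-width consensus from partial sites", {
  pw <- pfmToPwm(consensusPfm())
  seqs <- c(replicate(6, "GGGCATGTCCGGGCATGTCC"),
            replicate(6, "GGGCATGTCCGGGCA"))
  gr <- scanSet(stats::setNames(seqs, sprintf("s%02d", seq_along(seqs))))
  tab <- gradeVsPwmTable(gr, pw)
  expect_equal(tab$median[tab$grade == 5], 1, tolerance = 1e-9)
  # perfect 3Q sites (grade 3) sit well below the grade-5 median: the
  # over-penalization of partial sites by full-width matrices
  expect_lt(tab$median[tab$grade == 3], 0.95)
  # degenerate groups collapse to a single score
  one <- gradeVsPwmTable(gr[gr$grade == 5], pw)
  expect_equal(one$min, one$max)
})
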