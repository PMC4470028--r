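test_that("mismatch classification matches the degenerate consensus position by position", {
  p <- classifyMismatches("GGGCATGTCCGGGCATGTCC", "full")
  expect_length(p$positions, 0)
  expect_identical(p$coreWW, c("AT", "AT"))
  expect_identical(p$nQuartersHit, 0L)

  p1 <- classifyMismatches("TGGCATGTCCGGGCATGTCC", "full")
  expect_identical(p1$positions, 1L)
  expect_identical(p1$labels, "D")
  expect_identical(p1$quarters, 1L)
  expect_identical(p1$observed, "T")

  ph <- classifyMismatches("GGGAATGTCC", "half")
  expect_identical(ph$positions, 4L)
  expect_identical(ph$labels, "A")
  expect_identical(ph$quarters, 1L)

  # 3Q arrangements read different parts of the consensus
  pl <- classifyMismatches("GGGCATGTCCGGGCA", "3Q", "left")
  expect_length(pl$positions, 0)
  expect_identical(pl$coreWW, "AT")
  pr <- classifyMismatches("TGTCCGGGCATGTCC", "3Q", "right")
  expect_length(pr$positions, 0)
  expect_identical(pr$coreWW, "AT")

  expect_error(classifyMismatches("GGGCNTGTCC", "half"), "ambiguous")
  expect_error(classifyMismatches("GGGCATGTC", "half"), "10 bases")
  expect_error(classifyMismatches("gggcatgtcc", "half"), "ambiguous")
})

test_that("every consensus position carries exactly one label and quarter", {
  cm <- consensusModel()
  expect_length(cm$halfSitePattern, 10)
  expect_identical(sort(unique(cm$positionLabels)), c("A", "B", "C", "D"))
  expect_identical(max(cm$spacerRange), 13L)
  expect_identical(cm$internalQuarters, c(2L, 3L))
  # labels cover every decamer position exactly once
  expect_length(cm$positionLabels, 10)
  # per quarter: one A, one B, one C, two D
  tab <- table(cm$positionLabels[1:5])
  expect_identical(as.integer(tab[c("A", "B", "C", "D")]), c(1L, 1L, 1L, 2L))
})

test_that("AT core detection accepts only the A-then-T motif", {
  expect_true(atCorePresent("AT"))
  expect_false(atCorePresent("TA"))
  expect_false(atCorePresent("GC"))
  expect_identical(atCorePresent(c("AT", "TT", "AA")), c(TRUE, FALSE, FALSE))
  expect_error(atCorePresent("ANT"), "2-mer")
})

test_that("grading reproduces the documented categorical outcomes", {
  rt <- defaultRuleTable()
  perfect <- classifyMismatches("GGGCATGTCCGGGCATGTCC", "full")

  # mismatch-free full site with AT cores and no spacer: top grade
  expect_identical(gradeSite(perfect, "full", 0, rt)$grade, 5L)

  # >3 mismatches over 3+ quarters: unscored
  messy <- classifyMismatches("TTGCATGTCCCGGCATGTAC", "full")
  expect_gte(length(messy$positions), 4)
  expect_gte(messy$nQuartersHit, 3)
  expect_true(is.na(gradeSite(messy, "full", 0, rt)$grade))

  # long spacer: severe penalty, grade capped at 2 and below the spacer-0 grade
  g5sp <- gradeSite(perfect, "full", 5, rt)
  expect_lte(g5sp$grade, 2L)
  expect_lt(g5sp$grade, gradeSite(perfect, "full", 0, rt)$grade)

  # perfect half site with AT core tops out at the class ceiling 2
  gh <- gradeSite(classifyMismatches("GGGCATGTCC", "half"), "half", 0, rt)
  expect_identical(gh$grade, 2L)

  # perfect 3Q with AT core exceeds grade 2
  g3 <- gradeSite(classifyMismatches("GGGCATGTCCGGGCA", "3Q", "left"), "3Q", 0, rt)
  expect_identical(g3$grade, 3L)

  # grade-5 exception: two label-D mismatches, AT cores, no spacer
  twoD <- classifyMismatches("TGGCATGTCCGGGCATGTCA", "full")
  expect_identical(sort(twoD$labels), c("D", "D"))
  expect_identical(gradeSite(twoD, "full", 0, rt)$grade, 5L)

  # input validation
  expect_error(gradeSite(perfect, "full", 14, rt), "spacer")
  expect_error(gradeSite(perfect, "full", -1, rt), "spacer")
  expect_error(gradeSite(perfect, "3Q", 0, rt), "full site")
  expect_error(gradeSite(classifyMismatches("GGGCATGTCC", "half"), "half", 1, rt),
               "no spacer")
})

test_that("grading is deterministic, bit for bit", {
  rt <- defaultRuleTable()
  site <- "TGGCATGTCCCGGCATGTCC"
  g1 <- gradeSite(classifyMismatches(site, "full"), "full", 2, rt)
  g2 <- gradeSite(classifyMismatches(site, "full"), "full", 2, rt)
  expect_identical(g1, g2)
})

test_that("rule-table validity rejects inconsistent configurations", {
  expect_error(ruleTable(labelWeights = c(A = -1, B = 3, C = 2, D = 1)),
               "nonnegative")
  expect_error(ruleTable(internalQuarterMultiplier = 0.5), ">= 1")
  expect_error(ruleTable(gradeThresholds = c("5" = 0, "4" = 2, "3" = 2, "2" = 9, "1" = 14)),
               "increasing")
  expect_error(ruleTable(spacerPenalties = c(0, 3, 2, rep(8, 11))),
               "non-decreasing")
  expect_error(ruleTable(spacerPenalties = c(1, 2, 3, rep(8, 11))),
               "spacer 0")
  expect_error(ruleTable(classCeilings = c(full = 5L, "3Q" = 9L, half = 2L)),
               "1..5")
})

test_that("rule tables round-trip through YAML and the bundled default matches", {
  rt <- ruleTable(scatterSurcharge = 3, atCoreBonusFull = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeRuleTable(rt, path)
  expect_true(isTRUE(all.equal(readRuleTable(path), rt)))

  bundled <- system.file("extdata", "default_rules.yaml", package = "p53scan")
  expect_true(nzchar(bundled))
  expect_true(isTRUE(all.equal(readRuleTable(bundled), defaultRuleTable())))

  # unknown / missing keys are reported by name
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("wrong_key: 1", bad)
  expect_error(readRuleTable(bad), "wrong_key")
  y <- yaml::read_yaml(bundled)
  y$label_weights <- NULL
  yaml::write_yaml(y, bad)
  expect_error(readRuleTable(bad), "label_weights")
})
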