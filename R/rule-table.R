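#' @import methods
NULL

#' RuleTable: declarative grading configuration
#'
#' An S4 container for every tunable magnitude of the grading system:
#' per-label mismatch weights, the internal-quarter severity multipliers,
#' the scatter surcharge for mismatches spread over several quarter sites,
#' AT-core bonuses, spacer penalties, grade thresholds, the hard no-grade
#' rule, the grade-5 exception and per-class grade ceilings.
#'
#' @slot labelWeights Named numeric (`A`, `B`, `C`, `D`); nonnegative
#'   penalty per mismatch of that label.
#' @slot internalQuarterMultiplier Factor (>= 1) applied to mismatches in
#'   the internal quarters (Q2/Q3 of the full site and their images in 3Q
#'   sites).
#' @slot threeQuarterInternalMultiplier Additional factor (>= 1) stacked on
#'   top of `internalQuarterMultiplier` for internal-quarter mismatches of
#'   3Q sites, encoding their higher impact on non-canonical sites.
#' @slot scatterSurcharge Penalty added per distinct mismatched quarter
#'   beyond the first.
#' @slot atCoreBonusFull,atCoreBonusNoncanonical Penalty reduction per CWWG
#'   core whose central WW is exactly "AT", for full sites and for
#'   non-canonical (3Q/half) sites respectively.
#' @slot spacerPenalties Numeric of length 14 (spacer 0..13), non-decreasing,
#'   first element 0.
#' @slot longSpacerGradeCap Maximum grade when the spacer exceeds 2 nt.
#' @slot gradeThresholds Named numeric (`"5"` .. `"1"`): strictly increasing
#'   penalty cutoffs; a total penalty S maps to the best grade g with
#'   S <= threshold[g], and to no grade when S exceeds the grade-1 cutoff.
#' @slot classCeilings Named integer (`full`, `3Q`, `half`): maximum grade
#'   attainable by each site class.
#' @slot noGradeMinMismatches,noGradeMinQuarters The hard unscored rule: a
#'   site with at least `noGradeMinMismatches` mismatches spread over at
#'   least `noGradeMinQuarters` distinct quarters receives no grade.
#' @slot grade5MaxMismatches Maximum number of (label-D-only) mismatches
#'   admitted by the grade-5 exception.
#' @slot dropHalfSitesWithCoreMismatch When TRUE (default) half sites with
#'   any label-A or label-B mismatch are not reported at all.
#'
#' @seealso [defaultRuleTable()], [readRuleTable()], [writeRuleTable()]
#' @export
setClass("RuleTable",
  representation(
    labelWeights = "numeric",
    internalQuarterMultiplier = "numeric",
    threeQuarterInternalMultiplier = "numeric",
    scatterSurcharge = "numeric",
    atCoreBonusFull = "numeric",
    atCoreBonusNoncanonical = "numeric",
    spacerPenalties = "numeric",
    longSpacerGradeCap = "integer",
    gradeThresholds = "numeric",
    classCeilings = "integer",
    noGradeMinMismatches = "integer",
    noGradeMinQuarters = "integer",
    grade5MaxMismatches = "integer",
    dropHalfSitesWithCoreMismatch = "logical"
  )
)

setValidity("RuleTable", function(object) {
  msg <- character(0)
  lw <- object@labelWeights
  if (!identical(sort(names(lw)), c("A", "B", "C", "D"))) {
    msg <- c(msg, "labelWeights must be named A, B, C, D")
  } else if (any(lw < 0)) {
    msg <- c(msg, "labelWeights must be nonnegative")
  }
  if (object@internalQuarterMultiplier < 1) {
    msg <- c(msg, "internalQuarterMultiplier must be >= 1")
  }
  if (object@threeQuarterInternalMultiplier < 1) {
    msg <- c(msg, "threeQuarterInternalMultiplier must be >= 1 (3Q internal mismatches at least as severe as full-site ones)")
  }
  if (object@scatterSurcharge < 0) msg <- c(msg, "scatterSurcharge must be >= 0")
  if (object@atCoreBonusFull < 0 || object@atCoreBonusNoncanonical < 0) {
    msg <- c(msg, "AT-core bonuses must be >= 0")
  }
  sp <- object@spacerPenalties
  if (length(sp) != .MAX_SPACER + 1L) {
    msg <- c(msg, sprintf("spacerPenalties must have length %d (spacer 0..%d)",
                          .MAX_SPACER + 1L, .MAX_SPACER))
  } else {
    if (sp[1] != 0) msg <- c(msg, "spacerPenalties: spacer 0 must cost 0")
    if (is.unsorted(sp)) msg <- c(msg, "spacerPenalties must be non-decreasing in spacer length")
  }
  gt <- object@gradeThresholds
  if (!identical(names(gt), c("5", "4", "3", "2", "1"))) {
    msg <- c(msg, 'gradeThresholds must be named "5","4","3","2","1"')
  } else if (any(diff(gt) <= 0)) {
    msg <- c(msg, "gradeThresholds must be strictly increasing")
  }
  cc <- object@classCeilings
  if (!identical(sort(names(cc)), sort(.SITE_CLASSES))) {
    msg <- c(msg, "classCeilings must be named full, 3Q, half")
  } else if (any(cc < 1L | cc > 5L)) {
    msg <- c(msg, "classCeilings must lie in 1..5")
  }
  if (object@noGradeMinMismatches < 1L) msg <- c(msg, "noGradeMinMismatches must be >= 1")
  if (object@noGradeMinQuarters < 1L) msg <- c(msg, "noGradeMinQuarters must be >= 1")
  if (object@grade5MaxMismatches < 0L) msg <- c(msg, "grade5MaxMismatches must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a grading rule table
#'
#' All arguments default to the package's standard rule set; override any
#' subset to explore alternative penalty systems.  The defaults reproduce
#' the documented directional behaviour of the grading scheme: spacers
#' longer than two nucleotides are severely penalized and cap the grade at
#' 2, internal-quarter mismatches are more damaging than external ones
#' (and more so again for 3Q sites), mismatches grouped in one quarter
#' cost less than the same mismatches scattered across quarters, the AT
#' core is a bonus (stronger for non-canonical sites), more than three
#' mismatches on three or more quarters give no grade, and half sites
#' never exceed grade 2.
#'
#' @param labelWeights,internalQuarterMultiplier,threeQuarterInternalMultiplier,scatterSurcharge,atCoreBonusFull,atCoreBonusNoncanonical,spacerPenalties,longSpacerGradeCap,gradeThresholds,classCeilings,noGradeMinMismatches,noGradeMinQuarters,grade5MaxMismatches,dropHalfSitesWithCoreMismatch
#'   See the slot documentation of [`RuleTable-class`].
#' @return A validated [`RuleTable-class`] object.
#' @examples
#' rt <- ruleTable(scatterSurcharge = 3)
#' @export
ruleTable <- function(labelWeights = c(A = 4, B = 3, C = 2, D = 1),
                      internalQuarterMultiplier = 1.5,
                      threeQuarterInternalMultiplier = 1.25,
                      scatterSurcharge = 4,
                      atCoreBonusFull = 1,
                      atCoreBonusNoncanonical = 2,
                      spacerPenalties = c(0, 2, 3, rep(8, 11)),
                      longSpacerGradeCap = 2L,
                      gradeThresholds = c("5" = 0, "4" = 2, "3" = 5, "2" = 9, "1" = 14),
                      classCeilings = c(full = 5L, "3Q" = 3L, half = 2L),
                      noGradeMinMismatches = 4L,
                      noGradeMinQuarters = 3L,
                      grade5MaxMismatches = 2L,
                      dropHalfSitesWithCoreMismatch = TRUE) {
  new("RuleTable",
    labelWeights = labelWeights[c("A", "B", "C", "D")],
    internalQuarterMultiplier = as.numeric(internalQuarterMultiplier),
    threeQuarterInternalMultiplier = as.numeric(threeQuarterInternalMultiplier),
    scatterSurcharge = as.numeric(scatterSurcharge),
    atCoreBonusFull = as.numeric(atCoreBonusFull),
    atCoreBonusNoncanonical = as.numeric(atCoreBonusNoncanonical),
    spacerPenalties = as.numeric(spacerPenalties),
    longSpacerGradeCap = as.integer(longSpacerGradeCap),
    gradeThresholds = gradeThresholds[c("5", "4", "3", "2", "1")],
    classCeilings = vapply(c("full", "3Q", "half"), function(k) as.integer(classCeilings[[k]]), integer(1)),
    noGradeMinMismatches = as.integer(noGradeMinMismatches),
    noGradeMinQuarters = as.integer(noGradeMinQuarters),
    grade5MaxMismatches = as.integer(grade5MaxMismatches),
    dropHalfSitesWithCoreMismatch = isTRUE(dropHalfSitesWithCoreMismatch)
  )
}

#' The package's default rule table
#'
#' @return The default [`RuleTable-class`], identical to `ruleTable()` with
#'   no overrides.  A YAML serialization of the same table ships in
#'   `system.file("extdata", "default_rules.yaml", package = "p53scan")`.
#' @export
defaultRuleTable <- function() ruleTable()

setMethod("show", "RuleTable", function(object) {
  cat("RuleTable (p53 response element grading)\n")
  cat("  label weights:      ",
      paste(sprintf("%s=%g", names(object@labelWeights), object@labelWeights), collapse = " "), "\n")
  cat("  internal multiplier:", object@internalQuarterMultiplier,
      " (3Q extra:", object@threeQuarterInternalMultiplier, ")\n")
  cat("  scatter surcharge:  ", object@scatterSurcharge, "\n")
  cat("  AT-core bonus:      ", object@atCoreBonusFull, "(full) /",
      object@atCoreBonusNoncanonical, "(3Q, half)\n")
  cat("  spacer penalties:   ", paste(object@spacerPenalties, collapse = " "), "\n")
  cat("  grade thresholds:   ",
      paste(sprintf("%s<=%g", names(object@gradeThresholds), object@gradeThresholds), collapse = " "), "\n")
  cat("  class ceilings:     ",
      paste(sprintf("%s=%d", names(object@classCeilings), object@classCeilings), collapse = " "), "\n")
  invisible(object)
})

# flat-key serialization schema shared by the reader and writer
.RULE_YAML_KEYS <- c(
  "label_weights", "internal_quarter_multiplier",
  "three_quarter_internal_multiplier", "scatter_surcharge",
  "at_core_bonus_full", "at_core_bonus_noncanonical", "spacer_penalties",
  "long_spacer_grade_cap", "grade_thresholds", "class_ceilings",
  "no_grade_min_mismatches", "no_grade_min_quarters",
  "grade5_max_mismatches", "drop_half_sites_with_core_mismatch"
)

#' Read / write a rule table as YAML
#'
#' The on-disk schema is a flat mapping with keys `label_weights` (map
#' A/B/C/D), `internal_quarter_multiplier`,
#' `three_quarter_internal_multiplier`, `scatter_surcharge`,
#' `at_core_bonus_full`, `at_core_bonus_noncanonical`, `spacer_penalties`
#' (sequence of 14 numbers for spacers 0..13), `long_spacer_grade_cap`,
#' `grade_thresholds` (map "5".."1"), `class_ceilings` (map full/3Q/half),
#' `no_grade_min_mismatches`, `no_grade_min_quarters`,
#' `grade5_max_mismatches` and `drop_half_sites_with_core_mismatch`.
#' Unknown or missing keys are reported by name.
#'
#' @param path Path to a YAML file.
#' @return `readRuleTable` returns a validated [`RuleTable-class`];
#'   `writeRuleTable` returns `path` invisibly.
#' @export
readRuleTable <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stop("rule file is not a YAML mapping: ", path)
  unknown <- setdiff(names(y), .RULE_YAML_KEYS)
  if (length(unknown)) {
    stop("rule file has unknown key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(.RULE_YAML_KEYS, names(y))
  if (length(missing)) {
    stop("rule file is missing key(s): ", paste(missing, collapse = ", "))
  }
  ruleTable(
    labelWeights = unlist(y$label_weights),
    internalQuarterMultiplier = y$internal_quarter_multiplier,
    threeQuarterInternalMultiplier = y$three_quarter_internal_multiplier,
    scatterSurcharge = y$scatter_surcharge,
    atCoreBonusFull = y$at_core_bonus_full,
    atCoreBonusNoncanonical = y$at_core_bonus_noncanonical,
    spacerPenalties = unlist(y$spacer_penalties),
    longSpacerGradeCap = y$long_spacer_grade_cap,
    gradeThresholds = unlist(y$grade_thresholds),
    classCeilings = unlist(y$class_ceilings),
    noGradeMinMismatches = y$no_grade_min_mismatches,
    noGradeMinQuarters = y$no_grade_min_quarters,
    grade5MaxMismatches = y$grade5_max_mismatches,
    dropHalfSitesWithCoreMismatch = y$drop_half_sites_with_core_mismatch
  )
}

#' @rdname readRuleTable
#' @param rules A [`RuleTable-class`] object.
#' @export
writeRuleTable <- function(rules, path) {
  stopifnot(is(rules, "RuleTable"))
  y <- list(
    label_weights = as.list(rules@labelWeights),
    internal_quarter_multiplier = rules@internalQuarterMultiplier,
    three_quarter_internal_multiplier = rules@threeQuarterInternalMultiplier,
    scatter_surcharge = rules@scatterSurcharge,
    at_core_bonus_full = rules@atCoreBonusFull,
    at_core_bonus_noncanonical = rules@atCoreBonusNoncanonical,
    spacer_penalties = as.list(rules@spacerPenalties),
    long_spacer_grade_cap = rules@longSpacerGradeCap,
    grade_thresholds = as.list(rules@gradeThresholds),
    class_ceilings = as.list(rules@classCeilings),
    no_grade_min_mismatches = rules@noGradeMinMismatches,
    no_grade_min_quarters = rules@noGradeMinQuarters,
    grade5_max_mismatches = rules@grade5MaxMismatches,
    drop_half_sites_with_core_mismatch = rules@dropHalfSitesWithCoreMismatch
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
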