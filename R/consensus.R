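# Consensus geometry of the p53 response element.
#
# The canonical full site is two copies of the palindromic decamer
# RRRCWWGYYY (R = A/G, W = A/T, Y = C/T) separated by a 0-13 bp spacer.
# Each half site carries the invariant CWWG core (decamer positions 4-7);
# the 20-mer splits into four pentamer quarter sites, one per p53 monomer.
# Quarters 2 and 3 flank the junction between the two half sites and are
# the "internal" quarters where mismatches are most damaging.

.DECAMER_SYMBOLS <- c("R", "R", "R", "C", "W", "W", "G", "Y", "Y", "Y")

# Mismatch penalty class by distance from the CWWG core:
#   A = invariant C and G (decamer 4, 7), B = central WW (5, 6),
#   C = flanking R/Y (3, 8), D = outermost (1, 2, 9, 10).
.DECAMER_LABELS <- c("D", "D", "C", "A", "B", "B", "A", "C", "D", "D")

.IUPAC <- list(
  R = c("A", "G"),
  Y = c("C", "T"),
  W = c("A", "T"),
  C = "C",
  G = "G"
)

.FULL_SYMBOLS  <- rep(.DECAMER_SYMBOLS, 2L)
.FULL_LABELS   <- rep(.DECAMER_LABELS, 2L)
.FULL_QUARTERS <- rep(1:4, each = 5L)
.FULL_INTERNAL <- .FULL_QUARTERS %in% c(2L, 3L)

# Spacer-free 20-mer coordinates covered by each site class.  A 3Q site is
# three consecutive quarter sites, so it can sit on either end of the full
# consensus: "left" = positions 1-15 (half site + quarter), "right" =
# positions 6-20 (quarter + half site).  The two arrangements are reverse
# complements of one another.
.SITE_DEFS <- list(
  full         = list(map = 1:20, site_class = "full", arrangement = NA_character_),
  threeQ_left  = list(map = 1:15, site_class = "3Q",   arrangement = "left"),
  threeQ_right = list(map = 6:20, site_class = "3Q",   arrangement = "right"),
  half         = list(map = 1:10, site_class = "half", arrangement = NA_character_)
)

.SITE_CLASSES <- c("full", "3Q", "half")
.MAX_SPACER <- 13L

# ASCII lookup: allowed[charCode, fullPosition] is TRUE when the base is
# compatible with the degenerate symbol at that position of the 20-mer.
.ALLOWED_FULL <- local({
  m <- matrix(FALSE, nrow = 256L, ncol = 20L)
  for (j in seq_len(20L)) {
    bases <- .IUPAC[[.FULL_SYMBOLS[j]]]
    m[vapply(bases, utf8ToInt, integer(1)), j] <- TRUE
  }
  m
})

.ACGT_INT <- c(A = 65L, C = 67L, G = 71L, T = 84L)
.IS_ACGT <- local({
  v <- logical(256L)
  v[.ACGT_INT] <- TRUE
  v
})

# Spacer-free core WW positions (the two central bases of each CWWG core)
# for each site definition, in local site coordinates.
.CORE_WW <- list(
  full         = list(c(5L, 6L), c(15L, 16L)),
  threeQ_left  = list(c(5L, 6L)),
  threeQ_right = list(c(10L, 11L)),
  half         = list(c(5L, 6L))
)

# per-definition constants precomputed once (hot path: the scalar
# classifier runs once per candidate window in the brute-force oracle)
.SITE_CONST <- local({
  lapply(names(.SITE_DEFS), function(key) {
    def <- .SITE_DEFS[[key]]
    map <- def$map
    localQ <- ((map - 1L) %/% 5L) + 1L
    localQ <- localQ - localQ[1L] + 1L
    cores <- .CORE_WW[[key]]
    # a lone half site has no inter-half-site junction, hence no internal
    # quarter; 3Q sites inherit the internal status of the full-site frame
    internal <- if (def$site_class == "half") {
      rep(FALSE, length(map))
    } else {
      .FULL_INTERNAL[map]
    }
    list(
      map = map,
      len = length(map),
      labels = .FULL_LABELS[map],
      localQ = localQ,
      internal = internal,
      coreWW = cores,
      coreStart = vapply(cores, `[`, 0L, 1L),
      coreEnd = vapply(cores, `[`, 0L, 2L)
    )
  }) |> stats::setNames(names(.SITE_DEFS))
})

.siteDefKey <- function(siteClass, arrangement = "left") {
  switch(siteClass,
    full = "full",
    half = "half",
    "3Q" = switch(arrangement,
      left = "threeQ_left",
      right = "threeQ_right",
      stop("arrangement must be \"left\" or \"right\"")
    ),
    stop("unknown site class: ", siteClass)
  )
}

#' Consensus model of the p53 response element
#'
#' Returns the fixed geometry used throughout the package: the degenerate
#' half-site pattern `RRRCWWGYYY`, the mismatch-label assignment of every
#' decamer position, the quarter-site partition of the spacer-free 20-mer,
#' the internal (junction-flanking) quarters, the CWWG core positions and
#' the admissible spacer range of the full-site search.
#'
#' @return A list of class `"ConsensusModel"` with elements
#'   `halfSitePattern`, `positionLabels` (per decamer position),
#'   `fullSiteLabels`, `quarters`, `internalQuarters`, `corePositions`
#'   (decamer coordinates of the CWWG tetramer) and `spacerRange`.
#' @examples
#' consensusModel()$halfSitePattern
#' @export
consensusModel <- function() {
  structure(
    list(
      halfSitePattern  = .DECAMER_SYMBOLS,
      positionLabels   = .DECAMER_LABELS,
      fullSiteLabels   = .FULL_LABELS,
      quarters         = .FULL_QUARTERS,
      internalQuarters = c(2L, 3L),
      corePositions    = 4:7,
      spacerRange      = 0:.MAX_SPACER
    ),
    class = "ConsensusModel"
  )
}

#' Test for the high-activity AT core motif
#'
#' The central WW dinucleotide of a CWWG core boosts transactivation when
#' it is exactly `"AT"` (A then T); other W pairs (`"TA"`, `"AA"`, `"TT"`)
#' do not receive the bonus.
#'
#' @param coreDinucleotide Character vector of 2-mers over A/C/G/T.
#' @return Logical vector, `TRUE` where the 2-mer is exactly `"AT"`.
#' @examples
#' atCorePresent(c("AT", "TA", "GC"))
#' @export
atCorePresent <- function(coreDinucleotide) {
  stopifnot(is.character(coreDinucleotide))
  bad <- nchar(coreDinucleotide) != 2L |
    grepl("[^ACGT]", coreDinucleotide)
  if (any(bad)) {
    stop("coreDinucleotide must be 2-mers over ACGT")
  }
  coreDinucleotide == "AT"
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

.withSeed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
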