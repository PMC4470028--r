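.PWM_BASES <- c("A", "C", "G", "T")

#' LogOddsPWM: position weight matrix of log2 probability ratios
#'
#' @slot weights 4 x width numeric matrix (rows A, C, G, T) of
#'   log2(posterior base probability / background probability).
#' @slot background Named numeric of length 4, the background base
#'   distribution.
#' @slot priorStrength Total weight of the Dirichlet prior used in the
#'   posterior estimate.
#' @slot minScore,maxScore Sums of the column-wise minima / maxima; used
#'   to normalize match scores to `[0, 1]`.
#' @export
setClass("LogOddsPWM",
  representation(
    weights = "matrix", background = "numeric",
    priorStrength = "numeric", minScore = "numeric", maxScore = "numeric"
  )
)

setValidity("LogOddsPWM", function(object) {
  if (!identical(rownames(object@weights), .PWM_BASES)) {
    return("weights must have rows A, C, G, T")
  }
  if (object@maxScore < object@minScore) {
    return("maxScore must be at least minScore")
  }
  TRUE
})

setMethod("show", "LogOddsPWM", function(object) {
  cat(sprintf("LogOddsPWM: width %d, score range [%.3f, %.3f]\n",
              ncol(object@weights), object@minScore, object@maxScore))
  invisible(object)
})

#' Read a JASPAR-style position frequency matrix
#'
#' Accepts the JASPAR text format: an optional `>ID name` header followed
#' by four rows, either bracketed (`A [ 1 2 3 ]`) or plain whitespace-
#' separated numbers in A, C, G, T order.
#'
#' @param path Path to the PFM file.
#' @return A 4 x width numeric matrix with rows A, C, G, T; the matrix id
#'   (if present) is kept in the `"id"` attribute.
#' @export
readJasparPfm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  id <- NA_character_
  if (length(lines) && startsWith(lines[1], ">")) {
    id <- sub("^>\\s*(\\S+).*$", "\\1", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4L) stop("PFM file must contain four base rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- sub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  w <- lengths(rows)
  if (length(unique(w)) != 1L) stop("PFM rows have unequal widths")
  pfm <- do.call(rbind, rows)
  rownames(pfm) <- .PWM_BASES
  attr(pfm, "id") <- id
  pfm
}

#' Transform a position frequency matrix into a log2 probability-ratio PWM
#'
#' Per column, the posterior probability of base b is estimated under a
#' multinomial model with a Dirichlet conjugate prior:
#' `p(b) = (count_b + priorStrength * background_b) /
#' (columnTotal + priorStrength)`; the matrix entry is
#' `log2(p(b) / background_b)`.
#'
#' @param pfm 4 x width nonnegative matrix of counts or frequencies (rows
#'   A, C, G, T; a matrix from [readJasparPfm()] works directly).
#' @param background Base distribution of length 4 (A, C, G, T); must be
#'   strictly positive and sum to 1.  Default uniform.
#' @param priorStrength Total prior weight (default 1).
#' @return A [`LogOddsPWM-class`].
#' @examples
#' pfm <- matrix(c(100, 0, 0, 0), 4, 1, dimnames = list(c("A","C","G","T")))
#' pfmToPwm(pfm)@weights["A", 1]  # ~1.989
#' @export
pfmToPwm <- function(pfm, background = rep(0.25, 4), priorStrength = 1) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("pfm must have 4 rows (A, C, G, T)")
  if (any(pfm < 0)) stop("pfm entries must be nonnegative")
  if (any(colSums(pfm) == 0)) stop("pfm has an all-zero column")
  background <- as.numeric(background)
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  stopifnot(priorStrength > 0)
  tot <- colSums(pfm)
  post <- sweep(pfm + priorStrength * background, 2L, tot + priorStrength, "/")
  w <- log2(post / background)
  dimnames(w) <- list(.PWM_BASES, NULL)
  new("LogOddsPWM",
    weights = w,
    background = stats::setNames(background, .PWM_BASES),
    priorStrength = as.numeric(priorStrength),
    minScore = sum(apply(w, 2L, min)),
    maxScore = sum(apply(w, 2L, max))
  )
}

.baseIdx <- function(s) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], .PWM_BASES)
  if (anyNA(idx)) stop("sequence must contain only uppercase A, C, G, T")
  idx
}

#' Score a window against a PWM, normalized to [0, 1]
#'
#' The raw score is the sum of the weights of the observed bases; the
#' normalized score is `(raw - minScore) / (maxScore - minScore)`, so the
#' column-wise argmax sequence scores exactly 1 and the argmin sequence
#' exactly 0.
#'
#' @param pwm A [`LogOddsPWM-class`].
#' @param window Character string of exactly the PWM width, over A/C/G/T.
#' @return A number in `[0, 1]`.
#' @export
scoreMatch <- function(pwm, window) {
  stopifnot(is(pwm, "LogOddsPWM"))
  W <- ncol(pwm@weights)
  idx <- .baseIdx(window)
  if (length(idx) != W) {
    stop(sprintf("window must be %d bases, got %d", W, length(idx)))
  }
  raw <- sum(pwm@weights[cbind(idx, seq_len(W))])
  rng <- pwm@maxScore - pwm@minScore
  # a fully uninformative matrix scores every window as optimal
  if (rng == 0) return(1)
  (raw - pwm@minScore) / rng
}

#' Best normalized PWM score of a (possibly shorter) site
#'
#' Sites narrower than the PWM (3Q and half sites) are slid across the
#' matrix; at each alignment offset the raw score sums the weights of the
#' covered columns, with uncovered columns contributing zero (i.e. scored
#' as background), and is normalized by the full-width score range.  The
#' best offset's score is returned.  A site that spans only part of the
#' matrix therefore cannot reach 1 even when it matches its columns
#' perfectly — the full-width matrix structurally penalizes partial
#' sites.  Full-width sequences reduce to [scoreMatch()].
#'
#' @inheritParams scoreMatch
#' @param site Character string over A/C/G/T of width at most the PWM
#'   width.
#' @return A number in `[0, 1]`.
#' @export
scoreBestFit <- function(pwm, site) {
  stopifnot(is(pwm, "LogOddsPWM"))
  W <- ncol(pwm@weights)
  idx <- .baseIdx(site)
  L <- length(idx)
  if (L > W) stop("site is wider than the PWM")
  if (L == W) return(scoreMatch(pwm, site))
  rng <- pwm@maxScore - pwm@minScore
  if (rng == 0) return(1)
  best <- -Inf
  for (o in 0:(W - L)) {
    cols <- (o + 1L):(o + L)
    raw <- sum(pwm@weights[cbind(idx, cols)])
    best <- max(best, raw)
  }
  min(1, max(0, (best - pwm@minScore) / rng))
}

#' Per-grade summary of PWM scores of scanned response elements
#'
#' Scores every RE of a scan result with a PWM (full sites on their
#' spacer-free 20-mer, 3Q and half sites at their best alignment inside
#' the matrix) and summarizes the score distribution per grade.
#'
#' @param gr A response-element [GenomicRanges::GRanges] carrying the
#'   `sequence`, `site_class`, `spacer_length` and `grade` columns.
#' @param pwm A [`LogOddsPWM-class`].
#' @return A data.frame with one row per grade present: `grade`, `n`,
#'   `min`, `q1`, `median`, `q3`, `max` of the normalized scores.
#' @export
gradeVsPwmTable <- function(gr, pwm) {
  if (!length(gr)) {
    return(data.frame(grade = integer(0), n = integer(0), min = numeric(0),
                      q1 = numeric(0), median = numeric(0), q3 = numeric(0),
                      max = numeric(0)))
  }
  site <- .spacerFreeSite(gr$sequence, gr$site_class, gr$spacer_length)
  score <- vapply(site, scoreBestFit, numeric(1), pwm = pwm, USE.NAMES = FALSE)
  out <- lapply(sort(unique(gr$grade)), function(g) {
    s <- score[gr$grade == g]
    q <- stats::quantile(s, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(grade = g, n = length(s), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  })
  do.call(rbind, out)
}
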