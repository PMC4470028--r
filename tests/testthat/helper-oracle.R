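# Brute-force scanning oracle: enumerate every candidate window and apply
# the scalar classifier + grader directly, independently of the vectorized
# scan engine.

oracleScan <- function(seq, rules = defaultRuleTable(), minGrade = 1L) {
  cap <- 2e4L
  n <- 0L
  st <- integer(cap); en <- integer(cap); cl <- character(cap)
  sp <- integer(cap); gd <- integer(cap); pe <- numeric(cap)
  nm <- integer(cap); ar <- character(cap)
  dropAB <- rules@dropHalfSitesWithCoreMismatch
  for (cls in c("full", "3Q", "half")) {
    cand <- enumerateCandidates(seq, cls)
    if (!nrow(cand)) next
    off <- cand$offset; spc <- cand$spacer; arrv <- cand$arrangement
    site <- cand$site; wlen <- nchar(cand$window)
    for (i in seq_along(off)) {
      arr <- if (is.na(arrv[i])) "left" else arrv[i]
      prof <- classifyMismatches(site[i], cls, arr)
      if (cls == "half" && dropAB &&
          any(prof$labels == "A" | prof$labels == "B")) next
      g <- gradeSite(prof, cls, spc[i], rules)
      if (is.na(g$grade) || g$grade < minGrade) next
      n <- n + 1L
      st[n] <- off[i] + 1L; en[n] <- off[i] + wlen[i]; cl[n] <- cls
      sp[n] <- spc[i]; gd[n] <- g$grade; pe[n] <- g$penalty
      nm[n] <- length(prof$positions); ar[n] <- arr
    }
  }
  if (!n) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), spacer = integer(0),
                      grade = integer(0), penalty = numeric(0),
                      n_mismatches = integer(0)))
  }
  df <- data.frame(start = st[1:n], end = en[1:n], site_class = cl[1:n],
                   spacer = sp[1:n], grade = gd[1:n], penalty = pe[1:n],
                   n_mismatches = nm[1:n], arr = ar[1:n])
  # same twin-interval collapse as the scanner's raw output
  o <- order(df$start, df$end, df$site_class, -df$grade, df$penalty, df$arr)
  df <- df[o, , drop = FALSE]
  df[!duplicated(df[c("start", "end", "site_class")]), , drop = FALSE]
}

oracleKeys <- function(df) {
  sprintf("%d:%d:%s:%d:%d:%g:%d", df$start, df$end, df$site_class,
          df$spacer, df$grade, df$penalty, df$n_mismatches)
}

scanKeys <- function(gr) {
  sprintf("%d:%d:%s:%d:%d:%g:%d",
          GenomicRanges::start(gr), GenomicRanges::end(gr), gr$site_class,
          gr$spacer_length, gr$grade, gr$penalty, gr$n_mismatches)
}
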