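#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases
#' soft-masked bases and rejects empty files.  Gzipped input is handled
#' transparently.
#'
#' @param path Path to a FASTA (or FASTA.gz) file.
#' @return A [Biostrings::DNAStringSet], one record per FASTA entry, in
#'   file order.
#' @export
readFasta <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("cannot parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!length(x)) stop("FASTA file '", path, "' contains no records")
  names(x) <- sub("\\s.*$", "", names(x))
  # normalize soft-masking
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Read a table of transcription start sites
#'
#' Two dialects are supported, each following its format's convention:
#' a header-bearing TSV with columns `contig`, `tss` (1-based), `strand`,
#' `gene_id`; or BED (0-based half-open, columns chrom/start/end/name/
#' score/strand, TSS taken as the interval start).  Positions are stored
#' 0-based internally.
#'
#' @param path Path to the table (gzip transparent).
#' @param format `"tsv"` or `"bed"`; default guesses from the extension.
#' @return A data.frame with columns `contig`, `tss` (0-based), `strand`,
#'   `gene_id`.
#' @export
readTssTable <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(
      contig = bed[[1]],
      tss = as.integer(bed[[2]]),
      strand = if (ncol(bed) >= 6) bed[[6]] else "+",
      gene_id = if (ncol(bed) >= 4) as.character(bed[[4]]) else paste0("tss", seq_len(nrow(bed))),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "tss", "strand", "gene_id")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("TSS table is missing column(s): ", paste(miss, collapse = ", "))
    data.frame(
      contig = as.character(tab$contig),
      tss = as.integer(tab$tss) - 1L,
      strand = as.character(tab$strand),
      gene_id = as.character(tab$gene_id),
      stringsAsFactors = FALSE
    )
  }
}

#' Extract TSS-anchored windows from a genome
#'
#' Cuts the `[tss - flank, tss + flank)` window around every TSS,
#' truncating at contig edges with offset bookkeeping.  When
#' `strandAware = TRUE` (default), windows of minus-strand TSS are
#' reverse-complemented so that upstream is always at negative positions
#' relative to the TSS.
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param tss A TSS data.frame as from [readTssTable()] (columns `contig`,
#'   `tss` 0-based, `strand`, `gene_id`).
#' @param flank Half-width of the window in bp (default 10000, i.e. a
#'   20 kb window).
#' @param strandAware Reverse-complement minus-strand windows?
#' @return A [Biostrings::DNAStringSet] named by `gene_id` with metadata
#'   columns `tss_offset` (0-based position of the TSS within the window,
#'   after orientation), `contig`, `tss` and `strand`.  TSS on unknown
#'   contigs are skipped with one warning giving the count.
#' @export
extractWindows <- function(genome, tss, flank = 10000L, strandAware = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- readFasta(genome)
  }
  stopifnot(is(genome, "DNAStringSet"))
  flank <- as.integer(flank)
  stopifnot(flank > 0L)
  known <- tss$contig %in% names(genome)
  if (any(!known)) {
    warning(sum(!known), " TSS record(s) on unknown contig(s) skipped")
    tss <- tss[known, , drop = FALSE]
  }
  if (!nrow(tss)) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      tss_offset = integer(0), contig = character(0),
      tss = integer(0), strand = character(0))
    return(out)
  }
  lens <- Biostrings::width(genome)[match(tss$contig, names(genome))]
  a <- pmax(0L, tss$tss - flank)
  b <- pmin(lens, tss$tss + flank)
  seqs <- as.character(Biostrings::subseq(genome[tss$contig], start = a + 1L, end = b))
  offset <- tss$tss - a
  if (strandAware) {
    neg <- tss$strand == "-"
    if (any(neg)) {
      seqs[neg] <- .revcomp(seqs[neg])
      offset[neg] <- (b[neg] - 1L) - tss$tss[neg]
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tss$gene_id
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    tss_offset = as.integer(offset),
    contig = tss$contig,
    tss = tss$tss,
    strand = tss$strand
  )
  out
}

#' Merge open-chromatin interval sets and keep TSS-distal regions
#'
#' Reproduces the distal-enhancer selection logic: positions covered by at
#' least `minCellLines` of the input interval sets are merged into maximal
#' intervals, and merged intervals closer than `minTssDistance` (interval
#' edge to TSS point) to any TSS are dropped.
#'
#' @param intervalSets A list of [GenomicRanges::GRanges] (or BED file
#'   paths, imported via [rtracklayer::import]); one set per cell line.
#' @param tss TSS data.frame as from [readTssTable()], or a GRanges of TSS
#'   points.
#' @param minCellLines Minimum number of sets covering a position
#'   (default 2).
#' @param minTssDistance Minimum distance to the nearest TSS in bp
#'   (default 10000); intervals at or below it are dropped.
#' @return A sorted, disjoint [GenomicRanges::GRanges].
#' @export
mergeAndFilterDistal <- function(intervalSets, tss, minCellLines = 2L,
                                 minTssDistance = 10000L) {
  if (!length(intervalSets)) return(GenomicRanges::GRanges())
  sets <- lapply(intervalSets, function(s) {
    if (is.character(s)) s <- rtracklayer::import(s)
    GenomicRanges::reduce(s, ignore.strand = TRUE)
  })
  if (length(sets) < minCellLines) {
    warning("fewer interval sets than minCellLines; result is empty")
    return(GenomicRanges::GRanges())
  }
  lvls <- unique(unlist(lapply(sets, GenomeInfoDb::seqlevels)))
  # pad every per-set coverage to a common contig width before summing
  maxEnd <- setNames(rep(0L, length(lvls)), lvls)
  for (s in sets) {
    e <- vapply(split(GenomicRanges::end(s),
                      as.character(GenomicRanges::seqnames(s))), max, 0L)
    maxEnd[names(e)] <- pmax(maxEnd[names(e)], e)
  }
  cov <- Reduce(`+`, lapply(sets, function(s) {
    GenomeInfoDb::seqlevels(s) <- lvls
    GenomicRanges::coverage(s, width = maxEnd)
  }))
  merged <- GenomicRanges::reduce(GenomicRanges::GRanges(
    IRanges::slice(cov, lower = minCellLines, rangesOnly = TRUE)))
  if (!length(merged)) return(merged)
  if (is.data.frame(tss)) {
    tssGR <- GenomicRanges::GRanges(tss$contig,
                                    IRanges::IRanges(tss$tss + 1L, width = 1L))
  } else {
    tssGR <- tss
  }
  if (!length(tssGR)) return(sort(merged))
  hits <- GenomicRanges::distanceToNearest(merged, tssGR, ignore.strand = TRUE)
  dist <- rep(NA_integer_, length(merged))
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  sort(merged[is.na(dist) | dist > minTssDistance])
}

.openMaybeGz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

.RE_TSV_COLS <- c("contig", "start", "end", "strand", "site_class",
                  "spacer_length", "sequence", "mismatch_labels",
                  "n_mismatches", "penalty", "grade")

#' Write / read response-element calls as TSV
#'
#' Columns: `contig`, `start` (1-based), `end`, `strand`, `site_class`,
#' `spacer_length`, `sequence`, `mismatch_labels`, `n_mismatches`,
#' `penalty`, `grade`.  Writing then reading reproduces the in-memory
#' records exactly; `.gz` paths are compressed transparently.
#'
#' @param gr A response-element [GenomicRanges::GRanges] from
#'   [scanSequence()] / [scanSet()].
#' @param path Output (input) path.
#' @return `writeRETsv` returns `path` invisibly; `readRETsv` returns the
#'   GRanges.
#' @export
writeRETsv <- function(gr, path) {
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    site_class = gr$site_class,
    spacer_length = gr$spacer_length,
    sequence = gr$sequence,
    mismatch_labels = gr$mismatch_labels,
    n_mismatches = gr$n_mismatches,
    penalty = gr$penalty,
    grade = gr$grade,
    stringsAsFactors = FALSE
  )
  con <- .openMaybeGz(path, "wb")
  on.exit(close(con))
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRETsv
#' @export
readRETsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(
                            contig = "character", start = "integer",
                            end = "integer", strand = "character",
                            site_class = "character", spacer_length = "integer",
                            sequence = "character", mismatch_labels = "character",
                            n_mismatches = "integer", penalty = "numeric",
                            grade = "integer"))
  miss <- setdiff(.RE_TSV_COLS, names(df))
  if (length(miss)) stop("RE TSV is missing column(s): ", paste(miss, collapse = ", "))
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    site_class = df$site_class, spacer_length = df$spacer_length,
    sequence = df$sequence, n_mismatches = df$n_mismatches,
    mismatch_labels = df$mismatch_labels, penalty = df$penalty,
    grade = df$grade,
    arrangement = if ("arrangement" %in% names(df)) df$arrangement else NA_character_
  )
  gr
}

#' Write response-element calls as BED6
#'
#' Name is `class:grade`, score is `grade * 200` clamped to 1000.
#'
#' @inheritParams writeRETsv
#' @export
writeREBed <- function(gr, path) {
  out <- GenomicRanges::granges(gr)
  out$name <- paste0(gr$site_class, ":", gr$grade)
  out$score <- pmin(gr$grade * 200, 1000)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
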