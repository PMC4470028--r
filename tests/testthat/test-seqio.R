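GS <- GenomicRanges::start
GE <- GenomicRanges::end

test_that("FASTA reading preserves record order, unwraps and uppercases", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 first record", "GGGCATGTCC", "GGGCATGTCC",
               ">s2", "acgtacgt"), path)
  x <- readFasta(path)
  expect_identical(names(x), c("s1", "s2"))
  expect_identical(as.character(x[["s1"]]), "GGGCATGTCCGGGCATGTCC")
  expect_identical(as.character(x[["s2"]]), "ACGTACGT")

  # 60-column wrapping is transparent
  path2 <- withr::local_tempfile(fileext = ".fasta")
  long <- strrep("ACGTT", 50)
  writeLines(c(">w", substring(long, seq(1, 250, 60), pmin(seq(60, 310, 60), 250))),
             path2)
  expect_identical(as.character(readFasta(path2)[["w"]]), long)

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readFasta(empty), "no records|parse")
})

test_that("TSS tables follow each dialect's coordinate convention", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\ttss\tstrand\tgene_id", "chr1\t1001\t+\tGENE1"), tsv)
  t1 <- readTssTable(tsv)
  expect_identical(t1$tss, 1000L)  # 1-based input -> 0-based internal

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t1001\tGENE1\t0\t+", bed)
  t2 <- readTssTable(bed)
  expect_identical(t2$tss, 1000L)
  expect_identical(t1$gene_id, t2$gene_id)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tposition", "chr1\t5"), bad)
  expect_error(readTssTable(bad), "tss")
})

test_that("TSS windows are cut, truncated and oriented correctly", {
  withr::with_seed(21, {
    contig <- randomGCSequence(30000, 0.44)
    genome <- Biostrings::DNAStringSet(c(chrA = contig))

    tss <- data.frame(contig = "chrA", tss = 15000L, strand = "+", gene_id = "g1")
    w <- extractWindows(genome, tss, flank = 10000)
    expect_identical(Biostrings::width(w), 20000L)
    expect_identical(S4Vectors::mcols(w)$tss_offset, 10000L)
    expect_identical(as.character(w[[1]]), substring(contig, 5001, 25000))

    # truncation at the contig edge keeps the offset honest
    tss2 <- data.frame(contig = "chrA", tss = 3000L, strand = "+", gene_id = "g2")
    w2 <- extractWindows(genome, tss2, flank = 10000)
    expect_identical(Biostrings::width(w2), 13000L)
    expect_identical(S4Vectors::mcols(w2)$tss_offset, 3000L)

    # minus-strand windows are reverse complemented
    tss3 <- data.frame(contig = "chrA", tss = 15000L, strand = "-", gene_id = "g3")
    w3 <- extractWindows(genome, tss3, flank = 10000)
    expect_identical(as.character(w3[[1]]),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(substring(contig, 5001, 25000)))))
    expect_identical(S4Vectors::mcols(w3)$tss_offset, 9999L)

    # unknown contigs are skipped with a warning
    tss4 <- rbind(tss, data.frame(contig = "chrZ", tss = 5L, strand = "+",
                                  gene_id = "g4"))
    expect_warning(w4 <- extractWindows(genome, tss4, flank = 1000), "unknown")
    expect_length(w4, 1)
  })
})

test_that("distal-region selection keeps >=2-line coverage away from TSS", {
  GR <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  tss <- data.frame(contig = "chr1", tss = 50000L, strand = "+", gene_id = "g")

  # full agreement between two sets, far from any TSS
  r <- mergeAndFilterDistal(list(GR(101, 200), GR(101, 200)), tss)
  expect_length(r, 1)
  expect_identical(GS(r), 101L)
  expect_identical(GE(r), 200L)

  # an interval seen in only one set is dropped
  r <- mergeAndFilterDistal(list(GR(101, 200), GR(5001, 5100)), tss)
  expect_length(r, 0)

  # an interval 5 kb from a TSS is dropped
  near <- GR(44001, 44500)  # 4.5 kb upstream edge-to-point
  r <- mergeAndFilterDistal(list(near, near), tss)
  expect_length(r, 0)

  # partial overlaps merge into maximal intervals; output disjoint + sorted
  sets <- list(c(GR(101, 300), GR(1001, 1200)),
               c(GR(201, 400), GR(1101, 1300)),
               GR(250, 260))
  r <- mergeAndFilterDistal(sets, tss)
  expect_identical(GS(r), c(201L, 1101L))
  expect_identical(GE(r), c(300L, 1200L))
  expect_true(all(diff(GS(r)) > 0))
  expect_length(GenomicRanges::reduce(r), length(r))
})

test_that("RE calls round-trip exactly through TSV and export to BED", {
  withr::with_seed(22, {
    gr <- scanSequence(randomGCSequence(1500, 0.44), contig = "w1")
    expect_gt(length(gr), 0)

    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeRETsv(gr, tsv)
    back <- readRETsv(tsv)
    expect_identical(GS(back), GS(gr))
    expect_identical(GE(back), GE(gr))
    expect_identical(back$penalty, gr$penalty)
    expect_identical(back$grade, gr$grade)
    expect_identical(back$sequence, gr$sequence)
    expect_identical(back$mismatch_labels, gr$mismatch_labels)

    # gzip transparently
    tsvgz <- withr::local_tempfile(fileext = ".tsv.gz")
    writeRETsv(gr, tsvgz)
    expect_identical(readRETsv(tsvgz)$penalty, gr$penalty)

    bed <- withr::local_tempfile(fileext = ".bed")
    writeREBed(gr, bed)
    b <- rtracklayer::import(bed)
    expect_identical(GS(b), GS(gr))
    expect_identical(b$name, paste0(gr$site_class, ":", gr$grade))
    expect_identical(as.integer(b$score), pmin(gr$grade * 200L, 1000L))
  })
})
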