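test_that("GTF parsing converts coordinates and derives the TSS by strand", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t3000\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\ttranscript\t1001\t3000\t.\t-\t.\tgene_id "G2"; transcript_id "T2";',
    'chr1\tsrc\ttranscript\t5001\t6000\t.\t+\t.\tgene_id "G3"; transcript_id "T3a";',
    'chr1\tsrc\ttranscript\t5001\t7000\t.\t+\t.\tgene_id "G3"; transcript_id "T3b";'
  ), gtf)
  tx <- read_gtf_transcripts(gtf)
  t1 <- tx[tx$transcript_id == "T1", ]
  expect_equal(t1$tx_start, 1000L)
  expect_equal(t1$tx_end, 3000L)
  expect_equal(t1$tss, 1000L)
  expect_equal(t1$tx_length, 2000L)
  t2 <- tx[tx$transcript_id == "T2", ]
  expect_equal(t2$tss, 2999L)  # 5' end of a minus-strand transcript
  expect_equal(sum(tx$gene_id == "G3"), 2L)
})

test_that("malformed GTF lines fail with the line number; inverted spans are rejected", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t3000\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    "chr1 only three fields"
  ), bad)
  expect_error(read_gtf_transcripts(bad), "line 2")

  inv <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t3000\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\ttranscript\t9000\t8000\t.\t+\t.\tgene_id "G2"; transcript_id "T2";'
  ), inv)
  expect_warning(tx <- read_gtf_transcripts(inv), "rejected")
  expect_equal(tx$transcript_id, "T1")
})

test_that("protein-coding filter drops annotated non-coding genes", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t3000\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; gene_biotype "protein_coding";',
    'chr1\tsrc\ttranscript\t9001\t9500\t.\t+\t.\tgene_id "G2"; transcript_id "T2"; gene_biotype "lincRNA";'
  ), gtf)
  expect_equal(read_gtf_transcripts(gtf)$gene_id, "G1")
  expect_equal(sort(read_gtf_transcripts(gtf, protein_coding_only = FALSE)$gene_id),
               c("G1", "G2"))
})

test_that("transcript models survive a GTF round trip", {
  tx <- transcript_models(c("G1", "G2"), c("T1", "T2"), "chr7",
                          c("+", "-"), c(100L, 5000L), c(2100L, 9000L))
  f <- tempfile(fileext = ".gtf")
  write_transcript_gtf(tx, f)
  back <- read_gtf_transcripts(f)
  back <- back[match(tx$transcript_id, back$transcript_id), ]
  rownames(back) <- NULL
  expect_identical(back, tx)
})

test_that("primary transcript selection maximises body density with documented tie-breaks", {
  tx <- rbind(make_tx("G1", "T1", tx_start = 0L, tx_end = 5000L),
              make_tx("G1", "T2", tx_start = 0L, tx_end = 3000L))
  pick <- function(d) select_primary_transcripts(tx, d)$transcript_id
  expect_equal(pick(c(T1 = 0.4, T2 = 0.1)), "T1")
  expect_equal(pick(c(T1 = 0.1, T2 = 0.4)), "T2")
  # tie: longer transcript wins
  expect_equal(pick(c(T1 = 0.2, T2 = 0.2)), "T1")
  # tie and equal length: lexicographically smaller id
  tx2 <- rbind(make_tx("G1", "Tb", tx_start = 0L, tx_end = 3000L),
               make_tx("G1", "Ta", tx_start = 0L, tx_end = 3000L))
  expect_equal(select_primary_transcripts(tx2, c(Ta = 0, Tb = 0))$transcript_id,
               "Ta")
  # single transcript is its own primary
  expect_equal(select_primary_transcripts(tx[1, ], c(T1 = 0))$transcript_id,
               "T1")
  expect_error(select_primary_transcripts(tx[0, ], numeric()), "no transcripts")
  expect_error(select_primary_transcripts(tx, c(T1 = 0.1)), "missing")
})

test_that("windows follow the stated definitions on the plus strand", {
  w <- one_gene_windows("+", 10000L, 15000L)  # tss = 10000
  expect_equal(c(w$tss_start, w$tss_end), c(9850, 10150))
  expect_equal(c(w$body_start, w$body_end), c(10250, 15000))
  expect_equal(w$body_length, 4750)
  expect_equal(c(w$flank_start, w$flank_end), c(8000, 12500))
  expect_equal(w$tss_end - w$tss_start, 300)
  expect_equal(w$flank_end - w$flank_start, 4500)
})

test_that("minus-strand windows are the exact mirror of the plus-strand rule", {
  # spec'd fixture: tx span [10000, 15001), tss = 15000
  w <- one_gene_windows("-", 10000L, 15001L)
  expect_equal(c(w$tss_start, w$tss_end), c(14851, 15151))
  expect_equal(c(w$body_start, w$body_end), c(10000, 14751))

  # property: reflect about a pivot, flip strand, derive, reflect back
  set.seed(11)
  for (i in 1:25) {
    s <- sample.int(1e6, 1)
    len <- sample(600:20000, 1)
    wp <- derive_windows(make_tx(strand = "+", tx_start = s,
                                 tx_end = s + len))
    pivot <- sample.int(3e6, 1) + 2e6  # keep reflected coords positive
    refl <- function(a, b) c(pivot - b, pivot - a)  # [a,b) -> mirrored
    span <- refl(s, s + len)
    wm <- derive_windows(make_tx(strand = "-", tx_start = span[1],
                                 tx_end = span[2]))
    expect_equal(c(wm$tss_start, wm$tss_end),
                 refl(wp$tss_start, wp$tss_end))
    expect_equal(c(wm$flank_start, wm$flank_end),
                 refl(wp$flank_start, wp$flank_end))
    if (wp$body_ok) {
      expect_equal(c(wm$body_start, wm$body_end),
                   refl(wp$body_start, wp$body_end))
    }
  }
})

test_that("windows are clipped at the chromosome start and short bodies flagged", {
  w <- derive_windows(make_tx(strand = "+", tx_start = 50L,
                              tx_end = 5000L))
  expect_equal(w$tss_start, 0)    # clipped from -100
  expect_equal(w$flank_start, 0)  # clipped from -1950
  short <- derive_windows(make_tx(tx_start = 1000L, tx_end = 1300L))
  expect_false(short$body_ok)
  expect_equal(short$body_length, 0)
  # 451 bp is the shortest usable transcript at the defaults
  edge <- derive_windows(make_tx(tx_start = 1000L, tx_end = 1451L))
  expect_true(edge$body_ok)
})

test_that("window BED export is six-column, 0-based and skips empty bodies", {
  tx <- rbind(make_tx("G1", "T1", strand = "+", tx_start = 10000L,
                      tx_end = 15000L),
              make_tx("G2", "T2", strand = "-", tx_start = 40000L,
                      tx_end = 40300L))
  w <- derive_windows(tx)
  f <- tempfile(fileext = ".bed")
  windows_to_bed(w, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(ncol(bed), 6)
  expect_equal(nrow(bed), 5)  # 2 tss + 2 flank + 1 usable body
  tss1 <- bed[bed$V4 == "G1|T1|tss", ]
  expect_equal(c(tss1$V2, tss1$V3), c(9850, 10150))
  expect_true(all(bed$V6 %in% c("+", "-")))
})
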