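test_that("BED loading counts, skips and tolerates empty libraries", {
  reads <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                      end = c(36L, 136L, 236L))
  f <- write_bed3(reads)
  got <- load_reads(f)
  expect_equal(got$total, 3L)
  expect_equal(got$skipped, 0L)
  expect_equal(got$reads$start, reads$start)

  bad <- rbind(reads, data.frame(chrom = "chr1", start = 500L, end = 400L))
  expect_warning(got2 <- load_reads(write_bed3(bad)), "invalid")
  expect_equal(got2$total, 3L)
  expect_equal(got2$skipped, 1L)

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  got3 <- load_reads(empty)
  expect_equal(got3$total, 0L)
  expect_error(library_scale_factors(c(a = got3$total, b = 10)),
               "positive")
})

test_that("reads are counted into every window they overlap by >= 1 bp", {
  w <- one_gene_windows()  # tss [9850,10150), body [10250,15000)
  reads <- data.frame(
    chrom = "chr1",
    start = c(10000L,  # inside tss
              9820L,   # 1-bp overlap: [9820, 9856) vs tss start 9850
              10149L,  # 1-bp overlap at tss right edge
              10150L,  # in the tss/body gap: flank only
              20000L), # outside everything
    end = c(10036L, 9856L, 10185L, 10186L, 20036L))
  got <- assign_reads(reads, w)
  cnt <- got$counts
  expect_equal(cnt$raw_count[cnt$window_kind == "tss"], 3)
  expect_equal(cnt$raw_count[cnt$window_kind == "body"], 0)
  expect_equal(cnt$raw_count[cnt$window_kind == "flank"], 4)
  expect_equal(got$n_discarded, 0L)
  expect_equal(got$n_assigned + got$n_outside, nrow(reads))
})

test_that("reads spanning two genes' transcript spans are discarded and tallied", {
  tx <- rbind(make_tx("G1", "T1", tx_start = 1000L, tx_end = 2000L),
              make_tx("G2", "T2", tx_start = 2010L, tx_end = 3000L))
  w <- derive_windows(tx)
  reads <- data.frame(chrom = "chr1",
                      start = c(1995L, 1500L), end = c(2031L, 1536L))
  got <- assign_reads(reads, w)
  expect_equal(got$n_discarded, 1L)
  # the spanning read contributes to no window of either gene; the other
  # read sits in G1's body window [1250, 2000)
  cnt <- got$counts
  expect_equal(sum(cnt$raw_count[cnt$window_kind == "body"]), 1)
  expect_equal(sum(cnt$raw_count[cnt$window_kind == "tss"]), 0)
})

test_that("indexed assignment equals the brute-force all-pairs scan", {
  for (seed in 1:20) {
    set.seed(seed)
    n_genes <- 25L
    starts <- cumsum(sample(3000:6000, n_genes)) + 20000L
    tx <- transcript_models(
      gene_id = sprintf("G%02d", 1:n_genes),
      transcript_id = sprintf("T%02d", 1:n_genes),
      chrom = "chr1",
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      tx_start = starts,
      tx_end = starts + sample(400:2500, n_genes))
    w <- derive_windows(tx)
    reads <- random_reads(1000L, max(tx$tx_end) + 30000L)
    got <- assign_reads(reads, w)
    ref <- brute_force_assign(reads, w)
    key <- function(d) d[order(d$window_kind, d$gene_id),
                         c("gene_id", "window_kind", "raw_count")]
    expect_equal(key(got$counts), key(ref$counts),
                 ignore_attr = TRUE)
    expect_equal(got$n_discarded, ref$n_discarded)
    expect_equal(got$n_assigned + got$n_outside + got$n_discarded,
                 nrow(reads))
  }
})

test_that("scale factors match the smallest library and reject zeros", {
  expect_equal(library_scale_factors(c(A = 1e6, B = 2e6)),
               c(A = 1.0, B = 0.5))
  expect_equal(library_scale_factors(c(A = 3, B = 5, C = 7)),
               c(A = 1, B = 3 / 5, C = 3 / 7))
  expect_equal(library_scale_factors(c(only = 12345)), c(only = 1))
  expect_error(library_scale_factors(c(A = 0, B = 10)), "positive")
})

test_that("densities are scaled counts per bp and scale linearly", {
  counts <- data.frame(gene_id = "G1", transcript_id = "T1",
                       window_kind = "body", raw_count = 400,
                       window_length = 2000)
  full <- window_density(counts, 1)
  expect_equal(full$density, 0.2)
  half <- window_density(counts, 0.5)
  expect_equal(half$scaled_count, 200)
  expect_equal(half$density, 0.1)
  zero <- window_density(transform(counts, raw_count = 0), 1)
  expect_equal(zero$density, 0)
  flagged <- window_density(transform(counts, window_length = 0), 1)
  expect_true(is.na(flagged$density))
})

test_that("binned profiles are transcript-oriented and mirror exactly", {
  w <- one_gene_windows("+", 100000L, 110000L)  # flank [98000,102500)
  # all reads centred on the TSS -> single spike at bin 2000/50 + 1
  at_tss <- data.frame(chrom = "chr1", start = rep(99982L, 7),
                       end = rep(100018L, 7))
  m <- binned_profile(at_tss, w)
  expect_equal(ncol(m), 90)
  expect_equal(which(m[1, ] > 0), 41L)  # offset 2000 at 50-bp bins
  expect_equal(sum(m), 7)

  # uniform midpoints, one per bin -> flat row; scaled by the factor
  mids <- w$flank_start + seq(25L, by = 50L, length.out = 90L)
  flat <- data.frame(chrom = "chr1", start = mids - 18L, end = mids + 18L)
  expect_equal(unname(binned_profile(flat, w, scale_factor = 0.5)[1, ]),
               rep(0.5, 90))

  # a minus-strand gene on mirrored reads gives the same 5'->3' row as
  # the plus-strand gene on the originals (both rows are
  # transcript-oriented, so the two reversals cancel)
  set.seed(3)
  reads <- random_reads(500L, 200000L)
  pivot <- 400000L
  mirrored <- data.frame(chrom = "chr1", start = pivot - reads$end,
                         end = pivot - reads$start)
  wm <- derive_windows(make_tx(strand = "-",
                               tx_start = pivot - 110000L,
                               tx_end = pivot - 100000L + 1L))
  expect_equal(unname(binned_profile(mirrored, wm)[1, ]),
               unname(binned_profile(reads, w)[1, ]))
  # the minus-strand row is the reverse of genomic-order binning
  mid <- (mirrored$start + mirrored$end) %/% 2L
  sel <- mid >= wm$flank_start & mid < wm$flank_end
  genomic <- tabulate((mid[sel] - wm$flank_start) %/% 50L + 1L,
                      nbins = 90L)
  expect_equal(unname(binned_profile(mirrored, wm)[1, ]), rev(genomic))
})

test_that("mean body depth is the per-base pileup mean", {
  w <- derive_windows(make_tx(tx_start = 10000L, tx_end = 11250L))
  # body [10250, 11250): one fully contained 100-bp read -> 100/1000
  one <- data.frame(chrom = "chr1", start = 10500L, end = 10600L)
  expect_equal(unname(mean_body_depth(one, w)), 0.1)
  none <- data.frame(chrom = character(), start = integer(),
                     end = integer())
  expect_equal(unname(mean_body_depth(none, w)), 0)

  set.seed(8)
  reads <- random_reads(300L, 20000L)
  expect_equal(unname(mean_body_depth(reads, w, scale_factor = 0.7)),
               0.7 * brute_force_mean_depth(reads, "chr1", 10250L, 11250L))
})

test_that("bedGraph export reproduces scaled coverage", {
  reads <- data.frame(chrom = "chr1", start = c(10L, 20L), end = c(50L, 60L))
  f <- tempfile(fileext = ".bedGraph")
  export_bedgraph(reads, f, scale_factor = 0.5)
  bg <- read.delim(f, header = FALSE)
  # overlap zone [20,50) has depth 2 -> scaled 1
  expect_equal(bg$V4[bg$V2 == 20 & bg$V3 == 50], 1)
})
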