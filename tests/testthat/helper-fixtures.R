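# Shared fixture builders and independent oracles.

# Transcript table from terse arguments.
make_tx <- function(gene_id = "G1", transcript_id = "T1", chrom = "chr1",
                    strand = "+", tx_start = 10000L, tx_end = 15000L) {
  transcript_models(gene_id, transcript_id, chrom, strand, tx_start,
                    tx_end)
}

# Random read table on one chromosome.
random_reads <- function(n, chrom_len, read_len = 36L, chrom = "chr1") {
  s <- sample.int(chrom_len - read_len, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start = s, end = s + read_len, strand = "+",
             stringsAsFactors = FALSE)
}

# Brute-force all-pairs overlap counter over the same window table that
# assign_reads() consumes, including the multi-gene discard rule.
brute_force_assign <- function(reads, windows) {
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  # multi-gene rule against transcript spans
  genes_per_read <- vapply(seq_len(nrow(reads)), function(i) {
    hit <- reads$chrom[i] == windows$chrom &
      overlaps(reads$start[i], reads$end[i], windows$tx_start,
               windows$tx_end)
    length(unique(windows$gene_id[hit]))
  }, integer(1))
  kept <- reads[genes_per_read <= 1L, , drop = FALSE]
  out <- list()
  for (kind in c("tss", "body", "flank")) {
    ws <- windows[[paste0(kind, "_start")]]
    we <- windows[[paste0(kind, "_end")]]
    use <- !is.na(ws) & !is.na(we) & we > ws
    cnt <- vapply(which(use), function(j) {
      sum(kept$chrom == windows$chrom[j] &
            overlaps(kept$start, kept$end, ws[j], we[j]))
    }, integer(1))
    out[[kind]] <- data.frame(gene_id = windows$gene_id[use],
                              window_kind = kind,
                              raw_count = as.numeric(cnt),
                              stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, out),
       n_discarded = sum(genes_per_read > 1L))
}

# Per-base pileup mean coverage, computed positionwise.
brute_force_mean_depth <- function(reads, chrom, from, to) {
  pos <- from:(to - 1L)
  depth <- vapply(pos, function(p) {
    sum(reads$chrom == chrom & reads$start <= p & reads$end > p)
  }, numeric(1))
  mean(depth)
}

# Write a read table as BED3.
write_bed3 <- function(reads, path = tempfile(fileext = ".bed")) {
  write.table(reads[c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  path
}

# Minimal one-gene fixture with hand-placed reads giving exact densities.
# 60 reads over a 300-bp TSS window (density 0.2 at sf 1) etc. are built
# by the callers; this just centralises window derivation.
one_gene_windows <- function(strand = "+", tx_start = 10000L,
                             tx_end = 15000L) {
  derive_windows(make_tx(strand = strand, tx_start = tx_start,
                         tx_end = tx_end))
}
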