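#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`; the enrichment p-value used by
#' [call_peaks()].
#'
#' @param k Observed count(s).
#' @param lambda Expected count(s) under the background model.
#' @return Upper-tail probabilities.
#' @export
poisson_upper_tail <- function(k, lambda) {
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Call tag-enriched regions against a matched input library
#'
#' A deliberately simple sliding-window enrichment caller. The genome is
#' tiled in `window`-bp windows every `step` bp; both libraries are scaled
#' to the smaller of the pair; the expected count in each window is the
#' scaled input count, floored at the genome-wide mean scaled input per
#' window (guarding empty-input windows); a window is a candidate iff its
#' fold enrichment (scaled IP / expected) reaches `min_fold` and its
#' Poisson upper-tail p-value (raw IP count against `expected` rescaled to
#' the raw IP scale) is significant after Benjamini-Hochberg adjustment at
#' `fdr`. Overlapping and adjacent candidate windows are merged into one
#' peak keeping the statistics of the best-p window.
#'
#' @param ip,input Read tables (see [load_reads()]) for the
#'   immunoprecipitated and matched input libraries.
#' @param window,step Sliding-window width and offset (bp).
#' @param min_fold Minimum fold enrichment over background.
#' @param fdr Benjamini-Hochberg false-discovery-rate threshold.
#' @param chrom_sizes Optional named vector of chromosome lengths; by
#'   default the extent of the reads in either library.
#' @return `data.frame` of peaks: `chrom`, `start`, `end` (0-based
#'   half-open), `ip_count` (scaled), `expected`, `fold`, `p_value`,
#'   `q_value`.
#' @export
call_peaks <- function(ip, input, window = 500L, step = 100L,
                       min_fold = 4, fdr = 0.001, chrom_sizes = NULL) {
  if (nrow(input) == 0L) stop("input library has no reads")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), ip_count = numeric(),
                      expected = numeric(), fold = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(ip) == 0L) return(empty)
  sf <- library_scale_factors(c(ip = nrow(ip), input = nrow(input)))

  if (is.null(chrom_sizes)) {
    all_reads <- rbind(ip[c("chrom", "end")], input[c("chrom", "end")])
    chrom_sizes <- tapply(all_reads$end, all_reads$chrom, max)
  }
  tiles <- do.call(rbind, lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    s <- seq(0L, max(0L, len - 1L), by = step)
    data.frame(chrom = chrom, start = s, end = pmin(s + window, len),
               stringsAsFactors = FALSE)
  }))
  tgr <- GenomicRanges::GRanges(
    tiles$chrom, IRanges::IRanges(tiles$start + 1L, tiles$end))
  raw_ip <- GenomicRanges::countOverlaps(tgr, reads_granges(ip))
  raw_in <- GenomicRanges::countOverlaps(tgr, reads_granges(input))
  scaled_ip <- raw_ip * sf[["ip"]]
  scaled_in <- raw_in * sf[["input"]]
  expected <- pmax(scaled_in, mean(scaled_in))
  if (all(expected == 0)) stop("input library yields zero expected counts")
  fold <- scaled_ip / expected
  p <- poisson_upper_tail(raw_ip, expected / sf[["ip"]])
  q <- stats::p.adjust(p, method = "BH")
  cand <- fold >= min_fold & q <= fdr
  if (!any(cand)) return(empty)

  cgr <- tgr[cand]
  merged <- GenomicRanges::reduce(cgr)
  hit <- GenomicRanges::findOverlaps(cgr, merged)
  best <- tapply(which(cand)[S4Vectors::queryHits(hit)],
                 S4Vectors::subjectHits(hit),
                 function(ix) ix[which.min(p[ix])])
  best <- unlist(best)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    ip_count = scaled_ip[best],
    expected = expected[best],
    fold = fold[best],
    p_value = p[best],
    q_value = q[best],
    stringsAsFactors = FALSE)
}

#' Genes carrying an enrichment peak
#'
#' Cross-references peaks with transcript spans: a gene is included iff
#' any peak overlaps its span extended by `slop` bp on both sides.
#'
#' @param peaks Peak table from [call_peaks()].
#' @param tx Transcript-model `data.frame`.
#' @param slop Span extension in bp.
#' @return Character vector of `gene_id`s.
#' @export
genes_with_peak <- function(peaks, tx, slop = 2000L) {
  if (nrow(peaks) == 0L) return(character())
  pgr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  sgr <- GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(pmax(1L, tx$tx_start - slop + 1L), tx$tx_end + slop))
  hits <- GenomicRanges::findOverlaps(sgr, pgr)
  unique(tx$gene_id[S4Vectors::queryHits(hits)])
}

#' Export peaks as BED6+3
#'
#' Columns: chrom, start, end, name, fold (as score), strand ".",
#' then scaled IP count, p-value, q-value.
#'
#' @param peaks Peak table from [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
peaks_to_bed <- function(peaks, path) {
  bed <- data.frame(
    peaks$chrom, peaks$start, peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = peaks$fold, strand = ".",
    peaks$ip_count, peaks$p_value, peaks$q_value)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
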