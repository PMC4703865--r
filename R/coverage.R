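#' Load aligned reads from a BED (or BAM) file
#'
#' Reads one library of aligned, deduplicated ChIP-seq tags. BED input is
#' 0-based half-open (BED3 or BED6); BAM input requires the `Rsamtools`
#' package. Records with `end <= start` are skipped and tallied rather
#' than failing the whole library. Read strand is retained but ignored by
#' all downstream quantification (ChIP tags are unstranded with respect to
#' the template).
#'
#' @param path Path to a `.bed` or `.bam` file.
#' @param format `"auto"` (from extension), `"bed"` or `"bam"`.
#' @return A list with elements `reads` (a `data.frame` with `chrom`,
#'   `start`, `end` in 0-based half-open coordinates, `strand`), `total`
#'   (number of valid records: the library's total mapped reads) and
#'   `skipped` (invalid records dropped).
#' @export
load_reads <- function(path, format = c("auto", "bed", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  if (format == "bam") {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM input requires the Rsamtools package")
    }
    b <- Rsamtools::scanBam(
      path, param = Rsamtools::ScanBamParam(
        what = c("rname", "pos", "qwidth", "strand"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
    df <- data.frame(chrom = as.character(b$rname),
                     start = b$pos - 1L,
                     end = b$pos - 1L + b$qwidth,
                     strand = as.character(b$strand),
                     stringsAsFactors = FALSE)
  } else {
    df <- suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t",
                        data.table = FALSE))
    if (nrow(df) == 0L) {
      df <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character())
      return(list(reads = df, total = 0L, skipped = 0L))
    }
    if (ncol(df) < 3L) stop("BED input needs at least 3 columns: ", path)
    strand <- if (ncol(df) >= 6L) as.character(df[[6]]) else "*"
    df <- data.frame(chrom = as.character(df[[1]]),
                     start = as.integer(df[[2]]),
                     end = as.integer(df[[3]]),
                     strand = strand,
                     stringsAsFactors = FALSE)
  }
  bad <- is.na(df$start) | is.na(df$end) | df$end <= df$start | df$start < 0
  if (any(bad)) {
    warning(sum(bad), " invalid interval(s) skipped in ", path)
    df <- df[!bad, , drop = FALSE]
  }
  list(reads = df, total = nrow(df), skipped = sum(bad))
}

# GRanges view of an internal 0-based half-open read table.
reads_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(start = reads$start + 1L,
                                          end = reads$end))
}

#' Assign reads to quantification windows under the single-gene rule
#'
#' A read contributes to a window iff its alignment interval overlaps the
#' window by at least 1 bp. Reads overlapping the annotated transcript
#' spans of more than one gene are discarded entirely and tallied; the
#' rule is enforced against the (primary) transcript spans in `windows`,
#' not against flank windows, which routinely reach into neighbouring
#' genes.
#'
#' @param reads Read table from [load_reads()] (`$reads`), or a compatible
#'   `data.frame`.
#' @param windows Window table from [derive_windows()].
#' @param kinds Window kinds to count. Default counts TSS-proximal, body
#'   and flank windows.
#' @return A list: `counts` — a `data.frame` with one row per
#'   (gene, window kind) holding `gene_id`, `transcript_id`,
#'   `window_kind`, `raw_count`, `window_length`; `n_discarded` — reads
#'   dropped by the multi-gene rule; `n_assigned` — kept reads that hit at
#'   least one window; `n_outside` — kept reads hitting none.
#' @export
assign_reads <- function(reads, windows,
                         kinds = c("tss", "body", "flank")) {
  rg <- reads_granges(reads)
  spans <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$tx_start + 1L, end = windows$tx_end))
  hits <- GenomicRanges::findOverlaps(rg, spans)
  genes_hit <- windows$gene_id[S4Vectors::subjectHits(hits)]
  ngene <- tapply(genes_hit, S4Vectors::queryHits(hits),
                  function(g) length(unique(g)))
  multi <- as.integer(names(ngene)[ngene > 1L])
  keep <- setdiff(seq_along(rg), multi)
  rg_keep <- rg[keep]

  counts <- vector("list", length(kinds))
  touched <- logical(length(rg_keep))
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    wgr <- window_granges(windows, kind)
    n <- GenomicRanges::countOverlaps(wgr, rg_keep)
    ov <- GenomicRanges::findOverlaps(rg_keep, wgr)
    touched[unique(S4Vectors::queryHits(ov))] <- TRUE
    counts[[i]] <- data.frame(
      gene_id = GenomicRanges::mcols(wgr)$gene_id,
      transcript_id = GenomicRanges::mcols(wgr)$transcript_id,
      window_kind = kind,
      raw_count = as.numeric(n),
      window_length = GenomicRanges::width(wgr),
      stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, counts),
       n_discarded = length(multi),
       n_assigned = sum(touched),
       n_outside = sum(!touched))
}

#' Library scale factors matching the smallest library
#'
#' Every library's counts are linearly down-scaled so its effective number
#' of mapped reads matches the library with the fewest: the factor is
#' `min(totals) / total`, hence always in (0, 1] and exactly 1 for the
#' smallest library.
#'
#' @param totals Named numeric vector of total mapped reads per library.
#' @return Named numeric vector of scale factors.
#' @export
library_scale_factors <- function(totals) {
  totals <- unlist(totals)
  if (any(totals <= 0)) stop("all library totals must be positive")
  totals * 0 + min(totals) / totals
}

#' Scaled counts and per-bp read densities
#'
#' Applies a library scale factor to raw window counts and derives the
#' per-bp density `scaled_count / window_length` (reads per base pair).
#' Scaled counts are fractional by design. Windows of zero length (flagged
#' empty bodies) get `NA` density.
#'
#' @param counts Count table from [assign_reads()] (`$counts`).
#' @param scale_factor The library's scale factor (see
#'   [library_scale_factors()]).
#' @return The count table with `scaled_count` and `density` columns
#'   appended.
#' @export
window_density <- function(counts, scale_factor = 1) {
  stopifnot(scale_factor > 0, scale_factor <= 1)
  counts$scaled_count <- counts$raw_count * scale_factor
  counts$density <- ifelse(counts$window_length > 0,
                           counts$scaled_count / counts$window_length,
                           NA_real_)
  counts
}

#' TSS-centred binned profile matrix
#'
#' Bins scaled read counts over each gene's flank window (default
#' `(-2000, +2500)` about the TSS), oriented 5' to 3': rows of minus-strand
#' genes are reversed relative to genomic order so that column 1 is always
#' the most upstream bin. A read is assigned to the single bin containing
#' its midpoint.
#'
#' @param reads Read table (see [assign_reads()]).
#' @param windows Window table from [derive_windows()].
#' @param bin_size Bin width in bp; must divide the flank length.
#' @param scale_factor Library scale factor applied to all counts.
#' @return Numeric matrix, genes x bins, rownames `gene_id`.
#' @export
binned_profile <- function(reads, windows, bin_size = 50L,
                           scale_factor = 1) {
  flank_len <- windows$flank_end - windows$flank_start
  nbin <- as.integer(max(flank_len) %/% bin_size)
  mid <- (reads$start + reads$end) %/% 2L
  mat <- matrix(0, nrow = nrow(windows), ncol = nbin,
                dimnames = list(windows$gene_id, NULL))
  for (i in seq_len(nrow(windows))) {
    sel <- reads$chrom == windows$chrom[i] &
      mid >= windows$flank_start[i] & mid < windows$flank_end[i]
    if (!any(sel)) next
    off <- if (windows$strand[i] == "+") {
      mid[sel] - windows$flank_start[i]
    } else {
      windows$flank_end[i] - 1L - mid[sel]
    }
    bin <- off %/% bin_size + 1L
    tab <- tabulate(bin, nbins = nbin)
    mat[i, ] <- tab * scale_factor
  }
  mat
}

#' Mean per-base coverage depth over gene bodies
#'
#' Base-level mean coverage: each read contributes to every base it
#' overlaps, the per-base pileup is averaged over the body window, and the
#' result is multiplied by the library scale factor. Genes with a
#' flagged-empty body get `NA`.
#'
#' @param reads Read table.
#' @param windows Window table from [derive_windows()].
#' @param scale_factor Library scale factor.
#' @return Named numeric vector of mean depths (reads/bp), one per gene.
#' @export
mean_body_depth <- function(reads, windows, scale_factor = 1) {
  cov <- GenomicRanges::coverage(reads_granges(reads))
  out <- rep(NA_real_, nrow(windows))
  names(out) <- windows$gene_id
  for (i in seq_len(nrow(windows))) {
    if (!windows$body_ok[i]) next
    chrom <- windows$chrom[i]
    s <- windows$body_start[i] + 1L
    e <- windows$body_end[i]
    if (!chrom %in% names(cov)) { out[i] <- 0; next }
    rle <- cov[[chrom]]
    if (e > length(rle)) {  # pad: no reads beyond coverage extent
      rle <- c(rle, S4Vectors::Rle(0L, e - length(rle)))
    }
    out[i] <- mean(IRanges::Views(rle, start = s, end = e)[[1]]) *
      scale_factor
  }
  out
}

#' Export a scaled coverage track as bedGraph
#'
#' Writes the library's base-level coverage, multiplied by its scale
#' factor, as a 4-column bedGraph (0-based half-open) for genome-browser
#' inspection.
#'
#' @param reads Read table.
#' @param path Output path.
#' @param scale_factor Library scale factor.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(reads, path, scale_factor = 1) {
  cov <- GenomicRanges::coverage(reads_granges(reads)) * scale_factor
  rtracklayer::export(cov, path, format = "bedGraph")
  invisible(path)
}

#' Read a library sheet
#'
#' A library sheet is a TSV with columns `library_id`, `condition`,
#' `mark`, `path` describing one aligned library per
#' condition-by-antibody-mark combination (plus one `input` library per
#' condition).
#'
#' @param path TSV path.
#' @return `data.frame` with the four columns above.
#' @export
read_library_sheet <- function(path) {
  sheet <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("library_id", "condition", "mark", "path")
  if (!all(need %in% names(sheet))) {
    stop("library sheet must have columns: ", paste(need, collapse = ", "))
  }
  sheet
}
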