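#' Read transcript models from a GTF annotation
#'
#' Parses an Ensembl-dialect GTF and returns one transcript model per
#' annotated transcript. Coordinates are converted from GTF 1-based
#' inclusive to the package-internal 0-based half-open convention. The TSS
#' is the 5' end of the transcript: `tx_start` on the plus strand,
#' `tx_end - 1` on the minus strand.
#'
#' Transcript spans are taken from `transcript` features when present;
#' otherwise they are derived as the range of each transcript's `exon`
#' features. When a `gene_biotype` (or `gene_type`) attribute is present
#' and `protein_coding_only = TRUE`, non-coding genes are dropped.
#'
#' @param path Path to a GTF file.
#' @param protein_coding_only Keep only `gene_biotype == "protein_coding"`
#'   when the attribute exists. Default `TRUE`.
#' @return A `data.frame` with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end` (0-based half-open), `tss`, `tx_length`.
#' @export
read_gtf_transcripts <- function(path, protein_coding_only = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  body <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("malformed GTF line ", lineno[which(nf < 9)[1]],
         ": expected 9 tab-separated fields, found ", nf[which(nf < 9)[1]])
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ends   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(is.na(starts) | is.na(ends))[1]
    stop("malformed GTF line ", lineno[bad], ": non-numeric coordinates")
  }
  inverted <- ends < starts
  if (any(inverted)) {
    warning(sum(inverted), " GTF feature(s) with end < start rejected")
  }
  src <- path
  if (any(inverted)) {
    src <- tempfile(fileext = ".gtf")
    on.exit(unlink(src), add = TRUE)
    writeLines(lines[keep][!inverted], src)
  }
  gr <- rtracklayer::import(src, format = "gtf")

  md <- GenomicRanges::mcols(gr)
  type <- as.character(md$type)
  if (any(type == "transcript")) {
    gr <- gr[type == "transcript"]
  } else if (any(type == "exon")) {
    ex <- gr[type == "exon"]
    sp <- split(ex, GenomicRanges::mcols(ex)$transcript_id)
    gr <- unlist(range(sp))
    ids <- names(gr)
    g2t <- unique(data.frame(
      transcript_id = as.character(GenomicRanges::mcols(ex)$transcript_id),
      gene_id = as.character(GenomicRanges::mcols(ex)$gene_id),
      biotype = .biotype_attr(GenomicRanges::mcols(ex)),
      stringsAsFactors = FALSE))
    g2t <- g2t[match(ids, g2t$transcript_id), ]
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = g2t$gene_id, transcript_id = ids, gene_biotype = g2t$biotype)
  } else {
    stop("GTF contains neither 'transcript' nor 'exon' features")
  }

  md <- GenomicRanges::mcols(gr)
  biotype <- .biotype_attr(md)
  if (protein_coding_only && !all(is.na(biotype))) {
    gr <- gr[is.na(biotype) | biotype == "protein_coding"]
  }
  bad <- GenomicRanges::width(gr) < 1
  if (any(bad)) {
    warning(sum(bad), " transcript(s) with end <= start rejected")
    gr <- gr[!bad]
  }
  transcript_models(
    gene_id = as.character(GenomicRanges::mcols(gr)$gene_id),
    transcript_id = as.character(GenomicRanges::mcols(gr)$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = GenomicRanges::start(gr) - 1L,
    tx_end = GenomicRanges::end(gr))
}

.biotype_attr <- function(md) {
  if (!is.null(md$gene_biotype)) as.character(md$gene_biotype)
  else if (!is.null(md$gene_type)) as.character(md$gene_type)
  else rep(NA_character_, nrow(md))
}

#' Construct transcript models from coordinate vectors
#'
#' Builds the transcript-model table used throughout the package from
#' 0-based half-open genomic spans, deriving the TSS from the strand.
#'
#' @param gene_id,transcript_id Identifier vectors.
#' @param chrom Chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end 0-based half-open transcript span.
#' @return `data.frame` of transcript models (see [read_gtf_transcripts()]).
#' @export
transcript_models <- function(gene_id, transcript_id, chrom, strand,
                              tx_start, tx_end) {
  stopifnot(all(strand %in% c("+", "-")),
            all(tx_start >= 0), all(tx_end > tx_start))
  data.frame(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    tx_start = as.integer(tx_start),
    tx_end = as.integer(tx_end),
    tss = as.integer(ifelse(strand == "+", tx_start, tx_end - 1L)),
    tx_length = as.integer(tx_end - tx_start),
    stringsAsFactors = FALSE)
}

#' Serialize transcript models to GTF
#'
#' Writes one `transcript` feature per model, converting back to GTF
#' 1-based inclusive coordinates, so that
#' `read_gtf_transcripts(write_transcript_gtf(tx, f))` is the identity.
#'
#' @param tx Transcript-model `data.frame`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(tx, path) {
  gr <- GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(start = tx$tx_start + 1L, end = tx$tx_end),
    strand = tx$strand,
    type = "transcript",
    gene_id = tx$gene_id,
    transcript_id = tx$transcript_id,
    gene_biotype = "protein_coding")
  GenomicRanges::mcols(gr)$source <- "pausekit"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Select the primary transcript of each gene
#'
#' One transcript per gene is retained for all downstream pausing
#' statistics: the one with maximal gene-body read density (reads per bp
#' between +250 and the transcript 3' end). Ties are broken by greater
#' transcript length, then lexicographically smaller `transcript_id`.
#'
#' @param tx Transcript-model `data.frame` (may hold several genes).
#' @param body_density Named numeric vector: body read density per
#'   `transcript_id`. Zero is allowed; every transcript must be present.
#' @return The subset of `tx` rows containing one primary transcript per
#'   gene.
#' @export
select_primary_transcripts <- function(tx, body_density) {
  if (nrow(tx) == 0L) stop("no transcripts supplied")
  missing <- setdiff(tx$transcript_id, names(body_density))
  if (length(missing)) {
    stop("body density missing for transcript(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  dens <- unname(body_density[tx$transcript_id])
  ord <- order(tx$gene_id, -dens, -tx$tx_length, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  tx[!duplicated(tx$gene_id), , drop = FALSE]
}

#' Derive strand-aware quantification windows for transcripts
#'
#' For each transcript, derives three windows in transcript orientation
#' (offset +x means x bp downstream of the TSS in the direction of
#' transcription), as 0-based half-open genomic intervals:
#' \describe{
#'   \item{TSS-proximal}{`[-tss_halfwidth, +tss_halfwidth)` about the TSS;
#'     300 bp by default with the TSS at offset 150.}
#'   \item{gene body}{`+body_offset` to the transcript 3' end.}
#'   \item{flank}{`[-flank_up, +flank_down)` about the TSS; 4,500 bp by
#'     default, used for TSS-centred profiles.}
#' }
#' Windows are clipped at position 0. Transcripts too short to hold a
#' usable body window (`tx_length <= body_offset + min_body`) keep an
#' empty body and are flagged `body_ok = FALSE`; such genes are excluded
#' from pausing statistics rather than erroring.
#'
#' @param tx Transcript-model `data.frame`.
#' @param tss_halfwidth Half-width of the TSS-proximal window (bp).
#' @param body_offset Distance from TSS to body window start (bp).
#' @param flank_up,flank_down Flank window extent up/downstream of TSS (bp).
#' @param min_body Minimum usable body length (bp).
#' @return `data.frame`: the columns of `tx` plus `tss_start`, `tss_end`,
#'   `body_start`, `body_end`, `body_length`, `body_ok`, `flank_start`,
#'   `flank_end`.
#' @export
derive_windows <- function(tx, tss_halfwidth = 150L, body_offset = 250L,
                           flank_up = 2000L, flank_down = 2500L,
                           min_body = 200L) {
  w <- tx
  tssw <- .oriented_window(tx$tss, tx$strand, -tss_halfwidth, tss_halfwidth)
  w$tss_start <- tssw[, 1]
  w$tss_end <- tssw[, 2]

  body_ok <- tx$tx_length > body_offset + min_body
  bw <- .oriented_window(tx$tss, tx$strand, body_offset, tx$tx_length)
  w$body_start <- ifelse(body_ok, bw[, 1], NA_integer_)
  w$body_end <- ifelse(body_ok, bw[, 2], NA_integer_)
  w$body_length <- ifelse(body_ok, pmax(0L, tx$tx_length - body_offset),
                          0L)
  w$body_ok <- body_ok

  fw <- .oriented_window(tx$tss, tx$strand, -flank_up, flank_down)
  w$flank_start <- fw[, 1]
  w$flank_end <- fw[, 2]
  w
}

# Half-open window [up, down) in transcript coordinates about the TSS,
# mapped to genomic coordinates; clipped at the chromosome start.
.oriented_window <- function(tss, strand, up, down) {
  s <- ifelse(strand == "+", tss + up, tss - down + 1)
  e <- ifelse(strand == "+", tss + down, tss - up + 1)
  cbind(pmax(0, s), pmax(0, e))
}

#' Export derived windows as BED6
#'
#' Writes one record per (transcript, window kind), named
#' `gene_id|transcript_id|kind` with score 0, in 0-based half-open BED
#' coordinates. Flagged-empty body windows are skipped.
#'
#' @param windows Output of [derive_windows()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
windows_to_bed <- function(windows, path) {
  rows <- list()
  for (kind in c("tss", "body", "flank")) {
    s <- windows[[paste0(kind, "_start")]]
    e <- windows[[paste0(kind, "_end")]]
    keep <- !is.na(s) & !is.na(e) & e > s
    rows[[kind]] <- data.frame(
      chrom = windows$chrom[keep], start = s[keep], end = e[keep],
      name = paste(windows$gene_id[keep], windows$transcript_id[keep],
                   kind, sep = "|"),
      score = 0L, strand = windows$strand[keep],
      stringsAsFactors = FALSE)
  }
  bed <- do.call(rbind, rows)
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges view of one window kind; drops flagged-empty windows.
window_granges <- function(windows, kind = c("tss", "body", "flank")) {
  kind <- match.arg(kind)
  s <- windows[[paste0(kind, "_start")]]
  e <- windows[[paste0(kind, "_end")]]
  keep <- !is.na(s) & !is.na(e) & e > s
  gr <- GenomicRanges::GRanges(
    windows$chrom[keep],
    IRanges::IRanges(start = s[keep] + 1L, end = e[keep]),
    strand = windows$strand[keep])
  GenomicRanges::mcols(gr)$gene_id <- windows$gene_id[keep]
  GenomicRanges::mcols(gr)$transcript_id <- windows$transcript_id[keep]
  gr
}
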