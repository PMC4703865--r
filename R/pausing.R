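#' Pausing index
#'
#' The pausing index (PI) quantifies the net movement of Pol II from the
#' TSS region into the gene body: the ratio of read density in the
#' TSS-proximal window to read density in the gene body. High PI means
#' paused; a PI decrease between conditions means pause release. The PI is
#' undefined (`NA`) where the body density is not positive; such genes are
#' expected to be removed by [filter_expressed()] beforehand.
#'
#' Because numerator and denominator share the library's scale factor,
#' the PI is invariant to library scaling.
#'
#' @param tss_density,body_density Read densities (reads/bp).
#' @return Dimensionless ratio(s); `NA` where `body_density <= 0`.
#' @export
pausing_index <- function(tss_density, body_density) {
  ifelse(!is.na(body_density) & body_density > 0,
         tss_density / body_density, NA_real_)
}

#' Per-gene pausing records for one condition
#'
#' Pivots a long density table (from [window_density()], restricted to one
#' library) into one row per gene with TSS and body scaled counts,
#' densities, and the pausing index.
#'
#' @param density Density table for a single library with `tss` and
#'   `body` window rows.
#' @param condition Condition label to attach.
#' @return `data.frame`: `gene_id`, `transcript_id`, `condition`,
#'   `tss_count`, `body_count` (scaled), `tss_density`, `body_density`,
#'   `pausing_index`.
#' @export
pausing_records <- function(density, condition) {
  tss <- density[density$window_kind == "tss", ]
  body <- density[density$window_kind == "body", ]
  m <- match(tss$gene_id, body$gene_id)
  # the PI is computed from raw densities: the scale factor cancels
  # algebraically, and keeping it out avoids needless round-off, making
  # the index bit-identical across library scalings
  raw_tss_density <- tss$raw_count / tss$window_length
  raw_body_density <- ifelse(body$window_length[m] > 0,
                             body$raw_count[m] / body$window_length[m],
                             NA_real_)
  data.frame(
    gene_id = tss$gene_id,
    transcript_id = tss$transcript_id,
    condition = condition,
    tss_count = tss$scaled_count,
    body_count = body$scaled_count[m],
    tss_density = tss$density,
    body_density = body$density[m],
    pausing_index = pausing_index(raw_tss_density, raw_body_density),
    stringsAsFactors = FALSE)
}

#' Filter genes by gene-body read density
#'
#' Pausing indices are unstable at low occupancy, so genes whose body
#' read density does not exceed `threshold` are removed. Under the default
#' `"any"` policy a gene passes if it exceeds the threshold in at least
#' one of the conditions under comparison — genes silent at baseline but
#' induced afterwards are retained. The `"all"` policy requires every
#' condition to pass.
#'
#' @param densities `data.frame` with columns `gene_id`, `condition`,
#'   `body_density` (scaled; one row per gene per condition).
#' @param threshold Body density cutoff (reads/bp); a gene must exceed it
#'   strictly.
#' @param policy `"any"` or `"all"` across conditions.
#' @return Character vector of passing `gene_id`s.
#' @export
filter_expressed <- function(densities, threshold = 0.05,
                             policy = c("any", "all")) {
  policy <- match.arg(policy)
  ok <- !is.na(densities$body_density) & densities$body_density > threshold
  agg <- tapply(ok, densities$gene_id, if (policy == "any") any else all)
  names(agg)[agg]
}

#' Percent occupancy change between scaled counts
#'
#' `100 * (B - A) / max(A, pseudocount * scale_factor)`. The pseudocount
#' floor (scaled to the library depth) keeps the change finite for genes
#' unoccupied at baseline.
#'
#' @param scaled_count_a,scaled_count_b Scaled counts in the baseline and
#'   comparison conditions.
#' @param pseudocount Raw-count floor for the denominator.
#' @param scale_factor Scale factor of the baseline library.
#' @return Percent change(s).
#' @export
occupancy_change_pct <- function(scaled_count_a, scaled_count_b,
                                 pseudocount = 1, scale_factor = 1) {
  100 * (scaled_count_b - scaled_count_a) /
    pmax(scaled_count_a, pseudocount * scale_factor)
}

#' Contrast pausing records between two conditions
#'
#' Joins the per-gene records of a baseline condition A and a comparison
#' condition B, computing the pausing-index ratio `PI(A)/PI(B)` (values
#' above 1 mean pause release in B), TSS and body percent occupancy
#' changes, the expression-filter flag, and the activated classification.
#'
#' @param rec_a,rec_b Outputs of [pausing_records()] for conditions A
#'   (baseline, e.g. S0) and B (e.g. S15).
#' @param filter_genes Genes passing [filter_expressed()].
#' @param fold_threshold Activation threshold on the PI ratio.
#' @param require_body_increase Additionally require the scaled body count
#'   to increase in B. Default off.
#' @param pseudocount,scale_factor_a Passed to [occupancy_change_pct()].
#' @return `data.frame`: `gene_id`, `pi_a`, `pi_b`, `pi_ratio`,
#'   `tss_change_pct`, `body_change_pct`, `filter_pass`, `activated`.
#' @export
pausing_contrast <- function(rec_a, rec_b, filter_genes,
                             fold_threshold = 2,
                             require_body_increase = FALSE,
                             pseudocount = 1, scale_factor_a = 1) {
  common <- intersect(rec_a$gene_id, rec_b$gene_id)
  a <- rec_a[match(common, rec_a$gene_id), ]
  b <- rec_b[match(common, rec_b$gene_id), ]
  out <- data.frame(
    gene_id = common,
    transcript_id = a$transcript_id,
    pi_a = a$pausing_index,
    pi_b = b$pausing_index,
    pi_ratio = a$pausing_index / b$pausing_index,
    tss_change_pct = occupancy_change_pct(a$tss_count, b$tss_count,
                                          pseudocount, scale_factor_a),
    body_change_pct = occupancy_change_pct(a$body_count, b$body_count,
                                           pseudocount, scale_factor_a),
    body_count_a = a$body_count,
    body_count_b = b$body_count,
    filter_pass = common %in% filter_genes,
    stringsAsFactors = FALSE)
  out$activated <- out$gene_id %in%
    classify_activated(out, fold_threshold, require_body_increase)
  out
}

#' Classify transcriptionally activated (pause-released) genes
#'
#' A gene is activated iff it passed the expression filter, both
#' conditions' pausing indices are defined, and
#' `PI(A)/PI(B) > fold_threshold` — at the default threshold 2 this is the
#' "at least 50 percent PI reduction upon induction" criterion.
#' Optionally the scaled gene-body count must also increase.
#'
#' @param contrasts Contrast table from [pausing_contrast()].
#' @param fold_threshold PI-ratio threshold.
#' @param require_body_increase Extra gate on body-count increase.
#' @return Character vector of activated `gene_id`s.
#' @export
classify_activated <- function(contrasts, fold_threshold = 2,
                               require_body_increase = FALSE) {
  ok <- contrasts$filter_pass &
    !is.na(contrasts$pi_ratio) & contrasts$pi_ratio > fold_threshold
  if (require_body_increase) {
    ok <- ok & contrasts$body_count_b > contrasts$body_count_a
  }
  contrasts$gene_id[ok]
}
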