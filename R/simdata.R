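#' Synthetic gene panel for ChIP-seq simulation
#'
#' Builds a panel of non-overlapping genes on one synthetic chromosome,
#' placed with fixed gaps so the single-gene read rule is unambiguous,
#' with alternating strands and known generative parameters per gene:
#' `lambda_tss` (expected reads in the promoter-proximal pause peak),
#' `lambda_body` (expected reads per bp of gene body) and
#' `release_factor` (multiplicative body-rate increase upon induction; 1
#' for non-activated genes).
#'
#' @param n_genes Number of genes.
#' @param frac_activated Fraction of genes given `release_factor`.
#' @param release_factor Body-rate fold increase of activated genes on
#'   induction.
#' @param lambda_tss Expected reads in the TSS pause peak (per unit
#'   depth).
#' @param lambda_body Expected reads per bp of gene body (per unit depth).
#' @param tx_length_range Range transcript lengths are drawn from (bp).
#' @param peak_offset Centre of the paused peak, bp downstream of the TSS.
#' @param peak_sd Peak standard deviation (bp).
#' @param gap Intergenic gap (bp); at least 10 kb keeps flanks separate.
#' @param chrom Synthetic chromosome name.
#' @param seed PRNG seed for lengths, strands and the activated subset.
#' @return `data.frame` of gene specs with columns `gene_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `tss`, `tx_length`, `lambda_tss`,
#'   `lambda_body`, `release_factor`, `peak_offset`, `peak_sd`,
#'   `activated`; the chromosome length is in `attr(, "chrom_length")`.
#' @export
sim_gene_panel <- function(n_genes = 200L, frac_activated = 0.5,
                           release_factor = 3, lambda_tss = 300,
                           lambda_body = 0.25,
                           tx_length_range = c(2000L, 8000L),
                           peak_offset = 50, peak_sd = 30,
                           gap = 10000L, chrom = "chrS", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes >= 1, gap >= 10000L, min(tx_length_range) > 550L)
  len <- sample(seq(tx_length_range[1], tx_length_range[2]), n_genes,
                replace = TRUE)
  strand <- rep(c("+", "-"), length.out = n_genes)
  activated <- seq_len(n_genes) %in%
    sample.int(n_genes, round(frac_activated * n_genes))
  tx_start <- gap + cumsum(c(0, utils::head(len, -1) + gap))
  tx_end <- tx_start + len
  specs <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = chrom,
    strand = strand,
    tx_start = as.integer(tx_start),
    tx_end = as.integer(tx_end),
    tss = as.integer(ifelse(strand == "+", tx_start, tx_end - 1L)),
    tx_length = as.integer(len),
    lambda_tss = lambda_tss,
    lambda_body = lambda_body,
    release_factor = ifelse(activated, release_factor, 1),
    peak_offset = peak_offset,
    peak_sd = peak_sd,
    activated = activated,
    stringsAsFactors = FALSE)
  attr(specs, "chrom_length") <- as.integer(max(tx_end) + gap)
  specs
}

# Body-rate multiplier of a condition: induction applies the gene's
# release factor; an inhibitor condition (label containing "+") blocks
# release.
.release_multiplier <- function(condition, release_factor) {
  if (condition == "S15") release_factor
  else rep(1, length(release_factor))
}

# TSS-rate multiplier: inhibitor conditions retain extra Pol II at the
# TSS (release blocked while initiation continues).
.tss_multiplier <- function(condition, tss_retention) {
  if (grepl("+", condition, fixed = TRUE)) tss_retention else 1
}

#' Closed-form expected pausing index of simulated genes
#'
#' The plug-in pausing index implied by a gene's generative rates:
#' expected TSS density `lambda_tss / 300` over expected body density
#' `lambda_body * r`, where `r` is the gene's release factor under
#' induction (condition `"S15"`) and 1 otherwise (baseline `"S0"`, or any
#' inhibitor condition, where release is blocked). Background reads are
#' not part of the closed form.
#'
#' @param specs Gene panel from [sim_gene_panel()].
#' @param condition Condition label (`"S0"`, `"S15"`, or an inhibitor
#'   label such as `"S15+NU7441"`).
#' @param tss_halfwidth Half-width of the TSS window (bp).
#' @return Numeric vector of expected pausing indices; `NA` where the
#'   body rate is zero.
#' @export
expected_pausing_index <- function(specs, condition,
                                   tss_halfwidth = 150) {
  r <- .release_multiplier(condition, specs$release_factor)
  body_rate <- specs$lambda_body * r
  ifelse(body_rate > 0,
         (specs$lambda_tss / (2 * tss_halfwidth)) / body_rate,
         NA_real_)
}

#' Simulate one ChIP-seq library
#'
#' Draws aligned-read coordinates for one condition-by-mark library over
#' a synthetic gene panel:
#' \describe{
#'   \item{PolII}{per gene, `Poisson(lambda_tss * depth)` reads whose
#'     starts follow a truncated normal centred `peak_offset` bp
#'     downstream of the TSS (the paused peak), confined to the
#'     TSS-proximal window, plus `Poisson(lambda_body * body_length *
#'     depth * r)` reads uniform over the gene body, where `r` is the
#'     release multiplier of the condition. Inhibitor conditions multiply
#'     the TSS component by `tss_retention` (default 1.3), emulating TSS
#'     accumulation when release is blocked.}
#'   \item{gH2AX / S2PolII}{body-proportional only: reads uniform over the
#'     transcribed unit `[TSS - 150, transcript end)`, never outside it,
#'     with rate `lambda_body * r` per bp — the mark tracks elongating
#'     Pol II and stays within transcript boundaries.}
#'   \item{input}{background only.}
#' }
#' All marks additionally receive uniform genome-wide background at
#' `background_rate` reads/bp. Reads are `read_length` bp on the forward
#' span.
#'
#' @param specs Gene panel from [sim_gene_panel()].
#' @param condition `"S0"`, `"S15"` or an inhibitor label (contains
#'   `"+"`).
#' @param mark `"PolII"`, `"S2PolII"`, `"gH2AX"` or `"input"`.
#' @param background_rate Genome-wide background (reads/bp).
#' @param read_length Read length (bp).
#' @param depth_factor Library-depth multiplier (emulates differing
#'   library sizes).
#' @param seed PRNG seed.
#' @param chrom_length Chromosome length; default from the panel
#'   attribute.
#' @param tss_retention TSS multiplier of inhibitor conditions.
#' @return List: `reads` (read table as in [load_reads()]), `truth`
#'   (`data.frame` of per-gene expected TSS/body densities and expected
#'   PI for this library, signal components only), `condition`, `mark`.
#' @export
simulate_library <- function(specs, condition, mark,
                             background_rate = 0.01, read_length = 36L,
                             depth_factor = 1, seed = NULL,
                             chrom_length = attr(specs, "chrom_length"),
                             tss_retention = 1.3) {
  if (is.null(chrom_length)) stop("chrom_length required")
  if (nrow(specs) > 1) {
    o <- order(specs$tx_start)
    if (any(specs$tx_start[o][-1] <
            specs$tx_end[o][-nrow(specs)])) {
      stop("gene specs must be non-overlapping")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  r <- .release_multiplier(condition, specs$release_factor)
  tssmult <- .tss_multiplier(condition, tss_retention)
  n <- nrow(specs)
  starts <- list()

  if (mark == "PolII") {
    # paused-peak component, truncated normal inside the TSS window
    lam_tss <- specs$lambda_tss * depth_factor * tssmult
    for (i in seq_len(n)) {
      k <- stats::rpois(1, lam_tss[i])
      if (k == 0) next
      win <- .oriented_window(specs$tss[i], specs$strand[i], -150, 150)
      centre <- if (specs$strand[i] == "+") {
        specs$tss[i] + specs$peak_offset[i]
      } else specs$tss[i] - specs$peak_offset[i]
      lo <- stats::pnorm(win[1], centre, specs$peak_sd[i])
      hi <- stats::pnorm(win[2] - 1, centre, specs$peak_sd[i])
      u <- stats::runif(k, lo, hi)
      starts[[length(starts) + 1L]] <-
        floor(stats::qnorm(u, centre, specs$peak_sd[i]))
    }
    # elongating component, uniform over the gene body
    body_len <- specs$tx_length - 250
    lam_body <- specs$lambda_body * body_len * depth_factor * r
    for (i in seq_len(n)) {
      k <- stats::rpois(1, lam_body[i])
      if (k == 0) next
      win <- .oriented_window(specs$tss[i], specs$strand[i], 250,
                              specs$tx_length[i])
      starts[[length(starts) + 1L]] <-
        win[1] + floor(stats::runif(k, 0, win[2] - win[1]))
    }
  } else if (mark %in% c("S2PolII", "gH2AX")) {
    # body-proportional, confined to [TSS-150, transcript end)
    span_len <- specs$tx_length + 150
    lam <- specs$lambda_body * span_len * depth_factor * r
    for (i in seq_len(n)) {
      k <- stats::rpois(1, lam[i])
      if (k == 0) next
      win <- .oriented_window(specs$tss[i], specs$strand[i], -150,
                              specs$tx_length[i])
      starts[[length(starts) + 1L]] <-
        win[1] + floor(stats::runif(k, 0, win[2] - win[1] - read_length))
    }
  } else if (mark != "input") {
    stop("unknown mark: ", mark)
  }

  k_bg <- stats::rpois(1, background_rate * chrom_length * depth_factor)
  if (k_bg > 0) {
    starts[[length(starts) + 1L]] <-
      floor(stats::runif(k_bg, 0, chrom_length - read_length))
  }
  s <- if (length(starts)) pmax(0, unlist(starts)) else numeric(0)
  reads <- data.frame(chrom = rep(specs$chrom[1], length(s)),
                      start = as.integer(s),
                      end = as.integer(s + read_length),
                      strand = "+",
                      stringsAsFactors = FALSE)

  exp_tss_density <- specs$lambda_tss * depth_factor * tssmult / 300
  exp_body_density <- specs$lambda_body * depth_factor * r
  truth <- data.frame(
    gene_id = specs$gene_id,
    condition = condition, mark = mark,
    expected_tss_density = exp_tss_density,
    expected_body_density = exp_body_density,
    expected_pi = ifelse(exp_body_density > 0,
                         exp_tss_density / exp_body_density, NA_real_),
    stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, condition = condition, mark = mark)
}

#' Write a complete synthetic contrast dataset
#'
#' Generates a self-consistent dataset for an end-to-end run: a gene
#' panel, its GTF annotation, one BED of simulated reads per
#' condition-by-mark library (with condition-dependent depth factors, so
#' the library-scaling step is exercised), a library sheet and a per-gene
#' truth table.
#'
#' @param dir Output directory (created if needed).
#' @param conditions Condition labels; labels containing `"+"` are
#'   inhibitor conditions (release blocked).
#' @param marks Antibody marks to simulate; an `input` library is always
#'   added per condition.
#' @param depth_factors Named per-condition depth multipliers; default
#'   `1, 1.25, 0.8, ...` cycling, giving unequal library sizes.
#' @param background_rate,read_length,tss_retention Passed to
#'   [simulate_library()].
#' @param seed Master seed; per-library seeds are derived from it.
#' @param ... Passed to [sim_gene_panel()].
#' @return List: `specs`, `annotation` (GTF path), `sheet` (library-sheet
#'   path), `truth` (truth TSV path), `libraries` (per-library BED
#'   paths), `chrom_length`.
#' @export
simulate_contrast <- function(dir, conditions = c("S0", "S15"),
                              marks = c("PolII", "gH2AX"),
                              depth_factors = NULL,
                              background_rate = 0.01, read_length = 36L,
                              tss_retention = 1.3, seed = 1L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- sim_gene_panel(seed = seed, ...)
  chrom_length <- attr(specs, "chrom_length")
  if (is.null(depth_factors)) {
    depth_factors <- rep(c(1, 1.25, 0.8, 1.5),
                         length.out = length(conditions))
    names(depth_factors) <- conditions
  }
  annotation <- file.path(dir, "genes.gtf")
  write_transcript_gtf(
    transcript_models(specs$gene_id, paste0(specs$gene_id, ".t1"),
                      specs$chrom, specs$strand, specs$tx_start,
                      specs$tx_end),
    annotation)

  all_marks <- unique(c(marks, "input"))
  grid <- expand.grid(condition = conditions, mark = all_marks,
                      stringsAsFactors = FALSE)
  # input libraries are sequenced to a depth comparable to the matched
  # IP library: uniform background whose total matches the expected
  # Pol II library size of the condition
  body_len <- specs$tx_length - 250
  input_rate <- vapply(conditions, function(cond) {
    r <- .release_multiplier(cond, specs$release_factor)
    tssmult <- .tss_multiplier(cond, tss_retention)
    (sum(specs$lambda_tss * tssmult) + sum(specs$lambda_body * body_len * r)) /
      chrom_length + background_rate
  }, numeric(1))
  sheet <- data.frame(library_id = character(), condition = character(),
                      mark = character(), path = character(),
                      stringsAsFactors = FALSE)
  truth_rows <- list()
  paths <- character()
  for (i in seq_len(nrow(grid))) {
    cond <- grid$condition[i]
    mk <- grid$mark[i]
    lib <- simulate_library(
      specs, cond, mk,
      background_rate = if (mk == "input") input_rate[[cond]] else
        background_rate,
      read_length = read_length,
      depth_factor = depth_factors[[cond]],
      seed = (seed * 131L + i) %% .Machine$integer.max,
      chrom_length = chrom_length, tss_retention = tss_retention)
    id <- paste0(gsub("[^A-Za-z0-9]", "_", cond), "_", mk)
    path <- file.path(dir, paste0(id, ".bed"))
    utils::write.table(
      lib$reads[c("chrom", "start", "end")], path, sep = "\t",
      quote = FALSE, row.names = FALSE, col.names = FALSE)
    sheet <- rbind(sheet, data.frame(
      library_id = id, condition = cond, mark = mk, path = path,
      stringsAsFactors = FALSE))
    truth_rows[[i]] <- lib$truth
    paths[id] <- path
  }
  sheet_path <- file.path(dir, "libraries.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- do.call(rbind, truth_rows)
  truth <- merge(truth, specs[c("gene_id", "release_factor", "activated")],
                 by = "gene_id", sort = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(specs = specs, annotation = annotation, sheet = sheet_path,
       truth = truth_path, libraries = paths,
       chrom_length = chrom_length)
}
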