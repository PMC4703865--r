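#' Configuration for an end-to-end pausing contrast
#'
#' Bundles and validates all inputs and thresholds of [run_contrast()]:
#' the library sheet, the annotation, the baseline and induced condition
#' labels, an optional inhibitor condition (release-blocked comparator),
#' the marks to quantify, and every numeric parameter of the analysis.
#'
#' @param sheet Path to a library sheet (see [read_library_sheet()]).
#' @param annotation Path to a GTF annotation.
#' @param condition_a,condition_b Baseline and induced condition labels.
#' @param inhibitor_condition Optional label of a condition in which
#'   pause release is pharmacologically blocked; enables the
#'   inhibitor-versus-control cohort statistics.
#' @param marks Marks to quantify; the first must be the Pol II mark used
#'   for pausing indices.
#' @param density_threshold Gene-body density filter (reads/bp).
#' @param fold_threshold PI-ratio threshold calling a gene activated.
#' @param use_peak_gate Restrict the gene universe to genes with a Pol II
#'   enrichment peak (requires `input` libraries in the sheet).
#' @param peak_min_fold,peak_fdr Peak-caller parameters.
#' @param n_boot Bootstrap resamples for cohort statistics.
#' @param seed Master seed; all bootstrap seeds derive from it.
#' @param outdir Output directory.
#' @return An object of class `contrast_config`.
#' @export
contrast_config <- function(sheet, annotation,
                            condition_a = "S0", condition_b = "S15",
                            inhibitor_condition = NULL,
                            marks = c("PolII", "gH2AX"),
                            density_threshold = 0.05,
                            fold_threshold = 2,
                            use_peak_gate = FALSE,
                            peak_min_fold = 4, peak_fdr = 0.001,
                            n_boot = 1e5, seed = 1L,
                            outdir = tempfile("contrast")) {
  stopifnot(density_threshold > 0, fold_threshold > 0,
            peak_min_fold > 0, peak_fdr > 0, n_boot >= 1000)
  structure(list(
    sheet = sheet, annotation = annotation,
    condition_a = condition_a, condition_b = condition_b,
    inhibitor_condition = inhibitor_condition,
    marks = marks, pol2_mark = marks[1],
    density_threshold = density_threshold,
    fold_threshold = fold_threshold,
    use_peak_gate = use_peak_gate,
    peak_min_fold = peak_min_fold, peak_fdr = peak_fdr,
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    outdir = outdir), class = "contrast_config")
}

#' Run an end-to-end pausing contrast
#'
#' Executes the full downstream analysis on one baseline/induced
#' condition pair (optionally plus an inhibitor condition): annotation
#' parsing, optional peak calling and gene gating, read assignment under
#' the single-gene rule, library scaling to the smallest library,
#' densities, primary-transcript selection, the expression filter,
#' pausing indices per condition, the condition contrast with activated
#' classification, and cohort-level bootstrap effect sizes:
#' \itemize{
#'   \item Pol II mean gene-body coverage depth, induced vs baseline, on
#'     the activated set;
#'   \item each DDR mark's gene-body density, induced vs baseline, on the
#'     activated set;
#'   \item with an inhibitor condition: the PI-ratio distribution,
#'     control vs inhibitor, and TSS/body percent-change distributions,
#'     control vs inhibitor, plus the inhibitor pair's DDR body effect.
#' }
#' Writes a per-gene TSV, a cohort-statistics JSON, a TSS-centred profile
#' matrix of activated genes (rows sorted by induced body density),
#' scaled bedGraph tracks, and a run log with all parameters.
#'
#' @param config A [contrast_config()].
#' @return Invisibly, a list with elements `per_gene`, `records`,
#'   `effects`, `scale_factors`, `filter_genes`, `activated`, `profile`,
#'   `paths`.
#' @export
run_contrast <- function(config) {
  stopifnot(inherits(config, "contrast_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("pausing contrast: %s vs %s%s", config$condition_a,
       config$condition_b,
       if (is.null(config$inhibitor_condition)) "" else
         paste0(" (inhibitor: ", config$inhibitor_condition, ")"))
  logf("parameters: density>%g, PI-ratio fold>%g, peaks fold>=%g fdr %g, n_boot=%d, seed=%d",
       config$density_threshold, config$fold_threshold,
       config$peak_min_fold, config$peak_fdr, config$n_boot, config$seed)

  sheet <- read_library_sheet(config$sheet)
  conds <- c(config$condition_a, config$condition_b,
             config$inhibitor_condition)
  need_marks <- config$marks
  if (config$use_peak_gate) need_marks <- unique(c(need_marks, "input"))
  missing <- setdiff(
    paste(rep(conds, each = length(need_marks)), need_marks),
    paste(sheet$condition, sheet$mark))
  if (length(missing)) {
    stop("library sheet is missing condition/mark pair(s): ",
         paste(missing, collapse = "; "))
  }
  sheet <- sheet[sheet$condition %in% conds &
                   sheet$mark %in% need_marks, ]

  tx <- read_gtf_transcripts(config$annotation)
  libs <- lapply(seq_len(nrow(sheet)), function(i) {
    load_reads(sheet$path[i])
  })
  names(libs) <- sheet$library_id
  totals <- vapply(libs, `[[`, 0, "total")
  sf <- library_scale_factors(totals)
  logf("libraries: %s", paste(sprintf("%s=%d (sf %.3f)", names(totals),
                                      as.integer(totals), sf),
                              collapse = ", "))

  lib_id <- function(cond, mark) {
    sheet$library_id[sheet$condition == cond & sheet$mark == mark][1]
  }
  pol_a <- lib_id(config$condition_a, config$pol2_mark)
  pol_b <- lib_id(config$condition_b, config$pol2_mark)

  # primary transcript per gene: maximal body density, averaged over the
  # two Pol II libraries of the contrast
  all_win <- derive_windows(tx)
  dens_ab <- lapply(c(pol_a, pol_b), function(id) {
    window_density(assign_reads(libs[[id]]$reads, all_win,
                                kinds = "body")$counts, sf[[id]])
  })
  body_by_tx <- (dens_ab[[1]]$density + dens_ab[[2]]$density) / 2
  names(body_by_tx) <- dens_ab[[1]]$transcript_id
  body_by_tx[is.na(body_by_tx)] <- 0
  body_by_tx[setdiff(tx$transcript_id, names(body_by_tx))] <- 0
  primary <- select_primary_transcripts(tx, body_by_tx)
  windows <- derive_windows(primary)
  logf("%d genes, %d transcripts; %d primary bodies usable",
       length(unique(tx$gene_id)), nrow(tx), sum(windows$body_ok))

  universe <- primary$gene_id
  if (config$use_peak_gate) {
    peak_genes <- character()
    for (cond in c(config$condition_a, config$condition_b)) {
      pk <- call_peaks(libs[[lib_id(cond, config$pol2_mark)]]$reads,
                       libs[[lib_id(cond, "input")]]$reads,
                       min_fold = config$peak_min_fold,
                       fdr = config$peak_fdr)
      peak_genes <- union(peak_genes, genes_with_peak(pk, primary))
    }
    universe <- intersect(universe, peak_genes)
    logf("peak gate: %d of %d genes retained", length(universe),
         nrow(primary))
  }

  assigned <- lapply(sheet$library_id, function(id) {
    a <- assign_reads(libs[[id]]$reads, windows)
    window_density(a$counts, sf[[id]])
  })
  names(assigned) <- sheet$library_id

  pol_conds <- conds
  records <- lapply(pol_conds, function(cond) {
    rec <- pausing_records(assigned[[lib_id(cond, config$pol2_mark)]],
                           cond)
    rec[rec$gene_id %in% universe, ]
  })
  names(records) <- pol_conds

  filt_tab <- do.call(rbind, lapply(
    c(config$condition_a, config$condition_b), function(cond) {
      r <- records[[cond]]
      data.frame(gene_id = r$gene_id, condition = cond,
                 body_density = r$body_density)
    }))
  filter_genes <- filter_expressed(filt_tab, config$density_threshold)

  contrast <- pausing_contrast(
    records[[config$condition_a]], records[[config$condition_b]],
    filter_genes, config$fold_threshold,
    scale_factor_a = sf[[pol_a]])
  activated <- contrast$gene_id[contrast$activated]
  logf("%d genes pass the density filter; %d activated (PI ratio > %g)",
       length(filter_genes), length(activated), config$fold_threshold)

  inh_contrast <- NULL
  if (!is.null(config$inhibitor_condition)) {
    inh_contrast <- pausing_contrast(
      records[[config$condition_a]],
      records[[config$inhibitor_condition]],
      filter_genes, config$fold_threshold,
      scale_factor_a = sf[[pol_a]])
  }

  effects <- list()
  act_win <- windows[windows$gene_id %in% activated, ]
  if (length(activated) == 0L) {
    warning("empty activated set: cohort statistics skipped")
  } else {
    depth_a <- mean_body_depth(libs[[pol_a]]$reads, act_win, sf[[pol_a]])
    depth_b <- mean_body_depth(libs[[pol_b]]$reads, act_win, sf[[pol_b]])
    effects$pol2_body_depth <- bootstrap_effect(
      depth_b, depth_a, n_boot = config$n_boot,
      seed = config$seed + 101L, alternative = "greater")

    for (mk in setdiff(config$marks, config$pol2_mark)) {
      da <- assigned[[lib_id(config$condition_a, mk)]]
      db <- assigned[[lib_id(config$condition_b, mk)]]
      da <- da[da$window_kind == "body" & da$gene_id %in% activated, ]
      db <- db[db$window_kind == "body" & db$gene_id %in% activated, ]
      effects[[paste0(mk, "_body_density")]] <- bootstrap_effect(
        db$density, da$density, n_boot = config$n_boot,
        seed = config$seed + 211L, alternative = "greater")
      if (!is.null(config$inhibitor_condition)) {
        di <- assigned[[lib_id(config$inhibitor_condition, mk)]]
        di <- di[di$window_kind == "body" & di$gene_id %in% activated, ]
        effects[[paste0(mk, "_body_density_inhibited")]] <-
          bootstrap_effect(di$density, da$density,
                           n_boot = config$n_boot,
                           seed = config$seed + 223L,
                           alternative = "greater")
      }
    }
    if (!is.null(inh_contrast)) {
      ctl <- contrast[contrast$activated, ]
      inh <- inh_contrast[match(ctl$gene_id, inh_contrast$gene_id), ]
      effects$pi_ratio <- bootstrap_effect(
        ctl$pi_ratio, inh$pi_ratio, n_boot = config$n_boot,
        seed = config$seed + 307L, alternative = "greater")
      effects$tss_change_pct <- bootstrap_effect(
        ctl$tss_change_pct, inh$tss_change_pct, n_boot = config$n_boot,
        seed = config$seed + 401L, alternative = "less")
      effects$body_change_pct <- bootstrap_effect(
        ctl$body_change_pct, inh$body_change_pct,
        n_boot = config$n_boot, seed = config$seed + 409L,
        alternative = "greater")
    }
  }

  per_gene <- contrast
  names(per_gene)[names(per_gene) %in% c("pi_a", "pi_b")] <-
    paste0("pi_", c(config$condition_a, config$condition_b))
  if (!is.null(inh_contrast)) {
    per_gene$pi_ratio_inhibitor <-
      inh_contrast$pi_ratio[match(per_gene$gene_id,
                                  inh_contrast$gene_id)]
  }
  per_gene_path <- file.path(config$outdir, "per_gene.tsv")
  utils::write.table(per_gene, per_gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  profile <- NULL
  if (length(activated)) {
    profile <- binned_profile(libs[[pol_b]]$reads, act_win,
                              scale_factor = sf[[pol_b]])
    rec_b <- records[[config$condition_b]]
    ord <- order(-rec_b$body_density[match(act_win$gene_id,
                                           rec_b$gene_id)])
    profile <- profile[ord, , drop = FALSE]
    utils::write.table(profile,
                       file.path(config$outdir, "profile_polII.tsv"),
                       sep = "\t", quote = FALSE, col.names = FALSE)
  }

  stats_path <- file.path(config$outdir, "cohort_stats.json")
  jsonlite::write_json(
    lapply(effects, function(e) as.data.frame(e)),
    stats_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  for (id in sheet$library_id) {
    export_bedgraph(libs[[id]]$reads,
                    file.path(config$outdir, paste0(id, ".bedGraph")),
                    sf[[id]])
  }
  logf("outputs written to %s", config$outdir)

  invisible(list(per_gene = per_gene, records = records,
                 effects = effects, scale_factors = sf,
                 filter_genes = filter_genes, activated = activated,
                 contrast = contrast, inh_contrast = inh_contrast,
                 profile = profile,
                 paths = list(per_gene = per_gene_path,
                              cohort_stats = stats_path,
                              log = log_path)))
}
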