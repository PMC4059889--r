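# End-to-end orchestration: peaks -> normalization -> clustering ->
# annotation -> targets -> expression, from a single config.

#' Pipeline configuration
#'
#' Centralizes every threshold of the analysis; the defaults are the
#' pipeline's canonical constants (peak score filter 50, FDR 0.1 percent,
#' DE alpha 0.01, active-gene FPKM 4, promoter windows of 500 bp for binding
#' maps and 1 kb for target calls, 2 kb / 50 bp clustering windows, k = 5).
#'
#' @param input a [simulation_config] (synthetic mode) or a directory
#'   written by [write_dataset()].
#' @param min_score,max_fdr_percent peak quality filter ([filter_peaks()]).
#' @param alpha adjusted p-value cutoff for significant DE.
#' @param fpkm_active active-gene threshold (mean FPKM).
#' @param tss_flank_bind,tss_flank_target promoter half-widths (bp).
#' @param window_bp,bin_bp clustering matrix geometry.
#' @param k cluster count for the main cut; `k_range` for the pruning scan.
#' @param mode matrix anchoring mode (see [extract_matrix()]).
#' @param pseudocount input-normalization pseudocount.
#' @param classify_cell_type cell type whose peaks feed target
#'   classification (matching the knockdown background).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = simulation_config(),
                            min_score = 50, max_fdr_percent = 0.1,
                            alpha = 0.01, fpkm_active = 4,
                            tss_flank_bind = 500, tss_flank_target = 1000,
                            window_bp = 2000, bin_bp = 50,
                            k = 5, k_range = 2:10,
                            mode = "reference_point", pseudocount = 1,
                            classify_cell_type = "ESC") {
  stopifnot(min_score >= 0, max_fdr_percent >= 0,
            alpha >= 0, alpha <= 1, fpkm_active >= 0,
            tss_flank_bind > 0, tss_flank_target > 0,
            window_bp %% bin_bp == 0, k >= 2)
  if (is.character(input) && !dir.exists(input)) {
    stop("input directory does not exist: ", input)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

.load_inputs <- function(config) {
  input <- config$input
  if (inherits(input, "simulation_config")) {
    return(simulate_dataset(input))
  }
  if (inherits(input, "synthetic_dataset")) return(input)
  if (!is.character(input)) stop("unsupported pipeline input")
  read_dataset(input, bin_bp = config$bin_bp)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @param bin_bp bin size used to re-bin the bedGraph tracks.
#' @return a list shaped like a `synthetic_dataset` (truth = NULL).
#' @export
read_dataset <- function(dir, bin_bp = 50) {
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  gm <- read_gene_models(file.path(dir, "genes.gtf"))
  cpg <- read_bed(file.path(dir, "cpg_islands.bed"), "bed3")
  read_enh <- function(kind) {
    p <- file.path(dir, paste0(kind, "_enhancers.bed"))
    e <- read_bed(p, "bed6")
    if (length(e)) e$assigned_gene <- e$name
    e
  }
  ann <- annotation_bundle(gm, cpg, read_enh("typical"), read_enh("super"),
                           sizes)
  np <- list.files(dir, pattern = "\\.merged\\.narrowPeak$")
  samples <- sub("\\.merged\\.narrowPeak$", "", np)
  peaks <- lapply(samples, function(s) {
    list(rep1 = read_bed(file.path(dir, paste0(s, ".rep1.narrowPeak")),
                         "narrowpeak", sample_id = s),
         rep2 = read_bed(file.path(dir, paste0(s, ".rep2.narrowPeak")),
                         "narrowpeak", sample_id = s),
         merged = read_bed(file.path(dir, paste0(s, ".merged.narrowPeak")),
                           "narrowpeak", sample_id = s))
  })
  names(peaks) <- samples
  bg <- list.files(dir, pattern = "\\.bedGraph$")
  chip_files <- bg[!startsWith(bg, "input_")]
  input_files <- bg[startsWith(bg, "input_")]
  chip <- lapply(chip_files, function(f)
    read_bedgraph(file.path(dir, f), bin_bp, sizes,
                  sample_id = sub("\\.bedGraph$", "", f)))
  names(chip) <- sub("\\.bedGraph$", "", chip_files)
  input <- lapply(input_files, function(f)
    read_bedgraph(file.path(dir, f), bin_bp, sizes,
                  sample_id = sub("\\.bedGraph$", "", f)))
  names(input) <- sub("^input_(.*)\\.bedGraph$", "\\1", input_files)
  expr <- read.table(file.path(dir, "expression.tsv"), header = TRUE,
                     sep = "\t")
  de_files <- list.files(dir, pattern = "^de_.*\\.tsv$")
  de <- lapply(de_files, function(f)
    read.table(file.path(dir, f), header = TRUE, sep = "\t"))
  names(de) <- sub("^de_(.*)\\.tsv$", "\\1", de_files)
  tracks <- if (length(chip)) list(chip = chip, input = input,
                                   background_bins = NULL) else NULL
  list(config = NULL, annotation = ann, truth = NULL, tracks = tracks,
       peaks = peaks, expression = list(expression = expr, de = de,
                                        de_truth = NULL))
}

#' Run the full co-occupancy pipeline
#'
#' Stages, in dependency order: replicate consensus and quality filtering of
#' peaks; cross-sample peak union; SES depth scaling and input normalization
#' of coverage tracks; region signal-matrix extraction; rank-transform Ward
#' clustering at `k` (plus the pruning scan over `k_range`); cluster
#' summaries; regulatory domains and per-factor target classification
#' (restricted per condition to the significantly affected genes); active
#' genes, expression bins and DE cross-tabulations. Identical config (and
#' seed inside a synthetic input) gives identical results; [write_result_bundle()]
#' serializes every stage output deterministically.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional directory; when given, the bundle is written
#'   there via [write_result_bundle()].
#' @return a `result_bundle` list (see fields in the implementation's
#'   return value).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- .load_inputs(config)
  ann <- data$annotation
  sizes <- ann$chrom_sizes
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  consensus <- stage("consensus", lapply(data$peaks, function(pk) {
    filter_peaks(replicate_consensus(pk$merged, pk$rep1, pk$rep2),
                 config$min_score, config$max_fdr_percent)
  }))
  union_regions <- stage("union", peak_union(consensus))
  if (!length(union_regions)) {
    warning("no peaks survive consensus + filtering; downstream outputs empty")
  }
  presence <- stage("presence",
                    factor_presence(union_regions, consensus))
  ratio_tracks <- NULL; ses_factors <- NULL; matrix_raw <- NULL
  clustering <- NULL; scan <- NULL; summary <- NULL
  if (!is.null(data$tracks) && length(union_regions) >= max(config$k, 2)) {
    normalized <- stage("normalize", {
      out <- list()
      factors <- numeric(0)
      for (s in names(data$tracks$chip)) {
        ct <- .cell_type(s)
        inp <- data$tracks$input[[ct]]
        if (is.null(inp)) inp <- data$tracks$input[[1]]
        f <- ses_scale_factor(data$tracks$chip[[s]], inp)
        factors[s] <- f
        out[[s]] <- normalize_to_input(data$tracks$chip[[s]], inp,
                                       factor = f,
                                       pseudocount = config$pseudocount)
      }
      list(tracks = out, factors = factors)
    })
    ratio_tracks <- normalized$tracks
    ses_factors <- normalized$factors
    matrix_raw <- stage("matrix",
                        extract_matrix(union_regions, ratio_tracks,
                                       mode = config$mode,
                                       window_bp = config$window_bp,
                                       bin_bp = config$bin_bp))
    ranked <- stage("rank", rank_transform(matrix_raw))
    clustering <- stage("cluster", ward_cluster(ranked, config$k))
    scan <- stage("prune_scan",
                  prune_scan(ranked, config$k_range[config$k_range <=
                                                    length(union_regions)]))
    summary <- stage("summary",
                     cluster_summary(clustering, union_regions, ann,
                                     consensus))
  }
  domains <- stage("domains",
                   build_regulatory_domains(ann$genes, chrom_sizes = sizes))
  # per-protein ESC peak sets feed classification
  cc <- config$classify_cell_type
  prot <- unique(sub("_[^_]*$", "", names(consensus)))
  peaks_by_factor <- lapply(prot, function(p) {
    nm <- paste0(p, "_", cc)
    if (nm %in% names(consensus)) consensus[[nm]]
    else if (p %in% names(consensus)) consensus[[p]]
    else GenomicRanges::GRanges()
  })
  names(peaks_by_factor) <- prot
  expr <- data$expression$expression
  active <- stage("active_genes", call_active_genes(expr, config$fpkm_active))
  bins <- stage("expression_bins",
                tryCatch(expression_bins(expr), error = function(e) NULL))
  classification <- stage("classify", {
    lapply(data$expression$de, function(de_tab) {
      sig <- de_tab$gene_id[de_tab$padj <= config$alpha]
      classify_targets(ann$genes, peaks_by_factor, ann, domains = domains,
                       de_genes = sig,
                       tss_flank_bp = config$tss_flank_target)
    })
  })
  classification_all <- stage("classify_all",
    classify_targets(ann$genes, peaks_by_factor, ann, domains = domains,
                     tss_flank_bp = config$tss_flank_target))
  crosstabs <- stage("crosstab", {
    out <- list()
    for (f in names(data$expression$de)) {
      if (!(f %in% names(peaks_by_factor))) next
      cls <- classification_all[classification_all$factor == f, ]
      out[[f]] <- de_crosstab(data$expression$de[[f]], cls, groups = bins,
                              alpha = config$alpha)
    }
    out
  })
  manifest <- list(package_version = as.character(utils::packageVersion("chipcooc")),
                   seed = if (inherits(config$input, "simulation_config"))
                     config$input$seed else NA,
                   thresholds = config[c("min_score", "max_fdr_percent",
                                         "alpha", "fpkm_active",
                                         "tss_flank_bind", "tss_flank_target",
                                         "window_bp", "bin_bp", "k",
                                         "pseudocount", "mode")],
                   n_consensus_peaks = vapply(consensus, length, 0L),
                   n_union_regions = length(union_regions),
                   n_active_genes = length(active))
  bundle <- structure(list(config = config, data = data,
                           consensus = consensus,
                           union_regions = union_regions,
                           presence = presence,
                           ses_factors = ses_factors,
                           ratio_tracks = ratio_tracks,
                           matrix = matrix_raw, clustering = clustering,
                           scan = scan, summary = summary,
                           domains = domains,
                           active_genes = active, expression_bins = bins,
                           classification = classification,
                           classification_all = classification_all,
                           crosstabs = crosstabs, manifest = manifest),
                      class = "result_bundle")
  if (!is.null(out_dir)) write_result_bundle(bundle, out_dir)
  bundle
}

#' Write a result bundle to disk
#'
#' Serializes every stage output as plain text (BED/narrowPeak/TSV/JSON)
#' with fixed formatting and no timestamps, so reruns with the same config
#' and seed are byte-identical.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(bundle$consensus)) {
    write_bed(bundle$consensus[[s]],
              file.path(dir, paste0("consensus_", s, ".narrowPeak")),
              "narrowpeak")
  }
  write_bed(bundle$union_regions, file.path(dir, "union_regions.bed"), "bed3")
  pres <- bundle$presence
  write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(pres)),
               start = GenomicRanges::start(pres) - 1L,
               end = GenomicRanges::end(pres),
               present = vapply(pres$present, paste, "", collapse = ","),
               n_present = pres$n_present,
               solitary_factor = pres$solitary_factor),
    file.path(dir, "factor_presence.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$ses_factors)) {
    write.table(data.frame(sample = names(bundle$ses_factors),
                           ses_factor = format(bundle$ses_factors,
                                               digits = 10, trim = TRUE)),
                file.path(dir, "ses_factors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$matrix)) {
    write_signal_matrix(bundle$matrix, file.path(dir, "signal_matrix.tsv"))
  }
  if (!is.null(bundle$clustering)) {
    cl <- bundle$union_regions
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(cl)),
                     start = GenomicRanges::start(cl) - 1L,
                     end = GenomicRanges::end(cl),
                     cluster = bundle$clustering$labels)
    write.table(df, file.path(dir, "clusters.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(bundle$summary$clusters, file.path(dir, "cluster_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bundle$summary$sample_fractions)) {
      write.table(data.frame(cluster = rownames(bundle$summary$sample_fractions),
                             bundle$summary$sample_fractions),
                  file.path(dir, "cluster_sample_fractions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  dom <- bundle$domains
  write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(dom)),
               start = GenomicRanges::start(dom) - 1L,
               end = GenomicRanges::end(dom), gene_id = dom$gene_id,
               basal_start = dom$basal_start - 1L, basal_end = dom$basal_end),
    file.path(dir, "regulatory_domains.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$active_genes, file.path(dir, "active_genes.txt"))
  for (f in names(bundle$classification)) {
    write.table(bundle$classification[[f]],
                file.path(dir, paste0("targets_", f, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(bundle$classification_all, file.path(dir, "targets_all.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (f in names(bundle$crosstabs)) {
    write.table(bundle$crosstabs[[f]],
                file.path(dir, paste0("crosstab_", f, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Export basic figures from a result bundle
#'
#' Writes PDF figures derived purely from the bundle's tables: the
#' cluster-ordered signal heatmap, per-cluster mean profiles per sample,
#' and DE cross-tabulation bar charts. Empty components are skipped with a
#' warning.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory (created).
#' @return character vector of files written, invisibly.
#' @export
export_figures <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (!is.null(bundle$matrix) && !is.null(bundle$clustering)) {
    f <- file.path(dir, "cluster_heatmap.pdf")
    grDevices::pdf(f, width = 8, height = 10)
    ord <- order(bundle$clustering$labels)
    v <- bundle$matrix$values[ord, , drop = FALSE]
    graphics::image(t(v), axes = FALSE, useRaster = TRUE,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    main = sprintf("signal matrix, %d regions, k = %d",
                                   nrow(v), bundle$clustering$k))
    grDevices::dev.off()
    written <- c(written, f)
    f <- file.path(dir, "cluster_profiles.pdf")
    grDevices::pdf(f, width = 8, height = 6)
    nbin <- bundle$matrix$n_bins_per_sample
    k <- bundle$clustering$k
    for (cl in seq_len(k)) {
      sel <- bundle$clustering$labels == cl
      if (!any(sel)) { warning("empty cluster ", cl, " skipped"); next }
      prof <- vapply(seq_along(bundle$matrix$samples), function(j) {
        colMeans(bundle$matrix$values[sel, (j - 1) * nbin + seq_len(nbin),
                                      drop = FALSE])
      }, numeric(nbin))
      graphics::matplot(prof, type = "l", lty = 1,
                        xlab = "bin", ylab = "mean signal",
                        main = paste("cluster", cl))
      graphics::legend("topright", legend = bundle$matrix$samples,
                       col = seq_along(bundle$matrix$samples), lty = 1,
                       cex = 0.6)
    }
    grDevices::dev.off()
    written <- c(written, f)
  }
  if (length(bundle$crosstabs)) {
    f <- file.path(dir, "crosstabs.pdf")
    grDevices::pdf(f, width = 8, height = 6)
    for (nm in names(bundle$crosstabs)) {
      ct <- bundle$crosstabs[[nm]]
      if (!nrow(ct)) next
      m <- rbind(down = ct$frac_down, up = ct$frac_up)
      colnames(m) <- paste(ct$class, ct$group, sep = "\n")
      graphics::barplot(m, beside = TRUE, las = 2, cex.names = 0.5,
                        ylab = "fraction significant",
                        main = paste("knockdown", nm))
    }
    grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}
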