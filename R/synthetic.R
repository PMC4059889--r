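# Synthetic-data generator: plants known co-occupancy clusters, target genes
# and knockdown effects, and emits exactly the formats the pipeline reads.

#' Default planted co-occupancy patterns
#'
#' Five archetypes of multi-factor binding across two cell types, mirroring
#' the canonical outcome of clustering MOF/MSL/NSL ChIP profiles: three
#' patterns shared between stem (ESC) and neuronal progenitor (NPC) state —
#' all factors at promoters (A), MOF with the NSL subunits at promoters (B),
#' solitary MSL2 away from promoters (C) — and two stem-cell-specific
#' patterns, MOF+NSL at intergenic/enhancer-like sites (D) and MOF+MSL over
#' gene bodies (E).
#'
#' @param n_regions regions planted per pattern (default 200).
#' @param amplitude mean planted enrichment in log2 units over background
#'   (default 2).
#' @return list of pattern descriptors (name, present, n_regions,
#'   width_mean, width_sd, compartment, amplitude).
#' @export
default_cluster_spec <- function(n_regions = 200, amplitude = 2.0) {
  both <- function(f) as.vector(outer(f, c("ESC", "NPC"), paste, sep = "_"))
  esc <- function(f) paste0(f, "_ESC")
  list(
    list(name = "A", present = both(c("MOF", "MSL1", "MSL2", "KANSL3", "MCRS1")),
         n_regions = n_regions, width_mean = 1800, width_sd = 300,
         compartment = "promoter", amplitude = amplitude),
    list(name = "B", present = both(c("MOF", "KANSL3", "MCRS1")),
         n_regions = n_regions, width_mean = 1200, width_sd = 250,
         compartment = "promoter", amplitude = amplitude),
    list(name = "C", present = both("MSL2"),
         n_regions = n_regions, width_mean = 1400, width_sd = 300,
         compartment = "intergenic", amplitude = amplitude),
    list(name = "D", present = esc(c("MOF", "KANSL3", "MCRS1")),
         n_regions = n_regions, width_mean = 1100, width_sd = 250,
         compartment = "intergenic", amplitude = amplitude),
    list(name = "E", present = esc(c("MOF", "MSL1", "MSL2")),
         n_regions = n_regions, width_mean = 850, width_sd = 150,
         compartment = "gene_body", amplitude = amplitude))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generator. Defaults define the
#' standard study conditions used throughout the test-suite: a 3 x 10 Mb
#' genome, 500 genes, 50 bp bins, 5 planted patterns of 200 regions each
#' (1,000 regions total) over 10 ChIP samples, mean planted enrichment of
#' 2 log2 units, negative-binomial background (dispersion 0.2), and a
#' knockdown model in which 80 percent of a factor's planted promoter
#' targets are downregulated.
#'
#' @param seed integer master seed; all generator stages derive their RNG
#'   state from it.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_genes number of non-overlapping genes.
#' @param bin_bp track bin width.
#' @param cluster_spec planted patterns (see [default_cluster_spec()]).
#' @param depth_factors named per-sample sequencing-depth multipliers;
#'   default cycles 0.5 / 1 / 2 across samples.
#' @param background_mean,nb_dispersion negative-binomial background of the
#'   input track (per-bin mean counts; dispersion so that
#'   `variance = mu + dispersion * mu^2`).
#' @param peak_jitter_bp replicate peak borders are jittered uniformly in
#'   `[-jitter, +jitter]`.
#' @param false_peak_rate expected false peaks per planted peak; false peaks
#'   appear in the merged calls and exactly one replicate.
#' @param peak_fail_rate fraction of planted merged peaks whose score is
#'   drawn below the quality filter.
#' @param cpg_promoter_fraction fraction of promoters carrying a CpG island.
#' @param n_typical_enhancers,n_super_enhancers enhancer counts.
#' @param kd_factors knockdown conditions (factor names).
#' @param kd_pi_down probability a planted target is downregulated.
#' @param kd_lfc_mean,kd_lfc_sd effect-size distribution (log2 units).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_chromosomes = 3,
                              chrom_length_bp = 1e7, n_genes = 500,
                              bin_bp = 50,
                              cluster_spec = default_cluster_spec(),
                              depth_factors = NULL,
                              background_mean = 10, nb_dispersion = 0.2,
                              peak_jitter_bp = 50, false_peak_rate = 0.1,
                              peak_fail_rate = 0.02,
                              cpg_promoter_fraction = 0.6,
                              n_typical_enhancers = 120,
                              n_super_enhancers = 15,
                              kd_factors = c("MOF", "MSL1", "MSL2", "KANSL3"),
                              kd_pi_down = 0.8, kd_lfc_mean = 1.5,
                              kd_lfc_sd = 0.3) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp > 0, n_genes >= 1,
            bin_bp >= 1, length(cluster_spec) >= 1,
            background_mean > 0, nb_dispersion >= 0,
            peak_jitter_bp >= 0, false_peak_rate >= 0,
            peak_fail_rate >= 0, peak_fail_rate <= 1,
            kd_pi_down >= 0, kd_pi_down <= 1, kd_lfc_mean >= 0)
  samples <- unique(unlist(lapply(cluster_spec, `[[`, "present")))
  if (is.null(depth_factors)) {
    depth_factors <- setNames(rep_len(c(0.5, 1, 2), length(samples)), samples)
  }
  stopifnot(all(samples %in% names(depth_factors)), all(depth_factors > 0))
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp, n_genes = n_genes,
                 bin_bp = bin_bp, cluster_spec = cluster_spec,
                 samples = samples, depth_factors = depth_factors,
                 background_mean = background_mean,
                 nb_dispersion = nb_dispersion,
                 peak_jitter_bp = peak_jitter_bp,
                 false_peak_rate = false_peak_rate,
                 peak_fail_rate = peak_fail_rate,
                 cpg_promoter_fraction = cpg_promoter_fraction,
                 n_typical_enhancers = n_typical_enhancers,
                 n_super_enhancers = n_super_enhancers,
                 kd_factors = kd_factors, kd_pi_down = kd_pi_down,
                 kd_lfc_mean = kd_lfc_mean, kd_lfc_sd = kd_lfc_sd),
            class = "simulation_config")
}

.cell_type <- function(sample_id) sub(".*_", "", sample_id)

# per-chromosome start/end vectors for fast rejection-sampling overlap tests
.interval_index <- function(gr, chroms) {
  cn <- as.character(GenomicRanges::seqnames(gr))
  out <- lapply(chroms, function(c2) {
    sel <- cn == c2
    list(s = GenomicRanges::start(gr)[sel], e = GenomicRanges::end(gr)[sel])
  })
  names(out) <- chroms
  out
}

.idx_overlaps <- function(idx, cn, s, e) {
  v <- idx[[cn]]
  length(v$s) > 0 && any(s <= v$e & e >= v$s)
}

.idx_add <- function(idx, cn, s, e) {
  idx[[cn]]$s <- c(idx[[cn]]$s, s)
  idx[[cn]]$e <- c(idx[[cn]]$e, e)
  idx
}

.empty_idx <- function(chroms) {
  out <- lapply(chroms, function(c2) list(s = numeric(0), e = numeric(0)))
  names(out) <- chroms
  out
}


#' Generate a synthetic annotation bundle
#'
#' Places non-overlapping multi-exon genes (1-10 exons) uniformly across the
#' genome, CpG islands at a configurable fraction of promoters, typical
#' enhancers (about 700 bp) and super enhancers (10-30 kb) in intergenic
#' space, each enhancer assigned to the gene with the nearest TSS.
#' Deterministic given the config seed.
#'
#' @param config a [simulation_config].
#' @return an [annotation_bundle].
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  sizes <- setNames(rep(config$chrom_length_bp, config$n_chromosomes),
                    paste0("chr", seq_len(config$n_chromosomes)))
  per_chrom <- tabulate(rep_len(seq_len(config$n_chromosomes),
                                config$n_genes),
                        config$n_chromosomes)
  slot_ok <- config$chrom_length_bp / max(per_chrom)
  if (slot_ok < 12000) stop("genome too small for n_genes")
  gene_rows <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    nc <- per_chrom[ci]
    if (!nc) next
    slot <- floor(config$chrom_length_bp / nc)
    for (si in seq_len(nc)) {
      gi <- gi + 1L
      glen <- round(exp(runif(1, log(2000), log(min(40000, slot * 0.5)))))
      lo <- (si - 1) * slot + 2000
      hi <- si * slot - glen - 2000
      start <- if (hi > lo) lo + floor(runif(1) * (hi - lo)) else lo
      gene_rows[[gi]] <- data.frame(chrom = names(sizes)[ci],
                                    start = start, end = start + glen - 1,
                                    strand = sample(c("+", "-"), 1),
                                    gene_id = sprintf("g%04d", gi))
    }
  }
  gdf <- do.call(rbind, gene_rows)
  genes_gr <- GenomicRanges::GRanges(gdf$chrom,
                                     IRanges::IRanges(gdf$start, gdf$end),
                                     strand = gdf$strand)
  genes_gr$gene_id <- gdf$gene_id
  exons <- lapply(seq_len(nrow(gdf)), function(i) {
    glen <- gdf$end[i] - gdf$start[i] + 1
    n_ex <- sample(1:10, 1)
    nseg <- 2L * n_ex - 1L
    minw <- 50L
    if (glen < nseg * minw + nseg) n_ex <- 1L
    if (n_ex == 1L) {
      return(GenomicRanges::GRanges(gdf$chrom[i],
                                    IRanges::IRanges(gdf$start[i], gdf$end[i]),
                                    strand = gdf$strand[i]))
    }
    nseg <- 2L * n_ex - 1L
    w <- minw + rmultinom(1, glen - nseg * minw, prob = runif(nseg))[, 1]
    ends <- gdf$start[i] - 1 + cumsum(w)
    starts <- c(gdf$start[i], ends[-nseg] + 1)
    odd <- seq(1, nseg, by = 2)
    GenomicRanges::GRanges(gdf$chrom[i],
                           IRanges::IRanges(starts[odd], ends[odd]),
                           strand = gdf$strand[i])
  })
  names(exons) <- gdf$gene_id
  gm <- gene_models(genes_gr, GenomicRanges::GRangesList(exons))
  tss <- gm$genes$tss
  # CpG islands at a fraction of promoters
  has_cpg <- runif(length(tss)) < config$cpg_promoter_fraction
  cpg <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gm$genes)[has_cpg],
    IRanges::IRanges(pmax(1, tss[has_cpg] - round(runif(sum(has_cpg), 150, 500))),
                     pmin(sizes[as.character(GenomicRanges::seqnames(gm$genes))[has_cpg]],
                          tss[has_cpg] + round(runif(sum(has_cpg), 150, 500)))))
  # enhancers in intergenic space
  forbidden <- merge_intervals(GenomicRanges::resize(
    GenomicRanges::granges(genes_gr),
    GenomicRanges::width(genes_gr) + 4000, fix = "center"))
  forb_idx <- .interval_index(forbidden, names(sizes))
  taken_idx <- .empty_idx(names(sizes))
  place_enhancers <- function(n, width_fun) {
    got_c <- character(0); got_s <- numeric(0); got_e <- numeric(0)
    tries <- 0L
    while (length(got_s) < n && tries < n * 200L) {
      tries <- tries + 1L
      w <- width_fun()
      cn <- sample(names(sizes), 1)
      s <- 1 + floor(runif(1) * (sizes[[cn]] - w - 1))
      e <- s + w - 1
      if (.idx_overlaps(forb_idx, cn, s, e) ||
          .idx_overlaps(taken_idx, cn, s, e)) next
      taken_idx <<- .idx_add(taken_idx, cn, s, e)
      got_c <- c(got_c, cn); got_s <- c(got_s, s); got_e <- c(got_e, e)
    }
    GenomicRanges::GRanges(got_c, IRanges::IRanges(got_s, got_e))
  }
  te <- place_enhancers(config$n_typical_enhancers,
                        function() max(200, round(rnorm(1, 700, 80))))
  se <- place_enhancers(config$n_super_enhancers,
                        function() round(runif(1, 10000, 30000)))
  tss_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gm$genes),
                                   IRanges::IRanges(tss, tss))
  assign_nearest <- function(e) {
    if (!length(e)) { e$assigned_gene <- character(0); return(e) }
    idx <- GenomicRanges::nearest(e, tss_gr, ignore.strand = TRUE)
    e$assigned_gene <- gm$genes$gene_id[idx]
    e
  }
  annotation_bundle(gm, cpg, assign_nearest(te), assign_nearest(se), sizes)
}

#' Plant co-occupancy regions with known cluster labels
#'
#' Draws regions per pattern, placed according to the pattern's compartment
#' bias (promoter patterns centered near a random gene's TSS; gene-body
#' patterns inside a gene away from its promoter; intergenic patterns clear
#' of genes), globally non-overlapping with at least 1 kb spacing.
#'
#' @param config a [simulation_config].
#' @param annotation an [annotation_bundle] from [generate_annotation()].
#' @return a `synthetic_truth` list: `regions` (`GRanges` with `cluster`
#'   index, `pattern`, `anchor_gene`), `presence` (region x sample logical
#'   matrix), `patterns` (the spec), `tss_targets` (sample -> gene ids whose
#'   promoter carries a planted region of that sample).
#' @export
plant_cooccupancy <- function(config, annotation) {
  set.seed(config$seed + 1L)
  sizes <- annotation$chrom_sizes
  g <- annotation$genes$genes
  tss <- g$tss
  strand <- as.character(GenomicRanges::strand(g))
  chrom <- as.character(GenomicRanges::seqnames(g))
  gene_margin <- .interval_index(
    merge_intervals(GenomicRanges::resize(
      GenomicRanges::granges(g), GenomicRanges::width(g) + 3000,
      fix = "center")),
    names(sizes))
  placed <- .empty_idx(names(sizes))
  g_start <- GenomicRanges::start(g); g_end <- GenomicRanges::end(g)
  avail_genes <- seq_along(g)
  rows <- list(); pres <- list(); ri <- 0L
  for (pi in seq_along(config$cluster_spec)) {
    pat <- config$cluster_spec[[pi]]
    for (j in seq_len(pat$n_regions)) {
      w <- max(200, round(rnorm(1, pat$width_mean, pat$width_sd)))
      done <- FALSE
      for (try in seq_len(500)) {
        if (pat$compartment == "promoter") {
          if (!length(avail_genes)) stop("not enough genes for promoter placement")
          sel <- sample(avail_genes, 1)
          center <- tss[sel] + round(runif(1, -200, 200))
          cn <- chrom[sel]; anchor <- g$gene_id[sel]
        } else if (pat$compartment == "gene_body") {
          sel <- sample(seq_along(g), 1)
          lo <- g_start[sel]; hi <- g_end[sel]
          if (hi - lo < w + 4000) next
          safe_lo <- max(lo + 500, if (strand[sel] == "+") tss[sel] + 1500 + w / 2 else lo + 500 + w / 2)
          safe_hi <- min(hi - 500, if (strand[sel] == "-") tss[sel] - 1500 - w / 2 else hi - 500 - w / 2)
          if (safe_hi <= safe_lo) next
          center <- round(runif(1, safe_lo, safe_hi))
          cn <- chrom[sel]; anchor <- g$gene_id[sel]
        } else {
          cn <- sample(names(sizes), 1)
          center <- 1 + floor(runif(1) * (sizes[[cn]] - w - 2)) + w / 2
          anchor <- NA_character_
        }
        s <- max(1, round(center - w / 2)); e <- s + w - 1
        if (e > sizes[[cn]]) next
        ps <- s - 1000; pe <- e + 1000
        if (.idx_overlaps(placed, cn, ps, pe)) next
        if (pat$compartment == "intergenic" &&
            .idx_overlaps(gene_margin, cn, ps, pe)) next
        placed <- .idx_add(placed, cn, s, e)
        if (pat$compartment == "promoter") {
          avail_genes <- setdiff(avail_genes, sel)
        }
        ri <- ri + 1L
        rows[[ri]] <- data.frame(chrom = cn, start = s, end = e,
                                 cluster = pi, pattern = pat$name,
                                 anchor_gene = anchor,
                                 amplitude = pat$amplitude)
        pres[[ri]] <- config$samples %in% pat$present
        done <- TRUE
        break
      }
      if (!done) stop("region placement failed for pattern ", pat$name)
    }
  }
  df <- do.call(rbind, rows)
  regions <- GenomicRanges::GRanges(df$chrom,
                                    IRanges::IRanges(df$start, df$end))
  regions$cluster <- df$cluster
  regions$pattern <- df$pattern
  regions$anchor_gene <- df$anchor_gene
  regions$amplitude <- df$amplitude
  presence <- do.call(rbind, pres)
  dimnames(presence) <- list(NULL, config$samples)
  tss_targets <- lapply(config$samples, function(s) {
    sel <- presence[, s] & !is.na(regions$anchor_gene) & df$pattern %in%
      vapply(config$cluster_spec, function(p)
        if (p$compartment == "promoter") p$name else "", "")
    sort(unique(regions$anchor_gene[sel]))
  })
  names(tss_targets) <- config$samples
  structure(list(regions = regions, presence = presence,
                 patterns = config$cluster_spec, tss_targets = tss_targets),
            class = "synthetic_truth")
}

#' Simulate binned coverage tracks
#'
#' One shared input track per cell type with negative-binomial background.
#' Each ChIP sample inherits the input's bin-to-bin background shape scaled
#' by its depth factor, plus a Gaussian enrichment profile (peak amplitude
#' `2^amplitude - 1` times the local background) at every planted region
#' where the factor is present: per bin,
#' `chip = depth * input * (1 + profile)`. ChIP noise is thus inherited
#' from the input draw rather than redrawn, which matches the ratio
#' structure that input normalization assumes and makes the true
#' background ratio exactly the depth factor.
#'
#' @param truth from [plant_cooccupancy()].
#' @param annotation an [annotation_bundle].
#' @param config a [simulation_config].
#' @return list with `chip` (named list of [binned_track]), `input` (named
#'   by cell type), and `background_bins` (per sample, per chromosome
#'   logical: bins with zero planted enrichment).
#' @export
simulate_tracks <- function(truth, annotation, config) {
  set.seed(config$seed + 2L)
  sizes <- annotation$chrom_sizes
  bs <- config$bin_bp
  nb <- ceiling(sizes / bs)
  size_nb <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  draw_bg <- function(mu) {
    lapply(names(sizes), function(cn) {
      n <- nb[[cn]]
      if (is.finite(size_nb)) rnbinom(n, mu = mu, size = size_nb)
      else stats::rpois(n, mu)
    })
  }
  cell_types <- unique(.cell_type(config$samples))
  input <- lapply(cell_types, function(ct) {
    v <- draw_bg(config$background_mean)
    names(v) <- names(sizes)
    binned_track(v, bs, sizes, paste0("input_", ct))
  })
  names(input) <- cell_types
  reg_chrom <- as.character(GenomicRanges::seqnames(truth$regions))
  reg_center <- (GenomicRanges::start(truth$regions) +
                 GenomicRanges::end(truth$regions)) / 2
  reg_sigma <- GenomicRanges::width(truth$regions) / 4
  chip <- list(); background_bins <- list()
  for (s in config$samples) {
    depth <- config$depth_factors[[s]]
    amp_by_chrom <- lapply(names(sizes), function(cn) numeric(nb[[cn]]))
    names(amp_by_chrom) <- names(sizes)
    sel <- which(truth$presence[, s])
    for (i in sel) {
      cn <- reg_chrom[i]
      sg <- reg_sigma[i]
      lo <- max(1L, floor((reg_center[i] - 3 * sg) / bs))
      hi <- min(nb[[cn]], ceiling((reg_center[i] + 3 * sg) / bs))
      idx <- lo:hi
      d <- (idx - 0.5) * bs - reg_center[i]
      amp_by_chrom[[cn]][idx] <- amp_by_chrom[[cn]][idx] +
        (2^truth$regions$amplitude[i] - 1) * exp(-d^2 / (2 * sg^2))
    }
    ct <- .cell_type(s)
    v <- lapply(names(sizes), function(cn) {
      depth * input[[ct]]$values[[cn]] * (1 + amp_by_chrom[[cn]])
    })
    names(v) <- names(sizes)
    chip[[s]] <- binned_track(v, bs, sizes, s)
    background_bins[[s]] <- lapply(amp_by_chrom, function(a) a == 0)
  }
  list(chip = chip, input = input, background_bins = background_bins)
}

.new_peaks <- function(chrom, start, end, summit, score, fdr, sample_id) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$name <- paste0(sample_id, "_peak_", seq_along(gr))
  gr$summit <- as.integer(summit)
  gr$score_neg10log10p <- score
  gr$fdr_percent <- fdr
  gr$sample_id <- sample_id
  gr
}

#' Simulate MACS-style peak calls per sample
#'
#' Every planted region present in a sample yields a merged-replicate peak
#' with the region's exact borders plus two replicate calls with borders
#' jittered uniformly within `peak_jitter_bp`. A configurable fraction of
#' merged peaks receives a score below the quality filter; false peaks
#' (rate `false_peak_rate` per planted peak) are added to the merged calls
#' and to exactly one replicate, so that replicate consensus removes them.
#'
#' @param truth from [plant_cooccupancy()].
#' @param config a [simulation_config].
#' @param chrom_sizes named chromosome lengths.
#' @return named list per sample: list(rep1, rep2, merged) of peak `GRanges`.
#' @export
simulate_peak_calls <- function(truth, config, chrom_sizes) {
  set.seed(config$seed + 3L)
  out <- list()
  reg <- truth$regions
  chrom <- as.character(GenomicRanges::seqnames(reg))
  forb_idx <- .interval_index(
    GenomicRanges::resize(GenomicRanges::granges(reg),
                          GenomicRanges::width(reg) + 4000, fix = "center"),
    names(chrom_sizes))
  jit <- function(n) if (config$peak_jitter_bp > 0)
    round(runif(n, -config$peak_jitter_bp, config$peak_jitter_bp)) else
    integer(n)
  for (s in config$samples) {
    sel <- which(truth$presence[, s])
    n <- length(sel)
    st <- GenomicRanges::start(reg)[sel]; en <- GenomicRanges::end(reg)[sel]
    cn <- chrom[sel]
    summit <- floor((st + en) / 2)
    fail <- runif(n) < config$peak_fail_rate
    score <- ifelse(fail, runif(n, 10, 49.5), 50 + rexp(n, 1 / 150))
    fdr <- runif(n, 0, 0.1)
    merged <- .new_peaks(cn, st, en, summit, score, fdr, s)
    merged$planted <- TRUE
    reps <- lapply(1:2, function(r) {
      s2 <- pmax(1, st + jit(n)); e2 <- pmax(s2 + 50, en + jit(n))
      .new_peaks(cn, s2, e2, pmin(pmax(summit, s2), e2),
                 pmax(10, score + rnorm(n, 0, 5)),
                 pmin(99, fdr * exp(rnorm(n, 0, 0.2))), s)
    })
    n_false <- rbinom(1, n, min(1, config$false_peak_rate))
    if (n_false > 0) {
      fs <- character(0); fst <- integer(0); fen <- integer(0)
      tries <- 0L
      while (length(fst) < n_false && tries < n_false * 200L) {
        tries <- tries + 1L
        w <- round(runif(1, 400, 1200))
        cn2 <- sample(names(chrom_sizes), 1)
        p <- 1 + floor(runif(1) * (chrom_sizes[[cn2]] - w - 1))
        if (.idx_overlaps(forb_idx, cn2, p, p + w - 1)) next
        fs <- c(fs, cn2); fst <- c(fst, p); fen <- c(fen, p + w - 1L)
      }
      if (length(fst)) {
        fp <- .new_peaks(fs, fst, fen, floor((fst + fen) / 2),
                         50 + rexp(length(fst), 1 / 100),
                         runif(length(fst), 0, 0.1), s)
        fp$planted <- FALSE
        which_rep <- sample(1:2, length(fp), replace = TRUE)
        merged <- suppressWarnings(c(merged, fp))
        fp$planted <- NULL
        reps[[1]] <- suppressWarnings(c(reps[[1]], fp[which_rep == 1]))
        reps[[2]] <- suppressWarnings(c(reps[[2]], fp[which_rep == 2]))
      }
    }
    out[[s]] <- list(rep1 = reps[[1]], rep2 = reps[[2]], merged = merged)
  }
  out
}

#' Simulate baseline expression and knockdown differential expression
#'
#' Baseline FPKM is log-normal, with genes carrying a planted promoter
#' region drawn from a higher-mean component. For each knockdown condition,
#' the factor's planted promoter-target genes (stem-cell samples) are
#' downregulated with probability `kd_pi_down` (log2 fold change
#' `Normal(-kd_lfc_mean, kd_lfc_sd)`, small adjusted p-value); all other
#' genes are null (log2 fold change centered at 0, adjusted p-value uniform
#' on [0, 1], so the expected false-positive rate at any alpha equals
#' alpha).
#'
#' @param truth from [plant_cooccupancy()].
#' @param annotation an [annotation_bundle].
#' @param config a [simulation_config].
#' @return list with `expression` (data.frame from [expression_table()]),
#'   `de` (named list per condition: gene_id, log2_fold_change, padj,
#'   condition), and `de_truth` (per condition: is_target, planted_down).
#' @export
simulate_expression_and_kd <- function(truth, annotation, config) {
  set.seed(config$seed + 4L)
  gene_ids <- annotation$genes$genes$gene_id
  n <- length(gene_ids)
  promoter_bound <- gene_ids %in%
    unique(stats::na.omit(truth$regions$anchor_gene[
      truth$regions$pattern %in% vapply(config$cluster_spec, function(p)
        if (p$compartment == "promoter") p$name else "", "")]))
  meanlog <- ifelse(promoter_bound, 2.5, 0.8)
  gene_mean <- rlnorm(n, meanlog, 1)
  fpkm <- vapply(1:3, function(r) gene_mean * exp(rnorm(n, 0, 0.15)),
                 numeric(n))
  expr <- expression_table(gene_ids, fpkm)
  de <- list(); de_truth <- list()
  for (f in config$kd_factors) {
    esc_sample <- paste0(f, "_ESC")
    targets <- if (esc_sample %in% names(truth$tss_targets)) {
      truth$tss_targets[[esc_sample]]
    } else character(0)
    is_target <- gene_ids %in% targets
    down <- is_target & runif(n) < config$kd_pi_down
    lfc <- ifelse(down, rnorm(n, -config$kd_lfc_mean, config$kd_lfc_sd),
                  rnorm(n, 0, config$kd_lfc_sd))
    padj <- ifelse(down, 10^(-runif(n, 3, 8)), runif(n))
    de[[f]] <- data.frame(gene_id = gene_ids, log2_fold_change = lfc,
                          padj = padj, condition = f)
    de_truth[[f]] <- data.frame(gene_id = gene_ids, is_target = is_target,
                                planted_down = down)
  }
  list(expression = expr, de = de, de_truth = de_truth)
}

#' Generate a complete synthetic dataset
#'
#' Runs all generator stages from one config: annotation, planted regions,
#' coverage tracks, peak calls, expression and knockdown tables.
#'
#' @param config a [simulation_config].
#' @param tracks generate coverage tracks (the slowest stage); set FALSE
#'   when only peaks/annotation/expression are needed.
#' @return a `synthetic_dataset` list: `config`, `annotation`, `truth`,
#'   `tracks` (or NULL), `peaks`, `expression`.
#' @export
simulate_dataset <- function(config = simulation_config(), tracks = TRUE) {
  annotation <- generate_annotation(config)
  truth <- plant_cooccupancy(config, annotation)
  trk <- if (tracks) simulate_tracks(truth, annotation, config) else NULL
  peaks <- simulate_peak_calls(truth, config, annotation$chrom_sizes)
  expr <- simulate_expression_and_kd(truth, annotation, config)
  structure(list(config = config, annotation = annotation, truth = truth,
                 tracks = trk, peaks = peaks, expression = expr),
            class = "synthetic_dataset")
}

#' Planted cluster label for arbitrary regions
#'
#' Maps regions (e.g. the peak-union rows of a signal matrix) back to the
#' planted truth by overlap; regions overlapping no planted region get `NA`.
#'
#' @param regions `GRanges`.
#' @param truth a `synthetic_truth`.
#' @return integer vector of planted cluster indices (NA = unplanted).
#' @export
match_truth_labels <- function(regions, truth) {
  hits <- GenomicRanges::findOverlaps(regions, truth$regions,
                                      ignore.strand = TRUE, select = "first")
  truth$regions$cluster[hits]
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits chrom.sizes, GTF gene models, BED CpG islands, BED6 enhancers
#' (name = assigned gene), narrowPeak replicate/merged peak calls, bedGraph
#' coverage tracks, expression and DE TSVs, and a truth JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- dataset$annotation
  write_chrom_sizes(ann$chrom_sizes, file.path(dir, "chrom.sizes"))
  write_gtf(ann$genes, file.path(dir, "genes.gtf"))
  write_bed(ann$cpg_islands, file.path(dir, "cpg_islands.bed"), "bed3")
  for (kind in c("typical", "super")) {
    e <- ann[[paste0(kind, "_enhancers")]]
    e$name <- if (length(e)) e$assigned_gene else character(0)
    write_bed(e, file.path(dir, paste0(kind, "_enhancers.bed")), "bed6")
  }
  for (s in names(dataset$peaks)) {
    pk <- dataset$peaks[[s]]
    write_bed(pk$rep1, file.path(dir, paste0(s, ".rep1.narrowPeak")), "narrowpeak")
    write_bed(pk$rep2, file.path(dir, paste0(s, ".rep2.narrowPeak")), "narrowpeak")
    write_bed(pk$merged, file.path(dir, paste0(s, ".merged.narrowPeak")), "narrowpeak")
  }
  if (!is.null(dataset$tracks)) {
    for (s in names(dataset$tracks$chip)) {
      write_bedgraph(dataset$tracks$chip[[s]],
                     file.path(dir, paste0(s, ".bedGraph")))
    }
    for (ct in names(dataset$tracks$input)) {
      write_bedgraph(dataset$tracks$input[[ct]],
                     file.path(dir, paste0("input_", ct, ".bedGraph")))
    }
  }
  write.table(dataset$expression$expression, file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (f in names(dataset$expression$de)) {
    write.table(dataset$expression$de[[f]],
                file.path(dir, paste0("de_", f, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- dataset$truth
  truth_json <- list(
    regions = data.frame(
      chrom = as.character(GenomicRanges::seqnames(truth$regions)),
      start = GenomicRanges::start(truth$regions) - 1L,
      end = GenomicRanges::end(truth$regions),
      cluster = truth$regions$cluster, pattern = truth$regions$pattern,
      anchor_gene = truth$regions$anchor_gene),
    presence = as.data.frame(truth$presence),
    tss_targets = truth$tss_targets)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
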