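# Genomic annotation of peaks and the gene-target classification ledger:
# TSS-proximal vs TSS-distal vs non-target, plus MSL/NSL complex targets.

#' Genes bound at the promoter
#'
#' A gene counts as bound when at least one peak overlaps its
#' TSS +/- `flank_bp` window (500 bp for binding maps, 1000 bp for target
#' classification).
#'
#' @param genes [gene_models] or `GRanges` with `tss`/`gene_id`.
#' @param peaks peak `GRanges`.
#' @param flank_bp window half-width in bp.
#' @param chrom_sizes optional chromosome lengths for end clipping.
#' @return character vector of bound gene ids.
#' @export
tss_binding <- function(genes, peaks, flank_bp, chrom_sizes = NULL) {
  win <- tss_windows(genes, flank_bp, chrom_sizes)
  win$gene_id[IRanges::overlapsAny(win, peaks, ignore.strand = TRUE)]
}

#' Mutually exclusive genomic compartment of regions
#'
#' Assigns each region to exactly one of three compartments with precedence
#' upstream > gene body > intergenic: a region overlapping the strand-aware
#' 1 kb immediately upstream of any TSS is `upstream_1kb`; otherwise a region
#' overlapping any gene body (exons or introns) is `gene_body`; everything
#' else is `intergenic`.
#'
#' @param regions `GRanges`.
#' @param genes [gene_models] or `GRanges` with `tss`/`gene_id` and strand.
#' @param upstream_bp width of the upstream compartment (default 1000).
#' @return character vector in `{upstream_1kb, gene_body, intergenic}`.
#' @export
assign_compartment <- function(regions, genes, upstream_bp = 1000) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  strand <- as.character(GenomicRanges::strand(g))
  tss <- g$tss
  up_start <- ifelse(strand == "+", tss - upstream_bp, tss + 1)
  up_end <- ifelse(strand == "+", tss - 1, tss + upstream_bp)
  ok <- up_end >= 1
  upstream <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g)[ok],
    IRanges::IRanges(pmax(1, up_start[ok]), up_end[ok]))
  in_up <- IRanges::overlapsAny(regions, upstream, ignore.strand = TRUE)
  in_body <- IRanges::overlapsAny(regions, g, ignore.strand = TRUE)
  ifelse(in_up, "upstream_1kb", ifelse(in_body, "gene_body", "intergenic"))
}

#' GREAT-style basal-plus-extension regulatory domains
#'
#' Each gene receives a strand-aware basal domain (`basal_up` bp upstream to
#' `basal_down` bp downstream of the TSS) and an extended domain growing on
#' both sides up to `max_extension` bp but stopping at the nearest other
#' gene's basal domain (basal domains themselves are inviolate: a domain
#' never shrinks below its own basal region, and basal domains of different
#' genes may overlap). Defaults are the documented defaults of the
#' basal-plus-extension association rule (5 kb / 1 kb / 1 Mb).
#'
#' @param genes [gene_models] or `GRanges` with `tss`/`gene_id` and strand.
#' @param basal_up,basal_down basal extent up/downstream of the TSS (bp).
#' @param max_extension maximum extension per side (bp).
#' @param chrom_sizes named chromosome lengths (for clipping).
#' @return `GRanges` of extended domains with metadata `gene_id`,
#'   `basal_start`, `basal_end`.
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                                     max_extension = 1e6, chrom_sizes = NULL) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  strand <- as.character(GenomicRanges::strand(g))
  tss <- g$tss
  bs <- ifelse(strand == "+", tss - basal_up, tss - basal_down + 1)
  be <- ifelse(strand == "+", tss + basal_down - 1, tss + basal_up)
  bs <- pmax(1, bs)
  chrom <- as.character(GenomicRanges::seqnames(g))
  if (!is.null(chrom_sizes)) be <- pmin(be, chrom_sizes[chrom])
  ext_s <- numeric(length(g)); ext_e <- numeric(length(g))
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    clen <- if (!is.null(chrom_sizes)) chrom_sizes[[cn]] else Inf
    for (i in idx) {
      others <- setdiff(idx, i)
      # nearest basal edge to the left of this basal start (overlap blocks)
      left <- others[bs[others] <= bs[i]]
      L <- if (length(left)) max(pmin(be[left], bs[i] - 1), 0) else 0
      right <- others[be[others] >= be[i]]
      R <- if (length(right)) min(pmax(bs[right], be[i] + 1), Inf) else Inf
      ext_s[i] <- min(bs[i], max(bs[i] - max_extension, L + 1, 1))
      ext_e[i] <- max(be[i], min(be[i] + max_extension, R - 1, clen))
    }
  }
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ext_s, ext_e))
  out$gene_id <- g$gene_id
  out$basal_start <- as.integer(bs)
  out$basal_end <- as.integer(be)
  out
}

#' CpG islands per promoter
#'
#' Counts the CpG islands intersecting each transcript's
#' TSS +/- `flank_bp` window.
#'
#' @param genes [gene_models] or `GRanges` with `tss`/`gene_id`.
#' @param islands `GRanges` of CpG islands.
#' @param flank_bp window half-width (default 500).
#' @param chrom_sizes optional chromosome lengths.
#' @return named integer vector (gene_id -> island count).
#' @export
cpg_overlap <- function(genes, islands, flank_bp = 500, chrom_sizes = NULL) {
  win <- tss_windows(genes, flank_bp, chrom_sizes)
  setNames(GenomicRanges::countOverlaps(win, islands, ignore.strand = TRUE),
           win$gene_id)
}

#' Classify genes as TSS, TSS-distal or non-targets per factor
#'
#' Implements the target-definition ledger. Per factor and gene:
#' \itemize{
#' \item `tss_target` — at least one peak overlaps the gene's
#'   TSS +/- `tss_flank_bp` window;
#' \item otherwise `tss_distal_target` — a TSS-distal peak of that factor
#'   (a peak overlapping no TSS window of any gene) (a) overlaps the gene's
#'   published typical or super enhancer, (b) falls inside the gene's
#'   extended regulatory domain, or (c) overlaps at least one of the gene's
#'   introns;
#' \item otherwise `bound_unclassified` — the gene carries some binding
#'   evidence (its own gene body, or promoter/distal/body evidence from any
#'   other analyzed factor) but meets no target criterion for this factor;
#' \item `non_target` — no peak of any analyzed factor overlaps the
#'   promoter, the gene body, or any distal criterion of the gene.
#' }
#' Complex-level co-occupancy: a gene is an MSL target when MOF and at least
#' one of MSL1/MSL2 are tied to it through the same route (both at the TSS
#' window, or both assigned TSS-distally); NSL targets analogously with
#' KANSL3/MCRS1.
#'
#' @param genes [gene_models].
#' @param peaks_by_factor named list: factor (protein) -> peak `GRanges`.
#' @param annotation an [annotation_bundle] (enhancers + chrom sizes).
#' @param domains regulatory domains from [build_regulatory_domains()]
#'   (computed from `genes` if NULL).
#' @param de_genes optional character vector restricting classification to
#'   the significantly affected genes, as in a knockdown analysis.
#' @param tss_flank_bp promoter window half-width for target calls
#'   (default 1000).
#' @param mof,msl_factors,nsl_factors factor names used for the complex
#'   co-occupancy calls; absent names are skipped.
#' @return data.frame with one row per gene x factor: `gene_id`, `factor`,
#'   `status`, `evidence` (comma-joined tags), `msl_target`, `nsl_target`.
#' @export
classify_targets <- function(genes, peaks_by_factor, annotation,
                             domains = NULL, de_genes = NULL,
                             tss_flank_bp = 1000, mof = "MOF",
                             msl_factors = c("MSL1", "MSL2"),
                             nsl_factors = c("KANSL3", "MCRS1")) {
  stopifnot(inherits(genes, "gene_models"), length(peaks_by_factor) >= 1,
            !is.null(names(peaks_by_factor)))
  sizes <- annotation$chrom_sizes
  g <- genes$genes
  gene_ids <- g$gene_id
  if (!is.null(de_genes)) {
    keep <- gene_ids %in% de_genes
  } else keep <- rep(TRUE, length(gene_ids))
  win <- tss_windows(genes, tss_flank_bp, sizes)
  enh <- all_enhancers(annotation)
  if (length(enh) && !is.null(enh$assigned_gene)) {
    bad <- !is.na(enh$assigned_gene) & !(enh$assigned_gene %in% gene_ids)
    if (any(bad)) stop("enhancer assigned_gene missing from gene list")
  }
  if (is.null(domains)) {
    domains <- build_regulatory_domains(genes, chrom_sizes = sizes)
  }
  factors <- names(peaks_by_factor)
  nf <- length(factors); ng <- length(gene_ids)
  ev_names <- c("tss_overlap", "enhancer_overlap", "domain_assignment",
                "intron_overlap", "gene_body_overlap")
  evid <- array(FALSE, dim = c(ng, nf, length(ev_names)),
                dimnames = list(gene_ids, factors, ev_names))
  introns <- genes$introns
  intron_flat <- unlist(introns)
  intron_gene <- rep(names(introns), lengths(introns))
  for (f in factors) {
    pk <- GenomicRanges::granges(peaks_by_factor[[f]])
    if (!length(pk)) next
    evid[, f, "tss_overlap"] <-
      IRanges::overlapsAny(win, pk, ignore.strand = TRUE)
    evid[, f, "gene_body_overlap"] <-
      IRanges::overlapsAny(g, pk, ignore.strand = TRUE)
    distal <- pk[!IRanges::overlapsAny(pk, win, ignore.strand = TRUE)]
    if (length(distal)) {
      if (length(enh) && !is.null(enh$assigned_gene)) {
        hit_enh <- enh[IRanges::overlapsAny(enh, distal,
                                                  ignore.strand = TRUE)]
        eg <- unique(hit_enh$assigned_gene)
        evid[gene_ids %in% eg, f, "enhancer_overlap"] <- TRUE
      }
      hit_dom <- unique(domains$gene_id[
        IRanges::overlapsAny(domains, distal, ignore.strand = TRUE)])
      evid[gene_ids %in% hit_dom, f, "domain_assignment"] <- TRUE
      if (length(intron_flat)) {
        hit_int <- unique(intron_gene[
          IRanges::overlapsAny(intron_flat, distal,
                                     ignore.strand = TRUE)])
        evid[gene_ids %in% hit_int, f, "intron_overlap"] <- TRUE
      }
    }
  }
  dn <- list(gene_ids, factors)
  tssb <- evid[, , "tss_overlap", drop = FALSE][, , 1, drop = FALSE]
  dim(tssb) <- c(ng, nf); dimnames(tssb) <- dn
  distal_ev <- evid[, , "enhancer_overlap", drop = FALSE][, , 1] |
    evid[, , "domain_assignment", drop = FALSE][, , 1] |
    evid[, , "intron_overlap", drop = FALSE][, , 1]
  dim(distal_ev) <- c(ng, nf); dimnames(distal_ev) <- dn
  body_ev <- evid[, , "gene_body_overlap", drop = FALSE][, , 1]
  dim(body_ev) <- c(ng, nf); dimnames(body_ev) <- dn
  any_evidence <- rowSums(tssb | distal_ev | body_ev) > 0
  status <- base::matrix("non_target", ng, nf,
                         dimnames = list(gene_ids, factors))
  status[any_evidence, ] <- "bound_unclassified"
  status[distal_ev & !tssb] <- "tss_distal_target"
  status[tssb] <- "tss_target"
  complex_target <- function(partners) {
    if (!(mof %in% factors) || !any(partners %in% factors)) {
      return(rep(NA, ng))
    }
    partners <- intersect(partners, factors)
    p_tss <- rowSums(tssb[, partners, drop = FALSE]) > 0
    p_dist <- rowSums(distal_ev[, partners, drop = FALSE] &
                      !tssb[, partners, drop = FALSE]) > 0
    (tssb[, mof] & p_tss) |
      ((distal_ev[, mof] & !tssb[, mof]) & p_dist)
  }
  msl <- complex_target(msl_factors)
  nsl <- complex_target(nsl_factors)
  rows <- do.call(rbind, lapply(seq_along(factors), function(j) {
    ev_str <- vapply(seq_len(ng), function(i) {
      tags <- ev_names[evid[i, j, ]]
      paste(tags, collapse = ",")
    }, "")
    data.frame(gene_id = gene_ids, factor = factors[j],
               status = status[, j], evidence = ev_str,
               msl_target = msl, nsl_target = nsl,
               row.names = NULL)
  }))
  rows[rows$gene_id %in% gene_ids[keep], , drop = FALSE]
}
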