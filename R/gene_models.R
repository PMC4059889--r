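#' Construct gene models from gene bodies and exons
#'
#' A `gene_models` object holds one record per transcript: the gene body, the
#' strand-aware TSS (the 5' end of the transcript: `start` on `+`, `end` on
#' `-`), the ordered exons, and introns derived as the gaps between
#' consecutive exons. Alternative transcription start sites are deliberately
#' kept as individual records.
#'
#' @param genes `GRanges` of transcript bodies with a `gene_id` metadata
#'   column (unique) and strand `+` or `-`.
#' @param exons `GRangesList` named by `gene_id`, each element the exons of
#'   that transcript.
#' @return an object of class `gene_models`: list with elements `genes`
#'   (bodies + `gene_id`, `tss`), `exons`, `introns` (both `GRangesList`).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(!is.null(genes$gene_id))
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
  if (!all(as.character(GenomicRanges::strand(genes)) %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  exons <- exons[genes$gene_id]
  if (any(is.na(names(exons)))) stop("every gene needs an exon set")
  exons <- GenomicRanges::GRangesList(
    lapply(exons, function(e) GenomicRanges::sort(e, ignore.strand = TRUE)))
  # exons must lie within the gene body
  body_start <- GenomicRanges::start(genes)
  body_end <- GenomicRanges::end(genes)
  ex_start <- min(GenomicRanges::start(exons))
  ex_end <- max(GenomicRanges::end(exons))
  if (any(ex_start < body_start | ex_end > body_end)) {
    bad <- which(ex_start < body_start | ex_end > body_end)[1]
    stop("exons outside gene bounds for gene ", genes$gene_id[bad])
  }
  strand <- as.character(GenomicRanges::strand(genes))
  genes$tss <- ifelse(strand == "+", body_start, body_end)
  introns <- GenomicRanges::psetdiff(GenomicRanges::granges(genes), exons)
  names(introns) <- genes$gene_id
  structure(list(genes = genes, exons = exons, introns = introns),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "transcripts on",
      length(unique(as.character(GenomicRanges::seqnames(x$genes)))),
      "chromosomes\n")
  invisible(x)
}

#' @export
length.gene_models <- function(x) length(x$genes)

#' Read gene models from a GTF/GFF file
#'
#' Builds one gene model per transcript from the `exon` features (grouped by
#' `transcript_id`); the gene body is the `transcript` feature when present,
#' otherwise the range of the exons. Coordinates are converted from GTF's
#' 1-based closed convention by `rtracklayer`, so no shifting is applied.
#'
#' @param path GTF/GFF file with Ensembl-style attributes.
#' @return a [gene_models] object (gene_id = transcript_id).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  if (is.null(ex$transcript_id)) stop("exon features lack transcript_id")
  exl <- GenomicRanges::split(GenomicRanges::granges(ex), ex$transcript_id)
  tx <- gr[gr$type %in% c("transcript", "mRNA")]
  if (length(tx) && !is.null(tx$transcript_id) &&
      all(names(exl) %in% tx$transcript_id) && !anyDuplicated(tx$transcript_id)) {
    bodies <- tx[match(names(exl), tx$transcript_id)]
  } else {
    bodies <- unlist(range(exl))
    str <- vapply(seq_along(exl), function(i)
      as.character(GenomicRanges::strand(ex[ex$transcript_id == names(exl)[i]][1])),
      "")
    GenomicRanges::strand(bodies) <- str
  }
  bodies <- GenomicRanges::granges(bodies)
  bodies$gene_id <- names(exl)
  gene_models(bodies, exl)
}

#' Write gene models as GTF
#'
#' Emits `transcript` and `exon` features with `gene_id`/`transcript_id`
#' attributes so the file round-trips through [read_gene_models()].
#'
#' @param gm a [gene_models] object.
#' @param path output path.
#' @export
write_gtf <- function(gm, path) {
  g <- gm$genes
  chrom <- as.character(GenomicRanges::seqnames(g))
  strand <- as.character(GenomicRanges::strand(g))
  attr_of <- function(id) sprintf('gene_id "%s"; transcript_id "%s";', id, id)
  tx_lines <- sprintf("%s\tchipcooc\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      chrom, GenomicRanges::start(g), GenomicRanges::end(g),
                      strand, attr_of(g$gene_id))
  ex_lines <- unlist(lapply(seq_along(g), function(i) {
    e <- gm$exons[[g$gene_id[i]]]
    sprintf("%s\tchipcooc\texon\t%d\t%d\t.\t%s\t.\t%s",
            chrom[i], GenomicRanges::start(e), GenomicRanges::end(e),
            strand[i], attr_of(g$gene_id[i]))
  }))
  writeLines(c(tx_lines, ex_lines), path)
  invisible(path)
}

#' Bundle the annotation tracks used across the pipeline
#'
#' @param genes a [gene_models] object.
#' @param cpg_islands `GRanges` of CpG islands.
#' @param typical_enhancers,super_enhancers `GRanges` with an optional
#'   `assigned_gene` metadata column naming the regulated gene.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return an `annotation_bundle` (list, validated).
#' @export
annotation_bundle <- function(genes, cpg_islands, typical_enhancers,
                              super_enhancers, chrom_sizes) {
  stopifnot(inherits(genes, "gene_models"))
  check_within <- function(gr, what) {
    if (!length(gr)) return(invisible())
    chr <- as.character(GenomicRanges::seqnames(gr))
    if (!all(chr %in% names(chrom_sizes))) {
      stop(what, ": chromosome absent from chrom_sizes")
    }
    if (any(GenomicRanges::end(gr) > chrom_sizes[chr]) ||
        any(GenomicRanges::start(gr) < 1)) {
      stop(what, ": interval outside chromosome bounds")
    }
  }
  check_within(genes$genes, "genes")
  check_within(cpg_islands, "cpg_islands")
  check_within(typical_enhancers, "typical_enhancers")
  check_within(super_enhancers, "super_enhancers")
  gene_ids <- genes$genes$gene_id
  for (e in list(typical_enhancers, super_enhancers)) {
    if (length(e) && !is.null(e$assigned_gene)) {
      known <- is.na(e$assigned_gene) | e$assigned_gene %in% gene_ids
      if (!all(known)) stop("enhancer assigned_gene not in gene list")
    }
  }
  structure(list(genes = genes, cpg_islands = cpg_islands,
                 typical_enhancers = typical_enhancers,
                 super_enhancers = super_enhancers,
                 chrom_sizes = chrom_sizes),
            class = "annotation_bundle")
}

#' All enhancers of a bundle as one GRanges with a `kind` column
#' @param annotation an [annotation_bundle].
#' @return `GRanges` with `kind` in `{typical, super}` and `assigned_gene`.
#' @export
all_enhancers <- function(annotation) {
  te <- annotation$typical_enhancers
  se <- annotation$super_enhancers
  if (length(te)) te$kind <- "typical"
  if (length(se)) se$kind <- "super"
  c(te, se)
}
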