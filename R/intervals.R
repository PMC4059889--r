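#' @importFrom methods is
#' @importFrom stats median rnorm runif rexp rbinom rnbinom rlnorm setNames
#' @importFrom utils read.table write.table
NULL

# All interval containers are GRanges (1-based, closed). BED-family files are
# 0-based half-open on disk and converted on read/write. Windows phrased as
# "position +/- N bp" cover 2N bases: [pos - N, pos + N - 1] in 1-based
# coordinates, clipped at chromosome ends.

#' Read a two-column chromosome sizes file
#'
#' @param path path to a `chrom.sizes`-style file (name, length).
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric"))
  setNames(as.integer(df[[2]]), df[[1]])
}

#' Write chromosome sizes
#' @param sizes named integer vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), as.integer(sizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.split_bed_lines <- function(path, min_fields) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, got %d",
                 lineno[bad[1]], path, min_fields, nf[bad[1]]))
  }
  list(fields = fields, lineno = lineno)
}

.bed_num <- function(fields, idx, lineno, path, what) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", idx)))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: non-numeric %s field",
                 lineno[bad[1]], path, what))
  }
  v
}

#' Read BED-family interval files
#'
#' Supported dialects: `bed3` (chrom, start, end), `bed6` (+ name, score,
#' strand) and `narrowpeak` — a BED6+4 dialect as emitted by MACS-style peak
#' callers: column 7 signal, column 8 \eqn{-\log_{10} p}, column 9
#' \eqn{-\log_{10} q}, column 10 the summit offset from the region start.
#' On read, the p-value column is rescaled to \eqn{-10\log_{10} p} and the
#' q-value column converted to an FDR in percent
#' (\eqn{100 \times 10^{-\mathrm{col9}}}), matching the units of the
#' downstream peak filters. Coordinates on disk are 0-based half-open and are
#' converted to 1-based closed `GRanges`.
#'
#' @param path input file.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowpeak"`.
#' @param sample_id optional label stored in the `sample_id` metadata column.
#' @return a [GenomicRanges::GRanges]; for `narrowpeak`, metadata columns
#'   `summit` (absolute 1-based position), `score_neg10log10p`, `fdr_percent`
#'   and `sample_id`.
#' @export
read_bed <- function(path, dialect = c("bed3", "bed6", "narrowpeak"),
                     sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  min_fields <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowpeak = 10L)
  parsed <- .split_bed_lines(path, min_fields)
  if (is.null(parsed)) return(GenomicRanges::GRanges())
  f <- parsed$fields; ln <- parsed$lineno
  chrom <- vapply(f, `[[`, "", 1L)
  start0 <- .bed_num(f, 2L, ln, path, "start")
  end0 <- .bed_num(f, 3L, ln, path, "end")
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d in %s: start %d, end %d",
                 ln[bad[1]], path, start0[bad[1]], end0[bad[1]]))
  }
  strand <- "*"
  if (dialect != "bed3") {
    strand <- vapply(f, `[[`, "", 6L)
    strand[!strand %in% c("+", "-")] <- "*"
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (dialect != "bed3") gr$name <- vapply(f, `[[`, "", 4L)
  if (dialect == "narrowpeak") {
    neglog10p <- .bed_num(f, 8L, ln, path, "p-value")
    neglog10q <- .bed_num(f, 9L, ln, path, "q-value")
    offset <- .bed_num(f, 10L, ln, path, "summit-offset")
    gr$summit <- as.integer(start0 + offset + 1)
    gr$score_neg10log10p <- 10 * neglog10p
    gr$fdr_percent <- 100 * 10^(-neglog10q)
    gr$sample_id <- if (is.null(sample_id)) NA_character_ else sample_id
    bad <- which(gr$summit < GenomicRanges::start(gr) |
                 gr$summit > GenomicRanges::end(gr))
    if (length(bad)) {
      stop(sprintf("summit outside peak at line %d in %s", ln[bad[1]], path))
    }
  } else if (!is.null(sample_id)) {
    gr$sample_id <- sample_id
  }
  gr
}

#' Write intervals as BED3/BED6 or narrowPeak
#'
#' Inverse of [read_bed()]: emits 0-based half-open coordinates, and for the
#' narrowPeak dialect converts `score_neg10log10p` and `fdr_percent` back to
#' the \eqn{-\log_{10}} columns.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param dialect output dialect (see [read_bed()]).
#' @export
write_bed <- function(gr, path, dialect = c("bed3", "bed6", "narrowpeak")) {
  dialect <- match.arg(dialect)
  start0 <- as.integer(GenomicRanges::start(gr) - 1L)
  end0 <- as.integer(GenomicRanges::end(gr))
  if (dialect == "bed3") {
    df <- data.frame(as.character(GenomicRanges::seqnames(gr)), start0, end0)
  } else {
    name <- if (!is.null(gr$name)) gr$name else paste0("region_", seq_along(gr))
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "."
    if (dialect == "bed6") {
      score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
      df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                       start0, end0, name, score, strand)
    } else {
      stopifnot(!is.null(gr$summit), !is.null(gr$score_neg10log10p),
                !is.null(gr$fdr_percent))
      neglog10p <- gr$score_neg10log10p / 10
      neglog10q <- -log10(gr$fdr_percent / 100)
      signal <- if (!is.null(gr$signal_value)) gr$signal_value
                else rep(0, length(gr))
      df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                       start0, end0, name,
                       round(gr$score_neg10log10p), strand,
                       signal,
                       format(neglog10p, digits = 10, scientific = FALSE, trim = TRUE),
                       format(neglog10q, digits = 10, scientific = FALSE, trim = TRUE),
                       gr$summit - 1L - start0)
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge intervals into a sorted non-overlapping union
#'
#' Intervals whose gap is at most `min_gap` bases (book-ended intervals have
#' gap 0, as in `bedtools merge`) are joined. Strand is ignored.
#'
#' @param intervals a `GRanges`.
#' @param min_gap maximum gap (bp) across which intervals are still joined.
#' @return sorted, disjoint `GRanges`.
#' @export
merge_intervals <- function(intervals, min_gap = 0) {
  stopifnot(min_gap >= 0)
  GenomicRanges::reduce(GenomicRanges::granges(intervals),
                        min.gapwidth = min_gap + 1L,
                        ignore.strand = TRUE)
}

#' Fraction of each target interval covered by a set of intervals
#'
#' @param target `GRanges` of regions whose covered fraction is wanted.
#' @param others `GRanges` whose base-pair union does the covering.
#' @return numeric vector in `[0, 1]`, one entry per target.
#' @export
overlap_fraction <- function(target, others) {
  if (!length(target)) return(numeric(0))
  covered <- merge_intervals(others)
  hits <- GenomicRanges::findOverlaps(target, covered, ignore.strand = TRUE)
  ov <- IRanges::pintersect(
    GenomicRanges::ranges(target)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(covered)[S4Vectors::subjectHits(hits)])
  w <- numeric(length(target))
  if (length(hits)) {
    sums <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    w[as.integer(names(sums))] <- sums
  }
  w / GenomicRanges::width(target)
}

#' Symmetric windows around transcription start sites
#'
#' "TSS +/- N bp" denotes the 2N-base window `[tss - N, tss + N)` in 0-based
#' coordinates; windows are clipped at position 1 and, when `chrom_sizes` is
#' supplied, at chromosome ends.
#'
#' @param genes a `gene_models` object or a `GRanges` with `tss` and
#'   `gene_id` metadata columns.
#' @param flank_bp half-width N in bp.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return `GRanges` with a `gene_id` column, one window per transcript.
#' @export
tss_windows <- function(genes, flank_bp, chrom_sizes = NULL) {
  stopifnot(flank_bp > 0)
  gr <- if (inherits(genes, "gene_models")) genes$genes else genes
  tss <- gr$tss
  start <- pmax(1, tss - flank_bp)
  end <- tss + flank_bp - 1L
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, chrom_sizes[as.character(GenomicRanges::seqnames(gr))])
  }
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(start, end))
  out$gene_id <- gr$gene_id
  out
}
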