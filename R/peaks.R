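# Replicate handling and quality filtering of MACS-style peak calls.
# Peaks are GRanges with metadata columns summit, score_neg10log10p,
# fdr_percent, sample_id (see read_bed(dialect = "narrowpeak")).

#' Filter peaks on enrichment score and FDR
#'
#' Peaks with \eqn{-10\log_{10} p} below `min_score` or an FDR above
#' `max_fdr_percent` are excluded. The exclusion conditions are strict, so
#' peaks sitting exactly on a threshold are retained.
#'
#' @param peaks `GRanges` with `score_neg10log10p` and `fdr_percent`.
#' @param min_score minimum \eqn{-10\log_{10} p} (default 50).
#' @param max_fdr_percent maximum FDR in percent (default 0.1, i.e. 0.1\%).
#' @return the retained subset, order preserved.
#' @export
filter_peaks <- function(peaks, min_score = 50, max_fdr_percent = 0.1) {
  if (min_score < 0 || max_fdr_percent < 0) {
    stop("thresholds must be non-negative")
  }
  if (!length(peaks)) return(peaks)
  stopifnot(!is.null(peaks$score_neg10log10p), !is.null(peaks$fdr_percent))
  peaks[peaks$score_neg10log10p >= min_score &
        peaks$fdr_percent <= max_fdr_percent]
}

#' Replicate-consensus peaks
#'
#' Returns the subset of peaks called on the merged replicates that are
#' supported by both individual replicates, i.e. that overlap at least one
#' peak in each replicate's call set. Borders, summits and scores are those
#' of the merged calls. Symmetric in `rep1`/`rep2`.
#'
#' @param merged peaks called on the pooled replicates (`GRanges`).
#' @param rep1,rep2 peaks called on each replicate individually.
#' @param min_overlap_fraction optional minimum fraction of the merged peak
#'   that each replicate must cover (default 0: any 1-bp overlap counts).
#' @return the supported subset of `merged`.
#' @export
replicate_consensus <- function(merged, rep1, rep2, min_overlap_fraction = 0) {
  stopifnot(min_overlap_fraction >= 0, min_overlap_fraction <= 1)
  if (!length(merged)) return(merged)
  supported_by <- function(rep) {
    if (min_overlap_fraction == 0) {
      IRanges::overlapsAny(merged, rep, ignore.strand = TRUE)
    } else {
      overlap_fraction(merged, rep) >= min_overlap_fraction
    }
  }
  merged[supported_by(rep1) & supported_by(rep2)]
}

#' Union of peak regions across samples
#'
#' Merges the (consensus-filtered) peaks of all samples into sorted,
#' non-overlapping union regions, as `bedtools merge` on the pooled calls.
#'
#' @param samples named list of `GRanges`, one per sample.
#' @return disjoint `GRanges` of union regions.
#' @export
peak_union <- function(samples) {
  grl <- lapply(samples, GenomicRanges::granges)
  pooled <- do.call(c, unname(grl))
  if (is.null(pooled) || !length(pooled)) return(GenomicRanges::GRanges())
  merge_intervals(pooled)
}

#' Per-region factor presence calls
#'
#' For each (non-overlapping) region, records which samples have at least one
#' overlapping peak. A region with exactly one present sample is flagged with
#' that sample as its solitary factor — the "solitary enrichment" notion used
#' to describe regions bound by a single ChIPed protein.
#'
#' @param regions disjoint `GRanges` (e.g. from [peak_union()]).
#' @param samples named list of peak `GRanges`.
#' @return the `regions` with metadata columns `present`
#'   (a [IRanges::CharacterList] of sample ids), `n_present`, and
#'   `solitary_factor` (`NA` unless exactly one sample is present).
#' @export
factor_presence <- function(regions, samples) {
  if (!GenomicRanges::isDisjoint(regions)) {
    stop("regions must be non-overlapping")
  }
  stopifnot(length(names(samples)) == length(samples))
  pres <- vapply(samples, function(p) {
    IRanges::overlapsAny(regions, p, ignore.strand = TRUE)
  }, logical(length(regions)))
  if (length(regions) == 1L) pres <- matrix(pres, nrow = 1)
  present <- apply(pres, 1L, function(row) names(samples)[row],
                   simplify = FALSE)
  n <- vapply(present, length, 0L)
  out <- GenomicRanges::granges(regions)
  out$present <- if (length(present)) IRanges::CharacterList(present)
                 else IRanges::CharacterList()
  out$n_present <- n
  out$solitary_factor <- ifelse(n == 1L, vapply(present, function(p)
    if (length(p) == 1L) p else NA_character_, ""), NA_character_)
  out
}
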