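# Fixed-bin genome-wide signal tracks, SES depth scaling, input
# normalization and region-anchored matrix extraction.

#' Construct a binned signal track
#'
#' @param values named list (one numeric vector per chromosome) of bin
#'   values; vector `i` must have `ceiling(chrom_length / bin_size)` entries.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param sample_id track label.
#' @param is_ratio `TRUE` for log2-ratio tracks, which are exempt from the
#'   non-negativity check applied to raw coverage.
#' @return an object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, chrom_sizes, sample_id,
                         is_ratio = FALSE) {
  stopifnot(bin_size >= 1, is.list(values), !is.null(names(values)))
  chrom_sizes <- chrom_sizes[names(values)]
  if (any(is.na(chrom_sizes))) stop("chrom_sizes missing for some chromosomes")
  expected <- ceiling(chrom_sizes / bin_size)
  got <- lengths(values)
  if (!all(got == expected)) {
    stop("bin count mismatch: expected ceiling(chrom_length / bin_size) bins")
  }
  if (!is_ratio && any(vapply(values, function(v) any(v < 0), TRUE))) {
    stop("raw coverage values must be non-negative")
  }
  structure(list(sample_id = sample_id, bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes, values = values,
                 is_ratio = is_ratio),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track '%s': %d chromosomes, bin %d bp, total %.4g%s\n",
              x$sample_id, length(x$values), x$bin_size, track_total(x),
              if (x$is_ratio) " (log2 ratio)" else ""))
  invisible(x)
}

#' Total signal of a track (sum of bin values)
#' @param track a [binned_track].
#' @return numeric scalar.
#' @export
track_total <- function(track) sum(vapply(track$values, sum, 0))

#' Read a bedGraph file into a binned track
#'
#' Bin values are coverage-weighted means over each bin: bases not covered by
#' any bedGraph interval count as 0. Intervals beyond the chromosome end are
#' an error.
#'
#' @param path bedGraph file.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param sample_id track label (default: file name).
#' @param is_ratio whether the values are log2 ratios.
#' @return a [binned_track].
#' @export
read_bedgraph <- function(path, bin_size, chrom_sizes,
                          sample_id = basename(path), is_ratio = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (length(gr)) {
    if (!all(chr %in% names(chrom_sizes))) {
      stop("bedGraph chromosome absent from chrom_sizes")
    }
    if (any(GenomicRanges::end(gr) > chrom_sizes[chr])) {
      stop("bedGraph interval beyond chromosome end")
    }
  }
  values <- lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    nb <- ceiling(len / bin_size)
    v <- numeric(nb)
    sub <- gr[chr == cn]
    if (!length(sub)) return(v)
    # distribute interval signal across bins, per-base weighting
    s0 <- GenomicRanges::start(sub) - 1L   # 0-based half-open
    e0 <- GenomicRanges::end(sub)
    sc <- sub$score
    first <- s0 %/% bin_size
    last <- (e0 - 1L) %/% bin_size
    for (i in seq_along(sub)) {
      bins <- first[i]:last[i]
      bs <- pmax(s0[i], bins * bin_size)
      be <- pmin(e0[i], (bins + 1) * bin_size)
      v[bins + 1L] <- v[bins + 1L] + sc[i] * (be - bs)
    }
    binw <- pmin(bin_size, len - (seq_len(nb) - 1L) * bin_size)
    v / binw
  })
  names(values) <- names(chrom_sizes)
  binned_track(values, bin_size, chrom_sizes, sample_id, is_ratio = is_ratio)
}

#' Write a binned track as bedGraph
#'
#' Adjacent equal-valued bins are run-length collapsed; zero bins of raw
#' tracks are omitted.
#'
#' @param track a [binned_track].
#' @param path output path.
#' @param digits number of significant digits written.
#' @export
write_bedgraph <- function(track, path, digits = 8) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(track$values)) {
    v <- round(track$values[[cn]], digits)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    keep <- if (track$is_ratio) rep(TRUE, length(r$values)) else r$values != 0
    if (!any(keep)) next
    bs <- track$bin_size
    len <- track$chrom_sizes[[cn]]
    df <- data.frame(cn, as.integer(starts[keep] * bs),
                     as.integer(pmin(ends[keep] * bs, len)),
                     format(r$values[keep], digits = digits,
                            scientific = FALSE, trim = TRUE))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

.check_same_binning <- function(a, b) {
  if (a$bin_size != b$bin_size ||
      !identical(names(a$values), names(b$values)) ||
      !identical(lengths(a$values), lengths(b$values))) {
    stop("tracks must share bin size and chromosome layout")
  }
}

#' SES (signal extraction scaling) factor between ChIP and input
#'
#' Implements the signal-extraction method for sequencing-depth correction:
#' bins are ordered by increasing ChIP signal; over the k lowest-ChIP bins
#' the cumulative fractions of total ChIP and total input signal are
#' compared; the background cut k* is the (smallest) k maximizing
#' `|P_input(k) - P_chip(k)|`, and the returned factor is the ratio of input
#' to ChIP signal summed over bins 1..k*. Multiplying the ChIP track by this
#' factor equalizes the background of the two tracks.
#'
#' @param chip,input [binned_track]s with identical binning.
#' @return positive scaling factor to apply to the ChIP track.
#' @export
ses_scale_factor <- function(chip, input) {
  .check_same_binning(chip, input)
  vc <- unlist(chip$values, use.names = FALSE)
  vi <- unlist(input$values, use.names = FALSE)
  tc <- sum(vc); ti <- sum(vi)
  if (tc <= 0 || ti <= 0) stop("both tracks must have positive total signal")
  ord <- order(vc)
  cc <- cumsum(vc[ord])
  ci <- cumsum(vi[ord])
  gap <- abs(ci / ti - cc / tc)
  cand <- which(cc > 0)
  if (!length(cand)) stop("ChIP background sum is zero")
  k <- cand[which.max(gap[cand])]
  ci[k] / cc[k]
}

#' Normalize a ChIP track to its input as a log2 ratio
#'
#' Per bin: `log2((factor * chip + pseudocount) / (input + pseudocount))`.
#' With `factor = NULL` the SES factor is computed first.
#'
#' @param chip,input [binned_track]s with identical binning.
#' @param factor depth-scaling factor applied to the ChIP values (see
#'   [ses_scale_factor()]).
#' @param pseudocount positive stabilizer added to both numerator and
#'   denominator (default 1), keeping the chip == input case exactly 0.
#' @return a [binned_track] with `is_ratio = TRUE`.
#' @export
normalize_to_input <- function(chip, input, factor = NULL, pseudocount = 1.0) {
  .check_same_binning(chip, input)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (is.null(factor)) factor <- ses_scale_factor(chip, input)
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  values <- Map(function(c, i) log2((factor * c + pseudocount) /
                                    (i + pseudocount)),
                chip$values, input$values)
  binned_track(values, chip$bin_size, chip$chrom_sizes,
               paste0(chip$sample_id, ".log2ratio"), is_ratio = TRUE)
}

# Per-base prefix sum of a binned track on one chromosome: S(x) = sum of the
# per-base signal over [0, x), x real in [0, chrom_len]. Bases outside the
# chromosome contribute 0.
.track_prefix <- function(track, chrom) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  bs <- track$bin_size
  len <- track$chrom_sizes[[chrom]]
  nb <- length(v)
  binw <- pmin(bs, len - (seq_len(nb) - 1) * bs)
  c0 <- c(0, cumsum(v * binw))
  function(x) {
    x <- pmin(pmax(x, 0), len)
    i <- pmin(floor(x / bs), nb - 1)
    c0[i + 1] + (x - i * bs) * v[i + 1]
  }
}

#' Extract a region-anchored signal matrix
#'
#' The computeMatrix-like core. In `reference_point` mode a fixed window of
#' `window_bp` centered on each region's midpoint (or on supplied `anchors`,
#' e.g. TSS positions) is cut into `window_bp / bin_bp` bins; each matrix
#' entry is the mean per-base track signal over that bin, with bases outside
#' the genome contributing 0. In `scale_regions` mode each region is linearly
#' rescaled to `window_bp` before binning. Per-region vectors are
#' concatenated across samples in the order of `tracks`.
#'
#' @param regions `GRanges` of rows.
#' @param tracks named list of [binned_track]s (the sample order).
#' @param mode `"reference_point"` or `"scale_regions"`.
#' @param window_bp total window width (default 2000).
#' @param bin_bp bin width (default 50); must divide `window_bp`.
#' @param anchors optional integer vector of 1-based anchor positions
#'   (reference_point mode only); default: region midpoints.
#' @return a `region_signal_matrix`: list with `regions`, `samples`,
#'   `n_bins_per_sample`, `values` (rows x (samples*bins)), `mode`,
#'   `window_bp`, `bin_bp`.
#' @export
extract_matrix <- function(regions, tracks,
                           mode = c("reference_point", "scale_regions"),
                           window_bp = 2000, bin_bp = 50, anchors = NULL) {
  mode <- match.arg(mode)
  if (window_bp %% bin_bp != 0) stop("window_bp must be divisible by bin_bp")
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  nbin <- as.integer(window_bp / bin_bp)
  n <- length(regions)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  s0 <- GenomicRanges::start(regions) - 1
  e0 <- GenomicRanges::end(regions)
  sizes <- tracks[[1]]$chrom_sizes
  if (!all(chrom %in% names(sizes))) stop("region chromosome not in tracks")
  if (mode == "reference_point") {
    center <- if (!is.null(anchors)) {
      stopifnot(length(anchors) == n)
      anchors - 1
    } else floor((s0 + e0) / 2)
    if (any(center < 0 | center > sizes[chrom])) {
      stop("region center outside genome")
    }
    lo <- center - window_bp / 2
    bounds <- outer(rep(1, n), (0:nbin) * bin_bp) + lo  # n x (nbin+1)
  } else {
    w <- e0 - s0
    bounds <- outer(w, (0:nbin) / nbin) + s0
  }
  values <- matrix(0.0, nrow = n, ncol = nbin * length(tracks))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    for (cn in unique(chrom)) {
      idx <- which(chrom == cn)
      S <- .track_prefix(tr, cn)
      b <- bounds[idx, , drop = FALSE]
      sums <- S(b[, -1, drop = FALSE]) - S(b[, -(nbin + 1), drop = FALSE])
      widths <- b[, -1, drop = FALSE] - b[, -(nbin + 1), drop = FALSE]
      values[idx, (j - 1) * nbin + seq_len(nbin)] <- sums / widths
    }
  }
  colnames(values) <- paste(rep(names(tracks), each = nbin),
                            rep(seq_len(nbin), length(tracks)), sep = "|")
  structure(list(regions = regions, samples = names(tracks),
                 n_bins_per_sample = nbin, values = values, mode = mode,
                 window_bp = as.integer(window_bp),
                 bin_bp = as.integer(bin_bp)),
            class = "region_signal_matrix")
}

#' @export
print.region_signal_matrix <- function(x, ...) {
  cat(sprintf("region_signal_matrix: %d regions x %d samples x %d bins (%s)\n",
              nrow(x$values), length(x$samples), x$n_bins_per_sample, x$mode))
  invisible(x)
}

#' Write a region signal matrix as TSV with a header block
#'
#' The header (`#key value` lines) records mode, window, bin and sample
#' order so the matrix can be reproduced bit-exactly.
#'
#' @param mat a `region_signal_matrix`.
#' @param path output path.
#' @export
write_signal_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#mode\t", mat$mode),
               paste0("#window_bp\t", mat$window_bp),
               paste0("#bin_bp\t", mat$bin_bp),
               paste0("#samples\t", paste(mat$samples, collapse = ","))), con)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(mat$regions)),
                   start = GenomicRanges::start(mat$regions) - 1L,
                   end = GenomicRanges::end(mat$regions),
                   format(mat$values, digits = 10, trim = TRUE))
  names(df)[-(1:3)] <- colnames(mat$values)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Pairwise Pearson correlation of samples on coarse bins
#'
#' Tracks are re-binned to `bin_size` (signal summed within each coarse bin,
#' mirroring read counting in fixed windows) and all pairs correlated.
#' Zero-variance tracks yield `NA` against every other track; the diagonal
#' stays 1.
#'
#' @param tracks named list of [binned_track]s on the same genome/binning.
#' @param bin_size coarse bin width in bp (default 10 kb).
#' @return symmetric correlation matrix with sample names.
#' @export
correlate_samples <- function(tracks, bin_size = 10000) {
  stopifnot(length(tracks) >= 2)
  for (t in tracks[-1]) .check_same_binning(tracks[[1]], t)
  rebin <- function(track) {
    unlist(lapply(names(track$values), function(cn) {
      v <- track$values[[cn]]
      bs <- track$bin_size
      len <- track$chrom_sizes[[cn]]
      binw <- pmin(bs, len - (seq_along(v) - 1) * bs)
      grp <- floor((seq_along(v) - 1) * bs / bin_size)
      as.numeric(tapply(v * binw, grp, sum))
    }), use.names = FALSE)
  }
  m <- vapply(tracks, rebin, rebin(tracks[[1]]))
  sds <- apply(m, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(m, method = "pearson"))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- 1
  dimnames(cm) <- list(names(tracks), names(tracks))
  cm
}
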