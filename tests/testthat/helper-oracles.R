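# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and GenomicRanges where feasible): bitmaps per base, plain
# loops, closed-form statistics.

# ---- interval oracles (bitmap on a toy chromosome) ----

# df: data.frame(chrom, start, end) 1-based closed
bitmap_union <- function(df, chrom_len = 10000, min_gap = 0) {
  out <- list()
  for (cn in sort(unique(df$chrom))) {
    bm <- logical(chrom_len)
    sub <- df[df$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(sub))) bm[sub$start[i]:sub$end[i]] <- TRUE
    if (min_gap > 0) {
      # close gaps of size <= min_gap between covered runs
      r <- rle(bm)
      covered_seen <- cumsum(r$values) > 0
      fill <- !r$values & r$lengths <= min_gap & covered_seen &
        rev(cumsum(rev(r$values)) > 0)
      r$values[fill] <- TRUE
      bm <- inverse.rle(r)
    } else {
      # book-ended intervals are already contiguous in the bitmap
    }
    r <- rle(bm)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (any(keep)) {
      out[[cn]] <- data.frame(chrom = cn, start = starts[keep],
                              end = ends[keep])
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

bitmap_overlap_fraction <- function(t_start, t_end, others, chrom_len = 10000) {
  bm <- logical(chrom_len)
  for (i in seq_len(nrow(others))) bm[others$start[i]:others$end[i]] <- TRUE
  mean(bm[t_start:t_end])
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

random_intervals <- function(n, chrom_len = 10000, chroms = "chrT",
                             max_width = 300) {
  chrom <- sample(chroms, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  start <- vapply(w, function(wi) sample.int(chrom_len - wi, 1), 0L)
  data.frame(chrom = chrom, start = start, end = start + w - 1L)
}

# ---- naive Ward agglomeration (O(n^3)) ----

# Merge cost sqrt(2 * nu*nv/(nu+nv)) * ||centroid_u - centroid_v||, computed
# from raw cluster members at every step; ties by smallest pair index.
naive_ward <- function(x) {
  n <- nrow(x)
  members <- lapply(seq_len(n), identity)
  labels <- seq_len(n)
  heights <- numeric(n - 1)
  partitions <- list()
  partitions[[n]] <- labels
  for (step in seq_len(n - 1)) {
    ids <- sort(unique(labels))
    best <- NULL; best_cost <- Inf
    for (ai in seq_along(ids)) {
      for (bi in seq_along(ids)) {
        if (bi <= ai) next
        u <- ids[ai]; v <- ids[bi]
        mu <- colMeans(x[labels == u, , drop = FALSE])
        mv <- colMeans(x[labels == v, , drop = FALSE])
        nu <- sum(labels == u); nv <- sum(labels == v)
        cost <- sqrt(2 * nu * nv / (nu + nv)) * sqrt(sum((mu - mv)^2))
        if (cost < best_cost - 1e-12) {
          best_cost <- cost; best <- c(u, v)
        }
      }
    }
    labels[labels == best[2]] <- best[1]
    heights[step] <- best_cost
    partitions[[n - step]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

canon <- function(labels) match(labels, unique(labels))

# ---- closed-form statistics ----

welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                 vb^2 / (length(b)^2 * (length(b) - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, p_value = p, df = df)
}

chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# ---- independent target-classification oracle ----

# Evaluates the classification rules gene by gene with plain arithmetic.
# genes_df: gene_id, chrom, start, end, strand; exons: list gene_id ->
# matrix(start, end); enh_df: chrom, start, end, assigned_gene;
# peaks: list factor -> data.frame(chrom, start, end).
oracle_classify <- function(genes_df, exons, enh_df, peaks, chrom_sizes,
                            flank = 1000, basal_up = 5000, basal_down = 1000,
                            max_ext = 1e6) {
  ng <- nrow(genes_df)
  tss <- ifelse(genes_df$strand == "+", genes_df$start, genes_df$end)
  win_s <- pmax(1, tss - flank)
  win_e <- pmin(chrom_sizes[genes_df$chrom], tss + flank - 1)
  ov <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
  # basal domains
  bs <- pmax(1, ifelse(genes_df$strand == "+", tss - basal_up,
                       tss - basal_down + 1))
  be <- pmin(chrom_sizes[genes_df$chrom],
             ifelse(genes_df$strand == "+", tss + basal_down - 1,
                    tss + basal_up))
  ext_s <- numeric(ng); ext_e <- numeric(ng)
  for (i in seq_len(ng)) {
    same <- which(genes_df$chrom == genes_df$chrom[i])
    others <- setdiff(same, i)
    lim_l <- bs[i] - max_ext
    lim_r <- be[i] + max_ext
    for (j in others) {
      if (bs[j] <= bs[i]) lim_l <- max(lim_l, min(be[j], bs[i] - 1) + 1)
      if (be[j] >= be[i]) lim_r <- min(lim_r, max(bs[j], be[i] + 1) - 1)
    }
    ext_s[i] <- min(bs[i], max(1, lim_l))
    ext_e[i] <- max(be[i], min(chrom_sizes[[genes_df$chrom[i]]], lim_r))
  }
  introns_of <- function(i) {
    ex <- exons[[genes_df$gene_id[i]]]
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (nrow(ex) < 2) return(matrix(numeric(0), ncol = 2))
    cbind(ex[-nrow(ex), 2] + 1, ex[-1, 1] - 1)
  }
  factors <- names(peaks)
  # distal = peak overlapping no TSS window of any gene
  distal <- lapply(peaks, function(pk) {
    if (!nrow(pk)) return(pk)
    keep <- vapply(seq_len(nrow(pk)), function(p) {
      !any(genes_df$chrom == pk$chrom[p] &
           ov(pk$start[p], pk$end[p], win_s, win_e) &
           genes_df$chrom == pk$chrom[p])
    }, TRUE)
    # note: window rows on other chroms never satisfy chrom equality
    pk[keep, , drop = FALSE]
  })
  res <- list()
  tssb <- matrix(FALSE, ng, length(factors), dimnames = list(NULL, factors))
  distb <- tssb; bodyb <- tssb
  for (f in factors) {
    pk <- peaks[[f]]; dk <- distal[[f]]
    for (i in seq_len(ng)) {
      onchr <- pk[pk$chrom == genes_df$chrom[i], , drop = FALSE]
      tssb[i, f] <- any(ov(onchr$start, onchr$end, win_s[i], win_e[i]))
      bodyb[i, f] <- any(ov(onchr$start, onchr$end, genes_df$start[i],
                            genes_df$end[i]))
      dchr <- dk[dk$chrom == genes_df$chrom[i], , drop = FALSE]
      hit <- FALSE
      if (nrow(dchr)) {
        eg <- enh_df[!is.na(enh_df$assigned_gene) &
                     enh_df$assigned_gene == genes_df$gene_id[i] &
                     enh_df$chrom == genes_df$chrom[i], , drop = FALSE]
        for (p in seq_len(nrow(dchr))) {
          if (nrow(eg) && any(ov(dchr$start[p], dchr$end[p], eg$start, eg$end)))
            hit <- TRUE
          if (ov(dchr$start[p], dchr$end[p], ext_s[i], ext_e[i])) hit <- TRUE
          intr <- introns_of(i)
          if (nrow(intr) && any(ov(dchr$start[p], dchr$end[p],
                                   intr[, 1], intr[, 2]))) hit <- TRUE
        }
      }
      distb[i, f] <- hit
    }
  }
  any_ev <- rowSums(tssb | distb | bodyb) > 0
  status <- matrix("non_target", ng, length(factors),
                   dimnames = list(genes_df$gene_id, factors))
  status[any_ev, ] <- "bound_unclassified"
  status[distb & !tssb] <- "tss_distal_target"
  status[tssb] <- "tss_target"
  status
}
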