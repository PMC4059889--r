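# Fixture builders shared across test files; everything generated in code.

# n non-overlapping random genes with 1-4 exons on one chromosome
random_gene_set <- function(n, chrom_len = 200000, chrom = "chrT",
                            min_len = 1000, max_len = 8000) {
  slot <- floor(chrom_len / n)
  rows <- list(); exons <- list()
  for (i in seq_len(n)) {
    glen <- sample(min_len:max_len, 1)
    glen <- min(glen, slot - 2000)
    start <- (i - 1) * slot + sample.int(max(1, slot - glen - 1500), 1) + 700
    end <- start + glen - 1
    strand <- sample(c("+", "-"), 1)
    id <- sprintf("t%03d", i)
    n_ex <- sample(1:4, 1)
    if (n_ex == 1 || glen < 6 * n_ex * 50) {
      ex <- cbind(start, end)
    } else {
      cuts <- sort(sample(seq(start + 100, end - 100, by = 25), 2 * (n_ex - 1)))
      while (any(diff(cuts) < 30)) {
        cuts <- sort(sample(seq(start + 100, end - 100, by = 25),
                            2 * (n_ex - 1)))
      }
      ex <- cbind(c(start, cuts[seq(2, length(cuts), 2)] + 1),
                  c(cuts[seq(1, length(cuts), 2)], end))
    }
    rows[[i]] <- data.frame(gene_id = id, chrom = chrom, start = start,
                            end = end, strand = strand)
    exons[[id]] <- ex
  }
  genes_df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(genes_df$chrom,
                               IRanges::IRanges(genes_df$start, genes_df$end),
                               strand = genes_df$strand)
  gr$gene_id <- genes_df$gene_id
  exl <- GenomicRanges::GRangesList(lapply(genes_df$gene_id, function(id) {
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(exons[[id]][, 1], exons[[id]][, 2]),
                           strand = genes_df$strand[genes_df$gene_id == id])
  }))
  names(exl) <- genes_df$gene_id
  list(gm = gene_models(gr, exl), df = genes_df, exons = exons,
       chrom_sizes = stats::setNames(chrom_len, chrom))
}

# small binned track from an explicit vector of bin values
toy_track <- function(values, bin_size = 10, chrom = "chrT",
                      sample_id = "toy", is_ratio = FALSE,
                      chrom_len = length(values) * bin_size) {
  binned_track(stats::setNames(list(values), chrom), bin_size,
               stats::setNames(chrom_len, chrom), sample_id,
               is_ratio = is_ratio)
}

# random narrowPeak-style GRanges
random_peaks <- function(n, chrom_len = 10000, chrom = "chrT",
                         sample_id = "S", max_width = 400) {
  df <- random_intervals(n, chrom_len, chrom, max_width)
  gr <- df_to_gr(df)
  gr$name <- paste0(sample_id, "_", seq_len(n))
  gr$summit <- as.integer(floor((df$start + df$end) / 2))
  gr$score_neg10log10p <- runif(n, 20, 300)
  gr$fdr_percent <- runif(n, 0, 5)
  gr$sample_id <- sample_id
  gr
}

tiny_sim_config <- function(seed = 11, n_regions = 15) {
  simulation_config(seed = seed, n_chromosomes = 2, chrom_length_bp = 2e6,
                    n_genes = 60,
                    cluster_spec = default_cluster_spec(n_regions = n_regions))
}
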