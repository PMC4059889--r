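# Synthetic-data generator: determinism, planted structure, truth/file
# consistency.

test_that("generator stages are deterministic under a fixed seed", {
  cfg <- tiny_sim_config(seed = 21)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(gr_to_df(a$truth$regions), gr_to_df(b$truth$regions))
  expect_identical(a$truth$presence, b$truth$presence)
  expect_identical(a$tracks$chip$MOF_ESC$values, b$tracks$chip$MOF_ESC$values)
  expect_identical(gr_to_df(a$peaks$MOF_ESC$rep1), gr_to_df(b$peaks$MOF_ESC$rep1))
  expect_identical(a$expression$de$MOF, b$expression$de$MOF)
  # different seed -> different draws
  c2 <- simulate_dataset(tiny_sim_config(seed = 22))
  expect_false(identical(gr_to_df(a$truth$regions), gr_to_df(c2$truth$regions)))
})

test_that("generated annotation satisfies its invariants", {
  cfg <- tiny_sim_config(seed = 23)
  ann <- generate_annotation(cfg)
  g <- ann$genes$genes
  expect_equal(length(g), cfg$n_genes)
  expect_false(anyDuplicated(g$gene_id) > 0)
  # genes non-overlapping and inside the genome
  expect_true(GenomicRanges::isDisjoint(g, ignore.strand = TRUE))
  expect_true(all(GenomicRanges::end(g) <=
                  ann$chrom_sizes[as.character(GenomicRanges::seqnames(g))]))
  # introns always inside the gene body and exactly the exon gaps
  for (id in sample(g$gene_id, 20)) {
    body <- g[g$gene_id == id]
    ex <- ann$genes$exons[[id]]
    intr <- ann$genes$introns[[id]]
    expect_equal(sum(GenomicRanges::width(ex)) + sum(GenomicRanges::width(intr)),
                 GenomicRanges::width(body))
  }
  # enhancers assigned to existing genes, clear of gene bodies
  for (e in list(ann$typical_enhancers, ann$super_enhancers)) {
    expect_true(all(e$assigned_gene %in% g$gene_id))
    expect_false(any(IRanges::overlapsAny(e, g, ignore.strand = TRUE)))
  }
})

test_that("planted regions respect compartments and non-overlap", {
  cfg <- tiny_sim_config(seed = 24)
  ann <- generate_annotation(cfg)
  truth <- plant_cooccupancy(cfg, ann)
  expect_equal(length(truth$regions), 5 * 15)
  expect_true(GenomicRanges::isDisjoint(truth$regions))
  # promoter-biased patterns overlap their anchor gene's promoter window
  win <- tss_windows(ann$genes, 1000, ann$chrom_sizes)
  for (pat in c("A", "B")) {
    sel <- truth$regions[truth$regions$pattern == pat]
    frac <- mean(IRanges::overlapsAny(sel, win))
    expect_gte(frac, 0.8)
  }
  # intergenic patterns stay clear of genes
  selC <- truth$regions[truth$regions$pattern %in% c("C", "D")]
  expect_false(any(IRanges::overlapsAny(selC, ann$genes$genes,
                                        ignore.strand = TRUE)))
  # presence matches the pattern spec
  for (i in seq_along(cfg$cluster_spec)) {
    pat <- cfg$cluster_spec[[i]]
    rows <- which(truth$regions$pattern == pat$name)
    expect_true(all(truth$presence[rows, pat$present]))
    expect_false(any(truth$presence[rows,
                                    setdiff(cfg$samples, pat$present)]))
  }
})

test_that("with zero jitter, zero failures and no false peaks, consensus
           equals the planted regions exactly", {
  cfg <- simulation_config(seed = 25, n_chromosomes = 2,
                           chrom_length_bp = 2e6, n_genes = 60,
                           cluster_spec = default_cluster_spec(n_regions = 12),
                           peak_jitter_bp = 0, false_peak_rate = 0,
                           peak_fail_rate = 0)
  ann <- generate_annotation(cfg)
  truth <- plant_cooccupancy(cfg, ann)
  pks <- simulate_peak_calls(truth, cfg, ann$chrom_sizes)
  for (s in cfg$samples) {
    cons <- filter_peaks(replicate_consensus(pks[[s]]$merged, pks[[s]]$rep1,
                                             pks[[s]]$rep2))
    planted <- truth$regions[truth$presence[, s]]
    sort_df <- function(d) {
      d <- d[order(d$chrom, d$start), c("chrom", "start", "end")]
      rownames(d) <- NULL
      d
    }
    expect_equal(sort_df(gr_to_df(cons)), sort_df(gr_to_df(planted)))
  }
})

test_that("false peaks alone are eliminated by replicate consensus", {
  cfg <- simulation_config(seed = 26, n_chromosomes = 1,
                           chrom_length_bp = 2e6, n_genes = 30,
                           cluster_spec = list(list(
                             name = "Z", present = c("X_ESC"), n_regions = 10,
                             width_mean = 800, width_sd = 100,
                             compartment = "intergenic", amplitude = 2)),
                           false_peak_rate = 1, peak_fail_rate = 0,
                           peak_jitter_bp = 0)
  ann <- generate_annotation(cfg)
  truth <- plant_cooccupancy(cfg, ann)
  pks <- simulate_peak_calls(truth, cfg, ann$chrom_sizes)$X_ESC
  expect_gt(length(pks$merged), 10)  # false peaks present in merged calls
  cons <- replicate_consensus(pks$merged, pks$rep1, pks$rep2)
  expect_true(all(cons$planted))
})

test_that("simulated tracks have input-shaped background at the depth factor", {
  cfg <- tiny_sim_config(seed = 27)
  ann <- generate_annotation(cfg)
  truth <- plant_cooccupancy(cfg, ann)
  trk <- simulate_tracks(truth, ann, cfg)
  s <- "MSL1_ESC"
  depth <- cfg$depth_factors[[s]]
  bg <- trk$background_bins[[s]]$chr1
  chip <- trk$chip[[s]]$values$chr1[bg]
  input <- trk$input$ESC$values$chr1[bg]
  pos <- input > 0
  expect_equal(chip[pos] / input[pos], rep(depth, sum(pos)), tolerance = 1e-12)
  # enrichment raises the planted regions above background
  m <- extract_matrix(truth$regions[truth$presence[, s]],
                      trk$chip[s], window_bp = 2000, bin_bp = 50)
  center_mean <- mean(m$values[, 18:22])
  edge_mean <- mean(m$values[, c(1:3, 38:40)])
  expect_gt(center_mean, 2 * edge_mean)
})

test_that("null knockdown tables carry an exact uniform padj among nulls", {
  cfg <- tiny_sim_config(seed = 28)
  ann <- generate_annotation(cfg)
  truth <- plant_cooccupancy(cfg, ann)
  kd <- simulate_expression_and_kd(truth, ann, cfg)
  de <- kd$de$MOF
  tr <- kd$de_truth$MOF
  nulls <- de$padj[!tr$planted_down]
  expect_true(all(nulls >= 0 & nulls <= 1))
  expect_true(all(de$padj[tr$planted_down] <= 0.001))
  expect_true(all(de$log2_fold_change[tr$planted_down] < 0 |
                  abs(de$log2_fold_change[tr$planted_down]) < 2))
  # planted targets all carry FPKM records
  expect_setequal(kd$expression$gene_id, ann$genes$genes$gene_id)
})

test_that("dataset files round-trip and truth serializes", {
  cfg <- simulation_config(seed = 29, n_chromosomes = 1,
                           chrom_length_bp = 5e5, n_genes = 20,
                           cluster_spec = default_cluster_spec(n_regions = 4),
                           bin_bp = 500)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir, bin_bp = 500)
  expect_equal(gr_to_df(back$annotation$genes$genes),
               gr_to_df(ds$annotation$genes$genes))
  expect_setequal(names(back$peaks), names(ds$peaks))
  expect_equal(gr_to_df(back$peaks$MOF_ESC$merged),
               gr_to_df(ds$peaks$MOF_ESC$merged))
  expect_equal(back$tracks$chip$MOF_ESC$values$chr1,
               ds$tracks$chip$MOF_ESC$values$chr1, tolerance = 1e-6)
  expect_equal(back$expression$expression$mean_fpkm,
               ds$expression$expression$mean_fpkm, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$regions$cluster, ds$truth$regions$cluster)
})
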