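# Promoter binding, compartments, regulatory domains, CpG counting, and the
# full target-classification rules.

test_that("tss_binding respects the symmetric window", {
  g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, 9000),
                              strand = "+")
  g$gene_id <- "g1"; g$tss <- 5000
  # peak at tss+400 with flank 500 -> bound
  pk <- df_to_gr(data.frame(chrom = "chrT", start = 5400, end = 5420))
  expect_equal(tss_binding(g, pk, 500), "g1")
  # peak at tss+1500 with flank 1000 -> not bound
  pk2 <- df_to_gr(data.frame(chrom = "chrT", start = 6500, end = 6520))
  expect_length(tss_binding(g, pk2, 1000), 0)
  # matches pairwise-overlap oracle on random fixtures
  withr::local_seed(441)
  for (rep in 1:20) {
    gs <- random_gene_set(15, chrom_len = 300000)
    pks <- df_to_gr(random_intervals(40, chrom_len = 300000, max_width = 600))
    got <- tss_binding(gs$gm, pks, 500, gs$chrom_sizes)
    tss <- gs$gm$genes$tss
    ws <- pmax(1, tss - 500); we <- pmin(300000, tss + 499)
    want <- gs$gm$genes$gene_id[vapply(seq_along(tss), function(i) {
      any(GenomicRanges::start(pks) <= we[i] &
          GenomicRanges::end(pks) >= ws[i])
    }, TRUE)]
    expect_setequal(got, want)
  }
})

test_that("assign_compartment applies upstream > body > intergenic precedence", {
  g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, 9000),
                              strand = "+")
  g$gene_id <- "g1"; g$tss <- 5000
  # overlaps both the upstream kb and the gene body -> upstream wins
  both <- df_to_gr(data.frame(chrom = "chrT", start = 4500, end = 5500))
  expect_equal(assign_compartment(both, g), "upstream_1kb")
  inside <- df_to_gr(data.frame(chrom = "chrT", start = 6000, end = 6100))
  expect_equal(assign_compartment(inside, g), "gene_body")
  desert <- df_to_gr(data.frame(chrom = "chrT", start = 50000, end = 50100))
  expect_equal(assign_compartment(desert, g), "intergenic")
  # '-' strand gene: upstream is on the right of the TSS
  gm <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, 9000),
                               strand = "-")
  gm$gene_id <- "g2"; gm$tss <- 9000
  right <- df_to_gr(data.frame(chrom = "chrT", start = 9500, end = 9600))
  expect_equal(assign_compartment(right, gm), "upstream_1kb")
})

test_that("regulatory domains: single gene, neighbor truncation, end clipping", {
  sizes <- c(chrT = 5e6)
  lone <- GenomicRanges::GRanges("chrT", IRanges::IRanges(2e6, 2e6 + 1e4),
                                 strand = "+")
  lone$gene_id <- "solo"; lone$tss <- 2e6
  d <- build_regulatory_domains(lone, chrom_sizes = sizes)
  expect_equal(GenomicRanges::start(d), 2e6 - 5000 - 1e6)
  expect_equal(GenomicRanges::end(d), 2e6 + 999 + 1e6)

  # two '+' genes 20 kb apart: right gene's upstream extension stops at the
  # left gene's basal edge
  two <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(1e6, 1e6 + 2e4),
                                                         c(1e6 + 5e3, 1e6 + 2.5e4)),
                                strand = "+")
  two$gene_id <- c("left", "right"); two$tss <- c(1e6, 1e6 + 2e4)
  d2 <- build_regulatory_domains(two, chrom_sizes = sizes)
  left_basal_end <- 1e6 + 999
  expect_equal(GenomicRanges::start(d2)[2], left_basal_end + 1)
  # left gene's downstream extension stops at right gene's basal start
  right_basal_start <- 1e6 + 2e4 - 5000
  expect_equal(GenomicRanges::end(d2)[1], right_basal_start - 1)

  # gene at the chromosome start: clipped at 1
  first <- GenomicRanges::GRanges("chrT", IRanges::IRanges(10, 4000),
                                  strand = "+")
  first$gene_id <- "first"; first$tss <- 10
  d3 <- build_regulatory_domains(first, chrom_sizes = sizes)
  expect_equal(GenomicRanges::start(d3), 1)
})

test_that("domains of nearby genes tile without gaps", {
  withr::local_seed(442)
  gs <- random_gene_set(20, chrom_len = 500000)
  d <- build_regulatory_domains(gs$gm, chrom_sizes = gs$chrom_sizes)
  cov <- merge_intervals(d)
  # genes are < 2 Mb apart, so one contiguous covered block
  expect_length(cov, 1)
})

test_that("cpg_overlap counts islands in the half-open promoter window", {
  g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, 9000),
                              strand = "+")
  g$gene_id <- "g1"; g$tss <- 5000
  spanning <- df_to_gr(data.frame(chrom = "chrT", start = 4900, end = 5100))
  expect_equal(unname(cpg_overlap(g, spanning, 500)), 1L)
  # island ending just before the window ([.., tss-flank) on disk) -> 0
  before <- df_to_gr(data.frame(chrom = "chrT", start = 4300, end = 4499))
  expect_equal(unname(cpg_overlap(g, before, 500)), 0L)
  two <- df_to_gr(data.frame(chrom = "chrT", start = c(4600, 5200),
                             end = c(4700, 5300)))
  expect_equal(unname(cpg_overlap(g, two, 500)), 2L)
})

mk_tc_fixture <- function(n_genes = 40, chrom_len = 400000, n_enh = 8) {
  gs <- random_gene_set(n_genes, chrom_len = chrom_len)
  enh <- random_intervals(n_enh, chrom_len = chrom_len, max_width = 900)
  enh_gr <- df_to_gr(enh)
  enh_gr$assigned_gene <- sample(gs$df$gene_id, n_enh, replace = TRUE)
  ann <- annotation_bundle(gs$gm, GenomicRanges::GRanges(), enh_gr,
                           GenomicRanges::GRanges(), gs$chrom_sizes)
  list(gs = gs, ann = ann, enh = cbind(enh, assigned_gene = enh_gr$assigned_gene))
}

test_that("classify_targets implements the promoter/distal/non-target rules", {
  withr::local_seed(443)
  fx <- mk_tc_fixture()
  g <- fx$gs$gm$genes
  tss <- g$tss
  # factor A: peak at tss+800 of gene 1 -> tss_target
  pkA <- df_to_gr(data.frame(chrom = "chrT", start = tss[1] + 780,
                             end = tss[1] + 820))
  # factor B: peak only in an intron of a multi-exon gene -> distal target
  multi <- which(vapply(fx$gs$gm$introns, length, 0L) > 0)
  mg <- multi[which.min(abs(tss[multi] - 200000))]
  intr <- fx$gs$gm$introns[[mg]][1]
  # keep the intronic peak clear of every promoter window
  pkB_start <- GenomicRanges::start(intr)
  pkB <- df_to_gr(data.frame(chrom = "chrT", start = pkB_start,
                             end = min(GenomicRanges::end(intr),
                                       pkB_start + 50)))
  res <- classify_targets(fx$gs$gm, list(A = pkA, B = pkB), fx$ann)
  resA <- res[res$factor == "A", ]
  expect_equal(resA$status[resA$gene_id == g$gene_id[1]], "tss_target")
  resB <- res[res$factor == "B", ]
  gene_b <- g$gene_id[mg]
  if (!IRanges::overlapsAny(pkB, tss_windows(fx$gs$gm, 1000,
                                             fx$ann$chrom_sizes))) {
    expect_equal(resB$status[resB$gene_id == gene_b], "tss_distal_target")
    expect_match(resB$evidence[resB$gene_id == gene_b], "intron_overlap")
  }
  # genes with no evidence from any factor are non-targets
  far <- setdiff(g$gene_id, c(g$gene_id[1], gene_b))
  untouched <- res[res$gene_id %in% far & res$status == "non_target", ]
  expect_true(all(untouched$evidence == ""))
})

test_that("complex co-occupancy flags need both subunits at the same gene", {
  withr::local_seed(444)
  gs <- random_gene_set(10, chrom_len = 200000)
  ann <- annotation_bundle(gs$gm, GenomicRanges::GRanges(),
                           GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                           gs$chrom_sizes)
  tss <- gs$gm$genes$tss
  at_tss <- function(i) df_to_gr(data.frame(chrom = "chrT",
                                            start = tss[i] - 100,
                                            end = tss[i] + 100))
  res <- classify_targets(gs$gm,
                          list(MOF = at_tss(1), MSL2 = at_tss(1),
                               KANSL3 = at_tss(2)),
                          ann)
  one <- res[res$gene_id == gs$gm$genes$gene_id[1] & res$factor == "MOF", ]
  expect_true(one$msl_target)   # MOF + MSL2 at the same TSS window
  expect_false(one$nsl_target)  # KANSL3 sits at a different gene
  two <- res[res$gene_id == gs$gm$genes$gene_id[2] & res$factor == "MOF", ]
  expect_false(two$msl_target)
  expect_false(two$nsl_target)  # MOF absent from gene 2
})

test_that("classification equals the independent rule-evaluation oracle and
           is monotone under peak shrinkage", {
  withr::local_seed(445)
  for (rep in 1:8) {
    fx <- mk_tc_fixture(n_genes = 25)
    peaks <- list(
      MOF = random_intervals(15, chrom_len = 400000, max_width = 800),
      MSL2 = random_intervals(10, chrom_len = 400000, max_width = 800),
      KANSL3 = random_intervals(8, chrom_len = 400000, max_width = 800))
    res <- classify_targets(fx$gs$gm,
                            lapply(peaks, df_to_gr), fx$ann)
    want <- oracle_classify(fx$gs$df, fx$gs$exons, fx$enh, peaks,
                            fx$ann$chrom_sizes)
    for (f in names(peaks)) {
      sub <- res[res$factor == f, ]
      expect_equal(setNames(sub$status, sub$gene_id),
                   want[, f][sub$gene_id])
    }
    # monotonicity: dropping peaks never turns a non-target into a target
    fewer <- lapply(peaks, function(p) df_to_gr(p[seq_len(nrow(p) %/% 2), ,
                                                  drop = FALSE]))
    res2 <- classify_targets(fx$gs$gm, fewer, fx$ann)
    was_non <- res$gene_id[res$status == "non_target"]
    now <- res2[res2$gene_id %in% was_non, ]
    expect_false(any(now$status %in% c("tss_target", "tss_distal_target")))
  }
})

test_that("de_genes restriction and enhancer validation are enforced", {
  withr::local_seed(446)
  fx <- mk_tc_fixture(n_genes = 12)
  pk <- df_to_gr(random_intervals(5, chrom_len = 400000))
  keep <- fx$gs$df$gene_id[1:4]
  res <- classify_targets(fx$gs$gm, list(MOF = pk), fx$ann, de_genes = keep)
  expect_setequal(unique(res$gene_id), keep)
  bad_enh <- fx$ann
  bad_enh$typical_enhancers$assigned_gene[1] <- "nonexistent"
  expect_error(classify_targets(fx$gs$gm, list(MOF = pk), bad_enh),
               "missing from gene list")
})
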