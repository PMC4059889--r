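# Binned tracks, bedGraph IO, SES scaling, input normalization, matrix
# extraction, sample correlation.

test_that("read_bedgraph bins by coverage-weighted mean with zero gaps", {
  sizes <- c(chrT = 1000)
  tf <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chrT\t0\t1000\t3", tf)
  tr <- read_bedgraph(tf, 100, sizes)
  expect_equal(tr$values$chrT, rep(3, 10))

  writeLines(character(0), tf)
  expect_equal(read_bedgraph(tf, 100, sizes)$values$chrT, rep(0, 10))

  # piecewise track straddling a bin boundary: [0,150) = 4, [150,250) = 8
  writeLines(c("chrT\t0\t150\t4", "chrT\t150\t250\t8"), tf)
  tr <- read_bedgraph(tf, 100, sizes)
  per_base <- c(rep(4, 150), rep(8, 100), rep(0, 750))
  want <- vapply(1:10, function(b) mean(per_base[((b - 1) * 100 + 1):(b * 100)]), 0)
  expect_equal(tr$values$chrT, want)

  writeLines("chrT\t900\t1100\t1", tf)
  expect_error(read_bedgraph(tf, 100, sizes), "beyond chromosome end")
})

test_that("bedGraph round-trip preserves bin values", {
  withr::local_seed(421)
  v <- round(rnbinom(200, mu = 10, size = 5))
  tr <- toy_track(v, bin_size = 50)
  tf <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, tf)
  back <- read_bedgraph(tf, 50, tr$chrom_sizes)
  expect_equal(back$values$chrT, as.numeric(v))
})

test_that("ses_scale_factor handles identity, pure scaling, and enrichment", {
  withr::local_seed(422)
  v <- rnbinom(5000, mu = 10, size = 5) + 1
  chip <- toy_track(v); input <- toy_track(v)
  expect_equal(ses_scale_factor(chip, input), 1, tolerance = 0.01)

  chip2 <- toy_track(2 * v)
  expect_equal(ses_scale_factor(chip2, input), 0.5, tolerance = 0.005)

  # enrichment in 5% of bins on top of a ratio-1 background
  enriched <- v
  hot <- sample(length(v), length(v) * 0.05)
  enriched[hot] <- enriched[hot] * 8
  f <- ses_scale_factor(toy_track(enriched), input)
  truth_bg_ratio <- sum(v[-hot]) / sum(v[-hot])   # 1 by construction
  expect_equal(f, truth_bg_ratio, tolerance = 0.05)
})

test_that("ses_scale_factor is scale-consistent and validates inputs", {
  withr::local_seed(423)
  v <- rnbinom(2000, mu = 8, size = 5)
  w <- rnbinom(2000, mu = 12, size = 5)
  chip <- toy_track(v + 1); input <- toy_track(w)
  f1 <- ses_scale_factor(chip, input)
  f3 <- ses_scale_factor(toy_track(3 * (v + 1)), input)
  expect_equal(f3, f1 / 3, tolerance = 1e-6)
  expect_error(ses_scale_factor(toy_track(rep(0, 2000)), input), "positive total")
  expect_error(ses_scale_factor(chip, toy_track(numeric(10), bin_size = 10)),
               "share bin size")
})

test_that("normalize_to_input computes the log2 ratio formula bin by bin", {
  withr::local_seed(424)
  v <- rnbinom(500, mu = 20, size = 5)
  tr <- toy_track(v)
  same <- normalize_to_input(tr, tr, factor = 1)
  expect_true(same$is_ratio)
  expect_equal(same$values$chrT, rep(0, 500))

  big <- toy_track(rep(3e6, 100)); base <- toy_track(rep(1e6, 100))
  expect_equal(normalize_to_input(big, base, factor = 1)$values$chrT,
               rep(log2(3), 100), tolerance = 1e-5)

  chip <- toy_track(rnbinom(500, mu = 15, size = 5))
  input <- toy_track(rnbinom(500, mu = 10, size = 5))
  f <- 1.7; pc <- 0.5
  got <- normalize_to_input(chip, input, factor = f, pseudocount = pc)
  expect_equal(got$values$chrT,
               log2((f * chip$values$chrT + pc) / (input$values$chrT + pc)))
  expect_error(normalize_to_input(chip, input, factor = 1, pseudocount = 0),
               "pseudocount")
})

test_that("normalize_to_input is antisymmetric in the large-signal limit", {
  withr::local_seed(425)
  v1 <- runif(200, 1e5, 1e6); v2 <- runif(200, 1e5, 1e6)
  a <- toy_track(v1); b <- toy_track(v2)
  ab <- normalize_to_input(a, b, factor = 1)$values$chrT
  ba <- normalize_to_input(b, a, factor = 1)$values$chrT
  expect_equal(ab, -ba, tolerance = 1e-4)
})

test_that("extract_matrix anchors windows and averages per-base signal", {
  # delta-like track: single hot bin at the region center
  v <- numeric(100); v[50] <- 100   # hot bases [491,500] at bin 50
  tr <- toy_track(v, bin_size = 10)
  region <- df_to_gr(data.frame(chrom = "chrT", start = 396, end = 595))
  m <- extract_matrix(region, list(S = tr), window_bp = 200, bin_bp = 10)
  expect_equal(dim(m$values), c(1, 20))
  expect_equal(unname(which.max(m$values[1, ])), 10)  # center bin of the window

  const <- toy_track(rep(7, 100), bin_size = 10)
  mc <- extract_matrix(region, list(S = const), window_bp = 100, bin_bp = 20)
  expect_equal(as.numeric(mc$values), rep(7, 5))

  outside <- df_to_gr(data.frame(chrom = "chrT", start = 1, end = 3000))
  expect_error(extract_matrix(outside, list(S = tr), window_bp = 100,
                              bin_bp = 10), "center outside genome")
})

test_that("extract_matrix equals a per-base averaging oracle in both modes", {
  withr::local_seed(426)
  for (rep in 1:10) {
    v <- rnbinom(120, mu = 10, size = 3)
    bs <- 25
    tr <- toy_track(v, bin_size = bs)
    clen <- length(v) * bs
    per_base <- rep(v, each = bs)
    regions <- GenomicRanges::shift(
      df_to_gr(random_intervals(5, chrom_len = clen - 600, max_width = 500)),
      300)
    m <- extract_matrix(regions, list(S = tr), window_bp = 200, bin_bp = 50)
    for (i in seq_along(regions)) {
      s0 <- GenomicRanges::start(regions)[i] - 1
      e0 <- GenomicRanges::end(regions)[i]
      mid <- floor((s0 + e0) / 2)
      for (b in 1:4) {
        lo <- mid - 100 + (b - 1) * 50
        want <- mean(per_base[pmax(1, lo + 1):min(clen, lo + 50)] *
                     as.numeric((lo + 1):(lo + 50) <= clen))
        expect_equal(unname(m$values[i, b]), want, tolerance = 1e-10)
      }
    }
    # scale_regions: oracle over fractional segments via cumulative sums
    msr <- extract_matrix(regions, list(S = tr), mode = "scale_regions",
                          window_bp = 100, bin_bp = 25)
    cum <- c(0, cumsum(per_base))
    Sx <- function(x) cum[floor(x) + 1] + (x - floor(x)) * per_base[floor(x) + 1]
    for (i in seq_along(regions)) {
      s0 <- GenomicRanges::start(regions)[i] - 1
      w <- GenomicRanges::end(regions)[i] - s0
      for (b in 1:4) {
        a <- s0 + (b - 1) / 4 * w; z <- s0 + b / 4 * w
        expect_equal(unname(msr$values[i, b]), (Sx(z) - Sx(a)) / (z - a),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("extract_matrix is translation-equivariant", {
  withr::local_seed(427)
  v <- rnbinom(200, mu = 10, size = 5)
  shift_bins <- 40
  tr <- toy_track(v, bin_size = 10)
  tr_shift <- toy_track(c(numeric(shift_bins), v[1:(200 - shift_bins)]),
                        bin_size = 10)
  regions <- df_to_gr(data.frame(chrom = "chrT", start = c(501, 901),
                                 end = c(700, 1100)))
  shifted <- GenomicRanges::shift(regions, shift_bins * 10)
  m1 <- extract_matrix(regions, list(S = tr), window_bp = 200, bin_bp = 20)
  m2 <- extract_matrix(shifted, list(S = tr_shift), window_bp = 200,
                       bin_bp = 20)
  expect_equal(m1$values, m2$values)
})

test_that("correlate_samples matches the closed-form Pearson oracle", {
  withr::local_seed(428)
  tracks <- lapply(1:4, function(i)
    toy_track(rnbinom(400, mu = 10 * i, size = 5), bin_size = 100,
              sample_id = paste0("s", i)))
  names(tracks) <- paste0("s", 1:4)
  cm <- correlate_samples(tracks, bin_size = 1000)
  expect_equal(diag(cm), setNames(rep(1, 4), paste0("s", 1:4)))
  expect_equal(cm, t(cm))
  rebin <- function(v) vapply(seq_len(40), function(b)
    sum(v[((b - 1) * 10 + 1):(b * 10)] * 100), 0)
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cm[i, j], pearson(rebin(tracks[[i]]$values$chrT),
                                   rebin(tracks[[j]]$values$chrT)),
                 tolerance = 1e-12)
  }
  # anti-correlated two-level pattern
  a <- toy_track(rep(c(0, 10), 100), bin_size = 100, sample_id = "a")
  b <- toy_track(rep(c(10, 0), 100), bin_size = 100, sample_id = "b")
  cm2 <- correlate_samples(list(a = a, b = b), bin_size = 100)
  expect_equal(cm2["a", "b"], -1)
  # zero-variance track flagged NA, diagonal kept
  z <- toy_track(rep(5, 200), bin_size = 100, sample_id = "z")
  cm3 <- correlate_samples(list(a = a, z = z), bin_size = 100)
  expect_true(is.na(cm3["a", "z"]))
  expect_equal(diag(cm3), c(a = 1, z = 1))
})
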