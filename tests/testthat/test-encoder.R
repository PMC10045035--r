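# Search regions, channel rules, stacking/rasterizing, candidate encoding.

rec <- function(svtype, pos, end = pos, svlen = end - pos, chrom = "chr1",
                id = "x") {
  list(chrom = chrom, pos = pos, end = end, svtype = svtype, svlen = svlen,
       id = id)
}

test_that("search regions follow the per-type formulas", {
  cfg <- encoderConfig(alpha = 10000)
  # deletions / duplications: [bpt_left - svl, bpt_right + svl]
  w <- computeSearchRegion(rec("DEL", 1000, 1100), cfg)
  expect_equal(c(w$start, w$end), c(900, 1200))
  # insertions: [pos - svl, pos + 2 svl]
  w <- computeSearchRegion(rec("INS", 5000, 5000, svlen = 100), cfg)
  expect_equal(c(w$start, w$end), c(4900, 5200))
  # short inversion uses the spanning window
  w <- computeSearchRegion(rec("INV", 20000, 25000), cfg)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(15000, 30000))
  # long inversion splits into two breakpoint windows
  w <- computeSearchRegion(rec("INV", 100000, 150000), cfg)
  expect_equal(nrow(w), 2L)
  expect_equal(w$start, c(90000, 155000))
  expect_equal(w$end, c(105000, 160000))
  # windows clip to contig bounds
  w <- computeSearchRegion(rec("DEL", 30, 130), cfg, contig_length = 200)
  expect_equal(c(w$start, w$end), c(0, 200))
  expect_error(computeSearchRegion(rec("TRA", 1, 2), cfg), "unsupported")
})

test_that("channel assignment matches the printed rules on worked examples", {
  cfg <- encoderConfig()
  r <- rec("DEL", 1000, 1100)
  region <- computeSearchRegion(r, cfg)
  fr <- data.frame(read_id = "a", chrom = "chr1", start = 1005, end = 1095,
                   sig_type = "DEL", source = "cigar",
                   orientation_discordant = FALSE)
  ch <- assignChannels(fr, region, r)
  expect_equal(c(ch$R, ch$G, ch$B), c(255, 255, 255))
  # fragment of exactly twice the SV length: R stays 0 (strict inequality)
  fr2 <- transform(fr, end = start + 200)
  ch2 <- assignChannels(fr2, region, r)
  expect_equal(ch2$R, 0L)
  # fragment sticking out of the window: B stays 0
  fr3 <- transform(fr, start = 850)
  expect_equal(assignChannels(fr3, region, r)$B, 0L)
  # midpoint outside the breakpoints: G stays 0
  fr4 <- transform(fr, start = 1090, end = 1180)
  expect_equal(assignChannels(fr4, region, r)$G, 0L)
})

test_that("channel assignment equals the predicate-by-predicate oracle", {
  set.seed(31)
  cfg <- encoderConfig(alpha = 5000)
  for (tp in c("INS", "DEL", "INV", "DUP")) {
    n <- 1000
    svl <- sample(50:4000, 1)
    r <- rec(tp, 50000, if (tp == "INS") 50000 else 50000 + svl, svlen = svl)
    region <- computeSearchRegion(r, cfg)
    lo <- min(region$start) - 2000
    hi <- max(region$end) + 2000
    st <- sample(lo:hi, n, replace = TRUE)
    frs <- data.frame(read_id = "a", chrom = "chr1", start = st,
                      end = st + sample(10:(3 * svl), n, replace = TRUE),
                      sig_type = tp,
                      source = sample(c("cigar", "split"), n, replace = TRUE),
                      orientation_discordant = sample(c(TRUE, FALSE), n,
                                                      replace = TRUE))
    if (tp %in% c("INV", "DUP")) frs$source <- "split"
    got <- assignChannels(frs, region, r)
    for (k in seq_len(n)) {
      want <- oracleChannels(as.list(frs[k, ]), region, r)
      expect_identical(c(R = got$R[k], G = got$G[k], B = got$B[k]), want)
    }
  }
})

test_that("rasterization is size-invariant and keeps channels binary", {
  cfg <- testEncoder()
  r <- rec("DEL", 10000, 10500)
  region <- computeSearchRegion(r, cfg)
  # a single full-width white fragment at depth 1 fills the whole stack:
  # the one canvas row is resampled across every output row
  fr <- data.frame(read_id = "a", chrom = "chr1", start = region$start,
                   end = region$end, sig_type = "DEL", source = "cigar",
                   orientation_discordant = FALSE, R = 255L, G = 255L,
                   B = 255L)
  img <- stackAndRasterize(fr, region, cfg, depth = 1)
  px <- imagePixels(img)
  expect_equal(dim(px), c(32, 32, 3))
  expect_true(all(px == 255))
  # at depth 8 the same single fragment occupies 1/8 of the rows
  img8 <- stackAndRasterize(fr, region, cfg, depth = 8)
  expect_equal(mean(rowSums(imagePixels(img8)[, , 3]) > 0), 1 / 8)
  # zero fragments: all-zero image of the configured size
  img0 <- stackAndRasterize(fr[0, ], region, cfg, depth = 10)
  expect_equal(dim(imagePixels(img0)), c(32, 32, 3))
  expect_true(all(imagePixels(img0) == 0))
  # values always exactly 0 or 255
  expect_true(all(imagePixels(img8) %in% c(0, 255)))
})

test_that("overflowing fragments are dropped deterministically, short ones stay visible", {
  cfg <- testEncoder()
  r <- rec("DEL", 100000, 200000)   # 100 kb event, 300 kb window
  region <- computeSearchRegion(r, cfg)
  # five identical-span fragments but only three stack rows: the two that
  # sort last (here the blue ones) are dropped deterministically
  fr <- data.frame(read_id = sprintf("r%02d", 1:5), chrom = "chr1",
                   start = 150000, end = 150060, sig_type = "DEL",
                   source = "cigar", orientation_discordant = FALSE,
                   R = c(255L, 255L, 255L, 0L, 0L), G = 0L,
                   B = c(0L, 0L, 0L, 255L, 255L))
  img <- stackAndRasterize(fr, region, cfg, depth = 3)
  px <- imagePixels(img)
  # a 60 bp fragment in a 300 kb window still paints one column bin
  expect_gt(sum(px[, , 1] > 0), 0)
  expect_equal(sum(px[, , 3] > 0), 0)
})

test_that("encoding a candidate is pure and signature-free loci are blank", {
  sim <- sharedSim()
  cfg <- testEncoder()
  del <- sim$truth[svType(sim$truth) == "DEL"][1]
  a <- encodeCandidate(sim$bam, del, cfg)
  b <- encodeCandidate(sim$bam, del, cfg)
  expect_identical(imagePixels(a), imagePixels(b))
  blank <- encodeCandidate(sim$bam, rec("DEL", 430000, 430200, chrom = "chr2"),
                           cfg)
  expect_true(all(imagePixels(blank) == 0))
})

test_that("a homozygous deletion at 30x lights up most stack rows", {
  # long reads so nearly every overlapping read spans the event with flanks
  sim <- simulateDataset(
    simConfig(contigs = c(chr1 = 200000, chr2 = 80000), coverage = 30,
              read_len_mean = 8000, read_len_sd = 800,
              n_events = c(DEL = 1), len_range = list(DEL = c(300, 300)),
              n_decoys = c(DEL = 0), seed = 62),
    tempfile())
  cfg <- testEncoder()
  del <- sim$truth[1]
  img <- encodeCandidate(sim$bam, del, cfg)
  px <- imagePixels(img)
  full <- px[, , 1] == 255 & px[, , 2] == 255 & px[, , 3] == 255
  expect_gte(sum(rowSums(full) > 0), 20)
})

test_that("adding a supporting fragment never decreases nonzero pixels", {
  cfg <- testEncoder()
  r <- rec("DEL", 10000, 10500)
  region <- computeSearchRegion(r, cfg)
  set.seed(12)
  st <- sample(9500:10800, 30, replace = TRUE)
  fr <- data.frame(read_id = sprintf("r%02d", 1:30), chrom = "chr1",
                   start = st, end = st + sample(50:600, 30, replace = TRUE),
                   sig_type = "DEL", source = "cigar",
                   orientation_discordant = FALSE, R = 255L, G = 0L, B = 255L)
  fr <- fr[order(fr$start, fr$end, fr$read_id), ]
  prev <- -1
  for (k in seq(5, 30, by = 5)) {
    img <- stackAndRasterize(fr[1:k, ], region, cfg, depth = 30)
    nz <- sum(imagePixels(img) != 0)
    expect_gte(nz, prev)
    prev <- nz
  }
})
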