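# VCF loading, multi-caller merging, TRA clustering, truth labeling.

writeTestVcf <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"t\">",
    "##contig=<ID=chr1,length=1000000>",
    "##contig=<ID=chr2,length=1000000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body), path)
  path
}

test_that("SV records load with reconciled lengths and min-length filter", {
  p <- writeTestVcf(c(
    "chr1\t100\td1\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=200",
    "chr1\t500\ti1\tN\t<INS>\t60\tPASS\tSVTYPE=INS;SVLEN=300",
    "chr1\t900\tsmall\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=930"))
  r <- readSVCallset(p, min_svlen = 50, caller = "x")
  sv <- r$sv
  expect_equal(length(sv), 2L)  # the 30 bp DEL is dropped
  expect_equal(svLen(sv)[svID(sv) == "d1"], 100)
  ins <- sv[svType(sv) == "INS"]
  expect_equal(svPos(ins), svEnd(ins))
  expect_equal(svLen(ins), 300)
})

test_that("BND and SVTYPE=TRA records become translocation records", {
  p <- writeTestVcf(c(
    "chr1\t1000\tb1\tN\tN[chr2:5000[\t60\tPASS\tSVTYPE=BND",
    "chr1\t2000\tt1\tN\t<TRA>\t60\tPASS\tSVTYPE=TRA;CHR2=chr2;END=7000"))
  r <- readSVCallset(p, caller = "x")
  tt <- traTable(r$tra)
  expect_equal(nrow(tt), 2L)
  expect_equal(tt$pos2, c(5000, 7000))
  expect_equal(tt$chrom2, c("chr2", "chr2"))
  expect_equal(length(r$sv), 0L)
})

test_that("malformed VCF fails with a parse error naming the file", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "at all"), p)
  expect_error(readSVCallset(p), "parse|VCF|vcf")
})

test_that("a simulator-written truth VCF round-trips loss-free", {
  sim <- sharedSim()
  r <- readSVCallset(sim$truth_vcf, caller = "truth")
  expect_equal(length(r$sv), length(sim$truth))
  got <- as.data.frame(r$sv)
  want <- as.data.frame(sim$truth)
  ord <- function(d) d[order(d$id), c("chrom", "pos", "end", "svtype", "svlen", "id")]
  expect_equal(ord(got), ord(want), ignore_attr = TRUE)
  expect_equal(nrow(traTable(r$tra)), length(sim$tra_truth))
  # write-then-read identity through the package's own writer
  p2 <- tempfile(fileext = ".vcf")
  writeSVVcf(r$sv, p2, contigs = sim$contigs)
  r2 <- readSVCallset(p2, caller = "truth")
  expect_equal(ord(as.data.frame(r2$sv)), ord(want), ignore_attr = TRUE)
})

test_that("same-type nearby records merge; types never mix", {
  a <- SVCallSet("chr1", 1000, 1100, "DEL", 100, id = "a", callers = "A")
  b <- SVCallSet("chr1", 1010, 1115, "DEL", 105, id = "b", callers = "B")
  m <- mergeCallsets(list(A = a, B = b), merge_dist = 1000, size_sim = 0.7)
  expect_equal(length(m), 1L)
  expect_setequal(unlist(svCallers(m)), c("A", "B"))
  expect_equal(svPos(m), 1005)
  # a DEL and an INS at the same position never merge
  ins <- SVCallSet("chr1", 1000, 1000, "INS", 100, id = "c", callers = "B")
  m2 <- mergeCallsets(list(A = a, B = ins))
  expect_equal(length(m2), 2L)
  # distant same-type records stay apart
  far <- SVCallSet("chr1", 5000, 5100, "DEL", 100, id = "d", callers = "B")
  expect_equal(length(mergeCallsets(list(A = a, B = far))), 2L)
})

test_that("perturbed duplicates from pseudo-callers merge back to the truth count", {
  sim <- sharedSim()
  pc <- makePseudoCallsets(sim$truth, callers = paste0("c", 1:4),
                           miss_rate = 0, pos_jitter_sd = 30, seed = 9)
  m <- mergeCallsets(pc$callsets)
  expect_equal(length(m), length(sim$truth))
  expect_true(all(vapply(svCallers(m), length, 1L) == 4L))
  # idempotence: merging the merged set changes nothing
  m2 <- mergeCallsets(m)
  expect_equal(as.data.frame(m2)[, 1:5], as.data.frame(m)[, 1:5])
})

test_that("TRA same-event predicate follows the distance rule exactly", {
  a <- list(chrom1 = "chr1", pos1 = 1000, chrom2 = "chr5", pos2 = 2000)
  b <- list(chrom1 = "chr1", pos1 = 1500, chrom2 = "chr5", pos2 = 2500)
  expect_true(traSameEvent(a, b, gamma = 1000))
  b$pos2 <- 3001  # 1001 > gamma
  expect_false(traSameEvent(a, b, gamma = 1000))
  b$pos2 <- 3000  # exactly gamma is still the same event
  expect_true(traSameEvent(a, b, gamma = 1000))
  cmix <- list(chrom1 = "chr1", pos1 = 1000, chrom2 = "chr6", pos2 = 2000)
  expect_false(traSameEvent(a, cmix, gamma = 1000))
  # symmetry
  expect_identical(traSameEvent(a, b, 1000), traSameEvent(b, a, 1000))
})

test_that("TRA clustering applies the caller-support threshold", {
  tra <- TraRecords(rep("chr1", 3), c(1000, 1200, 900),
                    rep("chr2", 3), c(5000, 5100, 4950),
                    caller = c("A", "B", "C"))
  cl <- mergeTras(tra, gamma = 1000, c0 = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 3L)
  # a single record does not reach c0 = 2
  one <- TraRecords("chr1", 1000, "chr2", 5000, caller = "A")
  expect_equal(nrow(mergeTras(one, c0 = 2)), 0L)
  expect_equal(nrow(mergeTras(one, c0 = 1)), 1L)
})

test_that("greedy TRA clustering equals transitive closure on jittered events", {
  gamma <- 1000
  for (seed in 1:20) {
    set.seed(seed)
    nev <- 6
    base1 <- seq(10000, by = 5 * gamma, length.out = nev)
    base2 <- seq(200000, by = 5 * gamma, length.out = nev)
    k <- 50
    ev <- sample(nev, k, replace = TRUE)
    df <- data.frame(chrom1 = "chr1",
                     pos1 = base1[ev] + sample(-gamma:gamma, k, TRUE) %/% 2,
                     chrom2 = sample(c("chr2", "chr3"), k, TRUE),
                     pos2 = base2[ev] + sample(-gamma:gamma, k, TRUE) %/% 2)
    tra <- TraRecords(df$chrom1, df$pos1, df$chrom2, df$pos2,
                      caller = sample(LETTERS[1:4], k, TRUE))
    got <- mergeTras(tra, gamma = gamma, c0 = 2)
    want <- oracleTraClusters(traTable(tra), gamma, 2)
    expect_equal(nrow(got), length(want))
    # identical partitions of the kept records
    gotsets <- lapply(got$members, sort)
    wantsets <- lapply(want, sort)
    expect_setequal(vapply(gotsets, paste, "", collapse = ","),
                    vapply(wantsets, paste, "", collapse = ","))
  }
})

test_that("candidate labeling is one-to-one and type-strict", {
  truth <- SVCallSet(c("chr1", "chr1"), c(1005, 3000), c(1102, 3100),
                     c("DEL", "DEL"), c(97, 100), id = c("t1", "t2"))
  cand <- SVCallSet(c("chr1", "chr1", "chr1"), c(1000, 1010, 3000),
                    c(1100, 1110, 3100), c("DEL", "DEL", "INV"),
                    c(100, 100, 100), id = c("c1", "c2", "c3"))
  lab <- labelCandidates(cand, truth, refdist = 1000, pctsize = 0.7)
  expect_equal(lab$label, c("positive", "negative", "negative"))
  expect_equal(lab$matched_truth_id, c("t1", "", ""))
  expect_equal(sum(lab$label == "positive") + sum(lab$label == "negative"),
               length(cand))
})

test_that("labels recover the simulator's planted decoy flags exactly", {
  sim <- sharedSim()
  cand <- c(sim$truth, sim$decoys)
  lab <- labelCandidates(cand, sim$truth)
  is_decoy <- grepl("^decoy", lab$id)
  expect_true(all(lab$label[!is_decoy] == "positive"))
  expect_true(all(lab$label[is_decoy] == "negative"))
  expect_false(any(duplicated(lab$matched_truth_id[lab$matched_truth_id != ""])))
})

test_that("written VCFs are valid and carry the Table-style INFO schema", {
  sim <- sharedSim()
  p <- tempfile(fileext = ".vcf")
  cl <- mergeTras(TraRecords(c("chr1", "chr1"), c(1000, 1100),
                             c("chr2", "chr2"), c(5000, 5100),
                             caller = c("A", "B")), c0 = 2)
  writeSVVcf(sim$truth, p, tra_clusters = cl, contigs = sim$contigs,
             meta = c(svpixel_test = "1"))
  txt <- readLines(p)
  expect_true(any(grepl("^##svpixel_test=1", txt)))
  body <- txt[!startsWith(txt, "#")]
  expect_true(all(grepl("SVTYPE=", body)))
  expect_true(all(grepl("SUPPORT=", body)))
  expect_true(any(grepl("SVTYPE=TRA", body)))
  # external validator: bcftools must parse it without errors
  if (nzchar(Sys.which("bcftools"))) {
    code <- system2("bcftools", c("view", p), stdout = FALSE, stderr = FALSE)
    expect_equal(code, 0L)
  }
  # empty callset: header-only file that still parses
  p2 <- tempfile(fileext = ".vcf")
  writeSVVcf(SVCallSet(), p2)
  r2 <- readSVCallset(p2)
  expect_equal(length(r2$sv), 0L)
})
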