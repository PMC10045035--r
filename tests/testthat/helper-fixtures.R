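# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env()

# Write a BAM from hand-written alignment rows.
makeTestBam <- function(lines, contigs = c(chr1 = 100000L), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "t.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                       as.integer(contigs)),
               lines), sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "u"), overwrite = TRUE,
                           indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "t"))
  Rsamtools::indexBam(bam)
  bam
}

samRow <- function(qname, flag, chrom, pos1, cigar, mapq = 60L) {
  paste(qname, flag, chrom, pos1, mapq, cigar, "*", 0L, 0L, "*", "*",
        sep = "\t")
}

testEncoder <- function(...) {
  encoderConfig(image_width = 32L, image_height = 32L, ...)
}

# One modest simulated dataset shared by several test files.
sharedSim <- function() {
  if (is.null(.fixtureCache$sim)) {
    cfg <- simConfig(contigs = c(chr1 = 900000, chr2 = 600000), coverage = 30,
                     n_events = c(INS = 8, DEL = 8, INV = 5, DUP = 5, TRA = 3),
                     n_decoys = c(INS = 6, DEL = 6, INV = 4, DUP = 4),
                     seed = 424242)
    .fixtureCache$sim <- simulateDataset(cfg, file.path(tempdir(), "sharedsim"))
  }
  .fixtureCache$sim
}
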