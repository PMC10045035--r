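## Alignment reading and SV-signature extraction.
##
## Coordinates are 0-based half-open for segments and fragments (BAM native);
## conversion to/from the 1-based VCF convention happens in the callset layer.

emptyFragments <- function() {
  data.frame(read_id = character(), chrom = character(),
             start = numeric(), end = numeric(),
             sig_type = character(), source = character(),
             orientation_discordant = logical(), stringsAsFactors = FALSE)
}

emptySegments <- function() {
  data.frame(read_id = character(), chrom = character(),
             ref_start = numeric(), ref_end = numeric(),
             read_start = numeric(), read_end = numeric(),
             is_reverse = logical(), is_supplementary = logical(),
             mapq = integer(), stringsAsFactors = FALSE)
}

## data.frame assembly without the checking/deparse overhead of data.frame()
fastDF <- function(...) {
  x <- list(...)
  n <- max(vapply(x, length, 1L))
  x <- lapply(x, function(v) if (length(v) == n) v else rep_len(v, n))
  structure(x, class = "data.frame", row.names = .set_row_names(n))
}

sortFragments <- function(df) {
  if (!nrow(df)) return(df)
  ## sig_type last: breaks the rare tie where an I and a D of equal length
  ## share the same anchor on one read
  df <- df[order(df$start, df$end, df$read_id, df$sig_type), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Leading/trailing clip lengths (S + H) of a CIGAR, vectorized.
cigarClips <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead <- mapply(function(o, l) {
    i <- 1L; tot <- 0L
    while (i <= length(o) && o[i] %in% c("S", "H")) { tot <- tot + l[i]; i <- i + 1L }
    tot
  }, ops, lens)
  trail <- mapply(function(o, l) {
    i <- length(o); tot <- 0L
    while (i >= 1L && o[i] %in% c("S", "H")) { tot <- tot + l[i]; i <- i - 1L }
    tot
  }, ops, lens)
  list(lead = as.integer(lead), trail = as.integer(trail))
}

## BAM header targets, cached per path (headers are reread when the file
## changes on disk).
.headerCache <- new.env(parent = emptyenv())

.scanFlag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isDuplicate = FALSE)

bamTargets <- function(bam) {
  path <- if (is.character(bam)) bam else Rsamtools::path(bam)
  key <- paste0(normalizePath(path), "#", file.mtime(path))
  if (!is.null(.headerCache[[key]])) return(.headerCache[[key]])
  t <- Rsamtools::scanBamHeader(if (is.character(bam)) Rsamtools::BamFile(bam) else bam)$targets
  .headerCache[[key]] <- t
  t
}

## One indexed scan per region: primary + supplementary alignments (secondary
## and duplicates excluded). Downstream views (segments, CIGAR fragments,
## depth) are computed from this single result.
rawScan <- function(bam, chrom, start, end) {
  if (end <= start) stop("region must have length >= 1: ", chrom, ":", start, "-", end)
  targets <- bamTargets(bam)
  if (is.character(bam)) bam <- Rsamtools::BamFile(bam)
  if (!chrom %in% names(targets))
    stop("chromosome not found in BAM header: ", chrom)
  clen <- targets[[chrom]]
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(max(1, start + 1),
                                                          min(clen, end)))
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "mapq", "cigar"),
                               flag = .scanFlag, which = which)
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  r$chrom <- chrom
  r$is_supplementary <- bitwAnd(r$flag, 2048L) > 0L
  r$is_reverse <- bitwAnd(r$flag, 16L) > 0L
  r
}

segmentsFromScan <- function(r, min_mapq = 20L) {
  keep <- which(r$mapq >= min_mapq)
  if (!length(keep)) return(emptySegments())
  cigar <- r$cigar[keep]
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                                     after.soft.clipping = TRUE)
  clips <- cigarClips(cigar)
  is_rev <- r$is_reverse[keep]
  read_start <- ifelse(is_rev, clips$trail, clips$lead)
  df <- fastDF(
    read_id = r$qname[keep], chrom = rep_len(r$chrom, length(keep)),
    ref_start = r$pos[keep] - 1, ref_end = r$pos[keep] - 1 + refw,
    read_start = read_start, read_end = read_start + qw,
    is_reverse = is_rev, is_supplementary = r$is_supplementary[keep],
    mapq = r$mapq[keep])
  df <- df[order(df$read_id, df$read_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

cigarFragmentsFromScan <- function(r, start, end, min_len = 50L,
                                   min_mapq = 20L) {
  keep <- which(!r$is_supplementary & r$mapq >= min_mapq)
  if (!length(keep)) return(emptyFragments())
  cigar <- r$cigar[keep]; pos <- r$pos[keep]; qname <- r$qname[keep]
  dr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, ops = "D",
                                                          pos = pos)
  ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, ops = "I",
                                                          pos = pos)
  il <- GenomicAlignments::explodeCigarOpLengths(cigar, ops = "I")
  out <- list()
  dd <- as.data.frame(dr)
  if (nrow(dd)) {
    s0 <- dd$start - 1; e0 <- s0 + dd$width
    ok <- dd$width >= min_len & s0 < end & e0 > start
    if (any(ok)) {
      out[[length(out) + 1L]] <- fastDF(
        read_id = qname[dd$group[ok]], chrom = r$chrom,
        start = s0[ok], end = e0[ok], sig_type = "DEL", source = "cigar",
        orientation_discordant = FALSE)
    }
  }
  di <- as.data.frame(ir)
  if (nrow(di)) {
    anchor <- di$start - 1
    len <- unlist(il, use.names = FALSE)
    ok <- len >= min_len & anchor >= start & anchor < end
    if (any(ok)) {
      out[[length(out) + 1L]] <- fastDF(
        read_id = qname[di$group[ok]], chrom = r$chrom,
        start = anchor[ok], end = anchor[ok] + len[ok],
        sig_type = "INS", source = "cigar",
        orientation_discordant = FALSE)
    }
  }
  if (!length(out)) return(emptyFragments())
  sortFragments(do.call(rbind, out))
}

depthFromScan <- function(r, start, end) {
  keep <- which(!r$is_supplementary)
  if (!length(keep)) return(0)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(r$cigar[keep])
  s <- r$pos[keep] - 1; e <- s + refw
  ov <- pmin(e, end) - pmax(s, start)
  round(sum(pmax(ov, 0)) / (end - start), 2)
}

#' Read alignment segments overlapping a region
#'
#' Returns one row per primary or supplementary alignment, with reference and
#' read-offset coordinates suitable for split-read signature analysis. Read
#' offsets are expressed on the original read orientation, so the segments of
#' one split read are orderable by \code{read_start}. Secondary and duplicate
#' alignments are skipped.
#'
#' @param bam path to an indexed BAM, or a \code{BamFile}.
#' @param chrom,start,end region, 0-based half-open.
#' @param min_mapq minimum mapping quality (default 20).
#' @return data.frame with columns read_id, chrom, ref_start, ref_end,
#'   read_start, read_end, is_reverse, is_supplementary, mapq.
#' @export
readAlignmentSegments <- function(bam, chrom, start, end, min_mapq = 20L) {
  segmentsFromScan(rawScan(bam, chrom, start, end), min_mapq = min_mapq)
}

#' Extract intra-alignment (CIGAR) insertion/deletion signatures
#'
#' One signature fragment per I or D CIGAR operation of length at least
#' \code{min_len} whose reference anchor overlaps the region. DEL fragments
#' span the deleted reference interval; INS fragments are anchored at the
#' insertion locus with span equal to the inserted length (a synthetic span
#' used only for drawing). Only primary alignments are inspected;
#' supplementary segments contribute through
#' \code{\link{extractSplitFragments}} instead.
#'
#' @inheritParams readAlignmentSegments
#' @param min_len minimum operation length in bp (default 50, the canonical
#'   SV size floor).
#' @return signature fragment data.frame sorted by (start, end, read_id).
#' @export
extractCigarFragments <- function(bam, chrom, start, end, min_len = 50L,
                                  min_mapq = 20L) {
  stopifnot(min_len >= 1L)
  cigarFragmentsFromScan(rawScan(bam, chrom, start, end), start, end,
                         min_len = min_len, min_mapq = min_mapq)
}

## Classify one adjacent same-chromosome segment pair. Returns a fragment
## data.frame (possibly empty). Orientation-discordant pairs yield INV_SEG
## fragments over both segments; reference overlap yields DUP_SEG over both;
## otherwise the reference-gap / read-gap difference decides DEL vs INS.
classifySegmentPair <- function(s1, s2, min_delta = 50) {
  frag <- function(sig, st, en, disc = FALSE)
    fastDF(read_id = s1$read_id, chrom = s1$chrom, start = st, end = en,
           sig_type = sig, source = "split", orientation_discordant = disc)
  if (s1$is_reverse != s2$is_reverse) {
    return(rbind(frag("INV_SEG", s1$ref_start, s1$ref_end, TRUE),
                 frag("INV_SEG", s2$ref_start, s2$ref_end, TRUE)))
  }
  overlap <- min(s1$ref_end, s2$ref_end) - max(s1$ref_start, s2$ref_start)
  if (overlap > 0) {
    return(rbind(frag("DUP_SEG", s1$ref_start, s1$ref_end),
                 frag("DUP_SEG", s2$ref_start, s2$ref_end)))
  }
  read_gap <- s2$read_start - s1$read_end
  if (!s1$is_reverse) {
    ref_gap <- s2$ref_start - s1$ref_end
    junction <- s1$ref_end
    gap_lo <- s1$ref_end; gap_hi <- s2$ref_start
  } else {
    ref_gap <- s1$ref_start - s2$ref_end
    junction <- s2$ref_end
    gap_lo <- s2$ref_end; gap_hi <- s1$ref_start
  }
  if (ref_gap - read_gap > min_delta)
    return(frag("DEL", gap_lo, gap_hi))
  if (read_gap - ref_gap > min_delta)
    return(frag("INS", junction, junction + (read_gap - ref_gap)))
  emptyFragments()
}

#' Extract inter-alignment (split-read) signatures
#'
#' Walks adjacent segment pairs of each split read (ordered along the read)
#' and emits fragments for the four split-read geometries: a reference gap
#' exceeding the read gap by more than \code{min_delta} (DEL), the converse
#' (INS), reference overlap of the two segments (DUP_SEG over both), and
#' opposite orientations (INV_SEG over both, flagged discordant). Pairs on
#' different chromosomes are translocation evidence and are returned by
#' \code{\link{extractTraEvidence}}, not here.
#'
#' @param segments data.frame from \code{\link{readAlignmentSegments}}.
#' @param min_delta minimum read-vs-reference distance change in bp
#'   (default 50).
#' @return signature fragment data.frame sorted by (start, end, read_id).
#' @export
extractSplitFragments <- function(segments, min_delta = 50) {
  if (!nrow(segments)) return(emptyFragments())
  multi <- names(which(table(segments$read_id) >= 2L))
  segments <- segments[segments$read_id %in% multi, , drop = FALSE]
  if (!nrow(segments)) return(emptyFragments())
  segments <- segments[order(segments$read_id, segments$read_start), ,
                       drop = FALSE]
  out <- list()
  n <- nrow(segments)
  rowList <- function(k) list(read_id = segments$read_id[k],
                              chrom = segments$chrom[k],
                              ref_start = segments$ref_start[k],
                              ref_end = segments$ref_end[k],
                              read_start = segments$read_start[k],
                              read_end = segments$read_end[k],
                              is_reverse = segments$is_reverse[k])
  for (k in seq_len(n - 1L)) {
    if (segments$read_id[k] != segments$read_id[k + 1L]) next
    if (segments$chrom[k] != segments$chrom[k + 1L]) next
    out[[length(out) + 1L]] <- classifySegmentPair(rowList(k), rowList(k + 1L),
                                                   min_delta)
  }
  if (!length(out)) return(emptyFragments())
  sortFragments(do.call(rbind, out))
}

#' Extract translocation breakpoint evidence from split reads
#'
#' Adjacent segment pairs of one read on different chromosomes witness a
#' translocation junction. The breakpoint on each side is the segment
#' boundary adjacent to the junction in read order. TRA evidence is never
#' imaged; it feeds the breakpoint-merging stage and the simulator's tests
#' only.
#'
#' @inheritParams extractSplitFragments
#' @param caller provenance string stored on the records.
#' @return a \linkS4class{TraRecords}.
#' @export
extractTraEvidence <- function(segments, caller = "split") {
  c1 <- c2 <- character(); p1 <- p2 <- numeric()
  if (nrow(segments)) {
    multi <- names(which(table(segments$read_id) >= 2L))
    segments <- segments[segments$read_id %in% multi, , drop = FALSE]
  }
  if (nrow(segments)) {
    for (chunk in split(segments, segments$read_id)) {
      if (nrow(chunk) < 2L) next
      chunk <- chunk[order(chunk$read_start), , drop = FALSE]
      for (k in seq_len(nrow(chunk) - 1L)) {
        s1 <- chunk[k, ]; s2 <- chunk[k + 1L, ]
        if (s1$chrom == s2$chrom) next
        c1 <- c(c1, s1$chrom); p1 <- c(p1, s1$ref_end)
        c2 <- c(c2, s2$chrom); p2 <- c(p2, s2$ref_start)
      }
    }
  }
  TraRecords(c1, p1, c2, p2, caller = caller)
}

#' Mean read depth of a region
#'
#' Depth is the summed overlap length of primary, non-duplicate alignments
#' divided by the region length, rounded to two decimals.
#'
#' @inheritParams readAlignmentSegments
#' @return list(chrom, start, end, depth).
#' @export
regionDepth <- function(bam, chrom, start, end, min_mapq = 0L) {
  r <- rawScan(bam, chrom, start, end)
  r$is_supplementary <- r$is_supplementary | r$mapq < min_mapq
  list(chrom = chrom, start = start, end = end,
       depth = depthFromScan(r, start, end))
}
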