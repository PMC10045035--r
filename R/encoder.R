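## Encoding alignment signatures around one candidate SV into a fixed-size
## three-channel image.

#' Encoder configuration
#'
#' @param alpha inversion split threshold in bp: INV candidates longer than
#'   \code{alpha} are encoded from two breakpoint-flanking windows instead of
#'   one spanning window, bounding memory for very large inversions
#'   (default 10000).
#' @param image_width,image_height output image size in pixels (default 128;
#'   must be at least 32 and divisible by 8 for the downstream network).
#' @param min_sig_len minimum CIGAR signature length in bp (default 50).
#' @param max_stack_depth_factor multiplier on the measured region depth when
#'   sizing the read stack (default 1).
#' @param min_delta split-read distance-change threshold in bp (default 50).
#' @param min_mapq minimum mapping quality for alignments (default 20).
#' @return a validated list of class \code{EncoderConfig}.
#' @export
encoderConfig <- function(alpha = 10000, image_width = 128L,
                          image_height = 128L, min_sig_len = 50L,
                          max_stack_depth_factor = 1,
                          min_delta = 50, min_mapq = 20L) {
  stopifnot(alpha > 0, image_width >= 32L, image_height >= 32L,
            min_sig_len >= 1L, max_stack_depth_factor > 0)
  structure(list(alpha = alpha, image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 min_sig_len = as.integer(min_sig_len),
                 max_stack_depth_factor = max_stack_depth_factor,
                 min_delta = min_delta, min_mapq = as.integer(min_mapq)),
            class = "EncoderConfig")
}

recordFields <- function(record) {
  ## accept a 1-record SVCallSet or a plain list
  if (is(record, "SVCallSet")) {
    stopifnot(length(record) == 1L)
    list(chrom = svChrom(record), pos = svPos(record), end = svEnd(record),
         svtype = svType(record), svlen = svLen(record), id = svID(record))
  } else record
}

#' Search region of a candidate SV
#'
#' DEL/DUP: \code{[bpt_left - svl, bpt_right + svl]}. INS:
#' \code{[pos - svl, pos + 2 svl]}. INV of length at most \code{alpha}: the
#' DEL-style spanning window; longer INV: two windows
#' \code{[bpt_left - alpha, bpt_left + alpha/2]} and
#' \code{[bpt_right + alpha/2, bpt_right + alpha]}. Windows are clipped to
#' \code{[0, contig_length]} when bounds are supplied.
#'
#' @param record a 1-record \linkS4class{SVCallSet} or a list with chrom,
#'   pos, end, svtype, svlen.
#' @param config an \code{\link{encoderConfig}}.
#' @param contig_length optional contig length for clipping.
#' @return data.frame of 1 or 2 windows (chrom, start, end), ordered and
#'   disjoint.
#' @export
computeSearchRegion <- function(record, config = encoderConfig(),
                                contig_length = NULL) {
  r <- recordFields(record)
  if (!r$svtype %in% c("INS", "DEL", "INV", "DUP"))
    stop("unsupported svtype for encoding: ", r$svtype)
  svl <- max(r$svlen, 1)
  if (r$svtype == "INS") {
    w <- data.frame(start = r$pos - svl, end = r$pos + 2 * svl)
  } else if (r$svtype == "INV" && svl > config$alpha) {
    a <- config$alpha
    w <- data.frame(start = c(r$pos - a, r$end + a / 2),
                    end = c(r$pos + a / 2, r$end + a))
  } else {
    w <- data.frame(start = r$pos - svl, end = r$end + svl)
  }
  w$chrom <- r$chrom
  w$start <- pmax(w$start, 0)
  if (!is.null(contig_length)) w$end <- pmin(w$end, contig_length)
  stopifnot(all(w$end > w$start))
  w[, c("chrom", "start", "end")]
}

#' Assign RGB channel values to signature fragments
#'
#' For INS/DEL/DUP candidates: B = 255 when the fragment lies completely
#' inside a search window; G = 255 when the fragment midpoint lies between
#' the two breakpoints; R = 255 when the fragment is shorter than twice the
#' candidate length (strict). For INV candidates B = 255 when the evidence
#' comes from a split read, G as above, and R = 255 when the segment
#' orientation is discordant. Containment is tested on the unclipped fragment
#' extent.
#'
#' @param fragments signature fragment data.frame.
#' @param region windows from \code{\link{computeSearchRegion}}.
#' @param record the candidate (see \code{\link{computeSearchRegion}}).
#' @return \code{fragments} with added integer columns R, G, B in {0, 255}.
#' @export
assignChannels <- function(fragments, region, record) {
  r <- recordFields(record)
  n <- nrow(fragments)
  if (!n) {
    fragments$R <- fragments$G <- fragments$B <- integer(0)
    return(fragments)
  }
  contained <- rep(FALSE, n)
  for (k in seq_len(nrow(region)))
    contained <- contained |
      (fragments$start >= region$start[k] & fragments$end <= region$end[k])
  mid <- (fragments$start + fragments$end) / 2
  g <- mid >= r$pos & mid <= r$end
  if (r$svtype == "INV") {
    b <- fragments$source == "split"
    rr <- fragments$orientation_discordant
  } else {
    b <- contained
    rr <- (fragments$end - fragments$start) < 2 * r$svlen
  }
  fragments$R <- ifelse(rr, 255L, 0L)
  fragments$G <- ifelse(g, 255L, 0L)
  fragments$B <- ifelse(b, 255L, 0L)
  fragments
}

## Map window layout to column bins of the output image. Two-window regions
## are rendered side by side with a single black separator column.
windowBins <- function(region, width) {
  nw <- nrow(region)
  if (nw == 1L) {
    data.frame(start = region$start, end = region$end, col0 = 0L,
               ncol = width)
  } else {
    spans <- region$end - region$start
    n1 <- max(1L, min(width - 2L, as.integer(round((width - 1L) * spans[1] / sum(spans)))))
    n2 <- width - 1L - n1
    data.frame(start = region$start, end = region$end,
               col0 = c(0L, n1 + 1L), ncol = c(n1, n2))
  }
}

#' Stack channel-assigned fragments and rasterize to the configured size
#'
#' Fragments (sorted by start, end, read id) are packed top-down into a read
#' stack of \code{round(depth * max_stack_depth_factor)} rows: each fragment
#' takes the first row where its column span is free, and is dropped when all
#' rows collide. Columns bin the search region into \code{image_width} pixels
#' directly (every fragment paints each bin its span touches, so arbitrarily
#' short fragments stay visible at any region span); the row axis is then
#' resampled to \code{image_height} by nearest neighbor. Channel values
#' remain exactly 0 or 255. Two-window regions are drawn side by side with a
#' one-pixel black separator.
#'
#' @param fragments output of \code{\link{assignChannels}}.
#' @param region search windows.
#' @param config an \code{\link{encoderConfig}}.
#' @param depth region read depth (from \code{\link{regionDepth}}).
#' @param meta list stored in the image (id, svtype, ...).
#' @return an \linkS4class{EncodedImage}.
#' @export
stackAndRasterize <- function(fragments, region, config, depth, meta = list()) {
  W <- config$image_width; Hout <- config$image_height
  nrows <- max(1L, as.integer(round(depth * config$max_stack_depth_factor)))
  bins <- windowBins(region, W)
  canvas <- array(0L, c(nrows, W, 3L))
  occupied <- matrix(FALSE, nrows, W)
  if (nrow(fragments)) {
    fragments <- fragments[order(fragments$start, fragments$end, fragments$read_id), ,
                           drop = FALSE]
    for (k in seq_len(nrow(fragments))) {
      fs <- fragments$start[k]; fe <- fragments$end[k]
      cols <- integer(0)
      for (w in seq_len(nrow(bins))) {
        lo <- max(fs, bins$start[w]); hi <- min(fe, bins$end[w])
        if (hi < lo) next
        span <- bins$end[w] - bins$start[w]
        c1 <- floor((lo - bins$start[w]) / span * bins$ncol[w])
        c2 <- ceiling((hi - bins$start[w]) / span * bins$ncol[w]) - 1
        c1 <- max(0, min(c1, bins$ncol[w] - 1))
        c2 <- max(c1, min(c2, bins$ncol[w] - 1))
        cols <- c(cols, bins$col0[w] + (c1:c2) + 1L)
      }
      if (!length(cols)) next
      placed <- FALSE
      for (row in seq_len(nrows)) {
        if (!any(occupied[row, cols])) {
          occupied[row, cols] <- TRUE
          canvas[row, cols, 1L] <- fragments$R[k]
          canvas[row, cols, 2L] <- fragments$G[k]
          canvas[row, cols, 3L] <- fragments$B[k]
          placed <- TRUE
          break
        }
      }
      ## dropped deterministically when every row collides
    }
  }
  rowIdx <- pmin(nrows, floor((seq_len(Hout) - 0.5) * nrows / Hout) + 1L)
  pixels <- canvas[rowIdx, , , drop = FALSE]
  meta$windows <- region
  meta$depth <- depth
  new("EncodedImage", pixels = pixels, meta = meta)
}

#' Encode one candidate SV from a BAM
#'
#' Composition of \code{\link{computeSearchRegion}}, signature extraction,
#' \code{\link{assignChannels}} and \code{\link{stackAndRasterize}}. INS/DEL
#' candidates use CIGAR fragments plus split-read INS/DEL fragments; INV uses
#' discordant-orientation split segments; DUP uses overlapping split
#' segments. A candidate with no overlapping signature encodes to an all-zero
#' image ("no support"). Pure: identical inputs give byte-identical images.
#'
#' @param bam indexed BAM path or \code{BamFile}.
#' @param record 1-record \linkS4class{SVCallSet} or list.
#' @param config an \code{\link{encoderConfig}}.
#' @param contig_length optional contig length for window clipping.
#' @return an \linkS4class{EncodedImage}.
#' @export
encodeCandidate <- function(bam, record, config = encoderConfig(),
                            contig_length = NULL) {
  r <- recordFields(record)
  region <- computeSearchRegion(record, config, contig_length)
  spans <- region$end - region$start
  ## one indexed scan per window; depth, split segments and CIGAR fragments
  ## are all derived from it
  scans <- lapply(seq_len(nrow(region)), function(k)
    rawScan(bam, region$chrom[k], region$start[k], region$end[k]))
  depths <- vapply(seq_len(nrow(region)), function(k)
    depthFromScan(scans[[k]], region$start[k], region$end[k]), 0)
  depth <- sum(depths * spans) / sum(spans)
  frags <- emptyFragments()
  segs <- do.call(rbind, lapply(scans, segmentsFromScan,
                                min_mapq = config$min_mapq))
  if (nrow(region) > 1L) segs <- unique(segs)
  split_frags <- extractSplitFragments(segs, min_delta = config$min_delta)
  if (r$svtype %in% c("INS", "DEL")) {
    cig <- do.call(rbind, lapply(seq_len(nrow(region)), function(k)
      cigarFragmentsFromScan(scans[[k]], region$start[k], region$end[k],
                             min_len = config$min_sig_len,
                             min_mapq = config$min_mapq)))
    if (nrow(region) > 1L) cig <- unique(cig)
    frags <- rbind(cig[cig$sig_type == r$svtype, , drop = FALSE],
                   split_frags[split_frags$sig_type == r$svtype, , drop = FALSE])
  } else if (r$svtype == "INV") {
    frags <- split_frags[split_frags$sig_type == "INV_SEG", , drop = FALSE]
  } else if (r$svtype == "DUP") {
    frags <- split_frags[split_frags$sig_type == "DUP_SEG", , drop = FALSE]
  }
  ## keep fragments overlapping at least one window
  if (nrow(frags)) {
    ov <- rep(FALSE, nrow(frags))
    for (k in seq_len(nrow(region)))
      ov <- ov | (frags$start < region$end[k] & frags$end > region$start[k])
    frags <- frags[ov, , drop = FALSE]
  }
  frags <- sortFragments(frags)
  frags <- assignChannels(frags, region, record)
  stackAndRasterize(frags, region, config, depth,
                    meta = list(id = r$id, svtype = r$svtype))
}

#' Encode every record of a callset
#'
#' @param bam indexed BAM.
#' @param callset an \linkS4class{SVCallSet}.
#' @param config an \code{\link{encoderConfig}}.
#' @param labels optional "positive"/"negative" labels parallel to the
#'   callset.
#' @param contigs optional named contig lengths.
#' @return an \linkS4class{SVImageSet}.
#' @export
encodeCallset <- function(bam, callset, config = encoderConfig(),
                          labels = NULL, contigs = NULL) {
  n <- length(callset)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  df <- as.data.frame(callset)
  imgs <- vector("list", n)
  for (k in seq_len(n)) {
    rec <- list(chrom = df$chrom[k], pos = df$pos[k], end = df$end[k],
                svtype = df$svtype[k], svlen = df$svlen[k], id = df$id[k])
    cl <- if (!is.null(contigs)) unname(contigs[rec$chrom]) else NULL
    imgs[[k]] <- imagePixels(encodeCandidate(bam, rec, config, cl))
  }
  new("SVImageSet", images = imgs, ids = svID(callset), labels = labels,
      svtype = svType(callset))
}

#' Pixel array of an encoded image
#' @param x an \linkS4class{EncodedImage}.
#' @export
imagePixels <- function(x) x@pixels

#' Image metadata
#' @param x an \linkS4class{EncodedImage}.
#' @export
imageMeta <- function(x) x@meta

#' Export an encoded image as PNG for inspection
#'
#' @param image an \linkS4class{EncodedImage}.
#' @param dir output directory; the file is named \code{<id>.<svtype>.png}.
#' @return the file path, invisibly.
#' @export
exportPNG <- function(image, dir = ".") {
  m <- imageMeta(image)
  path <- file.path(dir, paste0(if (is.null(m$id)) "candidate" else m$id, ".",
                                if (is.null(m$svtype)) "NA" else m$svtype,
                                ".png"))
  png::writePNG(imagePixels(image) / 255, path)
  invisible(path)
}
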