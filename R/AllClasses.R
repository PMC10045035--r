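## Central S4 containers.

setClassUnion("listOrNULL", c("list", "NULL"))

#' SVCallSet: a set of structural variant records
#'
#' Thin wrapper around a \link[GenomicRanges]{GRanges} whose metadata columns
#' carry the SV annotation used throughout the package. Positions follow VCF
#' convention (1-based; \code{start} is the left breakpoint or insertion
#' point, \code{end} the right breakpoint; for INS \code{end == start}).
#' Required metadata columns: \code{svtype} (INS/DEL/INV/DUP), \code{svlen}
#' (bp, >= 0), \code{id}, \code{qual}, and \code{callers}
#' (\link[IRanges]{CharacterList} of caller names supporting the record).
#'
#' @slot gr the underlying \code{GRanges}.
#' @export
setClass("SVCallSet", representation(gr = "GRanges"))

setValidity("SVCallSet", function(object) {
  gr <- object@gr
  need <- c("svtype", "svlen", "id", "qual", "callers")
  missing <- setdiff(need, colnames(S4Vectors::mcols(gr)))
  if (length(missing))
    return(paste("missing metadata columns:", paste(missing, collapse = ", ")))
  sv <- S4Vectors::mcols(gr)
  bad <- !sv$svtype %in% c("INS", "DEL", "INV", "DUP")
  if (any(bad))
    return(paste("unsupported svtype:", paste(unique(sv$svtype[bad]), collapse = ", ")))
  if (any(sv$svlen < 0)) return("svlen must be >= 0")
  if (length(gr) && any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
    return("end must be >= start")
  nonins <- sv$svtype %in% c("DEL", "INV", "DUP")
  if (any(nonins)) {
    span <- GenomicRanges::end(gr)[nonins] - GenomicRanges::start(gr)[nonins]
    if (any(span != sv$svlen[nonins]))
      return("svlen must equal end - start for DEL/INV/DUP")
  }
  TRUE
})

#' TraRecords: translocation breakpoint records
#'
#' One row per TRA breakpoint pair, canonically ordered so that
#' (chrom1, pos1) sorts before (chrom2, pos2).
#'
#' @slot records data.frame with columns chrom1, pos1, chrom2, pos2,
#'   caller, id.
#' @export
setClass("TraRecords", representation(records = "data.frame"))

setValidity("TraRecords", function(object) {
  df <- object@records
  need <- c("chrom1", "pos1", "chrom2", "pos2", "caller", "id")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (nrow(df)) {
    swapped <- df$chrom1 > df$chrom2 |
      (df$chrom1 == df$chrom2 & df$pos1 > df$pos2)
    if (any(swapped)) return("records must be canonically ordered (chrom1, pos1) <= (chrom2, pos2)")
  }
  TRUE
})

#' EncodedImage: one candidate's pixel encoding
#'
#' A fixed-size image with three channels (R, G, B). Each row is a stacked
#' read-evidence slot, each column a genomic bin of the search region.
#' Channel values are exactly 0 or 255.
#'
#' @slot pixels numeric array of dimension height x width x 3.
#' @slot meta list with candidate id, svtype, search-region windows and the
#'   raw region depth used for stacking.
#' @export
setClass("EncodedImage",
         representation(pixels = "array", meta = "listOrNULL"))

setValidity("EncodedImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a height x width x 3 array")
  v <- object@pixels
  if (any(!(v == 0 | v == 255))) return("channel values must be exactly 0 or 255")
  TRUE
})

#' SVImageSet: a labeled collection of encoded images
#'
#' @slot images list of height x width x 3 arrays, all the same dimension.
#' @slot ids candidate identifiers, parallel to images.
#' @slot labels "positive"/"negative" (or NA when unlabeled).
#' @slot svtype SV type per image.
#' @export
setClass("SVImageSet",
         representation(images = "list", ids = "character",
                        labels = "character", svtype = "character"))

setValidity("SVImageSet", function(object) {
  n <- length(object@images)
  if (length(object@ids) != n || length(object@labels) != n ||
      length(object@svtype) != n)
    return("ids, labels and svtype must be parallel to images")
  if (n) {
    dims <- vapply(object@images, function(x) paste(dim(x), collapse = "x"), "")
    if (length(unique(dims)) > 1L) return("all images must share dimensions")
  }
  ok <- object@labels %in% c("positive", "negative") | is.na(object@labels)
  if (!all(ok)) return("labels must be positive/negative/NA")
  TRUE
})

#' SVFeatureMatrix: flattened image rows for mislabel elimination
#'
#' Rows are candidates, columns the per-column channel sums of the image
#' (one feature per image column); \code{reduced} holds the PCA projection
#' when \code{\link{reduceFeatures}} has been applied.
#'
#' @slot features numeric matrix, one row per image.
#' @slot reduced numeric matrix (0 columns until reduced).
#' @slot ids,labels,svtype per-row annotation.
#' @export
setClass("SVFeatureMatrix",
         representation(features = "matrix", reduced = "matrix",
                        ids = "character", labels = "character",
                        svtype = "character"))

setValidity("SVFeatureMatrix", function(object) {
  n <- nrow(object@features)
  if (length(object@ids) != n || length(object@labels) != n ||
      length(object@svtype) != n)
    return("ids, labels, svtype must have one entry per feature row")
  if (nrow(object@reduced) && nrow(object@reduced) != n)
    return("reduced must preserve row count")
  TRUE
})

#' CNNClassifier: the convolutional filtering model
#'
#' Three convolution blocks (3x3 kernel, ReLU, 2x2 max-pool) followed by two
#' fully connected layers with dropout and a single sigmoid output unit.
#'
#' @slot spec list: conv channel widths, FC widths, dropout rate.
#' @slot inputDim integer height/width of conforming images.
#' @slot weights list of parameter matrices/vectors.
#' @slot trained logical.
#' @export
setClass("CNNClassifier",
         representation(spec = "list", inputDim = "integer",
                        weights = "list", trained = "logical"))

setValidity("CNNClassifier", function(object) {
  if (length(object@inputDim) != 2L) return("inputDim must be height, width")
  if (any(object@inputDim %% 8L != 0L))
    return("image dimensions must be divisible by 8 (three 2x2 pools)")
  if (length(object@spec$conv_channels) != 3L)
    return("exactly three convolution blocks")
  if (length(object@spec$fc) != 2L) return("exactly two fully connected layers")
  dr <- object@spec$dropout
  if (!is.numeric(dr) || dr < 0 || dr >= 1) return("dropout rate must be in [0, 1)")
  TRUE
})

#' SVEvalResult: precision / recall / F1 against a truth set
#'
#' @slot counts named numeric (TP, FP, FN).
#' @slot metrics named numeric (precision, recall, f1); NA when a
#'   denominator is zero (undefined, never reported as 0).
#' @slot perType data.frame breakdown by svtype.
#' @slot params matcher parameters used.
#' @export
setClass("SVEvalResult",
         representation(counts = "numeric", metrics = "numeric",
                        perType = "data.frame", params = "list"))

setValidity("SVEvalResult", function(object) {
  if (!all(c("TP", "FP", "FN") %in% names(object@counts)))
    return("counts must contain TP, FP, FN")
  m <- object@metrics[!is.na(object@metrics)]
  if (length(m) && any(m < 0 | m > 1)) return("metrics must lie in [0, 1]")
  TRUE
})
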