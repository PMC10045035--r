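## Constructors, accessors, show methods.

#' Construct an SVCallSet
#'
#' @param chrom,pos,end chromosome and 1-based breakpoints (for INS,
#'   \code{end} defaults to \code{pos}).
#' @param svtype one of INS, DEL, INV, DUP per record.
#' @param svlen SV length in bp; for DEL/INV/DUP it is reconciled to
#'   \code{end - pos}.
#' @param id record identifiers (generated when missing).
#' @param qual numeric confidence scores.
#' @param callers caller provenance: a character vector (recycled) or a list
#'   of character vectors per record.
#' @return an \linkS4class{SVCallSet}.
#' @export
SVCallSet <- function(chrom = character(), pos = integer(), end = NULL,
                      svtype = character(), svlen = NULL, id = NULL,
                      qual = NULL, callers = "unknown") {
  n <- length(chrom)
  if (is.null(end)) end <- pos
  end <- ifelse(svtype == "INS", pos, end)
  if (is.null(svlen)) svlen <- ifelse(svtype == "INS", 0L, end - pos)
  svlen <- ifelse(svtype %in% c("DEL", "INV", "DUP"), end - pos, svlen)
  if (is.null(id)) id <- if (n) paste0(svtype, ".", seq_len(n)) else character()
  if (is.null(qual)) qual <- rep(60, n)
  if (!is(callers, "CharacterList")) {
    if (is.character(callers)) callers <- as.list(rep_len(callers, n))
    callers <- IRanges::CharacterList(callers)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, end = pmax(pos, end)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    svtype = svtype, svlen = as.numeric(svlen), id = id,
    qual = as.numeric(qual), callers = callers)
  new("SVCallSet", gr = gr)
}

#' Construct a TraRecords set
#'
#' Breakpoint pairs are canonicalized so (chrom1, pos1) orders before
#' (chrom2, pos2).
#'
#' @param chrom1,pos1,chrom2,pos2 the two breakpoints of each record.
#' @param caller caller name per record (recycled).
#' @param id record identifiers.
#' @return a \linkS4class{TraRecords}.
#' @export
TraRecords <- function(chrom1 = character(), pos1 = numeric(),
                       chrom2 = character(), pos2 = numeric(),
                       caller = "unknown", id = NULL) {
  n <- length(chrom1)
  caller <- rep_len(caller, n)
  if (is.null(id)) id <- if (n) paste0("TRA.", seq_len(n)) else character()
  swap <- chrom1 > chrom2 | (chrom1 == chrom2 & pos1 > pos2)
  df <- data.frame(
    chrom1 = ifelse(swap, chrom2, chrom1),
    pos1 = ifelse(swap, pos2, pos1),
    chrom2 = ifelse(swap, chrom1, chrom2),
    pos2 = ifelse(swap, pos1, pos2),
    caller = caller, id = id, stringsAsFactors = FALSE)
  new("TraRecords", records = df)
}

#' @describeIn SVCallSet number of records
#' @param x an SVCallSet
#' @export
setMethod("length", "SVCallSet", function(x) length(x@gr))

#' @export
setMethod("length", "TraRecords", function(x) nrow(x@records))

#' Accessors for SVCallSet annotation
#'
#' @param x an \linkS4class{SVCallSet}.
#' @return per-record vectors: type, length, id, quality, caller sets,
#'   chromosome and breakpoints.
#' @name sv-accessors
NULL

#' @rdname sv-accessors
#' @export
svType <- function(x) S4Vectors::mcols(x@gr)$svtype
#' @rdname sv-accessors
#' @export
svLen <- function(x) S4Vectors::mcols(x@gr)$svlen
#' @rdname sv-accessors
#' @export
svID <- function(x) S4Vectors::mcols(x@gr)$id
#' @rdname sv-accessors
#' @export
svQual <- function(x) S4Vectors::mcols(x@gr)$qual
#' @rdname sv-accessors
#' @export
svCallers <- function(x) S4Vectors::mcols(x@gr)$callers
#' @rdname sv-accessors
#' @export
svChrom <- function(x) as.character(GenomicRanges::seqnames(x@gr))
#' @rdname sv-accessors
#' @export
svPos <- function(x) GenomicRanges::start(x@gr)
#' @rdname sv-accessors
#' @export
svEnd <- function(x) GenomicRanges::end(x@gr)

#' @rdname sv-accessors
#' @export
traTable <- function(x) {
  stopifnot(is(x, "TraRecords"))
  x@records
}

#' @export
setMethod("[", "SVCallSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, gr = x@gr[i])
})

#' @export
setMethod("[", "TraRecords", function(x, i, j, ..., drop = TRUE) {
  initialize(x, records = x@records[i, , drop = FALSE])
})

#' Convert an SVCallSet to a data.frame
#' @param x an SVCallSet.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "SVCallSet", function(x, ...) {
  data.frame(chrom = svChrom(x), pos = svPos(x), end = svEnd(x),
             svtype = svType(x), svlen = svLen(x), id = svID(x),
             qual = svQual(x),
             callers = vapply(svCallers(x), function(v) paste(sort(unique(v)), collapse = ","), ""),
             stringsAsFactors = FALSE)
})

setMethod("show", "SVCallSet", function(object) {
  cat("SVCallSet with", length(object), "records\n")
  if (length(object)) {
    tb <- table(svType(object))
    cat(" ", paste(names(tb), tb, sep = ":", collapse = "  "), "\n")
    print(utils::head(as.data.frame(object), 5))
    if (length(object) > 5) cat("  ...\n")
  }
})

setMethod("show", "TraRecords", function(object) {
  cat("TraRecords with", length(object), "breakpoint pairs\n")
  if (length(object)) print(utils::head(object@records, 5))
})

setMethod("show", "EncodedImage", function(object) {
  d <- dim(object@pixels)
  nz <- sum(rowSums(object@pixels != 0) > 0)
  cat(sprintf("EncodedImage %dx%dx3 (%s %s), %d/%d rows carry signal\n",
              d[1], d[2],
              if (is.null(object@meta$id)) "?" else object@meta$id,
              if (is.null(object@meta$svtype)) "?" else object@meta$svtype,
              nz, d[1]))
})

setMethod("show", "SVImageSet", function(object) {
  cat("SVImageSet with", length(object@images), "images")
  if (length(object@images))
    cat(sprintf(" (%s)", paste(dim(object@images[[1]])[1:2], collapse = "x")))
  cat("\n")
  if (length(object@images)) {
    cat("  labels:", paste(names(table(object@labels, useNA = "ifany")),
                           table(object@labels, useNA = "ifany"),
                           sep = ":", collapse = "  "), "\n")
    cat("  types: ", paste(names(table(object@svtype)), table(object@svtype),
                           sep = ":", collapse = "  "), "\n")
  }
})

setMethod("show", "SVFeatureMatrix", function(object) {
  cat(sprintf("SVFeatureMatrix: %d rows x %d features", nrow(object@features),
              ncol(object@features)))
  if (ncol(object@reduced)) cat(sprintf(" (reduced to %d)", ncol(object@reduced)))
  cat("\n")
})

setMethod("show", "CNNClassifier", function(object) {
  cat(sprintf("CNNClassifier: input %dx%dx3, conv %s, fc %s, dropout %.2f [%s]\n",
              object@inputDim[1], object@inputDim[2],
              paste(object@spec$conv_channels, collapse = "-"),
              paste(object@spec$fc, collapse = "-"), object@spec$dropout,
              if (object@trained) "trained" else "untrained"))
  cat("  parameters:", parameterCount(object), "\n")
})

setMethod("show", "SVEvalResult", function(object) {
  cat("SVEvalResult  TP:", object@counts["TP"], " FP:", object@counts["FP"],
      " FN:", object@counts["FN"], "\n")
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              object@metrics["precision"], object@metrics["recall"],
              object@metrics["f1"]))
  if (nrow(object@perType)) print(object@perType, row.names = FALSE)
})

#' Image-set and feature-matrix accessors
#' @param x the object.
#' @name set-accessors
NULL

#' @rdname set-accessors
#' @export
imageList <- function(x) x@images
#' @rdname set-accessors
#' @export
imageIDs <- function(x) x@ids
#' @rdname set-accessors
#' @export
imageLabels <- function(x) x@labels
#' @rdname set-accessors
#' @export
imageTypes <- function(x) x@svtype
#' @rdname set-accessors
#' @export
featureMatrix <- function(x) x@features
#' @rdname set-accessors
#' @export
reducedMatrix <- function(x) x@reduced

#' Subset an SVImageSet
#' @param x an SVImageSet; @param i index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SVImageSet", function(x, i, j, ..., drop = TRUE) {
  new("SVImageSet", images = x@images[i], ids = x@ids[i],
      labels = x@labels[i], svtype = x@svtype[i])
})

#' Combine two SVImageSets
#' @param x,... SVImageSets.
#' @export
setMethod("c", "SVImageSet", function(x, ...) {
  rest <- list(...)
  for (y in rest) {
    x <- new("SVImageSet", images = c(x@images, y@images),
             ids = c(x@ids, y@ids), labels = c(x@labels, y@labels),
             svtype = c(x@svtype, y@svtype))
  }
  x
})

#' Combine SVCallSets
#' @param x,... SVCallSets.
#' @export
setMethod("c", "SVCallSet", function(x, ...) {
  grs <- lapply(list(x, ...), function(s) s@gr)
  new("SVCallSet", gr = do.call(c, grs))
})

#' @export
setMethod("c", "TraRecords", function(x, ...) {
  dfs <- lapply(list(x, ...), function(s) s@records)
  new("TraRecords", records = do.call(rbind, dfs))
})
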