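## Precision / recall / F1 against a truth set. The matcher is shared with
## labelCandidates so training labels and evaluation agree.

prf <- function(TP, FP, FN) {
  m <- svMetrics(TP, FP, FN)
  c(precision = m$precision, recall = m$recall, f1 = m$f1)
}

#' Precision, recall and F1 from match counts
#'
#' Precision = TP/(TP+FP); recall = TP/(TP+FN); F1 = 2 Pre Rec/(Pre+Rec),
#' the harmonic mean. Undefined values (zero denominators) are NA, never 0.
#' Vectorized over the three counts.
#'
#' @param TP,FP,FN true positive, false positive, false negative counts.
#' @return data.frame(precision, recall, f1).
#' @export
svMetrics <- function(TP, FP, FN) {
  pre <- ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)
  rec <- ifelse(TP + FN > 0, TP / (TP + FN), NA_real_)
  f1 <- ifelse(!is.na(pre) & !is.na(rec) & (pre + rec) > 0,
               2 * pre * rec / (pre + rec), NA_real_)
  data.frame(precision = pre, recall = rec, f1 = f1)
}

#' Score a candidate callset against a truth set
#'
#' One-to-one matching via \code{\link{labelCandidates}}; TP is the number of
#' matched truth records, FP the unmatched candidates, FN the unmatched
#' truths. Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic
#' mean. Zero-denominator cases are reported as NA (undefined), never as 0.
#'
#' @param candidates,truth \linkS4class{SVCallSet}s.
#' @param refdist,pctsize matcher parameters (defaults 1000 bp, 0.7).
#' @return an \linkS4class{SVEvalResult} with a per-type breakdown.
#' @export
svScore <- function(candidates, truth, refdist = 1000, pctsize = 0.7) {
  if (!length(truth))
    warning("empty truth set: recall is undefined")
  lab <- labelCandidates(candidates, truth, refdist, pctsize)
  TP <- sum(lab$label == "positive")
  FP <- sum(lab$label == "negative")
  FN <- length(truth) - TP
  types <- sort(unique(c(svType(candidates), svType(truth))))
  per <- do.call(rbind, lapply(types, function(tp) {
    ct <- lab$label[lab$svtype == tp]
    tp_n <- sum(ct == "positive"); fp_n <- sum(ct == "negative")
    fn_n <- sum(svType(truth) == tp) - tp_n
    m <- prf(tp_n, fp_n, fn_n)
    data.frame(svtype = tp, TP = tp_n, FP = fp_n, FN = fn_n,
               precision = m["precision"], recall = m["recall"], f1 = m["f1"],
               stringsAsFactors = FALSE)
  }))
  if (is.null(per)) per <- data.frame()
  rownames(per) <- NULL
  new("SVEvalResult", counts = c(TP = TP, FP = FP, FN = FN),
      metrics = prf(TP, FP, FN), perType = per,
      params = list(refdist = refdist, pctsize = pctsize))
}

#' Evaluation accessors
#' @param x an \linkS4class{SVEvalResult}.
#' @name eval-accessors
NULL

#' @rdname eval-accessors
#' @export
evalCounts <- function(x) x@counts
#' @rdname eval-accessors
#' @export
evalMetrics <- function(x) x@metrics
#' @rdname eval-accessors
#' @export
evalPerType <- function(x) x@perType

#' Serialize an evaluation result as JSON
#' @param x an \linkS4class{SVEvalResult}.
#' @param path output file.
#' @export
writeEvalJSON <- function(x, path) {
  jsonlite::write_json(list(counts = as.list(evalCounts(x)),
                            metrics = as.list(evalMetrics(x)),
                            per_type = evalPerType(x),
                            params = x@params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
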