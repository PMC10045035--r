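## Two-stage pipeline orchestration: train a filtering model from labeled
## candidates, then filter a candidate callset with it.

loadCallsets <- function(vcfs, min_svlen = 50) {
  if (is.null(names(vcfs)) || any(!nzchar(names(vcfs))))
    names(vcfs) <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(vcfs))
  loaded <- lapply(seq_along(vcfs), function(k)
    readSVCallset(vcfs[[k]], min_svlen = min_svlen, caller = names(vcfs)[k]))
  svs <- lapply(loaded, `[[`, "sv")
  names(svs) <- names(vcfs)
  tras <- lapply(loaded, `[[`, "tra")
  tra <- if (length(tras)) do.call(c, tras) else TraRecords()
  list(sv = svs, tra = tra)
}

#' Train the filtering model from candidate VCFs, a truth VCF and a BAM
#'
#' Runs the full training stage: load and merge the candidate callsets, label
#' them against the truth set, encode each candidate into an image, eliminate
#' mislabeled negatives (PCA + k-means), balance classes per SV type, and
#' train one classifier per SV type present (types with a single class are
#' skipped with a warning). Writes per-type checkpoints, the removed-sample
#' manifest and the per-epoch AUC log into \code{outdir}.
#'
#' @param bam indexed BAM of long-read alignments.
#' @param candidate_vcfs character vector of VCF paths (names = caller
#'   names).
#' @param truth_vcf ground-truth VCF path.
#' @param outdir output directory.
#' @param config an \code{\link{encoderConfig}}.
#' @param min_svlen minimum SV length (default 50).
#' @param merge_dist,size_sim merge parameters (see
#'   \code{\link{mergeCallsets}}).
#' @param refdist,pctsize matcher parameters (see
#'   \code{\link{labelCandidates}}).
#' @param omega,n_components,c,purity_threshold mislabel-elimination
#'   parameters (see \code{\link{mislabelFilter}}).
#' @param caps per-type balancing caps (see \code{\link{balanceClasses}}).
#' @param spec a \code{\link{networkSpec}}.
#' @param epochs,batch_size,lr,valid_fraction training parameters.
#' @param seed RNG seed for every stochastic stage.
#' @return list(checkpoints = named per-type paths, reports = per-type
#'   training reports, removed_manifest, images, labels).
#' @export
trainPipeline <- function(bam, candidate_vcfs, truth_vcf, outdir,
                          config = encoderConfig(), min_svlen = 50,
                          merge_dist = 1000, size_sim = 0.7,
                          refdist = 1000, pctsize = 0.7,
                          omega = 256, n_components = 10L, c = 8L,
                          purity_threshold = 0.5,
                          caps = c(INS = 5000L, DEL = 5000L, INV = 10000L,
                                   DUP = 10000L),
                          spec = networkSpec(), epochs = 10L,
                          batch_size = 64L, lr = 1e-3, valid_fraction = 0.2,
                          seed = 1L) {
  for (p in c(bam, candidate_vcfs, truth_vcf))
    if (!file.exists(p)) stop("input does not exist: ", p)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cs <- loadCallsets(candidate_vcfs, min_svlen)
  merged <- mergeCallsets(cs$sv, merge_dist, size_sim)
  truth <- readSVCallset(truth_vcf, min_svlen, caller = "truth")$sv
  lab <- labelCandidates(merged, truth, refdist, pctsize)
  contigs <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  images <- encodeCallset(bam, merged, config, labels = lab$label,
                          contigs = contigs)
  mf <- mislabelFilter(images, omega = omega, n_components = n_components,
                       c = c, purity_threshold = purity_threshold, seed = seed)
  writeRemovalManifest(mf$manifest, file.path(outdir, "removed_samples.tsv"))
  balanced <- withCallingHandlers(
    balanceClasses(mf$images, caps = caps, seed = seed),
    warning = function(w) { message(conditionMessage(w)); invokeRestart("muffleWarning") })
  checkpoints <- list(); reports <- list()
  for (tp in sort(unique(imageTypes(balanced)))) {
    sub <- balanced[imageTypes(balanced) == tp]
    if (length(unique(imageLabels(sub))) < 2L) next
    net <- buildNetwork(c(config$image_height, config$image_width), spec,
                        seed = seed)
    fit <- trainClassifier(net, sub, valid_fraction = valid_fraction,
                           epochs = epochs, batch_size = batch_size, lr = lr,
                           seed = seed)
    ckpt <- file.path(outdir, paste0("model_", tp, ".rds"))
    saveCheckpoint(fit$classifier, ckpt)
    utils::write.table(cbind(svtype = tp, fit$report),
                       file.path(outdir, paste0("auc_", tp, ".csv")),
                       sep = ",", quote = FALSE, row.names = FALSE)
    checkpoints[[tp]] <- ckpt
    reports[[tp]] <- fit$report
  }
  if (!length(checkpoints))
    stop("training failed: no SV type had both positive and negative samples")
  list(checkpoints = checkpoints, reports = reports,
       removed_manifest = mf$manifest, labels = lab, merged = merged)
}

#' Filter a candidate callset with trained models
#'
#' Loads and merges candidate VCFs, encodes INS/DEL/INV/DUP candidates, keeps
#' those whose classifier score strictly exceeds the threshold, merges TRA
#' records by the breakpoint-distance rule with caller-support threshold, and
#' writes one sorted VCF. Filter-only: every emitted record descends from the
#' input candidate set.
#'
#' @param bam indexed BAM.
#' @param candidate_vcfs VCF paths (names = caller names).
#' @param checkpoints named per-type checkpoint paths from
#'   \code{\link{trainPipeline}} (a single unnamed path is used for all
#'   types).
#' @param out_vcf output VCF path.
#' @param config an \code{\link{encoderConfig}} (must match the checkpoints).
#' @param threshold keep score threshold (default 0.5, strict).
#' @param gamma,c0 TRA merge parameters (defaults 1000 bp, 2 callers).
#' @param min_svlen,merge_dist,size_sim as in \code{\link{trainPipeline}}.
#' @param seed RNG seed (recorded in provenance; detection is deterministic).
#' @return list(callset = kept \linkS4class{SVCallSet}, scores, tra_clusters,
#'   out_vcf).
#' @export
detectPipeline <- function(bam, candidate_vcfs, checkpoints, out_vcf,
                           config = encoderConfig(), threshold = 0.5,
                           gamma = 1000, c0 = 2L, min_svlen = 50,
                           merge_dist = 1000, size_sim = 0.7, seed = 1L) {
  cs <- loadCallsets(candidate_vcfs, min_svlen)
  merged <- mergeCallsets(cs$sv, merge_dist, size_sim)
  contigs <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (is.null(names(checkpoints)) && length(checkpoints) == 1L)
    checkpoints <- stats::setNames(rep(checkpoints, 4),
                                   c("INS", "DEL", "INV", "DUP"))
  models <- lapply(checkpoints, loadCheckpoint)
  for (m in models)
    if (!all(m@inputDim == c(config$image_height, config$image_width)))
      stop("checkpoint input ", paste(m@inputDim, collapse = "x"),
           " does not match configured image size ",
           paste(c(config$image_height, config$image_width), collapse = "x"))
  keep <- logical(length(merged))
  scores <- rep(NA_real_, length(merged))
  for (tp in sort(unique(svType(merged)))) {
    idx <- which(svType(merged) == tp)
    if (!tp %in% names(models)) next  # no model: retained unfiltered
    imgs <- encodeCallset(bam, merged[idx], config, contigs = contigs)
    pf <- predictFilter(models[[tp]], imgs, threshold)
    keep[idx] <- pf$keep
    scores[idx] <- pf$score
  }
  keep[!svType(merged) %in% names(models)] <- TRUE
  kept <- merged[keep]
  tra_clusters <- mergeTras(cs$tra, gamma = gamma, c0 = c0)
  prov <- c(svpixel_version = as.character(utils::packageVersion("svpixel")),
            svpixel_seed = as.character(seed),
            svpixel_threshold = as.character(threshold),
            svpixel_config = paste0("alpha=", config$alpha, ";image=",
                                    config$image_height, "x",
                                    config$image_width))
  writeSVVcf(kept, out_vcf, tra_clusters = tra_clusters, contigs = contigs,
             meta = prov)
  list(callset = kept, scores = data.frame(id = svID(merged),
                                           svtype = svType(merged),
                                           score = scores, keep = keep),
       tra_clusters = tra_clusters, out_vcf = out_vcf, merged = merged)
}
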