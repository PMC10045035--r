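## Eliminating mislabeled negative training samples: image flattening,
## PCA reduction, k-means clustering, purity-based removal, class balancing.

#' Flatten encoded images into a feature matrix
#'
#' Each image collapses to one row: the j-th feature is
#' \code{sum_k (R[k,j] * omega^2 + G[k,j] * omega + B[k,j])} over image rows
#' k, computed in exact integer arithmetic (the default \code{omega = 256}
#' makes each pixel a 24-bit color code, collision-free per pixel). Because
#' the sum runs over rows, the flattening is invariant to permutations of
#' image rows.
#'
#' @param images an \linkS4class{SVImageSet} or list of pixel arrays.
#' @param omega channel weighting base (integer >= 2, default 256).
#' @param labels,ids,svtype row annotation when \code{images} is a plain
#'   list.
#' @return an \linkS4class{SVFeatureMatrix} with one column per image column.
#' @export
flattenImages <- function(images, omega = 256, labels = NULL, ids = NULL,
                          svtype = NULL) {
  stopifnot(omega >= 2)
  if (is(images, "SVImageSet")) {
    labels <- imageLabels(images); ids <- imageIDs(images)
    svtype <- imageTypes(images); images <- imageList(images)
  }
  n <- length(images)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(svtype)) svtype <- rep(NA_character_, n)
  dims <- vapply(images, function(x) paste(dim(x)[1:2], collapse = "x"), "")
  if (length(unique(dims)) > 1L)
    stop("images have mixed sizes: ", paste(unique(dims), collapse = ", "))
  d <- dim(images[[1]])
  feats <- t(vapply(images, function(px) {
    R <- matrix(px[, , 1], d[1], d[2])
    G <- matrix(px[, , 2], d[1], d[2])
    B <- matrix(px[, , 3], d[1], d[2])
    as.numeric(colSums(R) * omega^2 + colSums(G) * omega + colSums(B))
  }, numeric(d[2])))
  new("SVFeatureMatrix", features = feats,
      reduced = matrix(0, nrow(feats), 0), ids = ids,
      labels = labels, svtype = svtype)
}

#' Reduce the feature matrix by PCA
#'
#' Projects the centered rows onto the top principal components. Component
#' signs follow the convention that the largest-magnitude loading is
#' positive, making the projection deterministic.
#'
#' @param fm an \linkS4class{SVFeatureMatrix}.
#' @param n_components number of components to keep (default 10).
#' @return \code{fm} with the \code{reduced} slot filled.
#' @export
reduceFeatures <- function(fm, n_components = 10L) {
  x <- featureMatrix(fm)
  stopifnot(n_components < ncol(x), nrow(x) >= n_components)
  v <- apply(x, 2, stats::sd)
  if (all(v == 0))
    stop("feature matrix has zero variance in every column; nothing to reduce")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  fm@reduced <- scale(x, center = p$center, scale = FALSE) %*% rot
  fm
}

#' k-means clustering of feature rows
#'
#' Runs k-means on the reduced matrix (or the raw features when no reduction
#' was applied) with a fixed seed and multiple restarts.
#'
#' @param fm an \linkS4class{SVFeatureMatrix}.
#' @param c number of clusters (default 8).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return list of class \code{ClusterPartition}: assignments (one cluster
#'   index per row), c, and the input ids/labels.
#' @export
clusterRows <- function(fm, c = 8L, seed = 1L, nstart = 10L) {
  x <- if (ncol(reducedMatrix(fm))) reducedMatrix(fm) else featureMatrix(fm)
  if (nrow(x) < c)
    stop("fewer rows (", nrow(x), ") than clusters (", c, ")")
  stopifnot(c >= 2L)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(x, centers = c, nstart = nstart,
                                       iter.max = 100L))
  structure(list(assignments = km$cluster, c = c, ids = fm@ids,
                 labels = fm@labels, seed = seed),
            class = "ClusterPartition")
}

#' Remove negatives co-clustered with positives
#'
#' For each cluster the positive fraction p is computed; negative-labeled
#' rows in clusters with p at or above \code{purity_threshold} are removed
#' (their feature profile matches true variants, so their negative label is
#' suspect). Positives are never removed.
#'
#' @param partition a \code{ClusterPartition} from \code{\link{clusterRows}}.
#' @param purity_threshold minimum positive fraction for a cluster to be
#'   treated as mislabel-contaminated (default 0.5).
#' @return list(kept_ids, removed_ids, clusters): \code{clusters} is a
#'   data.frame(cluster, size, positive_fraction, removed).
#' @export
removeMislabeled <- function(partition, purity_threshold = 0.5) {
  lab <- partition$labels
  stopifnot(!any(is.na(lab)))
  cl <- partition$assignments
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(l) {
    idx <- cl == l
    data.frame(cluster = l, size = sum(idx),
               positive_fraction = mean(lab[idx] == "positive"))
  }))
  summ$removed <- summ$positive_fraction >= purity_threshold
  bad <- summ$cluster[summ$removed]
  drop <- cl %in% bad & lab == "negative"
  list(kept_ids = partition$ids[!drop], removed_ids = partition$ids[drop],
       clusters = summ)
}

#' Full mislabel-elimination pass over a labeled image set
#'
#' Per SV type: flatten (\code{\link{flattenImages}}), PCA
#' (\code{\link{reduceFeatures}}), k-means (\code{\link{clusterRows}}), and
#' purity-based removal (\code{\link{removeMislabeled}}). Types with too few
#' rows for the requested cluster count are passed through unfiltered.
#'
#' @param images a labeled \linkS4class{SVImageSet}.
#' @param omega flattening base (default 256).
#' @param n_components PCA components (default 10).
#' @param c clusters per SV type (default 8).
#' @param purity_threshold see \code{\link{removeMislabeled}}.
#' @param seed RNG seed.
#' @return list(images = filtered SVImageSet, manifest = data.frame(id,
#'   svtype, cluster, positive_fraction) of removed samples).
#' @export
mislabelFilter <- function(images, omega = 256, n_components = 10L, c = 8L,
                           purity_threshold = 0.5, seed = 1L) {
  manifest <- data.frame(id = character(), svtype = character(),
                         cluster = integer(), positive_fraction = numeric(),
                         stringsAsFactors = FALSE)
  removed <- character()
  for (tp in sort(unique(imageTypes(images)))) {
    idx <- which(imageTypes(images) == tp)
    sub <- images[idx]
    if (length(idx) < max(c, n_components + 1L)) next
    fm <- flattenImages(sub, omega = omega)
    fm <- tryCatch(reduceFeatures(fm, n_components), error = function(e) fm)
    part <- clusterRows(fm, c = c, seed = seed)
    res <- removeMislabeled(part, purity_threshold)
    if (length(res$removed_ids)) {
      ri <- match(res$removed_ids, part$ids)
      manifest <- rbind(manifest, data.frame(
        id = res$removed_ids, svtype = tp,
        cluster = part$assignments[ri],
        positive_fraction = res$clusters$positive_fraction[
          match(part$assignments[ri], res$clusters$cluster)],
        stringsAsFactors = FALSE))
      removed <- c(removed, res$removed_ids)
    }
  }
  keep <- !(imageIDs(images) %in% removed)
  list(images = images[keep], manifest = manifest)
}

#' Balance positive/negative classes per SV type
#'
#' Down-samples each class to the per-type cap by seeded uniform sampling.
#' The defaults (5000 for INS/DEL, 10000 for INV/DUP) follow the per-type
#' thresholds used for model training. A type with an empty class is dropped
#' with a warning: it cannot train a binary classifier.
#'
#' @param images a labeled \linkS4class{SVImageSet}.
#' @param caps named per-type cap.
#' @param seed RNG seed.
#' @return the balanced \linkS4class{SVImageSet}.
#' @export
balanceClasses <- function(images,
                           caps = c(INS = 5000L, DEL = 5000L,
                                    INV = 10000L, DUP = 10000L),
                           seed = 1L) {
  stopifnot(all(caps > 0))
  set.seed(seed)
  keep <- integer(0)
  for (tp in sort(unique(imageTypes(images)))) {
    cap <- if (tp %in% names(caps)) caps[[tp]] else max(caps)
    for (cls in c("positive", "negative")) {
      idx <- which(imageTypes(images) == tp & imageLabels(images) == cls)
      if (!length(idx)) {
        warning("type ", tp, " has no ", cls, " samples; skipped for training")
        keep <- keep[!(keep %in% which(imageTypes(images) == tp))]
        break
      }
      if (length(idx) > cap) idx <- sort(sample(idx, cap))
      keep <- c(keep, idx)
    }
  }
  images[sort(unique(keep))]
}

#' Write the removed-sample manifest as TSV
#'
#' @param manifest data.frame from \code{\link{mislabelFilter}}.
#' @param path output file.
#' @export
writeRemovalManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
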