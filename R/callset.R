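## VCF callset I/O, multi-caller merging, TRA clustering, truth labeling.

parseBndAlt <- function(alt) {
  ## "N[chr2:123[", "]chr2:123]N", etc.
  m <- regmatches(alt, regexec("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]", alt,
                               perl = TRUE))[[1]]
  if (length(m) == 3L) list(chrom = m[2], pos = as.numeric(m[3])) else NULL
}

infoCol <- function(inf, name, default) {
  if (name %in% colnames(inf)) {
    v <- inf[[name]]
    if (is(v, "List") || is.list(v))
      v <- vapply(v, function(x) if (length(x)) x[[1]] else NA, default)
    v
  } else rep(NA, nrow(inf))
}

#' Read an SV callset from a VCF
#'
#' Loads symbolic-ALT / INFO-annotated SV records. DEL/INV/DUP lengths are
#' reconciled to \code{END - POS}; INS records keep their SVLEN with
#' \code{end == pos}. Records shorter than \code{min_svlen} are dropped
#' (translocations exempt). Breakend (BND) and SVTYPE=TRA records are split
#' off into a \linkS4class{TraRecords}.
#'
#' @param path VCF file.
#' @param min_svlen minimum SV length in bp (default 50).
#' @param caller caller name recorded as provenance (defaults to the file
#'   base name).
#' @return list(sv = SVCallSet, tra = TraRecords).
#' @export
readSVCallset <- function(path, min_svlen = 50, caller = NULL) {
  if (is.null(caller))
    caller <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(path))
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (!n) {
    return(list(sv = SVCallSet(), tra = TraRecords()))
  }
  inf <- VariantAnnotation::info(vcf)
  altc <- vapply(VariantAnnotation::alt(vcf),
                 function(a) if (length(a)) as.character(a)[1] else "", "")
  svtype <- as.character(infoCol(inf, "SVTYPE", NA_character_))
  sym <- regmatches(altc, regexec("^<([A-Z]+)(:[^>]*)?>$", altc))
  for (k in seq_len(n)) {
    if (is.na(svtype[k]) && length(sym[[k]]) >= 2L) svtype[k] <- sym[[k]][2]
    if (is.na(svtype[k]) && grepl("[][]", altc[k])) svtype[k] <- "BND"
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  endv <- suppressWarnings(as.numeric(infoCol(inf, "END", NA_real_)))
  svlen <- suppressWarnings(as.numeric(infoCol(inf, "SVLEN", NA_real_)))
  chr2 <- as.character(infoCol(inf, "CHR2", NA_character_))
  qv <- VariantAnnotation::fixed(vcf)$QUAL
  qv[is.na(qv)] <- 60
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0("rec", seq_len(n))

  is_tra <- !is.na(svtype) & svtype %in% c("TRA", "BND")
  ## translocations
  tc1 <- tc2 <- character(); tp1 <- tp2 <- numeric(); tid <- character()
  for (k in which(is_tra)) {
    mate <- parseBndAlt(altc[k])
    if (is.null(mate) && !is.na(chr2[k]))
      mate <- list(chrom = chr2[k], pos = if (!is.na(endv[k])) endv[k] else pos[k])
    if (is.null(mate)) next
    tc1 <- c(tc1, chrom[k]); tp1 <- c(tp1, pos[k])
    tc2 <- c(tc2, mate$chrom); tp2 <- c(tp2, mate$pos); tid <- c(tid, ids[k])
  }
  tra <- TraRecords(tc1, tp1, tc2, tp2, caller = caller, id = tid)

  keep <- !is_tra & !is.na(svtype) & svtype %in% c("INS", "DEL", "INV", "DUP")
  svtype <- svtype[keep]; chrom <- chrom[keep]; pos <- pos[keep]
  endv <- endv[keep]; svlen <- svlen[keep]; qv <- qv[keep]; ids <- ids[keep]
  svlen <- abs(svlen)
  noend <- is.na(endv)
  endv[noend] <- ifelse(svtype[noend] == "INS", pos[noend],
                        pos[noend] + ifelse(is.na(svlen[noend]), 0, svlen[noend]))
  svlen[is.na(svlen)] <- (endv - pos)[is.na(svlen)]
  sv <- SVCallSet(chrom, pos, endv, svtype, svlen, id = ids, qual = qv,
                  callers = caller)
  sv <- sv[svLen(sv) >= min_svlen]
  list(sv = sv, tra = tra)
}

sizeSimilarity <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  ifelse(hi == 0, 1, lo / pmax(hi, 1e-9))
}

mergePass <- function(df, merge_dist, size_sim) {
  ## df: chrom,pos,end,svtype,svlen,id,qual, callers(list). Greedy: a record
  ## joins the first cluster (sorted order) whose median representative it
  ## matches.
  ord <- order(df$svtype, df$chrom, df$pos, df$end, df$id)
  df <- df[ord, , drop = FALSE]
  cl <- integer(nrow(df))
  reps <- list()  # per cluster: svtype, chrom, pos, svlen (medians)
  members <- list()
  for (k in seq_len(nrow(df))) {
    hit <- 0L
    for (ci in seq_along(reps)) {
      rp <- reps[[ci]]
      if (rp$svtype == df$svtype[k] && rp$chrom == df$chrom[k] &&
          abs(df$pos[k] - rp$pos) <= merge_dist &&
          sizeSimilarity(df$svlen[k], rp$svlen) >= size_sim) { hit <- ci; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- list(svtype = df$svtype[k], chrom = df$chrom[k],
                                        pos = df$pos[k], svlen = df$svlen[k])
      members[[length(members) + 1L]] <- k
      cl[k] <- length(reps)
    } else {
      members[[hit]] <- c(members[[hit]], k)
      idx <- members[[hit]]
      reps[[hit]]$pos <- stats::median(df$pos[idx])
      reps[[hit]]$svlen <- stats::median(df$svlen[idx])
      cl[k] <- hit
    }
  }
  out <- lapply(seq_along(members), function(ci) {
    idx <- members[[ci]]
    svtype <- df$svtype[idx[1]]
    pos <- round(stats::median(df$pos[idx]))
    svlen <- round(stats::median(df$svlen[idx]))
    end <- if (svtype == "INS") pos else pos + svlen
    data.frame(chrom = df$chrom[idx[1]], pos = pos, end = end,
               svtype = svtype, svlen = svlen, id = df$id[idx[1]],
               qual = max(df$qual[idx]),
               callers = I(list(sort(unique(unlist(df$callers[idx]))))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Merge multi-caller SV callsets
#'
#' Same-type records on the same chromosome whose positions lie within
#' \code{merge_dist} and whose length ratio is at least \code{size_sim} are
#' collapsed; a merged record keeps the member-median position and length and
#' the union of caller names. Greedy single-linkage passes are iterated to a
#' fixed point so the operation is idempotent.
#'
#' @param callsets a single SVCallSet or a list of them (names used as caller
#'   provenance when a callset lacks it).
#' @param merge_dist maximum breakpoint distance in bp (default 1000).
#' @param size_sim minimum length ratio min/max (default 0.7).
#' @return merged \linkS4class{SVCallSet}, sorted by (chrom, pos).
#' @export
mergeCallsets <- function(callsets, merge_dist = 1000, size_sim = 0.7) {
  if (is(callsets, "SVCallSet")) callsets <- list(callsets)
  stopifnot(length(callsets) >= 1L)
  dfs <- lapply(seq_along(callsets), function(k) {
    cs <- callsets[[k]]
    df <- as.data.frame(cs)
    df$callers <- lapply(svCallers(cs), identity)
    nm <- names(callsets)[k]
    if (!is.null(nm) && nzchar(nm))
      df$callers <- lapply(df$callers, function(v) unique(c(v, nm)))
    df[, c("chrom", "pos", "end", "svtype", "svlen", "id", "qual", "callers")]
  })
  df <- do.call(rbind, dfs)
  if (!nrow(df)) return(SVCallSet())
  repeat {
    merged <- mergePass(df, merge_dist, size_sim)
    if (nrow(merged) == nrow(df)) { df <- merged; break }
    df <- merged
  }
  df <- df[order(df$chrom, df$pos, df$svtype), , drop = FALSE]
  SVCallSet(df$chrom, df$pos, df$end, df$svtype, df$svlen, id = df$id,
            qual = df$qual, callers = df$callers)
}

#' Same-event predicate for two translocation records
#'
#' Two TRA records describe the same event when both chromosome pairs agree
#' and both breakpoint positions differ by at most \code{gamma} bp.
#'
#' @param a,b canonically ordered records: lists or 1-row data.frames with
#'   chrom1, pos1, chrom2, pos2.
#' @param gamma breakpoint bias threshold in bp (default 1000).
#' @return logical.
#' @export
traSameEvent <- function(a, b, gamma = 1000) {
  a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
    abs(a$pos1 - b$pos1) <= gamma && abs(a$pos2 - b$pos2) <= gamma
}

#' Cluster translocation records and apply the caller-support threshold
#'
#' Records are processed in (chrom1, pos1, chrom2, pos2) order; each joins
#' the first cluster whose representative (member-wise median positions) it
#' matches under \code{\link{traSameEvent}}, else founds a new cluster.
#' Clusters supported by at least \code{c0} distinct callers are returned.
#'
#' @param tra a \linkS4class{TraRecords}.
#' @param gamma breakpoint bias threshold (default 1000 bp).
#' @param c0 minimum number of distinct supporting callers (default 2).
#' @return data.frame of cluster representatives with columns chrom1, pos1,
#'   chrom2, pos2, support, n_members, callers, members (list of member row
#'   indices into \code{traTable(tra)}).
#' @export
mergeTras <- function(tra, gamma = 1000, c0 = 2L) {
  stopifnot(c0 >= 1L)
  df <- traTable(tra)
  empty <- data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      support = integer(), n_members = integer(),
                      callers = character(), stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty)
  ord <- order(df$chrom1, df$pos1, df$chrom2, df$pos2)
  reps <- list(); members <- list()
  for (k in ord) {
    rec <- df[k, ]
    hit <- 0L
    for (ci in seq_along(reps)) {
      if (traSameEvent(rec, reps[[ci]], gamma)) { hit <- ci; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- list(chrom1 = rec$chrom1, pos1 = rec$pos1,
                                        chrom2 = rec$chrom2, pos2 = rec$pos2)
      members[[length(members) + 1L]] <- k
    } else {
      members[[hit]] <- c(members[[hit]], k)
      idx <- members[[hit]]
      reps[[hit]]$pos1 <- stats::median(df$pos1[idx])
      reps[[hit]]$pos2 <- stats::median(df$pos2[idx])
    }
  }
  out <- do.call(rbind, lapply(seq_along(reps), function(ci) {
    idx <- members[[ci]]
    cal <- sort(unique(df$caller[idx]))
    data.frame(chrom1 = reps[[ci]]$chrom1, pos1 = reps[[ci]]$pos1,
               chrom2 = reps[[ci]]$chrom2, pos2 = reps[[ci]]$pos2,
               support = length(cal), n_members = length(idx),
               callers = paste(cal, collapse = ","),
               members = I(list(idx)), stringsAsFactors = FALSE)
  }))
  out <- out[out$support >= c0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label candidate records against a truth set
#'
#' A candidate is positive when a same-type truth record lies within
#' \code{refdist} bp and the length ratio min/max is at least \code{pctsize}.
#' Matching is one-to-one: candidate/truth pairs are assigned greedily by
#' increasing breakpoint distance (ties by length difference), so no truth
#' record is matched twice.
#'
#' @param candidates,truth \linkS4class{SVCallSet}s.
#' @param refdist maximum breakpoint distance in bp (default 1000).
#' @param pctsize minimum length ratio (default 0.7).
#' @return data.frame(id, svtype, label, matched_truth_id) in candidate order.
#' @export
labelCandidates <- function(candidates, truth, refdist = 1000, pctsize = 0.7) {
  nc <- length(candidates); nt <- length(truth)
  out <- data.frame(id = svID(candidates), svtype = svType(candidates),
                    label = rep("negative", nc),
                    matched_truth_id = rep("", nc), stringsAsFactors = FALSE)
  if (!nc || !nt) return(out)
  cd <- as.data.frame(candidates); td <- as.data.frame(truth)
  pairs <- list()
  for (i in seq_len(nc)) {
    same <- which(td$svtype == cd$svtype[i] & td$chrom == cd$chrom[i])
    if (!length(same)) next
    dist <- abs(td$pos[same] - cd$pos[i])
    ssim <- sizeSimilarity(td$svlen[same], cd$svlen[i])
    ok <- dist <= refdist & ssim >= pctsize
    if (any(ok)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        cand = i, truth = same[ok], dist = dist[ok],
        ldiff = abs(td$svlen[same[ok]] - cd$svlen[i]))
    }
  }
  if (!length(pairs)) return(out)
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$dist, pairs$ldiff, pairs$cand, pairs$truth), , drop = FALSE]
  cand_used <- logical(nc); truth_used <- logical(nt)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$cand[k]; j <- pairs$truth[k]
    if (cand_used[i] || truth_used[j]) next
    cand_used[i] <- TRUE; truth_used[j] <- TRUE
    out$label[i] <- "positive"
    out$matched_truth_id[i] <- td$id[j]
  }
  out
}

#' Write an SV callset (and optional TRA clusters) to VCF 4.2
#'
#' Emits symbolic ALT records with INFO keys SVTYPE, END, SVLEN and SUPPORT
#' (number of distinct supporting callers); TRA cluster representatives are
#' written as SVTYPE=TRA records with CHR2. All records get FILTER=PASS.
#'
#' @param callset an \linkS4class{SVCallSet}.
#' @param path output file.
#' @param tra_clusters optional data.frame from \code{\link{mergeTras}}.
#' @param contigs optional named vector of contig lengths for the header.
#' @param meta named character vector of extra header lines (provenance).
#' @return the path, invisibly.
#' @export
writeSVVcf <- function(callset, path, tra_clusters = NULL, contigs = NULL,
                       meta = character()) {
  df <- as.data.frame(callset)
  support <- vapply(svCallers(callset), function(v) length(unique(v)), 1L)
  alt <- if (nrow(df)) paste0("<", df$svtype, ">") else character(0)
  chrom <- df$chrom; pos <- df$pos; endv <- df$end; svlen <- df$svlen
  svtype <- df$svtype; ids <- df$id; qual <- df$qual
  chr2 <- rep(NA_character_, nrow(df))
  if (!is.null(tra_clusters) && nrow(tra_clusters)) {
    tn <- nrow(tra_clusters)
    chrom <- c(chrom, tra_clusters$chrom1)
    pos <- c(pos, tra_clusters$pos1)
    endv <- c(endv, tra_clusters$pos2)
    svlen <- c(svlen, rep(0, tn))
    svtype <- c(svtype, rep("TRA", tn))
    ids <- c(ids, paste0("TRA.", seq_len(tn)))
    qual <- c(qual, rep(60, tn))
    alt <- c(alt, rep("<TRA>", tn))
    support <- c(support, tra_clusters$support)
    chr2 <- c(chr2, tra_clusters$chrom2)
  }
  n <- length(chrom)
  hdr <- VariantAnnotation::VCFHeader(samples = character(0))
  mrows <- c(list(fileformat = S4Vectors::DataFrame(
    Value = "VCFv4.2", row.names = "fileformat")),
    lapply(seq_along(meta), function(k)
      S4Vectors::DataFrame(Value = unname(meta[k]), row.names = names(meta)[k])))
  if (length(meta)) names(mrows)[-1] <- names(meta)
  VariantAnnotation::meta(hdr) <- do.call(IRanges::DataFrameList, mrows)
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1", "1", "1"),
    Type = c("String", "Integer", "Integer", "Integer", "String"),
    Description = c("SV type", "End position (or mate position for TRA)",
                    "SV length", "Number of supporting callers",
                    "Mate chromosome for TRA"),
    row.names = c("SVTYPE", "END", "SVLEN", "SUPPORT", "CHR2"))
  if (!n) {
    ## header-only VCF
    lines <- c("##fileformat=VCFv4.2",
               if (length(meta)) paste0("##", names(meta), "=", meta),
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    writeLines(lines, path)
    return(invisible(path))
  }
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  names(rr) <- make.unique(ids)
  if (!is.null(contigs)) {
    GenomeInfoDb::seqlevels(rr) <- names(contigs)
    GenomeInfoDb::seqlengths(rr) <- unname(contigs)
  }
  infoDF <- S4Vectors::DataFrame(
    SVTYPE = svtype, END = as.integer(round(endv)),
    SVLEN = as.integer(round(svlen)), SUPPORT = as.integer(support),
    CHR2 = chr2)
  fixedDF <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(rep("N", n)),
    ALT = IRanges::CharacterList(as.list(alt)),
    QUAL = as.numeric(qual), FILTER = rep("PASS", n))
  v <- VariantAnnotation::VCF(rowRanges = rr, fixed = fixedDF, info = infoDF,
                              collapsed = TRUE)
  VariantAnnotation::header(v) <- hdr
  ord <- order(chrom, pos)
  VariantAnnotation::writeVcf(v[ord], path)
  invisible(path)
}
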