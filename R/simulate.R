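## Synthetic long-read alignment generator. Alignment records carrying SV
## signatures are synthesized directly (no read aligner in the loop): the
## package tests signature handling, not mapping. Reads spanning a truth
## DEL/INS carry the corresponding D/I CIGAR operation (split-read geometry
## when the event exceeds the read length); INV emits split segments with
## inverted orientation; DUP emits reference-overlapping split segments; TRA
## emits cross-chromosome split pairs.

#' Simulation configuration
#'
#' @param contigs named vector of contig lengths (bp).
#' @param coverage target mean read depth.
#' @param read_len_mean,read_len_sd read length distribution (bp).
#' @param n_events named per-type event counts (INS, DEL, INV, DUP, TRA).
#' @param len_range named list of c(min, max) event lengths per type
#'   (all >= 50).
#' @param jitter_sd sd in bp of the per-read jitter on signature lengths.
#' @param small_indel_rate probability that a background read carries one
#'   sub-threshold (10-30 bp) insertion, exercising the signature length
#'   floor.
#' @param n_decoys named per-type decoy candidate counts; half are random
#'   signature-free loci, half truth copies shifted beyond the matcher's
#'   reference distance.
#' @param het when TRUE only half the spanning reads carry the signature
#'   (heterozygous); default FALSE (all carriers).
#' @param seed mandatory RNG seed.
#' @export
simConfig <- function(contigs = c(chr1 = 600000, chr2 = 400000),
                      coverage = 30,
                      read_len_mean = 1500, read_len_sd = 200,
                      n_events = c(INS = 8, DEL = 8, INV = 4, DUP = 4, TRA = 2),
                      len_range = list(INS = c(100, 600), DEL = c(100, 600),
                                       INV = c(300, 2000), DUP = c(300, 1200)),
                      jitter_sd = 10, small_indel_rate = 0.1,
                      n_decoys = c(INS = 4, DEL = 4, INV = 2, DUP = 2),
                      het = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(coverage > 0, all(unlist(len_range) >= 50))
  list(contigs = contigs, coverage = coverage,
       read_len_mean = read_len_mean, read_len_sd = read_len_sd,
       n_events = n_events, len_range = len_range, jitter_sd = jitter_sd,
       small_indel_rate = small_indel_rate, n_decoys = n_decoys,
       het = het, seed = as.integer(seed))
}

## Place non-TRA events on contigs with enough spacing that no read overlaps
## two events. Deterministic given the RNG state.
placeEvents <- function(cfg) {
  margin <- 2L * as.integer(cfg$read_len_mean + 4 * cfg$read_len_sd) + 2000L
  cursors <- pmin(cfg$contigs, 10000)
  names(cursors) <- names(cfg$contigs)
  rows <- list()
  types <- c("INS", "DEL", "INV", "DUP")
  plan <- unlist(lapply(types, function(tp)
    rep(tp, if (tp %in% names(cfg$n_events)) cfg$n_events[[tp]] else 0L)))
  ci <- 0L
  for (tp in plan) {
    lr <- cfg$len_range[[tp]]
    svl <- round(stats::runif(1, lr[1], lr[2]))
    placed <- FALSE
    for (try in seq_along(cfg$contigs)) {
      ci <- ci %% length(cfg$contigs) + 1L
      chrom <- names(cfg$contigs)[ci]
      footprint <- if (tp == "INS") margin else svl + margin
      if (cursors[chrom] + footprint + 10000 <= cfg$contigs[chrom]) {
        pos <- as.integer(cursors[chrom] + margin %/% 2L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = pos,
          end = if (tp == "INS") pos else pos + svl,
          svtype = tp, svlen = svl, stringsAsFactors = FALSE)
        cursors[chrom] <- cursors[chrom] + footprint
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("event of type ", tp, " (", svl, " bp) does not fit any contig; ",
           "enlarge contigs or reduce event counts")
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), pos = integer(),
                                    end = integer(), svtype = character(),
                                    svlen = integer())
  df$id <- if (nrow(df)) paste0("truth.", df$svtype, ".", seq_len(nrow(df))) else character()
  ## translocations: breakpoints on distinct contigs, in the untouched tail
  ntra <- if ("TRA" %in% names(cfg$n_events)) cfg$n_events[["TRA"]] else 0L
  tra <- NULL
  if (ntra > 0) {
    if (length(cfg$contigs) < 2L) stop("TRA events need at least two contigs")
    c1 <- names(cfg$contigs)[1]; c2 <- names(cfg$contigs)[2]
    p1 <- p2 <- numeric(ntra)
    for (k in seq_len(ntra)) {
      if (cursors[c1] + margin + 10000 > cfg$contigs[c1] ||
          cursors[c2] + margin + 10000 > cfg$contigs[c2])
        stop("TRA event does not fit contigs; enlarge contigs")
      p1[k] <- cursors[c1] + margin %/% 2L; cursors[c1] <- cursors[c1] + margin
      p2[k] <- cursors[c2] + margin %/% 2L; cursors[c2] <- cursors[c2] + margin
    }
    tra <- TraRecords(rep(c1, ntra), p1, rep(c2, ntra), p2,
                      caller = "truth", id = paste0("truth.TRA.", seq_len(ntra)))
  } else tra <- TraRecords()
  list(events = df, tra = tra, cursors = cursors)
}

cigarString <- function(ops, lens) {
  keep <- lens > 0
  paste0(as.integer(lens[keep]), ops[keep], collapse = "")
}

## One SAM line. Read offsets q1/q2 (0-based, original orientation) are
## encoded as soft clips; reverse segments get mirrored clips.
samLine <- function(qname, chrom, ref_pos0, cigar_core, q1, q2, read_len,
                    reverse = FALSE, supplementary = FALSE) {
  lead <- as.integer(if (reverse) read_len - q2 else q1)
  trail <- as.integer(if (reverse) q1 else read_len - q2)
  cigar <- paste0(if (lead > 0) paste0(lead, "S") else "", cigar_core,
                  if (trail > 0) paste0(trail, "S") else "")
  flag <- 0L + if (reverse) 16L else 0L
  flag <- flag + if (supplementary) 2048L else 0L
  paste(qname, flag, chrom, as.integer(ref_pos0) + 1L, 60L, cigar, "*", 0L,
        0L, "*", "*", sep = "\t")
}

## Alignment records for one read on `chrom` spanning [rs, re). `ev` is the
## (at most one) event overlapping the read; NULL for background reads.
readRecords <- function(qname, chrom, rs, re, ev, tra, cfg, carrier) {
  rl <- re - rs
  plain <- function() {
    ql <- rl
    if (stats::runif(1) < cfg$small_indel_rate && rl > 200) {
      at <- rl %/% 2L
      il <- as.integer(round(stats::runif(1, 10, 30)))
      core <- cigarString(c("M", "I", "M"), c(at, il, rl - at))
      ql <- rl + il
    } else core <- cigarString("M", rl)
    samLine(qname, chrom, rs, core, 0L, ql, ql)
  }
  if (is.null(ev) || !carrier) return(plain())
  s <- ev$pos; e <- ev$end; svl <- ev$svlen
  jit <- function(x) max(55L, as.integer(round(stats::rnorm(1, x, cfg$jitter_sd))))
  flank <- 300L
  if (ev$svtype == "DEL") {
    if (rs + flank <= s && e + flank <= re && svl + 2L * flank < rl) {
      dl <- jit(svl)
      a <- s - rs; b <- re - (s + dl)
      if (b < 50) return(plain())
      core <- cigarString(c("M", "D", "M"), c(a, dl, b))
      ql <- a + b
      return(samLine(qname, chrom, rs, core, 0L, ql, ql))
    }
    if (rs + flank <= s && re >= s + flank && re <= e) {
      ## read enters the deletion: split pair jumping s -> e
      k1 <- s - rs; k2 <- rl - k1
      return(c(samLine(qname, chrom, rs, cigarString("M", k1), 0L, k1, rl),
               samLine(qname, chrom, e, cigarString("M", k2), k1, rl, rl,
                       supplementary = TRUE)))
    }
    return(plain())
  }
  if (ev$svtype == "INS") {
    if (rs + flank <= s && s + flank <= re && svl + 2L * flank < rl) {
      il <- jit(svl)
      a <- s - rs; b <- re - s
      core <- cigarString(c("M", "I", "M"), c(a, il, b))
      ql <- a + il + b
      return(samLine(qname, chrom, rs, core, 0L, ql, ql))
    }
    return(plain())
  }
  if (ev$svtype == "INV") {
    segs <- NULL
    if (rs + flank <= s && e + flank <= re) {
      segs <- list(list(p = rs, w = s - rs, rev = FALSE, q1 = 0L),
                   list(p = s, w = e - s, rev = TRUE, q1 = s - rs),
                   list(p = e, w = re - e, rev = FALSE, q1 = e - rs))
    } else if (rs + flank <= s && s + flank <= re && re < e) {
      segs <- list(list(p = rs, w = s - rs, rev = FALSE, q1 = 0L),
                   list(p = e - (re - s), w = re - s, rev = TRUE, q1 = s - rs))
    } else if (s < rs && rs + flank <= e && e + flank <= re) {
      segs <- list(list(p = s, w = e - rs, rev = TRUE, q1 = 0L),
                   list(p = e, w = re - e, rev = FALSE, q1 = e - rs))
    }
    if (is.null(segs)) return(plain())
    segs <- Filter(function(g) g$w >= 100, segs)
    if (length(segs) < 2L) return(plain())
    return(vapply(seq_along(segs), function(k) {
      g <- segs[[k]]
      samLine(qname, chrom, g$p, cigarString("M", g$w), g$q1, g$q1 + g$w, rl,
              reverse = g$rev, supplementary = k > 1L)
    }, ""))
  }
  if (ev$svtype == "DUP") {
    if (rs + flank <= s && e + flank <= re) {
      ## read spans the whole duplicated unit: jump back from e to s
      k1 <- e - rs; k2 <- re - e
      return(c(samLine(qname, chrom, rs, cigarString("M", k1), 0L, k1, rl),
               samLine(qname, chrom, s, cigarString("M", k2), k1, rl, rl,
                       supplementary = TRUE)))
    }
    if (rs > s && e - rs >= flank && re - e >= flank && rl - svl >= 100) {
      ## read starts inside the first copy and crosses the junction; the two
      ## segments overlap on the reference by rl - svl
      k1 <- e - rs
      return(c(samLine(qname, chrom, rs, cigarString("M", k1), 0L, k1, rl),
               samLine(qname, chrom, s, cigarString("M", rl - k1), k1, rl, rl,
                       supplementary = TRUE)))
    }
    return(plain())
  }
  plain()
}

#' Simulate a long-read SV dataset
#'
#' Writes a coordinate-sorted indexed BAM, a truth VCF (including TRA
#' records) and a decoy-candidate VCF into \code{outdir}. Byte-identical
#' outputs for the same seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param outdir output directory (created).
#' @return list with paths (bam, sam, truth_vcf, decoy_vcf), the truth
#'   \linkS4class{SVCallSet}, truth \linkS4class{TraRecords}, the decoy
#'   \linkS4class{SVCallSet} with a \code{planted} manifest, and the contigs.
#' @export
simulateDataset <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  placed <- placeEvents(cfg)
  ev <- placed$events
  tra <- traTable(placed$tra)

  chunks <- list()
  for (chrom in names(cfg$contigs)) {
    L <- cfg$contigs[[chrom]]
    nreads <- ceiling(cfg$coverage * L / cfg$read_len_mean)
    rl <- pmax(500L, as.integer(round(stats::rnorm(nreads, cfg$read_len_mean,
                                                   cfg$read_len_sd))))
    rs <- as.integer(floor(stats::runif(nreads, 0, pmax(1, L - rl))))
    chrev <- ev[ev$chrom == chrom, , drop = FALSE]
    chtra <- tra[tra$chrom1 == chrom, , drop = FALSE]
    re <- rs + rl
    qnames <- sprintf("%s_read%06d", chrom, seq_len(nreads))
    carrier <- if (cfg$het) stats::runif(nreads) < 0.5 else rep(TRUE, nreads)
    ## at most one event can overlap a read (events are spaced wider than
    ## the read length), so an interval lookup finds it
    jt <- if (nrow(chtra)) findInterval(re - 301, chtra$pos1) else integer(nreads)
    tra_hit <- jt >= 1 & carrier
    tra_hit[tra_hit] <- chtra$pos1[jt[tra_hit]] > rs[tra_hit] + 300
    je <- if (nrow(chrev)) findInterval(re - 1, chrev$pos) else integer(nreads)
    ev_hit <- je >= 1 & !tra_hit
    ev_hit[ev_hit] <- pmax(chrev$end, chrev$pos + 1)[je[ev_hit]] > rs[ev_hit]
    special <- which(tra_hit | ev_hit)
    ## background reads, vectorized; a fraction carries one sub-threshold
    ## insertion
    plain_idx <- setdiff(seq_len(nreads), special)
    pl <- rl[plain_idx]
    noisy <- stats::runif(length(plain_idx)) < cfg$small_indel_rate & pl > 200
    ilen <- as.integer(round(stats::runif(length(plain_idx), 10, 30)))
    core <- ifelse(noisy,
                   sprintf("%dM%dI%dM", pl %/% 2L, ilen, pl - pl %/% 2L),
                   sprintf("%dM", pl))
    plain_lines <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                           qnames[plain_idx], chrom, rs[plain_idx] + 1L, core)
    recs <- vector("list", length(special))
    for (i in seq_along(special)) {
      k <- special[i]
      if (tra_hit[k]) {
        t1 <- as.list(chtra[jt[k], ])
        k1 <- as.integer(t1$pos1) - rs[k]; k2 <- rl[k] - k1
        recs[[i]] <- c(samLine(qnames[k], chrom, rs[k], cigarString("M", k1),
                               0L, k1, rl[k]),
                       samLine(qnames[k], t1$chrom2, as.integer(t1$pos2),
                               cigarString("M", k2), k1, rl[k], rl[k],
                               supplementary = TRUE))
      } else {
        e1 <- as.list(chrev[je[k], ])
        recs[[i]] <- readRecords(qnames[k], chrom, rs[k], re[k], e1, NULL,
                                 cfg, carrier[k])
      }
    }
    chunks[[chrom]] <- c(plain_lines, unlist(recs, use.names = FALSE))
  }
  lines <- unlist(chunks, use.names = FALSE)
  ## coordinate sort
  f <- strsplit(lines, "\t", fixed = TRUE)
  ord <- order(match(vapply(f, `[[`, "", 3), names(cfg$contigs)),
               as.integer(vapply(f, `[[`, "", 4)))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(cfg$contigs),
                   as.integer(cfg$contigs)))
  sam <- file.path(outdir, "reads.sam")
  writeLines(c(hdr, lines[ord]), sam)
  bam0 <- Rsamtools::asBam(sam, file.path(outdir, "reads_unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(outdir, "reads"))
  Rsamtools::indexBam(bam)
  unlink(bam0)

  truth <- SVCallSet(ev$chrom, ev$pos, ev$end, ev$svtype, ev$svlen,
                     id = ev$id, callers = "truth")
  truth_vcf <- file.path(outdir, "truth.vcf")
  tra_cl <- NULL
  if (nrow(tra))
    tra_cl <- data.frame(chrom1 = tra$chrom1, pos1 = tra$pos1,
                         chrom2 = tra$chrom2, pos2 = tra$pos2,
                         support = 1L, stringsAsFactors = FALSE)
  writeSVVcf(truth, truth_vcf, tra_clusters = tra_cl, contigs = cfg$contigs)

  decoys <- makeDecoys(cfg, ev, cursors = placed$cursors)
  decoy_vcf <- file.path(outdir, "decoys.vcf")
  writeSVVcf(decoys$callset, decoy_vcf, contigs = cfg$contigs)

  list(bam = bam, sam = sam, truth_vcf = truth_vcf, decoy_vcf = decoy_vcf,
       truth = truth, tra_truth = placed$tra, decoys = decoys$callset,
       decoy_manifest = decoys$manifest, contigs = cfg$contigs, config = cfg)
}

## Decoys: type-labeled candidates with no underlying signature. Half random
## signature-free loci (drawn from the event-free contig tails, away from any
## event), half truth copies shifted beyond the matcher's reference distance.
makeDecoys <- function(cfg, ev, refdist = 1000, cursors = NULL) {
  if (is.null(cursors)) {
    cursors <- stats::setNames(rep(10000, length(cfg$contigs)),
                               names(cfg$contigs))
  }
  rows <- list()
  for (tp in names(cfg$n_decoys)) {
    nd <- cfg$n_decoys[[tp]]
    if (!nd) next
    lr <- cfg$len_range[[tp]]
    tp_ev <- ev[ev$svtype == tp, , drop = FALSE]
    n_shift <- if (nrow(tp_ev)) nd %/% 2L else 0L
    n_rand <- nd - n_shift
    k <- 0L; tries <- 0L
    while (n_rand > 0) {
      chrom <- names(cfg$contigs)[k %% length(cfg$contigs) + 1L]; k <- k + 1L
      svl <- round(stats::runif(1, lr[1], lr[2]))
      lo <- cursors[[chrom]] + 5000
      hi <- cfg$contigs[[chrom]] - svl - 10000
      if (hi <= lo) {
        tries <- tries + 1L
        if (tries > 1000L)
          stop("no event-free space left for random decoys; enlarge contigs")
        next
      }
      pos <- round(stats::runif(1, lo, hi))
      near <- ev$chrom == chrom & abs(ev$pos - pos) < 5000 + svl + ev$svlen
      if (any(near)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, end = if (tp == "INS") pos else pos + svl,
        svtype = tp, svlen = svl, kind = "random", stringsAsFactors = FALSE)
      n_rand <- n_rand - 1L
    }
    if (n_shift > 0) {
      src <- tp_ev[rep_len(seq_len(nrow(tp_ev)), n_shift), , drop = FALSE]
      shift <- round(stats::runif(n_shift, refdist + 500, refdist + 2000)) *
        sample(c(-1, 1), n_shift, replace = TRUE)
      pos <- src$pos + shift
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = src$chrom, pos = pos,
        end = if (tp == "INS") pos else pos + src$svlen,
        svtype = tp, svlen = src$svlen, kind = "shifted",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), pos = numeric(),
                                    end = numeric(), svtype = character(),
                                    svlen = numeric(), kind = character())
  df$id <- if (nrow(df)) paste0("decoy.", df$svtype, ".", seq_len(nrow(df))) else character()
  cs <- SVCallSet(df$chrom, df$pos, df$end, df$svtype, df$svlen, id = df$id,
                  callers = "decoy")
  list(callset = cs, manifest = df)
}

#' Perturbed pseudo-caller callsets from a truth set
#'
#' Emulates the output of several upstream callers: each caller reports each
#' truth event with breakpoint jitter and small length error, missing a
#' fraction of events, plus the supplied decoys. Used to exercise merging and
#' the end-to-end pipeline.
#'
#' @param truth truth \linkS4class{SVCallSet}.
#' @param tra_truth truth \linkS4class{TraRecords}.
#' @param decoys decoy \linkS4class{SVCallSet} appended to every caller.
#' @param callers caller names.
#' @param pos_jitter_sd breakpoint jitter sd (bp).
#' @param miss_rate per-caller event drop probability.
#' @param seed RNG seed.
#' @return list(callsets = named list of SVCallSet, tras = named list of
#'   TraRecords).
#' @export
makePseudoCallsets <- function(truth, tra_truth = TraRecords(),
                               decoys = SVCallSet(),
                               callers = c("callerA", "callerB", "callerC"),
                               pos_jitter_sd = 30, miss_rate = 0.1,
                               seed = 1L) {
  set.seed(seed)
  td <- as.data.frame(truth)
  tt <- traTable(tra_truth)
  out <- list(); tras <- list()
  for (cal in callers) {
    keep <- stats::runif(nrow(td)) >= miss_rate
    d <- td[keep, , drop = FALSE]
    if (nrow(d)) {
      d$pos <- pmax(1, round(d$pos + stats::rnorm(nrow(d), 0, pos_jitter_sd)))
      d$svlen <- pmax(50, round(d$svlen * stats::runif(nrow(d), 0.92, 1.08)))
      d$end <- ifelse(d$svtype == "INS", d$pos, d$pos + d$svlen)
    }
    cs <- SVCallSet(d$chrom, d$pos, d$end, d$svtype, d$svlen,
                    id = paste0(cal, ".", seq_len(nrow(d))), callers = cal)
    if (length(decoys)) {
      dd <- as.data.frame(decoys)
      cs <- c(cs, SVCallSet(dd$chrom, dd$pos, dd$end, dd$svtype, dd$svlen,
                            id = paste0(cal, ".", dd$id), callers = cal))
    }
    out[[cal]] <- cs
    if (nrow(tt)) {
      keep <- stats::runif(nrow(tt)) >= miss_rate
      t2 <- tt[keep, , drop = FALSE]
      tras[[cal]] <- TraRecords(t2$chrom1,
                                t2$pos1 + round(stats::rnorm(nrow(t2), 0, pos_jitter_sd)),
                                t2$chrom2,
                                t2$pos2 + round(stats::rnorm(nrow(t2), 0, pos_jitter_sd)),
                                caller = cal)
    } else tras[[cal]] <- TraRecords()
  }
  list(callsets = out, tras = tras)
}

#' Build a labeled training image set from a simulated dataset
#'
#' Encodes truth events (positives) and decoys (negatives). Optionally plants
#' "mislabeled" negatives: additional copies of truth events carrying a
#' negative label, flagged in the manifest for mislabel-recovery tests.
#'
#' @param sim output of \code{\link{simulateDataset}}.
#' @param config an \code{\link{encoderConfig}}.
#' @param mislabel_fraction fraction of truth events duplicated as flagged
#'   false negatives (default 0).
#' @param seed RNG seed for the mislabel draw.
#' @return list(images = \linkS4class{SVImageSet}, manifest =
#'   data.frame(id, svtype, label, planted_mislabel)).
#' @export
makeTrainingFixture <- function(sim, config = encoderConfig(),
                                mislabel_fraction = 0, seed = 1L) {
  pos <- encodeCallset(sim$bam, sim$truth, config,
                       labels = rep("positive", length(sim$truth)),
                       contigs = sim$contigs)
  neg <- encodeCallset(sim$bam, sim$decoys, config,
                       labels = rep("negative", length(sim$decoys)),
                       contigs = sim$contigs)
  images <- c(pos, neg)
  planted <- rep(FALSE, length(imageIDs(images)))
  if (mislabel_fraction > 0) {
    set.seed(seed)
    nt <- length(sim$truth)
    pick <- sort(sample(nt, round(nt * mislabel_fraction)))
    if (length(pick)) {
      extra <- pos[pick]
      extra@labels <- rep("negative", length(pick))
      extra@ids <- paste0(extra@ids, ".mislabeled")
      images <- c(images, extra)
      planted <- c(planted, rep(TRUE, length(pick)))
    }
  }
  manifest <- data.frame(id = imageIDs(images), svtype = imageTypes(images),
                         label = imageLabels(images),
                         planted_mislabel = planted, stringsAsFactors = FALSE)
  list(images = images, manifest = manifest)
}
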