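# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: the CIGAR walker parses the string character by character,
# the channel oracle evaluates each encoding rule separately, the flattening
# oracle is a naive double loop, and the TRA oracle clusters by transitive
# closure over the pairwise predicate.

# Single-pass character-level CIGAR interpreter. Returns I/D fragments of
# length >= min_len, 0-based half-open, for a read starting at pos0.
oracleCigarWalk <- function(cigar, pos0, min_len) {
  nums <- as.numeric(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  ref <- pos0
  out <- list()
  for (k in seq_along(ops)) {
    n <- nums[k]
    if (ops[k] %in% c("M", "=", "X")) {
      ref <- ref + n
    } else if (ops[k] == "D" || ops[k] == "N") {
      if (ops[k] == "D" && n >= min_len)
        out[[length(out) + 1L]] <- data.frame(start = ref, end = ref + n,
                                              sig_type = "DEL")
      ref <- ref + n
    } else if (ops[k] == "I") {
      if (n >= min_len)
        out[[length(out) + 1L]] <- data.frame(start = ref, end = ref + n,
                                              sig_type = "INS")
    }
    # S/H/P consume no reference
  }
  if (!length(out)) return(data.frame(start = numeric(), end = numeric(),
                                      sig_type = character()))
  do.call(rbind, out)
}

# Channel rules, one predicate at a time, straight from their statements.
oracleChannels <- function(frag, windows, rec) {
  if (rec$svtype == "INV") {
    B <- frag$source == "split"
    R <- isTRUE(frag$orientation_discordant)
  } else {
    B <- FALSE
    for (k in seq_len(nrow(windows)))
      if (frag$start >= windows$start[k] && frag$end <= windows$end[k]) B <- TRUE
    R <- (frag$end - frag$start) < 2 * rec$svlen
  }
  mid <- (frag$start + frag$end) / 2
  G <- mid >= rec$pos && mid <= rec$end
  c(R = if (R) 255L else 0L, G = if (G) 255L else 0L, B = if (B) 255L else 0L)
}

# Naive double-loop image flattening.
oracleFlatten <- function(px, omega) {
  d <- dim(px)
  out <- numeric(d[2])
  for (j in seq_len(d[2])) {
    acc <- 0
    for (k in seq_len(d[1]))
      acc <- acc + px[k, j, 1] * omega^2 + px[k, j, 2] * omega + px[k, j, 3]
    out[j] <- acc
  }
  out
}

# Transitive-closure TRA clustering: connected components of the pairwise
# same-event graph, then the caller-support threshold.
oracleTraClusters <- function(df, gamma, c0) {
  n <- nrow(df)
  if (!n) return(list())
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      same <- df$chrom1[i] == df$chrom1[j] && df$chrom2[i] == df$chrom2[j] &&
        abs(df$pos1[i] - df$pos1[j]) <= gamma &&
        abs(df$pos2[i] - df$pos2[j]) <= gamma
      if (same && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comps <- split(seq_len(n), comp)
  Filter(function(idx) length(unique(df$caller[idx])) >= c0, comps)
}

# Split-pair classification straight from the three arithmetic predicates.
oraclePairClass <- function(s1, s2, min_delta) {
  if (s1$is_reverse != s2$is_reverse) return("INV")
  overlap <- min(s1$ref_end, s2$ref_end) - max(s1$ref_start, s2$ref_start)
  if (overlap > 0) return("DUP")
  read_gap <- s2$read_start - s1$read_end
  ref_gap <- if (!s1$is_reverse) s2$ref_start - s1$ref_end
             else s1$ref_start - s2$ref_end
  if (ref_gap - read_gap > min_delta) return("DEL")
  if (read_gap - ref_gap > min_delta) return("INS")
  "none"
}
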