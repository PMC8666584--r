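# Independent brute-force oracles used to verify the implementation.
# These deliberately use the most literal possible computation.

# Character-level intron excision + CCA oracle.
oracle_mature <- function(sequence, introns) {
  chars <- strsplit(sequence, "")[[1]]
  drop <- unlist(lapply(introns, function(iv) iv[1]:iv[2]))
  if (length(drop) > 0) chars <- chars[-drop]
  paste0(paste(chars, collapse = ""), "CCA")
}

# Per-read loop pileup oracle.
oracle_pileup <- function(alignments, len) {
  depth <- integer(len)
  starts <- integer(len)
  for (i in seq_len(nrow(alignments))) {
    s <- alignments$start[i]
    e <- alignments$end[i]
    starts[s] <- starts[s] + 1L
    for (p in s:e) depth[p] <- depth[p] + 1L
  }
  list(depth = depth, starts = starts)
}

# Exhaustive sign-assignment null for the Wilcoxon signed-rank test
# (assumes no zero differences and no tied absolute differences).
oracle_signed_rank_p <- function(x, y, alternative = "two.sided") {
  d <- x - y
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = if (v_obs > n * (n + 1) / 4) min(1, 2 * p_ge) else
           min(1, 2 * p_le))
}

# Exhaustive group-assignment null for the Mann-Whitney U test
# (assumes no ties across the pooled sample).
oracle_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  if (u_obs > na * length(b) / 2) min(1, 2 * p_ge) else min(1, 2 * p_le)
}

# Spreadsheet-style ddCt oracle.
oracle_ddct <- function(t_ct, r_ct, cal_t_ct, cal_r_ct) {
  2^(-((t_ct - r_ct) - (cal_t_ct - cal_r_ct)))
}

# Position-by-position motif tally oracle.
oracle_motif_counts <- function(sequences, positions, flank) {
  counts <- matrix(0L, 4, 2 * flank + 1,
                   dimnames = list(c("A", "C", "G", "T"),
                                   as.character(-flank:flank)))
  for (i in seq_along(sequences)) {
    for (off in -flank:flank) {
      pos <- positions[i] + off
      if (pos >= 1 && pos <= nchar(sequences[i])) {
        b <- substr(sequences[i], pos, pos)
        counts[b, as.character(off)] <- counts[b, as.character(off)] + 1L
      }
    }
  }
  counts
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
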