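# Independent oracles used by the property and acceptance tests. These are
# deliberately naive (loops, enumeration, direct formulas) and must stay
# independent of the implementation paths they check.

# Brute-force any-overlap scan: which peak rows overlap region by >= 1 bp.
oracle_overlap_scan <- function(peaks, region) {
  hit <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    hit[i] <- peaks$chrom[i] == region$chrom &&
      min(peaks$end[i], region$end) - max(peaks$start[i], region$start) >= 1
  }
  which(hit)
}

# Per-base summation oracle for gene signal on disjoint peaks: walk every
# base of the region, collect the distinct peaks covering any base, sum
# their RPM.
oracle_gene_signal <- function(rpm_vec, peaks, region) {
  seen <- character(0)
  for (b in seq(region$start, region$end - 1L)) {
    for (i in seq_len(nrow(peaks))) {
      if (peaks$chrom[i] == region$chrom &&
          b >= peaks$start[i] && b < peaks$end[i])
        seen <- union(seen, peaks$peak_id[i])
    }
  }
  if (!length(seen)) 0 else sum(rpm_vec[seen])
}

# Exact hypergeometric min-tail RSA oracle via Pascal's triangle. All
# binomials for N <= 30 are integers < 2^53, so double arithmetic on them
# is exact; the single final division is correctly rounded.
oracle_choose_table <- function(N) {
  C <- matrix(0, N + 1, N + 1)
  C[, 1] <- 1
  for (n in 1:N) for (k in 1:n) {
    C[n + 1, k + 1] <- C[n, k] + C[n, k + 1]
  }
  C
}

oracle_rsa_p <- function(ranks, N) {
  C <- oracle_choose_table(N)
  ch <- function(n, k) if (k < 0 || k > n) 0 else C[n + 1, k + 1]
  ranks <- sort(ranks)
  k <- length(ranks)
  p_best <- Inf
  for (j in seq_len(k)) {
    r <- ranks[j]
    num <- 0
    for (i in j:min(k, r)) num <- num + ch(k, i) * ch(N - k, r - i)
    p_best <- min(p_best, num / ch(N, r))
  }
  p_best
}

# Direct O(n^2) step-up formula: q_i = min over {j : p_j >= p_i} of
# p_j * m / rank_j, clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p * m / rk
    q[i] <- min(1, min(cand[p >= p[i]]))
  }
  q
}

# Exhaustive rollup decision rule on explicit peak category/delta lists.
oracle_rollup <- function(categories, deltas) {
  if (!length(categories)) return("not_covered")
  n_inc <- sum(categories == "increased")
  n_red <- sum(categories == "reduced")
  if (n_inc > 0 && n_red == 0) return("increased")
  if (n_red > 0 && n_inc == 0) return("reduced")
  if (n_inc == 0 && n_red == 0) return("unchanged")
  s_inc <- sum(abs(deltas[categories == "increased"]))
  s_red <- sum(abs(deltas[categories == "reduced"]))
  if (s_inc > s_red) "increased" else if (s_red > s_inc) "reduced"
  else "unchanged"
}
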