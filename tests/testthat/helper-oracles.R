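# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery (IRanges) and stats shortcuts so that agreement is a
# genuine cross-check.

# All-pairs scan: does position (chrom, pos) fall in any [start, end)?
oracle_overlap <- function(positions, features) {
  vapply(seq_len(nrow(positions)), function(i) {
    any(features$chrom == positions$chrom[i] &
          features$start <= positions$pos[i] &
          positions$pos[i] < features$end)
  }, logical(1))
}

# Exhaustive min gap to any interval on the same chromosome (NA if none).
# The gap counts the bases strictly between the position and the interval's
# covered bases, so a position at `end` (or `start - 1`) has gap 0.
oracle_distance <- function(positions, features) {
  vapply(seq_len(nrow(positions)), function(i) {
    f <- features[features$chrom == positions$chrom[i], , drop = FALSE]
    if (nrow(f) == 0) return(NA_integer_)
    p <- positions$pos[i]
    d <- ifelse(f$start <= p & p < f$end, 0L,
                ifelse(p >= f$end, p - f$end, f$start - p - 1L))
    as.integer(min(d))
  }, integer(1))
}

# Hand step-up BH: q_i = min over j >= i (sorted) of p_(j) * n / j, capped 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Hypergeometric point mass from factorial arithmetic (log scale).
oracle_dhyper <- function(x, K, n, N) {
  if (x < max(0, n - (N - K)) || x > min(K, n)) return(0)
  exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
}

# Upper tail P(X >= k) by direct summation of the point mass.
oracle_hyper_upper <- function(k, K, n, N) {
  xs <- k:min(K, n)
  if (length(xs) == 0) return(0)
  sum(vapply(xs, oracle_dhyper, numeric(1), K = K, n = n, N = N))
}

# Two-sided Fisher p: sum of probabilities of all tables with the observed
# margins whose probability is <= that of the observed table.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- vapply(xs, oracle_dhyper, numeric(1), K = c1, n = r1, N = N)
  p_obs <- oracle_dhyper(a, K = c1, n = r1, N = N)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random positions/features fixture on a couple of chromosomes.
random_interval_fixture <- function(n_pos, n_feat, seed) {
  withr::with_seed(seed, {
    list(
      positions = tibble::tibble(
        chrom = sample(c("chr1", "chr2"), n_pos, replace = TRUE),
        pos = sample.int(100000, n_pos, replace = TRUE) - 1L),
      features = feature_set(tibble::tibble(
        chrom = sample(c("chr1", "chr2"), n_feat, replace = TRUE),
        start = st <- sample.int(99000, n_feat, replace = TRUE) - 1L,
        end = st + sample.int(500, n_feat, replace = TRUE))))
  })
}
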