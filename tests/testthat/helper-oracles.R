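# Independent oracles and shared fixtures. Every oracle here recomputes the
# quantity by brute force (per-base expansion, full enumeration) and never
# calls the code path it checks.

# signal in [a, b) on one chromosome by direct interval-overlap summation
# over the RAW (possibly overlapping) input intervals
oracle_window_sum <- function(iv, chrom, a, b) {
  iv <- iv[iv$chrom == chrom, , drop = FALSE]
  a <- max(a, 0); b <- max(b, 0)
  if (!nrow(iv) || b <= a) return(0)
  sum(pmax(0, pmin(b, iv$end) - pmax(a, iv$start)) * iv$value)
}

# per-base expansion of raw intervals over [0, limit)
oracle_per_base <- function(iv, chrom, limit) {
  v <- numeric(limit)
  iv <- iv[iv$chrom == chrom, , drop = FALSE]
  for (j in seq_len(nrow(iv))) {
    lo <- max(iv$start[j], 0) + 1
    hi <- min(iv$end[j], limit)
    if (hi >= lo) v[lo:hi] <- v[lo:hi] + iv$value[j]
  }
  v
}

# random raw interval set with integer values (keeps both summation orders
# exact in double arithmetic)
random_intervals <- function(n, max_pos = 5000, max_len = 400,
                             max_val = 20, chrom = "chr1") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             value = sample.int(max_val, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

track_from_intervals <- function(iv, ...) {
  coverage_track(iv$chrom, iv$start, iv$end, iv$value, ...)
}

# exact two-sided Mann-Whitney p by full enumeration over all C(N, nx)
# rank assignments (tie-free samples only)
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- colSums(matrix(seq_len(nx + ny)[combos], nrow = nx)) -
    nx * (nx + 1) / 2
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# exact two-sided Fisher p by explicit fixed-margin table enumeration with
# choose() arithmetic (minimum-likelihood rule)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  tot <- choose(m + n, k)
  probs <- choose(m, support) * choose(n, k - support) / tot
  obs <- choose(m, a) * choose(n, k - a) / tot
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# shared large synthetic dataset for acceptance-style checks (built once
# per test run)
acceptance_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(synthetic_config(n_genes = 2000,
                                                  seed = 42))
    cache
  }
})

rbind_genes <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("gene_models", "data.frame")
  out
}

# small quick dataset for unit tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(synthetic_config(
        n_genes = 150, depth = 2e5, expr_depth = 2e5, seed = 11))
    cache
  }
})
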