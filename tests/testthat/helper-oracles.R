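# Independent brute-force oracles, deliberately written as straight-line
# recomputations (sort-and-slice, exhaustive enumeration) so they share no
# code path with the package implementation.

# random gene x library count matrix with skewed counts
random_count_matrix <- function(n_genes, n_libs = 2L, seed = 1L,
                                zero_prop = 0.05) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_libs,
                    lambda = exp(runif(n_genes * n_libs, 1, 7))),
              nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("lib", seq_len(n_libs))))
  if (zero_prop > 0) {
    z <- sample(length(m), ceiling(zero_prop * length(m)))
    m[z] <- 0
  }
  m
}

# straight-line TMM log2 factor: recompute M, A, weights, the per-tail
# floor trim via explicit sorting, and the weighted mean
oracle_tmm_log2 <- function(m, k, r, m_trim = 0.30, a_trim = 0.05,
                            a_min = NULL, weighted = TRUE) {
  yk <- m[, k]; yr <- m[, r]
  nk <- sum(m[, k]); nr <- sum(m[, r])
  ok <- yk > 0 & yr > 0
  yk <- yk[ok]; yr <- yr[ok]
  M <- log2(yk / nk) - log2(yr / nr)
  A <- (log2(yk / nk) + log2(yr / nr)) / 2
  w <- 1 / ((nk - yk) / (nk * yk) + (nr - yr) / (nr * yr))
  if (!is.null(a_min)) {
    keep <- A >= a_min
    M <- M[keep]; A <- A[keep]; w <- w[keep]
  }
  n <- length(M)
  # mid-rank of each value computed from first principles: number of
  # strictly smaller values plus half the tied group (ties share a rank,
  # so a tied group survives or falls together)
  midrank <- function(v) vapply(v, function(x)
    sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
  band <- function(v, frac) {
    r <- midrank(v)
    r >= floor(n * frac) + 1 & r <= n - floor(n * frac)
  }
  sel <- which(band(M, m_trim) & band(A, a_trim))
  if (!weighted) w <- rep(1, n)
  sum(w[sel] * M[sel]) / sum(w[sel])
}

# exhaustive minimum-likelihood two-sided binomial p-value
oracle_binom_p <- function(y1, t, pr) {
  if (t == 0) return(1)
  probs <- dbinom(0:t, t, pr)
  min(1, sum(probs[probs <= probs[y1 + 1L] * (1 + 1e-7)]))
}

# write a small count table to a temp file, return the path
write_temp_counts <- function(m) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
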