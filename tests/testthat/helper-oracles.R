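# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Step-up BH adjustment by direct enumeration of the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# Two-sided Fisher exact p by exhaustive enumeration over the
# hypergeometric support of a 2x2 table (a b / c d).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  probs <- vapply(support, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  }, 0)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact binomial upper tail P(X >= k) by term-wise summation.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# Brute-force variant merge: plain group-by-and-sum on a data.frame.
merge_oracle <- function(meta, abundance) {
  pos <- vapply(strsplit(meta$positions, ";"), function(v) {
    paste(sort(as.integer(v[nzchar(v)])), collapse = "+")
  }, "")
  keep <- pos != "" & !grepl(";", meta$locus, fixed = TRUE)
  key <- paste(meta$locus[keep], pos[keep], sep = ":")
  rowsum(abundance[keep, , drop = FALSE], group = key)
}

# A 15-mer window of all 'A' with the given residue placed at a window
# position (-7..7).
make_window <- function(res_at = list(), fill = "A") {
  w <- rep(fill, 15)
  for (p in names(res_at)) w[as.integer(p) + 8] <- res_at[[p]]
  paste(w, collapse = "")
}

# Small random quant table on the standard LD design.
random_ld_table <- function(n = 10, seed = 1) {
  withr::with_seed(seed, {
    keys <- as.vector(outer(c(0, 4, 8, 12, 16, 20), LETTERS[1:5],
                            function(z, r) format_sample_keys("LD", z, r)))
    ab <- matrix(stats::rlnorm(n * 30, 5, 1), n, 30,
                 dimnames = list(sprintf("f%03d", 1:n), keys))
    quant_table(ab)
  })
}
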