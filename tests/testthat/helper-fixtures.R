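# shared fixture builders and independent oracles

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# alignment pair with exactly n differing sites out of len
pair_with_p <- function(len, n_diff, seed = 1) {
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  b <- a
  idx <- sample(len, n_diff)
  for (i in idx) b[i] <- setdiff(c("A", "C", "G", "T"), a[i])[1]
  c(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins, probability by the hypergeometric mass written out with choose()
fisher_brute <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  total <- choose(m + n, k)
  xs <- max(0, k - n):min(k, m)
  probs <- sapply(xs, function(x) choose(m, x) * choose(n, k - x) / total)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hamming distance between two equal-length strings
hamming <- function(x, y) sum(str_chars(x) != str_chars(y))
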