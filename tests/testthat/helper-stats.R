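# Independent full-enumeration oracle for the exact two-sided Mann-Whitney
# p-value: evaluates every choose(n + m, n) assignment of the pooled midranks.
mwu_brute_force <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(n)])
  subsets <- utils::combn(N, n)
  w <- colSums(matrix(r[subsets], nrow = n))
  min(1, 2 * min(mean(w <= wobs + 1e-9), mean(w >= wobs - 1e-9)))
}
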