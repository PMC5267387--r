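# Independent pure-R oracle for the exact null distribution at desk scale.
# For k, n <= 6 the total {k(k-1)}^n is below 2^53, so plain doubles hold all
# counts exactly and no big-integer arithmetic is involved: this oracle is
# fully independent of the compiled engine it checks.

oracle_counts <- function(k, n) {
  base <- vapply(-(k - 1):(k - 1), function(t) if (t == 0) 0 else k - abs(t),
                 numeric(1))
  cur <- 1
  for (b in seq_len(n)) {
    nxt <- numeric(length(cur) + length(base) - 1)
    for (i in seq_along(cur)) {
      if (cur[i] == 0) next
      idx <- seq_along(base) + i - 1
      nxt[idx] <- nxt[idx] + cur[i] * base
    }
    cur <- nxt
  }
  cur  # indexed d = -n(k-1) .. n(k-1)
}

oracle_tail <- function(d, k, n) {
  cnt <- oracle_counts(k, n)
  off <- n * (k - 1) + 1
  sum(cnt[seq.int(off + d, length(cnt))])
}

oracle_pvalue_ge <- function(d, k, n) {
  if (d == 0) return(1)
  2 * oracle_tail(d, k, n) / (k * (k - 1))^n
}

small_grid <- expand.grid(k = 2:6, n = 1:6)
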