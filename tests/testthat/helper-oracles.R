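# Independent oracles the implementation is checked against.

# Brute-force two-sided exact rank-sum p: enumerate every assignment of the
# pooled observations to group labels and tabulate the rank-sum null
# directly. Independent of the dynamic program in rank_sum_exact().
brute_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2L, function(idx) sum(rk[idx]))
  lower <- mean(ws <= w_obs)
  upper <- mean(ws >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Closed-form Pearson statistic for a 2x2 table: N (ad - bc)^2 over the
# product of the four marginals.
chi2_2x2_closed_form <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- sum(m)
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}
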