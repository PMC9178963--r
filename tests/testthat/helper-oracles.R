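# Brute-force midrank oracle for Dunn's z statistics, written independently
# of the package implementation (explicit loops, no shared helpers).
dunn_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- numeric(n)
  # midrank = (#strictly below) + (#tied + 1) / 2
  for (i in seq_len(n)) r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  tie_tab <- table(x)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  vt <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  out <- NULL
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      zi <- mean(r[idx == i]) - mean(r[idx == j])
      se <- sqrt(vt * (1 / sizes[i] + 1 / sizes[j]))
      out <- rbind(out, data.frame(i = i, j = j, z = zi / se))
    }
  }
  out
}
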