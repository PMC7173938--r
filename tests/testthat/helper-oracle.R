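# Independent oracles used across tests.

# Binomial point probability computed from log-factorial sums, independent of
# the dbinom() code path used by the package.
pmf_oracle <- function(k, n, p) {
  lg <- function(m) if (m < 1) 0 else sum(log(seq_len(m)))
  vapply(k, function(ki) {
    exp(lg(n) - lg(ki) - lg(n - ki) + ki * log(p) + (n - ki) * log1p(-p))
  }, numeric(1))
}

# Brute-force threshold scan built on the oracle pmf.
thresholds_oracle <- function(a, n, criterion) {
  k <- 0:n
  keep <- pmf_oracle(k, n, 1 / a) - criterion > 1e-12
  if (!any(keep)) return(list(degenerate = TRUE))
  list(degenerate = FALSE,
       lower_hits = min(k[keep]), upper_hits = max(k[keep]),
       lower = min(k[keep]) / n, upper = max(k[keep]) / n)
}

round3 <- function(x) floor(x * 1000 + 0.5) / 1000

# Grid used by the published threshold tables.
published_trials <- c(2, 4, 6, 8, 10, 15, 20, 25, 30, 40, 50, 100)
published_alternatives <- 2:10

read_published_table <- function(which = c("one-sided", "two-sided")) {
  which <- match.arg(which)
  read.csv(test_path(sprintf("published-thresholds-%s.csv", which)),
           check.names = FALSE)
}
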