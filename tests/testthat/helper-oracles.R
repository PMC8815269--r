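# Independent oracles, kept algorithmically distinct from the package
# implementations they check.

# Running-sum oracle: walk the ranked list position by position, stepping
# the set's empirical CDF at hits, and track the largest excursions above
# and below the uniform diagonal.
ksOracle <- function(positions, n) {
  positions <- sort(positions)
  t <- length(positions)
  cum <- 0
  above <- -Inf
  below <- -Inf
  for (i in seq_len(n)) {
    if (i %in% positions) {
      below <- max(below, i / n - cum)
      cum <- cum + 1 / t
    }
    above <- max(above, cum - i / n)
  }
  # the implementation breaks exact above/below ties toward the negative
  # branch; excursion differences are multiples of 1/(t*n), far above
  # float accumulation noise, so a tiny epsilon reproduces the rule
  if (above > below + 1e-9) above else -below
}

# Exact Mann-Whitney oracle: enumerate every C(n+m, n) assignment of the
# pooled values to the two groups and compare U statistics.
mwOracle <- function(x, y, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  uObs <- uOf(seq_len(n))
  uNull <- combn(length(pooled), n, uOf)
  pg <- mean(uNull >= uObs)
  pl <- mean(uNull <= uObs)
  if (alternative == "greater") pg else min(1, 2 * min(pg, pl))
}

# Brute-force co-occurrence tally over every (drug, list) pair.
mergeOracle <- function(lists, cutoff) {
  drugs <- sort(unique(unlist(lists)))
  counts <- vapply(drugs, function(d)
    sum(vapply(lists, function(l) d %in% l, logical(1))), integer(1))
  list(counts = counts, kept = sort(drugs[counts >= cutoff]))
}
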