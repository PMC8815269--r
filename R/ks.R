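#' Kolmogorov-Smirnov running-sum enrichment score
#'
#' The unweighted two-sided running-sum statistic of the Connectivity-Map
#' family, the primitive behind every enrichment level of the screen: genes
#' in pathways, pathways in a pathway-rank profile, and drugs in a
#' drug ranking. Given the positions (ranks) that a set of \eqn{t} items
#' occupies inside a total ranking of \eqn{n} items, with sorted positions
#' \eqn{p_1 < \dots < p_t}, let
#' \deqn{a = \max_j (j/t - p_j/n), \qquad b = \max_j (p_j/n - (j-1)/t).}
#' The score is \eqn{a} if \eqn{a > b} and \eqn{-b} otherwise. Positive
#' scores mean the set concentrates at the top of the ranking (most
#' up-regulated side), negative at the bottom; the score always lies in
#' \eqn{(-1, 1]}.
#'
#' @param positions Integer vector of distinct positions in \code{1..n}
#'   (any order; sorted internally).
#' @param n Size of the ranked universe.
#' @return A single numeric enrichment score.
#' @examples
#' ksStatistic(c(1, 2), 10)   #  0.8 : concentrated at the top
#' ksStatistic(c(9, 10), 10)  # -0.9 : concentrated at the bottom
#' ksStatistic(1:10, 10)      # -0.1 : the whole universe, forced to -1/n
#' @export
ksStatistic <- function(positions, n) {
  n <- stopIfNot1(as.integer(n), "n")
  if (length(positions) == 0L)
    stop("'positions' must be non-empty", call. = FALSE)
  p <- as.integer(positions)
  if (anyNA(p) || any(p < 1L) || any(p > n))
    stop("positions must lie in 1..n", call. = FALSE)
  if (anyDuplicated(p))
    stop("positions must be distinct", call. = FALSE)
  p <- sort.int(p)
  t <- length(p)
  j <- as.numeric(seq_len(t))
  # excursion maxima as exact integer numerators over the common
  # denominator t*n, so the a-vs-b comparison (ties go to the negative
  # branch) never depends on float rounding
  a <- max(j * n - p * t)
  b <- max(p * t - (j - 1) * n)
  if (a > b) a / (t * n) else -b / (t * n)
}

# Null distribution of the score for random size-t subsets of 1..n.
# For a fixed ranking, a random same-size set occupies a uniform random
# subset of positions, so the null depends only on (t, n); one table is
# shared across pathways/instances of the same size. Uses the current RNG.
ksNullScores <- function(t, n, nPerm) {
  vapply(seq_len(nPerm),
    function(i) ksStatistic(sample.int(n, t), n), numeric(1))
}

# Deterministic null tables for a set of sizes: size s uses sub-seed
# (seed, s) so results do not depend on which sizes are requested together.
ksNullTable <- function(sizes, n, nPerm, seed) {
  sizes <- sort(unique(as.integer(sizes)))
  nulls <- lapply(sizes, function(t)
    withSeed(subSeed(seed, t), ksNullScores(t, n, nPerm)))
  names(nulls) <- as.character(sizes)
  nulls
}
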