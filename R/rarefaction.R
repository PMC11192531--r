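# Exact average gene-accumulation curves.
#
# The expected number of distinct genes discovered in a random subset of x of
# the n sampled individuals, averaged over ALL C(n, x) subsets, has a
# hypergeometric closed form per gene: a gene carried by m individuals is
# missed by a subset with probability C(n-m, x) / C(n, x). Summing the
# complement over genes gives the curve exactly in O(genes * n), equivalent
# to (but vastly cheaper than) enumerating every subset and averaging the
# per-step increments. The enumeration is kept as a test oracle.

#' Number of weighted subset choices at step x
#'
#' The number of ways to choose `x - 1` individuals out of `n` and then add
#' one more not yet chosen: `C(n, x-1) * (n - x + 1)`, which equals
#' `C(n, x) * x`. Both forms are computed and checked against each other.
#'
#' @param n sample size (positive integer).
#' @param x step, `1 <= x <= n`.
#' @return the weight, as a double (exact for the sizes used here).
#' @export
subset_weight <- function(n, x) {
  stopifnot(n >= 1, x >= 1, x <= n)
  w <- choose(n, x - 1) * (n - x + 1)
  w2 <- choose(n, x) * x
  stopifnot(isTRUE(all.equal(w, w2)))
  w
}

# P(gene with occupancy m is absent from a uniform random x-subset of n).
# Computed as a product of <= x factors for numerical stability; exactly 0
# once x > n - m.
subset_miss_prob <- function(m, n, x) {
  if (x > n - m) return(0)
  if (m == 0L) return(1)
  prod((n - m - seq_len(x) + 1) / (n - seq_len(x) + 1))
}

#' Expected cumulative gene count at sample size x
#'
#' Closed-form mean, over all `C(n, x)` equally likely subsets of the sample,
#' of the number of distinct genes present in at least one subset member:
#' `G(x) = sum_g (1 - C(n - m_g, x) / C(n, x))`.
#'
#' @param occ an `occupancy_vector` (see [occupancy()]).
#' @param x sample size, `1 <= x <= n`.
#' @return expected cumulative count (real-valued).
#' @export
expected_cumulative <- function(occ, x) {
  stopifnot(inherits(occ, "occupancy_vector"))
  n <- occ$n
  if (length(x) != 1L || x < 1 || x > n) stop("x out of range", call. = FALSE)
  tab <- table(occ$m)
  ms <- as.integer(names(tab))
  miss <- vapply(ms, subset_miss_prob, numeric(1), n = n, x = x)
  sum(as.integer(tab) * (1 - miss))
}

new_accumulation_curve <- function(scope, G) {
  n <- length(G)
  structure(
    data.frame(scope = rep(scope, n), x = seq_len(n), G = G,
               delta = diff(c(0, G))),
    class = c("accumulation_curve", "data.frame")
  )
}

#' Exact average accumulation (rarefaction) curve
#'
#' For each sample size `x = 1..n`, the mean cumulative number of distinct
#' genes discovered across all possible x-subsets of the in-scope
#' individuals, plus the mean per-step increment `delta(x) = G(x) - G(x-1)`
#' (with `G(0) = 0`). The curve is exact, not a Monte-Carlo estimate; it is
#' nondecreasing with nonincreasing increments and ends at the observed pan
#' size.
#'
#' @param x a `presence_matrix`, or an `occupancy_vector` already restricted
#'   to the desired scope.
#' @param scope population label or `"ALL"` (ignored for occupancy input).
#' @return an `accumulation_curve` data frame: scope, x, G, delta.
#' @export
accumulation_curve <- function(x, scope = "ALL") {
  occ <- if (inherits(x, "occupancy_vector")) x else occupancy(x, scope)
  if (occ$n < 1L) stop("scope has no individuals", call. = FALSE)
  G <- vapply(seq_len(occ$n), function(k) expected_cumulative(occ, k),
              numeric(1))
  new_accumulation_curve(occ$scope, G)
}

#' Brute-force accumulation curve by subset enumeration
#'
#' Enumerates every subset of each size, counts the distinct genes present in
#' each, and averages. Exponential in `n`; guarded to `n <= 12`. Serves as an
#' independent oracle for [accumulation_curve()].
#'
#' @inheritParams accumulation_curve
#' @param max_n enumeration guard.
#' @return an `accumulation_curve` data frame.
#' @export
brute_force_curve <- function(x, scope = "ALL", max_n = 12L) {
  stopifnot(inherits(x, "presence_matrix"))
  ids <- scope_individuals(x, scope)
  n <- length(ids)
  if (n < 1L) stop("scope has no individuals", call. = FALSE)
  if (n > max_n) stop("n too large for enumeration", call. = FALSE)
  pres <- x$data[, ids, drop = FALSE] > 0L
  G <- vapply(seq_len(n), function(k) {
    subsets <- utils::combn(n, k)
    mean(apply(subsets, 2L, function(cols) {
      if (nrow(pres) == 0L) 0 else sum(rowSums(pres[, cols, drop = FALSE]) > 0L)
    }))
  }, numeric(1))
  new_accumulation_curve(if (identical(scope, "ALL")) "ALL" else scope, G)
}
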