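# Internal numerical helpers shared across modules.

#' Derive a reproducible substream seed from a global seed and labels
#'
#' A single experiment-level seed fans out to independent per-library
#' substreams by hashing the library labels, so simulated libraries are
#' reproducible regardless of the order in which they are generated.
#'
#' @param seed integer global seed.
#' @param ... labels (coerced to character) identifying the substream,
#'   e.g. antibody, timepoint, replicate.
#' @return An integer in [0, 2^31 - 2] usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = ":")
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Centered moving sum over `w` positions; positions outside the vector
# contribute 0 (partial sums at the edges).
moving_sum <- function(x, w) {
  stopifnot(w >= 1L)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- c(0, cumsum(as.numeric(x)))
  h1 <- (w - 1L) %/% 2L
  h2 <- w - 1L - h1
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  cs[hi + 1L] - cs[lo]
}

# bp-weighted sum of per-bin counts over [a, b): each bin's count is treated
# as uniformly distributed across its bin_size bp.
prorated_sum <- function(values, bin_size, a, b) {
  cums <- c(0, cumsum(as.numeric(values)))
  n <- length(values)
  a <- pmax(a, 0)
  b <- pmin(b, n * bin_size)
  bad <- b <= a
  ia <- pmin(a %/% bin_size, n - 1L)
  ib <- pmin((b - 1) %/% bin_size, n - 1L)
  tot <- cums[ib + 2L] - cums[ia + 1L]
  frac_lo <- (a - ia * bin_size) / bin_size * values[ia + 1L]
  frac_hi <- ((ib + 1L) * bin_size - b) / bin_size * values[ib + 1L]
  out <- tot - frac_lo - frac_hi
  out[bad] <- 0
  out
}

#' Two-sided Fisher exact p-values for 2x2 tables, vectorized
#'
#' Computes the two-sided exact p-value for tables \code{[[a, b], [c, d]]} by
#' summing hypergeometric point probabilities no larger than that of the
#' observed table (with the conventional relative tolerance for floating-point
#' ties, as used by \code{stats::fisher.test}).  The odds ratio returned is
#' the sample odds ratio \code{ad/bc} (possibly \code{Inf} on degenerate
#' tables), not the conditional MLE.
#'
#' @param a,b,c,d integer vectors, the table cells (recycled to a common
#'   length): rows are the two groups, columns flagged/unflagged.
#' @return A data.frame with columns \code{odds_ratio} and \code{p}.
#' @examples
#' fisher_2x2(3, 1, 1, 3)
#' @export
fisher_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative cell in 2x2 table")
  p <- vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 total
    nn <- c[i] + d[i]         # row 2 total
    k <- a[i] + c[i]          # column 1 total
    if (k == 0L || k == m + nn || m == 0L || nn == 0L) return(1)
    x <- max(0L, k - nn):min(k, m)
    dens <- stats::dhyper(x, m, nn, k)
    obs <- stats::dhyper(a[i], m, nn, k)
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }, numeric(1))
  or <- (as.numeric(a) * d) / (as.numeric(b) * c)
  or[a == 0 & b == 0] <- NaN
  data.frame(odds_ratio = or, p = p)
}

# bp-weighted mean of per-bin values over [a, b)
interval_mean <- function(values, bin_size, a, b) {
  prorated_sum(values, bin_size, a, b) * bin_size / (b - a)
}

# run code under a local RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
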