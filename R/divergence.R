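#' Uniform binning scheme for discretizing connectivity values
#'
#' Defines a uniform partition of a closed interval into bins of equal width,
#' used to turn vectors of edge values (Pearson correlations, or paired
#' differences of correlations) into discrete probability distributions.
#'
#' Bins follow a half-open convention: every bin is `[lo, hi)` except the last,
#' which is closed `[lo, hi]`, so both interval endpoints are always
#' representable. A value falling exactly on an interior edge belongs to the
#' bin on its right (up to floating-point representation of the edge).
#'
#' @param lower Inclusive lower end of the range.
#' @param upper Inclusive upper end of the range; must exceed `lower`.
#' @param width Uniform bin width; `(upper - lower) / width` must be an
#'   integer (within 1e-8 of one).
#'
#' @return An object of class `binning_scheme` with elements `lower`, `upper`,
#'   `width`, `n_bins` and the numeric `breaks` vector of length `n_bins + 1`.
#'
#' @examples
#' binning_scheme(-1, 1, 0.2)   # 10 bins over the Pearson range
#' binning_scheme(-2, 2, 0.1)   # 40 bins over the paired-difference range
#' @export
binning_scheme <- function(lower, upper, width) {
  stopifnot(is.numeric(lower), is.numeric(upper), is.numeric(width),
            length(lower) == 1L, length(upper) == 1L, length(width) == 1L)
  if (!(upper > lower)) stop("binning_scheme: 'upper' must exceed 'lower'")
  if (width <= 0) stop("binning_scheme: 'width' must be positive")
  n <- (upper - lower) / width
  if (abs(n - round(n)) > 1e-8)
    stop("binning_scheme: (upper - lower)/width must be an integer number of bins")
  n <- as.integer(round(n))
  structure(
    # breaks rounded to 10 decimals so decimal-grid bin edges (e.g. 0.1, 0.2)
    # compare consistently against data values on the same grid
    list(lower = lower, upper = upper, width = width, n_bins = n,
         breaks = round(lower + (0:n) * width, 10)),
    class = "binning_scheme"
  )
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> [%g, %g], width %g (%d bins)\n",
              x$lower, x$upper, x$width, x$n_bins))
  invisible(x)
}

#' Default binning schemes
#'
#' `default_binning()` is the 10-bin width-0.2 scheme over the Pearson range
#' \eqn{[-1, 1]} used for unpaired cohort comparisons; `paired_binning()` is
#' the 40-bin width-0.1 scheme over \eqn{[-2, 2]} used for element-wise
#' paired differences.
#'
#' @return A `binning_scheme`.
#' @export
default_binning <- function() binning_scheme(-1, 1, 0.2)

#' @rdname default_binning
#' @export
paired_binning <- function() binning_scheme(-2, 2, 0.1)

same_binning <- function(a, b) {
  isTRUE(all.equal(a$lower, b$lower)) &&
    isTRUE(all.equal(a$upper, b$upper)) &&
    a$n_bins == b$n_bins
}

#' Map values to bin indices under a binning scheme
#'
#' Internal workhorse shared by [discretize()] and the vectorised edgewise
#' routines. Errors on values outside the binning range.
#'
#' @param values Numeric vector.
#' @param binning A [binning_scheme()].
#' @return Integer vector of 1-based bin indices.
#' @keywords internal
bin_index <- function(values, binning) {
  bad <- !is.finite(values) | values < binning$lower | values > binning$upper
  if (any(bad))
    stop(sprintf(
      "value %g outside binning range [%g, %g]",
      values[which(bad)[1L]], binning$lower, binning$upper))
  findInterval(values, binning$breaks, rightmost.closed = TRUE)
}

#' Discretize a vector of values into a probability distribution
#'
#' Counts the occurrence of each value in the bins of `binning` and normalises
#' by the number of values, producing the discrete probability distribution
#' (the P, Q of the Jensen-Shannon machinery) over the ordered bins.
#'
#' @param values Nonempty numeric vector; every value must lie inside the
#'   binning range (values exactly at the upper end go to the final, closed
#'   bin).
#' @param binning A [binning_scheme()].
#'
#' @return An object of class `prob_vector`: a numeric vector of bin masses
#'   summing to 1, with the binning attached as attribute `binning`.
#'
#' @examples
#' p <- discretize(rep(0.5, 50), binning_scheme(-1, 1, 0.2))
#' sum(p)  # 1
#' @export
discretize <- function(values, binning) {
  stopifnot(inherits(binning, "binning_scheme"))
  if (length(values) == 0L) stop("discretize: empty input")
  idx <- bin_index(values, binning)
  masses <- tabulate(idx, nbins = binning$n_bins) / length(values)
  prob_vector(masses, binning)
}

#' Construct a probability vector over the bins of a binning scheme
#'
#' @param masses Nonnegative numeric vector, one mass per bin, summing to 1
#'   within 1e-12.
#' @param binning A [binning_scheme()] with `n_bins == length(masses)`.
#' @return A `prob_vector`.
#' @export
prob_vector <- function(masses, binning) {
  stopifnot(inherits(binning, "binning_scheme"))
  if (length(masses) != binning$n_bins)
    stop("prob_vector: length(masses) must equal the number of bins")
  if (any(masses < 0)) stop("prob_vector: masses must be nonnegative")
  if (abs(sum(masses) - 1) > 1e-12)
    stop("prob_vector: masses must sum to 1 (tolerance 1e-12)")
  structure(as.numeric(masses), binning = binning, class = "prob_vector")
}

#' @export
print.prob_vector <- function(x, ...) {
  b <- attr(x, "binning")
  cat(sprintf("<prob_vector> %d bins on [%g, %g]\n", b$n_bins, b$lower, b$upper))
  print(as.numeric(x))
  invisible(x)
}

check_pq <- function(P, Q) {
  stopifnot(inherits(P, "prob_vector"), inherits(Q, "prob_vector"))
  if (!same_binning(attr(P, "binning"), attr(Q, "binning")))
    stop("P and Q must share the same binning")
}

#' Kullback-Leibler divergence between two discrete distributions (bits)
#'
#' \deqn{D_{KL}(P \| Q) = \sum_i P(i) \log_2 \frac{P(i)}{Q(i)}}
#' with the convention that bins with \eqn{P(i) = 0} contribute 0. The result
#' is `Inf` when some bin has positive P mass but zero Q mass; within the
#' Jensen-Shannon computation this never happens because the mixture M is
#' positive wherever P is.
#'
#' @param P,Q `prob_vector`s sharing a binning.
#' @return Nonnegative divergence in bits (possibly `Inf`).
#' @export
kl_divergence <- function(P, Q) {
  check_pq(P, Q)
  p <- as.numeric(P); q <- as.numeric(Q)
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' \deqn{JSD(P \| Q) = \tfrac12 D_{KL}(P \| M) + \tfrac12 D_{KL}(Q \| M),
#'   \quad M = \tfrac12 (P + Q).}
#' With base-2 logarithms the divergence is bounded in \eqn{[0, 1]}: it is 0
#' iff \eqn{P = Q} and reaches 1 exactly when P and Q have disjoint support.
#'
#' @param P,Q `prob_vector`s sharing a binning.
#' @return Divergence in bits, in \eqn{[0, 1]}.
#' @export
js_divergence <- function(P, Q) {
  check_pq(P, Q)
  js_divergence_num(as.numeric(P), as.numeric(Q))
}

# numeric-core JS divergence on bare mass vectors (no class checks)
js_divergence_num <- function(p, q) {
  m <- (p + q) / 2
  ip <- p > 0
  iq <- q > 0
  0.5 * sum(p[ip] * log2(p[ip] / m[ip])) +
    0.5 * sum(q[iq] * log2(q[iq] / m[iq]))
}

#' Jensen-Shannon distance (square root of the divergence)
#'
#' The square root of [js_divergence()] is a true distance metric on discrete
#' distributions (symmetric, zero iff identical, triangle inequality), bounded
#' in \eqn{[0, 1]} with base-2 logarithms.
#'
#' @param P,Q `prob_vector`s sharing a binning.
#' @return Distance in \eqn{[0, 1]}.
#' @export
js_distance <- function(P, Q) {
  sqrt(js_divergence(P, Q))
}

#' Paired Jensen-Shannon distance between repeated measurements
#'
#' For cohorts with repeated measurements on the same subjects, the unpaired
#' edgewise comparison is replaced by a paired one: the element-wise
#' differences `task - rest` (subjects index-aligned) are discretized over
#' \eqn{[-2, 2]} with bin width 0.1 into a distribution P, which is compared
#' against the point-mass null Q placing probability 1 on the bin containing
#' 0 — the expectation of no change between repeated measurements.
#'
#' @param rest_values,task_values Equal-length numeric vectors of one edge's
#'   correlation values, indexed by the same subjects in the same order.
#' @param binning Binning for the difference distribution; defaults to
#'   [paired_binning()].
#' @return The Jensen-Shannon distance between P and the zero-difference null,
#'   in \eqn{[0, 1]}.
#' @export
paired_js_distance <- function(rest_values, task_values,
                               binning = paired_binning()) {
  if (length(rest_values) != length(task_values))
    stop("paired_js_distance: rest and task vectors must have equal length")
  if (length(rest_values) == 0L) stop("paired_js_distance: empty input")
  d <- task_values - rest_values
  P <- discretize(d, binning)
  zero_bin <- findInterval(0, binning$breaks, rightmost.closed = TRUE)
  q <- numeric(binning$n_bins)
  q[zero_bin] <- 1
  sqrt(js_divergence_num(as.numeric(P), q))
}
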