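#' Functional connectivity matrix for one subject and condition
#'
#' A symmetric matrix of Pearson correlations between region time courses,
#' kept in signed weighted form (neither thresholded nor binarized), with
#' unit diagonal and region labels on both dimensions.
#'
#' @param values Square numeric matrix of correlations.
#' @param region_ids Character vector of region labels; defaults to existing
#'   dimnames or `R1..Rn`.
#' @return An object of class `fc_matrix` (a matrix with region dimnames).
#' @export
fc_matrix <- function(values, region_ids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("fc_matrix: matrix must be square")
  if (is.null(region_ids)) {
    region_ids <- rownames(values)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  }
  if (length(region_ids) != n) stop("fc_matrix: region_ids length mismatch")
  if (anyDuplicated(region_ids)) stop("fc_matrix: duplicated region ids")
  if (max(abs(values - t(values))) > 1e-10)
    stop("fc_matrix: matrix not symmetric within 1e-10")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > 1e-10)
    stop("fc_matrix: diagonal must be 1")
  diag(values) <- 1
  off <- values[upper.tri(values)]
  if (any(off < -1 - 1e-12 | off > 1 + 1e-12))
    stop("fc_matrix: off-diagonal values must lie in [-1, 1]")
  dimnames(values) <- list(region_ids, region_ids)
  class(values) <- c("fc_matrix", "matrix", "array")
  values
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d regions\n", nrow(x)))
  invisible(x)
}

region_ids <- function(x) rownames(x)

#' A labeled cohort of functional connectomes
#'
#' One condition label (e.g. `"REST"`, `"EMOTION"`) plus one [fc_matrix()]
#' per subject. All matrices must share region labels in identical order;
#' multi-subject operations verify this rather than silently realigning.
#'
#' @param condition Single condition label.
#' @param matrices Named list of `fc_matrix` objects (names are subject IDs),
#'   or an unnamed list plus `subjects`.
#' @param subjects Optional character vector of subject IDs.
#' @return An object of class `cohort`.
#' @export
cohort <- function(condition, matrices, subjects = names(matrices)) {
  stopifnot(is.character(condition), length(condition) == 1L)
  if (length(matrices) == 0L) stop("cohort: no matrices supplied")
  if (is.null(subjects)) subjects <- paste0("S", seq_along(matrices))
  if (length(subjects) != length(matrices))
    stop("cohort: subjects/matrices length mismatch")
  if (anyDuplicated(subjects)) stop("cohort: duplicated subject ids")
  ref <- region_ids(matrices[[1L]])
  for (m in matrices) {
    if (!inherits(m, "fc_matrix")) stop("cohort: all matrices must be fc_matrix")
    if (!identical(region_ids(m), ref))
      stop("cohort: all matrices must share identical region ordering")
  }
  names(matrices) <- subjects
  structure(list(condition = condition, subjects = subjects,
                 matrices = matrices, region_ids = ref),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> condition %s: %d subjects, %d regions\n",
              x$condition, length(x$subjects), length(x$region_ids)))
  invisible(x)
}

#' Parcellated time series for one subject
#'
#' Regions as rows, time points as columns, with the sampling interval in
#' seconds per frame. The series are assumed already parcellated and cleaned
#' (no missing values).
#'
#' @param subject Subject ID.
#' @param data Numeric matrix, n regions x T time points; rownames are region
#'   IDs (defaulting to `R1..Rn`).
#' @param sampling_interval Seconds per frame (e.g. the fMRI repetition time).
#' @return An object of class `time_series_set`.
#' @export
time_series_set <- function(subject, data, sampling_interval) {
  data <- as.matrix(data)
  if (ncol(data) < 2L) stop("time_series_set: need at least 2 time points")
  if (anyNA(data)) stop("time_series_set: missing values not allowed")
  stopifnot(is.numeric(sampling_interval), sampling_interval > 0)
  if (is.null(rownames(data))) rownames(data) <- paste0("R", seq_len(nrow(data)))
  structure(list(subject = as.character(subject), data = data,
                 sampling_interval = sampling_interval),
            class = "time_series_set")
}

#' @export
print.time_series_set <- function(x, ...) {
  cat(sprintf("<time_series_set> subject %s: %d regions x %d frames (dt = %gs)\n",
              x$subject, nrow(x$data), ncol(x$data), x$sampling_interval))
  invisible(x)
}

#' Region-to-functional-network partition
#'
#' Assigns every region to exactly one functional network (FN). The default
#' naming follows the eight-network scheme used throughout: seven cortical
#' systems (VIS, SM, DA, VA, L, FP, DMN) plus a subcortical block (SUBC).
#'
#' @param assignment Named character vector: names are region IDs, values are
#'   network labels; or a two-column data.frame (region_id, network).
#' @param networks Ordered character vector of network labels; defaults to
#'   the order of first appearance.
#' @return An object of class `network_partition` with elements `assignment`
#'   (named character vector) and `networks`.
#' @export
network_partition <- function(assignment, networks = NULL) {
  if (is.data.frame(assignment)) {
    a <- as.character(assignment[[2L]])
    names(a) <- as.character(assignment[[1L]])
    assignment <- a
  }
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("network_partition: assignment must be uniquely named by region id")
  if (is.null(networks)) networks <- unique(assignment)
  if (!all(assignment %in% networks))
    stop("network_partition: assignment uses labels absent from 'networks'")
  if (!all(networks %in% assignment))
    stop("network_partition: every listed network must be nonempty")
  structure(list(assignment = assignment, networks = networks),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d regions in %d networks: %s\n",
              length(x$assignment), length(x$networks),
              paste(x$networks, collapse = ", ")))
  invisible(x)
}

# network label per region of a matrix, verifying coverage
partition_labels <- function(part, regions) {
  missing <- setdiff(regions, names(part$assignment))
  if (length(missing) > 0L)
    stop("partition does not cover regions: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  factor(part$assignment[regions], levels = part$networks)
}

#' Zero-phase first-order Butterworth bandpass filter
#'
#' Applies a first-order Butterworth bandpass filter in forward and reverse
#' directions (zero phase) to every region's series. Resting-state data
#' conventionally use the band \eqn{[0.001, 0.08]} Hz and task data the more
#' liberal \eqn{[0.001, 0.25]} Hz.
#'
#' @param ts A [time_series_set()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz <` Nyquist (`0.5 / sampling_interval`).
#' @return A filtered `time_series_set` of the same shape.
#' @export
bandpass_filter <- function(ts, low_hz, high_hz) {
  stopifnot(inherits(ts, "time_series_set"))
  nyq <- 0.5 / ts$sampling_interval
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf(
      "bandpass_filter: need 0 < low (%g) < high (%g) < Nyquist (%g Hz)",
      low_hz, high_hz, nyq))
  bf <- signal::butter(1, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(ts$data, 1L, function(x) zero_phase_filter(bf$b, bf$a, x)))
  dimnames(out) <- dimnames(ts$data)
  time_series_set(ts$subject, out, ts$sampling_interval)
}

# forward-reverse (zero-phase) IIR filtering with constant-history initial
# conditions: each pass starts from the steady state for a constant input at
# the boundary sample, which suppresses the startup transient (a constant
# series maps to exactly zero under a band-pass filter)
zero_phase_filter <- function(b, a, x) {
  g <- sum(b) / sum(a)  # DC gain
  pass <- function(v) {
    edge <- v[1L]
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(edge, length(b) - 1L),
                              init.y = rep(edge * g, length(a) - 1L)))
  }
  rev(pass(rev(pass(x))))
}

#' Functional connectome from parcellated time series
#'
#' Pearson correlation between every pair of region time courses, with the
#' diagonal forced to exactly 1.
#'
#' @param ts A [time_series_set()]; every region's series must have nonzero
#'   variance.
#' @return An [fc_matrix()].
#' @export
fc_from_timeseries <- function(ts) {
  stopifnot(inherits(ts, "time_series_set"))
  v <- apply(ts$data, 1L, stats::var)
  if (any(v == 0))
    stop("fc_from_timeseries: zero-variance region(s): ",
         paste(utils::head(rownames(ts$data)[v == 0], 5L), collapse = ", "))
  r <- stats::cor(t(ts$data))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  fc_matrix(r, rownames(ts$data))
}

#' Average two runs of the same session
#'
#' Entry-wise mean of two functional connectomes from the same subject and
#' session (e.g. the two phase-encoding runs), preserving the unit diagonal.
#'
#' @param fc_a,fc_b [fc_matrix()] objects with identical region ordering.
#' @return The entry-wise mean as an `fc_matrix`.
#' @export
average_runs <- function(fc_a, fc_b) {
  stopifnot(inherits(fc_a, "fc_matrix"), inherits(fc_b, "fc_matrix"))
  if (!identical(region_ids(fc_a), region_ids(fc_b)))
    stop("average_runs: region orderings differ")
  m <- (unclass(fc_a) + unclass(fc_b)) / 2
  diag(m) <- 1
  fc_matrix(m, region_ids(fc_a))
}

#' Reorder a connectome by functional networks
#'
#' Permutes rows and columns so that regions of each functional network are
#' contiguous, with networks in partition order (and original order preserved
#' within a network). Values are untouched.
#'
#' @param fc An [fc_matrix()] (or any square matrix with region dimnames).
#' @param part A [network_partition()] covering all regions of `fc`.
#' @return The reordered matrix, with the permutation attached as attribute
#'   `permutation`.
#' @export
reorder_by_partition <- function(fc, part) {
  regions <- rownames(fc)
  labels <- partition_labels(part, regions)
  perm <- order(as.integer(labels))
  out <- fc[perm, perm]
  class(out) <- class(fc)
  attr(out, "permutation") <- perm
  out
}
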