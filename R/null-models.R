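# Null models for the connectivity-distance analysis: AAFT surrogate time
# series (preserving amplitude distribution and power spectrum) and
# task/rest label permutation on intact FC matrices.

# random phases with conjugate symmetry, drawn independently per column so
# every series is randomized on its own (univariate scheme: cross-spectra,
# hence inter-regional correlations, are destroyed); DC (and Nyquist, if
# present) stay real
random_phase_rotation <- function(n, k) {
  half <- floor((n - 1) / 2)
  phases <- matrix(0, n, k)
  if (half >= 1) {
    ph <- matrix(stats::runif(half * k, 0, 2 * pi), half, k)
    phases[2:(half + 1), ] <- ph
    phases[n:(n - half + 1), ] <- -ph
  }
  complex(modulus = 1, argument = phases)
}

# phase-randomize the columns of a matrix (one FFT per column via mvfft)
phase_randomize_cols <- function(x) {
  n <- nrow(x)
  rot <- random_phase_rotation(n, ncol(x))
  dim(rot) <- dim(x)
  Re(stats::mvfft(stats::mvfft(x) * rot, inverse = TRUE)) / n
}

# AAFT on the columns of a T x k matrix, consuming the current RNG stream
aaft_cols <- function(x) {
  n <- nrow(x); k <- ncol(x)
  const <- apply(x, 2L, function(col) all(col == col[1L]))
  if (any(const))
    stop("aaft: constant series (column ", which(const)[1L], ")")
  # 1. rank-remap each series onto a sorted Gaussian realization
  g <- matrix(stats::rnorm(n * k), n, k)
  g <- apply(g, 2L, sort)
  ranks <- apply(x, 2L, rank, ties.method = "first")
  y <- vapply(seq_len(k), function(j) g[ranks[, j], j], numeric(n))
  # 2. phase-randomize the Gaussianized series
  y <- phase_randomize_cols(y)
  # 3. rank-remap the original amplitudes onto the randomized series
  xs <- apply(x, 2L, sort)
  ranks2 <- apply(y, 2L, rank, ties.method = "first")
  vapply(seq_len(k), function(j) xs[ranks2[, j], j], numeric(n))
}

#' Amplitude-adjusted Fourier-transform (AAFT) surrogate series
#'
#' Generates a randomized version of a time series that preserves its
#' amplitude distribution exactly (the sorted surrogate values equal the
#' sorted original values) and approximately preserves its power spectrum,
#' following the Schreiber-Schmitz scheme: the series is rank-remapped onto a
#' sorted Gaussian realization, the Gaussianized series is Fourier
#' phase-randomized, and the original amplitudes are rank-remapped onto the
#' result.
#'
#' @param series Numeric vector, length at least 4, non-constant.
#' @param seed Optional integer seed; when supplied the call is fully
#'   reproducible and the caller's RNG state is left untouched.
#' @return Numeric surrogate vector of the same length.
#' @export
aaft_surrogate <- function(series, seed = NULL) {
  if (length(series) < 4L) stop("aaft_surrogate: series must have length >= 4")
  if (all(series == series[1L]))
    stop("aaft_surrogate: constant series has no surrogate")
  with_seed(seed, as.numeric(aaft_cols(matrix(series, ncol = 1L))))
}

#' Surrogate a whole time-series set
#'
#' Applies [aaft_surrogate()] independently to every region's series
#' (univariate scheme: inter-regional correlation is destroyed, which is the
#' point of the connectivity null).
#'
#' @param ts A [time_series_set()].
#' @param seed Optional integer seed.
#' @return A surrogate `time_series_set` of the same shape.
#' @export
aaft_surrogate_set <- function(ts, seed = NULL) {
  stopifnot(inherits(ts, "time_series_set"))
  run <- function() {
    out <- t(aaft_cols(t(ts$data)))
    dimnames(out) <- dimnames(ts$data)
    time_series_set(ts$subject, out, ts$sampling_interval)
  }
  with_seed(seed, run())
}

# evaluate expr under a temporary RNG seed (NULL = use current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# draw k sub-seeds (< 2^31) from a master seed without disturbing the caller
spawn_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

null_distribution <- function(condition, counts, observed = NA_real_) {
  counts <- as.integer(counts)
  stopifnot(all(counts >= 0))
  structure(list(condition = condition, counts = counts,
                 n_realizations = length(counts), observed = observed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: %d realizations, counts in [%d, %d]",
              x$condition, x$n_realizations, min(x$counts), max(x$counts)))
  if (!is.na(x$observed))
    cat(sprintf("; observed %d (p = %.4g)", x$observed, empirical_p(x)))
  cat("\n")
  invisible(x)
}

#' Empirical p-value of an observed count against a null distribution
#'
#' Computed as `(1 + #\{null >= observed\}) / (1 + n_realizations)`, which is
#' guaranteed to lie in (0, 1].
#'
#' @param null A `null_distribution` (from [surrogate_null()] or
#'   [label_permutation_test()]).
#' @param observed Observed suprathreshold edge count; defaults to the one
#'   stored in `null`.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(null, observed = null$observed) {
  if (is.na(observed)) stop("empirical_p: no observed count available")
  (1 + sum(null$counts >= observed)) / (1 + null$n_realizations)
}

# suprathreshold upper-tri count of an edgewise JS map built from two cohorts
js_count_above <- function(rest, task, cutoff, binning) {
  js <- edgewise_js_matrix(rest, task, binning)
  sum(upper_tri_values(unclass(js)) > cutoff)
}

#' Surrogate null distribution for suprathreshold JS edge counts
#'
#' Per realization, every region series of every subject (both conditions) is
#' replaced by an AAFT surrogate, functional connectomes are rebuilt, the
#' edgewise JS matrix is recomputed, and the number of edges exceeding
#' `cutoff` is recorded. By default the cutoff is the one obtained from the
#' original data's pooled threshold; set `rethreshold = TRUE` to re-derive a
#' percentile cutoff within each realization instead.
#'
#' @param rest_ts,task_ts Lists of [time_series_set()] (one per subject).
#' @param cutoff JS cutoff from the original data (see [threshold_pooled()]).
#' @param n_realizations Number of surrogate realizations (>= 1); 100 is the
#'   conventional choice.
#' @param seed Integer master seed; per-realization substreams are derived
#'   from it so results are reproducible.
#' @param binning Binning for the JS computation; default [default_binning()].
#' @param condition Label stored on the result.
#' @param rethreshold If `TRUE`, count edges above the `percentile` of each
#'   realization's own JS values rather than above `cutoff`.
#' @param percentile Percentile used when `rethreshold = TRUE`.
#' @param observed Optional observed count to store alongside the null.
#' @return A `null_distribution`.
#' @export
surrogate_null <- function(rest_ts, task_ts, cutoff, n_realizations = 100,
                           seed = 1, binning = default_binning(),
                           condition = "TASK", rethreshold = FALSE,
                           percentile = 95, observed = NA_real_) {
  if (n_realizations < 1) stop("surrogate_null: n_realizations must be >= 1")
  stopifnot(length(rest_ts) > 0L, length(task_ts) > 0L)
  seeds <- spawn_seeds(seed, n_realizations)
  counts <- integer(n_realizations)
  for (r in seq_len(n_realizations)) {
    counts[r] <- with_seed(seeds[r], {
      sur_fc <- function(ts_list, cond) {
        mats <- lapply(ts_list, function(ts)
          fc_from_timeseries(aaft_surrogate_set(ts)))
        cohort(cond, mats, vapply(ts_list, `[[`, character(1L), "subject"))
      }
      rest_c <- sur_fc(rest_ts, "REST")
      task_c <- sur_fc(task_ts, condition)
      js <- suppressWarnings(edgewise_js_matrix(rest_c, task_c, binning))
      vals <- upper_tri_values(unclass(js))
      thr <- if (rethreshold)
        unname(stats::quantile(vals, percentile / 100, type = 7))
      else cutoff
      sum(vals > thr)
    })
  }
  null_distribution(condition, counts, observed)
}

#' Task/rest label-permutation test for suprathreshold edge counts
#'
#' Pools the rest and task FC matrices, randomly reassigns whole matrices to
#' the two groups (cohort sizes preserved, correlation structure intact),
#' recomputes the edgewise JS matrix, and counts edges above the
#' original-data cutoff. The observed count from the unpermuted labels is
#' stored on the result, so [empirical_p()] can be applied directly.
#'
#' @param rest,task [cohort()]s sharing region ordering.
#' @param cutoff JS cutoff from the original data.
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer master seed.
#' @param binning Binning for the JS computation.
#' @return A `null_distribution` with the observed count attached.
#' @export
label_permutation_test <- function(rest, task, cutoff, n_permutations = 100,
                                   seed = 1, binning = default_binning()) {
  if (n_permutations < 1)
    stop("label_permutation_test: n_permutations must be >= 1")
  stopifnot(inherits(rest, "cohort"), inherits(task, "cohort"))
  if (!identical(rest$region_ids, task$region_ids))
    stop("label_permutation_test: cohorts must share region ordering")
  n_rest <- length(rest$subjects)
  pool <- c(rest$matrices, task$matrices)
  ids <- make.unique(c(paste0("rest.", rest$subjects),
                       paste0("task.", task$subjects)))
  observed <- suppressWarnings(
    js_count_above(rest, task, cutoff, binning))
  seeds <- spawn_seeds(seed, n_permutations)
  counts <- integer(n_permutations)
  for (p in seq_len(n_permutations)) {
    counts[p] <- with_seed(seeds[p], {
      perm <- sample.int(length(pool))
      g1 <- perm[seq_len(n_rest)]
      g2 <- perm[-seq_len(n_rest)]
      r <- cohort("REST", pool[g1], ids[g1])
      t_ <- cohort(task$condition, pool[g2], ids[g2])
      suppressWarnings(js_count_above(r, t_, cutoff, binning))
    })
  }
  null_distribution(task$condition, counts, observed)
}

#' Write a null distribution to TSV and JSON summary
#'
#' The TSV holds (condition, realization_index, count); the JSON summary
#' records the observed count and empirical p-value.
#'
#' @param null A `null_distribution`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list.
#' @export
write_null_distribution <- function(null, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    tab <- data.frame(condition = null$condition,
                      realization_index = seq_along(null$counts),
                      count = null$counts)
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  summary <- list(condition = null$condition,
                  n_realizations = null$n_realizations,
                  observed = null$observed,
                  max_null = max(null$counts),
                  empirical_p = if (is.na(null$observed)) NA_real_
                                else empirical_p(null))
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
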