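# Edgewise JS maps, percentile thresholding, and the centralized/distributed
# processing statistics over a functional-network partition.

# subjects x edges matrix of upper-triangular (i < j) values for a cohort
cohort_edge_values <- function(coh) {
  n <- length(coh$region_ids)
  ut <- upper.tri(matrix(0, n, n))
  t(vapply(coh$matrices, function(m) unclass(m)[ut],
           numeric(sum(ut))))
}

# n_bins x n_edges matrix of bin probabilities for a subjects x edges matrix
edge_bin_probs <- function(values, binning) {
  idx <- bin_index(values, binning)
  dim(idx) <- dim(values)
  n_sub <- nrow(values)
  probs <- matrix(0, binning$n_bins, ncol(values))
  for (b in seq_len(binning$n_bins))
    probs[b, ] <- colSums(idx == b)
  probs / n_sub
}

# vectorised JS divergence down the columns of two probability matrices
js_divergence_cols <- function(P, Q) {
  M <- (P + Q) / 2
  termP <- P * suppressWarnings(log2(P / M))
  termP[P == 0] <- 0
  termQ <- Q * suppressWarnings(log2(Q / M))
  termQ[Q == 0] <- 0
  0.5 * colSums(termP) + 0.5 * colSums(termQ)
}

# fold a vector of upper-tri edge values back into a symmetric matrix
edges_to_matrix <- function(edge_values, regions, diag_value = 0) {
  n <- length(regions)
  m <- matrix(diag_value, n, n, dimnames = list(regions, regions))
  m[upper.tri(m)] <- edge_values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

# upper-triangular values of a square matrix
upper_tri_values <- function(m) m[upper.tri(m)]

js_matrix_obj <- function(values, condition, mode, binning) {
  structure(values, condition = condition, mode = mode, binning = binning,
            class = c("js_matrix", "matrix", "array"))
}

#' @export
print.js_matrix <- function(x, ...) {
  cat(sprintf("<js_matrix> %s (%s): %d regions\n",
              attr(x, "condition"), attr(x, "mode"), nrow(x)))
  invisible(x)
}

#' Edgewise Jensen-Shannon distance matrix between two cohorts
#'
#' For every region pair (i, j), the across-subject vectors of that edge's
#' correlation values in the rest and task cohorts are discretized with
#' `binning` and the Jensen-Shannon distance between the two distributions is
#' computed, producing a symmetric map of task-vs-rest connectivity distance.
#'
#' @param rest,task [cohort()] objects with identical region ordering; in
#'   unpaired use the subject sets should be disjoint (a warning is issued if
#'   not).
#' @param binning A [binning_scheme()]; defaults to [default_binning()]
#'   (width 0.2 over the Pearson range).
#' @return A `js_matrix`: symmetric, zero diagonal, entries in \eqn{[0, 1]},
#'   with attributes `condition` (the task cohort's label), `mode`
#'   (`"unpaired"`) and `binning`.
#' @export
edgewise_js_matrix <- function(rest, task, binning = default_binning()) {
  stopifnot(inherits(rest, "cohort"), inherits(task, "cohort"))
  if (!identical(rest$region_ids, task$region_ids))
    stop("edgewise_js_matrix: cohorts must share region ordering")
  if (length(intersect(rest$subjects, task$subjects)) > 0L)
    warning("edgewise_js_matrix: cohorts share subjects; ",
            "consider edgewise_paired_js_matrix()")
  P <- edge_bin_probs(cohort_edge_values(rest), binning)
  Q <- edge_bin_probs(cohort_edge_values(task), binning)
  js <- sqrt(pmax(js_divergence_cols(P, Q), 0))
  js_matrix_obj(edges_to_matrix(js, rest$region_ids),
                task$condition, "unpaired", binning)
}

#' Edgewise paired Jensen-Shannon distance matrix
#'
#' For cohorts with repeated measurements on the same subjects: per edge, the
#' element-wise differences task - rest are discretized over \eqn{[-2, 2]}
#' (width 0.1) and compared against the point-mass null at the zero bin (see
#' [paired_js_distance()]).
#'
#' @param rest,task [cohort()]s with identical subject lists in identical
#'   order and identical region ordering.
#' @param binning Difference binning; defaults to [paired_binning()].
#' @return A `js_matrix` with `mode = "paired"`.
#' @export
edgewise_paired_js_matrix <- function(rest, task, binning = paired_binning()) {
  stopifnot(inherits(rest, "cohort"), inherits(task, "cohort"))
  if (!identical(rest$region_ids, task$region_ids))
    stop("edgewise_paired_js_matrix: cohorts must share region ordering")
  if (!identical(rest$subjects, task$subjects))
    stop("edgewise_paired_js_matrix: subject lists must be identical and aligned")
  d <- cohort_edge_values(task) - cohort_edge_values(rest)
  P <- edge_bin_probs(d, binning)
  zero_bin <- findInterval(0, binning$breaks, rightmost.closed = TRUE)
  Q <- matrix(0, binning$n_bins, ncol(P))
  Q[zero_bin, ] <- 1
  js <- sqrt(pmax(js_divergence_cols(P, Q), 0))
  js_matrix_obj(edges_to_matrix(js, rest$region_ids),
                task$condition, "paired", binning)
}

threshold_mask_obj <- function(mask, cutoff, percentile) {
  structure(mask, cutoff = cutoff, percentile = percentile,
            class = c("threshold_mask", "matrix", "array"))
}

#' @export
print.threshold_mask <- function(x, ...) {
  cat(sprintf("<threshold_mask> %d regions, cutoff %.6g (percentile %g): %d surviving edges\n",
              nrow(x), attr(x, "cutoff"), attr(x, "percentile"),
              sum(upper_tri_values(x))))
  invisible(x)
}

#' Pooled percentile threshold across task JS matrices
#'
#' The cutoff is one percentile (default 95) of the pooled upper-triangular
#' JS values across all supplied task matrices, computed by linear
#' interpolation on the sorted pooled values. Each matrix is then binarized:
#' an edge survives iff its JS value is strictly greater than the cutoff, so
#' with all entries tied nothing survives.
#'
#' @param js A `js_matrix` or list of them (one per task), all of the same
#'   dimension.
#' @param percentile Percentile in \eqn{[0, 100]}; default 95. At 0 the
#'   cutoff is the pooled minimum (every entry strictly above it survives);
#'   at 100 it is the maximum (nothing survives).
#' @return A list with `cutoff` (numeric) and `masks` (list of
#'   `threshold_mask`, named by task condition when available).
#' @export
threshold_pooled <- function(js, percentile = 95) {
  if (inherits(js, "js_matrix")) js <- list(js)
  if (length(js) == 0L) stop("threshold_pooled: empty input list")
  if (!(percentile >= 0 && percentile <= 100))
    stop("threshold_pooled: percentile must be in [0, 100]")
  dims <- vapply(js, nrow, integer(1L))
  if (length(unique(dims)) != 1L)
    stop("threshold_pooled: matrices must share dimension")
  pooled <- unlist(lapply(js, upper_tri_values), use.names = FALSE)
  cutoff <- unname(stats::quantile(pooled, percentile / 100, type = 7))
  masks <- lapply(js, function(m) {
    mk <- (unclass(m) > cutoff) * 1L
    diag(mk) <- 0L
    threshold_mask_obj(mk, cutoff, percentile)
  })
  conds <- vapply(js, function(m) {
    cond <- attr(m, "condition")
    if (is.null(cond)) NA_character_ else cond
  }, character(1L))
  if (!anyNA(conds) && !anyDuplicated(conds)) names(masks) <- conds
  list(cutoff = cutoff, masks = masks)
}

# per-edge network classification: within-network k, or between pair (k, l)
edge_classes <- function(regions, part) {
  labels <- partition_labels(part, regions)
  n <- length(regions)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  a <- as.integer(labels)[ij[, 1L]]
  b <- as.integer(labels)[ij[, 2L]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  list(lo = lo, hi = hi, within = lo == hi, networks = levels(labels))
}

#' Centralized processing per functional network
#'
#' For each functional network k, CP_k is the number of within-k edges
#' surviving the JS threshold divided by the total number of within-k edges
#' (each undirected edge counted once, diagonal excluded). Stored as a
#' fraction in \eqn{[0, 1]}; multiply by 100 for the percentage form used in
#' reports.
#'
#' @param mask A `threshold_mask` from [threshold_pooled()].
#' @param part A [network_partition()] covering the mask's regions.
#' @return Named numeric vector of CP values, one per network (NA with a
#'   warning for networks with fewer than 2 regions).
#' @export
centralized_processing <- function(mask, part) {
  cls <- edge_classes(rownames(mask), part)
  surv <- upper_tri_values(unclass(mask)) != 0
  K <- length(cls$networks)
  cp <- setNames(rep(NA_real_, K), cls$networks)
  for (k in seq_len(K)) {
    idx <- cls$within & cls$lo == k
    if (!any(idx)) {
      warning("centralized_processing: network ", cls$networks[k],
              " has < 2 regions; CP undefined")
      next
    }
    cp[k] <- sum(surv[idx]) / sum(idx)
  }
  cp
}

#' Distributed processing per functional-network pair
#'
#' For each unordered network pair (k, l), DP_kl is the number of surviving
#' edges with one endpoint in k and the other in l divided by the total
#' number of k-l edges (|k| * |l|). Stored as a fraction.
#'
#' @inheritParams centralized_processing
#' @return Named numeric vector of DP values, names of the form `"k|l"` in
#'   partition order.
#' @export
distributed_processing <- function(mask, part) {
  cls <- edge_classes(rownames(mask), part)
  surv <- upper_tri_values(unclass(mask)) != 0
  K <- length(cls$networks)
  pairs <- which(upper.tri(diag(K)), arr.ind = TRUE)
  dp <- setNames(
    rep(NA_real_, nrow(pairs)),
    paste(cls$networks[pairs[, 1L]], cls$networks[pairs[, 2L]], sep = "|"))
  for (p in seq_len(nrow(pairs))) {
    idx <- !cls$within & cls$lo == pairs[p, 1L] & cls$hi == pairs[p, 2L]
    if (!any(idx)) next
    dp[p] <- sum(surv[idx]) / sum(idx)
  }
  dp
}

#' Centralized/distributed processing table for one task
#'
#' Bundles [centralized_processing()] and [distributed_processing()] for one
#' thresholded task map.
#'
#' @inheritParams centralized_processing
#' @param condition Task label; defaults to the mask's stored condition if
#'   any.
#' @return An object of class `cpdp_table`: list with `cp` (per network),
#'   `dp` (per network pair) and `condition`.
#' @export
cpdp_table <- function(mask, part, condition = NULL) {
  if (is.null(condition)) condition <- attr(mask, "condition")
  if (is.null(condition)) condition <- NA_character_
  structure(list(cp = centralized_processing(mask, part),
                 dp = distributed_processing(mask, part),
                 condition = condition),
            class = "cpdp_table")
}

#' @export
print.cpdp_table <- function(x, ...) {
  cat(sprintf("<cpdp_table> condition %s\nCP (%%):\n", x$condition))
  print(round(100 * x$cp, 2))
  cat("DP (%):\n")
  print(round(100 * x$dp, 2))
  invisible(x)
}

#' Long-format data frame from CP/DP tables
#'
#' @param tables A `cpdp_table` or list of them.
#' @return data.frame with columns condition, network_or_pair, statistic
#'   (`"CP"`/`"DP"`), value (fraction).
#' @export
cpdp_long <- function(tables) {
  if (inherits(tables, "cpdp_table")) tables <- list(tables)
  do.call(rbind, lapply(tables, function(tb) {
    rbind(
      data.frame(condition = tb$condition, network_or_pair = names(tb$cp),
                 statistic = "CP", value = unname(tb$cp)),
      data.frame(condition = tb$condition, network_or_pair = names(tb$dp),
                 statistic = "DP", value = unname(tb$dp)))
  }))
}

#' Edgewise max/median summary across task JS matrices
#'
#' Entry-wise maximum or median of the per-task JS maps, thresholded at a
#' percentile of the summary map's own upper-triangular values. The median
#' over an even number of tasks is the mean of the two central order
#' statistics.
#'
#' @param js List of `js_matrix` objects sharing dimensions.
#' @param statistic `"max"` or `"median"`.
#' @param percentile Threshold percentile for the summary map; default 95.
#' @return List with `summary` (a `js_matrix` labeled by the statistic) and
#'   `mask` (a `threshold_mask`).
#' @export
cross_task_summary <- function(js, statistic = c("max", "median"),
                               percentile = 95) {
  statistic <- match.arg(statistic)
  if (inherits(js, "js_matrix")) js <- list(js)
  if (length(js) == 0L) stop("cross_task_summary: empty input list")
  dims <- vapply(js, nrow, integer(1L))
  if (length(unique(dims)) != 1L)
    stop("cross_task_summary: matrices must share dimension")
  arr <- simplify2array(lapply(js, unclass))
  vals <- if (statistic == "max") apply(arr, c(1L, 2L), max)
          else apply(arr, c(1L, 2L), stats::median)
  dimnames(vals) <- dimnames(js[[1L]])
  summ <- js_matrix_obj(vals, statistic, attr(js[[1L]], "mode"),
                        attr(js[[1L]], "binning"))
  thr <- threshold_pooled(list(summ), percentile)
  list(summary = summ, mask = thr$masks[[1L]])
}

#' Nodal strength of suprathreshold JS distance
#'
#' For each region i, the sum of JS distances over its surviving edges
#' divided by the total number of regions — a nodal density of functional
#' reconfiguration.
#'
#' @param js A `js_matrix`.
#' @param mask A `threshold_mask` of the same dimension.
#' @return Named numeric vector, one value per region.
#' @export
nodal_js_strength <- function(js, mask) {
  if (!all(dim(js) == dim(mask)))
    stop("nodal_js_strength: shape mismatch between js and mask")
  rowSums(unclass(js) * unclass(mask)) / nrow(js)
}

#' Correlation between JS distance and the resting-state FC baseline
#'
#' Pearson correlation between upper-triangular JS values and the edgewise
#' median resting-state correlation across subjects — a diagnostic that the
#' distance map is not driven by baseline correlation magnitude.
#'
#' @param js A `js_matrix`.
#' @param rest The resting-state [cohort()].
#' @return Pearson correlation coefficient.
#' @export
js_baseline_correlation <- function(js, rest) {
  stopifnot(inherits(rest, "cohort"))
  if (!identical(rownames(js), rest$region_ids))
    stop("js_baseline_correlation: region sets differ")
  x <- upper_tri_values(unclass(js))
  y <- apply(cohort_edge_values(rest), 2L, stats::median)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("js_baseline_correlation: constant vector; correlation undefined")
  stats::cor(x, y)
}

#' Cosine similarity of CP/DP coordinates between two analyses
#'
#' For each functional network, forms the vector of its processing
#' coordinates — its CP value followed by its DP values (all pairs involving
#' the network, or their mean) — under the two analyses, and returns the
#' cosine of the angle between the two vectors. Used to check robustness of
#' the CP/DP pattern, e.g. under a different bandpass filter.
#'
#' @param a,b `cpdp_table`s over the same networks.
#' @param dp_coordinates `"full"` (all DP pairs involving the network,
#'   default) or `"mean"` (single mean-DP coordinate).
#' @return Named numeric vector of cosine similarities, one per network.
#' @export
cpdp_cosine_similarity <- function(a, b, dp_coordinates = c("full", "mean")) {
  dp_coordinates <- match.arg(dp_coordinates)
  stopifnot(inherits(a, "cpdp_table"), inherits(b, "cpdp_table"))
  if (!identical(names(a$cp), names(b$cp)) ||
      !identical(names(a$dp), names(b$dp)))
    stop("cpdp_cosine_similarity: tables must share networks")
  coords <- function(tb, k) {
    involved <- vapply(strsplit(names(tb$dp), "|", fixed = TRUE),
                       function(p) k %in% p, logical(1L))
    dpk <- tb$dp[involved]
    if (dp_coordinates == "mean") dpk <- mean(dpk, na.rm = TRUE)
    c(tb$cp[[k]], unname(dpk))
  }
  out <- setNames(numeric(length(a$cp)), names(a$cp))
  for (k in names(a$cp)) {
    u <- coords(a, k); v <- coords(b, k)
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0)
      stop("cpdp_cosine_similarity: zero coordinate vector for network ", k)
    out[k] <- sum(u * v) / (nu * nv)
  }
  out
}
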