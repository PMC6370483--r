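# Synthetic rest/task cohorts with known ground truth. Region time series are
# drawn from a zero-mean multivariate normal whose target correlation matrix
# is block-structured over the functional-network partition; a configurable
# set of planted edges has its coupling shifted in the task condition.

#' Specification for synthetic rest/task data
#'
#' Defines the study conditions emulated by the generator: two cohorts of
#' subjects (default 50 + 50, disjoint unless `paired`), a modular target
#' correlation structure over 8 functional networks on 374 regions (360
#' cortical + 14 subcortical by default), a set of planted edges whose
#' coupling shifts by `delta_r` between rest and task, and run length T
#' (default 1200 frames, a typical resting-state run).
#'
#' @param n_regions Number of regions (default 374).
#' @param n_subjects_rest,n_subjects_task Cohort sizes (default 50 each).
#' @param partition Optional [network_partition()]; default splits the
#'   regions into the eight canonical networks (VIS, SM, DA, VA, L, FP, DMN
#'   of near-equal size over the first `n_regions - n_subcortical` regions,
#'   plus SUBC on the remainder).
#' @param n_subcortical Size of the SUBC block when the default partition is
#'   built (default 14, scaled down proportionally for small `n_regions`).
#' @param planted_edges data.frame with columns `i`, `j` (region indices) and
#'   `delta_r` (additive task shift of the target correlation); may be empty.
#' @param within_block_r Baseline target correlation for region pairs in the
#'   same network (default 0.2).
#' @param between_block_r Baseline for pairs in different networks
#'   (default 0.05).
#' @param noise_sd Standard deviation of white observation noise added to
#'   each series after sampling (default 0: empirical correlations are
#'   centred on the targets).
#' @param paired If `TRUE`, the same subjects appear in both cohorts and
#'   each subject's random deflection is shared between their rest and task
#'   draws (so it cancels in paired differences).
#' @param subject_effect_sd Standard deviation of the subject-level random
#'   deflection added to each subject's target correlations (default 0.05) —
#'   the stable individual differences of real cohorts. In unpaired mode
#'   deflections are independent across all subjects; set to 0 for
#'   homogeneous cohorts.
#' @param t_frames Time points per run (default 1200).
#' @param sampling_interval Seconds per frame (default 0.72).
#' @param seed Master seed; everything downstream is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regions = 374,
                           n_subjects_rest = 50,
                           n_subjects_task = 50,
                           partition = NULL,
                           n_subcortical = NULL,
                           planted_edges = NULL,
                           within_block_r = 0.2,
                           between_block_r = 0.05,
                           noise_sd = 0,
                           paired = FALSE,
                           subject_effect_sd = 0.05,
                           t_frames = 1200,
                           sampling_interval = 0.72,
                           seed = 1) {
  stopifnot(n_regions >= 12, n_subjects_rest >= 2, n_subjects_task >= 2,
            t_frames >= 8, sampling_interval > 0)
  if (is.null(partition)) {
    if (is.null(n_subcortical))
      n_subcortical <- max(2L, round(14 / 374 * n_regions))
    partition <- default_partition(n_regions, n_subcortical)
  }
  regions <- names(partition$assignment)
  if (length(regions) != n_regions)
    stop("synthetic_spec: partition size must match n_regions")
  if (is.null(planted_edges))
    planted_edges <- data.frame(i = integer(), j = integer(),
                                delta_r = numeric())
  stopifnot(all(c("i", "j", "delta_r") %in% names(planted_edges)))
  if (nrow(planted_edges) > 0L) {
    ii <- pmin(planted_edges$i, planted_edges$j)
    jj <- pmax(planted_edges$i, planted_edges$j)
    if (any(ii == jj) || any(ii < 1) || any(jj > n_regions))
      stop("synthetic_spec: planted edge indices out of range")
    if (anyDuplicated(paste(ii, jj)))
      stop("synthetic_spec: planted edges must be distinct")
    planted_edges$i <- ii; planted_edges$j <- jj
  }
  structure(list(n_regions = n_regions,
                 n_subjects_rest = n_subjects_rest,
                 n_subjects_task = n_subjects_task,
                 partition = partition,
                 planted_edges = planted_edges,
                 within_block_r = within_block_r,
                 between_block_r = between_block_r,
                 noise_sd = noise_sd,
                 paired = paired,
                 subject_effect_sd = subject_effect_sd,
                 t_frames = t_frames,
                 sampling_interval = sampling_interval,
                 seed = seed,
                 region_ids = regions),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d regions, %d+%d subjects%s, T = %d, %d planted edges, seed %d\n",
    x$n_regions, x$n_subjects_rest, x$n_subjects_task,
    if (x$paired) " (paired)" else "", x$t_frames,
    nrow(x$planted_edges), x$seed))
  invisible(x)
}

#' Default eight-network partition
#'
#' Splits `n_regions` region labels into the seven cortical networks (VIS,
#' SM, DA, VA, L, FP, DMN) of near-equal size plus a final SUBC block of
#' `n_subcortical` regions.
#'
#' @param n_regions Total number of regions.
#' @param n_subcortical Regions in the subcortical block.
#' @return A [network_partition()].
#' @export
default_partition <- function(n_regions, n_subcortical = 14) {
  stopifnot(n_regions > n_subcortical + 7)
  cortical <- c("VIS", "SM", "DA", "VA", "L", "FP", "DMN")
  n_cort <- n_regions - n_subcortical
  sizes <- diff(round(seq(0, n_cort, length.out = 8L)))
  labels <- c(rep(cortical, times = sizes), rep("SUBC", n_subcortical))
  regions <- paste0("R", seq_len(n_regions))
  network_partition(setNames(labels, regions), c(cortical, "SUBC"))
}

# block-structured target correlation matrix (no planted shifts)
baseline_target <- function(spec) {
  labels <- partition_labels(spec$partition, spec$region_ids)
  same <- outer(labels, labels, `==`)
  m <- matrix(spec$between_block_r, spec$n_regions, spec$n_regions)
  m[same] <- spec$within_block_r
  diag(m) <- 1
  dimnames(m) <- list(spec$region_ids, spec$region_ids)
  m
}

# apply planted deltas to a target matrix (task condition)
apply_planted <- function(target, planted) {
  for (r in seq_len(nrow(planted))) {
    i <- planted$i[r]; j <- planted$j[r]
    v <- target[i, j] + planted$delta_r[r]
    if (v >= 1 || v <= -1)
      stop("synthetic target correlation out of (-1, 1) at planted edge ",
           i, "-", j)
    target[i, j] <- v; target[j, i] <- v
  }
  target
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping followed by renormalization to unit diagonal; applied
#' to planted target matrices, whose arbitrary deltas can break positive
#' definiteness.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param eps Smallest retained eigenvalue (default 1e-8).
#' @return A positive-definite correlation matrix.
#' @export
nearest_correlation <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / (d %o% d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}

# sample one subject's T x n series with target correlation sigma (chol given)
sample_series <- function(chol_sigma, t_frames, noise_sd) {
  n <- ncol(chol_sigma)
  x <- matrix(stats::rnorm(t_frames * n), t_frames, n) %*% chol_sigma
  if (noise_sd > 0)
    x <- x + matrix(stats::rnorm(t_frames * n, sd = noise_sd), t_frames, n)
  t(x)  # regions x time
}

# symmetric zero-diagonal deflection matrix for one subject (paired mode)
subject_deflection <- function(n, sd) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::rnorm(n * (n - 1) / 2, sd = sd)
  d + t(d)
}

#' Generate synthetic rest and task cohorts with known ground truth
#'
#' Per subject, a regions x T series is drawn from a zero-mean multivariate
#' normal whose target correlation matrix is the block-structured baseline
#' (task targets additionally carry the planted `delta_r` shifts), repaired
#' to the nearest valid correlation matrix when planting breaks positive
#' definiteness. In paired mode the same subjects appear in both cohorts and
#' a shared subject-level deflection is added to their targets before
#' sampling. Functional connectomes are computed with
#' [fc_from_timeseries()].
#'
#' @param spec A [synthetic_spec()].
#' @return List with `rest`, `task` ([cohort()]s), `rest_ts`, `task_ts`
#'   (lists of [time_series_set()]), `truth` (the planted-edge table with
#'   region labels attached), and `partition`.
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base <- baseline_target(spec)
  task_target <- apply_planted(base, spec$planted_edges)
  n <- spec$n_regions
  seeds <- spawn_seeds(spec$seed, 2L)
  make_cohort <- function(target_base, n_subjects, subject_ids, cond,
                          deflections, seed) {
    homogeneous <- is.null(deflections)
    chol_plain <- if (homogeneous)
      chol(nearest_correlation(target_base)) else NULL
    sub_seeds <- spawn_seeds(seed, n_subjects)
    ts_list <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      ch <- if (homogeneous) chol_plain
      else chol(nearest_correlation(target_base + deflections[[s]]))
      ts_list[[s]] <- with_seed(sub_seeds[s], {
        dat <- sample_series(ch, spec$t_frames, spec$noise_sd)
        rownames(dat) <- spec$region_ids
        time_series_set(subject_ids[s], dat, spec$sampling_interval)
      })
    }
    list(ts = ts_list,
         cohort = cohort(cond, lapply(ts_list, fc_from_timeseries),
                         subject_ids))
  }
  if (spec$paired) {
    n_sub <- spec$n_subjects_rest
    if (spec$n_subjects_task != n_sub)
      stop("generate_cohorts: paired mode requires equal cohort sizes")
    ids <- sprintf("SUB%03d", seq_len(n_sub))
    deflections <- with_seed(seeds[1L], lapply(seq_len(n_sub), function(s)
      subject_deflection(n, spec$subject_effect_sd)))
    rest <- make_cohort(base, n_sub, ids, "REST", deflections, seeds[1L] + 1L)
    task <- make_cohort(task_target, n_sub, ids, "TASK", deflections,
                        seeds[2L])
  } else {
    ids_rest <- sprintf("SUB%03d", seq_len(spec$n_subjects_rest))
    ids_task <- sprintf("SUB%03d",
                        spec$n_subjects_rest + seq_len(spec$n_subjects_task))
    # stable individual differences: one independent deflection per subject
    defl <- function(k, seed) if (spec$subject_effect_sd > 0)
      with_seed(seed, lapply(seq_len(k), function(s)
        subject_deflection(n, spec$subject_effect_sd)))
    else NULL
    rest <- make_cohort(base, spec$n_subjects_rest, ids_rest, "REST",
                        defl(spec$n_subjects_rest, seeds[1L] + 1L), seeds[1L])
    task <- make_cohort(task_target, spec$n_subjects_task, ids_task, "TASK",
                        defl(spec$n_subjects_task, seeds[2L] + 1L), seeds[2L])
  }
  truth <- spec$planted_edges
  if (nrow(truth) > 0L) {
    truth$region_i <- spec$region_ids[truth$i]
    truth$region_j <- spec$region_ids[truth$j]
  }
  list(rest = rest$cohort, task = task$cohort,
       rest_ts = rest$ts, task_ts = task$ts,
       truth = truth, partition = spec$partition)
}

#' Generate a synthetic structural connectome coupled to the spec
#'
#' Produces a symmetric nonnegative weight matrix on the log10-like scale
#' \eqn{[0, 5]}: within-network weights are drawn higher than between-network
#' ones, and (when `planted_weight = TRUE`) planted edges receive weights
#' that increase linearly with their `|delta_r|`, so structural weight
#' covaries with the planted functional shifts. The graph on positive weights
#' is complete, hence connected.
#'
#' @param spec A [synthetic_spec()].
#' @param within_range,between_range Uniform weight ranges for unplanted
#'   within- and between-network edges.
#' @param planted_weight Couple planted-edge weights to `|delta_r|`
#'   (default `TRUE`).
#' @param planted_range Weight range onto which `|delta_r|` is mapped.
#' @return An [sc_matrix()].
#' @export
generate_sc <- function(spec,
                        within_range = c(1.5, 4),
                        between_range = c(0.5, 3),
                        planted_weight = TRUE,
                        planted_range = c(3.5, 5)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_regions
  labels <- partition_labels(spec$partition, spec$region_ids)
  with_seed(spec$seed + 104729L, {
    w <- matrix(0, n, n, dimnames = list(spec$region_ids, spec$region_ids))
    ut <- which(upper.tri(w), arr.ind = TRUE)
    same <- labels[ut[, 1L]] == labels[ut[, 2L]]
    vals <- numeric(nrow(ut))
    vals[same] <- stats::runif(sum(same), within_range[1L], within_range[2L])
    vals[!same] <- stats::runif(sum(!same), between_range[1L], between_range[2L])
    w[upper.tri(w)] <- vals
    w <- w + t(w)
    if (planted_weight && nrow(spec$planted_edges) > 0L) {
      p <- spec$planted_edges
      d <- abs(p$delta_r)
      span <- if (diff(range(d)) > 0) (d - min(d)) / diff(range(d))
              else rep(1, length(d))
      pw <- planted_range[1L] + span * diff(planted_range)
      for (r in seq_len(nrow(p))) {
        w[p$i[r], p$j[r]] <- pw[r]
        w[p$j[r], p$i[r]] <- pw[r]
      }
    }
    w <- pmin(w, 5)
    sc_matrix(w, spec$region_ids)
  })
}

#' Write a complete synthetic fixture directory
#'
#' Materializes a [synthetic_spec()] on disk: cohort manifest + FC TSVs,
#' per-subject time-series TSVs, partition TSV, structural matrix TSV, the
#' planted-edge truth table, and the spec itself as YAML, so a full pipeline
#' run can be reproduced from plain-text files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param timeseries Also write per-subject time series (default `TRUE`).
#' @param sc_args Extra arguments passed on to [generate_sc()] (e.g. weight
#'   ranges).
#' @return Invisibly, the generated data list from [generate_cohorts()].
#' @export
write_synthetic_fixture <- function(spec, dir, timeseries = TRUE,
                                    sc_args = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_cohorts(spec)
  write_cohort_manifest(gen$rest, dir)
  write_cohort_manifest(gen$task, dir)
  write_partition_tsv(gen$partition, file.path(dir, "partition.tsv"))
  write_sc_matrix(do.call(generate_sc, c(list(spec), sc_args)),
                  file.path(dir, "sc.tsv"))
  utils::write.table(gen$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (timeseries) {
    ts_dir <- file.path(dir, "timeseries")
    dir.create(ts_dir, showWarnings = FALSE)
    for (i in seq_along(gen$rest_ts))
      write_timeseries_tsv(gen$rest_ts[[i]],
        file.path(ts_dir, sprintf("REST_%s.tsv", gen$rest$subjects[i])))
    for (i in seq_along(gen$task_ts))
      write_timeseries_tsv(gen$task_ts[[i]],
        file.path(ts_dir, sprintf("%s_%s.tsv", gen$task$condition,
                                  gen$task$subjects[i])))
  }
  cfg <- spec[setdiff(names(spec), c("partition", "region_ids",
                                     "planted_edges"))]
  cfg$planted_edges <- if (nrow(spec$planted_edges) > 0L)
    lapply(seq_len(nrow(spec$planted_edges)), function(r)
      as.list(spec$planted_edges[r, c("i", "j", "delta_r")]))
  else list()
  yaml::write_yaml(cfg, file.path(dir, "spec.yaml"))
  invisible(gen)
}
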