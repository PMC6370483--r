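# Structural-connectome side of the analysis: group-averaged log10 weights,
# search information on weighted shortest paths, percentile-bin assignment,
# CP/DP per bin, and the one-way ANOVA across bins.

#' Structural connectivity matrix (log10-transformed weights)
#'
#' Symmetric nonnegative matrix of structural connection weights between
#' regions, conventionally log10-transformed streamline measures spanning
#' roughly \eqn{[0, 5]}; zero entries mean absent connections.
#'
#' @param values Square numeric matrix, symmetric within 1e-10, nonnegative,
#'   zero diagonal.
#' @param region_ids Region labels; default from dimnames or `R1..Rn`.
#' @return An object of class `sc_matrix`.
#' @export
sc_matrix <- function(values, region_ids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("sc_matrix: matrix must be square")
  if (is.null(region_ids)) {
    region_ids <- rownames(values)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  }
  if (max(abs(values - t(values))) > 1e-10)
    stop("sc_matrix: matrix not symmetric within 1e-10")
  values <- (values + t(values)) / 2
  if (any(values < 0)) stop("sc_matrix: weights must be nonnegative")
  diag(values) <- 0
  dimnames(values) <- list(region_ids, region_ids)
  class(values) <- c("sc_matrix", "matrix", "array")
  values
}

#' @export
print.sc_matrix <- function(x, ...) {
  pos <- upper_tri_values(unclass(x))
  pos <- pos[pos > 0]
  cat(sprintf("<sc_matrix> %d regions, %d positive edges, weights in [%.3g, %.3g]\n",
              nrow(x), length(pos), if (length(pos)) min(pos) else NA,
              if (length(pos)) max(pos) else NA))
  invisible(x)
}

#' Read and write structural connectomes
#'
#' @param path File path (TSV matrix dialect).
#' @param sc An [sc_matrix()].
#' @export
read_sc_matrix <- function(path) sc_matrix(read_matrix_tsv(path))

#' @rdname read_sc_matrix
#' @export
write_sc_matrix <- function(sc, path) write_matrix_tsv(sc, path)

#' Group-averaged structural connectome
#'
#' Entry-wise arithmetic mean of individual log10-transformed structural
#' matrices sharing region ordering.
#'
#' @param scs An `sc_matrix` or list of them.
#' @return The mean `sc_matrix`.
#' @export
group_average_sc <- function(scs) {
  if (inherits(scs, "sc_matrix")) scs <- list(scs)
  if (length(scs) == 0L) stop("group_average_sc: empty input")
  ref <- rownames(scs[[1L]])
  for (m in scs)
    if (!identical(rownames(m), ref))
      stop("group_average_sc: region orderings differ")
  sc_matrix(Reduce(`+`, lapply(scs, unclass)) / length(scs), ref)
}

#' Search information on weighted shortest paths
#'
#' Search information SI(i -> j) is the number of bits a random walker needs
#' to follow the shortest path from i to j: \eqn{-\log_2} of the product over
#' consecutive path steps (u -> v) of the transition probability
#' \eqn{w_{uv} / s_u}, where \eqn{s_u} is the strength (sum of weights) of u.
#' High SI marks hidden, poorly accessible paths; low SI marks integrated
#' ones. Shortest paths are computed on edge lengths `1/weight` by default
#' (`"minusLog"` uses \eqn{-\log_{10}(w / \max w)} instead). The default
#' walker has no memory of the incoming step; `memory = TRUE` excludes the
#' edge just traversed from the strength at intermediate nodes.
#'
#' @param sc An [sc_matrix()]; the graph on its positive weights should be
#'   connected (unreachable pairs yield `NA` with a warning).
#' @param lengths `"inverse"` (default) or `"minusLog"` weight-to-length
#'   transform.
#' @param memory Logical; walker memory convention (default `FALSE`).
#' @return An `si_matrix`: n x n matrix of SI values in bits, zero diagonal,
#'   generally asymmetric, with attribute `symmetrized = FALSE`.
#' @export
search_information <- function(sc, lengths = c("inverse", "minusLog"),
                               memory = FALSE) {
  lengths <- match.arg(lengths)
  stopifnot(inherits(sc, "sc_matrix"))
  w <- unclass(sc)
  n <- nrow(w)
  len <- w
  pos <- w > 0
  len[pos] <- if (lengths == "inverse") 1 / w[pos]
              else -log10(w[pos] / max(w[pos]))
  # -log10 lengths can be 0 at the max edge; nudge to keep lengths positive
  if (lengths == "minusLog") len[pos] <- len[pos] + 1e-12
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  strength <- rowSums(w)
  si <- matrix(NA_real_, n, n, dimnames = dimnames(w))
  diag(si) <- 0
  for (i in seq_len(n)) {
    # igraph warns on unreachable vertices; those pairs are detected below
    # (empty vpath) and reported once as NA
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = i, to = igraph::V(g),
                             mode = "out", output = "vpath"))
    for (j in seq_len(n)) {
      if (j == i) next
      path <- as.integer(sp$vpath[[j]])
      if (length(path) < 2L) next  # unreachable
      bits <- 0
      for (s in seq_len(length(path) - 1L)) {
        u <- path[s]; v <- path[s + 1L]
        denom <- strength[u]
        if (memory && s > 1L) denom <- denom - w[path[s - 1L], u]
        bits <- bits - log2(w[u, v] / denom)
      }
      si[i, j] <- bits
    }
  }
  if (anyNA(si))
    warning("search_information: disconnected pairs reported as NA")
  structure(si, symmetrized = FALSE, lengths = lengths, memory = memory,
            class = c("si_matrix", "matrix", "array"))
}

#' @export
print.si_matrix <- function(x, ...) {
  cat(sprintf("<si_matrix> %d regions%s, SI in [%.3g, %.3g] bits\n",
              nrow(x), if (isTRUE(attr(x, "symmetrized"))) " (symmetrized)" else "",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Symmetrize a search-information matrix
#'
#' Mean of SI(i -> j) and SI(j -> i), used to build the group-average SI map
#' that is binned against the (undirected) JS masks.
#'
#' @param si An `si_matrix`.
#' @return A symmetrized `si_matrix`.
#' @export
symmetrize_si <- function(si) {
  stopifnot(inherits(si, "si_matrix"))
  out <- (unclass(si) + t(unclass(si))) / 2
  structure(out, symmetrized = TRUE, lengths = attr(si, "lengths"),
            memory = attr(si, "memory"),
            class = c("si_matrix", "matrix", "array"))
}

#' Assign edges to five percentile intervals
#'
#' Positive upper-triangular entries of a group-average SC (or symmetrized
#' SI) matrix are ranked and assigned to the five percentile intervals
#' \{0-20, 20-40, 40-60, 60-80, 80-100\}: interval b holds entries whose
#' percentile rank (100 * average rank / m) lies in (20(b-1), 20b]. Zero
#' entries (absent structural connections) are excluded. With all values tied
#' the average-rank rule places everything in one interval.
#'
#' @param matrix An `sc_matrix` or symmetrized `si_matrix` with at least 5
#'   positive upper-triangular entries.
#' @return An object of class `bin_assignment`: list with `bin` (n x n
#'   integer matrix, 1-5 for binned edges, NA elsewhere), `intervals` (labels)
#'   and `n_edges` (occupancy per interval).
#' @export
percentile_bin_assignment <- function(matrix) {
  m <- unclass(matrix)
  if (max(abs(m - t(m))) > 1e-10)
    stop("percentile_bin_assignment: matrix must be symmetric (symmetrize SI first)")
  ut <- upper.tri(m)
  vals <- m[ut]
  keep <- is.finite(vals) & vals > 0
  if (sum(keep) < 5L)
    stop("percentile_bin_assignment: need at least 5 positive entries")
  prank <- 100 * rank(vals[keep], ties.method = "average") / sum(keep)
  b <- pmin(ceiling(prank / 20), 5L)
  bin_ut <- rep(NA_integer_, length(vals))
  bin_ut[keep] <- as.integer(b)
  bin <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  bin[ut] <- bin_ut
  bin[lower.tri(bin)] <- t(bin)[lower.tri(bin)]
  intervals <- c("0-20", "20-40", "40-60", "60-80", "80-100")
  structure(list(bin = bin, intervals = intervals,
                 n_edges = tabulate(bin_ut, nbins = 5L)),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat("<bin_assignment> edges per percentile interval:\n")
  print(setNames(x$n_edges, x$intervals))
  invisible(x)
}

#' CP/DP percentages per structural percentile bin
#'
#' For each task mask and each percentile interval: the CP-type value is the
#' percentage of within-network edges in that interval that survive the JS
#' threshold; the DP-type value likewise for between-network edges. This is
#' the table behind the structure-function association analysis.
#'
#' @param masks A `threshold_mask` or list of them (one per task; names are
#'   used as condition labels).
#' @param part A [network_partition()].
#' @param bins A [percentile_bin_assignment()] on the matching regions.
#' @return data.frame with columns condition, interval, statistic
#'   (`"CP"`/`"DP"`), n_edges, n_surviving, percentage (NA for empty cells).
#' @export
cpdp_by_bin <- function(masks, part, bins) {
  if (inherits(masks, "threshold_mask")) masks <- list(masks)
  stopifnot(inherits(bins, "bin_assignment"))
  conds <- names(masks)
  if (is.null(conds)) conds <- paste0("TASK", seq_along(masks))
  out <- list()
  for (t in seq_along(masks)) {
    mask <- masks[[t]]
    cls <- edge_classes(rownames(mask), part)
    surv <- upper_tri_values(unclass(mask)) != 0
    bin_ut <- bins$bin[upper.tri(bins$bin)]
    for (b in 1:5) {
      for (stat in c("CP", "DP")) {
        idx <- !is.na(bin_ut) & bin_ut == b &
          (if (stat == "CP") cls$within else !cls$within)
        n_edges <- sum(idx)
        n_surv <- sum(surv[idx])
        out[[length(out) + 1L]] <- data.frame(
          condition = conds[t], interval = bins$intervals[b],
          statistic = stat, n_edges = n_edges, n_surviving = n_surv,
          percentage = if (n_edges > 0) 100 * n_surv / n_edges else NA_real_)
      }
    }
  }
  do.call(rbind, out)
}

#' Classical one-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA of values across groups (here: CP or
#' DP values of the tasks across the five percentile intervals), via
#' [stats::lm()].
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("one_way_anova: need at least 2 groups")
  if (length(values) != length(groups))
    stop("one_way_anova: values and groups must have equal length")
  if (length(values) <= nlevels(groups))
    stop("one_way_anova: need more observations than groups")
  if (stats::var(values) == 0)
    stop("one_way_anova: all values identical; F undefined")
  fit <- stats::lm(values ~ groups)
  tab <- stats::anova(fit)
  list(F = tab$`F value`[1L], df_between = tab$Df[1L],
       df_within = tab$Df[2L], p = tab$`Pr(>F)`[1L])
}

#' ANOVA of CP and DP across percentile bins
#'
#' Runs [one_way_anova()] separately for the CP and DP rows of a
#' [cpdp_by_bin()] table, with observations being the per-task percentages
#' and groups the five percentile intervals.
#'
#' @param bin_table Output of [cpdp_by_bin()].
#' @return Named list with elements `CP` and `DP`, each a one_way_anova
#'   result (or `NULL` with a warning when degenerate).
#' @export
anova_by_bin <- function(bin_table) {
  out <- list()
  for (stat in c("CP", "DP")) {
    rows <- bin_table[bin_table$statistic == stat & !is.na(bin_table$percentage), ]
    res <- tryCatch(one_way_anova(rows$percentage, rows$interval),
                    error = function(e) {
                      warning("anova_by_bin (", stat, "): ", conditionMessage(e))
                      NULL
                    })
    out[[stat]] <- res
  }
  out
}
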