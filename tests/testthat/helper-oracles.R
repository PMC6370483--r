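# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the package internals.

# Jensen-Shannon divergence by explicit loop over bins, base-2 logs
oracle_js_divergence <- function(p, q) {
  m <- numeric(length(p))
  for (i in seq_along(p)) m[i] <- (p[i] + q[i]) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# random probability vector over the bins of a binning scheme
random_prob <- function(binning, concentrate = FALSE) {
  k <- binning$n_bins
  w <- stats::rexp(k)
  if (concentrate) w[sample.int(k, sample(1:(k - 1), 1))] <- 0
  prob_vector(w / sum(w), binning)
}

# --- search-information oracle: exhaustive simple-path enumeration ----------

# all simple paths i -> j on the positive-weight graph
enumerate_paths <- function(w, i, j) {
  n <- nrow(w)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == j) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in seq_len(n))
      if (w[u, v] > 0 && !(v %in% path)) walk(c(path, v))
  }
  walk(i)
  paths
}

# SI via brute force: find the minimum-length simple path on lengths 1/w and
# multiply walker step probabilities along it
oracle_search_information <- function(w, i, j, memory = FALSE) {
  if (i == j) return(0)
  paths <- enumerate_paths(w, i, j)
  if (length(paths) == 0L) return(NA_real_)
  lens <- vapply(paths, function(p) {
    s <- 0
    for (k in seq_len(length(p) - 1L)) s <- s + 1 / w[p[k], p[k + 1L]]
    s
  }, numeric(1L))
  path <- paths[[which.min(lens)]]
  strength <- rowSums(w)
  prob <- 1
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    denom <- strength[u]
    if (memory && k > 1L) denom <- denom - w[path[k - 1L], u]
    prob <- prob * w[u, v] / denom
  }
  -log2(prob)
}

# random connected weighted graph on n nodes: random spanning tree (to force
# connectivity) plus extra random edges, weights U(0.5, 3)
random_connected_graph <- function(n) {
  w <- matrix(0, n, n)
  perm <- sample.int(n)
  for (k in seq_len(n - 1L)) {
    i <- perm[k]; j <- perm[k + 1L]
    w[i, j] <- w[j, i] <- stats::runif(1, 0.5, 3)
  }
  extra <- which(upper.tri(w) & w == 0)
  if (length(extra) > 0L) {
    add <- extra[stats::runif(length(extra)) < 0.4]
    w[add] <- stats::runif(length(add), 0.5, 3)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    w <- pmax(w, t(w))
  }
  w
}

# --- small fixture builders --------------------------------------------------

# naive symmetric matrix from upper-tri values (test-side, loop-based)
edges_to_matrix_for_test <- function(vals, n) {
  m <- matrix(0, n, n, dimnames = list(paste0("R", 1:n), paste0("R", 1:n)))
  k <- 0L
  for (j in 2:n) for (i in 1:(j - 1)) {
    k <- k + 1L
    m[i, j] <- m[j, i] <- vals[k]
  }
  m
}

upper_tri_values_for_test <- function(m) {
  m <- unclass(m)
  out <- c()
  for (j in 2:ncol(m)) for (i in 1:(j - 1)) out <- c(out, m[i, j])
  out
}

# a valid FC matrix where one edge (i, j) has value r and the rest ~0
fc_with_edge <- function(n, i, j, r, regions = paste0("R", seq_len(n))) {
  m <- diag(n)
  m[i, j] <- m[j, i] <- r
  fc_matrix(m, regions)
}

# cohort of n_sub copies of per-subject FCs built by fun(s)
build_cohort <- function(condition, n_sub, fun) {
  cohort(condition, lapply(seq_len(n_sub), fun),
         sprintf("%s%02d", condition, seq_len(n_sub)))
}

# quick random FC cohort from random time series (valid by construction)
random_fc_cohort <- function(condition, n_sub, n_regions, t_frames = 100,
                             prefix = condition) {
  build_cohort(condition, n_sub, function(s)
    fc_from_timeseries(time_series_set(
      paste0(prefix, s),
      matrix(stats::rnorm(n_regions * t_frames), n_regions, t_frames),
      0.72)))
}

# recall of planted edges inside a threshold mask
planted_recall <- function(mask, truth) {
  if (nrow(truth) == 0L) return(NA_real_)
  mean(mask[cbind(truth$i, truth$j)] != 0)
}
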