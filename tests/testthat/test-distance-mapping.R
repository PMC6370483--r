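test_that("edgewise_js_matrix is zero for identical cohorts and has zero diagonal", {
  set.seed(41)
  rest <- random_fc_cohort("REST", 10, 8)
  task <- cohort("TASK", rest$matrices, paste0("T", 1:10))
  js <- edgewise_js_matrix(rest, task)
  expect_identical(max(abs(js)), 0)
  rest2 <- random_fc_cohort("TASK", 10, 8)
  js2 <- edgewise_js_matrix(rest, rest2)
  expect_identical(unname(diag(unclass(js2))), rep(0, 8))
  expect_identical(unclass(js2), t(unclass(js2)))
  expect_true(all(js2 >= 0 & js2 <= 1))
})

test_that("edgewise_js_matrix is invariant to subject order within cohorts", {
  set.seed(43)
  rest <- random_fc_cohort("REST", 12, 10)
  task <- random_fc_cohort("TASK", 9, 10)
  js <- edgewise_js_matrix(rest, task)
  perm <- sample(length(rest$subjects))
  rest_p <- cohort("REST", rest$matrices[perm], rest$subjects[perm])
  expect_identical(unclass(edgewise_js_matrix(rest_p, task)), unclass(js))
})

test_that("planted edges dominate the unpaired JS map", {
  truth <- data.frame(i = 1:20, j = 21:40, delta_r = 0.8)
  spec <- synthetic_spec(n_regions = 60, n_subjects_rest = 50,
                         n_subjects_task = 50, t_frames = 300,
                         planted_edges = truth, seed = 101)
  gen <- generate_cohorts(spec)
  js <- edgewise_js_matrix(gen$rest, gen$task)
  planted <- js[cbind(truth$i, truth$j)]
  ut <- upper.tri(js)
  ut[cbind(truth$i, truth$j)] <- FALSE
  unplanted <- unclass(js)[ut]
  expect_gt(mean(planted), quantile(unplanted, 0.99))
})

test_that("edgewise_paired_js_matrix honours the paired contract", {
  set.seed(47)
  rest <- random_fc_cohort("REST", 8, 6)
  same <- cohort("TASK", rest$matrices, rest$subjects)
  expect_identical(max(abs(edgewise_paired_js_matrix(rest, same))), 0)
  # one edge shifted by exactly +1.0 for every subject -> distance 1 there
  base <- build_cohort("REST", 8, function(s) fc_with_edge(6, 1, 2, -0.5))
  task <- build_cohort("TASK", 8, function(s) fc_with_edge(6, 1, 2, 0.5))
  task <- cohort("TASK", task$matrices, base$subjects)
  js <- edgewise_paired_js_matrix(base, task)
  expect_identical(js[1, 2], 1)
  expect_identical(sum(unclass(js) != 0), 2L)  # only that edge (and its mirror)
  # jitter inside the zero bin [0, 0.1) stays at distance zero
  set.seed(48)
  jit <- build_cohort("TASK", 8, function(s)
    fc_with_edge(6, 1, 2, -0.5 + runif(1, 0, 0.099)))
  jit <- cohort("TASK", jit$matrices, base$subjects)
  expect_identical(max(abs(edgewise_paired_js_matrix(base, jit))), 0)
  # subject mismatch is a pairing error
  other <- cohort("TASK", rest$matrices, paste0("X", 1:8))
  expect_error(edgewise_paired_js_matrix(rest, other), "subject lists")
})

test_that("threshold_pooled uses linear-interpolation percentile and strict survival", {
  # 10 distinct upper-tri entries 0.01..0.10 at percentile 95 -> only the max
  vals <- seq(0.01, 0.10, by = 0.01)
  m <- edges_to_matrix_for_test(vals, 5)
  js <- structure(m, condition = "T1", class = c("js_matrix", "matrix", "array"))
  thr <- threshold_pooled(list(js), 95)
  expect_equal(thr$cutoff, unname(quantile(vals, 0.95, type = 7)))
  expect_identical(sum(upper_tri_values_for_test(thr$masks[[1]])), 1L)
  expect_identical(thr$masks[[1]][4, 5], 1L)  # the 0.10 entry
  # all-tied entries: strict inequality keeps nothing
  tied <- structure(edges_to_matrix_for_test(rep(0.3, 10), 5),
                    class = c("js_matrix", "matrix", "array"))
  thr2 <- threshold_pooled(list(tied), 95)
  expect_identical(sum(thr2$masks[[1]]), 0L)
  # pooled across seven tie-free maps: survivors match the brute-force top-5%
  set.seed(53)
  maps <- lapply(1:7, function(k) structure(
    edges_to_matrix_for_test(runif(45), 10),
    condition = paste0("T", k), class = c("js_matrix", "matrix", "array")))
  thr3 <- threshold_pooled(maps, 95)
  pooled <- sort(unlist(lapply(maps, upper_tri_values_for_test)))
  expected <- sum(pooled > quantile(pooled, 0.95, type = 7))
  got <- sum(vapply(thr3$masks, function(m) sum(m != 0) / 2, numeric(1)))
  expect_identical(as.integer(got), as.integer(expected))
  expect_lte(abs(got - 0.05 * length(pooled)), 1)
  # boundary percentiles
  thr0 <- threshold_pooled(maps, 0)
  expect_identical(
    as.integer(sum(vapply(thr0$masks, function(m) sum(m != 0) / 2, numeric(1)))),
    as.integer(sum(pooled > min(pooled))))
  thr100 <- threshold_pooled(maps, 100)
  expect_identical(sum(vapply(thr100$masks, sum, numeric(1))), 0)
  expect_error(threshold_pooled(list(), 95), "empty")
  expect_error(threshold_pooled(maps, 101), "percentile")
})

test_that("CP and DP count surviving edges per network correctly", {
  # 7 regions: network A = 4 regions, B = 3 regions
  regions <- paste0("R", 1:7)
  part <- network_partition(setNames(c(rep("A", 4), rep("B", 3)), regions))
  mask <- matrix(0L, 7, 7, dimnames = list(regions, regions))
  # 3 of A's 6 within edges survive
  mask[1, 2] <- mask[1, 3] <- mask[3, 4] <- 1L
  # 6 of the 12 A-B edges survive
  mask[1, 5] <- mask[1, 6] <- mask[2, 5] <- mask[2, 7] <- mask[3, 6] <- mask[4, 7] <- 1L
  mask <- mask + t(mask)
  mask <- structure(mask, cutoff = 0.5, percentile = 95,
                    class = c("threshold_mask", "matrix", "array"))
  cp <- centralized_processing(mask, part)
  expect_equal(cp[["A"]], 0.5)
  expect_equal(cp[["B"]], 0)
  dp <- distributed_processing(mask, part)
  expect_equal(dp[["A|B"]], 0.5)
  # all within edges survive -> CP 1; empty mask -> all zero
  full <- structure((1 - diag(7)) * 1L, cutoff = 0, percentile = 95,
                    dimnames = list(regions, regions),
                    class = c("threshold_mask", "matrix", "array"))
  expect_equal(unname(centralized_processing(full, part)), c(1, 1))
  expect_equal(unname(distributed_processing(full, part)), 1)
  empty <- structure(matrix(0L, 7, 7, dimnames = list(regions, regions)),
                     cutoff = 1, percentile = 95,
                     class = c("threshold_mask", "matrix", "array"))
  expect_equal(unname(centralized_processing(empty, part)), c(0, 0))
  expect_equal(unname(distributed_processing(empty, part)), 0)
  # a singleton network has undefined CP
  part3 <- network_partition(setNames(c(rep("A", 6), "C"), regions))
  expect_warning(cp3 <- centralized_processing(mask, part3), "C")
  expect_true(is.na(cp3[["C"]]))
})

test_that("edge-class conservation: within + between survivors = total", {
  set.seed(59)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    regions <- paste0("R", seq_len(n))
    k <- sample(2:5, 1)
    part <- network_partition(setNames(
      sample(LETTERS[1:k], n, replace = TRUE), regions))
    # force every network nonempty
    part <- network_partition(setNames(
      c(LETTERS[1:k], sample(LETTERS[1:k], n - k, replace = TRUE)), regions))
    mask <- matrix(0L, n, n, dimnames = list(regions, regions))
    ut <- which(upper.tri(mask))
    on <- sample(ut, ceiling(length(ut) / 4))
    mask[on] <- 1L
    mask <- mask + t(mask)
    mask <- structure(mask, cutoff = 0, percentile = 95,
                      class = c("threshold_mask", "matrix", "array"))
    total <- length(on)
    cls <- connectodist:::edge_classes(regions, part)
    surv <- connectodist:::upper_tri_values(unclass(mask)) != 0
    cp_counts <- sum(surv[cls$within])
    dp_counts <- sum(surv[!cls$within])
    expect_identical(cp_counts + dp_counts, total)
  }
})

test_that("cross_task_summary computes entry-wise max and median", {
  regions <- paste0("R", 1:4)
  mk <- function(v) structure(
    edges_to_matrix_for_test(v, 4), dimnames = list(regions, regions),
    condition = "X", class = c("js_matrix", "matrix", "array"))
  maps <- list(mk(rep(0.1, 6)), mk(rep(0.2, 6)), mk(rep(0.6, 6)))
  cs_max <- cross_task_summary(maps, "max")
  cs_med <- cross_task_summary(maps, "median")
  expect_equal(cs_max$summary[1, 2], 0.6)
  expect_equal(cs_med$summary[1, 2], 0.2)
  # even task count: midpoint mean
  cs2 <- cross_task_summary(maps[1:2], "median")
  expect_equal(cs2$summary[1, 2], 0.15)
  # single task: summary values equal the input values
  vals <- function(m) structure(as.numeric(unclass(m)), dim = dim(m))
  expect_equal(vals(cross_task_summary(maps[3], "max")$summary),
               vals(maps[[3]]))
  expect_equal(vals(cross_task_summary(maps[3], "median")$summary),
               vals(maps[[3]]))
  expect_error(cross_task_summary(list(), "max"), "empty")
})

test_that("nodal_js_strength divides suprathreshold strength by region count", {
  regions <- paste0("R", 1:4)
  js <- structure(edges_to_matrix_for_test(rep(0, 6), 4),
                  dimnames = list(regions, regions),
                  class = c("js_matrix", "matrix", "array"))
  js[1, 2] <- js[2, 1] <- 0.8
  mask <- matrix(0L, 4, 4, dimnames = list(regions, regions))
  mask[1, 2] <- mask[2, 1] <- 1L
  strength <- nodal_js_strength(js, structure(
    mask, class = c("threshold_mask", "matrix", "array")))
  expect_equal(unname(strength), c(0.2, 0.2, 0, 0))
  # empty mask -> zeros
  zero <- nodal_js_strength(js, structure(
    mask * 0L, class = c("threshold_mask", "matrix", "array")))
  expect_identical(unname(zero), rep(0, 4))
  # permutation equivariance
  set.seed(61)
  js_r <- structure(edges_to_matrix_for_test(runif(6), 4),
                    dimnames = list(regions, regions),
                    class = c("js_matrix", "matrix", "array"))
  mask_r <- structure((unclass(js_r) > 0.3) * 1L,
                      class = c("threshold_mask", "matrix", "array"))
  s <- nodal_js_strength(js_r, mask_r)
  perm <- c(3, 1, 4, 2)
  s_p <- nodal_js_strength(
    structure(unclass(js_r)[perm, perm],
              class = c("js_matrix", "matrix", "array")),
    structure(unclass(mask_r)[perm, perm],
              class = c("threshold_mask", "matrix", "array")))
  expect_equal(unname(s_p), unname(s)[perm])
})

test_that("js_baseline_correlation detects construction and independence", {
  set.seed(67)
  rest <- random_fc_cohort("REST", 7, 30, t_frames = 80)
  med <- apply(connectodist:::cohort_edge_values(rest), 2, median)
  # JS built as an increasing function of the median rest FC
  js_inc <- structure(
    connectodist:::edges_to_matrix((med + 1) / 2.2, rest$region_ids),
    class = c("js_matrix", "matrix", "array"))
  expect_gt(js_baseline_correlation(js_inc, rest), 0.99)
  # independent random JS over many edges: negligible correlation
  rest_big <- random_fc_cohort("REST", 5, 142, t_frames = 60)
  n_edges <- 142 * 141 / 2
  js_rand <- structure(
    connectodist:::edges_to_matrix(runif(n_edges), rest_big$region_ids),
    class = c("js_matrix", "matrix", "array"))
  expect_lt(abs(js_baseline_correlation(js_rand, rest_big)), 0.05)
  # constant JS vector -> undefined correlation
  js_const <- structure(
    connectodist:::edges_to_matrix(rep(0.4, 435), rest$region_ids),
    class = c("js_matrix", "matrix", "array"))
  expect_error(js_baseline_correlation(js_const, rest), "constant")
})

test_that("cpdp_cosine_similarity is 1 for identical/scaled tables, 0 for orthogonal", {
  cp <- c(A = 0.2, B = 0.1)
  dp <- c(`A|B` = 0.3)
  ta <- structure(list(cp = cp, dp = dp, condition = "X"),
                  class = "cpdp_table")
  tb <- structure(list(cp = 2 * cp, dp = 2 * dp, condition = "Y"),
                  class = "cpdp_table")
  expect_equal(unname(cpdp_cosine_similarity(ta, ta)), c(1, 1))
  expect_equal(unname(cpdp_cosine_similarity(ta, tb)), c(1, 1))
  t_orth_a <- structure(list(cp = c(A = 1, B = 1), dp = c(`A|B` = 0),
                             condition = "X"), class = "cpdp_table")
  t_orth_b <- structure(list(cp = c(A = 0, B = 0), dp = c(`A|B` = 1),
                             condition = "Y"), class = "cpdp_table")
  expect_equal(unname(cpdp_cosine_similarity(t_orth_a, t_orth_b)), c(0, 0))
  t_zero <- structure(list(cp = c(A = 0, B = 0), dp = c(`A|B` = 0),
                           condition = "Z"), class = "cpdp_table")
  expect_error(cpdp_cosine_similarity(t_orth_a, t_zero), "zero")
})
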