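test_that("generation is bit-identical under the same seed", {
  spec <- synthetic_spec(n_regions = 24, n_subjects_rest = 4,
                         n_subjects_task = 4, t_frames = 80, seed = 5)
  g1 <- generate_cohorts(spec)
  g2 <- generate_cohorts(spec)
  expect_identical(lapply(g1$rest$matrices, unclass),
                   lapply(g2$rest$matrices, unclass))
  expect_identical(lapply(g1$task$matrices, unclass),
                   lapply(g2$task$matrices, unclass))
  expect_identical(g1$rest_ts[[2]]$data, g2$rest_ts[[2]]$data)
  g3 <- generate_cohorts(synthetic_spec(n_regions = 24, n_subjects_rest = 4,
                                        n_subjects_task = 4, t_frames = 80,
                                        seed = 6))
  expect_false(identical(g1$rest_ts[[1]]$data, g3$rest_ts[[1]]$data))
})

test_that("generated FCs satisfy the FC invariants and cohorts are disjoint", {
  spec <- synthetic_spec(n_regions = 20, n_subjects_rest = 5,
                         n_subjects_task = 6, t_frames = 100, seed = 7)
  gen <- generate_cohorts(spec)
  expect_identical(length(gen$rest$subjects), 5L)
  expect_identical(length(gen$task$subjects), 6L)
  expect_length(intersect(gen$rest$subjects, gen$task$subjects), 0)
  for (m in c(gen$rest$matrices, gen$task$matrices)) {
    expect_s3_class(m, "fc_matrix")   # constructor enforced the invariants
    expect_identical(unname(diag(unclass(m))), rep(1, 20))
  }
})

test_that("planted edges hit their target correlation on average", {
  truth <- data.frame(i = 1, j = 2, delta_r = 0.5)  # same block: baseline 0.2
  spec <- synthetic_spec(n_regions = 30, n_subjects_rest = 50,
                         n_subjects_task = 50, t_frames = 1200,
                         within_block_r = 0.2, planted_edges = truth,
                         seed = 11)
  gen <- generate_cohorts(spec)
  task_r <- vapply(gen$task$matrices, function(m) m[1, 2], numeric(1))
  rest_r <- vapply(gen$rest$matrices, function(m) m[1, 2], numeric(1))
  expect_lt(abs(mean(task_r) - 0.7), 0.05)
  expect_lt(abs(mean(rest_r) - 0.2), 0.05)
})

test_that("no-effect cohorts are exchangeable with a same-condition split", {
  # JS values from rest-vs-task (no planted effect) should be distributed
  # like JS values from splitting one condition's cohort in half
  ps <- numeric(5)
  for (rep in 1:5) {
    spec <- synthetic_spec(n_regions = 30, n_subjects_rest = 40,
                           n_subjects_task = 20, t_frames = 150,
                           seed = 300 + rep)
    gen <- generate_cohorts(spec)
    half1 <- cohort("REST", gen$rest$matrices[1:20], gen$rest$subjects[1:20])
    half2 <- cohort("RESTB", gen$rest$matrices[21:40], gen$rest$subjects[21:40])
    js_split <- edgewise_js_matrix(half1, half2)
    js_task <- edgewise_js_matrix(half1, gen$task)
    ks <- suppressWarnings(ks.test(js_split[upper.tri(js_split)],
                                   js_task[upper.tri(js_task)]))
    ps[rep] <- ks$p.value
  }
  expect_gt(median(ps), 0.05)
})

test_that("planted-edge recovery improves with effect size", {
  deltas <- c(0.1, 0.3, 0.5, 0.8)
  recall <- matrix(NA_real_, 10, length(deltas))
  for (rep in 1:10) {
    for (d in seq_along(deltas)) {
      truth <- data.frame(i = 1:10, j = 21:30, delta_r = deltas[d])
      spec <- synthetic_spec(n_regions = 50, n_subjects_rest = 20,
                             n_subjects_task = 20, t_frames = 120,
                             planted_edges = truth,
                             seed = 1000 + 17 * rep + d)
      gen <- generate_cohorts(spec)
      js <- edgewise_js_matrix(gen$rest, gen$task)
      mask <- threshold_pooled(list(js), 95)$masks[[1]]
      recall[rep, d] <- planted_recall(mask, gen$truth)
    }
  }
  avg <- colMeans(recall)
  expect_true(all(diff(avg) >= -0.02))   # nondecreasing in delta
  expect_gte(avg[4], 0.9)                # large effects are recovered
})

test_that("subject effects cancel in the paired differences but inflate unpaired JS", {
  # the task-rest difference removes the shared per-subject deflection, so
  # the paired map is insensitive to subject_effect_sd; the unpaired map
  # sees the wider across-subject spread and its sampling JS grows
  stats_at <- function(sd) {
    spec <- synthetic_spec(n_regions = 24, n_subjects_rest = 30,
                           n_subjects_task = 30, t_frames = 800,
                           paired = TRUE, subject_effect_sd = sd, seed = 23)
    gen <- generate_cohorts(spec)
    expect_identical(gen$rest$subjects, gen$task$subjects)
    paired <- edgewise_paired_js_matrix(gen$rest, gen$task)
    unpaired <- suppressWarnings(edgewise_js_matrix(gen$rest, gen$task))
    c(paired = mean(paired[upper.tri(paired)]),
      unpaired = mean(unpaired[upper.tri(unpaired)]))
  }
  lo <- stats_at(0)
  hi <- stats_at(0.25)
  expect_lt(abs(hi[["paired"]] - lo[["paired"]]), 0.02)
  expect_gt(hi[["unpaired"]] - lo[["unpaired"]], 0.01)
  # and a genuinely shifted edge still stands far above the paired floor
  truth <- data.frame(i = 1, j = 2, delta_r = 0.6)
  spec <- synthetic_spec(n_regions = 24, n_subjects_rest = 30,
                         n_subjects_task = 30, t_frames = 800, paired = TRUE,
                         subject_effect_sd = 0.1, planted_edges = truth,
                         seed = 27)
  gen <- generate_cohorts(spec)
  paired <- edgewise_paired_js_matrix(gen$rest, gen$task)
  floor_vals <- paired[upper.tri(paired)]
  expect_gt(paired[1, 2], quantile(floor_vals, 0.99))
})

test_that("synthetic SC spans [0,5], favors within-block edges, is connected", {
  truth <- data.frame(i = c(1, 2, 3), j = c(4, 5, 6),
                      delta_r = c(0.2, 0.5, 0.7))
  spec <- synthetic_spec(n_regions = 30, n_subjects_rest = 4,
                         n_subjects_task = 4, t_frames = 80,
                         planted_edges = truth, seed = 29)
  sc <- generate_sc(spec)
  w <- unclass(sc)
  expect_lte(max(w), 5)
  expect_gte(min(w), 0)
  labels <- spec$partition$assignment[rownames(sc)]
  same <- outer(labels, labels, "==") & upper.tri(w)
  diff_b <- (!outer(labels, labels, "==")) & upper.tri(w)
  expect_gt(mean(w[same]), mean(w[diff_b]))
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  expect_identical(as.integer(igraph::components(g)$no), 1L)
  # planted weights increase with |delta_r|
  pw <- w[cbind(truth$i, truth$j)]
  expect_true(all(diff(pw) > 0))
  # deterministic given the spec seed
  expect_identical(unclass(generate_sc(spec)), w)
})

test_that("target repair yields valid correlation matrices under heavy planting", {
  # many large planted shifts can break positive definiteness; the generator
  # must repair and still return legal FCs
  truth <- data.frame(i = rep(1, 8), j = 2:9,
                      delta_r = rep(0.75, 8))
  spec <- synthetic_spec(n_regions = 12, n_subjects_rest = 3,
                         n_subjects_task = 3, t_frames = 60,
                         within_block_r = 0.1, planted_edges = truth,
                         seed = 31)
  gen <- generate_cohorts(spec)
  expect_s3_class(gen$task$matrices[[1]], "fc_matrix")
  m <- nearest_correlation(matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9,
                                    -0.9, 0.9, 1), 3, 3))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_identical(unname(diag(m)), rep(1, 3))
})
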