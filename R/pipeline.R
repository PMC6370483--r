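# End-to-end pipeline commands over a YAML run configuration. These are the
# functions behind the inst/cli front end: simulate / distance / null /
# structure, each writing TSV tables plus a JSON run summary.

#' Read and validate a run configuration
#'
#' A flat YAML file describing one analysis run. Recognised keys (defaults in
#' parentheses): `manifest` (path to a cohort manifest TSV), `rest_condition`
#' (`"REST"`), `task_conditions` (all non-rest conditions in the manifest),
#' `partition` (path), `sc` (path, optional), `mode` (`"unpaired"`),
#' `binning`: `lower`/`upper`/`width` (-1/1/0.2 unpaired, -2/2/0.1 paired),
#' `percentile` (95), `null`: `n_realizations` (100), `kind`
#' (`"permutation"`), `bandpass`: `rest` ([0.001, 0.08] Hz), `task`
#' ([0.001, 0.25] Hz), `seed` (1), `out` (output directory).
#'
#' @param path YAML config path.
#' @param require Character vector of keys that must be present.
#' @return Named list with defaults filled in, class `run_config`.
#' @export
read_run_config <- function(path, require = "manifest") {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  defaults <- list(rest_condition = "REST", mode = "unpaired",
                   percentile = 95, seed = 1,
                   null = list(n_realizations = 100, kind = "permutation"),
                   bandpass = list(rest = c(0.001, 0.08),
                                   task = c(0.001, 0.25)))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$binning))
    cfg$binning <- if (identical(cfg$mode, "paired"))
      list(lower = -2, upper = 2, width = 0.1)
    else list(lower = -1, upper = 1, width = 0.2)
  for (k in require)
    if (is.null(cfg[[k]])) stop("config: required field '", k, "' missing")
  for (k in intersect(c("manifest", "partition", "sc"), names(cfg))) {
    if (!file.exists(cfg[[k]]) && file.exists(file.path(base, cfg[[k]])))
      cfg[[k]] <- file.path(base, cfg[[k]])
    if (!file.exists(cfg[[k]]))
      stop("config: file for '", k, "' not found: ", cfg[[k]])
  }
  if (!(cfg$percentile > 0 && cfg$percentile < 100))
    stop("config: percentile must be in (0, 100)")
  if (!cfg$mode %in% c("unpaired", "paired"))
    stop("config: mode must be 'unpaired' or 'paired'")
  if (cfg$null$n_realizations < 1)
    stop("config: null.n_realizations must be >= 1")
  structure(cfg, class = c("run_config", "list"))
}

config_binning <- function(cfg)
  binning_scheme(cfg$binning$lower, cfg$binning$upper, cfg$binning$width)

# load all task cohorts named in the config
load_cohorts <- function(cfg) {
  manifest <- utils::read.table(cfg$manifest, sep = "\t", header = TRUE,
                                colClasses = "character")
  conds <- unique(manifest$condition)
  if (!cfg$rest_condition %in% conds)
    stop("config: rest condition '", cfg$rest_condition,
         "' absent from manifest")
  tasks <- cfg$task_conditions
  if (is.null(tasks)) tasks <- setdiff(conds, cfg$rest_condition)
  rest <- read_cohort_manifest(cfg$manifest, cfg$rest_condition)
  task_cohorts <- lapply(tasks, function(tc)
    read_cohort_manifest(cfg$manifest, tc))
  names(task_cohorts) <- tasks
  list(rest = rest, tasks = task_cohorts)
}

run_summary <- function(cfg, extra = list()) {
  c(list(package_version = as.character(utils::packageVersion("connectodist")),
         seed = cfg$seed,
         config_hash = config_hash(cfg),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

# deterministic hash of the config contents (not file identity)
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  # polynomial rolling hash over the serialized text; hex string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the simulate command
#'
#' Builds a [synthetic_spec()] from the `simulate` section of the config
#' (fields mirror the `synthetic_spec()` arguments) and writes a complete
#' fixture directory with [write_synthetic_fixture()].
#'
#' @param config Path to a YAML config (needs a `simulate` section) or a
#'   `run_config`.
#' @param out Output directory (overrides the config's `out`).
#' @param seed Optional seed override.
#' @return Invisibly, the generated data list.
#' @export
run_simulate <- function(config, out = NULL, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config, require = character())
  sim <- cfg$simulate
  if (is.null(sim)) sim <- list()
  if (!is.null(seed)) cfg$seed <- seed
  sim$seed <- cfg$seed
  if (!is.null(sim$planted_edges))
    sim$planted_edges <- do.call(rbind, lapply(sim$planted_edges, as.data.frame))
  spec <- do.call(synthetic_spec, sim)
  out <- out %||% cfg$out %||% stop("run_simulate: no output directory")
  gen <- write_synthetic_fixture(spec, out)
  jsonlite::write_json(run_summary(cfg, list(command = "simulate",
                                             n_regions = spec$n_regions)),
                       file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(gen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the distance command
#'
#' Computes one edgewise JS matrix per task against the rest baseline, the
#' pooled percentile cutoff and masks, CP/DP tables, cross-task max and
#' median summary maps with their own masks, nodal JS strengths, and a JSON
#' run summary.
#'
#' @param config Path to a YAML config or a `run_config`; needs `manifest`
#'   and `partition`.
#' @param out Output directory (overrides config).
#' @param seed Optional seed override (recorded; the distance computation
#'   itself is deterministic).
#' @return Invisibly, a list with `js` (per task), `cutoff`, `masks`,
#'   `cpdp`, `summaries`.
#' @export
run_distance <- function(config, out = NULL, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config, require = c("manifest", "partition"))
  if (!is.null(seed)) cfg$seed <- seed
  out <- out %||% cfg$out %||% stop("run_distance: no output directory")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  part <- read_partition_tsv(cfg$partition)
  data <- load_cohorts(cfg)
  binning <- config_binning(cfg)
  js_list <- lapply(data$tasks, function(tc) {
    if (identical(cfg$mode, "paired"))
      edgewise_paired_js_matrix(data$rest, tc, binning)
    else edgewise_js_matrix(data$rest, tc, binning)
  })
  thr <- threshold_pooled(js_list, cfg$percentile)
  tables <- lapply(names(js_list), function(cond)
    cpdp_table(thr$masks[[cond]], part, cond))
  names(tables) <- names(js_list)
  for (cond in names(js_list)) {
    write_matrix_tsv(js_list[[cond]],
                     file.path(out, sprintf("js_%s.tsv", cond)))
    write_matrix_tsv(thr$masks[[cond]],
                     file.path(out, sprintf("mask_%s.tsv", cond)))
  }
  cpdp_tab <- cpdp_long(tables)
  utils::write.table(cpdp_tab, file.path(out, "cpdp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summaries <- list()
  for (stat in c("max", "median")) {
    cs <- cross_task_summary(js_list, stat, cfg$percentile)
    summaries[[stat]] <- cs
    write_matrix_tsv(cs$summary, file.path(out, sprintf("js_%s.tsv", stat)))
    write_matrix_tsv(cs$mask, file.path(out, sprintf("mask_%s.tsv", stat)))
    strength <- nodal_js_strength(cs$summary, cs$mask)
    utils::write.table(
      data.frame(region_id = names(strength), strength = fmt_num(strength)),
      file.path(out, sprintf("nodal_strength_%s.tsv", stat)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  n_edges <- length(upper_tri_values(unclass(js_list[[1L]])))
  jsonlite::write_json(
    run_summary(cfg, list(
      command = "distance", cutoff = thr$cutoff,
      percentile = cfg$percentile, mode = cfg$mode,
      tasks = names(js_list),
      surviving_edges = vapply(thr$masks, function(m)
        sum(upper_tri_values(unclass(m))), numeric(1L)),
      edges_per_task = n_edges)),
    file.path(out, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(js = js_list, cutoff = thr$cutoff, masks = thr$masks,
                 cpdp = tables, summaries = summaries))
}

#' Run the null command
#'
#' Label-permutation null (always) and, when per-subject time series are
#' available under `timeseries_dir`, the AAFT surrogate null, per task. The
#' cutoff is taken from a previous [run_distance()] summary in `distance_dir`
#' or recomputed inline.
#'
#' @param config Path to a YAML config or a `run_config`.
#' @param out Output directory.
#' @param seed Optional seed override.
#' @param distance_dir Directory holding a `run_summary.json` from
#'   [run_distance()]; defaults to `out`.
#' @return Invisibly, a list of `null_distribution`s per task and kind.
#' @export
run_null <- function(config, out = NULL, seed = NULL, distance_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config, require = c("manifest"))
  if (!is.null(seed)) cfg$seed <- seed
  out <- out %||% cfg$out %||% stop("run_null: no output directory")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data <- load_cohorts(cfg)
  binning <- config_binning(cfg)
  distance_dir <- distance_dir %||% out
  summary_path <- file.path(distance_dir, "run_summary.json")
  cutoff <- if (file.exists(summary_path)) {
    s <- jsonlite::read_json(summary_path)
    if (!is.null(s$cutoff)) as.numeric(s$cutoff) else NULL
  } else NULL
  js_list <- lapply(data$tasks, function(tc)
    suppressWarnings(edgewise_js_matrix(data$rest, tc, binning)))
  if (is.null(cutoff))
    cutoff <- threshold_pooled(js_list, cfg$percentile)$cutoff
  results <- list()
  for (cond in names(data$tasks)) {
    observed <- sum(upper_tri_values(unclass(js_list[[cond]])) > cutoff)
    perm <- label_permutation_test(data$rest, data$tasks[[cond]], cutoff,
                                   cfg$null$n_realizations, cfg$seed, binning)
    write_null_distribution(perm,
      file.path(out, sprintf("null_permutation_%s.tsv", cond)),
      file.path(out, sprintf("null_permutation_%s.json", cond)))
    results[[paste0("permutation_", cond)]] <- perm
    if (!is.null(cfg$timeseries_dir)) {
      read_ts <- function(c_, subjects) lapply(subjects, function(s)
        read_timeseries_tsv(
          file.path(cfg$timeseries_dir, sprintf("%s_%s.tsv", c_, s)),
          s, cfg$sampling_interval %||% 0.72))
      sur <- surrogate_null(
        read_ts(cfg$rest_condition, data$rest$subjects),
        read_ts(cond, data$tasks[[cond]]$subjects),
        cutoff, cfg$null$n_realizations, cfg$seed, binning,
        condition = cond, observed = observed)
      write_null_distribution(sur,
        file.path(out, sprintf("null_surrogate_%s.tsv", cond)),
        file.path(out, sprintf("null_surrogate_%s.json", cond)))
      results[[paste0("surrogate_", cond)]] <- sur
    }
  }
  jsonlite::write_json(
    run_summary(cfg, list(command = "null", cutoff = cutoff,
                          n_realizations = cfg$null$n_realizations)),
    file.path(out, "null_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Run the structure command
#'
#' Bins the group-average structural weights and the symmetrized search
#' information into five percentile intervals, tabulates CP/DP per interval
#' and task, and runs the one-way ANOVA of CP and DP across intervals.
#'
#' @param config Path to a YAML config or `run_config`; needs `manifest`,
#'   `partition` and `sc`.
#' @param out Output directory.
#' @param seed Optional seed override.
#' @return Invisibly, list with `sc_table`, `si_table` and `anova` results.
#' @export
run_structure <- function(config, out = NULL, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config,
                              require = c("manifest", "partition", "sc"))
  if (!is.null(seed)) cfg$seed <- seed
  out <- out %||% cfg$out %||% stop("run_structure: no output directory")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  part <- read_partition_tsv(cfg$partition)
  sc <- read_sc_matrix(cfg$sc)
  dist <- run_distance(cfg, out = file.path(out, "distance"))
  masks <- dist$masks
  sc_bins <- percentile_bin_assignment(sc)
  si <- symmetrize_si(search_information(sc))
  si_bins <- percentile_bin_assignment(si)
  sc_table <- cpdp_by_bin(masks, part, sc_bins)
  si_table <- cpdp_by_bin(masks, part, si_bins)
  utils::write.table(sc_table, file.path(out, "cpdp_by_sc_bin.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(si_table, file.path(out, "cpdp_by_si_bin.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  anova <- list(sc = anova_by_bin(sc_table), si = anova_by_bin(si_table))
  jsonlite::write_json(
    run_summary(cfg, list(command = "structure", anova = anova)),
    file.path(out, "structure_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(sc_table = sc_table, si_table = si_table, anova = anova))
}
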