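# Plain-text I/O. All matrices use one TSV dialect: a header row of region
# IDs followed by n numeric rows; numbers are written with 17 significant
# digits so write/read round-trips are bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write square matrices as TSV
#'
#' The matrix dialect used for FC, JS, SC, SI and mask matrices: a header row
#' with the n region IDs, then n tab-separated numeric rows. Values are
#' written with 17 significant digits, making write-then-read round-trips
#' bit-exact.
#'
#' @param path File path.
#' @param x Square numeric matrix with region IDs as dimnames.
#' @return `read_matrix_tsv` returns a plain numeric matrix with region
#'   dimnames; use [fc_matrix()] or [sc_matrix()] to validate it as a typed
#'   object. `write_matrix_tsv` returns `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                   header = FALSE,
                                   colClasses = "numeric"))
  if (ncol(m) != length(header) || nrow(m) != length(header))
    stop("read_matrix_tsv: matrix in ", path, " is not square against header")
  dimnames(m) <- list(header, header)
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  x <- as.matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  utils::write.table(matrix(fmt_num(x), nrow(x)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write functional connectomes
#'
#' Thin wrappers around the TSV matrix dialect that validate the result as an
#' [fc_matrix()].
#'
#' @param path File path.
#' @param fc An [fc_matrix()].
#' @export
read_fc_matrix <- function(path) fc_matrix(read_matrix_tsv(path))

#' @rdname read_fc_matrix
#' @export
write_fc_matrix <- function(fc, path) write_matrix_tsv(fc, path)

#' Read and write parcellated time series as TSV
#'
#' Regions as rows and time points as columns; the first column holds the
#' region ID, the remaining columns the series.
#'
#' @param path File path.
#' @param subject Subject ID for the returned [time_series_set()].
#' @param sampling_interval Seconds per frame.
#' @param ts A [time_series_set()].
#' @export
read_timeseries_tsv <- function(path, subject, sampling_interval) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(data) <- as.character(tab[[1L]])
  colnames(data) <- NULL
  time_series_set(subject, data, sampling_interval)
}

#' @rdname read_timeseries_tsv
#' @export
write_timeseries_tsv <- function(ts, path) {
  tab <- cbind(rownames(ts$data), matrix(fmt_num(ts$data), nrow(ts$data)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write a region-to-network partition
#'
#' Two-column TSV (`region_id`, `network_label`) with a header row. Network
#' order is the order of first appearance in the file.
#'
#' @param path File path.
#' @param part A [network_partition()].
#' @export
read_partition_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  network_partition(tab)
}

#' @rdname read_partition_tsv
#' @export
write_partition_tsv <- function(part, path) {
  tab <- data.frame(region_id = names(part$assignment),
                    network_label = unname(part$assignment))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a cohort via a manifest table
#'
#' A cohort on disk is a manifest TSV (`subject_id`, `condition`,
#' `relative_path`) plus one FC matrix TSV per subject, paths relative to the
#' manifest's directory. A manifest may mix several conditions;
#' `read_cohort_manifest` extracts one.
#'
#' @param path Manifest file path.
#' @param condition Condition label to extract.
#' @param coh A [cohort()]; matrices are written under `dir`.
#' @param dir Directory receiving the manifest and matrix files.
#' @export
read_cohort_manifest <- function(path, condition) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  tab <- tab[tab$condition == condition, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("read_cohort_manifest: no subjects with condition ", condition)
  base <- dirname(path)
  mats <- lapply(file.path(base, tab$relative_path), read_fc_matrix)
  cohort(condition, mats, tab$subject_id)
}

#' @rdname read_cohort_manifest
#' @export
write_cohort_manifest <- function(coh, dir, path = file.path(dir, "manifest.tsv")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- sprintf("%s_%s.tsv", coh$condition, coh$subjects)
  for (i in seq_along(coh$subjects))
    write_fc_matrix(coh$matrices[[i]], file.path(dir, rel[i]))
  tab <- data.frame(subject_id = coh$subjects, condition = coh$condition,
                    relative_path = rel)
  if (file.exists(path)) {
    old <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character")
    old <- old[old$condition != coh$condition, , drop = FALSE]
    tab <- rbind(old, tab)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
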