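#' Write a simulated cohort to disk
#'
#' Per-subject time series go out as TSV (header row of region labels, one
#' data row per volume), motion traces as 6-column whitespace text (SPM "rp"
#' dialect: translations in mm, rotations in radians), the design table as
#' TSV and the planted truth as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param design the cohort design table.
#' @param truth the [synthetic_truth()] object, or `NULL` to skip.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, design, truth = NULL, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  for (ts in cohort$timeseries)
    write_timeseries_tsv(ts, file.path(dir, "timeseries",
                                       paste0(ts$subject_id, "_ts.tsv")))
  for (mo in cohort$motion)
    write_motion_trace(mo, file.path(dir, "motion",
                                     paste0("rp_", mo$subject_id, ".txt")))
  utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(planted_edges = truth$planted_edges, delta = truth$delta,
           affected_group = truth$affected_group,
           base_correlation = truth$base_correlation, seed = truth$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param ts an [roi_ts()] object.
#' @param path file path.
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = ts$region_labels)
  invisible(path)
}

#' Read a parcellated time-series TSV
#'
#' @param path TSV with a header of region labels and T data rows.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param tr_seconds repetition time in seconds.
#' @return an [roi_ts()] object.
#' @export
read_timeseries_tsv <- function(path, subject_id = NULL, tr_seconds = 2) {
  if (is.null(subject_id))
    subject_id <- sub("_ts$", "", tools::file_path_sans_ext(basename(path)))
  x <- utils::read.delim(path, check.names = FALSE)
  roi_ts(subject_id, as.matrix(x), tr_seconds, colnames(x))
}

#' @rdname write_cohort
#' @param mo a [motion_trace()] object.
#' @export
write_motion_trace <- function(mo, path) {
  utils::write.table(format(mo$values, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a six-column rigid-body motion trace
#'
#' @param path whitespace-delimited text, six columns per volume.
#' @param subject_id subject identifier; defaults to the file stem with any
#'   leading `rp_` removed.
#' @param rotation_units units of columns 4-6 (`"rad"`, the SPM convention,
#'   or `"deg"`).
#' @return a [motion_trace()] object.
#' @export
read_motion_trace <- function(path, subject_id = NULL,
                              rotation_units = c("rad", "deg")) {
  if (is.null(subject_id))
    subject_id <- sub("^rp_", "", tools::file_path_sans_ext(basename(path)))
  x <- as.matrix(utils::read.table(path))
  motion_trace(subject_id, x, match.arg(rotation_units))
}

#' Write a connectivity matrix as whitespace-delimited text
#'
#' @param C a [correlation_matrix()] result.
#' @param path file path.
#' @export
write_connectivity <- function(C, path) {
  utils::write.table(C$values, path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' @param path file path.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param clipped whether the stored matrix was negative-clipped.
#' @return a `connectivity_matrix` object.
#' @export
read_connectivity <- function(path, subject_id = NULL, clipped = FALSE) {
  if (is.null(subject_id))
    subject_id <- sub("_conn$", "", tools::file_path_sans_ext(basename(path)))
  V <- as.matrix(utils::read.table(path))
  dimnames(V) <- NULL
  new_connectivity(subject_id, V, clipped = clipped)
}

#' Write an adjacency stack as a long edge-list TSV
#'
#' One row per (edge, threshold): columns `node_i`, `node_j` (0-based) and
#' `threshold`.
#'
#' @param stack an [threshold_sweep()] result.
#' @param path file path.
#' @export
write_adjacency_edgelist <- function(stack, path) {
  rows <- lapply(seq_along(stack$thresholds), function(k) {
    e <- which(upper.tri(stack$adjacency[[k]]) & stack$adjacency[[k]] == 1L,
               arr.ind = TRUE)
    if (!nrow(e)) return(NULL)
    data.frame(node_i = e[, 1] - 1L, node_j = e[, 2] - 1L,
               threshold = stack$thresholds[k])
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a cohort design table from TSV
#'
#' Requires columns `subject_id`, `group`, `age`, `sex`; any additional
#' columns are kept as clinical scores.
#'
#' @param path TSV file.
#' @return a validated `cohort_design` data frame.
#' @export
load_design <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop("design table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d$group <- factor(d$group, levels = unique(d$group))
  validate_cohort_design(d)
}

#' Load a node (parcellation) table from TSV
#'
#' Requires columns `index` (0-based), `name`, `abbreviation`, `hemisphere`;
#' optional MNI coordinate columns are preserved.
#'
#' @param path TSV file.
#' @return a data frame of nodes, ordered by `index`.
#' @export
load_node_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("index", "name", "abbreviation", "hemisphere")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop("node table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- d[order(d$index), , drop = FALSE]
  if (!identical(d$index, seq_len(nrow(d)) - 1L) &&
      !identical(as.integer(d$index), seq_len(nrow(d)) - 1L))
    stop("node table `index` must be contiguous 0-based", call. = FALSE)
  for (h in unique(d$hemisphere)) {
    ab <- d$abbreviation[d$hemisphere == h]
    if (anyDuplicated(ab))
      stop("abbreviations must be unique within hemisphere", call. = FALSE)
  }
  d
}

#' The 90-region cerebral parcellation table
#'
#' The standard 90-parcel anatomical labelling scheme (cerebellum excluded),
#' 45 regions per hemisphere, with field-standard abbreviations.
#'
#' @return a data frame with columns `index` (0-based), `name`,
#'   `abbreviation`, `hemisphere`.
#' @export
aal90_node_table <- function() {
  load_node_table(system.file("extdata", "aal90_nodes.tsv",
                              package = "connectograph", mustWork = TRUE))
}
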