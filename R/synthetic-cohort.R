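#' Create a synthetic cohort design table
#'
#' Generates a subject-level design table (subject id, group, age, sex and
#' clinical scores) with exactly the requested group sizes. Defaults mirror a
#' three-group euthymic bipolar / recurrent depression / healthy control
#' cohort of 20/15/30 subjects.
#'
#' @param n_per_group named integer vector (or list of `(label, count)` pairs)
#'   of subjects per group; every count must be at least 2.
#' @param age_range numeric length-2, years; ages drawn uniformly within.
#' @param sex_ratio proportion of subjects coded `sex = 1`, in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @param scores logical; add plausible clinical score columns (`bdi`,
#'   `brmas`, `illness_duration`, the latter `NA` for the last group, which is
#'   treated as the control group).
#' @return a `cohort_design` data frame with columns `subject_id`, `group`
#'   (factor, levels in the order given), `age`, `sex` and, if requested,
#'   clinical scores.
#' @examples
#' d <- make_cohort_design(c(BD = 20, MDD = 15, HC = 30), seed = 1)
#' table(d$group)
#' @export
make_cohort_design <- function(n_per_group = c(BD = 20, MDD = 15, HC = 30),
                               age_range = c(20, 62),
                               sex_ratio = 0.5,
                               seed = 1,
                               scores = TRUE) {
  if (is.list(n_per_group)) {
    labels <- vapply(n_per_group, function(x) as.character(x[[1]]), "")
    counts <- vapply(n_per_group, function(x) as.integer(x[[2]]), 0L)
  } else {
    labels <- names(n_per_group)
    counts <- as.integer(n_per_group)
  }
  if (is.null(labels) || any(!nzchar(labels)))
    stop("group labels are required", call. = FALSE)
  if (any(counts < 2L))
    stop("invalid design: every group needs at least 2 subjects", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("`sex_ratio` must lie in [0, 1]", call. = FALSE)
  if (length(age_range) != 2L || any(age_range <= 0) || diff(age_range) < 0)
    stop("`age_range` must be two positive increasing years", call. = FALSE)

  n <- sum(counts)
  with_seed(seed, {
    design <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = factor(rep(labels, counts), levels = labels),
      age = round(runif(n, age_range[1], age_range[2]), 1),
      sex = rbinom(n, 1L, sex_ratio),
      stringsAsFactors = FALSE
    )
    if (scores) {
      control <- labels[length(labels)]
      patient <- design$group != control
      design$bdi <- round(abs(rnorm(n, ifelse(patient, 7, 2.6),
                                    ifelse(patient, 4.9, 3.9))), 1)
      design$brmas <- round(abs(rnorm(n, 0.4, 1.0)), 1)
      design$illness_duration <- ifelse(
        patient, round(abs(rnorm(n, 13, 11)), 1), NA_real_)
    }
    class(design) <- c("cohort_design", "data.frame")
    validate_cohort_design(design)
  })
}

#' Validate a cohort design table
#'
#' @param design data frame with at least `subject_id`, `group`, `age`, `sex`.
#' @return the validated design, classed `cohort_design`.
#' @export
validate_cohort_design <- function(design) {
  req <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(req, names(design))
  if (length(missing))
    stop("design is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(design$subject_id))
    stop("duplicate subject_id in design", call. = FALSE)
  if (!is.factor(design$group)) design$group <- factor(design$group)
  counts <- table(design$group)
  if (any(counts < 2L))
    stop("invalid design: every group needs at least 2 subjects", call. = FALSE)
  if (any(!is.finite(design$age)) || any(design$age <= 0))
    stop("ages must be finite and positive", call. = FALSE)
  if (!all(design$sex %in% c(0, 1)))
    stop("sex must be coded 0/1", call. = FALSE)
  if (!inherits(design, "cohort_design"))
    class(design) <- c("cohort_design", "data.frame")
  design
}

#' Ground truth for a planted subnetwork effect
#'
#' Describes the edges whose population correlation is raised by `delta` in
#' one group, on top of a uniform `base_correlation` background. Downstream
#' recovery tests compare detected subnetworks against this truth.
#'
#' @param planted_edges two-column matrix of node indices (1-based, no
#'   self-pairs); stored with `i < j`.
#' @param delta correlation offset added on planted edges for the affected
#'   group, `0 <= delta`, with `base_correlation + delta < 1`.
#' @param affected_group group label receiving the offset.
#' @param base_correlation background off-diagonal correlation.
#' @param seed integer seed associated with the truth (for bookkeeping).
#' @return a `synthetic_truth` object.
#' @export
synthetic_truth <- function(planted_edges, delta, affected_group,
                            base_correlation = 0.1, seed = 1) {
  planted_edges <- as.matrix(planted_edges)
  if (ncol(planted_edges) != 2L)
    stop("`planted_edges` must be a two-column matrix", call. = FALSE)
  storage.mode(planted_edges) <- "integer"
  if (any(planted_edges[, 1] == planted_edges[, 2]))
    stop("planted edges may not be self-pairs", call. = FALSE)
  planted_edges <- t(apply(planted_edges, 1, sort))
  if (delta < 0 || base_correlation + delta >= 1)
    stop("require 0 <= delta and base_correlation + delta < 1", call. = FALSE)
  structure(
    list(planted_edges = planted_edges, delta = delta,
         affected_group = as.character(affected_group),
         base_correlation = base_correlation, seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' Planted edges forming a clique
#'
#' Convenience constructor: all `choose(k, 2)` edges among the first `k`
#' nodes (a 5-clique gives the canonical 10-edge planted subnetwork).
#'
#' @param nodes integer vector of node indices forming the clique.
#' @return two-column matrix of edges.
#' @export
clique_edges <- function(nodes) {
  t(combn(sort(as.integer(nodes)), 2L))
}

#' Build the population correlation matrix for one group
#'
#' Uniform `base_correlation` off the diagonal; planted edges get
#' `base + delta` when `for_group` is the affected group. If the target is
#' not positive semi-definite it is repaired by eigenvalue clipping at 1e-8
#' followed by re-normalization to unit diagonal; the repair is recorded in
#' the `"repaired"` attribute.
#'
#' @param n_nodes number of regions (>= 3).
#' @param truth a [synthetic_truth()] object.
#' @param for_group group label the matrix is for.
#' @return an `n_nodes` x `n_nodes` correlation matrix.
#' @export
build_group_covariance <- function(n_nodes, truth, for_group) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_nodes < 3L) stop("`n_nodes` must be at least 3", call. = FALSE)
  pe <- truth$planted_edges
  if (nrow(pe) && max(pe) > n_nodes)
    stop("planted edge index exceeds `n_nodes`", call. = FALSE)
  S <- matrix(truth$base_correlation, n_nodes, n_nodes)
  diag(S) <- 1
  if (identical(as.character(for_group), truth$affected_group) &&
      truth$delta > 0 && nrow(pe)) {
    target <- truth$base_correlation + truth$delta
    S[pe] <- target
    S[pe[, 2:1, drop = FALSE]] <- target
  }
  repaired <- FALSE
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) < 1e-8) {
    vals <- pmax(eg$values, 1e-8)
    S <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    diag(S) <- 1
    repaired <- TRUE
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("target correlation matrix is not repairable to PSD", call. = FALSE)
  }
  attr(S, "repaired") <- repaired
  S
}

#' One subject's parcellated ROI time series
#'
#' @param subject_id subject identifier.
#' @param values T x N numeric matrix (volumes x regions), no missing values.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param region_labels length-N character vector of region names.
#' @return a `roi_ts` object.
#' @export
roi_ts <- function(subject_id, values, tr_seconds, region_labels = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("time series must be finite with no missing values", call. = FALSE)
  if (nrow(values) < 2L) stop("need at least 2 volumes", call. = FALSE)
  if (tr_seconds <= 0) stop("`tr_seconds` must be positive", call. = FALSE)
  if (is.null(region_labels)) {
    region_labels <- if (!is.null(colnames(values))) colnames(values) else
      default_region_labels(ncol(values))
  }
  if (length(region_labels) != ncol(values))
    stop("`region_labels` length must equal the number of columns", call. = FALSE)
  colnames(values) <- region_labels
  structure(list(subject_id = as.character(subject_id), values = values,
                 tr_seconds = tr_seconds, region_labels = region_labels),
            class = "roi_ts")
}

default_region_labels <- function(n) {
  if (n == 90L) aal90_node_table()$name else sprintf("R%03d", seq_len(n))
}

#' A subject's six-parameter rigid-body motion trace
#'
#' @param subject_id subject identifier.
#' @param values T x 6 matrix: three translations (mm) then three rotations.
#' @param rotation_units `"rad"` (SPM realignment convention) or `"deg"`.
#' @return a `motion_trace` object.
#' @export
motion_trace <- function(subject_id, values, rotation_units = c("rad", "deg")) {
  rotation_units <- match.arg(rotation_units)
  values <- as.matrix(values)
  if (ncol(values) != 6L)
    stop("malformed motion trace: expected 6 columns, got ", ncol(values),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("motion trace must be finite", call. = FALSE)
  colnames(values) <- c("tx_mm", "ty_mm", "tz_mm", "rx", "ry", "rz")
  structure(list(subject_id = as.character(subject_id), values = values,
                 rotation_units = rotation_units),
            class = "motion_trace")
}

#' Simulate a cohort of ROI time series and motion traces
#'
#' Each subject's series is drawn volume-by-volume from a zero-mean
#' multivariate Gaussian with the group's population correlation matrix
#' (optionally AR(1)-correlated in time so band-pass filtering acts on a
#' nontrivial spectrum). Motion traces carry Gaussian jitter; a configurable
#' fraction of subjects get a 2.5 mm translation step so the motion QC rule
#' has unambiguous failures.
#'
#' @param design a [make_cohort_design()] table.
#' @param truth a [synthetic_truth()] object.
#' @param n_nodes number of regions (default 90).
#' @param T_volumes volumes acquired per subject (default 300; >= 30).
#' @param tr repetition time in seconds (default 2).
#' @param noise_sd overall signal scale (leaves correlations unchanged).
#' @param motion_outlier_fraction fraction of subjects given a motion
#'   excursion beyond the exclusion limits.
#' @param ar1 AR(1) coefficient in time, `0 <= ar1 < 1` (0 = independent
#'   volumes, the default sampling model).
#' @param age_effect_nodes optional node indices whose signal s.d. scales
#'   linearly with centered age.
#' @param age_effect_slope slope of that variance nuisance effect per year.
#' @param seed integer seed; fixed seed reproduces the cohort exactly.
#' @return list with `timeseries` (named list of [roi_ts()]), `motion`
#'   (named list of [motion_trace()]) and `outlier_subjects` (character).
#' @export
simulate_cohort <- function(design, truth, n_nodes = 90L, T_volumes = 300L,
                            tr = 2, noise_sd = 1,
                            motion_outlier_fraction = 0, ar1 = 0,
                            age_effect_nodes = NULL, age_effect_slope = 0,
                            seed = 1) {
  design <- validate_cohort_design(design)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (T_volumes < 30L) stop("too-short series: need T >= 30 volumes", call. = FALSE)
  if (motion_outlier_fraction < 0 || motion_outlier_fraction > 1)
    stop("`motion_outlier_fraction` must lie in [0, 1]", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("`ar1` must lie in [0, 1)", call. = FALSE)

  groups <- levels(design$group)
  chol_by_group <- lapply(groups, function(g)
    chol(build_group_covariance(n_nodes, truth, g)))
  names(chol_by_group) <- groups
  labels <- default_region_labels(n_nodes)
  n <- nrow(design)
  age_c <- design$age - mean(design$age)

  with_seed(seed, {
    n_out <- round_half_up(motion_outlier_fraction * n)
    outlier_idx <- if (n_out > 0) sort(sample.int(n, n_out)) else integer(0)

    ts_list <- vector("list", n)
    mo_list <- vector("list", n)
    for (s in seq_len(n)) {
      L <- chol_by_group[[as.character(design$group[s])]]
      Z <- matrix(rnorm(T_volumes * n_nodes), T_volumes, n_nodes)
      if (ar1 > 0) {
        Z <- apply(Z, 2, function(z) stats::filter(z, ar1, "recursive"))
        Z <- Z * sqrt(1 - ar1^2)  # restore unit stationary variance
      }
      X <- (Z %*% L) * noise_sd
      if (!is.null(age_effect_nodes) && age_effect_slope != 0) {
        sc <- pmax(1 + age_effect_slope * age_c[s], 0.05)
        X[, age_effect_nodes] <- X[, age_effect_nodes] * sc
      }
      ts_list[[s]] <- roi_ts(design$subject_id[s], X, tr, labels)

      M <- cbind(matrix(rnorm(T_volumes * 3, sd = 0.05), T_volumes, 3),
                 matrix(rnorm(T_volumes * 3, sd = 0.05 * pi / 180),
                        T_volumes, 3))
      if (s %in% outlier_idx) {
        from <- sample.int(T_volumes - 1L, 1L) + 1L
        M[from:T_volumes, 1] <- M[from:T_volumes, 1] + 2.5
      }
      mo_list[[s]] <- motion_trace(design$subject_id[s], M, "rad")
    }
    names(ts_list) <- names(mo_list) <- design$subject_id
    list(timeseries = ts_list, motion = mo_list,
         outlier_subjects = design$subject_id[outlier_idx])
  })
}

#' Recall of planted edges by a detected subnetwork
#'
#' Fraction of the planted edges recovered in the detected components of an
#' NBS result: `|planted intersect detected| / |planted|`.
#'
#' @param result an [nbs_test()] result (or a two-column edge matrix).
#' @param truth a [synthetic_truth()] object.
#' @param alpha if non-`NULL`, only components with `fwer_p < alpha` count.
#' @return a number in `[0, 1]`.
#' @export
truth_edge_recall <- function(result, truth, alpha = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  planted <- edge_keys(truth$planted_edges)
  if (!length(planted)) return(0)
  if (inherits(result, "nbs_result")) {
    comps <- result$components
    if (!is.null(alpha))
      comps <- comps[vapply(comps, function(k) k$fwer_p < alpha, TRUE)]
    detected <- unlist(lapply(comps, function(k) edge_keys(k$edges)))
  } else {
    detected <- edge_keys(as.matrix(result))
  }
  if (!length(detected)) return(0)
  length(intersect(planted, unique(detected))) / length(planted)
}

# canonical "i-j" keys (i < j) for unordered edges
edge_keys <- function(edges) {
  if (is.null(edges) || !nrow(edges)) return(character(0))
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  paste(lo, hi, sep = "-")
}
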