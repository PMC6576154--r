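#' Motion quality control
#'
#' Applies the head-motion exclusion rule: a subject is excluded if any
#' volume shows more than `max_translation_mm` of translation on any axis or
#' more than `max_rotation_deg` of rotation about any axis (rotations are
#' converted from radians when the trace uses the SPM radian convention).
#'
#' @param trace a [motion_trace()] object.
#' @param max_translation_mm translation limit in mm (default 2).
#' @param max_rotation_deg rotation limit in degrees (default 2).
#' @return list with `decision` (`"keep"` or `"exclude"`) and `offending`, a
#'   data frame of limit violations (first offending volume first).
#' @export
qc_motion <- function(trace, max_translation_mm = 2, max_rotation_deg = 2) {
  stopifnot(inherits(trace, "motion_trace"))
  v <- trace$values
  if (!nrow(v)) stop("motion trace is empty", call. = FALSE)
  rot_deg <- v[, 4:6, drop = FALSE]
  if (trace$rotation_units == "rad") rot_deg <- rot_deg * 180 / pi

  viol <- function(mat, limit, kind, unit) {
    hit <- which(abs(mat) > limit, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(volume = hit[, 1], axis = paste0(kind, hit[, 2]),
               value = mat[hit], unit = unit, stringsAsFactors = FALSE)
  }
  off <- rbind(viol(v[, 1:3, drop = FALSE], max_translation_mm, "trans", "mm"),
               viol(rot_deg, max_rotation_deg, "rot", "deg"))
  if (is.null(off)) {
    list(decision = "keep",
         offending = data.frame(volume = integer(0), axis = character(0),
                                value = numeric(0), unit = character(0)))
  } else {
    list(decision = "exclude", offending = off[order(off$volume), , drop = FALSE])
  }
}

# least-squares linear detrend of every column (removes intercept and slope)
detrend_columns <- function(X) {
  t_idx <- seq_len(nrow(X))
  B <- cbind(1, t_idx - mean(t_idx))
  X - B %*% qr.coef(qr(B), X)
}

#' Preprocess an ROI time series
#'
#' Discards the initial equilibration volumes, removes each column's linear
#' trend, then band-pass filters with a zero-phase (forward-backward)
#' order-4 Butterworth design.
#'
#' @param ts an [roi_ts()] object.
#' @param discard_volumes initial volumes to drop (default 10).
#' @param band numeric length-2, pass band in Hz (default `c(0.01, 0.08)`);
#'   `NULL` skips filtering. The upper edge must stay below the Nyquist
#'   frequency `1 / (2 * tr)`.
#' @return a new [roi_ts()] with `T - discard_volumes` rows.
#' @export
preprocess_timeseries <- function(ts, discard_volumes = 10,
                                  band = c(0.01, 0.08)) {
  stopifnot(inherits(ts, "roi_ts"))
  T_total <- nrow(ts$values)
  if (T_total - discard_volumes < 30)
    stop("too few volumes: need T - discard_volumes >= 30", call. = FALSE)
  X <- ts$values[(discard_volumes + 1):T_total, , drop = FALSE]
  X <- detrend_columns(X)
  if (!is.null(band)) {
    nyquist <- 1 / (2 * ts$tr_seconds)
    if (band[1] <= 0 || band[2] >= nyquist || band[1] >= band[2])
      stop("invalid band: need 0 < low < high < Nyquist = ", nyquist, " Hz",
           call. = FALSE)
    bf <- signal::butter(4, band / nyquist, type = "pass")
    X <- apply(X, 2, function(col) signal::filtfilt(bf, col))
  }
  out <- ts
  out$values <- X
  colnames(out$values) <- ts$region_labels
  out
}

#' Construct a connectivity matrix from a numeric matrix
#'
#' Validates symmetry and range, forces the diagonal to zero, and wraps the
#' values in a `connectivity_matrix` object (for externally computed or toy
#' matrices; [correlation_matrix()] is the standard route).
#'
#' @param values square numeric matrix, entries in `[-1, 1]` (`[0, 1]` when
#'   `clipped`).
#' @param subject_id subject identifier.
#' @param clipped whether the matrix is already negative-clipped.
#' @return a `connectivity_matrix` object.
#' @export
as_connectivity <- function(values, subject_id = "subject", clipped = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || max(abs(values - t(values))) > 1e-8)
    stop("connectivity values must be square and symmetric", call. = FALSE)
  diag(values) <- 0
  lo <- if (clipped) 0 else -1
  if (any(values < lo - 1e-12) || any(values > 1 + 1e-12))
    stop("connectivity entries must lie in [", lo, ", 1]", call. = FALSE)
  new_connectivity(subject_id, (values + t(values)) / 2, clipped)
}

new_connectivity <- function(subject_id, values, clipped) {
  structure(list(subject_id = as.character(subject_id), values = values,
                 clipped = clipped),
            class = "connectivity_matrix")
}

#' Pearson connectivity matrix
#'
#' Pairwise Pearson correlations between all region time courses. The
#' diagonal is forced to zero (self-connections are not edges).
#'
#' @param ts an [roi_ts()] object; every column must be nonconstant.
#' @return a `connectivity_matrix` (raw, `clipped = FALSE`).
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  sds <- apply(ts$values, 2, sd)
  if (any(sds == 0))
    stop("degenerate signal: constant time course in region(s) ",
         paste(ts$region_labels[sds == 0], collapse = ", "), call. = FALSE)
  V <- cor(ts$values)
  V <- (V + t(V)) / 2
  diag(V) <- 0
  dimnames(V) <- NULL
  new_connectivity(ts$subject_id, V, clipped = FALSE)
}

#' Zero out negative connectivity weights
#'
#' @param C a raw `connectivity_matrix`.
#' @return the matrix with negative entries set to zero and `clipped = TRUE`.
#' @export
clip_negative <- function(C) {
  stopifnot(inherits(C, "connectivity_matrix"))
  C$values <- pmax(C$values, 0)
  C$clipped <- TRUE
  C
}

# upper-triangle edges ordered by descending weight, ties broken by
# ascending lexicographic (i, j); only strictly positive weights
ordered_positive_edges <- function(V) {
  n <- nrow(V)
  ut <- which(upper.tri(V), arr.ind = TRUE)
  w <- V[ut]
  keep <- w > 0
  ut <- ut[keep, , drop = FALSE]
  w <- w[keep]
  o <- order(-w, ut[, 1], ut[, 2])
  list(i = ut[o, 1], j = ut[o, 2], w = w[o], n = n)
}

adjacency_from_prefix <- function(edges, k) {
  A <- matrix(0L, edges$n, edges$n)
  if (k > 0) {
    idx <- seq_len(k)
    A[cbind(edges$i[idx], edges$j[idx])] <- 1L
    A[cbind(edges$j[idx], edges$i[idx])] <- 1L
  }
  A
}

#' Binarize a connectivity matrix at one sparsity level
#'
#' Retains the strongest `round(S * N(N-1)/2)` connections (rounding half
#' away from zero), breaking weight ties deterministically by ascending
#' lexicographic node-pair order. If fewer positive weights exist than
#' requested, all positive edges are kept and a shortfall warning recorded
#' in the `"shortfall"` attribute.
#'
#' @param C a negative-clipped `connectivity_matrix`.
#' @param S sparsity in `(0, 1]`: the fraction of possible edges retained.
#' @return binary symmetric N x N adjacency matrix with zero diagonal.
#' @export
sparsity_threshold <- function(C, S) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (!C$clipped) stop("clip negative weights before thresholding", call. = FALSE)
  if (S <= 0 || S > 1) stop("invalid sparsity: S must lie in (0, 1]", call. = FALSE)
  edges <- ordered_positive_edges(C$values)
  n <- edges$n
  K <- round_half_up(S * n * (n - 1) / 2)
  shortfall <- FALSE
  if (length(edges$w) < K) {
    warning(sprintf("sparsity %.3g requests %d edges but only %d positive weights exist",
                    S, K, length(edges$w)))
    K <- length(edges$w)
    shortfall <- TRUE
  }
  A <- adjacency_from_prefix(edges, K)
  attr(A, "shortfall") <- shortfall
  A
}

#' Binarize over the full sparsity grid
#'
#' Generates the threshold grid on an integer lattice (avoiding
#' floating-point drift) and builds one adjacency per level. Because every
#' level takes a prefix of the same deterministic edge ordering, the edge
#' sets are nested: the graph at a smaller sparsity is a subgraph of the
#' graph at any larger one.
#'
#' @param C a negative-clipped `connectivity_matrix`.
#' @param s_min,s_max,step grid limits and spacing (defaults 0.10, 0.50,
#'   0.01: the standard 41-level sweep).
#' @return an `adjacency_stack`: list with `subject_id`, `thresholds`,
#'   `adjacency` (list of binary matrices), `edge_counts` and `shortfall`
#'   (logical per level).
#' @export
threshold_sweep <- function(C, s_min = 0.10, s_max = 0.50, step = 0.01) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (!C$clipped) stop("clip negative weights before thresholding", call. = FALSE)
  if (s_min <= 0 || s_max > 1 || s_min > s_max || step <= 0)
    stop("invalid grid: need 0 < s_min <= s_max <= 1 and step > 0", call. = FALSE)
  n_levels <- round((s_max - s_min) / step) + 1L
  if (n_levels < 1) stop("invalid grid: empty threshold set", call. = FALSE)
  thresholds <- s_min + (seq_len(n_levels) - 1L) * step

  edges <- ordered_positive_edges(C$values)
  n <- edges$n
  M <- n * (n - 1) / 2
  Ks <- round_half_up(thresholds * M)
  shortfall <- Ks > length(edges$w)
  if (any(shortfall))
    warning(sprintf("%d threshold level(s) short of positive weights for subject %s",
                    sum(shortfall), C$subject_id))
  Ks <- pmin(Ks, length(edges$w))
  structure(
    list(subject_id = C$subject_id,
         thresholds = thresholds,
         adjacency = lapply(Ks, function(k) adjacency_from_prefix(edges, k)),
         edge_counts = as.integer(Ks),
         shortfall = shortfall),
    class = "adjacency_stack")
}
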