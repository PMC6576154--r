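check_adjacency <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  if (nrow(A) != ncol(A) || !identical(A, t(A)))
    stop("adjacency must be square and symmetric", call. = FALSE)
  if (any(diag(A) != 0L)) stop("adjacency must have zero diagonal", call. = FALSE)
  if (!all(A %in% c(0L, 1L))) stop("adjacency must be binary", call. = FALSE)
  A
}

#' Nodal degree
#'
#' Number of links connected to each node.
#'
#' @param A binary symmetric adjacency matrix, zero diagonal.
#' @return integer vector of length N.
#' @export
nodal_degree <- function(A) {
  A <- check_adjacency(A)
  as.integer(rowSums(A))
}

#' Nodal clustering coefficient
#'
#' For each node, the fraction of its neighbour pairs that are themselves
#' connected: `2 * triangles_i / (deg_i * (deg_i - 1))`, defined as 0 for
#' nodes of degree below 2. The global clustering coefficient is the mean of
#' this vector over all nodes.
#'
#' @param A binary symmetric adjacency matrix, zero diagonal.
#' @return numeric vector in `[0, 1]` of length N.
#' @export
nodal_clustering <- function(A) {
  A <- check_adjacency(A)
  Ad <- A * 1.0
  deg <- rowSums(Ad)
  triangles <- diag(Ad %*% Ad %*% Ad) / 2
  cc <- ifelse(deg >= 2, 2 * triangles / (deg * (deg - 1)), 0)
  as.numeric(cc)
}

#' All-pairs shortest-path distances
#'
#' Hop-count distances by breadth-first search; unreachable pairs are `Inf`,
#' the diagonal is 0.
#'
#' @param A binary symmetric adjacency matrix, zero diagonal.
#' @return numeric N x N distance matrix.
#' @export
distance_matrix <- function(A) {
  A <- check_adjacency(A)
  .bfs_distances(A)
}

#' Characteristic path length, global efficiency and nodal path length
#'
#' Nodal path length of node i is the mean of its finite off-diagonal
#' distances (`Inf` for an isolated node). Characteristic path length is the
#' mean over all ordered node pairs with finite distance; global efficiency
#' is the mean of inverse distances over all ordered off-diagonal pairs,
#' with `1/Inf = 0` so disconnected pairs count as zero efficiency.
#'
#' @param D distance matrix from [distance_matrix()].
#' @return list with `characteristic_pl`, `global_ef` and `nodal_pl`.
#' @export
path_and_efficiency <- function(D) {
  n <- nrow(D)
  off <- !diag(n)
  d <- D[off]
  finite <- is.finite(d)
  if (!any(finite))
    stop("characteristic path length undefined: all pairs unreachable",
         call. = FALSE)
  nodal_pl <- vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    fi <- is.finite(di)
    if (!any(fi)) Inf else mean(di[fi])
  }, 0.0)
  list(characteristic_pl = mean(d[finite]),
       global_ef = mean(ifelse(finite, 1 / d, 0)),
       nodal_pl = nodal_pl)
}

#' Betweenness centrality
#'
#' Brandes accumulation of the fraction of all-pairs shortest paths passing
#' through each node, over unordered source-target pairs with endpoints
#' excluded, unnormalized.
#'
#' @param A binary symmetric adjacency matrix, zero diagonal.
#' @return numeric vector of length N.
#' @export
betweenness <- function(A) {
  A <- check_adjacency(A)
  as.numeric(.brandes_betweenness(A))
}

#' Compute all graph metrics across an adjacency stack
#'
#' One long-form record per (threshold x metric x scope): the global
#' clustering coefficient (CC), characteristic path length (PL) and global
#' efficiency (EF), plus nodal CC, PL, degree (DEG) and betweenness
#' centrality (BC) for every node.
#'
#' @param stack an [threshold_sweep()] result.
#' @return a `metric_table` data frame with columns `subject_id`,
#'   `threshold`, `scope` (`"global"`/`"nodal"`), `node` (0-based index, `NA`
#'   for global records), `metric` and `value`.
#' @export
metrics_over_stack <- function(stack) {
  stopifnot(inherits(stack, "adjacency_stack"))
  recs <- lapply(seq_along(stack$thresholds), function(k) {
    A <- stack$adjacency[[k]]
    n <- nrow(A)
    S <- stack$thresholds[k]
    cc <- nodal_clustering(A)
    D <- distance_matrix(A)
    pe <- path_and_efficiency(D)
    deg <- nodal_degree(A)
    bc <- betweenness(A)
    nodes <- seq_len(n) - 1L
    rbind(
      data.frame(threshold = S, scope = "global", node = NA_integer_,
                 metric = c("CC", "PL", "EF"),
                 value = c(mean(cc), pe$characteristic_pl, pe$global_ef)),
      data.frame(threshold = S, scope = "nodal",
                 node = rep(nodes, 4L),
                 metric = rep(c("CC", "PL", "DEG", "BC"), each = n),
                 value = c(cc, pe$nodal_pl, as.numeric(deg), bc))
    )
  })
  out <- do.call(rbind, recs)
  out <- cbind(subject_id = stack$subject_id, out)
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Compute metric tables for a list of subjects
#'
#' @param stacks list of adjacency stacks (one per subject).
#' @return a single `metric_table` data frame.
#' @export
metrics_for_cohort <- function(stacks) {
  out <- do.call(rbind, lapply(stacks, metrics_over_stack))
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Write a metric table as long-form TSV
#'
#' @param metrics a `metric_table`.
#' @param path file path.
#' @export
write_metric_table <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
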