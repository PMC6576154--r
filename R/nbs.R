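# subjects x edges matrix of upper-triangle edge values, optionally Fisher
# r-to-z transformed; rows follow `connectomes` order
edge_value_matrix <- function(connectomes, transform = c("fisher_z", "none")) {
  transform <- match.arg(transform)
  n_nodes <- nrow(connectomes[[1]]$values)
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  X <- t(vapply(connectomes, function(C) {
    if (nrow(C$values) != n_nodes)
      stop("connectomes must share the same region set", call. = FALSE)
    C$values[ut]
  }, numeric(nrow(ut))))
  if (transform == "fisher_z") {
    # guard exact +/-1 correlations against infinite z
    X <- atanh(pmin(pmax(X, -1 + 1e-12), 1 - 1e-12))
  }
  list(X = X, pairs = ut, n_nodes = n_nodes)
}

# pooled two-sample t per edge for a batch of 0/1 group-1 indicator columns;
# X: subjects x edges, G1: subjects x B. Returns edges x B.
edge_t_batch <- function(X, G1) {
  n <- nrow(X)
  n1 <- colSums(G1); n2 <- n - n1
  S1 <- crossprod(X, G1)               # edges x B
  Q1 <- crossprod(X^2, G1)
  tot <- colSums(X); tot2 <- colSums(X^2)
  S2 <- tot - S1
  Q2 <- tot2 - Q1
  m1 <- sweep(S1, 2, n1, "/"); m2 <- sweep(S2, 2, n2, "/")
  v1 <- sweep(Q1 - sweep(m1^2, 2, n1, "*"), 2, n1 - 1, "/")
  v2 <- sweep(Q2 - sweep(m2^2, 2, n2, "*"), 2, n2 - 1, "/")
  sp2 <- pmax(sweep(sweep(v1, 2, n1 - 1, "*") + sweep(v2, 2, n2 - 1, "*"),
                    2, n1 + n2 - 2, "/"), 0)
  se <- sqrt(sweep(sp2, 2, 1 / n1 + 1 / n2, "*"))
  tt <- (m1 - m2) / se
  tt[se == 0] <- 0
  tt
}

#' Edgewise two-sample statistics between two groups
#'
#' Pooled-variance two-sample t statistic at every edge of the connectome,
#' computed on Fisher r-to-z transformed raw correlations by default.
#' Group 1 minus group 2, so positive statistics mean stronger connectivity
#' in the first group of `contrast`. Edges with zero variance in both groups
#' get statistic 0 with a warning.
#'
#' @param connectomes list of `connectivity_matrix` objects sharing region
#'   order (raw, unclipped correlations are the intended input).
#' @param labels group label per connectome.
#' @param contrast character length-2: the two group labels to compare.
#' @param transform `"fisher_z"` (default) or `"none"`.
#' @return symmetric N x N statistic matrix with zero diagonal.
#' @export
edgewise_statistics <- function(connectomes, labels,
                                contrast = NULL,
                                transform = c("fisher_z", "none")) {
  transform <- match.arg(transform)
  labels <- as.character(labels)
  if (is.null(contrast)) contrast <- unique(labels)
  if (length(contrast) != 2)
    stop("`contrast` must name exactly two groups", call. = FALSE)
  keep <- labels %in% contrast
  if (sum(labels == contrast[1]) < 2 || sum(labels == contrast[2]) < 2)
    stop("each contrast group needs >= 2 subjects", call. = FALSE)
  ev <- edge_value_matrix(connectomes[keep], transform)
  g1 <- matrix(as.numeric(labels[keep] == contrast[1]), ncol = 1)
  tt <- edge_t_batch(ev$X, g1)
  if (any(apply(ev$X, 2, var) == 0 & tt[, 1] == 0))
    warning("edge(s) with zero variance in both groups: statistic set to 0")
  M <- matrix(0, ev$n_nodes, ev$n_nodes)
  M[ev$pairs] <- tt[, 1]
  M[ev$pairs[, 2:1]] <- tt[, 1]
  M
}

# edges x 1 logical of supra-threshold survival per direction
supra_mask <- function(tvals, t_primary, direction) {
  switch(direction,
         greater = tvals > t_primary,
         less = tvals < -t_primary,
         two_sided = abs(tvals) > t_primary)
}

#' Connected components of supra-threshold edges
#'
#' Thresholds the statistic matrix at `t_primary` (per the chosen
#' direction), keeps the surviving edges, and returns their connected
#' components sorted by size (edge count) descending, ties broken by the
#' smallest node index.
#'
#' @param stat_matrix symmetric statistic matrix.
#' @param t_primary primary statistic threshold (default 3.40).
#' @param direction `"greater"`, `"less"` or `"two_sided"`.
#' @return list of components, each with `nodes` (1-based), `edges`
#'   (two-column matrix), `n_edges` and `n_nodes`; empty list if no edge
#'   survives.
#' @export
supra_threshold_components <- function(stat_matrix, t_primary = 3.40,
                                       direction = c("greater", "less",
                                                     "two_sided")) {
  direction <- match.arg(direction)
  n <- nrow(stat_matrix)
  ut <- which(upper.tri(stat_matrix), arr.ind = TRUE)
  surv <- supra_mask(stat_matrix[ut], t_primary, direction)
  if (!any(surv)) return(list())
  e <- ut[surv, , drop = FALSE]
  # components via BFS reachability on the surviving-edge subgraph: two
  # nodes share a component iff their hop distance is finite
  A <- matrix(0L, n, n)
  A[e] <- 1L
  A[e[, c(2, 1), drop = FALSE]] <- 1L
  reach <- is.finite(.bfs_distances(A))
  comp_id <- apply(reach, 1, function(r) min(which(r)))
  edge_comp <- comp_id[e[, 1]]
  comps <- lapply(split(seq_len(nrow(e)), edge_comp), function(rows) {
    edges <- e[rows, , drop = FALSE]
    nodes <- sort(unique(as.vector(edges)))
    list(nodes = nodes, edges = edges,
         n_edges = nrow(edges), n_nodes = length(nodes))
  })
  ord <- order(-vapply(comps, `[[`, 0L, "n_edges"),
               vapply(comps, function(k) min(k$nodes), 0L))
  unname(comps[ord])
}

#' Network Based Statistic permutation test
#'
#' Computes edgewise two-sample statistics between the two contrast groups,
#' forms supra-threshold connected components, and assigns each component a
#' family-wise-error-corrected p-value by comparing its size (edge count)
#' with the maximum component size obtained under `n_perm` random
#' relabelings of the subjects:
#' `fwer_p = (1 + #\{null max size >= observed size\}) / (1 + n_perm)`.
#'
#' @inheritParams edgewise_statistics
#' @param t_primary primary statistic threshold (default 3.40, the
#'   field-standard choice corresponding to a nominal p < 0.001).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param direction `"greater"` (group 1 > group 2), `"less"` or
#'   `"two_sided"`.
#' @return an `nbs_result`: `contrast`, `t_primary`, `direction`,
#'   `transform`, `n_perm`, `seed`, `components` (each with `nodes`,
#'   `edges`, `n_edges`, `n_nodes`, `fwer_p`), `null_max_sizes` and the
#'   `stat_matrix`.
#' @export
nbs_test <- function(connectomes, labels, contrast = NULL,
                     t_primary = 3.40, n_perm = 10000, seed = 1,
                     transform = c("fisher_z", "none"),
                     direction = c("greater", "less", "two_sided")) {
  transform <- match.arg(transform)
  direction <- match.arg(direction)
  labels <- as.character(labels)
  if (is.null(contrast)) contrast <- unique(labels)
  if (length(contrast) != 2)
    stop("`contrast` must name exactly two groups", call. = FALSE)
  keep <- which(labels %in% contrast)
  lab <- labels[keep]
  n1 <- sum(lab == contrast[1]); n2 <- sum(lab == contrast[2])
  if (n1 < 2 || n2 < 2)
    stop("each contrast group needs >= 2 subjects", call. = FALSE)
  ev <- edge_value_matrix(connectomes[keep], transform)
  n_sub <- length(keep)

  g1_obs <- as.numeric(lab == contrast[1])
  t_obs <- edge_t_batch(ev$X, matrix(g1_obs, ncol = 1))[, 1]
  stat_matrix <- matrix(0, ev$n_nodes, ev$n_nodes)
  stat_matrix[ev$pairs] <- t_obs
  stat_matrix[ev$pairs[, 2:1]] <- t_obs
  comps <- supra_threshold_components(stat_matrix, t_primary, direction)

  null_max <- with_seed(seed, {
    # permute in batches to bound memory at edges x batch doubles
    batch <- max(1L, min(n_perm, floor(2e7 / nrow(ev$pairs))))
    out <- numeric(0)
    left <- n_perm
    while (left > 0) {
      b <- min(batch, left)
      G1 <- vapply(seq_len(b), function(k) g1_obs[sample.int(n_sub)],
                   numeric(n_sub))
      tt <- edge_t_batch(ev$X, G1)
      out <- c(out, vapply(seq_len(b), function(k) {
        surv <- supra_mask(tt[, k], t_primary, direction)
        if (!any(surv)) return(0L)
        e <- ev$pairs[surv, , drop = FALSE]
        .max_component_edges(e[, 1] - 1L, e[, 2] - 1L, ev$n_nodes)
      }, 0L))
      left <- left - b
    }
    out
  })

  for (k in seq_along(comps))
    comps[[k]]$fwer_p <- (1 + sum(null_max >= comps[[k]]$n_edges)) /
      (1 + n_perm)
  structure(
    list(contrast = contrast, t_primary = t_primary, direction = direction,
         transform = transform, n_perm = n_perm, seed = as.integer(seed),
         components = comps, null_max_sizes = null_max,
         stat_matrix = stat_matrix),
    class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS: %s vs %s (%s, t_primary = %.3g, %d permutations)\n",
              x$contrast[1], x$contrast[2], x$direction, x$t_primary,
              x$n_perm))
  if (!length(x$components)) {
    cat("  no supra-threshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      cm <- x$components[[k]]
      cat(sprintf("  component %d: %d edges on %d nodes, FWER p = %.4g\n",
                  k, cm$n_edges, cm$n_nodes, cm$fwer_p))
    }
  }
  invisible(x)
}

#' Map a tail probability to the corresponding t threshold
#'
#' Reports the p-to-t correspondence of a primary threshold: the t value
#' whose (one- or two-sided) tail probability equals `p` at the given
#' degrees of freedom.
#'
#' @param p tail probability in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @param two_sided if `TRUE` (default) `p` is split across both tails.
#' @return the t threshold.
#' @export
t_for_p <- function(p, df, two_sided = TRUE) {
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  qt(1 - (if (two_sided) p / 2 else p), df)
}

#' @rdname t_for_p
#' @param t t threshold to convert back to a tail probability.
#' @export
p_for_t <- function(t, df, two_sided = TRUE) {
  tail <- pt(t, df, lower.tail = FALSE)
  if (two_sided) 2 * tail else tail
}

#' Write an NBS result to disk
#'
#' Emits a component edge-list TSV (`node_i`, `node_j`, 0-based, with the
#' edge statistic), a component summary TSV (`component`, `n_nodes`,
#' `n_edges`, `fwer_p`) and a JSON metadata file (threshold, permutations,
#' seed, contrast).
#'
#' @param result an `nbs_result`.
#' @param dir output directory.
#' @param prefix file-name prefix (default the contrast).
#' @export
write_nbs_result <- function(result, dir, prefix = NULL) {
  stopifnot(inherits(result, "nbs_result"))
  if (is.null(prefix))
    prefix <- paste0(paste(result$contrast, collapse = "-"), "_",
                     result$direction)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- do.call(rbind, lapply(seq_along(result$components), function(k) {
    e <- result$components[[k]]$edges
    data.frame(component = k, node_i = e[, 1] - 1L, node_j = e[, 2] - 1L,
               t = result$stat_matrix[e])
  }))
  if (is.null(edges))
    edges <- data.frame(component = integer(0), node_i = integer(0),
                        node_j = integer(0), t = numeric(0))
  utils::write.table(edges, file.path(dir, paste0(prefix, "_edges.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- data.frame(
    component = seq_along(result$components),
    n_nodes = vapply(result$components, `[[`, 0L, "n_nodes"),
    n_edges = vapply(result$components, `[[`, 0L, "n_edges"),
    fwer_p = vapply(result$components, `[[`, 0.0, "fwer_p"))
  utils::write.table(summ, file.path(dir, paste0(prefix, "_components.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(contrast = result$contrast, t_primary = result$t_primary,
         direction = result$direction, transform = result$transform,
         n_perm = result$n_perm, seed = result$seed),
    file.path(dir, paste0(prefix, "_meta.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
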