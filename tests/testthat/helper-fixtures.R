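# small graph fixtures and cohort builders shared across test files

adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  if (length(edges)) {
    e <- matrix(unlist(edges), ncol = 2, byrow = TRUE)
    A[e] <- 1L
    A[e[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

graph_k4 <- function() adj_from_edges(4, list(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4)))
graph_star5 <- function() adj_from_edges(5, list(c(1,2), c(1,3), c(1,4), c(1,5)))
graph_ring5 <- function() adj_from_edges(5, list(c(1,2), c(2,3), c(3,4), c(4,5), c(5,1)))
graph_path4 <- function() adj_from_edges(4, list(c(1,2), c(2,3), c(3,4)))
graph_tri_pendant <- function() adj_from_edges(4, list(c(1,2), c(1,3), c(2,3), c(3,4)))
graph_two_triangles <- function()
  adj_from_edges(6, list(c(1,2), c(1,3), c(2,3), c(4,5), c(4,6), c(5,6)))

# Erdos-Renyi draw as a plain binary adjacency matrix
random_gnp <- function(n, p) {
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- as.integer(stats::runif(sum(ut)) < p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# symmetric toy connectivity with the given upper-triangle weights
# (column-major upper-triangle order)
toy_connectivity <- function(n, weights, clipped = TRUE, id = "toy") {
  V <- matrix(0, n, n)
  V[upper.tri(V)] <- weights
  V <- V + t(V)
  as_connectivity(V, id, clipped = clipped)
}

# small two-group cohort of raw connectomes with an optional planted clique
toy_connectomes <- function(n_per_group = 10, n_nodes = 20, T_volumes = 100,
                            delta = 0, seed = 1, clique = 1:5,
                            groups = c("A", "B")) {
  design <- make_cohort_design(setNames(rep(n_per_group, 2), groups),
                               seed = seed, scores = FALSE)
  truth <- synthetic_truth(clique_edges(clique), delta, groups[1],
                           base_correlation = 0.1, seed = seed)
  cohort <- simulate_cohort(design, truth, n_nodes = n_nodes,
                            T_volumes = T_volumes, seed = seed)
  conns <- lapply(cohort$timeseries, correlation_matrix)
  list(design = design, truth = truth, cohort = cohort, connectomes = conns)
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
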