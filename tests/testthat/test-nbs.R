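test_that("edgewise statistics match the pooled-t hand computation", {
  # two groups of 3 subjects, 3 nodes; edge (1,2) carries the toy values
  make_conn <- function(r12, id) {
    V <- matrix(0.05, 3, 3); diag(V) <- 0
    V[1, 2] <- V[2, 1] <- r12
    as_connectivity(V, id)
  }
  conns <- c(lapply(c(0.5, 0.6, 0.7), make_conn, id = "g1"),
             lapply(c(0.1, 0.2, 0.3), make_conn, id = "g2"))
  labels <- rep(c("g1", "g2"), each = 3)
  # off-toy edges are constant 0.05, so the zero-variance warning is expected
  expect_warning(
    S <- edgewise_statistics(conns, labels, c("g1", "g2"), transform = "none"),
    "zero variance")
  expect_equal(S[1, 2], 4.898979, tolerance = 1e-6)  # 0.4 / sqrt(0.01 * 2/3)
  expect_symmetric(S)
  expect_equal(diag(S), rep(0, 3))
  # identical groups give zero statistics (with a zero-variance warning)
  same <- c(lapply(c(0.5, 0.5, 0.5), make_conn, id = "a"),
            lapply(c(0.5, 0.5, 0.5), make_conn, id = "b"))
  expect_warning(S0 <- edgewise_statistics(same, labels, c("g1", "g2")),
                 "zero variance")
  expect_equal(max(abs(S0)), 0)
})

test_that("a planted edge shift attains the maximal statistic", {
  set.seed(14)
  n <- 8
  mats <- lapply(1:12, function(k) {
    V <- tanh(matrix(rnorm(n * n, 0.1, 0.02), n, n))
    V <- (V + t(V)) / 2
    if (k <= 6) V[2, 5] <- V[5, 2] <- tanh(atanh(V[2, 5]) + 0.4)
    as_connectivity(V, paste0("s", k))
  })
  S <- edgewise_statistics(mats, rep(c("g1", "g2"), each = 6), c("g1", "g2"))
  ut <- which(upper.tri(S), arr.ind = TRUE)
  planted_idx <- which(ut[, 1] == 2 & ut[, 2] == 5)
  expect_equal(which.max(abs(S[upper.tri(S)])), planted_idx)
})

test_that("supra-threshold components are found, sized and ordered correctly", {
  S <- matrix(0, 7, 7)
  put <- function(i, j, v) S[i, j] <<- S[j, i] <<- v
  put(1, 2, 4); put(2, 3, 4.5); put(5, 6, 5)
  comps <- supra_threshold_components(S, 3.4, "greater")
  expect_length(comps, 2)
  expect_equal(comps[[1]]$n_edges, 2)  # sorted by size descending
  expect_equal(comps[[1]]$nodes, 1:3)
  expect_equal(comps[[2]]$n_edges, 1)
  expect_equal(comps[[2]]$nodes, 5:6)

  expect_length(supra_threshold_components(S, 10, "greater"), 0)
  # direction handling
  expect_length(supra_threshold_components(-S, 3.4, "greater"), 0)
  expect_length(supra_threshold_components(-S, 3.4, "less"), 2)
  expect_length(supra_threshold_components(-S, 3.4, "two_sided"), 2)
})

test_that("components agree with the igraph oracle on random matrices", {
  set.seed(99)
  for (rep in 1:30) {
    n <- 12
    S <- matrix(0, n, n)
    ut <- upper.tri(S)
    S[ut] <- rnorm(sum(ut), 0, 2.5)
    S <- S + t(S)
    comps <- supra_threshold_components(S, 3.0, "two_sided")
    # oracle: igraph components on the thresholded graph
    A <- (abs(S) > 3.0) * 1
    diag(A) <- 0
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    memb <- igraph::components(g)$membership
    sizes_ref <- sort(table(memb[igraph::degree(g) > 0]), decreasing = TRUE)
    # compare component node-set partitions (sizes in nodes and edges)
    expect_equal(sum(vapply(comps, `[[`, 0L, "n_edges")), sum(A) / 2)
    if (length(comps)) {
      node_sets <- lapply(comps, `[[`, "nodes")
      for (ns in node_sets)
        expect_length(unique(memb[ns]), 1)  # internally connected
      expect_equal(sort(vapply(node_sets, length, 0L)),
                   sort(as.vector(sizes_ref)))
    }
  }
})

test_that("raising the primary threshold never grows a component", {
  set.seed(7)
  S <- matrix(0, 15, 15)
  ut <- upper.tri(S)
  S[ut] <- rnorm(sum(ut), 0, 2)
  S <- S + t(S)
  for (thr in list(c(1, 1.5), c(1.5, 2.5), c(2.5, 3.5))) {
    lo <- supra_threshold_components(S, thr[1], "two_sided")
    hi <- supra_threshold_components(S, thr[2], "two_sided")
    if (length(lo) && length(hi))
      expect_lte(max(vapply(hi, `[[`, 0L, "n_edges")),
                 max(vapply(lo, `[[`, 0L, "n_edges")))
  }
})

test_that("NBS detects a planted clique and is exchangeable on duplicates", {
  fix <- toy_connectomes(n_per_group = 15, n_nodes = 20, T_volumes = 200,
                         delta = 0.4, seed = 5, clique = 1:5)
  res <- nbs_test(fix$connectomes, fix$design$group, c("A", "B"),
                  t_primary = 3.4, n_perm = 500, seed = 8,
                  direction = "greater")
  expect_s3_class(res, "nbs_result")
  expect_true(length(res$components) >= 1)
  expect_lt(res$components[[1]]$fwer_p, 0.05)
  expect_gte(truth_edge_recall(res, fix$truth, alpha = 0.05), 0.5)
  # determinism
  res2 <- nbs_test(fix$connectomes, fix$design$group, c("A", "B"),
                   t_primary = 3.4, n_perm = 500, seed = 8,
                   direction = "greater")
  expect_identical(res$null_max_sizes, res2$null_max_sizes)

  # duplicated groups: observed equals every permuted max, so FWER p = 1
  half <- fix$connectomes[fix$design$group == "A"]
  dup <- c(half, half)
  dup_lab <- rep(c("x", "y"), each = length(half))
  resd <- nbs_test(dup, dup_lab, c("x", "y"), t_primary = 3.4,
                   n_perm = 200, seed = 2, direction = "greater")
  if (length(resd$components))
    expect_true(all(vapply(resd$components, `[[`, 0.0, "fwer_p") == 1))
})

test_that("node relabeling permutes NBS components consistently", {
  fix <- toy_connectomes(n_per_group = 10, n_nodes = 12, T_volumes = 150,
                         delta = 0.5, seed = 13, clique = 1:4)
  set.seed(6)
  perm <- sample(12)  # new node i carries old node perm[i]
  permuted <- lapply(fix$connectomes, function(C)
    as_connectivity(C$values[perm, perm], C$subject_id))
  r1 <- nbs_test(fix$connectomes, fix$design$group, c("A", "B"),
                 n_perm = 50, seed = 3, direction = "greater")
  r2 <- nbs_test(permuted, fix$design$group, c("A", "B"),
                 n_perm = 50, seed = 3, direction = "greater")
  keys1 <- sort(unlist(lapply(r1$components, function(k)
    paste(k$edges[, 1], k$edges[, 2], sep = "-"))))
  keys2 <- sort(unlist(lapply(r2$components, function(k)
    paste(pmin(perm[k$edges[, 1]], perm[k$edges[, 2]]),
          pmax(perm[k$edges[, 1]], perm[k$edges[, 2]]), sep = "-"))))
  expect_equal(keys2, keys1)
})

test_that("t_for_p inverts the t tail mapping", {
  expect_equal(t_for_p(1 - 1e-12, 10), 0, tolerance = 1e-6)
  expect_equal(t_for_p(0.001, 48), 3.505068, tolerance = 1e-5)
  for (df in c(5, 30, 48)) for (p in c(0.001, 0.01, 0.2)) {
    expect_equal(p_for_t(t_for_p(p, df), df), p, tolerance = 1e-10)
    expect_equal(p_for_t(t_for_p(p, df, FALSE), df, FALSE), p,
                 tolerance = 1e-10)
  }
})

test_that("NBS results serialize to edge lists, summaries and metadata", {
  fix <- toy_connectomes(n_per_group = 8, n_nodes = 10, T_volumes = 120,
                         delta = 0.5, seed = 17, clique = 1:4)
  res <- nbs_test(fix$connectomes, fix$design$group, c("A", "B"),
                  n_perm = 100, seed = 4, direction = "greater")
  dir <- withr::local_tempdir()
  write_nbs_result(res, dir)
  files <- list.files(dir)
  expect_true(any(grepl("_edges\\.tsv$", files)))
  expect_true(any(grepl("_components\\.tsv$", files)))
  meta <- jsonlite::read_json(file.path(dir, grep("_meta", files, value = TRUE)))
  expect_equal(meta$t_primary, 3.4)
  expect_equal(meta$n_perm, 100)
})
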