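# ---- permutation engine ------------------------------------------------

# enumerate every distinct assignment of the label multiset to positions;
# returns an n x M integer matrix (label codes per position)
enumerate_labelings <- function(counts) {
  g <- length(counts)
  n <- sum(counts)
  # choose positions for each label code in turn; the last code fills the rest
  assignments <- list(list(free = seq_len(n), col = integer(n)))
  for (code in seq_len(g - 1)) {
    nxt <- list()
    for (a in assignments) {
      picks <- combn(length(a$free), counts[code], simplify = FALSE)
      for (p in picks) {
        col <- a$col
        col[a$free[p]] <- code
        nxt[[length(nxt) + 1L]] <- list(free = a$free[-p], col = col)
      }
    }
    assignments <- nxt
  }
  out <- vapply(assignments, function(a) {
    col <- a$col
    col[a$free] <- g
    col
  }, integer(n))
  out
}

n_distinct_labelings <- function(counts) {
  exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
}

# group sums / sums of squares for a batch of label assignments.
# values: n x p; lab_mat: n x B integer label codes; returns per-group
# p x B matrices of sums and sums of squares.
batch_group_stats <- function(values, lab_mat, g, stat) {
  n <- nrow(values)
  counts <- tabulate(lab_mat[, 1], g)
  V2 <- values^2
  S <- vector("list", g)
  Q <- vector("list", g)
  for (code in seq_len(g)) {
    P <- (lab_mat == code) * 1
    S[[code]] <- crossprod(values, P)   # p x B
    Q[[code]] <- crossprod(V2, P)
  }
  if (stat == "t") {
    n1 <- counts[1]; n2 <- counts[2]
    m1 <- S[[1]] / n1; m2 <- S[[2]] / n2
    v1 <- (Q[[1]] - n1 * m1^2) / (n1 - 1)
    v2 <- (Q[[2]] - n2 * m2^2) / (n2 - 1)
    sp2 <- pmax(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2), 0)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tt <- (m1 - m2) / se
    tt[se == 0 & (m1 - m2) == 0] <- 0
    tt
  } else {
    n_tot <- n
    tot <- Reduce(`+`, S)               # p x B, constant across B
    between <- Reduce(`+`, lapply(seq_len(g), function(code)
      S[[code]]^2 / counts[code]))      # sum_g n_g * mean_g^2
    ssb <- pmax(between - tot^2 / n_tot, 0)
    sstot <- colSums(V2)                # per column, invariant under permutation
    ssw <- pmax(sstot - between, 0)     # sum x^2 - sum_g n_g mean_g^2
    df1 <- g - 1; df2 <- n_tot - g
    Fv <- (ssb / df1) / (ssw / df2)
    Fv[ssw == 0 & ssb == 0] <- 0
    Fv[ssw == 0 & ssb > 0] <- Inf
    Fv
  }
}

# core permutation machinery shared by scalar and matrix interfaces.
# values: n x p matrix; returns observed stats, permutation p per column,
# parametric p, and the method used.
perm_test_matrix <- function(values, labels, stat = c("F", "t"),
                             n_perm = 10000, force_mc = FALSE,
                             force_exhaustive = FALSE) {
  stat <- match.arg(stat)
  values <- as.matrix(values)
  labels <- droplevels(factor(labels))
  g <- nlevels(labels)
  counts <- as.integer(table(labels))
  n <- nrow(values)
  if (length(labels) != n) stop("labels/values length mismatch", call. = FALSE)
  if (g < 2 || any(counts < 2))
    stop("invalid groups: need >= 2 groups with >= 2 subjects each",
         call. = FALSE)
  if (stat == "t" && g != 2)
    stop("t statistic requires exactly 2 groups", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite for permutation testing", call. = FALSE)

  lab_int <- as.integer(labels)
  obs <- batch_group_stats(values, matrix(lab_int, ncol = 1), g, stat)
  obs_cmp <- if (stat == "t") abs(obs) else obs  # two-sided via |t|

  exhaustive <- force_exhaustive ||
    (!force_mc && n_distinct_labelings(counts) <= n_perm)
  if (force_exhaustive && n_distinct_labelings(counts) > 1e6)
    stop("too many labelings for exhaustive enumeration", call. = FALSE)
  if (exhaustive) {
    lab_mat <- enumerate_labelings(counts)
    # relabel so code order matches the observed factor coding
    perm <- batch_group_stats(values, lab_mat, g, stat)
    perm_cmp <- if (stat == "t") abs(perm) else perm
    p_perm <- rowMeans(perm_cmp >= as.vector(obs_cmp) - 1e-12)
    n_used <- ncol(lab_mat)
  } else {
    idx <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
    lab_mat <- matrix(lab_int[idx], n, n_perm)
    perm <- batch_group_stats(values, lab_mat, g, stat)
    perm_cmp <- if (stat == "t") abs(perm) else perm
    p_perm <- (1 + rowSums(perm_cmp >= as.vector(obs_cmp) - 1e-12)) /
      (1 + n_perm)
    n_used <- n_perm
  }
  df2 <- n - g
  p_param <- if (stat == "t") 2 * pt(-abs(obs), df2) else
    pf(obs, g - 1, df2, lower.tail = FALSE)
  list(statistic = as.vector(obs), p_perm = as.vector(p_perm),
       p_param = as.vector(p_param),
       method = if (exhaustive) "exhaustive" else "monte-carlo",
       n_perm = n_used)
}

#' Permutation group test for one variable
#'
#' Group labels are randomly reassigned (keeping the original group sizes)
#' and the test statistic recomputed to build the permutation null. When the
#' number of distinct labelings is at most `n_perm` the full enumeration is
#' used instead of Monte-Carlo sampling; otherwise the p-value is
#' `(1 + #permuted >= observed) / (1 + n_perm)`, which is strictly positive
#' and valid. The F statistic is one-way ANOVA; the t statistic is the
#' pooled-variance two-sample t, compared two-sided via its absolute value.
#'
#' @param values numeric vector, one value per subject.
#' @param labels group labels (>= 2 groups, each with >= 2 subjects).
#' @param stat `"F"` (any number of groups) or `"t"` (two groups).
#' @param n_perm permutations (default 10000, the field-standard count).
#' @param seed integer seed.
#' @param method `"auto"` (exhaustive when feasible, the default),
#'   `"exhaustive"` or `"monte-carlo"`.
#' @return a `group_test` list: `statistic`, `p_perm`, `p_param`, `method`
#'   (`"exhaustive"` or `"monte-carlo"`), `n_perm`, `seed`.
#' @export
permutation_group_test <- function(values, labels, stat = c("F", "t"),
                                   n_perm = 10000, seed = 1,
                                   method = c("auto", "exhaustive",
                                              "monte-carlo")) {
  stat <- match.arg(stat)
  method <- match.arg(method)
  res <- with_seed(seed, perm_test_matrix(matrix(values, ncol = 1), labels,
                                          stat, n_perm,
                                          force_mc = method == "monte-carlo",
                                          force_exhaustive =
                                            method == "exhaustive"))
  structure(list(statistic = res$statistic, p_perm = res$p_perm,
                 p_param = res$p_param, method = res$method,
                 n_perm = res$n_perm, stat = stat, seed = as.integer(seed)),
            class = "group_test")
}

# ---- covariate residualization ----------------------------------------

#' Residualize values on nuisance covariates
#'
#' Ordinary least-squares residuals of the values on an intercept plus the
#' requested covariates, fitted once on the full sample (no group terms, so
#' the permutation null is untouched).
#'
#' @param values numeric vector or n x p matrix, rows matching `design`.
#' @param design a `cohort_design` data frame.
#' @param covariates columns of `design` to regress out (default age, sex).
#' @return residuals with the same shape as `values`.
#' @export
residualize_covariates <- function(values, design, covariates = c("age", "sex")) {
  vec <- is.null(dim(values))
  Y <- as.matrix(values)
  missing <- setdiff(covariates, names(design))
  if (length(missing))
    stop("design lacks covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- cbind(intercept = 1, as.matrix(design[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  if (nrow(Y) != nrow(X)) stop("values/design row mismatch", call. = FALSE)
  # constant covariates carry no information; the intercept absorbs them
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col) var(col) > 0))
  X <- X[, keep, drop = FALSE]
  if (nrow(X) < (ncol(X) - 1) + 3)
    stop("need at least 3 more subjects than covariates", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient covariate matrix (collinear covariates)",
         call. = FALSE)
  R <- qr.resid(qx, Y)
  if (vec) as.vector(R) else R
}

# ---- multiple testing --------------------------------------------------

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, plus the
#' rejection mask at level `q`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` and `reject`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adjusted <- p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}

# ---- metric-table inference -------------------------------------------

# subjects x nodes matrix for one (metric, threshold); Inf sentinels
# (isolated-node path length) are replaced by n_nodes, an upper bound on any
# finite hop distance, so OLS and permutation stay defined
metric_matrix <- function(metrics, subjects, metric, threshold) {
  sub <- metrics[metrics$scope == "nodal" & metrics$metric == metric &
                   abs(metrics$threshold - threshold) < 1e-9, , drop = FALSE]
  nodes <- sort(unique(sub$node))
  M <- matrix(NA_real_, length(subjects), length(nodes),
              dimnames = list(subjects, as.character(nodes)))
  idx <- cbind(match(sub$subject_id, subjects), match(sub$node, nodes))
  M[idx] <- sub$value
  if (anyNA(M))
    stop("metric table does not cover all subjects in the design", call. = FALSE)
  M[!is.finite(M)] <- length(nodes)
  M
}

#' Nodal permutation inference across metrics and thresholds
#'
#' For every (metric, threshold) cell: residualize nodal values on the
#' nuisance covariates, run the omnibus permutation F test across all
#' groups per node, then pairwise permutation t tests, and apply
#' Benjamini-Hochberg FDR across nodes within each
#' (metric, threshold, contrast) family.
#'
#' @param metrics a `metric_table` from [metrics_for_cohort()].
#' @param design a `cohort_design` covering the table's subjects.
#' @param n_perm permutations per test.
#' @param seed integer seed (one stream drives the whole table).
#' @param q FDR level.
#' @param covariates nuisance columns of `design` (default age, sex).
#' @param thresholds restrict to these sparsity levels (default: all found).
#' @param metric_names restrict to these metrics (default: all nodal).
#' @return data frame: `metric`, `threshold`, `node` (0-based), `contrast`,
#'   `stat`, `statistic`, `p_perm`, `p_param`, `p_fdr`, `significant`,
#'   `n_perm`, `seed`.
#' @export
nodal_inference <- function(metrics, design, n_perm = 1000, seed = 1,
                            q = 0.05, covariates = c("age", "sex"),
                            thresholds = NULL, metric_names = NULL) {
  design <- validate_cohort_design(design)
  subjects <- design$subject_id
  nodal <- metrics[metrics$scope == "nodal", , drop = FALSE]
  if (is.null(thresholds)) thresholds <- sort(unique(nodal$threshold))
  if (is.null(metric_names)) metric_names <- unique(nodal$metric)
  groups <- levels(design$group)
  pairs <- if (length(groups) >= 2) combn(groups, 2, simplify = FALSE) else list()
  omnibus_label <- paste(groups, collapse = "-")

  with_seed(seed, {
    out <- list()
    for (m in metric_names) for (S in thresholds) {
      V <- metric_matrix(nodal, subjects, m, S)
      R <- residualize_covariates(V, design, covariates)
      nodes <- as.integer(colnames(V))

      cells <- list(list(label = omnibus_label, stat = "F",
                         idx = seq_len(nrow(design))))
      for (pr in pairs)
        cells <- c(cells, list(list(label = paste(pr, collapse = "-"),
                                    stat = "t",
                                    idx = which(design$group %in% pr))))
      for (cell in cells) {
        res <- perm_test_matrix(R[cell$idx, , drop = FALSE],
                                design$group[cell$idx],
                                cell$stat, n_perm, force_mc = TRUE)
        fdr <- bh_fdr(res$p_perm, q)
        out[[length(out) + 1L]] <- data.frame(
          metric = m, threshold = S, node = nodes, contrast = cell$label,
          stat = cell$stat, statistic = res$statistic,
          p_perm = res$p_perm, p_param = res$p_param,
          p_fdr = fdr$adjusted, significant = fdr$reject,
          n_perm = res$n_perm, seed = as.integer(seed))
      }
    }
    do.call(rbind, out)
  })
}

#' Global-metric permutation inference across thresholds
#'
#' Same machinery as [nodal_inference()] applied to the global metrics; the
#' FDR family is the set of thresholds within each (metric, contrast), so
#' per-threshold p-values are reported alongside an adjusted column.
#'
#' @inheritParams nodal_inference
#' @return data frame as in [nodal_inference()] but without a `node` column.
#' @export
global_inference <- function(metrics, design, n_perm = 1000, seed = 1,
                             q = 0.05, covariates = c("age", "sex")) {
  design <- validate_cohort_design(design)
  subjects <- design$subject_id
  glob <- metrics[metrics$scope == "global", , drop = FALSE]
  thresholds <- sort(unique(glob$threshold))
  metric_names <- unique(glob$metric)
  groups <- levels(design$group)
  pairs <- combn(groups, 2, simplify = FALSE)
  omnibus_label <- paste(groups, collapse = "-")

  with_seed(seed, {
    out <- list()
    for (m in metric_names) {
      V <- vapply(thresholds, function(S) {
        sub <- glob[glob$metric == m & abs(glob$threshold - S) < 1e-9, ]
        sub$value[match(subjects, sub$subject_id)]
      }, numeric(length(subjects)))
      V <- matrix(V, nrow = length(subjects))
      if (anyNA(V)) stop("global metrics do not cover the design", call. = FALSE)
      V[!is.finite(V)] <- max(V[is.finite(V)], 0) + 1
      R <- residualize_covariates(V, design, covariates)

      cells <- list(list(label = omnibus_label, stat = "F",
                         idx = seq_len(nrow(design))))
      for (pr in pairs)
        cells <- c(cells, list(list(label = paste(pr, collapse = "-"),
                                    stat = "t",
                                    idx = which(design$group %in% pr))))
      for (cell in cells) {
        res <- perm_test_matrix(R[cell$idx, , drop = FALSE],
                                design$group[cell$idx],
                                cell$stat, n_perm, force_mc = TRUE)
        fdr <- bh_fdr(res$p_perm, q)
        out[[length(out) + 1L]] <- data.frame(
          metric = m, threshold = thresholds, contrast = cell$label,
          stat = cell$stat, statistic = res$statistic,
          p_perm = res$p_perm, p_param = res$p_param,
          p_fdr = fdr$adjusted, significant = fdr$reject,
          n_perm = res$n_perm, seed = as.integer(seed))
      }
    }
    do.call(rbind, out)
  })
}

# ---- clinical correlations and summary-statistic tests ----------------

#' Pearson correlation between a graph metric and a clinical score
#'
#' @param metric_values per-subject metric values.
#' @param scores per-subject clinical scores (pairs with `NA` are dropped).
#' @return list with `r`, `p` (two-sided, t transform with n-2 df) and `n`.
#' @export
clinical_correlation <- function(metric_values, scores) {
  ok <- is.finite(metric_values) & is.finite(scores)
  x <- metric_values[ok]; y <- scores[ok]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: constant variable", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pooled two-sample t test from summary statistics
#'
#' @param mean1,sd1,n1 first group's mean, standard deviation and size.
#' @param mean2,sd2,n2 second group's summaries.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- if (se == 0) {
    if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else (mean1 - mean2) / se
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' One-way ANOVA from summary statistics
#'
#' Reconstructs the F test from group means, standard deviations and sizes:
#' between-group sums of squares from the means, within-group from
#' `(n - 1) * sd^2`.
#'
#' @param groups list of `c(mean, sd, n)` triplets (>= 2 groups, n >= 2).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
summary_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  m <- vapply(groups, `[`, 0.0, 1)
  s <- vapply(groups, `[`, 0.0, 2)
  n <- vapply(groups, `[`, 0.0, 3)
  if (any(n < 2)) stop("need n >= 2 per group", call. = FALSE)
  grand <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- length(groups) - 1
  df2 <- sum(n) - length(groups)
  Fv <- if (ssw == 0) { if (ssb == 0) 0 else Inf } else
    (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction, matching the standard contingency-table test on
#' demographic categories.
#'
#' @param counts R x C matrix of counts with positive marginals.
#' @return list with `chi2`, `df`, `p`.
#' @export
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero marginal", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(res$expected <= 0))
    stop("all expected counts must be positive", call. = FALSE)
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Demographic summary table with group tests
#'
#' Mirrors a cohort-characteristics table: per-group mean (sd) for each
#' numeric covariate with an ANOVA p across all groups, and a chi-squared
#' p for sex.
#'
#' @param design a `cohort_design` data frame.
#' @return data frame with one row per variable.
#' @export
demographics_report <- function(design) {
  design <- validate_cohort_design(design)
  groups <- levels(design$group)
  num_vars <- setdiff(names(design)[vapply(design, is.numeric, TRUE)], "sex")
  rows <- lapply(num_vars, function(v) {
    cells <- vapply(groups, function(g) {
      x <- design[[v]][design$group == g]
      x <- x[is.finite(x)]
      if (length(x) < 2) return(NA_character_)
      sprintf("%.2f ± %.2f", mean(x), sd(x))
    }, "")
    gs <- lapply(groups, function(g) {
      x <- design[[v]][design$group == g]
      x <- x[is.finite(x)]
      if (length(x) < 2) NULL else c(mean(x), sd(x), length(x))
    })
    gs <- gs[!vapply(gs, is.null, TRUE)]
    p <- if (length(gs) >= 2) summary_anova(gs)$p else NA_real_
    data.frame(variable = v, t(cells), test = "ANOVA", p = p,
               check.names = FALSE)
  })
  sex_tab <- table(design$group, design$sex)
  sex_row <- data.frame(
    variable = "sex",
    t(vapply(groups, function(g)
      paste(sex_tab[g, ], collapse = "/"), "")),
    test = "chi-squared", p = chisq_independence(sex_tab)$p,
    check.names = FALSE)
  out <- rbind(do.call(rbind, rows), sex_row)
  names(out)[2:(1 + length(groups))] <- groups
  rownames(out) <- NULL
  out
}
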