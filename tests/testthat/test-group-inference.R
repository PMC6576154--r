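test_that("covariate residualization matches OLS and is orthogonal", {
  design <- data.frame(subject_id = sprintf("s%d", 1:8),
                       group = factor(rep(c("A", "B"), 4)),
                       age = c(10, 20, 30, 50, 15, 25, 35, 45),
                       sex = c(0, 1, 0, 1, 1, 0, 1, 0))
  design <- validate_cohort_design(design)

  # values that are an exact linear function of age leave zero residuals
  r0 <- residualize_covariates(2 * design$age, design)
  expect_lt(max(abs(r0)), 1e-10)

  # constant covariate: residuals are centered values
  d2 <- design; d2$age <- rep(40, 8)
  vals <- rnorm(8)
  expect_equal(residualize_covariates(vals, d2, "age"), vals - mean(vals),
               tolerance = 1e-10)

  # normal-equations oracle on the worked 4-subject example
  d3 <- data.frame(subject_id = letters[1:4], group = factor(rep("A", 4)),
                   age = c(10, 20, 30, 50), sex = rep(1, 4))
  class(d3) <- c("cohort_design", "data.frame")
  y <- c(1, 2, 3, 4)
  X <- cbind(1, d3$age)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize_covariates(y, d3, "age"),
               as.vector(y - X %*% beta), tolerance = 1e-10)

  # residuals orthogonal to centered covariates
  set.seed(3)
  r <- residualize_covariates(rnorm(8), design)
  expect_lt(abs(sum(r * (design$age - mean(design$age)))), 1e-8)
  expect_lt(abs(sum(r * (design$sex - mean(design$sex)))), 1e-8)

  d4 <- design; d4$age2 <- design$age
  expect_error(residualize_covariates(rnorm(8), d4, c("age", "age2")),
               "rank-deficient")
})

test_that("permutation test enumerates exhaustively on toy problems", {
  # (10, 11 | 1, 2): only the observed split and its mirror reach max |t|
  res <- permutation_group_test(c(10, 11, 1, 2), c("g1", "g1", "g2", "g2"),
                                stat = "t", n_perm = 100, seed = 1)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_perm, 6)  # C(4,2)
  expect_equal(res$p_perm, 2 / 6, tolerance = 1e-12)

  # all values equal -> p = 1
  same <- permutation_group_test(rep(3, 6), rep(c("a", "b"), 3), "t",
                                 n_perm = 100, seed = 1)
  expect_equal(same$p_perm, 1)

  # label-symmetry: consistent relabeling leaves p unchanged
  v <- c(5, 7, 1, 2, 9, 4)
  l <- c("a", "a", "b", "b", "a", "b")
  o <- order(l)
  r1 <- permutation_group_test(v, l, "F", n_perm = 50, seed = 4)
  r2 <- permutation_group_test(v[o], l[o], "F", n_perm = 50, seed = 4)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_equal(r1$statistic, r2$statistic)

  expect_error(permutation_group_test(1:3, c("a", "a", "b"), "t"),
               "invalid groups")
})

test_that("Monte-Carlo p-values track the exhaustive reference", {
  set.seed(42)
  for (rep in 1:4) {
    v <- rnorm(5)
    l <- c("a", "a", "b", "b", "b")
    ex <- permutation_group_test(v, l, "t", seed = 1, method = "exhaustive")
    mc <- permutation_group_test(v, l, "t", n_perm = 10000, seed = rep,
                                 method = "monte-carlo")
    expect_equal(mc$method, "monte-carlo")
    expect_lt(abs(mc$p_perm - ex$p_perm), 0.02)
  }
})

test_that("permutation F agrees with parametric ANOVA statistic", {
  set.seed(11)
  v <- rnorm(18)
  l <- rep(c("a", "b", "c"), each = 6)
  res <- permutation_group_test(v, l, "F", n_perm = 99, seed = 2)
  expect_equal(res$statistic,
               unname(summary(aov(v ~ l))[[1]]$`F value`[1]),
               tolerance = 1e-9)
  tt <- permutation_group_test(v[1:12], l[1:12], "t", n_perm = 99, seed = 2)
  expect_equal(tt$statistic,
               unname(t.test(v[1:6], v[7:12], var.equal = TRUE)$statistic),
               tolerance = 1e-9)
})

test_that("BH-FDR reproduces the hand step-up computation", {
  fdr <- bh_fdr(c(0.005, 0.009, 0.05, 0.5))
  expect_equal(fdr$adjusted, c(0.018, 0.018, 0.05 * 4 / 3, 0.5),
               tolerance = 1e-12)
  expect_equal(fdr$reject, c(TRUE, TRUE, FALSE, FALSE))

  expect_equal(bh_fdr(rep(0.01, 5))$adjusted, rep(0.01, 5))
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")

  # monotone transform, invariant to input order
  set.seed(9)
  p <- runif(20)
  o <- sample(20)
  a1 <- bh_fdr(p)$adjusted
  a2 <- bh_fdr(p[o])$adjusted
  expect_equal(a2, a1[o])
  expect_true(all(diff(a1[order(p)]) >= -1e-12))
  expect_true(all(a1 >= p - 1e-12))
})

test_that("type-I error of the permutation test is nominal", {
  set.seed(123)
  n_sim <- 400
  rej <- logical(n_sim)
  l <- rep(c("a", "b"), each = 10)
  for (i in seq_len(n_sim)) {
    v <- rnorm(20)
    p <- permutation_group_test(v, l, "t", n_perm = 199, seed = i,
                                method = "monte-carlo")$p_perm
    rej[i] <- p <= 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("null permutation p-values are uniformly distributed", {
  set.seed(77)
  l <- rep(c("a", "b"), each = 6)
  ps <- vapply(1:200, function(i)
    permutation_group_test(rnorm(12), l, "t", n_perm = 199, seed = i,
                           method = "monte-carlo")$p_perm, 0.0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("nodal inference recovers a planted degree effect and keeps nulls flat", {
  fix <- toy_connectomes(n_per_group = 12, n_nodes = 16, T_volumes = 150,
                         delta = 0.5, seed = 21, clique = 1:4)
  stacks <- lapply(fix$connectomes, function(C)
    threshold_sweep(clip_negative(C), 0.2, 0.2, 0.01))
  metrics <- metrics_for_cohort(stacks)
  res <- nodal_inference(metrics, fix$design, n_perm = 500, seed = 3,
                         metric_names = "DEG")
  omni <- res[res$contrast == "A-B" & res$stat == "F", ]
  expect_equal(nrow(omni), 16)
  # row bookkeeping: nodes x contrasts (omnibus + 1 pair over 2 groups)
  expect_equal(nrow(res), 16 * 2)
  # planted-clique nodes (higher correlations -> higher degree) lead the
  # signed pairwise contrast; the omnibus F also reacts to the compensatory
  # degree decrease elsewhere (total degree is fixed at 2K per graph), so
  # the directional t is the sharp ranking
  tt <- res[res$stat == "t", ]
  top4 <- tt$node[order(-tt$statistic)][1:4]
  expect_setequal(top4, 0:3)
  expect_gt(min(rank(omni$statistic)[omni$node %in% 0:3]), 8)
  expect_true(all(omni$p_fdr >= omni$p_perm - 1e-12))
  expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
})

test_that("clinical correlations follow the Pearson t transform", {
  m <- c(1, 2, 3, 4)
  expect_equal(clinical_correlation(m, 2 * m)$r, 1)
  expect_equal(clinical_correlation(m, -m)$r, -1)
  cc <- clinical_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(cc$r, 0.8, tolerance = 1e-12)
  tstat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(cc$p, 2 * pt(-tstat, 2), tolerance = 1e-12)
  expect_error(clinical_correlation(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("summary-statistic tests reproduce cohort-table p-values", {
  # printed cohort table: BDI-II 5.85 +/- 4.83 (n=20) vs 8.07 +/- 4.92 (n=15)
  expect_equal(summary_ttest(5.85, 4.83, 20, 8.07, 4.92, 15)$p, 0.191,
               tolerance = 0.002)
  expect_equal(summary_ttest(27.70, 11.16, 20, 29.47, 14.57, 15)$p, 0.687,
               tolerance = 0.002)
  eq <- summary_ttest(5, 1, 10, 5, 1, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  expect_equal(summary_anova(list(c(42.60, 10.14, 20), c(41.60, 13.69, 15),
                                  c(39.47, 13.19, 30)))$p, 0.667,
               tolerance = 0.002)
  expect_equal(summary_anova(list(c(0.50, 1.10, 20), c(0.20, 0.78, 15),
                                  c(0.37, 0.96, 30)))$p, 0.665,
               tolerance = 0.002)
  ident <- summary_anova(list(c(3, 1, 10), c(3, 1, 10)))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)

  expect_equal(chisq_independence(rbind(c(10, 10), c(4, 11), c(11, 19)))$p,
               0.359, tolerance = 0.002)
  prop <- rbind(c(10, 20), c(5, 10))
  expect_equal(chisq_independence(prop)$chi2, 0, tolerance = 1e-12)
  perfect <- rbind(c(10, 0), c(0, 10))
  res <- chisq_independence(perfect)
  expect_equal(res$chi2, 20)  # closed form n(ad-bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$df, 1)
  expect_error(chisq_independence(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("summary tests agree with raw-data tests on exact-moment samples", {
  set.seed(31)
  exact_sample <- function(m, s, n) {
    z <- rnorm(n)
    m + s * (z - mean(z)) / sd(z)
  }
  x <- exact_sample(5.85, 4.83, 20)
  y <- exact_sample(8.07, 4.92, 15)
  ref <- t.test(x, y, var.equal = TRUE)
  st <- summary_ttest(5.85, 4.83, 20, 8.07, 4.92, 15)
  expect_equal(st$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(st$p, ref$p.value, tolerance = 1e-9)

  g <- list(c(42.60, 10.14, 20), c(41.60, 13.69, 15), c(39.47, 13.19, 30))
  raw <- unlist(lapply(g, function(p) exact_sample(p[1], p[2], p[3])))
  lab <- factor(rep(seq_along(g), times = vapply(g, `[`, 0.0, 3)))
  ref_f <- summary(aov(raw ~ lab))[[1]]$`F value`[1]
  expect_equal(summary_anova(g)$F, ref_f, tolerance = 1e-9)
})

test_that("demographics report carries per-group summaries and tests", {
  d <- make_cohort_design(c(BD = 10, MDD = 8, HC = 12), seed = 6)
  rep_tab <- demographics_report(d)
  expect_true(all(c("age", "sex", "bdi") %in% rep_tab$variable))
  expect_true(all(c("BD", "MDD", "HC") %in% names(rep_tab)))
  age_p <- rep_tab$p[rep_tab$variable == "age"]
  gs <- lapply(levels(d$group), function(g) {
    x <- d$age[d$group == g]; c(mean(x), sd(x), length(x))
  })
  expect_equal(age_p, summary_anova(gs)$p, tolerance = 1e-12)
})
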