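mk_paired_table <- function(tumor, normal, marker = "m1") {
  n <- length(tumor)
  out <- data.frame(
    sample_id = c(paste0("p", seq_len(n), "_T"), paste0("p", seq_len(n), "_N")),
    pair_id = rep(paste0("p", seq_len(n)), 2L),
    group = rep(c("tumor", "normal"), each = n))
  out[[marker]] <- c(tumor, normal)
  out
}

test_that("paired marker tests match sign-flip enumeration", {
  # identical values: p = 1
  tab0 <- mk_paired_table(c(50, 60, 70, 55, 65), c(50, 60, 70, 55, 65))
  expect_equal(marker_test_paired(tab0, "m1")$p_value, 1)
  # n = 6, all tumor lower, no ties: exact p = 2/64
  tab6 <- mk_paired_table(c(40, 45, 50, 42, 47, 52),
                          c(60, 61, 62, 63, 64, 65))
  expect_equal(marker_test_paired(tab6, "m1")$p_value, 2 / 64)
  # random no-tie cases against the enumeration oracle
  set.seed(81)
  for (k in 1:15) {
    n <- sample(5:10, 1L)
    t_vals <- round(runif(n, 20, 80), 3)
    n_vals <- round(t_vals + rnorm(n, 0, 8), 4)
    tab <- mk_paired_table(t_vals, n_vals)
    got <- marker_test_paired(tab, "m1")$p_value
    want <- oracle_signed_rank_p(t_vals, n_vals)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(marker_test_paired(mk_paired_table(1:3, 4:6), "m1"),
               "complete pairs")
})

test_that("Kruskal-Wallis agrees with the rank-variance form and permutations", {
  tab <- data.frame(group = rep(c("a", "b"), each = 3L),
                    m1 = c(1, 2, 3, 10, 11, 12),
                    sample_id = paste0("s", 1:6), pair_id = NA)
  res <- marker_test_groups(tab, "m1")
  expect_equal(res$statistic, oracle_kw_h(tab$m1, tab$group))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)  # 3.857
  # identical groups: H = 0 (up to ties), p ~ 1
  tab0 <- data.frame(group = rep(c("a", "b"), each = 4L),
                     m1 = rep(c(5, 6, 7, 8), 2L),
                     sample_id = paste0("s", 1:8), pair_id = NA)
  res0 <- marker_test_groups(tab0, "m1")
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_gte(res0$p_value, 0.99)
  # H matches the oracle under ties and >2 groups
  set.seed(82)
  for (k in 1:15) {
    g <- rep(c("a", "b", "c"), each = 3L)
    v <- sample(1:5, 9L, replace = TRUE)
    tabk <- data.frame(group = g, m1 = v,
                       sample_id = paste0("s", 1:9), pair_id = NA)
    if (stats::sd(v) == 0) next
    expect_equal(marker_test_groups(tabk, "m1")$statistic,
                 oracle_kw_h(v, g), tolerance = 1e-10)
  }
  expect_error(marker_test_groups(tab[tab$group == "a", ], "m1"),
               ">= 2 groups")
})

test_that("chi-square Kruskal-Wallis p tracks the exact permutation null", {
  set.seed(83)
  for (k in 1:5) {
    g <- rep(c("a", "b"), each = 4L)
    v <- round(runif(8L, 0, 10), 2)
    tab <- data.frame(group = g, m1 = v,
                      sample_id = paste0("s", 1:8), pair_id = NA)
    p_chisq <- marker_test_groups(tab, "m1")$p_value
    p_perm <- oracle_kw_perm_p(v, g)
    expect_lt(abs(p_chisq - p_perm), 0.15)
  }
})

test_that("BH q-values implement the step-up procedure", {
  fdr <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(unname(fdr$q_values), rep(0.04, 4L))
  expect_true(all(fdr$selected))
  expect_equal(unname(bh_fdr(0.2)$q_values), 0.2)
  all1 <- bh_fdr(rep(1, 5L))
  expect_equal(unname(all1$q_values), rep(1, 5L))
  expect_false(any(all1$selected))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  # permutation invariance and q >= p elementwise
  set.seed(84)
  p <- runif(20L)
  q1 <- bh_fdr(p)$q_values
  perm <- sample(20L)
  q2 <- bh_fdr(p[perm])$q_values
  expect_equal(q2, q1[perm])
  expect_true(all(q1 >= p))
  # q is monotone non-decreasing with p
  o <- order(p)
  expect_true(all(diff(q1[o]) >= -1e-15))
})

test_that("ridge logistic matches glm at tiny penalty and handles separation", {
  set.seed(85)
  n <- 80L
  x <- cbind(a = rnorm(n), b = rnorm(n))
  eta <- 0.5 + 0.8 * x[, 1L] - 0.4 * x[, 2L]
  y <- runif(n) < stats::plogis(eta)
  fit <- ridge_logistic(x, y, lambda = 1e-8)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(fit$intercept, unname(stats::coef(ref)[1L]), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)[2:3]),
               tolerance = 1e-4)
  expect_equal(unname(fit$fitted), unname(stats::fitted(ref)),
               tolerance = 1e-5)
  # a binary perfectly separating marker yields near-0/1 probabilities
  # yet converges thanks to the penalty
  x_sep <- cbind(m = rep(c(0, 1), each = 20L))
  y_sep <- rep(c(FALSE, TRUE), each = 20L)
  fit_sep <- ridge_logistic(x_sep, y_sep, lambda = 1e-4)
  expect_true(fit_sep$converged)
  expect_true(all(fit_sep$fitted[y_sep] > 0.99))
  expect_true(all(fit_sep$fitted[!y_sep] < 0.01))
  # predict() agrees with the training fit
  expect_equal(unname(predict(fit_sep, data.frame(m = x_sep[, 1L]))),
               unname(fit_sep$fitted))
  expect_error(ridge_logistic(x, rep(TRUE, n)), "both classes")
})

test_that("ridge estimates maximize the penalized likelihood", {
  set.seed(86)
  n <- 60L
  x <- cbind(a = rnorm(n))
  y <- runif(n) < stats::plogis(1.2 * x[, 1L])
  lambda <- 0.05
  fit <- ridge_logistic(x, y, lambda = lambda)
  xs <- scale(x)
  pen_loglik <- function(b0, b1) {
    eta <- b0 + b1 * xs[, 1L]
    mean(y * eta - log1p(exp(eta))) - lambda / 2 * b1^2
  }
  at_opt <- pen_loglik(fit$intercept + fit$coefficients * attr(xs, "scaled:center"),
                       fit$coefficients_std)
  for (k in 1:25) {
    d <- rnorm(2L, 0, 0.05)
    expect_lte(pen_loglik(fit$intercept +
                            fit$coefficients * attr(xs, "scaled:center") + d[1L],
                          fit$coefficients_std + d[2L]),
               at_opt + 1e-12)
  }
})

test_that("AUC follows the rank formula, its conventions, and the ROC area", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(scores, labels)$auc, 1)
  expect_equal(roc_auc(rev(scores), labels)$auc, 0)
  expect_equal(roc_auc(rep(0.5, 6L), labels)$auc, 0.5)  # all tied
  expect_error(roc_auc(scores, rep(TRUE, 6L)), "both classes")
  # expectation over label shuffles is 0.5
  set.seed(87)
  aucs <- vapply(1:200, function(k)
    roc_auc(scores, sample(labels))$auc, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # rank-formula AUC equals the trapezoidal area under the step ROC,
  # and an independent reference implementation
  for (k in 1:25) {
    s <- round(runif(30L), 2)  # rounded: forces ties
    l <- runif(30L) < 0.4
    if (!any(l) || all(l)) next
    ra <- roc_auc(s, l)
    expect_equal(ra$auc, oracle_trapezoid_auc(ra$roc), tolerance = 1e-12)
    expect_equal(ra$auc,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("the cascade selects shifted markers and reports honest AUCs", {
  set.seed(88)
  n_pairs <- 20L
  markers <- sprintf("mk%02d", 1:6)
  normal <- matrix(rnorm(n_pairs * 6L, 70, 5), n_pairs, 6L,
                   dimnames = list(NULL, markers))
  tumor <- normal + matrix(rnorm(n_pairs * 6L, 0, 5), n_pairs, 6L)
  tumor[, 1L] <- tumor[, 1L] - 15  # one true hypomethylation marker
  tab <- data.frame(
    sample_id = c(sprintf("p%02d_T", 1:n_pairs), sprintf("p%02d_N", 1:n_pairs)),
    pair_id = rep(sprintf("p%02d", 1:n_pairs), 2L),
    group = rep(c("tumor", "normal"), each = n_pairs))
  tab <- cbind(tab, rbind(tumor, normal))
  model <- run_diagnostics(tab)
  expect_true("mk01" %in% model$selected)
  expect_gte(model$auc_oof, 0.8)
  expect_gte(model$auc_insample, model$auc_oof - 0.05)
  expect_equal(nrow(model$tests), 6L)
  expect_true(all(model$pi_oof >= 0 & model$pi_oof <= 1))
})

test_that("group-design cascades run on blood-style cohorts", {
  set.seed(89)
  n_per <- 10L
  groups <- rep(c("healthy_blood", "pancreas_blood", "stomach_blood"),
                each = n_per)
  m1 <- c(rnorm(n_per, 80, 4), rnorm(n_per, 65, 4), rnorm(n_per, 70, 4))
  m2 <- rnorm(3L * n_per, 75, 4)
  tab <- data.frame(sample_id = sprintf("s%02d", seq_along(groups)),
                    pair_id = NA_character_, group = groups,
                    mk1 = m1, mk2 = m2)
  model <- run_diagnostics(tab, design = "groups")
  expect_true("mk1" %in% model$selected)
  expect_false("mk2" %in% model$selected)
  expect_gte(model$auc_insample, 0.8)
})

test_that("marker tables pivot from long cohort format", {
  set.seed(90)
  st <- example_study_config(seed = 5L, n_pairs = 6L)
  co <- simulate_cohort(st$config)
  mt <- as_marker_table(co$table)
  expect_equal(nrow(mt), 12L)
  expect_setequal(marker_names(mt), names(st$panel$loci))
  long_row <- co$table[co$table$sample_id == mt$sample_id[1L] &
                         co$table$locus_id == "L1X3", ]
  expect_equal(mt$L1X3[1L], long_row$mean_methylation)
})
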