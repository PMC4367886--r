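mk_matrix <- function(calls, locus = "L", sample = "s") {
  read_meth_matrix(calls, locus, sample)
}

test_that("per-CpG means, coverage and the coverage floor behave as specified", {
  m <- mk_matrix(rbind(c(1L, 1L, 1L),
                       c(1L, NA, 1L),
                       c(0L, 0L, 1L),
                       c(0L, 1L, 1L)))
  pr <- per_cpg_mean(m, min_coverage = 1L)
  expect_equal(pr$mean, c(0.5, 2 / 3, 1))
  expect_equal(pr$coverage, c(4L, 3L, 4L))
  pr10 <- per_cpg_mean(m, min_coverage = 10L)
  expect_true(all(is.na(pr10$mean)))
  expect_equal(pr10$coverage, pr$coverage)
})

test_that("per-CpG means converge to the generative probabilities", {
  set.seed(51)
  model <- epiallele_model("patchy", base_methylation = 0.85,
                           seed_cpg_indices = c(3L, 9L),
                           seed_demethylation_prob = 0.9,
                           spread_decay = 0.4)
  n <- 10000L
  m <- mk_matrix(draw_epialleles(model, 12L, n))
  pr <- per_cpg_mean(m)
  p <- epiallele_mean(model, 12L)
  expect_true(all(abs(pr$mean - p) <= 4 * sqrt(p * (1 - p) / n)))
})

test_that("entropy boundary identities hold exactly", {
  # one epiallele -> 0
  m0 <- mk_matrix(matrix(rep(c(1L, 0L, 1L, 1L), each = 20L), 20L, 4L))
  expect_equal(methylation_entropy(m0, b = 4L)$entropy, 0)
  # all 16 window patterns equally frequent -> 1
  all16 <- as.matrix(expand.grid(rep(list(c(0L, 1L)), 4L)))
  storage.mode(all16) <- "integer"
  m1 <- mk_matrix(all16)
  expect_equal(methylation_entropy(m1, b = 4L)$entropy, 1)
})

test_that("the worked epiallele-count example evaluates correctly", {
  # 8 reads, epiallele counts {4, 2, 1, 1}:
  # ME = (1/4) [ (4/8)*1 + (2/8)*2 + 2*(1/8)*3 ] = 0.4375
  patterns <- rbind(matrix(rep(c(1L, 1L, 1L, 1L), 4L), 4L, byrow = TRUE),
                    matrix(rep(c(0L, 0L, 0L, 0L), 2L), 2L, byrow = TRUE),
                    c(1L, 0L, 1L, 0L),
                    c(0L, 1L, 0L, 1L))
  m <- mk_matrix(patterns)
  expect_equal(methylation_entropy(m, b = 4L, min_reads = 8L)$entropy, 0.4375)
})

test_that("entropy equals the pattern-enumeration oracle on random matrices", {
  set.seed(52)
  for (k in 1:40) {
    n_reads <- sample(10:12, 1L)
    n_cpg <- sample(4:6, 1L)
    calls <- matrix(sample(c(0L, 1L), n_reads * n_cpg, replace = TRUE),
                    n_reads, n_cpg)
    # sprinkle missing calls into some matrices
    if (k %% 2L == 0L) {
      calls[sample(length(calls), ceiling(length(calls) * 0.1))] <- NA_integer_
    }
    m <- mk_matrix(calls)
    got <- methylation_entropy(m, b = 4L, min_reads = 5L)$entropy
    want <- oracle_entropy(calls, b = 4L, min_reads = 5L)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("entropy is invariant to read permutation and bounded in [0,1]", {
  set.seed(53)
  calls <- draw_epialleles(epiallele_model("allelic", 0.9, 0.5), 8L, 30L)
  e1 <- methylation_entropy(mk_matrix(calls))$entropy
  e2 <- methylation_entropy(mk_matrix(calls[sample(30L), ]))$entropy
  expect_equal(e1, e2)
  expect_true(all(e1 >= 0 & e1 <= 1))
})

test_that("window preconditions are enforced", {
  m <- mk_matrix(matrix(1L, 12L, 3L))
  expect_error(methylation_entropy(m, b = 4L), "fewer than the window")
  # too few complete reads in a window -> missing entropy
  calls <- matrix(1L, 12L, 4L)
  calls[1:5, 2L] <- NA_integer_
  e <- methylation_entropy(mk_matrix(calls), b = 4L, min_reads = 10L)
  expect_true(is.na(e$entropy))
  expect_equal(e$n_reads, 7L)
})

test_that("profile comparison uses the exact paired Wilcoxon", {
  mk_profile <- function(means, locus = "L", sample = "s") {
    m <- mk_matrix(matrix(1L, 12L, length(means)))
    pr <- per_cpg_mean(m, min_coverage = 1L)
    pr$mean <- means
    pr
  }
  p1 <- mk_profile(c(0.9, 0.8, 0.7, 0.85, 0.75, 0.95))
  expect_equal(compare_profiles(p1, p1)$p_value, 1)
  # 6 sites, all tumor below normal, no ties: exact p = 2/64
  p_lo <- mk_profile(c(0.50, 0.41, 0.33, 0.46, 0.38, 0.57))
  cmp <- compare_profiles(p_lo, p1)
  expect_equal(cmp$p_value, 2 / 64)
  expect_equal(cmp$n_sites, 6L)
  short <- mk_profile(c(0.9, 0.8, 0.7, 0.85))
  expect_error(compare_profiles(short, short), "need >= 5")
})

test_that("entropy comparison mirrors profile comparison over windows", {
  set.seed(54)
  m_t <- mk_matrix(draw_epialleles(canonical_models(25L)$patchy, 25L, 400L))
  m_n <- mk_matrix(draw_epialleles(epiallele_model("uniform", 0.95), 25L, 400L))
  e_t <- methylation_entropy(m_t)
  e_n <- methylation_entropy(m_n)
  expect_equal(compare_entropy(e_t, e_t)$p_value, 1)
  expect_lt(compare_entropy(e_t, e_n)$p_value, 0.05)
})

test_that("patchy tumors separate from uniform normals by entropy", {
  set.seed(55)
  hits <- vapply(1:40, function(r) {
    m_t <- mk_matrix(draw_epialleles(canonical_models(25L)$patchy, 25L, 500L))
    m_n <- mk_matrix(draw_epialleles(epiallele_model("uniform", 0.95),
                                     25L, 500L))
    compare_entropy(methylation_entropy(m_t),
                    methylation_entropy(m_n))$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("change calls implement the strict 10-point rule", {
  cc <- call_change(c(60, 50, 50, 60, 65), c(75, 60, 50, 50, 50))
  expect_equal(as.character(cc$label),
               c("hypomethylated", "unchanged", "unchanged",
                 "unchanged", "hypermethylated"))
  expect_equal(cc$delta, c(-15, -10, 0, 10, 15))
  # missing means yield no call
  cc_na <- call_change(c(NA, 60), c(50, NA))
  expect_true(all(is.na(cc_na$label)))
})

test_that("change calls are antisymmetric under tumor/normal swap", {
  set.seed(56)
  t_vals <- runif(200L, 0, 100)
  n_vals <- runif(200L, 0, 100)
  fwd <- call_change(t_vals, n_vals)
  rev <- call_change(n_vals, t_vals)
  expect_equal(fwd$delta, -rev$delta)
  map <- c(hypomethylated = "hypermethylated",
           unchanged = "unchanged",
           hypermethylated = "hypomethylated")
  expect_equal(as.character(rev$label),
               unname(map[as.character(fwd$label)]))
})

test_that("sample summaries categorize hypo/hyper combinations", {
  mk_calls <- function(labels) data.frame(label = labels)
  expect_equal(as.character(summarize_sample(
    mk_calls(c("hypomethylated", "hypomethylated", "unchanged")))$category),
    "hypo_only")
  expect_equal(as.character(summarize_sample(
    mk_calls(c("hypomethylated", "hypermethylated")))$category), "both")
  expect_equal(as.character(summarize_sample(
    mk_calls(c("unchanged", "unchanged")))$category), "none")
  expect_equal(as.character(summarize_sample(
    mk_calls("hypermethylated"))$category), "hyper_only")
  s <- summarize_sample(mk_calls(c("hypomethylated", NA, "unchanged")))
  expect_equal(s$n_hypo_loci, 1L)
})

test_that("inter-locus correlation flags duplicated loci and small groups", {
  set.seed(57)
  tab <- expand.grid(pair_id = sprintf("p%02d", 1:12),
                     locus_id = c("A", "B", "C"),
                     group = c("tumor", "normal"),
                     stringsAsFactors = FALSE)
  tab$sample_id <- paste0(tab$pair_id, "_", substr(tab$group, 1, 1))
  tab$mean_methylation <- runif(nrow(tab), 20, 90)
  # locus C duplicates locus A exactly
  for (g in c("tumor", "normal")) {
    sel_a <- tab$group == g & tab$locus_id == "A"
    sel_c <- tab$group == g & tab$locus_id == "C"
    tab$mean_methylation[sel_c] <-
      tab$mean_methylation[sel_a][match(tab$pair_id[sel_c],
                                        tab$pair_id[sel_a])]
  }
  res <- inter_locus_correlation(tab, "tumor")
  expect_equal(res$rho["A", "C"], 1)
  expect_equal(res$n_pairs_tested, 3L)
  small <- tab[tab$pair_id %in% sprintf("p%02d", 1:4), ]
  expect_error(inter_locus_correlation(small, "tumor"), ">= 5 samples")
})

test_that("independent markers are nominally significant at ~ the alpha rate", {
  set.seed(58)
  hits <- 0L
  n_tests <- 0L
  for (rep in 1:60) {
    tab <- expand.grid(pair_id = sprintf("p%02d", 1:20),
                       locus_id = c("A", "B", "C", "D"),
                       stringsAsFactors = FALSE)
    tab$group <- "tumor"
    tab$sample_id <- paste0(tab$pair_id, "_T")
    tab$mean_methylation <- runif(nrow(tab), 20, 90)
    res <- inter_locus_correlation(tab, "tumor")
    p <- res$p[upper.tri(res$p)]
    hits <- hits + sum(p < 0.05, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(p))
  }
  rate <- hits / n_tests
  expect_true(abs(rate - 0.05) < 3 * sqrt(0.05 * 0.95 / n_tests))
})
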