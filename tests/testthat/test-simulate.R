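test_that("degenerate epiallele models are deterministic", {
  m_all <- epiallele_model("uniform", base_methylation = 1)
  expect_true(all(draw_epialleles(m_all, 10, 50) == 1L))
  m_none <- epiallele_model("uniform", base_methylation = 0)
  expect_true(all(draw_epialleles(m_none, 10, 50) == 0L))
  m_allelic <- epiallele_model("allelic", base_methylation = 1,
                               allelic_fraction = 1)
  expect_true(all(draw_epialleles(m_allelic, 10, 50) == 1L))
})

test_that("model validation rejects bad configurations", {
  expect_error(epiallele_model("uniform", base_methylation = 1.2), "\\[0,1\\]")
  expect_error(epiallele_model("uniform", seed_cpg_indices = 3), "patchy")
  expect_error(epiallele_model("patchy"), "seed")
  expect_error(epiallele_model("patchy", seed_cpg_indices = 0), "positive")
  m <- epiallele_model("patchy", seed_cpg_indices = 30)
  expect_error(draw_epialleles(m, 10, 5), "exceeds")
})

test_that("empirical per-CpG methylation matches the analytic law for all kinds", {
  set.seed(101)
  n <- 10000L
  models <- list(
    uniform = epiallele_model("uniform", base_methylation = 0.7),
    allelic = epiallele_model("allelic", base_methylation = 0.9,
                              allelic_fraction = 0.3),
    patchy = epiallele_model("patchy", base_methylation = 0.8,
                             seed_cpg_indices = c(4L, 11L),
                             seed_demethylation_prob = 0.95,
                             spread_decay = 0.6))
  for (nm in names(models)) {
    p <- epiallele_mean(models[[nm]], 15L)
    emp <- colMeans(draw_epialleles(models[[nm]], 15L, n))
    sd4 <- 4 * sqrt(p * (1 - p) / n)
    expect_true(all(abs(emp - p) <= pmax(sd4, 1e-12)), label = nm)
  }
})

test_that("a fully penetrant point seed demethylates only its own CpG", {
  set.seed(7)
  m <- epiallele_model("patchy", base_methylation = 0.8,
                       seed_cpg_indices = 4L,
                       seed_demethylation_prob = 1, spread_decay = 0)
  emp <- colMeans(draw_epialleles(m, 10L, 10000L))
  expect_equal(emp[4L], 0)
  sd3 <- 3 * sqrt(0.8 * 0.2 / 10000)
  expect_true(all(abs(emp[-4L] - 0.8) <= sd3))
})

test_that("bisulfite conversion follows the chemistry at zero error rates", {
  # methylated CpG C retained, non-CpG C converted
  expect_equal(bisulfite_convert("ACGTC", 1L, 1L), "ACGTT")
  # unmethylated CpG C converted too
  expect_equal(bisulfite_convert("ACGTC", 1L, 0L), "ATGTT")
  # no CpGs: every C becomes T
  expect_equal(bisulfite_convert("CCATC", integer(0), integer(0)), "TTATT")
  expect_error(bisulfite_convert("ACGT", 1L, c(1L, 0L)), "length")
  expect_error(bisulfite_convert("ACGT", 0L, 1L), "does not point at a C")
})

test_that("identical seeds give byte-identical simulated output", {
  set.seed(99)
  ref <- random_locus_reference("L1T", 8L, spacing_bp = 10L)
  cfg <- simulation_config(list(ref),
                           epiallele_model("uniform", 0.7),
                           epiallele_model("uniform", 0.9),
                           n_reads = 25L, n_pairs = 3L, rng_seed = 11L)
  s1 <- simulate_sample(cfg, "tumor", "a")
  s2 <- simulate_sample(cfg, "tumor", "a")
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_reads(s1$reads[[1L]], f1)
  write_reads(s2$reads[[1L]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$table, c2$table)
  # different conditions / samples use distinct streams
  expect_false(identical(simulate_sample(cfg, "normal", "a")$truth, s1$truth))
})

test_that("fastq round trip preserves sequences and ids", {
  set.seed(5)
  ref <- random_locus_reference("L1T", 6L)
  cfg <- simulation_config(list(ref), epiallele_model("uniform", 0.5),
                           epiallele_model("uniform", 0.5),
                           n_reads = 12L, rng_seed = 2L)
  sim <- simulate_sample(cfg, "tumor")
  for (fmt in c("fastq", "fasta")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_reads(sim$reads[[1L]], f, format = fmt)
    back <- read_reads(f)
    expect_identical(back, sim$reads[[1L]])
  }
})

test_that("cohort tables have the paired layout and expected deltas", {
  set.seed(3)
  loci <- lapply(1:3, function(i)
    random_locus_reference(paste0("L", i), 10L))
  null_cfg <- simulation_config(loci, epiallele_model("uniform", 0.8),
                                epiallele_model("uniform", 0.8),
                                n_pairs = 1L, rng_seed = 4L)
  co <- simulate_cohort(null_cfg)
  expect_equal(nrow(co$table), 2L * 3L)  # one tumor + one normal per locus
  expect_setequal(co$table$group, c("tumor", "normal"))

  # null config: per-locus mean delta ~ 0 within sampling error
  null_cfg2 <- simulation_config(loci, epiallele_model("uniform", 0.8),
                                 epiallele_model("uniform", 0.8),
                                 n_pairs = 60L, effective_depth = 100L,
                                 rng_seed = 5L)
  co2 <- simulate_cohort(null_cfg2)
  cc <- change_calls(co2$table)
  se <- sqrt(2 * 0.8 * 0.2 / 100) * 100 / sqrt(60)  # SE of the mean delta
  expect_true(all(abs(tapply(cc$delta, cc$locus_id, mean)) < 4 * se))

  # +15-point shift at one locus is recovered in expectation
  shift_cfg <- simulation_config(
    loci,
    tumor_models = list(epiallele_model("uniform", 0.95),
                        epiallele_model("uniform", 0.8),
                        epiallele_model("uniform", 0.8)),
    normal_models = epiallele_model("uniform", 0.8),
    n_pairs = 60L, rng_seed = 6L)
  co3 <- simulate_cohort(shift_cfg)
  cc3 <- change_calls(co3$table)
  d1 <- mean(cc3$delta[cc3$locus_id == "L1"])
  expect_true(abs(d1 - 15) < 4 * sqrt((0.95 * 0.05 + 0.8 * 0.2) / 100) * 100 / sqrt(60))
  expect_equal(co3$truth$expected_label,
               c("hypermethylated", "unchanged", "unchanged"))
})

test_that("configuration validation enforces the preconditions", {
  ref <- local({set.seed(1); random_locus_reference("L", 5L)})
  um <- epiallele_model("uniform", 0.5)
  expect_error(simulation_config(list(ref), um, um, n_reads = 0), "n_reads")
  expect_error(simulation_config(list(ref), um, um, n_pairs = 0), "n_pairs")
  expect_error(simulation_config(list(ref), um, um,
                                 sequencing_error_rate = 1.5), "rates")
})
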