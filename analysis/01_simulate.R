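#!/usr/bin/env Rscript
# Simulate the synthetic study: an 11-locus LINE-1 promoter panel
# (5 autosomal + 6 X-linked loci sharing a consensus CpG frame), a paired
# tumor-normal pyrosequencing-style cohort of 20 pairs, and deep
# bisulfite amplicon reads for one sequenced tumor-normal pair.
#
# Outputs under results/: per-locus references (FASTA + BED CpG track),
# the locus -> consensus CpG map, the cohort mean-methylation table with
# its generating truth, and per-locus FASTQ files for the sequenced pair.

library(line1meth)

seed <- 1L
n_pairs <- 20L
n_reads <- 200L  # reads per locus for the sequenced pair

dir.create("results/references", recursive = TRUE, showWarnings = FALSE)
dir.create("results/reads", recursive = TRUE, showWarnings = FALSE)

study <- example_study_config(seed = seed, n_pairs = n_pairs,
                              n_reads = n_reads)
cat("Locus panel:", length(study$panel$loci), "loci;",
    sum(vapply(study$panel$loci, `[[`, "", "chromosome_class") == "X_linked"),
    "X-linked\n")
cat("Tumor architecture scenario:\n")
print(study$scenario)

for (ref in study$panel$loci) {
  write_reference(ref,
                  file.path("results/references", paste0(ref$locus_id, ".fa")),
                  file.path("results/references", paste0(ref$locus_id, ".bed")))
}
write_consensus_map(study$panel$consensus_map, "results/consensus_map.tsv")

cohort <- simulate_cohort(study$config)
write.table(cohort$table, "results/cohort_methylation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cohort$truth, "results/cohort_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nCohort:", n_pairs, "tumor-normal pairs x",
    length(study$panel$loci), "loci ->", nrow(cohort$table), "records\n")
cat("True per-locus deltas (percentage points):\n")
print(cohort$truth[, c("locus_id", "true_delta", "expected_label")],
      row.names = FALSE)

# deep sequencing of one pair
truth_cells <- 0L
for (cond in c("tumor", "normal")) {
  sim <- simulate_sample(study$config, cond, paste0("pair001_", cond))
  for (locus in names(sim$reads)) {
    write_reads(sim$reads[[locus]],
                file.path("results/reads",
                          sprintf("%s_%s.fastq", locus, cond)))
    truth <- read_meth_matrix(sim$truth[[locus]], locus,
                              paste0("pair001_", cond))
    write_matrix_tsv(truth,
                     file.path("results/reads",
                               sprintf("%s_%s.truth.tsv", locus, cond)))
    truth_cells <- truth_cells + length(sim$truth[[locus]])
  }
}
cat("\nSequenced pair: ", n_reads, " reads/locus/condition written as FASTQ (",
    truth_cells, " ground-truth CpG states recorded)\n", sep = "")
cat("Done: results/references, results/reads, results/cohort_methylation.tsv\n")
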