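#!/usr/bin/env Rscript
# Per-CpG methylation profiles and sliding-window (b = 4) methylation
# entropy for the sequenced pair, with paired Wilcoxon comparisons of
# tumor vs normal per locus; plus the cohort-level change-call analysis:
# per-pair per-locus hypo/hyper calls at the strict +/-10-point rule and
# the sample-level summary (how many pairs carry at least one changed
# locus; hypo-only / hyper-only / both).
#
# Requires: analysis/01_simulate.R and 02_reads_to_matrices.R outputs.

library(line1meth)

map <- read_consensus_map("results/consensus_map.tsv")
locus_ids <- unique(map$locus_id)

profiles <- list()
entropies <- list()
cmp_rows <- list()
for (locus in locus_ids) {
  mats <- lapply(c("tumor", "normal"), function(cond)
    read_matrix_tsv(file.path("results/matrices",
                              sprintf("%s_%s.tsv", locus, cond))))
  names(mats) <- c("tumor", "normal")
  prof <- lapply(mats, per_cpg_mean)
  ent <- lapply(mats, methylation_entropy)
  for (cond in names(prof)) {
    profiles[[paste(locus, cond)]] <- cbind(locus_id = locus, group = cond,
                                            prof[[cond]])
    entropies[[paste(locus, cond)]] <- cbind(locus_id = locus, group = cond,
                                             ent[[cond]])
  }
  p_prof <- compare_profiles(prof$tumor, prof$normal)
  # short loci (e.g. the 7-CpG locus) have < 5 windows: no entropy test
  p_ent <- tryCatch(compare_entropy(ent$tumor, ent$normal),
                    error = function(e) list(p_value = NA_real_))
  cmp_rows[[locus]] <- data.frame(
    locus_id = locus,
    mean_tumor = 100 * mean(prof$tumor$mean, na.rm = TRUE),
    mean_normal = 100 * mean(prof$normal$mean, na.rm = TRUE),
    mean_entropy_tumor = mean(ent$tumor$entropy, na.rm = TRUE),
    mean_entropy_normal = mean(ent$normal$entropy, na.rm = TRUE),
    p_profile = p_prof$p_value,
    p_entropy = p_ent$p_value)
}
write.table(do.call(rbind, profiles), "results/cpg_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, entropies), "results/entropy_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cmp <- do.call(rbind, cmp_rows)
write.table(cmp, "results/locus_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Sequenced pair, per-locus tumor vs normal:\n")
print(transform(cmp, delta = round(mean_tumor - mean_normal, 1),
                p_profile = signif(p_profile, 3),
                p_entropy = signif(p_entropy, 3)),
      row.names = FALSE, digits = 3)

# cohort-level change calls
cohort <- read.delim("results/cohort_methylation.tsv")
calls <- change_calls(cohort, threshold = 10)
write.table(calls, "results/change_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
summary <- summarize_cohort(calls)
write.table(summary, "results/sample_summaries.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
n_changed <- sum(summary$category != "none")
cat(sprintf("\nCohort: %d / %d pairs carry a methylation change at >= 1 locus (%.0f%%)\n",
            n_changed, nrow(summary), 100 * n_changed / nrow(summary)))
print(table(summary$category))

# inter-locus Spearman correlations, tumor and normal separately
for (grp in c("tumor", "normal")) {
  res <- inter_locus_correlation(cohort, grp)
  write.table(round(res$rho, 3),
              sprintf("results/inter_locus_rho_%s.tsv", grp),
              sep = "\t", quote = FALSE)
  cat(sprintf("%s: %d / %d locus pairs Bonferroni-significant\n",
              grp, sum(res$significant, na.rm = TRUE) / 2L,
              res$n_pairs_tested))
}
cat("Done: results/cpg_profiles.tsv, entropy_profiles.tsv, locus_comparisons.tsv, change_calls.tsv, sample_summaries.tsv\n")
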