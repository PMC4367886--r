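#' Per-CpG mean methylation profile
#'
#' Column-wise fraction of methylated calls among non-missing calls, with
#' coverage. Means at CpGs covered by fewer than `min_coverage` reads are
#' flagged missing.
#'
#' @param x A [read_meth_matrix()].
#' @param min_coverage Minimum non-missing calls per CpG (default 10).
#' @return A `meth_profile`: data.frame with columns `cpg_index`
#'   (1-based), `mean` (fraction in \[0,1\], NA below coverage) and
#'   `coverage`; attributes `locus_id`, `sample_id`.
#' @export
per_cpg_mean <- function(x, min_coverage = 10L) {
  stopifnot(inherits(x, "read_meth_matrix"))
  cov <- colSums(!is.na(x$calls))
  m <- colMeans(x$calls, na.rm = TRUE)
  m[cov == 0L] <- NA_real_
  m[cov < min_coverage] <- NA_real_
  out <- data.frame(cpg_index = seq_len(ncol(x$calls)),
                    mean = as.numeric(m),
                    coverage = as.integer(cov))
  attr(out, "locus_id") <- x$locus_id
  attr(out, "sample_id") <- x$sample_id
  class(out) <- c("meth_profile", "data.frame")
  out
}

#' Sliding-window methylation entropy
#'
#' Normalized Shannon entropy of epiallele frequencies in sliding windows
#' of `b` consecutive CpGs (stride 1):
#' \deqn{ME = \frac{1}{b} \sum_i \frac{n_i}{N} \log_2 \frac{N}{n_i}}
#' where the sum runs over the distinct length-`b` methylation patterns
#' (epialleles) observed in the window, \eqn{n_i} is the count of reads
#' carrying pattern i, and N the number of reads with complete calls in
#' the window. ME is 0 when all molecules share one pattern and 1 when
#' all \eqn{2^b} patterns are equally frequent. Reads with any missing
#' call inside a window are excluded from that window only; windows with
#' fewer than `min_reads` complete reads get a missing entropy.
#'
#' @param x A [read_meth_matrix()].
#' @param b Window size in CpGs (default 4).
#' @param min_reads Minimum complete reads per window (default 10).
#' @return An `entropy_profile`: data.frame with columns `window_start`
#'   (1-based CpG index of the first window column), `b`, `entropy`
#'   (in \[0,1\], NA below `min_reads`) and `n_reads`; attributes
#'   `locus_id`, `sample_id`.
#' @export
methylation_entropy <- function(x, b = 4L, min_reads = 10L) {
  stopifnot(inherits(x, "read_meth_matrix"))
  b <- as.integer(b)
  n_cpg <- ncol(x$calls)
  if (b < 1L) stop("window size b must be >= 1")
  if (n_cpg < b) {
    stop("locus '", x$locus_id, "' has ", n_cpg,
         " CpGs, fewer than the window size b = ", b)
  }
  starts <- seq_len(n_cpg - b + 1L)
  ent <- rep(NA_real_, length(starts))
  nn <- integer(length(starts))
  pow <- 2L^(seq_len(b) - 1L)
  for (w in starts) {
    sub <- x$calls[, w:(w + b - 1L), drop = FALSE]
    complete <- stats::complete.cases(sub)
    nn[w] <- sum(complete)
    if (nn[w] < min_reads) next
    codes <- as.vector(sub[complete, , drop = FALSE] %*% pow)
    n_i <- tabulate(codes + 1L, nbins = 2L^b)
    n_i <- n_i[n_i > 0L]
    N <- nn[w]
    ent[w] <- sum((n_i / N) * log2(N / n_i)) / b
  }
  out <- data.frame(window_start = starts, b = b,
                    entropy = ent, n_reads = nn)
  attr(out, "locus_id") <- x$locus_id
  attr(out, "sample_id") <- x$sample_id
  class(out) <- c("entropy_profile", "data.frame")
  out
}

# Paired Wilcoxon signed-rank with the conventions used throughout:
# zero differences dropped, exact null for n <= 25 (ties permitting),
# normal approximation with continuity correction above; all differences
# zero gives p = 1.
paired_wilcoxon <- function(x, y) {
  d <- x - y
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, n_used = 0L))
  }
  n_nonzero <- sum(d != 0)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = n_nonzero <= 25,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = n_nonzero)
}

#' Compare paired methylation profiles (Wilcoxon over CpG sites)
#'
#' Two-sided Wilcoxon signed-rank test on the per-CpG means of a tumor
#' and a normal profile of the same locus, paired by CpG site.
#'
#' @param tumor,normal `meth_profile` objects from [per_cpg_mean()].
#' @param min_sites Minimum number of CpGs with a defined mean in both
#'   profiles (default 5).
#' @return A list: `p_value`, `statistic` (V), `n_sites` (paired CpGs
#'   used, zero differences included in the count of shared sites).
#' @export
compare_profiles <- function(tumor, normal, min_sites = 5L) {
  stopifnot(inherits(tumor, "meth_profile"), inherits(normal, "meth_profile"))
  shared <- merge(tumor, normal, by = "cpg_index",
                  suffixes = c("_t", "_n"))
  shared <- shared[!is.na(shared$mean_t) & !is.na(shared$mean_n), ]
  if (nrow(shared) < min_sites) {
    stop("only ", nrow(shared), " CpGs with defined means in both profiles",
         " (need >= ", min_sites, ")")
  }
  wt <- paired_wilcoxon(shared$mean_t, shared$mean_n)
  list(p_value = wt$p_value, statistic = wt$statistic,
       n_sites = nrow(shared))
}

#' Compare paired entropy profiles (Wilcoxon over windows)
#'
#' As [compare_profiles()], paired over sliding windows of the two
#' entropy profiles (matched by `window_start`).
#'
#' @param tumor,normal `entropy_profile` objects from
#'   [methylation_entropy()].
#' @param min_windows Minimum shared windows with defined entropy
#'   (default 5).
#' @return A list: `p_value`, `statistic`, `n_windows`.
#' @export
compare_entropy <- function(tumor, normal, min_windows = 5L) {
  stopifnot(inherits(tumor, "entropy_profile"),
            inherits(normal, "entropy_profile"))
  shared <- merge(tumor, normal, by = "window_start",
                  suffixes = c("_t", "_n"))
  shared <- shared[!is.na(shared$entropy_t) & !is.na(shared$entropy_n), ]
  if (nrow(shared) < min_windows) {
    stop("only ", nrow(shared), " shared windows with defined entropy",
         " (need >= ", min_windows, ")")
  }
  wt <- paired_wilcoxon(shared$entropy_t, shared$entropy_n)
  list(p_value = wt$p_value, statistic = wt$statistic,
       n_windows = nrow(shared))
}

#' Call a tumor-normal methylation change at one locus
#'
#' Delta = tumor - normal in percentage points (inputs on the 0-100
#' scale). A locus is called hypomethylated when the tumor mean is more
#' than `threshold` points below the normal mean, hypermethylated when
#' more than `threshold` points above; deltas of exactly +/- threshold
#' are unchanged (strict inequality).
#'
#' @param tumor_mean,normal_mean Mean methylation values (percent,
#'   0-100); vectorized.
#' @param threshold Change threshold in percentage points (default 10).
#' @return A data.frame with columns `delta` and `label` (factor:
#'   hypomethylated / unchanged / hypermethylated). Rows with a missing
#'   mean get an NA label.
#' @export
call_change <- function(tumor_mean, normal_mean, threshold = 10) {
  stopifnot(length(tumor_mean) == length(normal_mean), threshold >= 0)
  delta <- tumor_mean - normal_mean
  label <- rep(NA_character_, length(delta))
  ok <- !is.na(delta)
  label[ok & delta < -threshold] <- "hypomethylated"
  label[ok & delta > threshold] <- "hypermethylated"
  label[ok & abs(delta) <= threshold] <- "unchanged"
  data.frame(delta = delta,
             label = factor(label, levels = c("hypomethylated",
                                              "unchanged",
                                              "hypermethylated")))
}

#' Change calls for every pair and locus of a cohort table
#'
#' @param table Long cohort table with columns `pair_id`, `group`
#'   ("tumor"/"normal"), `locus_id`, `mean_methylation` (percent), as
#'   produced by [simulate_cohort()].
#' @param threshold Change threshold in percentage points (default 10).
#' @return Data.frame with one row per (pair, locus): `pair_id`,
#'   `locus_id`, `tumor_mean`, `normal_mean`, `delta`, `label`.
#' @export
change_calls <- function(table, threshold = 10) {
  need <- c("pair_id", "group", "locus_id", "mean_methylation")
  stopifnot(all(need %in% names(table)))
  t_tab <- table[table$group == "tumor", ]
  n_tab <- table[table$group == "normal", ]
  m <- merge(t_tab[, c("pair_id", "locus_id", "mean_methylation")],
             n_tab[, c("pair_id", "locus_id", "mean_methylation")],
             by = c("pair_id", "locus_id"), suffixes = c("_t", "_n"))
  cc <- call_change(m$mean_methylation_t, m$mean_methylation_n, threshold)
  out <- data.frame(pair_id = m$pair_id, locus_id = m$locus_id,
                    tumor_mean = m$mean_methylation_t,
                    normal_mean = m$mean_methylation_n,
                    delta = cc$delta, label = cc$label,
                    stringsAsFactors = FALSE)
  out[order(out$pair_id, out$locus_id), ]
}

#' Summarize change calls for one sample pair
#'
#' Counts hypo- and hypermethylated loci and assigns the sample to one of
#' four categories: `none`, `hypo_only`, `hyper_only`, `both`.
#'
#' @param calls Data.frame of change calls for one pair (needs a `label`
#'   column; NA labels are ignored).
#' @return A one-row data.frame: `n_hypo_loci`, `n_hyper_loci`,
#'   `category`.
#' @export
summarize_sample <- function(calls) {
  stopifnot("label" %in% names(calls), nrow(calls) >= 1L)
  lab <- as.character(calls$label)
  n_hypo <- sum(lab == "hypomethylated", na.rm = TRUE)
  n_hyper <- sum(lab == "hypermethylated", na.rm = TRUE)
  category <- if (n_hypo > 0L && n_hyper > 0L) "both"
  else if (n_hypo > 0L) "hypo_only"
  else if (n_hyper > 0L) "hyper_only"
  else "none"
  data.frame(n_hypo_loci = n_hypo, n_hyper_loci = n_hyper,
             category = factor(category,
                               levels = c("none", "hypo_only",
                                          "hyper_only", "both")))
}

#' Summarize change calls over a whole cohort
#'
#' @param calls Change calls from [change_calls()] (multiple pairs).
#' @return Data.frame with one row per pair: `pair_id`, `n_hypo_loci`,
#'   `n_hyper_loci`, `category`.
#' @export
summarize_cohort <- function(calls) {
  stopifnot(all(c("pair_id", "label") %in% names(calls)))
  pieces <- lapply(split(calls, calls$pair_id), summarize_sample)
  out <- do.call(rbind, pieces)
  out <- data.frame(pair_id = names(pieces), out,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Inter-locus Spearman correlation within one sample group
#'
#' Pairwise Spearman correlation of per-sample mean methylation between
#' loci, computed separately for tumor or normal samples, with Bonferroni
#' adjustment over the number of tested locus pairs.
#'
#' @param table Long cohort table (see [change_calls()]).
#' @param group `"tumor"` or `"normal"`.
#' @param alpha Familywise significance level (default 0.05, Bonferroni
#'   over the tested pairs).
#' @return A list: `rho` (symmetric matrix, diagonal 1; NA where a locus
#'   is constant), `p` (matrix of Spearman p-values), `significant`
#'   (logical matrix, Bonferroni-adjusted), `n_samples`, `n_pairs_tested`.
#' @export
inter_locus_correlation <- function(table, group = c("tumor", "normal"),
                                    alpha = 0.05) {
  group <- match.arg(group)
  sub <- table[table$group == group, ]
  wide <- stats::xtabs(mean_methylation ~ sample_id + locus_id, data = sub)
  wide <- as.data.frame.matrix(wide)
  n <- nrow(wide)
  if (n < 5L) stop("need >= 5 samples per group, have ", n)
  loci <- colnames(wide)
  k <- length(loci)
  rho <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  p <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  diag(rho) <- 1
  n_tested <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- wide[[i]]; xj <- wide[[j]]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next  # constant marker
      ct <- suppressWarnings(
        stats::cor.test(xi, xj, method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      n_tested <- n_tested + 1L
    }
  }
  significant <- p < (alpha / max(n_tested, 1L))
  list(rho = rho, p = p, significant = significant,
       n_samples = n, n_pairs_tested = n_tested)
}
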