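#' Default thresholds for read-level pattern classification
#'
#' All constants of the [classify_pattern()] decision rule, exposed so
#' each can be tuned and reported with the call evidence.
#'
#' @param hi Per-read mean methylation at or above which a read counts as
#'   "high" (default 0.8).
#' @param lo Per-read mean at or below which a read counts as "low"
#'   (default 0.2).
#' @param uniform_fraction Fraction of high (low) reads required for a
#'   uniformly methylated (unmethylated) call (default 0.9).
#' @param allelic_min_fraction Minimum fraction of reads in each of the
#'   high and low groups for an allelic call (default 0.2).
#' @param allelic_total_fraction Minimum combined high+low fraction for
#'   an allelic call (default 0.8).
#' @param entropy_range Minimum entropy range (max - min over windows)
#'   for a patchy call (default 0.3).
#' @param min_reads Minimum reads for any call (default 10).
#' @param min_cpgs Minimum CpGs for any call (default 4).
#' @return A named list of thresholds.
#' @export
pattern_config <- function(hi = 0.8, lo = 0.2,
                           uniform_fraction = 0.9,
                           allelic_min_fraction = 0.2,
                           allelic_total_fraction = 0.8,
                           entropy_range = 0.3,
                           min_reads = 10L, min_cpgs = 4L) {
  list(hi = hi, lo = lo,
       uniform_fraction = uniform_fraction,
       allelic_min_fraction = allelic_min_fraction,
       allelic_total_fraction = allelic_total_fraction,
       entropy_range = entropy_range,
       min_reads = as.integer(min_reads), min_cpgs = as.integer(min_cpgs))
}

#' Classify the read-level methylation architecture of one locus/sample
#'
#' Assigns one of the architectures discernible in deep bisulfite
#' sequencing of LINE-1 promoters: uniformly methylated, uniformly
#' unmethylated, allelic (reads fall into a nearly fully methylated and
#' a nearly fully unmethylated group), or patchy (alternating methylated
#' and demethylated stretches, visible as fluctuating window entropy).
#'
#' Decision rule (all constants from [pattern_config()]): compute each
#' read's mean methylation over its non-missing calls; let `f_hi` be the
#' fraction of reads with mean >= `hi` and `f_lo` the fraction with mean
#' <= `lo`. Then, in order: uniform_methylated if
#' `f_hi >= uniform_fraction`; uniform_unmethylated if
#' `f_lo >= uniform_fraction`; allelic if both `f_hi` and `f_lo` are at
#' least `allelic_min_fraction` and their sum is at least
#' `allelic_total_fraction`; patchy if the entropy range across windows
#' (max - min, over windows with defined entropy) is at least
#' `entropy_range`; otherwise indeterminate. Indeterminate is a
#' first-class outcome, not a forced nearest class.
#'
#' @param x A [read_meth_matrix()].
#' @param entropy Optional `entropy_profile` for `x` (computed via
#'   [methylation_entropy()] with defaults when omitted).
#' @param config Thresholds from [pattern_config()].
#' @return A `pattern_call`: one-row data.frame with `locus_id`,
#'   `sample_id`, `label` (factor over the five outcomes), and the
#'   evidence columns `f_hi`, `f_lo`, `mean_entropy`, `entropy_range`,
#'   `n_reads`, plus a `reason` string for indeterminate calls.
#' @export
classify_pattern <- function(x, entropy = NULL, config = pattern_config()) {
  stopifnot(inherits(x, "read_meth_matrix"))
  labels <- c("uniform_methylated", "uniform_unmethylated",
              "allelic", "patchy", "indeterminate")
  n_reads <- nrow(x$calls)
  n_cpg <- ncol(x$calls)
  make_call <- function(label, f_hi = NA_real_, f_lo = NA_real_,
                        mean_ent = NA_real_, ent_range = NA_real_,
                        reason = "") {
    data.frame(locus_id = x$locus_id, sample_id = x$sample_id,
               label = factor(label, levels = labels),
               f_hi = f_hi, f_lo = f_lo,
               mean_entropy = mean_ent, entropy_range = ent_range,
               n_reads = n_reads, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (n_reads < config$min_reads) {
    return(make_call("indeterminate",
                     reason = sprintf("only %d reads (need >= %d)",
                                      n_reads, config$min_reads)))
  }
  if (n_cpg < config$min_cpgs) {
    return(make_call("indeterminate",
                     reason = sprintf("only %d CpGs (need >= %d)",
                                      n_cpg, config$min_cpgs)))
  }
  if (is.null(entropy)) entropy <- methylation_entropy(x)
  stopifnot(inherits(entropy, "entropy_profile"))
  read_means <- rowMeans(x$calls, na.rm = TRUE)
  read_means <- read_means[!is.nan(read_means)]
  f_hi <- mean(read_means >= config$hi)
  f_lo <- mean(read_means <= config$lo)
  ent <- entropy$entropy[!is.na(entropy$entropy)]
  mean_ent <- if (length(ent)) mean(ent) else NA_real_
  ent_range <- if (length(ent)) max(ent) - min(ent) else NA_real_
  label <-
    if (f_hi >= config$uniform_fraction) "uniform_methylated"
    else if (f_lo >= config$uniform_fraction) "uniform_unmethylated"
    else if (f_hi >= config$allelic_min_fraction &&
             f_lo >= config$allelic_min_fraction &&
             f_hi + f_lo >= config$allelic_total_fraction) "allelic"
    else if (!is.na(ent_range) && ent_range >= config$entropy_range) "patchy"
    else "indeterminate"
  make_call(label, f_hi, f_lo, mean_ent, ent_range,
            reason = if (label == "indeterminate") "no rule fired" else "")
}

#' Confusion matrix and per-class recall for pattern calls
#'
#' Validation harness for synthetic runs where the generating
#' architecture of every matrix is known.
#'
#' @param calls Data.frame of `pattern_call` rows (rbind of
#'   [classify_pattern()] outputs), in the same order as `truth`.
#' @param truth Character vector of true class labels, from
#'   `c("uniform_methylated", "uniform_unmethylated", "allelic",
#'   "patchy")`.
#' @return A list: `confusion` (5 predicted x 4 true contingency matrix)
#'   and `recall` (named vector, fraction of each true class predicted
#'   correctly).
#' @export
confusion_report <- function(calls, truth) {
  if (NROW(calls) == 0L) stop("no pattern calls supplied")
  if (NROW(calls) != length(truth)) {
    stop("calls and truth have different lengths")
  }
  pred_levels <- c("uniform_methylated", "uniform_unmethylated",
                   "allelic", "patchy", "indeterminate")
  true_levels <- pred_levels[1:4]
  if (!all(truth %in% true_levels)) {
    stop("truth labels must be one of: ", paste(true_levels, collapse = ", "))
  }
  pred <- factor(as.character(calls$label), levels = pred_levels)
  tru <- factor(truth, levels = true_levels)
  confusion <- table(predicted = pred, true = tru)
  recall <- vapply(true_levels, function(cl) {
    n <- sum(tru == cl)
    if (n == 0L) NA_real_ else sum(pred == cl & tru == cl) / n
  }, 0)
  list(confusion = confusion, recall = recall)
}
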