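#' Epiallele architecture model
#'
#' Generative model for the methylation state of single DNA molecules at
#' one locus. Three architectures are supported, mirroring the read-level
#' patterns seen in deep bisulfite sequencing of LINE-1 promoters:
#' \describe{
#'   \item{uniform}{every CpG methylated i.i.d. Bernoulli(`base_methylation`);
#'     with `base_methylation` near 0 or 1 this yields uniformly
#'     unmethylated / methylated molecules.}
#'   \item{allelic}{a two-class mixture: with probability `allelic_fraction`
#'     the molecule comes from a high-methylation class
#'     (Bernoulli(`base_methylation`) per CpG, `base_methylation` high),
#'     otherwise from a mirrored low class (Bernoulli(1 - `base_methylation`)).}
#'   \item{patchy}{molecules start uniformly methylated at
#'     `base_methylation`; each seed CpG is then demethylated with
#'     probability `seed_demethylation_prob`, and its neighbours with
#'     probability `seed_demethylation_prob * spread_decay^distance`,
#'     distance counted in CpG steps. Demethylation spreads symmetrically
#'     in CpG-index space.}
#' }
#'
#' @param kind `"uniform"`, `"allelic"` or `"patchy"`.
#' @param base_methylation Per-CpG methylation probability in \[0,1\].
#' @param allelic_fraction Mixture weight of the methylated class
#'   (allelic kind only), in \[0,1\].
#' @param seed_cpg_indices 1-based CpG indices of demethylation seeds
#'   (patchy kind only).
#' @param seed_demethylation_prob Probability a seed CpG is demethylated
#'   on a given molecule, in \[0,1\].
#' @param spread_decay Per-CpG-step decay of the demethylation
#'   probability away from a seed, in \[0,1\].
#' @return An object of class `epiallele_model`.
#' @export
epiallele_model <- function(kind = c("uniform", "allelic", "patchy"),
                            base_methylation = 0.8,
                            allelic_fraction = 0.5,
                            seed_cpg_indices = integer(0),
                            seed_demethylation_prob = 0.9,
                            spread_decay = 0.5) {
  kind <- match.arg(kind)
  probs <- c(base_methylation = base_methylation,
             allelic_fraction = allelic_fraction,
             seed_demethylation_prob = seed_demethylation_prob,
             spread_decay = spread_decay)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  seed_cpg_indices <- as.integer(seed_cpg_indices)
  if (kind != "patchy" && length(seed_cpg_indices) > 0L) {
    stop("seed_cpg_indices must be empty unless kind = 'patchy'")
  }
  if (kind == "patchy" && length(seed_cpg_indices) == 0L) {
    stop("patchy model requires at least one seed CpG index")
  }
  if (any(seed_cpg_indices < 1L)) {
    stop("seed_cpg_indices must be positive (1-based CpG indices)")
  }
  structure(
    list(kind = kind,
         base_methylation = base_methylation,
         allelic_fraction = allelic_fraction,
         seed_cpg_indices = seed_cpg_indices,
         seed_demethylation_prob = seed_demethylation_prob,
         spread_decay = spread_decay),
    class = "epiallele_model"
  )
}

#' Draw epialleles (per-molecule methylation state vectors)
#'
#' @param model An [epiallele_model()].
#' @param n_cpg Number of CpGs at the locus (>= 1; patchy seeds must be
#'   valid indices into `1:n_cpg`).
#' @param n Number of molecules to draw.
#' @return Integer matrix `n x n_cpg` of methylation states
#'   (1 = methylated, 0 = unmethylated). Uses the current RNG state.
#' @export
draw_epialleles <- function(model, n_cpg, n = 1L) {
  stopifnot(inherits(model, "epiallele_model"), n_cpg >= 1L, n >= 1L)
  n_cpg <- as.integer(n_cpg)
  n <- as.integer(n)
  if (model$kind == "patchy" && any(model$seed_cpg_indices > n_cpg)) {
    stop("patchy seed index exceeds the locus CpG count (", n_cpg, ")")
  }
  states <- switch(
    model$kind,
    uniform = matrix(stats::rbinom(n * n_cpg, 1L, model$base_methylation),
                     nrow = n, ncol = n_cpg),
    allelic = {
      hi <- stats::rbinom(n, 1L, model$allelic_fraction) == 1L
      p <- ifelse(hi, model$base_methylation, 1 - model$base_methylation)
      matrix(stats::rbinom(n * n_cpg, 1L, rep(p, times = n_cpg)),
             nrow = n, ncol = n_cpg)
    },
    patchy = {
      m <- matrix(stats::rbinom(n * n_cpg, 1L, model$base_methylation),
                  nrow = n, ncol = n_cpg)
      # per-CpG demethylation probability contributed by each seed;
      # a CpG hit by any seed's (independent) demethylation event goes U
      for (s in model$seed_cpg_indices) {
        d <- abs(seq_len(n_cpg) - s)
        p_dem <- model$seed_demethylation_prob * model$spread_decay^d
        hit <- matrix(stats::rbinom(n * n_cpg, 1L, rep(p_dem, each = n)),
                      nrow = n, ncol = n_cpg)
        m[hit == 1L] <- 0L
      }
      m
    }
  )
  storage.mode(states) <- "integer"
  states
}

#' Analytic per-CpG methylation probability of an epiallele model
#'
#' The expected methylation fraction at each CpG under the generative
#' law of [draw_epialleles()]; used to check simulated output against
#' its own model and to define ground-truth deltas.
#'
#' @inheritParams draw_epialleles
#' @return Numeric vector of length `n_cpg` in \[0,1\].
#' @export
epiallele_mean <- function(model, n_cpg) {
  stopifnot(inherits(model, "epiallele_model"), n_cpg >= 1L)
  n_cpg <- as.integer(n_cpg)
  switch(
    model$kind,
    uniform = rep(model$base_methylation, n_cpg),
    allelic = {
      p <- model$allelic_fraction * model$base_methylation +
        (1 - model$allelic_fraction) * (1 - model$base_methylation)
      rep(p, n_cpg)
    },
    patchy = {
      keep <- rep(1, n_cpg)  # P(CpG escapes every seed's demethylation)
      for (s in model$seed_cpg_indices) {
        d <- abs(seq_len(n_cpg) - s)
        keep <- keep * (1 - model$seed_demethylation_prob * model$spread_decay^d)
      }
      model$base_methylation * keep
    }
  )
}

#' Simulation configuration for a paired tumor-normal study
#'
#' Describes the synthetic study: the loci, the tumor and normal epiallele
#' model at each locus, sequencing depth and error rates, and the cohort
#' size. Identical configurations (including `rng_seed`) produce
#' byte-identical outputs.
#'
#' @param loci List of [locus_reference()] objects.
#' @param tumor_models,normal_models Lists of [epiallele_model()]s, one per
#'   locus (recycled if length 1).
#' @param n_reads Reads simulated per locus per sample (default 500).
#' @param conversion_failure_rate Probability an unmethylated C escapes
#'   bisulfite conversion (read as C).
#' @param inappropriate_conversion_rate Probability a methylated CpG C is
#'   converted anyway (read as T).
#' @param sequencing_error_rate Per-base substitution error rate.
#' @param n_pairs Number of tumor-normal sample pairs (default 20, the
#'   approximate per-tissue cohort size of the emulated study design).
#' @param effective_depth Effective read depth behind each cohort-level
#'   mean methylation value (binomial denominator; default 100).
#' @param rng_seed Integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(loci, tumor_models, normal_models,
                              n_reads = 500L,
                              conversion_failure_rate = 0.005,
                              inappropriate_conversion_rate = 0.005,
                              sequencing_error_rate = 0.002,
                              n_pairs = 20L,
                              effective_depth = 100L,
                              rng_seed = 1L) {
  stopifnot(is.list(loci), length(loci) >= 1L)
  lapply(loci, function(x) stopifnot(inherits(x, "locus_reference")))
  recycle <- function(models) {
    if (inherits(models, "epiallele_model")) models <- list(models)
    if (length(models) == 1L) models <- rep(models, length(loci))
    stopifnot(length(models) == length(loci))
    lapply(models, function(m) stopifnot(inherits(m, "epiallele_model")))
    models
  }
  tumor_models <- recycle(tumor_models)
  normal_models <- recycle(normal_models)
  rates <- c(conversion_failure_rate, inappropriate_conversion_rate,
             sequencing_error_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0,1]")
  if (n_reads < 1L) stop("n_reads must be >= 1")
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  if (effective_depth < 1L) stop("effective_depth must be >= 1")
  structure(
    list(loci = loci,
         tumor_models = tumor_models,
         normal_models = normal_models,
         n_reads = as.integer(n_reads),
         conversion_failure_rate = conversion_failure_rate,
         inappropriate_conversion_rate = inappropriate_conversion_rate,
         sequencing_error_rate = sequencing_error_rate,
         n_pairs = as.integer(n_pairs),
         effective_depth = as.integer(effective_depth),
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config"
  )
}

#' Bisulfite-convert a reference segment given molecule methylation states
#'
#' Applies the top-strand bisulfite conversion chemistry in silico:
#' unmethylated cytosines deaminate and read as T, methylated CpG
#' cytosines resist conversion and read as C. Conversion failures retain
#' unmethylated Cs, inappropriate conversion turns methylated CpG Cs into
#' T, and sequencing errors substitute random bases. Only the top (sense)
#' strand is modelled; the molecule length is preserved (no indels).
#'
#' @param sequence Reference DNA string.
#' @param cpg_positions 0-based offsets of CpG cytosines in `sequence`.
#' @param states Integer vector (1 = methylated, 0 = unmethylated), one
#'   per CpG, aligned to `cpg_positions`.
#' @param conversion_failure_rate,inappropriate_conversion_rate,sequencing_error_rate
#'   Rates as in [simulation_config()] (defaults 0: deterministic
#'   conversion).
#' @return The simulated read (character scalar). Uses the current RNG
#'   state when any rate is positive.
#' @export
bisulfite_convert <- function(sequence, cpg_positions, states,
                              conversion_failure_rate = 0,
                              inappropriate_conversion_rate = 0,
                              sequencing_error_rate = 0) {
  sequence <- toupper(as.character(sequence))
  cpg_positions <- as.integer(cpg_positions)
  if (length(states) != length(cpg_positions)) {
    stop("states length (", length(states),
         ") does not match the number of CpG positions (",
         length(cpg_positions), ")")
  }
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  is_c <- bases == "C"
  cpg_c <- rep(FALSE, length(bases))
  cpg_c[cpg_positions + 1L] <- TRUE
  if (any(bases[cpg_positions + 1L] != "C")) {
    stop("a cpg_position does not point at a C in the sequence")
  }
  # non-CpG cytosines: convert to T unless the conversion fails
  non_cpg_c <- which(is_c & !cpg_c)
  if (length(non_cpg_c)) {
    fail <- stats::runif(length(non_cpg_c)) < conversion_failure_rate
    bases[non_cpg_c[!fail]] <- "T"
  }
  # CpG cytosines: follow the molecule's methylation state
  idx <- cpg_positions + 1L
  meth <- states == 1L
  if (any(meth)) {
    flip <- stats::runif(sum(meth)) < inappropriate_conversion_rate
    bases[idx[meth][flip]] <- "T"        # inappropriate conversion
  }
  if (any(!meth)) {
    fail <- stats::runif(sum(!meth)) < conversion_failure_rate
    bases[idx[!meth][!fail]] <- "T"      # normal conversion
    # retained (failed) positions keep their C
  }
  # per-base sequencing substitution errors
  if (sequencing_error_rate > 0) {
    err <- which(stats::runif(length(bases)) < sequencing_error_rate)
    if (length(err)) {
      alphabet <- c("A", "C", "G", "T")
      for (i in err) {
        bases[i] <- sample(setdiff(alphabet, bases[i]), 1L)
      }
    }
  }
  paste(bases, collapse = "")
}

#' Simulate one sample: bisulfite reads per locus plus ground truth
#'
#' Draws `n_reads` molecules per locus from the condition's epiallele
#' model, bisulfite-converts each against the locus reference, and
#' records the true per-read methylation states.
#'
#' @param config A [simulation_config()].
#' @param condition `"tumor"` or `"normal"`.
#' @param sample_id Sample identifier used in read names.
#' @return A list with class `simulated_sample`:
#'   \item{reads}{named list per locus of character vectors of read
#'     sequences (names are read ids).}
#'   \item{truth}{named list per locus of integer state matrices
#'     (`n_reads x n_cpg`), the ground-truth methylation states.}
#'   \item{true_means}{named list per locus of the analytic per-CpG
#'     methylation probabilities of the generating model.}
#' @export
simulate_sample <- function(config, condition = c("tumor", "normal"),
                            sample_id = condition) {
  stopifnot(inherits(config, "simulation_config"))
  condition <- match.arg(condition)
  set.seed(make_sub_seed(config$rng_seed, condition, sample_id))
  models <- if (condition == "tumor") config$tumor_models else config$normal_models
  reads <- list()
  truth <- list()
  true_means <- list()
  for (i in seq_along(config$loci)) {
    ref <- config$loci[[i]]
    n_cpg <- length(ref$cpg_positions)
    states <- draw_epialleles(models[[i]], n_cpg, config$n_reads)
    seqs <- character(config$n_reads)
    for (r in seq_len(config$n_reads)) {
      seqs[r] <- bisulfite_convert(
        ref$sequence, ref$cpg_positions, states[r, ],
        config$conversion_failure_rate,
        config$inappropriate_conversion_rate,
        config$sequencing_error_rate
      )
    }
    ids <- sprintf("%s|%s|read%04d", sample_id, ref$locus_id,
                   seq_len(config$n_reads))
    names(seqs) <- ids
    rownames(states) <- ids
    reads[[ref$locus_id]] <- seqs
    truth[[ref$locus_id]] <- states
    true_means[[ref$locus_id]] <- epiallele_mean(models[[i]], n_cpg)
  }
  structure(list(reads = reads, truth = truth, true_means = true_means,
                 sample_id = sample_id, condition = condition),
            class = "simulated_sample")
}

#' Simulate a paired tumor-normal cohort of mean-methylation values
#'
#' Emulates pyrosequencing-style per-sample per-locus mean methylation:
#' for each pair and locus, the tumor and normal means are drawn as
#' binomial proportions at `effective_depth` around the respective
#' model's analytic mean methylation (averaged over CpGs).
#'
#' @param config A [simulation_config()].
#' @return A list with class `simulated_cohort`:
#'   \item{table}{data.frame with columns `sample_id`, `pair_id`, `group`
#'     ("tumor"/"normal"), `locus_id`, `mean_methylation` (percent,
#'     0-100).}
#'   \item{truth}{data.frame per pair and locus with the model means
#'     (percent), true delta (tumor - normal, percentage points) and the
#'     expected change label at the +/-10-point rule.}
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(make_sub_seed(config$rng_seed, "cohort"))
  n_loci <- length(config$loci)
  locus_ids <- vapply(config$loci, `[[`, "", "locus_id")
  mu_t <- vapply(seq_len(n_loci), function(i)
    mean(epiallele_mean(config$tumor_models[[i]],
                        length(config$loci[[i]]$cpg_positions))), 0)
  mu_n <- vapply(seq_len(n_loci), function(i)
    mean(epiallele_mean(config$normal_models[[i]],
                        length(config$loci[[i]]$cpg_positions))), 0)
  rows <- vector("list", config$n_pairs)
  for (p in seq_len(config$n_pairs)) {
    pid <- sprintf("pair%03d", p)
    t_vals <- stats::rbinom(n_loci, config$effective_depth, mu_t) /
      config$effective_depth * 100
    n_vals <- stats::rbinom(n_loci, config$effective_depth, mu_n) /
      config$effective_depth * 100
    rows[[p]] <- data.frame(
      sample_id = c(paste0(pid, "_T"), paste0(pid, "_N"))[
        rep(1:2, each = n_loci)],
      pair_id = pid,
      group = rep(c("tumor", "normal"), each = n_loci),
      locus_id = rep(locus_ids, 2L),
      mean_methylation = c(t_vals, n_vals),
      stringsAsFactors = FALSE
    )
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  true_delta <- (mu_t - mu_n) * 100
  truth <- data.frame(
    locus_id = locus_ids,
    true_tumor_mean = mu_t * 100,
    true_normal_mean = mu_n * 100,
    true_delta = true_delta,
    expected_label = ifelse(true_delta < -10, "hypomethylated",
                            ifelse(true_delta > 10, "hypermethylated",
                                   "unchanged")),
    stringsAsFactors = FALSE
  )
  structure(list(table = table, truth = truth, config = config),
            class = "simulated_cohort")
}

#' Write simulated reads as FASTQ (constant quality) or FASTA
#'
#' @param reads Named character vector of read sequences (as produced per
#'   locus by [simulate_sample()]).
#' @param path Output path.
#' @param format `"fastq"` (constant quality "I") or `"fasta"`.
#' @return Invisibly, `path`.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  seqs <- Biostrings::DNAStringSet(unname(reads))
  names(seqs) <- names(reads)
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(vapply(
      Biostrings::width(seqs),
      function(w) paste(rep("I", w), collapse = ""), ""))
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = quals)
  } else {
    Biostrings::writeXStringSet(seqs, path, format = "fasta")
  }
  invisible(path)
}

#' Read bisulfite amplicon reads from FASTQ or FASTA
#'
#' @param path Input path; format inferred from the extension
#'   (`.fastq`/`.fq` vs anything else).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

# Derive a reproducible 32-bit sub-seed from a base seed and string labels,
# so different simulation entry points under one config do not share streams.
make_sub_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(labels)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}
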