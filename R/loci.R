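#' Synthetic 11-locus LINE-1 promoter panel
#'
#' Builds a deterministic synthetic stand-in for a panel of 11 specific
#' LINE-1 promoter amplicons (5 autosomal, 6 X-linked), all derived from
#' one shared CpG-rich consensus promoter sequence: each locus is a
#' contiguous window of the consensus carrying a few percent of point
#' substitutions and up to two lost CpGs, so the loci are homologous,
#' individually distinguishable, and share the consensus CpG coordinate
#' frame. Locus sizes emulate the assayed amplicons (about 190-430 bp;
#' autosomal loci with 12-15 CpGs, X-linked loci with 25-31 except one
#' short 7-CpG locus).
#'
#' @param seed Integer seed; the same seed always yields the same panel.
#' @return A `locus_panel`: list with `loci` (named list of
#'   [locus_reference()] objects with consensus maps attached),
#'   `consensus_sequence`, `consensus_cpg_positions` (0-based), and
#'   `consensus_map` (TSV-ready data.frame, see [read_consensus_map()]).
#' @export
example_loci <- function(seed = 20150301L) {
  set.seed(make_sub_seed(seed, "locus-panel"))
  # consensus frame: 31 CpGs spaced 8-18 bp apart over ~430 bp
  n_cons <- 31L
  spacing <- sample(8:18, n_cons - 1L, replace = TRUE)
  cons_pos <- as.integer(cumsum(c(12L, spacing)))  # 0-based C offsets
  cons_len <- cons_pos[n_cons] + 20L
  bases <- sample(c("A", "C", "G", "T"), cons_len, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  # scrub accidental CG dinucleotides, then plant the consensus CpGs
  cg <- which(bases[-cons_len] == "C" & bases[-1L] == "G")
  bases[cg + 1L] <- "A"
  bases[cons_pos + 1L] <- "C"
  bases[cons_pos + 2L] <- "G"
  consensus <- paste(bases, collapse = "")

  specs <- list(
    L1A1 = list(n_cpg = 13L, class = "autosomal"),
    L1A2 = list(n_cpg = 15L, class = "autosomal"),
    L1A3 = list(n_cpg = 12L, class = "autosomal"),
    L1A4 = list(n_cpg = 14L, class = "autosomal"),
    L1A5 = list(n_cpg = 13L, class = "autosomal"),
    L1X1 = list(n_cpg = 7L,  class = "X_linked"),
    L1X2 = list(n_cpg = 31L, class = "X_linked"),
    L1X3 = list(n_cpg = 28L, class = "X_linked"),
    L1X4 = list(n_cpg = 25L, class = "X_linked"),
    L1X5 = list(n_cpg = 27L, class = "X_linked"),
    L1X6 = list(n_cpg = 29L, class = "X_linked")
  )
  loci <- vector("list", length(specs))
  names(loci) <- names(specs)
  map_rows <- list()
  for (nm in names(specs)) {
    k <- specs[[nm]]$n_cpg
    s <- sample.int(n_cons - k + 1L, 1L)
    idx <- s:(s + k - 1L)                     # consensus CpG indices
    margin <- sample(8:15, 2L)
    a <- max(0L, cons_pos[s] - margin[1L])    # 0-based window [a, b)
    b <- min(cons_len, cons_pos[idx[k]] + 2L + margin[2L])
    loc_bases <- bases[(a + 1L):b]
    loc_cpg <- cons_pos[idx] - a              # 0-based within the locus
    # point substitutions away from CpG dinucleotides, never creating a CG
    cpg_footprint <- c(loc_cpg + 1L, loc_cpg + 2L)
    mutable <- setdiff(seq_along(loc_bases), cpg_footprint)
    n_mut <- stats::rbinom(1L, length(mutable), 0.03)
    for (pos in sample(mutable, n_mut)) {
      new <- sample(setdiff(c("A", "C", "G", "T"), loc_bases[pos]), 1L)
      left_c <- pos > 1L && loc_bases[pos - 1L] == "C" && new == "G"
      right_g <- pos < length(loc_bases) && loc_bases[pos + 1L] == "G" &&
        new == "C"
      if (!left_c && !right_g) loc_bases[pos] <- new
    }
    # lose up to two CpGs (C -> T), as real loci diverge from consensus
    n_drop <- sample(0:2, 1L)
    keep <- rep(TRUE, k)
    if (n_drop > 0L && k - n_drop >= 7L) {
      drop <- sample.int(k, n_drop)
      keep[drop] <- FALSE
      loc_bases[loc_cpg[drop] + 1L] <- "T"
    }
    ref <- locus_reference(
      nm, paste(loc_bases, collapse = ""),
      cpg_positions = loc_cpg[keep],
      chromosome_class = specs[[nm]]$class,
      consensus_cpg_index = idx[keep],
      consensus_bp = cons_pos[idx[keep]])
    loci[[nm]] <- ref
    map_rows[[nm]] <- data.frame(
      locus_id = nm,
      local_cpg_index = seq_len(sum(keep)),
      consensus_cpg_index = idx[keep],
      consensus_bp_position = cons_pos[idx[keep]])
  }
  structure(list(loci = loci,
                 consensus_sequence = consensus,
                 consensus_cpg_positions = cons_pos,
                 consensus_map = do.call(rbind, c(map_rows,
                                                  make.row.names = FALSE))),
            class = "locus_panel")
}

#' Random locus reference with evenly spaced CpGs
#'
#' Generates a synthetic amplicon reference whose CpGs sit at a fixed
#' base-pair spacing, with an identity consensus map (local CpG i =
#' consensus index i at base-pair position `(i-1) * spacing_bp`).
#' Uses the current RNG state.
#'
#' @param locus_id Identifier.
#' @param n_cpg Number of CpGs.
#' @param spacing_bp Base pairs between consecutive CpG cytosines
#'   (default 12).
#' @param margin Non-CpG flank length on each side (default 10).
#' @param chromosome_class Passed to [locus_reference()].
#' @return A [locus_reference()] with consensus map attached.
#' @export
random_locus_reference <- function(locus_id, n_cpg, spacing_bp = 12L,
                                   margin = 10L,
                                   chromosome_class = "autosomal") {
  stopifnot(n_cpg >= 1L, spacing_bp >= 2L)
  cpg_pos <- margin + (seq_len(n_cpg) - 1L) * spacing_bp  # 0-based
  total <- cpg_pos[n_cpg] + 2L + margin
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  cg <- which(bases[-total] == "C" & bases[-1L] == "G")
  bases[cg + 1L] <- "A"
  bases[cpg_pos + 1L] <- "C"
  bases[cpg_pos + 2L] <- "G"
  locus_reference(locus_id, paste(bases, collapse = ""),
                  cpg_positions = cpg_pos,
                  chromosome_class = chromosome_class,
                  consensus_cpg_index = seq_len(n_cpg),
                  consensus_bp = (seq_len(n_cpg) - 1L) * spacing_bp)
}

#' Simulate a planted-seed consensus study
#'
#' Ground-truth scenario for hotspot recovery: several homologous loci
#' sharing one consensus frame, several tumor and normal samples, tumor
#' molecules drawn from a patchy model seeded at known consensus CpG
#' indices, normal molecules uniformly methylated at the same base
#' level. Returns the per-(locus, sample) methylation profiles projected
#' onto the consensus frame, ready for [find_hotspots()].
#'
#' @param consensus_seeds Consensus CpG indices of the planted
#'   demethylation seeds (default c(5, 13, 21)).
#' @param n_cpg Consensus CpG count (default 25).
#' @param spacing_bp Base pairs between consecutive consensus CpGs
#'   (default 12).
#' @param n_loci,n_samples Loci sharing the frame and sample pairs
#'   (defaults 2 and 3).
#' @param n_reads Reads per locus per sample (default 200).
#' @param base_methylation Background methylation of both conditions
#'   (default 0.9).
#' @param seed_demethylation_prob,spread_decay Patchy parameters
#'   (defaults 0.9 and 0.5; at these defaults the planted effect at a
#'   seed is about 73 percentage points).
#' @param min_obs Passed to [build_consensus_profile()] (default 3).
#' @param rng_seed Integer seed.
#' @return A list: `tumor` and `normal` (consensus_profile rows per
#'   group), `profiles`, `refs`, `groups`, `consensus_seeds`,
#'   `seed_bp` (planted base-pair positions).
#' @export
planted_seed_study <- function(consensus_seeds = c(5L, 13L, 21L),
                               n_cpg = 25L, spacing_bp = 12L,
                               n_loci = 2L, n_samples = 3L,
                               n_reads = 200L,
                               base_methylation = 0.9,
                               seed_demethylation_prob = 0.9,
                               spread_decay = 0.5,
                               min_obs = 3L, rng_seed = 1L) {
  stopifnot(all(consensus_seeds >= 1L & consensus_seeds <= n_cpg))
  set.seed(make_sub_seed(rng_seed, "planted-seeds"))
  refs <- lapply(seq_len(n_loci), function(l)
    random_locus_reference(sprintf("locus%02d", l), n_cpg, spacing_bp))
  names(refs) <- vapply(refs, `[[`, "", "locus_id")
  tumor_model <- epiallele_model(
    "patchy", base_methylation = base_methylation,
    seed_cpg_indices = consensus_seeds,
    seed_demethylation_prob = seed_demethylation_prob,
    spread_decay = spread_decay)
  normal_model <- epiallele_model("uniform",
                                  base_methylation = base_methylation)
  profiles <- list()
  groups <- character(0)
  for (s in seq_len(n_samples)) {
    for (nm in names(refs)) {
      for (grp in c("tumor", "normal")) {
        model <- if (grp == "tumor") tumor_model else normal_model
        states <- draw_epialleles(model, n_cpg, n_reads)
        m <- read_meth_matrix(states, nm, sprintf("%s_s%02d", grp, s))
        profiles[[length(profiles) + 1L]] <- per_cpg_mean(m)
        groups <- c(groups, grp)
      }
    }
  }
  cp <- build_consensus_profile(profiles, refs, groups, min_obs = min_obs)
  list(tumor = cp[cp$group == "tumor", ],
       normal = cp[cp$group == "normal", ],
       profiles = profiles, refs = refs, groups = groups,
       consensus_seeds = as.integer(consensus_seeds),
       seed_bp = (as.integer(consensus_seeds) - 1L) * spacing_bp)
}

#' Canonical epiallele architectures
#'
#' The four read-level methylation architectures in their well-separated
#' canonical parameterizations, used as ground truth for classifier
#' validation: uniformly methylated (base 0.95), uniformly unmethylated
#' (base 0.05), allelic (two mirrored read classes at base 0.95, mixture
#' weight 0.5), and patchy (near-complete background methylation, base
#' 0.98, with demethylation seeds at well-separated CpGs, seed
#' probability 0.9, spread decay 0.5 per CpG step). The high patchy
#' background reflects that patches of demethylation appear on an
#' otherwise consistently methylated molecule population.
#'
#' @param n_cpg Locus CpG count (default 25); patchy seeds are placed at
#'   approximately equal spacing across the locus.
#' @return Named list of four [epiallele_model()] objects.
#' @export
canonical_models <- function(n_cpg = 25L) {
  seeds <- unique(pmin(pmax(round(seq(3, n_cpg - 2, length.out = 3L)), 1L),
                       n_cpg))
  list(
    uniform_methylated = epiallele_model("uniform", base_methylation = 0.95),
    uniform_unmethylated = epiallele_model("uniform", base_methylation = 0.05),
    allelic = epiallele_model("allelic", base_methylation = 0.95,
                              allelic_fraction = 0.5),
    patchy = epiallele_model("patchy", base_methylation = 0.98,
                             seed_cpg_indices = seeds,
                             seed_demethylation_prob = 0.9,
                             spread_decay = 0.5))
}

#' Default synthetic study configuration
#'
#' One paired tumor-normal cohort over the [example_loci()] panel with
#' the epiallele architectures seen in deep sequencing of LINE-1
#' promoters. Normal tissue is uniformly highly methylated everywhere
#' (base methylation 0.85-0.9). In tumor, per locus: two loci undergo
#' allelic hypomethylation (a near-fully-unmethylated read class at
#' mixture weight 0.45), three undergo patchy hypomethylation seeded at
#' fixed CpGs (seed demethylation probability 0.9, spread decay 0.5),
#' one is hypermethylated, and the rest are unchanged. Defaults: 500
#' reads per locus, 20 pairs, conversion failure 0.5%, inappropriate
#' conversion 0.5%, sequencing error 0.2%, effective pyrosequencing
#' depth 100.
#'
#' @param seed Integer RNG seed for the simulated data.
#' @param panel_seed Seed of the locus panel (default: the
#'   [example_loci()] default, so the panel is fixed across studies).
#' @param n_pairs,n_reads Cohort size and read depth overrides.
#' @return A list: `config` (a [simulation_config()]), `panel` (the
#'   `locus_panel`), and `scenario` (data.frame: locus_id, tumor pattern,
#'   expected direction of change).
#' @export
example_study_config <- function(seed = 1L, panel_seed = 20150301L,
                                 n_pairs = 20L, n_reads = 500L) {
  panel <- example_loci(panel_seed)
  loci <- panel$loci
  normal <- lapply(loci, function(ref) {
    epiallele_model("uniform",
                    base_methylation =
                      if (ref$chromosome_class == "autosomal") 0.9 else 0.85)
  })
  tumor <- normal
  scenario <- data.frame(locus_id = names(loci),
                         tumor_pattern = "uniform_unchanged",
                         stringsAsFactors = FALSE)
  allelic_at <- c("L1A2", "L1X4")
  patchy_at <- c("L1A5", "L1X3", "L1X6")
  hyper_at <- "L1A3"
  for (nm in allelic_at) {
    tumor[[nm]] <- epiallele_model("allelic", base_methylation = 0.95,
                                   allelic_fraction = 0.45)
    scenario$tumor_pattern[scenario$locus_id == nm] <- "allelic_hypo"
  }
  for (nm in patchy_at) {
    n_cpg <- length(loci[[nm]]$cpg_positions)
    seeds <- unique(pmin(pmax(round(seq(3, n_cpg - 2, length.out = 3)), 1L),
                         n_cpg))
    tumor[[nm]] <- epiallele_model("patchy", base_methylation = 0.98,
                                   seed_cpg_indices = seeds,
                                   seed_demethylation_prob = 0.9,
                                   spread_decay = 0.5)
    scenario$tumor_pattern[scenario$locus_id == nm] <- "patchy_hypo"
  }
  tumor[[hyper_at]] <- epiallele_model("uniform", base_methylation = 0.98)
  normal[[hyper_at]] <- epiallele_model("uniform", base_methylation = 0.75)
  scenario$tumor_pattern[scenario$locus_id == hyper_at] <- "uniform_hyper"
  config <- simulation_config(
    loci = unname(loci),
    tumor_models = unname(tumor),
    normal_models = unname(normal),
    n_reads = n_reads, n_pairs = n_pairs, rng_seed = seed)
  list(config = config, panel = panel, scenario = scenario)
}
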