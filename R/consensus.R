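#' Project per-CpG profiles onto the consensus CpG coordinate system
#'
#' Averages per-CpG mean methylation over all (locus, sample)
#' observations that map to each consensus CpG index, separately per
#' group (e.g. tumor / normal / blood). Averaging is unweighted per
#' observation; an index supported by fewer than `min_obs` observations
#' gets a missing mean.
#'
#' @param profiles List of `meth_profile` objects ([per_cpg_mean()]).
#' @param refs Named list of [locus_reference()] objects (names =
#'   locus_id) carrying `consensus_cpg_index` / `consensus_bp` maps; each
#'   profile's locus must be present and mapped.
#' @param groups Character vector, one group label per profile.
#' @param min_obs Minimum observations per consensus index (default 3).
#' @return A `consensus_profile`: data.frame with columns
#'   `consensus_index`, `consensus_bp` (representative base-pair position,
#'   NA if the map carries none), `group`, `mean` (fraction, NA below
#'   `min_obs`) and `n_obs`.
#' @export
build_consensus_profile <- function(profiles, refs, groups, min_obs = 3L) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            length(groups) == length(profiles))
  rows <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    stopifnot(inherits(pr, "meth_profile"))
    locus <- attr(pr, "locus_id")
    ref <- refs[[locus]]
    if (is.null(ref)) stop("no reference supplied for locus '", locus, "'")
    if (is.null(ref$consensus_cpg_index)) {
      stop("locus '", locus, "' carries no consensus CpG map")
    }
    ok <- !is.na(pr$mean)
    if (!any(ok)) next
    rows[[i]] <- data.frame(
      consensus_index = ref$consensus_cpg_index[pr$cpg_index[ok]],
      consensus_bp = if (is.null(ref$consensus_bp)) NA_real_ else
        ref$consensus_bp[pr$cpg_index[ok]],
      group = groups[i],
      mean = pr$mean[ok])
  }
  obs <- do.call(rbind, rows)
  if (is.null(obs) || nrow(obs) == 0L) {
    stop("no profile observation maps to any consensus index")
  }
  agg <- stats::aggregate(mean ~ consensus_index + group, data = obs, mean)
  n <- stats::aggregate(mean ~ consensus_index + group, data = obs, length)
  bp <- stats::aggregate(consensus_bp ~ consensus_index, data = obs,
                         function(v) v[1L], na.action = NULL)
  out <- merge(agg, n, by = c("consensus_index", "group"),
               suffixes = c("", "_n"))
  out <- merge(out, bp, by = "consensus_index")
  names(out)[names(out) == "mean_n"] <- "n_obs"
  out$mean[out$n_obs < min_obs] <- NA_real_
  out <- out[order(out$group, out$consensus_index),
             c("consensus_index", "consensus_bp", "group", "mean", "n_obs")]
  rownames(out) <- NULL
  class(out) <- c("consensus_profile", "data.frame")
  out
}

#' Detect recurrent hypomethylation hotspots on the consensus frame
#'
#' Works on the per-index tumor-normal methylation delta. A
#' hypomethylation hotspot ("seed") is a local minimum of the delta
#' profile lying at or below `median(delta) - k * mad(delta)`; a
#' protected index is a local maximum at or above
#' `median(delta) + k * mad(delta)`. Local extrema are strict against at
#' least one neighbour, so a flat delta yields no hotspots; endpoints
#' qualify via their single neighbour. The median/MAD centering makes
#' the rule invariant to adding a constant to all deltas.
#'
#' @param tumor,normal `consensus_profile` rows for one group each
#'   (data.frames with `consensus_index`, `consensus_bp`, `mean`).
#' @param k Robust deviation multiplier (default 1.5; MAD is the
#'   median absolute deviation scaled by 1.4826).
#' @param min_shared Minimum shared consensus indices (default 8).
#' @return A `hotspot_set`: list with `hypo` and `protected`
#'   (data.frames: `consensus_index`, `consensus_bp`, `delta`),
#'   `spacing_bp` (base pairs between consecutive hypomethylated
#'   hotspots), and the thresholds used.
#' @export
find_hotspots <- function(tumor, normal, k = 1.5, min_shared = 8L) {
  m <- merge(tumor[, c("consensus_index", "consensus_bp", "mean")],
             normal[, c("consensus_index", "mean")],
             by = "consensus_index", suffixes = c("_t", "_n"))
  m <- m[!is.na(m$mean_t) & !is.na(m$mean_n), ]
  m <- m[order(m$consensus_index), ]
  if (nrow(m) < min_shared) {
    stop("only ", nrow(m), " shared consensus indices (need >= ",
         min_shared, ")")
  }
  delta <- m$mean_t - m$mean_n
  n <- length(delta)
  med <- stats::median(delta)
  dev <- stats::mad(delta)
  lo_thr <- med - k * dev
  hi_thr <- med + k * dev
  left <- c(Inf, delta[-n])    # neighbour values; Inf so endpoints
  right <- c(delta[-1L], Inf)  # qualify via their single real neighbour
  is_min <- delta <= left & delta <= right & (delta < left | delta < right)
  left2 <- c(-Inf, delta[-n])
  right2 <- c(delta[-1L], -Inf)
  is_max <- delta >= left2 & delta >= right2 & (delta > left2 | delta > right2)
  # strict deviation from the median keeps plateau edges out when MAD = 0
  hypo_idx <- which(is_min & delta <= lo_thr & delta < med)
  prot_idx <- which(is_max & delta >= hi_thr & delta > med)
  hypo <- data.frame(consensus_index = m$consensus_index[hypo_idx],
                     consensus_bp = m$consensus_bp[hypo_idx],
                     delta = delta[hypo_idx])
  protected <- data.frame(consensus_index = m$consensus_index[prot_idx],
                          consensus_bp = m$consensus_bp[prot_idx],
                          delta = delta[prot_idx])
  spacing <- if (nrow(hypo) >= 2L) diff(sort(hypo$consensus_bp)) else numeric(0)
  structure(list(hypo = hypo, protected = protected,
                 spacing_bp = as.numeric(spacing),
                 threshold_lo = lo_thr, threshold_hi = hi_thr,
                 k = k, n_indices = n),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("<hotspot_set> ", nrow(x$hypo), " hypomethylated, ",
      nrow(x$protected), " protected indices over ", x$n_indices,
      " consensus CpGs\n", sep = "")
  invisible(x)
}

#' Spacing statistics of hypomethylation hotspots
#'
#' Summarizes the base-pair distances between consecutive hypomethylated
#' hotspots and the fraction of spacings falling in configured bands
#' (defaults: the 40-60 nt and 80-100 nt bands in which recurrently
#' hypomethylated LINE-1 CpGs tend to be spaced).
#'
#' @param hotspots A `hotspot_set` from [find_hotspots()].
#' @param bands Named list of `c(lower, upper)` base-pair bands
#'   (inclusive).
#' @return A list: `n_spacings`, `median`, `iqr`, `spacings`, and
#'   `band_fraction` (named numeric). With fewer than two hotspots all
#'   statistics are NA and `n_spacings` is 0.
#' @export
hotspot_periodicity <- function(hotspots,
                                bands = list(`40-60` = c(40, 60),
                                             `80-100` = c(80, 100))) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  sp <- hotspots$spacing_bp
  if (length(sp) == 0L) {
    return(list(n_spacings = 0L, median = NA_real_, iqr = NA_real_,
                spacings = numeric(0),
                band_fraction = stats::setNames(
                  rep(NA_real_, length(bands)), names(bands))))
  }
  band_fraction <- vapply(bands, function(bd)
    mean(sp >= bd[1L] & sp <= bd[2L]), 0)
  list(n_spacings = length(sp),
       median = stats::median(sp),
       iqr = stats::IQR(sp),
       spacings = sp,
       band_fraction = band_fraction)
}

#' Inter-sample Spearman correlation of per-CpG profiles at one locus
#'
#' A recurrent (sample-independent) methylation pattern at a locus shows
#' up as high positive Spearman correlation between the per-CpG profiles
#' of different samples.
#'
#' @param profiles Named list of `meth_profile` objects for the same
#'   locus across samples (names = sample ids; taken from the profile
#'   attributes when unnamed).
#' @param min_shared Minimum shared CpGs with defined means per sample
#'   pair (default 5).
#' @return A list: `rho` and `p` (symmetric matrices; NA where a profile
#'   is constant over the shared CpGs), `n_shared` (matrix of shared CpG
#'   counts).
#' @export
inter_sample_profile_correlation <- function(profiles, min_shared = 5L) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(profiles, function(p) attr(p, "sample_id"), "")
  }
  k <- length(profiles)
  rho <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  p <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  n_shared <- matrix(0L, k, k, dimnames = list(ids, ids))
  diag(rho) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- profiles[[i]]; b <- profiles[[j]]
      sh <- merge(a, b, by = "cpg_index", suffixes = c("_a", "_b"))
      sh <- sh[!is.na(sh$mean_a) & !is.na(sh$mean_b), ]
      n_shared[i, j] <- n_shared[j, i] <- nrow(sh)
      if (nrow(sh) < min_shared) {
        stop("samples '", ids[i], "' and '", ids[j], "' share only ",
             nrow(sh), " CpGs with defined means (need >= ", min_shared, ")")
      }
      if (stats::sd(sh$mean_a) == 0 || stats::sd(sh$mean_b) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(sh$mean_a, sh$mean_b, method = "spearman",
                        exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p, n_shared = n_shared)
}
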