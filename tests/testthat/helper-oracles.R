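# Independent brute-force oracles used across the suite. Each is written
# from first principles, separately from the package implementation it
# checks.

# --- Gotoh dynamic-programming oracle ---------------------------------
# Semi-global alignment score: pattern (read) aligned end to end, free
# end gaps on the subject (reference), affine gap cost
# open + L * extension, asymmetric substitution scoring.
oracle_align_score <- function(pattern, subject, submat,
                               gap_opening = 4, gap_extension = 1) {
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  s <- strsplit(toupper(subject), "", fixed = TRUE)[[1L]]
  n <- length(p); m <- length(s)
  neg <- -1e18
  open_ext <- gap_opening + gap_extension
  M <- matrix(neg, n + 1L, m + 1L)  # ends in an aligned pair
  X <- matrix(neg, n + 1L, m + 1L)  # ends in a gap in the subject
  Y <- matrix(neg, n + 1L, m + 1L)  # ends in a gap in the pattern
  A0 <- rep(0, m + 1L)              # empty pattern prefix, any start
  for (i in seq_len(n)) {
    prevA <- if (i == 1L) A0 else pmax(M[i, ], pmax(X[i, ], Y[i, ]))
    X[i + 1L, 1L] <- max(prevA[1L] - open_ext, X[i, 1L] - gap_extension)
    for (j in seq_len(m)) {
      sc <- submat[p[i], s[j]]
      M[i + 1L, j + 1L] <- prevA[j] + sc
      X[i + 1L, j + 1L] <- max(prevA[j + 1L] - open_ext,
                               X[i, j + 1L] - gap_extension)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open_ext,
                               X[i + 1L, j] - open_ext,
                               Y[i + 1L, j] - gap_extension)
    }
  }
  last <- pmax(M[n + 1L, ], pmax(X[n + 1L, ], Y[n + 1L, ]))
  max(last)  # free trailing subject positions
}

# --- entropy oracle ---------------------------------------------------
# Enumerates every possible length-b pattern and counts the complete
# reads matching each one, then applies the epiallele entropy formula
# term by term.
oracle_entropy <- function(calls, b = 4L, min_reads = 10L) {
  n_cpg <- ncol(calls)
  starts <- seq_len(n_cpg - b + 1L)
  all_patterns <- as.matrix(expand.grid(rep(list(c(0L, 1L)), b)))
  vapply(starts, function(w) {
    sub <- calls[, w:(w + b - 1L), drop = FALSE]
    complete <- !apply(sub, 1L, anyNA)
    N <- sum(complete)
    if (N < min_reads) return(NA_real_)
    sub <- sub[complete, , drop = FALSE]
    me <- 0
    for (k in seq_len(nrow(all_patterns))) {
      n_i <- sum(apply(sub, 1L, function(row)
        all(row == all_patterns[k, ])))
      if (n_i > 0L) me <- me + (n_i / N) * log2(N / n_i)
    }
    me / b
  }, 0)
}

# --- exact Wilcoxon signed-rank oracle --------------------------------
# Full sign-flip enumeration of the two-sided exact p-value for paired
# differences without zeros or tied absolute values.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1L, n <= 12L, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- Kruskal-Wallis oracle --------------------------------------------
# Tie-corrected H from first principles (rank variance decomposition)
# and an exact permutation p-value for small n.
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  groups <- factor(groups)
  N <- length(r)
  ss_total <- sum((r - mean(r))^2)
  group_means <- tapply(r, groups, mean)
  sizes <- tabulate(groups)
  ss_between <- sum(sizes * (group_means - mean(r))^2)
  (N - 1) * ss_between / ss_total
}

oracle_kw_perm_p <- function(values, groups, max_n = 9L) {
  groups <- factor(groups)
  N <- length(values)
  stopifnot(N <= max_n)
  h_obs <- oracle_kw_h(values, groups)
  perms <- permutations_of(seq_len(N))
  h_perm <- apply(perms, 1L, function(ix)
    oracle_kw_h(values, groups[ix]))
  mean(h_perm >= h_obs - 1e-12)
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}

# --- trapezoidal ROC area ---------------------------------------------
oracle_trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]; tpr <- roc$tpr[o]
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

# --- shared fixtures --------------------------------------------------
# A molecule sequence with mutations/indels relative to the converted
# reference, for alignment fixtures.
mutate_sequence <- function(seq, n_sub = 0L, n_del = 0L, n_ins = 0L) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (n_sub > 0L) {
    at <- sample(seq_along(bases), n_sub)
    for (i in at) bases[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                             bases[i]), 1L)
  }
  if (n_del > 0L && length(bases) > n_del + 1L) {
    bases <- bases[-sample(seq_along(bases), n_del)]
  }
  if (n_ins > 0L) {
    for (k in seq_len(n_ins)) {
      at <- sample(seq_along(bases), 1L)
      bases <- append(bases, sample(c("A", "C", "G", "T"), 1L), after = at)
    }
  }
  paste(bases, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tempfile_with <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}
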