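#' Pivot a long cohort table to a wide marker table
#'
#' @param table Long table with columns `sample_id`, `pair_id`, `group`,
#'   `locus_id`, `mean_methylation` (as from [simulate_cohort()]).
#' @return A wide data.frame: `sample_id`, `pair_id`, `group`, then one
#'   numeric column per marker (locus), values in percent.
#' @export
as_marker_table <- function(table) {
  need <- c("sample_id", "pair_id", "group", "locus_id", "mean_methylation")
  stopifnot(all(need %in% names(table)))
  meta <- unique(table[, c("sample_id", "pair_id", "group")])
  wide <- stats::reshape(
    table[, need], direction = "wide",
    idvar = "sample_id", timevar = "locus_id",
    v.names = "mean_methylation", drop = c("pair_id", "group"))
  names(wide) <- sub("^mean_methylation\\.", "", names(wide))
  out <- merge(meta, wide, by = "sample_id")
  out <- out[order(out$pair_id, out$group), ]
  rownames(out) <- NULL
  out
}

#' Marker columns of a marker table
#'
#' @param table A wide marker table ([as_marker_table()]).
#' @return Character vector of marker column names (everything except
#'   the metadata columns).
#' @export
marker_names <- function(table) {
  setdiff(names(table),
          c("sample_id", "pair_id", "group", "tissue", "sex"))
}

#' Paired tumor-normal test for one marker
#'
#' Two-sided Wilcoxon signed-rank test over complete tumor-normal pairs
#' (exact null for up to 25 non-zero differences, normal approximation
#' with continuity correction above; all-zero differences give p = 1).
#'
#' @param table Wide marker table with `pair_id` and `group`
#'   ("tumor"/"normal") columns.
#' @param marker Marker column name.
#' @param min_pairs Minimum complete pairs (default 5).
#' @return A list: `statistic` (V), `p_value`, `n_pairs`.
#' @export
marker_test_paired <- function(table, marker, min_pairs = 5L) {
  stopifnot(marker %in% names(table))
  t_val <- table[table$group == "tumor", c("pair_id", marker)]
  n_val <- table[table$group == "normal", c("pair_id", marker)]
  m <- merge(t_val, n_val, by = "pair_id", suffixes = c("_t", "_n"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < min_pairs) {
    stop("marker '", marker, "': only ", nrow(m),
         " complete pairs (need >= ", min_pairs, ")")
  }
  wt <- paired_wilcoxon(m[[paste0(marker, "_t")]],
                        m[[paste0(marker, "_n")]])
  list(statistic = wt$statistic, p_value = wt$p_value, n_pairs = nrow(m))
}

#' Kruskal-Wallis test for one marker across sample groups
#'
#' Rank-based comparison of a marker across several groups (e.g. blood
#' from patients with different cancer types vs healthy controls), with
#' tie correction and chi-square p-value.
#'
#' @param table Wide marker table with a `group` column.
#' @param marker Marker column name.
#' @param min_per_group Minimum samples per group (default 3).
#' @return A list: `statistic` (H), `p_value`, `df`, `n`.
#' @export
marker_test_groups <- function(table, marker, min_per_group = 3L) {
  stopifnot(marker %in% names(table))
  ok <- !is.na(table[[marker]]) & !is.na(table$group)
  values <- table[[marker]][ok]
  groups <- factor(table$group[ok])
  if (nlevels(groups) < 2L) {
    stop("marker '", marker, "': need >= 2 groups, have ", nlevels(groups))
  }
  sizes <- table(groups)
  if (any(sizes < min_per_group)) {
    stop("marker '", marker, "': every group needs >= ", min_per_group,
         " samples")
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up q-values and the selected set at `q < alpha`.
#'
#' @param p_values Numeric vector of p-values in \[0,1\] (names kept).
#' @param alpha FDR level (default 0.05).
#' @return A list: `q_values` (same order and names as the input),
#'   `selected` (logical, `q < alpha`).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0,1] with no NA")
  }
  q <- stats::p.adjust(p, method = "BH")
  names(q) <- names(p_values)
  list(q_values = q, selected = q < alpha)
}

#' ROC curve and AUC
#'
#' AUC by the tie-corrected Mann-Whitney rank formula (average ranks at
#' ties), with the ROC as a step curve over the distinct score
#' thresholds. AUC 1 = perfect separation, 0.5 = chance.
#'
#' @param scores Numeric scores (higher = more tumor-like).
#' @param labels Logical or two-level vector; `TRUE` (or the level
#'   `"tumor"`/the second factor level) marks the positive class.
#' @return A list: `auc`, `roc` (data.frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an ROC curve")
  }
  r <- rank(scores)  # average ranks handle ties
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores[!y] >= t) / n0, 0),
    tpr = vapply(thr, function(t) sum(scores[y] >= t) / n1, 0))
  list(auc = auc, roc = roc)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  f <- factor(labels)
  if (nlevels(f) > 2L) stop("labels must have exactly two levels")
  if ("tumor" %in% levels(f)) return(f == "tumor")
  f == levels(f)[2L]
}

#' Ridge-penalized logistic regression (IRLS)
#'
#' Maximum-likelihood logistic fit with a small L2 penalty on the
#' standardized predictors (intercept unpenalized), by Newton iteration
#' on the penalized log-likelihood
#' \deqn{\ell(\beta) = \frac{1}{n}\sum_i \log p_i(y_i) -
#'   \frac{\lambda}{2}\lVert\beta_{-0}\rVert^2.}
#' The penalty guarantees a finite optimum when FDR-selected markers
#' separate the classes perfectly, which is common at small n.
#'
#' @param x Numeric matrix (samples x markers).
#' @param y Logical/binary response (TRUE = positive class).
#' @param lambda Ridge penalty on standardized coefficients
#'   (default 1e-4).
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `ridge_logistic`: coefficients on the
#'   original scale (`intercept`, `coefficients`), standardization
#'   (`center`, `scale`), `lambda`, fitted probabilities `fitted`,
#'   `converged`.
#' @export
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100L,
                           tol = 1e-10) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to fit the model")
  }
  n <- nrow(x)
  stopifnot(length(y) == n, n >= 4L)
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  if (any(scale_ == 0)) {
    stop("constant marker column(s): ",
         paste(colnames(x)[scale_ == 0], collapse = ", "))
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  X <- cbind(1, xs)
  p_dim <- ncol(X)
  pen <- c(0, rep(lambda, p_dim - 1L))  # intercept unpenalized
  beta <- rep(0, p_dim)
  yy <- as.numeric(y)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, yy - mu)) / n - pen * beta
    hess <- crossprod(X * w, X) / n + diag(pen, p_dim)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  coef_std <- beta[-1L]
  fitted <- stats::plogis(drop(X %*% beta))
  structure(
    list(intercept = unname(beta[1L]) - sum(coef_std * center / scale_),
         coefficients = stats::setNames(coef_std / scale_, colnames(x)),
         coefficients_std = stats::setNames(coef_std, colnames(x)),
         center = center, scale = scale_, lambda = lambda,
         fitted = fitted, converged = converged),
    class = "ridge_logistic")
}

#' @rdname ridge_logistic
#' @param object A fitted `ridge_logistic` model.
#' @param newdata Matrix/data.frame with the model's marker columns.
#' @param ... Unused.
#' @return `predict`: vector of class probabilities.
#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
  stats::plogis(object$intercept + drop(x %*% object$coefficients))
}

#' Fit the multivariate logistic marker model
#'
#' Combines the FDR-selected markers into one ridge-penalized logistic
#' model predicting the probability that a sample is tumor
#' (see [ridge_logistic()]).
#'
#' @param table Wide marker table with a `group` column.
#' @param selected Character vector of selected marker names; empty
#'   selection returns a skip report rather than a model.
#' @param lambda Ridge penalty (default 1e-4).
#' @param labels Optional binary response overriding the default
#'   `group == "tumor"` / second-factor-level rule (used e.g. for
#'   patient-vs-healthy blood designs).
#' @return A list: `model` (a `ridge_logistic`, or NULL), `pi`
#'   (per-sample tumor probability, named by sample_id), `skipped`
#'   (logical), `reason`.
#' @export
fit_logistic <- function(table, selected, lambda = 1e-4, labels = NULL) {
  if (length(selected) == 0L) {
    return(list(model = NULL, pi = NULL, skipped = TRUE,
                reason = "no marker passed FDR"))
  }
  stopifnot(all(selected %in% names(table)))
  x <- as.matrix(table[, selected, drop = FALSE])
  y <- if (is.null(labels)) as_binary_labels(table$group) else
    as_binary_labels(labels)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 samples per class")
  }
  fit <- ridge_logistic(x, y, lambda = lambda)
  pi_hat <- fit$fitted
  names(pi_hat) <- table$sample_id
  list(model = fit, pi = pi_hat, skipped = FALSE, reason = "")
}

#' Run the full diagnostic biomarker cascade
#'
#' Per-marker paired Wilcoxon signed-rank tests (or Kruskal-Wallis for
#' unpaired group designs), Benjamini-Hochberg FDR at `alpha`,
#' ridge-penalized multivariate logistic regression on the selected
#' markers, and ROC/AUC. Two AUCs are reported: the in-sample AUC of the
#' final model and an out-of-fold AUC from `nfolds`-fold cross-validation
#' in which the whole cascade (testing, FDR selection, fitting) is re-run
#' on each training set, so marker selection cannot leak into the
#' held-out predictions. Folds split by pair (paired design) or by sample
#' (group design); training folds selecting no marker predict their
#' training positive-class rate.
#'
#' @param table Wide marker table ([as_marker_table()]).
#' @param markers Marker columns to test (default: all via
#'   [marker_names()]).
#' @param design `"paired"` (tumor vs normal, Wilcoxon) or `"groups"`
#'   (Kruskal-Wallis across `group` levels; the positive class for the
#'   logistic model and the ROC is every group whose name does not start
#'   with `"healthy"`).
#' @param alpha FDR selection level (default 0.05).
#' @param lambda Ridge penalty (default 1e-4).
#' @param nfolds Cross-validation folds (default 5).
#' @param fold_seed Integer seed for the fold split (default 1).
#' @return A `marker_model`: list with `tests` (data.frame: marker,
#'   statistic, p_value, q_value, selected), `selected`, `fit`
#'   (see [fit_logistic()]), `auc_insample`, `roc_insample`, `auc_oof`,
#'   `pi_oof`, `design`, `n_samples`.
#' @export
run_diagnostics <- function(table, markers = marker_names(table),
                            design = c("paired", "groups"),
                            alpha = 0.05, lambda = 1e-4,
                            nfolds = 5L, fold_seed = 1L) {
  design <- match.arg(design)
  stopifnot(length(markers) >= 1L)
  run_tests <- function(tab) {
    res <- lapply(markers, function(mk) {
      if (design == "paired") marker_test_paired(tab, mk)
      else marker_test_groups(tab, mk)
    })
    data.frame(marker = markers,
               statistic = vapply(res, `[[`, 0, "statistic"),
               p_value = vapply(res, `[[`, 0, "p_value"),
               stringsAsFactors = FALSE)
  }
  labels_of <- function(tab) {
    if (design == "paired") tab$group == "tumor"
    else !grepl("^healthy", tab$group)
  }
  tests <- run_tests(table)
  fdr <- bh_fdr(tests$p_value, alpha = alpha)
  tests$q_value <- fdr$q_values
  tests$selected <- fdr$selected
  selected <- tests$marker[tests$selected]
  y <- labels_of(table)
  fit <- fit_logistic(table, selected, lambda = lambda, labels = y)
  auc_in <- NA_real_
  roc_in <- NULL
  if (!fit$skipped) {
    ra <- roc_auc(fit$pi, y)
    auc_in <- ra$auc
    roc_in <- ra$roc
  }
  # nested out-of-fold probabilities
  units <- if (design == "paired") table$pair_id else table$sample_id
  uniq <- unique(units)
  # seed the fold split locally without disturbing the caller's RNG stream
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(fold_seed)
  fold_of <- sample(rep_len(seq_len(nfolds), length(uniq)))
  if (is.null(rng_state)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", rng_state, envir = globalenv())
  }
  names(fold_of) <- uniq
  pi_oof <- rep(NA_real_, nrow(table))
  for (f in seq_len(nfolds)) {
    hold <- fold_of[units] == f
    train <- table[!hold, , drop = FALSE]
    t_f <- run_tests(train)
    sel_f <- t_f$marker[bh_fdr(t_f$p_value, alpha = alpha)$selected]
    if (length(sel_f) == 0L) {
      pi_oof[hold] <- mean(labels_of(train))
    } else {
      fit_f <- fit_logistic(train, sel_f, lambda = lambda,
                            labels = labels_of(train))
      pi_oof[hold] <- predict(fit_f$model, table[hold, , drop = FALSE])
    }
  }
  auc_oof <- roc_auc(pi_oof, y)$auc
  structure(
    list(tests = tests, selected = selected, fit = fit,
         auc_insample = auc_in, roc_insample = roc_in,
         auc_oof = auc_oof,
         pi_oof = stats::setNames(pi_oof, table$sample_id),
         design = design, n_samples = nrow(table)),
    class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat("<marker_model> ", x$design, " design, ", x$n_samples, " samples; ",
      length(x$selected), "/", nrow(x$tests), " markers selected (q < 0.05)",
      "\n", sep = "")
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
    cat(sprintf("  AUC in-sample %.3f, out-of-fold %.3f\n",
                x$auc_insample, x$auc_oof))
  } else {
    cat("  no marker passed FDR; out-of-fold AUC ",
        sprintf("%.3f", x$auc_oof), "\n", sep = "")
  }
  invisible(x)
}
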