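#' Read x CpG methylation call matrix
#'
#' The object behind a per-locus, per-sample read-level methylation heat
#' map: one row per retained read, one column per CpG of the locus, cells
#' 1 (methylated), 0 (unmethylated) or NA (missing: gap or unexpected
#' base at that CpG).
#'
#' @param calls Integer/numeric matrix of 1/0/NA calls; column count must
#'   equal the locus CpG count. Row names are read ids.
#' @param locus_id,sample_id Identifiers.
#' @param retention Optional numeric vector (one value per read) of the
#'   per-read non-CpG cytosine retention fraction; defaults to 0 (e.g.
#'   for simulator ground-truth matrices).
#' @return An object of class `read_meth_matrix`.
#' @export
read_meth_matrix <- function(calls, locus_id, sample_id,
                             retention = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1L) stop("matrix must contain at least one read")
  if (!all(calls %in% c(0L, 1L, NA_integer_))) {
    stop("calls must be 1, 0 or NA")
  }
  if (is.null(retention)) retention <- rep(0, nrow(calls))
  if (length(retention) != nrow(calls)) {
    stop("retention must have one value per read")
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("read%04d", seq_len(nrow(calls)))
  }
  structure(list(calls = calls,
                 locus_id = locus_id,
                 sample_id = sample_id,
                 retention = as.numeric(retention)),
            class = "read_meth_matrix")
}

#' @export
print.read_meth_matrix <- function(x, ...) {
  cat("<read_meth_matrix> ", x$locus_id, " / ", x$sample_id, ": ",
      nrow(x$calls), " reads x ", ncol(x$calls), " CpGs, overall ",
      sprintf("%.1f%%", 100 * mean(x$calls, na.rm = TRUE)),
      " methylated\n", sep = "")
  invisible(x)
}

#' @export
dim.read_meth_matrix <- function(x) dim(x$calls)

#' Call per-CpG methylation states from one read alignment
#'
#' At each CpG cytosine of the reference, an aligned read C is called
#' methylated, a read T unmethylated, anything else (gap, other base,
#' outside the aligned span) missing. Non-CpG reference cytosines covered
#' by the read measure bisulfite conversion quality: the fraction still
#' read as C (the retention fraction) must not exceed `max_retention`.
#'
#' @param alignment A `bs_alignment` from [align_read()].
#' @param ref The [locus_reference()] the read was aligned to.
#' @param max_retention Maximum tolerated non-CpG cytosine retention
#'   fraction (default 0.05).
#' @return A list: `states` (integer vector 1/0/NA over the locus CpGs),
#'   `retention` (fraction, NA if no non-CpG C covered), `n_cpg_covered`,
#'   and `status` (`"ok"`, `"high_retention"` or `"no_cpg"`).
#' @export
call_read <- function(alignment, ref, max_retention = 0.05) {
  stopifnot(inherits(alignment, "bs_alignment"),
            inherits(ref, "locus_reference"))
  aln <- alignment$aln
  cpg_idx <- ref$cpg_positions + 1L
  base_at_cpg <- aln[cpg_idx]
  states <- rep(NA_integer_, length(cpg_idx))
  states[base_at_cpg %in% "C"] <- 1L
  states[base_at_cpg %in% "T"] <- 0L
  ref_bases <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  non_cpg_c <- setdiff(which(ref_bases == "C"), cpg_idx)
  covered <- non_cpg_c[aln[non_cpg_c] %in% c("A", "C", "G", "T")]
  retention <- if (length(covered) == 0L) NA_real_ else
    mean(aln[covered] == "C")
  n_cov <- sum(!is.na(states))
  status <- if (n_cov == 0L) "no_cpg"
  else if (!is.na(retention) && retention > max_retention) "high_retention"
  else "ok"
  list(states = states, retention = retention,
       n_cpg_covered = n_cov, status = status)
}

#' Build a read x CpG methylation matrix from bisulfite reads
#'
#' Aligns every read to the locus reference ([align_reads()]), calls
#' per-read methylation states ([call_read()]), and assembles the
#' retained reads (input order preserved) into a [read_meth_matrix()].
#' Reads are discarded for low alignment identity, excessive non-CpG
#' cytosine retention (failed bisulfite conversion), or zero covered
#' CpGs; the QC report counts each.
#'
#' @param reads Named character vector of read sequences, or a FASTA/FASTQ
#'   path (read via [read_reads()]).
#' @param ref A [locus_reference()].
#' @param sample_id Sample identifier.
#' @param min_identity Alignment identity floor (default 0.80).
#' @param max_retention Conversion-QC ceiling (default 0.05).
#' @param ... Further arguments passed to [align_reads()].
#' @return A list: `matrix` (a [read_meth_matrix()]) and `qc` (one-row
#'   data.frame with columns `n_input`, `n_retained`, `n_low_identity`,
#'   `n_high_retention`, `n_no_cpg`).
#' @export
build_matrix <- function(reads, ref, sample_id,
                         min_identity = 0.80, max_retention = 0.05, ...) {
  stopifnot(inherits(ref, "locus_reference"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_reads(reads)
  }
  if (length(reads) < 1L) stop("no reads supplied")
  alns <- align_reads(reads, ref, min_identity = min_identity, ...)
  n_cpg <- length(ref$cpg_positions)
  states <- matrix(NA_integer_, length(alns), n_cpg)
  retention <- rep(NA_real_, length(alns))
  status <- character(length(alns))
  for (i in seq_along(alns)) {
    if (!alns[[i]]$passed) {
      status[i] <- "low_identity"
      next
    }
    cr <- call_read(alns[[i]], ref, max_retention = max_retention)
    status[i] <- cr$status
    if (cr$status == "ok") {
      states[i, ] <- cr$states
      retention[i] <- cr$retention
    }
  }
  keep <- status == "ok"
  qc <- data.frame(locus_id = ref$locus_id,
                   sample_id = sample_id,
                   n_input = length(alns),
                   n_retained = sum(keep),
                   n_low_identity = sum(status == "low_identity"),
                   n_high_retention = sum(status == "high_retention"),
                   n_no_cpg = sum(status == "no_cpg"),
                   stringsAsFactors = FALSE)
  if (!any(keep)) {
    stop("locus '", ref$locus_id, "', sample '", sample_id,
         "': no reads retained (", qc$n_low_identity, " low identity, ",
         qc$n_high_retention, " high retention, ", qc$n_no_cpg,
         " without CpG coverage)")
  }
  calls <- states[keep, , drop = FALSE]
  rownames(calls) <- vapply(alns[keep], `[[`, "", "read_id")
  ret <- retention[keep]
  ret[is.na(ret)] <- 0
  list(matrix = read_meth_matrix(calls, ref$locus_id, sample_id,
                                 retention = ret),
       qc = qc)
}

#' Serialize / deserialize a read x CpG matrix as TSV
#'
#' One row per read: `read_id`, then one column per CpG (`cpg1`, `cpg2`,
#' ...) with values 1/0/NA, then `retention`.
#'
#' @param x A [read_meth_matrix()].
#' @param path Output (input) TSV path.
#' @return `write_matrix_tsv` invisibly returns `path`;
#'   `read_matrix_tsv` returns a [read_meth_matrix()].
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "read_meth_matrix"))
  df <- data.frame(read_id = rownames(x$calls), x$calls,
                   retention = x$retention,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("read_id", paste0("cpg", seq_len(ncol(x$calls))),
                 "retention")
  attr_line <- sprintf("# locus_id=%s sample_id=%s", x$locus_id, x$sample_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
                     regexec("locus_id=(\\S+) sample_id=(\\S+)", header))[[1L]]
  if (length(meta) != 3L) stop("not a read-matrix TSV: ", path)
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  cpg_cols <- grep("^cpg[0-9]+$", names(df))
  calls <- as.matrix(df[, cpg_cols, drop = FALSE])
  dimnames(calls) <- list(df$read_id, NULL)
  read_meth_matrix(calls, meta[2L], meta[3L], retention = df$retention)
}
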