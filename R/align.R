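#' Bisulfite-aware nucleotide substitution matrix
#'
#' Asymmetric scoring for aligning bisulfite-converted reads against an
#' untreated reference: a read T opposite a reference C scores as a match
#' (the expected conversion product of an unmethylated C), while a read C
#' opposite a reference T stays a mismatch. Rows index the read base,
#' columns the reference base.
#'
#' @param match Match score (default 1).
#' @param mismatch Mismatch score (default -1).
#' @return A 4x4 numeric matrix with dimnames A/C/G/T.
#' @export
bisulfite_substitution_matrix <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 4L, 4L,
              dimnames = list(read = c("A", "C", "G", "T"),
                              ref = c("A", "C", "G", "T")))
  diag(m) <- match
  m["T", "C"] <- match
  m
}

#' Align bisulfite reads to a locus reference
#'
#' Semi-global alignment (the read is aligned end to end, free end gaps on
#' the read so it may sit anywhere inside the reference) with
#' bisulfite-aware asymmetric scoring and affine gap costs (a gap of
#' length L costs `gap_opening + L * gap_extension`). Both the read and
#' its reverse complement are tried and the better-scoring orientation is
#' kept. Reads whose alignment identity falls below `min_identity` are
#' flagged as discarded.
#'
#' Identity is computed over aligned (non-gap) columns, counting the
#' bisulfite pairing read-T/reference-C as identical.
#'
#' @param reads Character vector (or `DNAStringSet`) of read sequences;
#'   names are used as read ids.
#' @param ref A [locus_reference()].
#' @param match,mismatch Substitution scores (see
#'   [bisulfite_substitution_matrix()]).
#' @param gap_opening,gap_extension Affine gap parameters (defaults 4, 1).
#' @param min_identity Identity floor below which a read is discarded
#'   (default 0.80).
#' @param try_reverse_complement Also align the reverse complement and
#'   keep the better orientation (default TRUE).
#' @return A list of `bs_alignment` objects (one per read): each has
#'   `read_id`, `aln` (character vector, one entry per reference
#'   position: the aligned read base, `"-"` for a deletion, `NA` outside
#'   the aligned span), `score`, `identity`, `orientation`
#'   (`"forward"`/`"reverse"`), and `passed` (identity >= floor).
#' @export
align_reads <- function(reads, ref,
                        match = 1, mismatch = -1,
                        gap_opening = 4, gap_extension = 1,
                        min_identity = 0.80,
                        try_reverse_complement = TRUE) {
  stopifnot(inherits(ref, "locus_reference"))
  seqs <- Biostrings::DNAStringSet(reads)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- sprintf("read%04d", seq_along(seqs))
  }
  if (any(Biostrings::width(seqs) < 20L)) {
    stop("all reads must be at least 20 nt long")
  }
  subject <- Biostrings::DNAString(ref$sequence)
  submat <- bisulfite_substitution_matrix(match, mismatch)
  pa_fwd <- Biostrings::pairwiseAlignment(
    seqs, subject, type = "global-local", substitutionMatrix = submat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  use_rev <- rep(FALSE, length(seqs))
  pa_rev <- NULL
  if (try_reverse_complement) {
    pa_rev <- Biostrings::pairwiseAlignment(
      Biostrings::reverseComplement(seqs), subject, type = "global-local",
      substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
    use_rev <- Biostrings::score(pa_rev) > Biostrings::score(pa_fwd)
  }
  ref_len <- nchar(ref$sequence)
  # pattern()/subject() give the gapped aligned strings for the whole
  # set at once; with pattern-global alignment they span the full read
  extract <- function(pa) list(
    p = as.character(Biostrings::pattern(pa)),
    s = as.character(Biostrings::subject(pa)),
    start = Biostrings::start(Biostrings::subject(pa)),
    score = Biostrings::score(pa))
  fwd <- extract(pa_fwd)
  rev <- if (try_reverse_complement) extract(pa_rev)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    src <- if (use_rev[i]) rev else fwd
    p_chars <- strsplit(src$p[i], "", fixed = TRUE)[[1L]]
    s_chars <- strsplit(src$s[i], "", fixed = TRUE)[[1L]]
    aln <- rep(NA_character_, ref_len)
    consumes <- s_chars != "-"
    ref_pos <- src$start[i] - 1L + cumsum(consumes)
    aln[ref_pos[consumes]] <- p_chars[consumes]
    both <- p_chars != "-" & consumes
    n_cols <- sum(both)
    ident <- if (n_cols == 0L) 0 else {
      hit <- p_chars[both] == s_chars[both] |
        (p_chars[both] == "T" & s_chars[both] == "C")
      sum(hit) / n_cols
    }
    out[[i]] <- structure(
      list(read_id = names(seqs)[i],
           aln = aln,
           score = src$score[i],
           identity = ident,
           orientation = if (use_rev[i]) "reverse" else "forward",
           passed = ident >= min_identity),
      class = "bs_alignment")
  }
  out
}

#' @rdname align_reads
#' @param read A single read sequence (character scalar).
#' @return `align_read`: a single `bs_alignment` object.
#' @export
align_read <- function(read, ref,
                       match = 1, mismatch = -1,
                       gap_opening = 4, gap_extension = 1,
                       min_identity = 0.80,
                       try_reverse_complement = TRUE) {
  align_reads(stats::setNames(as.character(read), "read0001"), ref,
              match = match, mismatch = mismatch,
              gap_opening = gap_opening, gap_extension = gap_extension,
              min_identity = min_identity,
              try_reverse_complement = try_reverse_complement)[[1L]]
}

#' @export
print.bs_alignment <- function(x, ...) {
  cat("<bs_alignment> ", x$read_id, ": score ", x$score,
      ", identity ", sprintf("%.3f", x$identity),
      ", ", x$orientation,
      if (!x$passed) " [discarded]" else "", "\n", sep = "")
  invisible(x)
}

#' In-silico fully converted reference sequence
#'
#' Every cytosine replaced by T: the expected read sequence of a fully
#' unmethylated, fully converted molecule.
#'
#' @param ref A [locus_reference()] (or a DNA string).
#' @return Character scalar.
#' @export
converted_reference <- function(ref) {
  s <- if (inherits(ref, "locus_reference")) ref$sequence else
    toupper(as.character(ref))
  gsub("C", "T", s, fixed = TRUE)
}
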