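#' Locus reference for a LINE-1 promoter amplicon
#'
#' Bundles the amplicon sequence of one LINE-1 locus with the 0-based
#' offsets of its CpG cytosines and, optionally, a map from each local CpG
#' to a CpG index (and representative base-pair position) in the shared
#' L1Hs consensus coordinate frame.
#'
#' @param locus_id Character scalar, e.g. "L1C2" or "L1X8".
#' @param sequence DNA string (character scalar, A/C/G/T).
#' @param cpg_positions Integer vector of 0-based offsets of the C of each
#'   CpG, strictly increasing. If `NULL`, positions are derived by scanning
#'   the sequence for "CG".
#' @param chromosome_class `"autosomal"` or `"X_linked"`.
#' @param consensus_cpg_index Optional integer vector, same length as
#'   `cpg_positions`, strictly increasing: consensus CpG index of each
#'   local CpG.
#' @param consensus_bp Optional numeric vector of representative base-pair
#'   positions (consensus frame) parallel to `consensus_cpg_index`.
#'
#' @return An object of class `locus_reference`.
#' @export
locus_reference <- function(locus_id, sequence,
                            cpg_positions = NULL,
                            chromosome_class = c("autosomal", "X_linked"),
                            consensus_cpg_index = NULL,
                            consensus_bp = NULL) {
  chromosome_class <- match.arg(chromosome_class)
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("locus '", locus_id, "': empty sequence")
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("locus '", locus_id, "': sequence contains non-ACGT characters")
  }
  if (is.null(cpg_positions)) {
    cpg_positions <- find_cpg_sites(sequence)
  }
  cpg_positions <- as.integer(cpg_positions)
  if (length(cpg_positions) == 0L) {
    stop("locus '", locus_id, "': no CpG sites")
  }
  if (is.unsorted(cpg_positions, strictly = TRUE)) {
    stop("locus '", locus_id, "': cpg_positions must be strictly increasing")
  }
  # every position must point at the C of a CG dinucleotide (0-based)
  dinucs <- substring(sequence, cpg_positions + 1L, cpg_positions + 2L)
  bad <- which(dinucs != "CG")
  if (length(bad)) {
    stop("locus '", locus_id, "': position ", cpg_positions[bad[1L]],
         " (0-based) is not on a CpG cytosine")
  }
  if (!is.null(consensus_cpg_index)) {
    consensus_cpg_index <- as.integer(consensus_cpg_index)
    if (length(consensus_cpg_index) != length(cpg_positions)) {
      stop("locus '", locus_id,
           "': consensus_cpg_index length must match cpg_positions")
    }
    if (is.unsorted(consensus_cpg_index, strictly = TRUE)) {
      stop("locus '", locus_id,
           "': consensus_cpg_index must be strictly increasing")
    }
    if (!is.null(consensus_bp) &&
        length(consensus_bp) != length(consensus_cpg_index)) {
      stop("locus '", locus_id,
           "': consensus_bp length must match consensus_cpg_index")
    }
  } else if (!is.null(consensus_bp)) {
    stop("locus '", locus_id, "': consensus_bp given without consensus_cpg_index")
  }
  structure(
    list(locus_id = locus_id,
         sequence = sequence,
         cpg_positions = cpg_positions,
         chromosome_class = chromosome_class,
         consensus_cpg_index = consensus_cpg_index,
         consensus_bp = consensus_bp),
    class = "locus_reference"
  )
}

#' @export
print.locus_reference <- function(x, ...) {
  cat("<locus_reference> ", x$locus_id, " (", x$chromosome_class, "), ",
      nchar(x$sequence), " bp, ", length(x$cpg_positions), " CpGs",
      if (!is.null(x$consensus_cpg_index)) ", consensus-mapped" else "",
      "\n", sep = "")
  invisible(x)
}

#' Find CpG cytosine offsets in a sequence
#'
#' @param sequence DNA string.
#' @return Integer vector of 0-based offsets of the C of each "CG".
#' @export
find_cpg_sites <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Load a locus reference from FASTA (+ optional BED CpG track)
#'
#' The FASTA must contain exactly one record per call. If a BED file is
#' given, its intervals (0-based, half-open, length 1 or 2) mark the CpG
#' cytosines and are validated against the sequence; otherwise CpG
#' positions are found by scanning for "CG".
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param bed_path Optional path to a BED file of CpG positions.
#' @param chromosome_class `"autosomal"` or `"X_linked"`.
#' @return A [locus_reference()].
#' @export
load_reference <- function(fasta_path, bed_path = NULL,
                           chromosome_class = c("autosomal", "X_linked")) {
  chromosome_class <- match.arg(chromosome_class)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("expected exactly one FASTA record in '", fasta_path, "', found ",
         length(seqs))
  }
  locus_id <- sub("\\s.*$", "", names(seqs)[1L])
  sequence <- as.character(seqs[[1L]])
  cpg <- NULL
  if (!is.null(bed_path)) {
    gr <- rtracklayer::import(bed_path, format = "BED")
    w <- GenomicRanges::width(gr)
    if (any(w < 1L | w > 2L)) {
      stop("BED intervals for locus '", locus_id,
           "' must have length 1 or 2 (the CpG C or the CG dinucleotide)")
    }
    cpg <- sort(GenomicRanges::start(gr)) - 1L  # GRanges is 1-based
  }
  locus_reference(locus_id, sequence, cpg_positions = cpg,
                  chromosome_class = chromosome_class)
}

#' Write a locus reference as FASTA plus a BED CpG track
#'
#' @param ref A [locus_reference()].
#' @param fasta_path Output FASTA path.
#' @param bed_path Optional output BED path (0-based, half-open, width-1
#'   intervals at each CpG cytosine).
#' @return Invisibly, `ref`.
#' @export
write_reference <- function(ref, fasta_path, bed_path = NULL) {
  stopifnot(inherits(ref, "locus_reference"))
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$locus_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(
      seqnames = ref$locus_id,
      ranges = IRanges::IRanges(start = ref$cpg_positions + 1L, width = 1L)
    )
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  invisible(ref)
}

#' Read / write a locus -> consensus CpG map
#'
#' The map is a TSV with columns `locus_id`, `local_cpg_index` (1-based
#' index into the locus CpG list), `consensus_cpg_index`, and
#' `consensus_bp_position`.
#'
#' @param path TSV path.
#' @return `read_consensus_map`: a data.frame with the four columns above.
#' @export
read_consensus_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "local_cpg_index", "consensus_cpg_index",
            "consensus_bp_position")
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols)) {
    stop("consensus map is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  map
}

#' @rdname read_consensus_map
#' @param map Data.frame as returned by [read_consensus_map()].
#' @export
write_consensus_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map)
}

#' Attach a consensus map to locus references
#'
#' @param loci List of [locus_reference()] objects.
#' @param map Consensus map data.frame (see [read_consensus_map()]).
#' @return The list of references with `consensus_cpg_index` /
#'   `consensus_bp` filled in where the map covers them.
#' @export
apply_consensus_map <- function(loci, map) {
  lapply(loci, function(ref) {
    rows <- map[map$locus_id == ref$locus_id, , drop = FALSE]
    if (nrow(rows) == 0L) return(ref)
    rows <- rows[order(rows$local_cpg_index), , drop = FALSE]
    if (!all(rows$local_cpg_index %in% seq_along(ref$cpg_positions))) {
      stop("consensus map for locus '", ref$locus_id,
           "' names local CpG indices outside the locus CpG list")
    }
    if (nrow(rows) != length(ref$cpg_positions)) {
      stop("consensus map for locus '", ref$locus_id, "' covers ",
           nrow(rows), " of ", length(ref$cpg_positions), " CpGs; ",
           "a mapped locus must be fully mapped")
    }
    idx <- rows$consensus_cpg_index
    bp <- rows$consensus_bp_position
    locus_reference(ref$locus_id, ref$sequence, ref$cpg_positions,
                    ref$chromosome_class,
                    consensus_cpg_index = idx, consensus_bp = bp)
  })
}
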