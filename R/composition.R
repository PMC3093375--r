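# Nucleotide composition: GC content overall and by codon position.
#
# Compositional comparisons require homologous stretches, so sequences are
# first trimmed to a fixed number of ungapped bases from the 5' end of the
# barcode region. GC is computed over unambiguous bases only (gaps and
# IUPAC letters are excluded from numerator and denominator alike).

#' Trim a sequence for composition analysis
#'
#' @param sequence nucleotide string (gaps allowed)
#' @param length number of ungapped bases to keep from the 5' end
#'   (default 500)
#' @param offset 0-based number of ungapped bases to skip first (default 0)
#' @return The trimmed ungapped sequence; an error if fewer than
#'   \code{offset + length} ungapped bases are available (such records
#'   should have been removed by QC).
#' @export
trim_for_composition <- function(sequence, length = 500, offset = 0) {
  s <- strip_gaps(toupper(sequence))
  if (nchar(s) < offset + length) {
    stop("sequence has ", nchar(s), " ungapped bases; need ",
         offset + length)
  }
  substr(s, offset + 1L, offset + length)
}

#' GC content of a sequence
#'
#' @param sequence nucleotide string
#' @return Percent G+C over the unambiguous (A/C/G/T) bases; an error if no
#'   unambiguous base is present.
#' @export
gc_content <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1]]
  n_gc <- sum(v == "G" | v == "C")
  n_acgt <- sum(v %in% BASES)
  if (n_acgt == 0L) stop("no unambiguous bases")
  100 * n_gc / n_acgt
}

#' GC content by codon position
#'
#' Positions are assigned from the reading-frame offset; the trailing
#' partial codon is ignored.
#'
#' @param sequence gap-free nucleotide string
#' @param frame 0-based offset of codon position 1
#' @return Named numeric vector \code{c(gc1, gc2, gc3)} in percent.
#' @export
gc_by_codon_position <- function(sequence, frame = 0) {
  v <- strsplit(toupper(sequence), "")[[1]]
  if (frame > 0L) v <- v[-seq_len(frame)]
  n_codons <- length(v) %/% 3L
  if (n_codons == 0L) stop("no complete codon")
  v <- v[seq_len(3L * n_codons)]
  pos <- rep(1:3, n_codons)
  out <- vapply(1:3, function(p) {
    b <- v[pos == p]
    known <- b %in% BASES
    if (!any(known)) return(NA_real_)
    100 * sum(b[known] %in% c("G", "C")) / sum(known)
  }, numeric(1))
  stats::setNames(out, c("gc1", "gc2", "gc3"))
}

#' Pooled nucleotide frequencies of a dataset
#'
#' @param dataset a \code{\link{barcode_dataset}} (sequences are used as
#'   given; trim first if homology matters)
#' @return Named numeric vector of percent frequencies for T, C, A, G over
#'   pooled unambiguous bases (sums to 100).
#' @export
nucleotide_frequencies <- function(dataset) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  v <- unlist(strsplit(toupper(dataset$sequence), ""), use.names = FALSE)
  counts <- vapply(c("T", "C", "A", "G"), function(b) sum(v == b), numeric(1))
  if (sum(counts) == 0) stop("no unambiguous bases")
  100 * counts / sum(counts)
}

#' Composition table by taxonomic group
#'
#' Per group: min/mean/SE/max of per-sequence GC and mean/SE of GC at each
#' codon position, computed on sequences trimmed to \code{trim} ungapped
#' bases. Per-position GC is pooled within each sequence, then averaged
#' across sequences (SE over sequences). Rows are sorted by ascending mean
#' GC.
#'
#' @param dataset a \code{\link{barcode_dataset}}
#' @param group_by \code{"family"} or \code{"order"} (one pooled row)
#' @param trim ungapped bases kept per sequence (default 500); set
#'   \code{NULL} to use sequences as given
#' @param frames named integer vector of per-record 0-based frames; by
#'   default inferred via \code{\link{infer_reading_frame}}
#' @return Data frame with columns taxon, n_sequences, gc_min, gc_mean,
#'   gc_se, gc_max, gc1_mean, gc1_se, gc2_mean, gc2_se, gc3_mean, gc3_se.
#' @export
composition_table <- function(dataset, group_by = c("family", "order"),
                              trim = 500, frames = NULL) {
  group_by <- match.arg(group_by)
  seqs <- dataset$sequence
  if (!is.null(trim)) {
    seqs <- vapply(seqs, trim_for_composition, character(1), length = trim,
                   USE.NAMES = FALSE)
  } else {
    seqs <- vapply(seqs, strip_gaps, character(1), USE.NAMES = FALSE)
  }
  if (is.null(frames)) {
    frames <- vapply(seqs, function(s) infer_reading_frame(s)$frame,
                     integer(1), USE.NAMES = FALSE)
  } else {
    frames <- unname(frames[dataset$record_id])
  }
  gc <- vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE)
  by_pos <- t(vapply(seq_along(seqs),
                     function(i) gc_by_codon_position(seqs[i], frames[i]),
                     numeric(3)))
  groups <- if (group_by == "order") rep("all", nrow(dataset)) else
    dataset$family
  rows <- lapply(sort(unique(groups)), function(g) {
    in_g <- which(groups == g)
    data.frame(taxon = g, n_sequences = length(in_g),
               gc_min = min(gc[in_g]), gc_mean = mean(gc[in_g]),
               gc_se = se_mean(gc[in_g]), gc_max = max(gc[in_g]),
               gc1_mean = mean(by_pos[in_g, 1L]),
               gc1_se = se_mean(by_pos[in_g, 1L]),
               gc2_mean = mean(by_pos[in_g, 2L]),
               gc2_se = se_mean(by_pos[in_g, 2L]),
               gc3_mean = mean(by_pos[in_g, 3L]),
               gc3_se = se_mean(by_pos[in_g, 3L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$gc_mean), , drop = FALSE]
}
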