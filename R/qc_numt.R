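# Quality control and numt screening.
#
# COI barcodes are protein-coding mtDNA: a genuine mitochondrial copy
# translates without internal stop codons under the invertebrate
# mitochondrial genetic code (NCBI translation table 5), while nuclear
# pseudogene copies (numts) accumulate frame disruptions, stop codons and
# compositional shifts. The filters here mirror standard barcode-database
# curation: minimum length, stop codons, alignment indels, and three numt
# heuristics (excessive intraspecific distance, aberrant GC composition,
# unusually long terminal branches).

# NCBI translation table 5 (invertebrate mitochondrial):
# AGA/AGG = Ser, ATA = Met, TGA = Trp; stops are TAA and TAG only.
MITO_CODE_5 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "S", AGG = "S",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

QC_REASONS <- c("too_short", "stop_codon", "indel",
                "high_intraspecific", "aberrant_composition", "long_branch")

#' Translate a nucleotide sequence under the invertebrate mitochondrial code
#'
#' Uses NCBI translation table 5 (AGA/AGG = Ser, ATA = Met, TGA = Trp; TAA
#' and TAG are the only stops). The trailing partial codon, if any, is
#' dropped; stops are rendered \code{*}; codons containing a gap or IUPAC
#' ambiguity letter are rendered \code{X}.
#'
#' @param sequence nucleotide string
#' @param frame 0-based offset (0, 1 or 2) at which codon position 1 begins
#' @return Amino-acid string.
#' @export
translate_mt <- function(sequence, frame = 0) {
  stopifnot(frame %in% 0:2)
  s <- toupper(sequence)
  s <- substring(s, frame + 1L)
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codons)
  codons <- substring(s, starts, starts + 2L)
  aa <- MITO_CODE_5[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Infer the reading frame of a COI fragment
#'
#' Barcode fragments start at an arbitrary codon position, so the frame is
#' chosen as the offset whose translation has the fewest stop codons; ties go
#' to the smallest offset. A fragment with stops in every frame is flagged as
#' a stop-codon suspect (frame disruption is a classic numt signature).
#'
#' @param sequence nucleotide string; gaps are removed before translation
#' @return List with \code{frame} (0-based offset), \code{stop_counts}
#'   (stops in frames 0, 1, 2) and \code{flagged} (\code{TRUE} when the best
#'   frame still contains a stop).
#' @export
infer_reading_frame <- function(sequence) {
  s <- strip_gaps(toupper(sequence))
  if (nchar(s) < 9L) stop("sequence shorter than 9 ungapped bases")
  stops <- vapply(0:2, function(f) {
    sum(strsplit(translate_mt(s, f), "")[[1]] == "*")
  }, integer(1))
  frame <- which.min(stops) - 1L  # which.min takes the first (smallest offset)
  list(frame = frame, stop_counts = stops, flagged = stops[frame + 1L] > 0L)
}

#' Filter a dataset on sequence quality
#'
#' Removes records that are too short (fewer than \code{min_length} ungapped
#' bases), whose best reading frame still contains a stop codon, or that
#' carry interior gap characters (indels relative to the alignment). A record
#' failing several filters is tallied once, under the first applicable reason
#' in the order too_short, stop_codon, indel.
#'
#' @param dataset a \code{\link{barcode_dataset}}
#' @param min_length minimum ungapped length in bases (default 500)
#' @return List with \code{dataset} (the surviving records) and \code{report}
#'   (list with \code{kept} and the named count vector
#'   \code{removed_by_reason}; kept + removed equals the input size).
#' @export
qc_filter <- function(dataset, min_length = 500) {
  reasons <- rep(NA_character_, nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    s <- trim_terminal_gaps(dataset$sequence[i])
    ungapped <- strip_gaps(s)
    if (nchar(ungapped) < min_length) {
      reasons[i] <- "too_short"
    } else if (infer_reading_frame(ungapped)$flagged) {
      reasons[i] <- "stop_codon"
    } else if (grepl("-", s, fixed = TRUE)) {
      reasons[i] <- "indel"
    }
  }
  removed <- vapply(QC_REASONS, function(r) sum(reasons == r, na.rm = TRUE),
                    integer(1))
  kept <- dataset[is.na(reasons), , drop = FALSE]
  kept <- if (nrow(kept) > 0L) barcode_dataset(kept) else {
    structure(kept, class = c("barcode_dataset", "data.frame"))
  }
  list(dataset = kept,
       report = list(kept = nrow(kept), removed_by_reason = removed))
}

#' Flag putative numts and other suspect records
#'
#' Three heuristics, each a classic numt/misidentification signature:
#' \describe{
#'   \item{HIGH_INTRASPECIFIC}{any conspecific K2P distance above
#'     \code{max_intraspecific} (default 10\%);}
#'   \item{ABERRANT_COMPOSITION}{record GC\% deviating from its family mean
#'     by more than \code{gc_sd} family standard deviations (families with
#'     fewer than \code{min_family_n} records fall back to the dataset-wide
#'     mean/SD);}
#'   \item{LONG_BRANCH}{terminal branch on the NJ tree longer than
#'     \code{branch_factor} times the median terminal branch.}
#' }
#'
#' @param dataset a \code{\link{barcode_dataset}}
#' @param distance_matrix K2P matrix covering all records (fractions)
#' @param tree optional NJ tree (\code{phylo}); built from the matrix when
#'   \code{NULL} and at least 3 records are present
#' @param max_intraspecific,gc_sd,branch_factor,min_family_n thresholds, see
#'   above
#' @return Named list: record id -> character vector of flags (possibly
#'   empty).
#' @export
flag_numt_suspects <- function(dataset, distance_matrix, tree = NULL,
                               max_intraspecific = 0.10, gc_sd = 3,
                               branch_factor = 5, min_family_n = 5) {
  ids <- dataset$record_id
  absent <- setdiff(ids, rownames(distance_matrix))
  if (length(absent) > 0L) {
    stop("record(s) absent from distance matrix: ",
         paste(absent, collapse = ", "))
  }
  flags <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(flags)) flags[[i]] <- character(0)
  add <- function(id, flag) flags[[id]] <<- union(flags[[id]], flag)

  # HIGH_INTRASPECIFIC: both members of an offending conspecific pair.
  for (members in species_index(dataset)) {
    if (length(members) < 2L) next
    sub <- distance_matrix[members, members, drop = FALSE]
    hit <- which(sub > max_intraspecific, arr.ind = TRUE)
    for (id in unique(members[hit])) add(id, "HIGH_INTRASPECIFIC")
  }

  # ABERRANT_COMPOSITION against the family (or global) GC distribution.
  gc <- vapply(dataset$sequence, gc_content, numeric(1), USE.NAMES = FALSE)
  glob_mu <- mean(gc)
  glob_sd <- stats::sd(gc)
  fam <- dataset$family
  for (f in unique(fam[nzchar(fam)])) {
    in_f <- which(fam == f)
    if (length(in_f) >= min_family_n) {
      mu <- mean(gc[in_f]); sdev <- stats::sd(gc[in_f])
    } else {
      mu <- glob_mu; sdev <- glob_sd
    }
    if (is.na(sdev) || sdev == 0) next
    for (i in in_f[abs(gc[in_f] - mu) > gc_sd * sdev]) {
      add(ids[i], "ABERRANT_COMPOSITION")
    }
  }

  # LONG_BRANCH on the NJ tree. Saturated (undefined) K2P pairs typically
  # involve the very pseudogenes being screened for, so the screening tree
  # falls back to NJ* for incomplete matrices rather than failing.
  if (is.null(tree) && length(ids) >= 3L) {
    D <- distance_matrix[ids, ids, drop = FALSE]
    tree <- if (anyNA(D)) ape::njs(as.dist(D)) else build_nj(D)
  }
  if (!is.null(tree)) {
    tip_edge <- match(seq_along(tree$tip.label), tree$edge[, 2L])
    term <- tree$edge.length[tip_edge]
    med <- stats::median(term)
    if (med > 0) {
      long <- tree$tip.label[term > branch_factor * med]
      for (id in intersect(long, ids)) add(id, "LONG_BRANCH")
    }
  }
  flags
}

#' Count amino-acid differences between two aligned sequences
#'
#' Translates both sequences in the given frame and counts aligned residue
#' positions whose translations differ; positions rendered \code{X} in either
#' translation are excluded.
#'
#' @param sequence_a,sequence_b equal-length, gap-free nucleotide strings
#' @param frame shared 0-based reading-frame offset
#' @return Integer count of differing residues.
#' @export
amino_acid_diff <- function(sequence_a, sequence_b, frame = 0) {
  if (nchar(sequence_a) != nchar(sequence_b)) {
    stop("sequences differ in length")
  }
  a <- strsplit(translate_mt(sequence_a, frame), "")[[1]]
  b <- strsplit(translate_mt(sequence_b, frame), "")[[1]]
  ok <- a != "X" & b != "X"
  sum(a[ok] != b[ok])
}
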