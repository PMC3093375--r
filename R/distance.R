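# Kimura 2-parameter distances with pairwise deletion.
#
# The K2P model corrects observed divergence separately for transitions
# (A<->G, C<->T; proportion P) and transversions (proportion Q):
#   d = -1/2 * ln(1 - 2P - Q) - 1/4 * ln(1 - 2Q).
# Sites where either sequence carries a gap or ambiguity letter are excluded
# pair by pair (pairwise deletion), never column-wide. Distances are held
# internally as fractions (0.02 = 2%); report layers multiply by 100.

#' Count transition/transversion site differences between two sequences
#'
#' @param sequence_a,sequence_b aligned nucleotide strings of equal length
#' @return List with \code{L} (compared sites after pairwise deletion of
#'   gap/ambiguity positions), \code{P_count} (transitions) and
#'   \code{Q_count} (transversions).
#' @export
count_site_differences <- function(sequence_a, sequence_b) {
  if (nchar(sequence_a) != nchar(sequence_b)) {
    stop("sequences differ in aligned length")
  }
  a <- match(strsplit(toupper(sequence_a), "")[[1]], BASES)
  b <- match(strsplit(toupper(sequence_b), "")[[1]], BASES)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & ((a + b) %% 2L == 0L)  # {A,G} and {C,T} sum to even codes
  list(L = sum(ok), P_count = sum(ts), Q_count = sum(diff) - sum(ts))
}

#' Kimura 2-parameter distance from site counts
#'
#' @param site_counts list as returned by
#'   \code{\link{count_site_differences}}
#' @return Distance as a fraction, or \code{NA} when the divergence is
#'   outside the model's domain (saturated pair: a log argument is zero or
#'   negative).
#' @export
k2p_distance <- function(site_counts) {
  L <- site_counts$L
  if (is.null(L) || L <= 0) stop("L must be positive")
  P <- site_counts$P_count / L
  Q <- site_counts$Q_count / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for a dataset
#'
#' @param dataset a \code{\link{barcode_dataset}} whose sequences share one
#'   aligned length
#' @return Symmetric matrix of K2P fractions with zero diagonal, dimnames =
#'   record ids. Saturated pairs are \code{NA}; their ids are listed in the
#'   \code{undefined_pairs} attribute. A pair with zero comparable sites is
#'   an error naming the pair.
#' @export
distance_matrix <- function(dataset) {
  ids <- dataset$record_id
  n <- length(ids)
  S <- encode_seqs(dataset$sequence)  # sites x records
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  undef <- character(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      a <- S[, i]
      B <- S[, (i + 1L):n, drop = FALSE]
      ok <- !is.na(a) & !is.na(B)
      diff <- (B != a) & ok
      ts <- diff & ((B + a) %% 2L == 0L)
      ts[!ok] <- FALSE
      L <- colSums(ok)
      if (any(L == 0L)) {
        j <- (i:n)[-1L][which(L == 0L)[1L]]
        stop("no comparable sites for pair (", ids[i], ", ", ids[j], ")")
      }
      P <- colSums(ts) / L
      Q <- (colSums(diff) - colSums(ts)) / L
      w1 <- 1 - 2 * P - Q
      w2 <- 1 - 2 * Q
      d <- ifelse(w1 > 0 & w2 > 0, -0.5 * log(pmax(w1, 1e-300)) -
                    0.25 * log(pmax(w2, 1e-300)), NA_real_)
      if (anyNA(d)) {
        bad <- (i:n)[-1L][is.na(d)]
        undef <- c(undef, paste(ids[i], ids[bad], sep = ":"))
      }
      D[i, (i + 1L):n] <- d
      D[(i + 1L):n, i] <- d
    }
  }
  attr(D, "undefined_pairs") <- undef
  D
}

#' Transition/transversion ratio of a dataset
#'
#' R = (sum of transitional differences) / (sum of transversional
#' differences) over all record pairs, optionally restricted to one codon
#' position. Summing per-site discordances over pairs is equivalent to, and
#' much faster than, enumerating the pairs: a site with base counts
#' (nA, nC, nG, nT) contributes nA*nG + nC*nT transition pairs and
#' (nA+nG)*(nC+nT) transversion pairs.
#'
#' @param dataset a \code{\link{barcode_dataset}} with one aligned length
#' @param codon_position \code{"all"}, 1, 2 or 3; positions are assigned
#'   from \code{frame} (alignment-wide offset of codon position 1)
#' @param frame shared 0-based reading-frame offset (see
#'   \code{\link{infer_reading_frame}})
#' @return Ratio R, or \code{NA} when no transversions are observed.
#' @export
tstv_ratio <- function(dataset, codon_position = "all", frame = 0) {
  S <- encode_seqs(dataset$sequence)
  L <- nrow(S)
  if (!identical(codon_position, "all")) {
    pos <- as.integer(codon_position)
    stopifnot(pos %in% 1:3)
    site_pos <- ((seq_len(L) - 1L - frame) %% 3L) + 1L
    site_pos[seq_len(L) <= frame] <- NA_integer_
    S <- S[which(site_pos == pos), , drop = FALSE]
  }
  counts <- apply(S, 1L, function(row) tabulate(row, nbins = 4L))
  nA <- counts[1L, ]; nC <- counts[2L, ]; nG <- counts[3L, ]; nT <- counts[4L, ]
  ts <- sum(nA * nG + nC * nT)
  tv <- sum((nA + nG) * (nC + nT))
  if (tv == 0) return(NA_real_)
  ts / tv
}
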