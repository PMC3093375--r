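# Partitioning pairwise divergences by taxonomic rank.
#
# Every unordered record pair is assigned to exactly one rank by the deepest
# taxon the two records share: S (conspecific), G (congeneric
# heterospecific), F (confamilial heterogeneric) or O (different families
# within the order). The partition is exhaustive: |S|+|G|+|F|+|O| = C(n, 2).

RANKS <- c("S", "G", "F", "O")

#' Partition all record pairs by shared taxonomic rank
#'
#' @param dataset a \code{\link{barcode_dataset}}; every record must carry
#'   species, genus and family
#' @param distance_matrix K2P matrix covering the dataset (fractions)
#' @return List with \code{pairs}: data frame (id_a, id_b, rank, distance),
#'   one row per unordered pair with a defined distance; \code{counts}:
#'   named pair counts per rank including undefined pairs; and
#'   \code{n_undefined}: pairs excluded for undefined (saturated) distance.
#' @export
partition_pairs <- function(dataset, distance_matrix) {
  miss <- !nzchar(dataset$species) | !nzchar(dataset$genus) |
    !nzchar(dataset$family)
  if (any(miss)) {
    stop("record(s) without full classification: ",
         paste(dataset$record_id[miss], collapse = ", "))
  }
  ids <- dataset$record_id
  n <- length(ids)
  if (n < 2L) {
    return(list(pairs = data.frame(id_a = character(0), id_b = character(0),
                                   rank = character(0), distance = numeric(0)),
                counts = stats::setNames(rep(0L, 4L), RANKS), n_undefined = 0L))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  rank <- ifelse(dataset$species[i] == dataset$species[j], "S",
          ifelse(dataset$genus[i] == dataset$genus[j], "G",
          ifelse(dataset$family[i] == dataset$family[j], "F", "O")))
  d <- distance_matrix[ids, ids][cbind(i, j)]
  counts <- vapply(RANKS, function(r) sum(rank == r), integer(1))
  keep <- !is.na(d)
  pairs <- data.frame(id_a = ids[i][keep], id_b = ids[j][keep],
                      rank = rank[keep], distance = d[keep],
                      stringsAsFactors = FALSE)
  list(pairs = pairs, counts = counts, n_undefined = sum(!keep))
}

#' Summary statistics for a set of pairwise divergences
#'
#' Minimum, mean, maximum and standard error of the mean, reported in
#' percent. The SE is computed over pairwise comparisons; pairs sharing a
#' record are not independent, so the SE is descriptive only.
#'
#' @param distances numeric vector of distances as fractions
#' @return List with \code{n_comparisons}, \code{min}, \code{mean},
#'   \code{se}, \code{max} (all but the count in percent).
#' @export
summarize_divergence <- function(distances) {
  if (length(distances) == 0L) stop("no comparisons to summarize")
  pct <- 100 * distances
  list(n_comparisons = length(pct), min = min(pct), mean = mean(pct),
       se = se_mean(pct), max = max(pct))
}

#' Rank summary table for a dataset
#'
#' One row per taxonomic rank present (S, G, F, O), mirroring the layout of
#' order-level divergence tables in barcoding studies.
#'
#' @inheritParams partition_pairs
#' @return Data frame with columns rank, n_comparisons, min, mean, se, max
#'   (percent).
#' @export
rank_summary_table <- function(dataset, distance_matrix) {
  part <- partition_pairs(dataset, distance_matrix)
  rows <- lapply(RANKS, function(r) {
    d <- part$pairs$distance[part$pairs$rank == r]
    if (length(d) == 0L) return(NULL)
    s <- summarize_divergence(d)
    data.frame(rank = r, n_comparisons = s$n_comparisons, min = s$min,
               mean = s$mean, se = s$se, max = s$max,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-family divergence summaries
#'
#' Restricts the comparison to well-sampled families: at least
#' \code{min_sequences} records and at least \code{min_species} species.
#' Within each qualifying family, S/G/F summaries are computed from the
#' family's own pairs; ranks without pairs (a single-genus family has no F
#' pairs) are absent from the output.
#'
#' @inheritParams partition_pairs
#' @param min_sequences minimum records per family (default 50)
#' @param min_species minimum species per family (default 6, i.e. more than
#'   5 species)
#' @return Data frame with columns family, rank, n_comparisons, min, mean,
#'   se, max (percent), plus per-family record/species/genus counts.
#' @export
family_summaries <- function(dataset, distance_matrix, min_sequences = 50,
                             min_species = 6) {
  rows <- list()
  for (f in sort(unique(dataset$family[nzchar(dataset$family)]))) {
    sub <- dataset[dataset$family == f, , drop = FALSE]
    n_sp <- length(unique(sub$species))
    if (nrow(sub) < min_sequences || n_sp < min_species) next
    sub <- barcode_dataset(sub)
    part <- partition_pairs(sub, distance_matrix)
    for (r in c("S", "G", "F")) {
      d <- part$pairs$distance[part$pairs$rank == r]
      if (length(d) == 0L) next
      s <- summarize_divergence(d)
      rows[[length(rows) + 1L]] <-
        data.frame(family = f, rank = r, n_sequences = nrow(sub),
                   n_species = n_sp, n_genera = length(unique(sub$genus)),
                   n_comparisons = s$n_comparisons, min = s$min,
                   mean = s$mean, se = s$se, max = s$max,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(family = character(0), rank = character(0),
                      n_sequences = integer(0), n_species = integer(0),
                      n_genera = integer(0), n_comparisons = integer(0),
                      min = numeric(0), mean = numeric(0), se = numeric(0),
                      max = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank test across divergence distributions
#'
#' Wraps \code{stats::kruskal.test} (H statistic with tie correction, p from
#' the chi-square approximation with k - 1 degrees of freedom). When every
#' value in every group is identical the statistic is 0 and p is 1 by
#' convention (the chi-square approximation is undefined under total ties).
#'
#' @param groups list of at least two non-empty numeric vectors
#' @return List with \code{H}, \code{df} and \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    stop("need at least two non-empty groups")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
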