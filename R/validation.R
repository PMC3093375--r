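# Data validation: subsampling, threshold clustering, anomaly flagging and
# the raw-vs-taxon-weighted sampling-bias test suite.
#
# Two artefacts can bias an intraspecific divergence assessment: unequal
# representation of taxa (heavily sampled species dominate the raw pairwise
# distribution) and incorrect taxonomy (cryptic or non-monophyletic
# species). The tools here cap records per species, delimit 2%-threshold
# MOTU clusters, flag problem species from clusters + tree, and compare four
# intraspecific-distance distributions: A (full) / B (flagged species
# removed) crossed with R (raw pairwise values) / M (one mean per species).

SPECIES_FLAGS <- c("CRYPTIC", "NON_MONOPHYLETIC", "LOW_CONGENERIC")

#' Cap the number of records per species
#'
#' Species with more than \code{max_per_species} records are uniformly
#' subsampled without replacement; smaller species are untouched. Draws are
#' made in species label order from a private RNG stream, so the result is
#' deterministic given the seed and leaves the caller's RNG untouched.
#'
#' @param dataset a \code{\link{barcode_dataset}}
#' @param max_per_species cap (default 10)
#' @param seed integer seed for the subsampling draws
#' @return A \code{barcode_dataset} in original record order.
#' @export
subsample_per_species <- function(dataset, max_per_species = 10, seed) {
  if (missing(seed)) stop("a seed is required for reproducible subsampling")
  idx <- species_index(dataset)
  keep <- with_rng(seed, {
    unlist(lapply(sort(names(idx)), function(sp) {
      ids <- idx[[sp]]
      if (length(ids) <= max_per_species) ids
      else sample(ids, max_per_species)
    }), use.names = FALSE)
  })
  keep <- c(keep, dataset$record_id[!nzchar(dataset$species)])
  subset_records(dataset, dataset$record_id[dataset$record_id %in% keep])
}

#' Single-linkage threshold clusters (MOTUs)
#'
#' Records i and j belong to one cluster iff a chain of records connects
#' them with every consecutive distance strictly below the threshold -
#' connected components of the sub-threshold graph, the usual MOTU
#' convention.
#'
#' @param distance_matrix symmetric distance matrix (fractions), no
#'   \code{NA} among clustered records
#' @param threshold strict upper bound on linking distances (default 0.02)
#' @return List of character vectors of record ids, in order of first
#'   appearance.
#' @export
threshold_clusters <- function(distance_matrix, threshold = 0.02) {
  D <- as.matrix(distance_matrix)
  ids <- rownames(D)
  n <- nrow(D)
  comp <- integer(n)
  current <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    current <- current + 1L
    queue <- s
    comp[s] <- current
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(D[v, ] < threshold & comp == 0L)
      comp[nb] <- current
      queue <- c(queue, nb)
    }
  }
  lapply(seq_len(current), function(k) ids[comp == k])
}

#' Flag taxonomically suspect species
#'
#' \describe{
#'   \item{CRYPTIC}{the species' records occupy two or more threshold
#'     clusters (a deep intraspecific split);}
#'   \item{NON_MONOPHYLETIC}{the species' leaves do not form an exclusive
#'     clade on the rooted tree;}
#'   \item{LOW_CONGENERIC}{some heterospecific congeneric pair involving the
#'     species lies strictly below the threshold.}
#' }
#'
#' @param dataset a \code{\link{barcode_dataset}}
#' @param distance_matrix K2P matrix covering the dataset
#' @param rooted_tree rooted \code{phylo} whose tips are the record ids
#' @param threshold divergence threshold as a fraction (default 0.02)
#' @return Named list: species -> character vector of flags; species
#'   without flags are absent.
#' @export
flag_problem_species <- function(dataset, distance_matrix, rooted_tree,
                                 threshold = 0.02) {
  ids <- dataset$record_id
  D <- as.matrix(distance_matrix)[ids, ids]
  clusters <- threshold_clusters(D, threshold)
  cl_of <- stats::setNames(rep(seq_along(clusters), lengths(clusters)),
                           unlist(clusters))
  flags <- list()
  add <- function(sp, flag) flags[[sp]] <<- union(flags[[sp]], flag)
  sp_idx <- species_index(dataset)
  for (sp in names(sp_idx)) {
    members <- sp_idx[[sp]]
    if (length(unique(cl_of[members])) >= 2L) add(sp, "CRYPTIC")
    if (!is_monophyletic(rooted_tree, members)) add(sp, "NON_MONOPHYLETIC")
  }
  # LOW_CONGENERIC: heterospecific congeneric pair below threshold.
  for (g in unique(dataset$genus[nzchar(dataset$genus)])) {
    sub <- dataset[dataset$genus == g, , drop = FALSE]
    if (length(unique(sub$species)) < 2L) next
    gi <- sub$record_id
    Dg <- D[gi, gi, drop = FALSE]
    hetero <- outer(sub$species, sub$species, "!=")
    low <- which(hetero & Dg < threshold, arr.ind = TRUE)
    for (sp in unique(sub$species[low])) add(sp, "LOW_CONGENERIC")
  }
  flags
}

#' Build the four intraspecific-distance variants
#'
#' A = the full dataset, B = the dataset with all flagged species' records
#' removed; R = every conspecific pairwise distance, M = one mean
#' intraspecific distance per multi-record species. Values are in percent.
#'
#' @param dataset a \code{\link{barcode_dataset}}
#' @param distance_matrix K2P matrix covering the dataset
#' @param flags species flags from \code{\link{flag_problem_species}}
#' @return List with elements \code{A_R}, \code{A_M}, \code{B_R},
#'   \code{B_M} (numeric vectors, percent) and \code{B_dataset} (the
#'   validated dataset).
#' @export
make_variants <- function(dataset, distance_matrix, flags) {
  intraspecific <- function(ds) {
    idx <- species_index(ds)
    raw <- list(); means <- numeric(0)
    for (sp in sort(names(idx))) {
      members <- idx[[sp]]
      if (length(members) < 2L) next
      sub <- as.matrix(distance_matrix)[members, members]
      vals <- 100 * sub[upper.tri(sub)]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) next
      raw[[sp]] <- vals
      means <- c(means, mean(vals))
    }
    list(R = unlist(raw, use.names = FALSE), M = means)
  }
  flagged <- names(flags)[lengths(flags) > 0L]
  b_ds <- dataset[!(dataset$species %in% flagged), , drop = FALSE]
  if (nrow(b_ds) == 0L) stop("removing flagged species empties the dataset")
  b_ds <- barcode_dataset(b_ds)
  a <- intraspecific(dataset)
  b <- intraspecific(b_ds)
  list(A_R = a$R, A_M = a$M, B_R = b$R, B_M = b$M, B_dataset = b_ds)
}

#' Mann-Whitney U test
#'
#' U is reported as min(U_x, U_y). The p value is exact (enumeration) when
#' n_x + n_y <= 12 and there are no ties, otherwise the normal approximation
#' with tie and continuity correction is used - both via
#' \code{stats::wilcox.test}.
#'
#' @param x,y non-empty numeric vectors
#' @return List with \code{U} and two-sided \code{p}.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 12L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  u_x <- unname(wt$statistic)
  u_y <- length(x) * length(y) - u_x
  list(U = min(u_x, u_y), p = wt$p.value)
}

#' Sampling-bias report over the four dataset variants
#'
#' Runs the four Mann-Whitney comparisons (A_R vs B_R, A_M vs B_M, A_R vs
#' A_M, B_R vs B_M) and reports, per variant, the fraction of intraspecific
#' distances strictly below 3\%. No verdict is hardcoded: p values are
#' returned alongside \code{alpha} for the caller, and no multiplicity
#' correction is applied across the four tests.
#'
#' @param variants list from \code{\link{make_variants}}
#' @param alpha nominal significance level carried through to the report
#' @return List with \code{comparisons} (data frame: comparison, U, p),
#'   \code{freq_below_3pct} (named numeric) and \code{alpha}.
#' @export
bias_report <- function(variants, alpha = 0.05) {
  pairs <- list(c("A_R", "B_R"), c("A_M", "B_M"),
                c("A_R", "A_M"), c("B_R", "B_M"))
  rows <- lapply(pairs, function(pr) {
    mw <- mann_whitney(variants[[pr[1L]]], variants[[pr[2L]]])
    data.frame(comparison = paste(pr, collapse = " vs "),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  freq <- vapply(c("A_R", "A_M", "B_R", "B_M"), function(v) {
    mean(variants[[v]] < 3)
  }, numeric(1))
  list(comparisons = do.call(rbind, rows), freq_below_3pct = freq,
       alpha = alpha)
}

#' Identification success under a divergence threshold
#'
#' Fraction of multi-record species whose intraspecific divergence stays
#' within the threshold: in \code{raw} mode the maximum, in \code{mean} mode
#' the mean, intraspecific distance must be at most the threshold.
#'
#' @param dataset a \code{\link{barcode_dataset}} with at least one
#'   multi-record species
#' @param distance_matrix K2P matrix covering the dataset
#' @param threshold fraction (default 0.02)
#' @param mode \code{"raw"} or \code{"mean"}
#' @return Fraction in [0, 1].
#' @export
identification_success <- function(dataset, distance_matrix,
                                   threshold = 0.02, mode = c("raw", "mean")) {
  mode <- match.arg(mode)
  idx <- species_index(dataset)
  idx <- idx[lengths(idx) >= 2L]
  if (length(idx) == 0L) stop("no multi-record species")
  ok <- vapply(idx, function(members) {
    sub <- as.matrix(distance_matrix)[members, members]
    vals <- sub[upper.tri(sub)]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA)
    stat <- if (mode == "raw") max(vals) else mean(vals)
    stat <= threshold
  }, logical(1))
  mean(ok, na.rm = TRUE)
}
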