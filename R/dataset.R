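#' Construct a barcode dataset
#'
#' A \code{barcode_dataset} is the unit every analysis function in the package
#' consumes: an ordered table of COI barcode records, each carrying a unique
#' record id, an optional accession, a species/genus/family assignment and an
#' upper-case nucleotide sequence (gaps \code{-} and IUPAC ambiguity letters
#' are retained and handled by pairwise deletion at comparison time).
#'
#' @param records data frame with columns \code{record_id}, \code{accession},
#'   \code{species}, \code{genus}, \code{family}, \code{sequence} and
#'   optionally \code{source}. Missing \code{accession}/\code{source} columns
#'   are filled with empty strings.
#' @return An object of class \code{barcode_dataset}: the record data frame
#'   (row order preserved as given) with rank indexes available through
#'   \code{\link{species_index}} and friends.
#' @details Validity rules enforced here: record ids unique; sequences
#'   non-empty; every record with a species has non-empty genus and family;
#'   and the species -> (genus, family) mapping is functional (a species
#'   string may not map to two different genera or families).
#' @export
barcode_dataset <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("record_id", "species", "genus", "family", "sequence")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(records$accession)) records$accession <- ""
  if (is.null(records$source)) records$source <- ""
  records <- records[, c("record_id", "accession", "species", "genus",
                         "family", "sequence", "source")]
  for (col in names(records)) records[[col]] <- as.character(records[[col]])
  records$sequence <- toupper(records$sequence)

  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0L) {
    stop("duplicate record_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(records$sequence))) {
    stop("empty sequence for record(s): ",
         paste(records$record_id[!nzchar(records$sequence)], collapse = ", "))
  }
  has_sp <- nzchar(records$species)
  bad <- has_sp & (!nzchar(records$genus) | !nzchar(records$family))
  if (any(bad)) {
    stop("species without genus/family for record(s): ",
         paste(records$record_id[bad], collapse = ", "))
  }
  map <- unique(records[has_sp, c("species", "genus", "family")])
  dup_sp <- map$species[duplicated(map$species)]
  if (length(dup_sp) > 0L) {
    stop("species mapped to more than one (genus, family): ",
         paste(unique(dup_sp), collapse = ", "))
  }
  rownames(records) <- NULL
  structure(records, class = c("barcode_dataset", "data.frame"))
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("barcode_dataset: %d records, %d species, %d genera, %d families\n",
              nrow(x), length(unique(x$species[nzchar(x$species)])),
              length(unique(x$genus[nzchar(x$genus)])),
              length(unique(x$family[nzchar(x$family)]))))
  print(utils::head(as.data.frame(x)[, c("record_id", "species", "genus", "family")]))
  invisible(x)
}

#' Rank indexes of a dataset
#'
#' Record ids grouped by species, genus or family. Groups partition the
#' records carrying a non-empty label at that rank.
#'
#' @param dataset a \code{\link{barcode_dataset}}
#' @return Named list of character vectors of record ids.
#' @export
species_index <- function(dataset) {
  keep <- nzchar(dataset$species)
  split(dataset$record_id[keep], dataset$species[keep])
}

#' @rdname species_index
#' @export
genus_index <- function(dataset) {
  keep <- nzchar(dataset$genus)
  split(dataset$record_id[keep], dataset$genus[keep])
}

#' @rdname species_index
#' @export
family_index <- function(dataset) {
  keep <- nzchar(dataset$family)
  split(dataset$record_id[keep], dataset$family[keep])
}

#' Subset a dataset by record id
#'
#' @param dataset a \code{\link{barcode_dataset}}
#' @param record_ids ids to keep, in dataset order
#' @return A \code{barcode_dataset} with the matching records.
#' @export
subset_records <- function(dataset, record_ids) {
  unknown <- setdiff(record_ids, dataset$record_id)
  if (length(unknown) > 0L) {
    stop("unknown record id(s): ", paste(unknown, collapse = ", "))
  }
  barcode_dataset(dataset[dataset$record_id %in% record_ids, , drop = FALSE])
}
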