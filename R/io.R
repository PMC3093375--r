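#' Read a barcode dataset from FASTA plus a taxonomy table
#'
#' Sequences come from a FASTA file; taxonomic assignments come from a
#' sidecar tab-separated table with header
#' \code{record_id<TAB>accession<TAB>species<TAB>genus<TAB>family}.
#' As a fallback dialect, FASTA headers of the form
#' \code{record_id|species|genus|family} are accepted when no taxonomy file
#' is given.
#'
#' @param fasta_file path to a FASTA file
#' @param taxonomy_file path to the taxonomy TSV, or \code{NULL} to parse
#'   pipe-delimited FASTA headers instead
#' @return A \code{\link{barcode_dataset}}, one record per FASTA entry, in
#'   file order, sequences upper-cased.
#' @export
read_fasta_with_taxonomy <- function(fasta_file, taxonomy_file = NULL) {
  dna <- ape::read.FASTA(fasta_file)
  ids <- names(dna)
  seqs <- vapply(as.character(dna), function(x) paste(toupper(x), collapse = ""),
                 character(1))
  if (is.null(taxonomy_file)) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    if (any(lengths(parts) != 4L)) {
      stop("no taxonomy file given and FASTA headers are not ",
           "'record_id|species|genus|family'")
    }
    tax <- data.frame(record_id = vapply(parts, `[`, "", 1L),
                      accession = "",
                      species = vapply(parts, `[`, "", 2L),
                      genus = vapply(parts, `[`, "", 3L),
                      family = vapply(parts, `[`, "", 4L),
                      stringsAsFactors = FALSE)
    ids <- tax$record_id
  } else {
    tax <- utils::read.delim(taxonomy_file, sep = "\t", quote = "",
                             colClasses = "character")
    needed <- c("record_id", "species", "genus", "family")
    missing_cols <- setdiff(needed, names(tax))
    if (length(missing_cols) > 0L) {
      stop("taxonomy table lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    if (is.null(tax$accession)) tax$accession <- ""
  }
  if (any(duplicated(ids))) {
    stop("duplicate record_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  hit <- match(ids, tax$record_id)
  if (anyNA(hit)) {
    stop("FASTA id(s) absent from taxonomy table: ",
         paste(ids[is.na(hit)], collapse = ", "))
  }
  tax <- tax[hit, , drop = FALSE]
  barcode_dataset(data.frame(record_id = ids,
                             accession = tax$accession,
                             species = tax$species,
                             genus = tax$genus,
                             family = tax$family,
                             sequence = seqs,
                             source = "file",
                             stringsAsFactors = FALSE))
}

#' Read a BOLD-style specimen TSV export
#'
#' Rows without a species-level assignment are skipped (and counted), since a
#' barcode without a species label cannot enter rank-partitioned analyses.
#'
#' @param tsv_file path to a tab-separated export with a header row
#' @param col_map named character vector mapping the dataset fields
#'   \code{record_id}, \code{accession}, \code{species}, \code{genus},
#'   \code{family}, \code{sequence} to column names in the file. The default
#'   covers the common BOLD column names.
#' @return A \code{\link{barcode_dataset}} with attribute \code{skipped}
#'   giving the number of rows dropped for lacking a species assignment.
#' @export
read_bold_tsv <- function(tsv_file,
                          col_map = c(record_id = "processid",
                                      accession = "genbank_accession",
                                      species = "species_name",
                                      genus = "genus_name",
                                      family = "family_name",
                                      sequence = "nucleotides")) {
  first <- readLines(tsv_file, n = 1L)
  if (length(first) == 0L || !nzchar(first)) stop("no header in ", tsv_file)
  tab <- utils::read.delim(tsv_file, sep = "\t", quote = "",
                           colClasses = "character")
  mandatory <- c("record_id", "species", "genus", "family", "sequence")
  want <- col_map[mandatory]
  absent <- want[!want %in% names(tab)]
  if (length(absent) > 0L) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  }
  get_col <- function(field) {
    col <- col_map[[field]]
    if (!is.null(col) && col %in% names(tab)) tab[[col]] else rep("", nrow(tab))
  }
  rec <- data.frame(record_id = get_col("record_id"),
                    accession = get_col("accession"),
                    species = get_col("species"),
                    genus = get_col("genus"),
                    family = get_col("family"),
                    sequence = get_col("sequence"),
                    source = rep("bold", nrow(tab)),
                    stringsAsFactors = FALSE)
  keep <- nzchar(trimws(rec$species))
  skipped <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  out <- if (nrow(rec) > 0L) barcode_dataset(rec) else {
    structure(rec, class = c("barcode_dataset", "data.frame"))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a dataset as FASTA plus taxonomy TSV
#'
#' Round-trips with \code{\link{read_fasta_with_taxonomy}}: reading the two
#' files back yields the same records in the same order.
#'
#' @param dataset a non-empty \code{\link{barcode_dataset}}
#' @param fasta_file,taxonomy_file output paths
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, fasta_file, taxonomy_file) {
  if (nrow(dataset) == 0L) stop("refusing to write an empty dataset")
  con <- file(fasta_file, "w")
  on.exit(close(con))
  writeLines(paste0(">", dataset$record_id, "\n", dataset$sequence), con)
  tax <- as.data.frame(dataset)[, c("record_id", "accession", "species",
                                    "genus", "family")]
  utils::write.table(tax, taxonomy_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}
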