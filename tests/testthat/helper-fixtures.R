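# Small in-code fixtures shared across test files.

# A hand-built dataset: 2 genera in one family plus a second family.
toy_dataset <- function() {
  barcode_dataset(data.frame(
    record_id = c("a1", "a2", "b1", "b2", "c1"),
    accession = "",
    species = c("Aus alpha", "Aus alpha", "Aus beta", "Aus beta",
                "Cus gamma"),
    genus = c("Aus", "Aus", "Aus", "Aus", "Cus"),
    family = c("Aidae", "Aidae", "Aidae", "Aidae", "Cidae"),
    sequence = c("ATGAAACCCGGG", "ATGAAACCCGGA", "ATGAAACCCTTT",
                 "ATGAAACCCTTA", "ATGTTTAACGGG"),
    source = "test",
    stringsAsFactors = FALSE))
}

# Random dataset with arbitrary (non-phylogenetic) sequences; fast, for
# structural/property tests that do not need realistic divergences.
random_dataset <- function(n_records = 20, seq_len = 60) {
  n_sp <- max(2L, n_records %/% 3L)
  sp <- sprintf("G%02d s%02d", ((seq_len(n_sp) - 1L) %/% 2L) + 1L,
                seq_len(n_sp))
  pick <- sort(sample.int(n_sp, n_records, replace = TRUE))
  gen <- sub(" .*", "", sp)
  fam <- paste0("F", (match(gen, unique(gen)) - 1L) %/% 2L + 1L)
  barcode_dataset(data.frame(
    record_id = sprintf("r%03d", seq_len(n_records)),
    accession = "",
    species = sp[pick], genus = gen[pick], family = fam[pick],
    sequence = vapply(seq_len(n_records), function(i)
      paste(sample(c("A", "C", "G", "T"), seq_len, replace = TRUE),
            collapse = ""), character(1)),
    source = "test", stringsAsFactors = FALSE))
}

# Random rooted binary tree with positive branch lengths; its cophenetic
# matrix is additive by construction.
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0.05, 1))
  list(tree = tr, D = stats::cophenetic(tr))
}

# A small clean simulated dataset reused by several files.
small_sim <- function(seed = 101, ...) {
  spec <- sim_spec(n_families = 2, genera_per_family = 2,
                   species_per_genus = 2, records_per_species = 3,
                   p_cryptic = 0, p_merge = 0, p_numt = 0, ...)
  simulate_dataset(spec, seed)
}
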