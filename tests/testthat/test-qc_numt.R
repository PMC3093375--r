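test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(translate_mt("ATGTTT"), "MF")
  # table-5 departures from the standard code
  expect_equal(translate_mt("AGAAGG"), "SS")  # Ser, not Arg/stop
  expect_equal(translate_mt("ATA"), "M")      # Met, not Ile
  expect_equal(translate_mt("TGA"), "W")      # Trp, not stop
  expect_equal(translate_mt("TAATAG"), "**")
  expect_equal(translate_mt("ATNGGG"), "XG")  # ambiguity -> X
  expect_equal(translate_mt("ATGTT"), "M")    # trailing partial codon dropped
  expect_equal(translate_mt("GATGTTT", frame = 1), "MF")
})

test_that("reading-frame inference picks the minimal-stop frame", {
  # codon-aware simulated sequences are stop-free in frame 0
  sim <- small_sim()
  for (s in sim$dataset$sequence[1:5]) {
    fr <- infer_reading_frame(s)
    expect_equal(fr$frame, 0L)
    expect_equal(fr$stop_counts[1], 0L)
    expect_false(fr$flagged)
  }
  # a TAA tiling is rescued by frame 1 (AAT AAT ...): not flagged
  rescued <- infer_reading_frame("TAATAATAA")
  expect_false(rescued$flagged)
  expect_equal(rescued$frame, 1L)
  expect_equal(rescued$stop_counts, c(3L, 0L, 0L))
  # a 12-mer with a stop in every frame stays flagged, tie -> frame 0
  all_stop <- infer_reading_frame("TAAATAAATAAT")
  expect_true(all_stop$flagged)
  expect_equal(all_stop$frame, 0L)
  expect_true(all(all_stop$stop_counts >= 1L))
  # tie on all-zero stop counts resolves to frame 0
  expect_equal(infer_reading_frame("AAAAAAAAA")$frame, 0L)
})

test_that("qc_filter removes short, stop-bearing and gapped records once each", {
  sim <- small_sim()
  ds <- as.data.frame(sim$dataset)
  ds$record_id <- paste0(ds$record_id, "q")
  ds$sequence[1] <- substr(ds$sequence[1], 1, 499)           # too short
  ds$sequence[2] <- paste(rep("TAAATAAATAAT", 50), collapse = "")  # stops in all frames
  ds$sequence[3] <- paste0(substr(ds$sequence[3], 1, 300), "---",
                           substring(ds$sequence[3], 304))   # interior gap
  res <- qc_filter(barcode_dataset(ds), min_length = 500)
  r <- res$report$removed_by_reason
  expect_equal(unname(r[c("too_short", "stop_codon", "indel")]), c(1L, 1L, 1L))
  expect_equal(res$report$kept + sum(r), nrow(ds))
  expect_false(any(c(paste0(ds$record_id[1:3])) %in% res$dataset$record_id))

  # boundary: exactly min_length - 1 clean bases is too short
  one <- barcode_dataset(data.frame(
    record_id = "x", accession = "", species = "S a", genus = "S",
    family = "F", sequence = paste(rep("A", 499), collapse = ""),
    source = ""))
  expect_equal(unname(qc_filter(one)$report$removed_by_reason["too_short"]), 1L)
})

test_that("qc report conserves record counts on random datasets", {
  set.seed(42)
  for (i in 1:15) {
    ds <- random_dataset(n_records = sample(4:20, 1), seq_len = 30)
    res <- qc_filter(ds, min_length = 9)
    expect_equal(res$report$kept + sum(res$report$removed_by_reason), nrow(ds))
  }
})

test_that("amino-acid difference counting excludes ambiguous positions", {
  expect_equal(amino_acid_diff("ATGTTTGGG", "ATGTTTGGG"), 0L)
  expect_equal(amino_acid_diff("ATGTTTGGG", "ATGCTTGGG"), 1L)  # F -> L
  # synonymous third-position change
  expect_equal(amino_acid_diff("ATGTTTGGG", "ATGTTCGGG"), 0L)
  # ambiguity excluded, not counted as difference
  expect_equal(amino_acid_diff("ATGTTTGGG", "ATGTNTGGG"), 0L)
  expect_error(amino_acid_diff("ATG", "ATGTTT"), "length")
})

test_that("conspecific records above the distance ceiling are flagged", {
  sim <- small_sim()
  ds <- sim$dataset
  D <- distance_matrix(ds)
  sp1 <- ds$species[1]
  members <- ds$record_id[ds$species == sp1]
  D[members[1], members[2]] <- D[members[2], members[1]] <- 0.12
  flags <- flag_numt_suspects(ds, D)
  expect_true("HIGH_INTRASPECIFIC" %in% flags[[members[1]]])
  expect_true("HIGH_INTRASPECIFIC" %in% flags[[members[2]]])
  expect_error(flag_numt_suspects(ds[-1, ] , D[-1, -1]), NA)
  expect_error(flag_numt_suspects(ds, D[-1, -1]), "absent")
})

test_that("clean simulated datasets carry no composition or branch flags", {
  sim <- small_sim(seed = 77)
  D <- distance_matrix(sim$dataset)
  flags <- flag_numt_suspects(sim$dataset, D)
  expect_false(any(unlist(flags) %in%
                     c("ABERRANT_COMPOSITION", "HIGH_INTRASPECIFIC")))
})

test_that("injected numts are recovered by stop/composition/branch screens", {
  hits <- 0L; total <- 0L; false_pos <- 0L; clean_total <- 0L
  for (seed in 1:10) {
    spec <- sim_spec(n_families = 3, genera_per_family = 2,
                     species_per_genus = 2, records_per_species = 4,
                     p_cryptic = 0, p_merge = 0, p_numt = 0.08)
    sim <- simulate_dataset(spec, 1000 + seed)
    numts <- sim$truth$numt_records
    qc <- qc_filter(sim$dataset)
    removed_stop <- setdiff(sim$dataset$record_id, qc$dataset$record_id)
    detected <- removed_stop
    if (nrow(qc$dataset) >= 3L) {
      D <- distance_matrix(qc$dataset)
      fl <- flag_numt_suspects(qc$dataset, D)
      detected <- union(detected, names(fl)[vapply(fl, function(f)
        "ABERRANT_COMPOSITION" %in% f, TRUE)])
    }
    hits <- hits + length(intersect(numts, detected))
    total <- total + length(numts)
    clean <- setdiff(sim$dataset$record_id, numts)
    false_pos <- false_pos + length(intersect(clean, detected))
    clean_total <- clean_total + length(clean)
  }
  expect_gte(hits / total, 0.9)
  expect_lte(false_pos / clean_total, 0.05)
})
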