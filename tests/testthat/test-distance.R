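test_that("site differences use pairwise deletion and the standard ts/tv split", {
  expect_equal(count_site_differences("ACGT", "ACGT"),
               list(L = 4L, P_count = 0L, Q_count = 0L))
  expect_equal(count_site_differences("AG", "GG"),
               list(L = 2L, P_count = 1L, Q_count = 0L))
  expect_equal(count_site_differences("ACGTN", "ACGTA"),
               list(L = 4L, P_count = 0L, Q_count = 0L))
  expect_equal(count_site_differences("A-GT", "ACGT")$L, 3L)
  expect_equal(count_site_differences("ACTT", "ACGA"),
               list(L = 4L, P_count = 0L, Q_count = 2L))
  expect_error(count_site_differences("ACG", "ACGT"), "length")
  expect_error(count_site_differences("NNN", "ACG"), "comparable")
})

test_that("K2P matches its closed form and returns NA past the domain edge", {
  expect_equal(k2p_distance(list(L = 100, P_count = 0, Q_count = 0)), 0)
  # d = -1/2 ln(0.75) - 1/4 ln(0.90)
  expect_equal(k2p_distance(list(L = 100, P_count = 10, Q_count = 5)),
               -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-12)
  expect_equal(k2p_distance(list(L = 100, P_count = 10, Q_count = 5)),
               0.170181, tolerance = 1e-6)
  expect_true(is.na(k2p_distance(list(L = 100, P_count = 50, Q_count = 0))))
  expect_error(k2p_distance(list(L = 0, P_count = 0, Q_count = 0)), "positive")
})

test_that("distance matrices are symmetric, zero-diagonal and order-invariant", {
  set.seed(7)
  ds <- random_dataset(n_records = 15, seq_len = 120)
  D <- distance_matrix(ds)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, nrow(ds)))
  expect_true(all(D >= 0, na.rm = TRUE))
  # reordering records permutes but does not change distances
  perm <- sample(nrow(ds))
  D2 <- distance_matrix(barcode_dataset(as.data.frame(ds)[perm, ]))
  expect_equal(D2[rownames(D), colnames(D)], D, ignore_attr = TRUE)
  # identical sequences -> all-zero matrix
  same <- barcode_dataset(data.frame(
    record_id = c("x", "y", "z"), accession = "", species = "S a",
    genus = "S", family = "F", sequence = "ACGTACGT", source = ""))
  expect_equal(unname(distance_matrix(same)), matrix(0, 3, 3),
               ignore_attr = TRUE)
})

test_that("K2P dominates the p-distance and agrees with it when divergence is small", {
  set.seed(11)
  ds <- random_dataset(n_records = 10, seq_len = 200)
  D <- distance_matrix(ds)
  S <- lapply(ds$sequence, function(s) strsplit(s, "")[[1]])
  for (i in 1:9) for (j in (i + 1):10) {
    p <- mean(S[[i]] != S[[j]])
    if (!is.na(D[i, j])) expect_gte(D[i, j] + 1e-12, p)
  }
  # Taylor limit: tiny divergence, K2P ~ p-distance
  base <- paste(rep("ACGT", 250), collapse = "")
  mut <- base
  substr(mut, 5, 5) <- "G"  # one transition among 1000 sites
  cs <- count_site_differences(base, mut)
  p <- (cs$P_count + cs$Q_count) / cs$L
  expect_lt(abs(k2p_distance(cs) - p), 1e-3)
})

test_that("our K2P agrees with the ape reference implementation", {
  sim <- small_sim(seed = 52)
  ds <- as.data.frame(sim$dataset)
  # sprinkle ambiguity and gap characters to exercise pairwise deletion
  set.seed(21)
  for (i in sample(nrow(ds), 6)) {
    s <- strsplit(ds$sequence[i], "")[[1]]
    s[sample(length(s), 10)] <- sample(c("N", "-", "R"), 10, replace = TRUE)
    ds$sequence[i] <- paste(s, collapse = "")
  }
  ds <- barcode_dataset(ds)
  D <- distance_matrix(ds)
  bin <- ape::as.DNAbin(t(sapply(ds$sequence,
                                 function(s) strsplit(tolower(s), "")[[1]])))
  rownames(bin) <- ds$record_id
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_false(anyNA(D))
  expect_equal(D[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("transition/transversion ratios match direct pair counts", {
  ds <- barcode_dataset(data.frame(
    record_id = c("p", "q"), accession = "", species = "S a", genus = "S",
    family = "F", sequence = c("AAACCCGGG", "GAATCCGGC"), source = ""))
  # differences: pos1 A->G (ts), pos4 C->T (ts), pos9 G->C (tv)
  expect_equal(tstv_ratio(ds), 2)
  expect_true(is.na(tstv_ratio(ds, codon_position = 1)))  # 2 ts, 0 tv
  expect_equal(tstv_ratio(ds, codon_position = 3), 0)     # 0 ts, 1 tv
  same <- barcode_dataset(data.frame(
    record_id = c("p", "q"), accession = "", species = "S a", genus = "S",
    family = "F", sequence = "ACGTACGTA", source = ""))
  expect_true(is.na(tstv_ratio(same)))
})

test_that("kappa-driven simulations recover the expected ts/tv ratio", {
  # uniform composition: the model reduces to K80 with expected R = kappa
  spec <- sim_spec(n_families = 1, genera_per_family = 1,
                   species_per_genus = 5, records_per_species = 10,
                   d_S = 0.02, d_G = 0.08, d_F = 0.1, d_O = 0.12,
                   kappa = 2, gc3_targets = 0.5, sequence_length = 600,
                   p_cryptic = 0, p_merge = 0, p_numt = 0)
  sim <- simulate_dataset(spec, 555)
  R <- tstv_ratio(sim$dataset)
  expect_gte(R, 1.7)
  expect_lte(R, 2.3)
})
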