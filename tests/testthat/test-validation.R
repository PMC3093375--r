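test_that("per-species subsampling caps large species deterministically", {
  set.seed(1)
  ds <- random_dataset(n_records = 40, seq_len = 30)
  big_sp <- names(which.max(table(ds$species)))
  sub1 <- subsample_per_species(ds, max_per_species = 2, seed = 5)
  sub2 <- subsample_per_species(ds, max_per_species = 2, seed = 5)
  expect_identical(as.data.frame(sub1), as.data.frame(sub2))
  expect_true(all(table(sub1$species) <= 2))
  # small species untouched; caps bind only above the threshold
  counts <- table(ds$species)
  kept <- table(factor(sub1$species, levels = names(counts)))
  expect_equal(unname(pmin(counts, 2)), unname(kept), ignore_attr = TRUE)
  # record order preserved as read
  expect_equal(sub1$record_id,
               ds$record_id[ds$record_id %in% sub1$record_id])
  expect_error(subsample_per_species(ds, 10), "seed")
})

test_that("threshold clustering is single-linkage with a strict bound", {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 0.01, 0.05, 0.01, 0, 0.05, 0.05, 0.05, 0), 3, 3,
              dimnames = list(ids, ids))
  cl <- threshold_clusters(D, 0.02)
  expect_equal(cl, list(c("A", "B"), "C"))
  # chaining: A-B and B-C below threshold link A-C transitively
  Dc <- matrix(c(0, 0.015, 0.03, 0.015, 0, 0.015, 0.03, 0.015, 0), 3, 3,
               dimnames = list(ids, ids))
  expect_equal(threshold_clusters(Dc, 0.02), list(c("A", "B", "C")))
  # boundaries: zero threshold isolates every record; huge threshold merges all
  expect_equal(lengths(threshold_clusters(Dc, 0)), rep(1L, 3))
  expect_equal(lengths(threshold_clusters(Dc, Inf)), 3L)
  # strictness: distance exactly at the threshold does not link
  expect_equal(length(threshold_clusters(Dc, 0.015)), 3L)
})

test_that("problem-species flags recover injected anomalies with their truth labels", {
  spec <- sim_spec(n_families = 3, genera_per_family = 2,
                   species_per_genus = 3, records_per_species = 5,
                   p_cryptic = 0.25, p_merge = 0.5, p_numt = 0)
  sim <- simulate_dataset(spec, 424)
  expect_gte(length(sim$truth$expected_flags), 2L)
  D <- distance_matrix(sim$dataset)
  rooted <- midpoint_root(build_nj(D))
  flags <- flag_problem_species(sim$dataset, D, rooted)
  for (sp in names(sim$truth$expected_flags)) {
    expect_setequal(flags[[sp]], sim$truth$expected_flags[[sp]])
  }
  expect_length(setdiff(names(flags), names(sim$truth$expected_flags)), 0L)
})

test_that("clean simulations yield no species flags", {
  sim <- small_sim(seed = 88)
  D <- distance_matrix(sim$dataset)
  rooted <- midpoint_root(build_nj(D))
  expect_length(flag_problem_species(sim$dataset, D, rooted), 0L)
})

test_that("variants split raw vs mean and full vs validated correctly", {
  ds <- barcode_dataset(data.frame(
    record_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    accession = "",
    species = c("X a", "X a", "X a", "X b", "X b", "X c"),
    genus = "X", family = "F", sequence = "ACGTACGT", source = ""))
  ids <- ds$record_id
  D <- matrix(0, 6, 6, dimnames = list(ids, ids))
  D["a1", "a2"] <- D["a2", "a1"] <- 0.00
  D["a1", "a3"] <- D["a3", "a1"] <- 0.02
  D["a2", "a3"] <- D["a3", "a2"] <- 0.02
  D["b1", "b2"] <- D["b2", "b1"] <- 0.01
  v <- make_variants(ds, D, list(`X a` = "CRYPTIC"))
  expect_equal(sort(v$A_R), c(0, 1, 2, 2))
  expect_equal(sort(v$A_M), sort(c(mean(c(0, 2, 2)), 1)))
  expect_equal(v$B_R, 1)       # only species X b survives with pairs
  expect_equal(v$B_M, 1)
  # the singleton species stays in B but contributes to neither R nor M
  expect_true("X c" %in% v$B_dataset$species)
  expect_error(make_variants(ds, D,
    list(`X a` = "CRYPTIC", `X b` = "CRYPTIC", `X c` = "CRYPTIC")), "empties")
})

test_that("Mann-Whitney matches exact enumeration and the U identity", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  set.seed(13)
  for (i in 1:50) {
    x <- stats::rnorm(sample(2:20, 1))
    y <- stats::rnorm(sample(2:20, 1))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    u_x <- unname(wt$statistic)
    expect_equal(mann_whitney(x, y)$U, min(u_x, length(x) * length(y) - u_x))
  }
})

test_that("the bias report runs all four comparisons with frequencies in range", {
  sim <- small_sim(seed = 303)
  D <- distance_matrix(sim$dataset)
  v <- make_variants(sim$dataset, D, list())
  rep <- bias_report(v)
  expect_equal(rep$comparisons$comparison,
               c("A_R vs B_R", "A_M vs B_M", "A_R vs A_M", "B_R vs B_M"))
  expect_true(all(rep$comparisons$p >= 0 & rep$comparisons$p <= 1))
  expect_true(all(rep$freq_below_3pct >= 0 & rep$freq_below_3pct <= 1))
  # identical A and B (nothing flagged): the A-vs-B comparisons are null
  expect_gte(rep$comparisons$p[1], 0.99)
})

test_that("imbalanced sampling is detected as raw-vs-mean bias and balance is not", {
  reject_bal <- 0L; reject_imb <- 0L; n_rep <- 20L
  for (r in seq_len(n_rep)) {
    base <- sim_spec(n_families = 3, genera_per_family = 2,
                     species_per_genus = 3, records_per_species = 5,
                     p_cryptic = 0, p_merge = 0, p_numt = 0)
    bal <- simulate_dataset(base, 5000 + r)
    Db <- distance_matrix(bal$dataset)
    pb <- bias_report(make_variants(bal$dataset, Db, list()))
    if (pb$comparisons$p[3] < 0.05) reject_bal <- reject_bal + 1L

    imb_spec <- sim_spec(n_families = 3, genera_per_family = 2,
                         species_per_genus = 3, records_per_species = 5,
                         p_cryptic = 0, p_merge = 0, p_numt = 0,
                         imbalance = 18)
    imb <- simulate_dataset(imb_spec, 6000 + r)
    Di <- distance_matrix(imb$dataset)
    pi_ <- bias_report(make_variants(imb$dataset, Di, list()))
    if (pi_$comparisons$p[3] < 0.05) reject_imb <- reject_imb + 1L
  }
  expect_lte(reject_bal / n_rep, 0.1)
  expect_gte(reject_imb / n_rep, 0.9)
})

test_that("identification success counts species within the threshold", {
  ds <- barcode_dataset(data.frame(
    record_id = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    accession = "",
    species = rep(c("X a", "X b", "X c", "X d"), each = 2),
    genus = "X", family = "F", sequence = "ACGT", source = ""))
  ids <- ds$record_id
  D <- matrix(0, 8, 8, dimnames = list(ids, ids))
  D["d1", "d2"] <- D["d2", "d1"] <- 0.03
  expect_equal(identification_success(ds, D, 0.02, mode = "raw"), 0.75)
  expect_equal(identification_success(ds, D, 0.02, mode = "mean"), 0.75)
  D["d1", "d2"] <- D["d2", "d1"] <- 0.01
  expect_equal(identification_success(ds, D, 0.02, mode = "raw"), 1)
  # mean mode can never be stricter than raw mode (mean <= max)
  sim <- small_sim(seed = 206)
  Dd <- distance_matrix(sim$dataset)
  for (thr in c(0.001, 0.003, 0.005, 0.01, 0.02)) {
    expect_gte(identification_success(sim$dataset, Dd, thr, mode = "mean"),
               identification_success(sim$dataset, Dd, thr, mode = "raw"))
  }
  single <- barcode_dataset(ds[c(1, 3), ])
  expect_error(identification_success(single, D[c(1, 3), c(1, 3)], 0.02),
               "multi-record")
})

test_that("removing flagged species cannot raise the intraspecific maximum", {
  for (seed in 1:5) {
    spec <- sim_spec(n_families = 2, genera_per_family = 2,
                     species_per_genus = 3, records_per_species = 4,
                     p_cryptic = 0.3, p_merge = 0.3, p_numt = 0)
    sim <- simulate_dataset(spec, 7000 + seed)
    D <- distance_matrix(sim$dataset)
    rooted <- midpoint_root(build_nj(D))
    flags <- flag_problem_species(sim$dataset, D, rooted)
    if (length(flags) == 0L) next
    v <- tryCatch(make_variants(sim$dataset, D, flags),
                  error = function(e) NULL)
    if (is.null(v) || length(v$B_R) == 0L) next
    expect_lte(max(v$B_R), max(v$A_R))
  }
})
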