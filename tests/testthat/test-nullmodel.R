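test_that("null communities preserve per-sample richness and totals exactly", {
  m <- rand_otu(6, 40, seed = 81)
  m[m < 8] <- 0L   # introduce real absences
  m[, 1] <- m[, 1] + 1L
  nulls <- generate_null_communities(m, n_iter = 25, seed = 9)
  expect_length(nulls, 25)
  for (null in nulls) {
    expect_identical(rowSums(null), rowSums(m))
    expect_identical(rowSums(null > 0), rowSums(m > 0))
    expect_identical(dimnames(null), dimnames(m))
  }
  # identities do get shuffled
  expect_false(all(vapply(nulls, function(x) identical(x, m), TRUE)))

  single <- m[1, , drop = FALSE]
  n1 <- generate_null_communities(single, n_iter = 3, seed = 2)
  expect_equal(sum(n1[[1]]), sum(single))
  expect_equal(sum(n1[[1]] > 0), sum(single > 0))
})

test_that("null OTU selection frequency follows occupancy", {
  set.seed(91)
  m <- rand_otu(10, 30, seed = 91)
  m[m < 12] <- 0L
  m[, 1] <- m[, 1] + 1L
  occ <- colMeans(m > 0)
  nulls <- generate_null_communities(m, n_iter = 300, seed = 5)
  freq <- Reduce(`+`, lapply(nulls, function(x) colSums(x > 0)))
  keep <- occ > 0 & occ < 1
  expect_gt(cor(freq[keep], occ[keep], method = "spearman"), 0)
})

test_that("SES follows its defining formula and invariances", {
  nulls <- c(0.552 - 0.0604 / sqrt(2), 0.552 + 0.0604 / sqrt(2))
  expect_equal(ses(0.703, nulls), 2.50, tolerance = 0.01)
  expect_equal(ses(mean(nulls), nulls), 0)
  expect_equal(ses(0.703 + 0.1, nulls + 0.1), ses(0.703, nulls))
  expect_error(ses(0.5, c(0.4, 0.4)), "sd is zero")
  expect_error(ses(0.5, 0.4), "at least two")
})

test_that("SES of the null model against itself is centred near zero", {
  m <- rand_otu(8, 30, seed = 95)
  m[m < 10] <- 0L
  m[, 1] <- m[, 1] + 1L
  nulls <- generate_null_communities(m, n_iter = 300, seed = 6)
  betas <- vapply(nulls, function(x) mean_pairwise(bray_curtis(x)), 0)
  ref <- betas[1:200]
  ses_vals <- vapply(201:300, function(k) ses(betas[k], ref), 0)
  expect_lt(abs(mean(ses_vals)), 0.3)
})

test_that("classification applies a strict alpha cut on the permutation p", {
  m <- rand_otu(8, 40, seed = 97)
  r <- observed_vs_null_test(m, n_iter = 49, n_perm = 99, seed = 11)
  expect_true(r$classification %in% c("Determinism", "Stochasticity"))
  # p < alpha is strict: alpha equal to p must read Stochasticity
  r_at <- observed_vs_null_test(m, n_iter = 49, n_perm = 99, seed = 11,
                                alpha = r$p)
  expect_identical(r_at$classification, "Stochasticity")
  r_above <- observed_vs_null_test(m, n_iter = 49, n_perm = 99, seed = 11,
                                   alpha = r$p + 1e-9)
  expect_identical(r_above$classification, "Determinism")
  expect_equal(r_at$p, r$p)
  expect_error(observed_vs_null_test(m[1:2, ]), "at least 3")
})

test_that("assembly report has the stated schema, rows, and determinism", {
  cfg <- simulation_config(n_sites = 12, n_species = 60,
                           reads_per_sample = 300, seed = 7,
                           media = c("soil", "water"))
  ds <- simulate_communities(cfg)
  rep1 <- assembly_report(ds$otu_table, ds$metadata, n_iter = 19,
                          n_perm = 49, seed = 1)
  expect_identical(names(rep1),
                   c("stratum", "mean_observed_similarity",
                     "mean_null_similarity", "F", "p", "SES",
                     "classification"))
  # 4 regions x 2 media + 3 types x 2 media
  expect_equal(nrow(rep1), 8 + 6)
  expect_true(all(grepl("^(soil|water)\\|(region|peatland_type)\\|", rep1$stratum)))
  expect_true(all(rep1$mean_observed_similarity >= 0 &
                    rep1$mean_observed_similarity <= 1))
  rep2 <- assembly_report(ds$otu_table, ds$metadata, n_iter = 19,
                          n_perm = 49, seed = 1)
  expect_identical(rep1, rep2)
})

test_that("under-filled strata yield NA rows with a warning", {
  cfg <- simulation_config(n_sites = 5, replicates_per_site = 2,
                           n_species = 40, reads_per_sample = 200,
                           media = "soil", seed = 8,
                           region_layout = data.frame(
                             site_id = paste0("S", 1:5),
                             region = c("SJ", "SJ", "CB", "CB", "LK"),
                             peatland_type = rep("fen", 5)))
  ds <- simulate_communities(cfg)
  expect_warning(
    rep <- assembly_report(ds$otu_table, ds$metadata, strata = "region",
                           n_iter = 9, n_perm = 19, seed = 2),
    "fewer than 3")
  lk <- rep[rep$stratum == "soil|region|LK", ]
  expect_true(is.na(lk$F) && is.na(lk$classification))
  expect_false(anyNA(rep[rep$stratum == "soil|region|SJ", ]))
})
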