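# Small configurations keep the generator tests fast; the full default
# scale is exercised by the parameter-recovery suite in test-acceptance.R.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_sites = 8, n_species = 60, reads_per_sample = 400, media = "soil"),
    list(...))
  do.call(simulation_config, args)
}

test_that("configuration bounds are enforced at construction", {
  expect_error(simulation_config(n_sites = 1), "n_sites")
  expect_error(simulation_config(assembly_weight = 1.2), "assembly_weight")
  expect_error(simulation_config(niche_breadth = 0), "niche_breadth")
  expect_error(simulation_config(dispersal_decay = -1), "dispersal_decay")
  expect_error(simulation_config(env_spatial_correlation = 2),
               "env_spatial_correlation")
  expect_error(simulation_config(media = "sediment"), "media")
})

test_that("landscape couples the gradient to latitude through rho", {
  # rho = 1: gradient is a deterministic monotone function of latitude
  l1 <- simulate_landscape(simulation_config(n_sites = 20, seed = 3,
                                             env_spatial_correlation = 1))
  expect_equal(cor(l1$env, l1$latitude), 1, tolerance = 1e-12)
  expect_equal(order(l1$env), order(l1$latitude))

  # rho = 0: decoupled (Monte-Carlo check at large n)
  l0 <- simulate_landscape(simulation_config(n_sites = 1000, seed = 4,
                                             env_spatial_correlation = 0))
  expect_lt(abs(cor(l0$env, l0$latitude)), 0.1)

  # a 15-site landscape spans at least the packaged extent
  l <- simulate_landscape(simulation_config(seed = 5))
  soil <- load_env_table("table1_soil")
  expect_lte(min(l$latitude), min(soil$latitude) + 1)
  expect_gte(max(l$latitude), max(soil$latitude) - 1)
  expect_true(all(l$region %in% c("SJ", "CB", "LK", "GK")))
})

test_that("species pool respects guild fraction, filter exercise, and normalization", {
  cfg <- small_cfg(seed = 11, guild_fraction = 0)
  pool0 <- simulate_metacommunity(cfg)
  ref <- load_guild_reference()
  expect_false(any(pool0$genus %in% names(ref)))
  expect_equal(sum(pool0$regional_abundance), 1, tolerance = 1e-12)

  cfg1 <- small_cfg(seed = 12, guild_fraction = 1, subthreshold_fraction = 0)
  pool1 <- simulate_metacommunity(cfg1)
  expect_true(all(pool1$genus %in% names(ref)))
  asn <- classify_otus(data.frame(otu_id = pool1$otu_id, genus = pool1$genus,
                                  best_hit_similarity = pool1$best_hit_similarity))
  expect_true(all(asn$guild != "none"))

  # a positive subthreshold fraction puts some guild species at/below 97
  cfg2 <- small_cfg(seed = 13, guild_fraction = 1, subthreshold_fraction = 0.5)
  pool2 <- simulate_metacommunity(cfg2)
  expect_gt(sum(pool2$best_hit_similarity <= 97), 0)

  expect_warning(simulate_metacommunity(small_cfg(seed = 14,
                                                  guild_fraction = 0.001)),
                 "no guild species")
})

test_that("datasets are deterministic under seed and conserve read sums", {
  cfg <- small_cfg(seed = 21)
  a <- simulate_communities(cfg)
  b <- simulate_communities(cfg)
  expect_identical(a$otu_table, b$otu_table)
  expect_identical(a$metadata, b$metadata)
  expect_true(all(rowSums(a$otu_table) == cfg$reads_per_sample))
  expect_equal(nrow(a$otu_table),
               cfg$n_sites * cfg$replicates_per_site * length(cfg$media))
  c2 <- simulate_communities(small_cfg(seed = 22))
  expect_false(identical(a$otu_table, c2$otu_table))
})

test_that("pure sorting with flat niches collapses to the sampling noise floor", {
  cfg <- small_cfg(seed = 31, assembly_weight = 1, niche_breadth = Inf,
                   reads_per_sample = 5000)
  ds <- simulate_communities(cfg)
  noise <- mean_pairwise(bray_curtis(ds$otu_table))
  # all sites share one expected composition; only multinomial noise remains
  expect_lt(noise, 0.1)
  # a sharp-niche run on the same seed is far above that floor
  sharp <- simulate_communities(small_cfg(seed = 31, assembly_weight = 1,
                                          niche_breadth = 0.3,
                                          reads_per_sample = 5000))
  expect_gt(mean_pairwise(bray_curtis(sharp$otu_table)), 2 * noise)
})

test_that("community-environment coupling strengthens with assembly weight", {
  mantel_r <- function(omega, seed) {
    ds <- simulate_communities(small_cfg(seed = seed, assembly_weight = omega,
                                         niche_breadth = 0.3,
                                         reads_per_sample = 1000))
    md <- ds$metadata
    bc <- bray_curtis(ds$otu_table)
    ed <- env_distance(data.frame(site_id = md$sample_id, env = md$env),
                       variables = "env", log_vars = character(0))
    mantel_test(bc, ed, n_perm = 49, seed = seed)$r
  }
  omegas <- c(0, 0.5, 0.9)
  means <- vapply(omegas, function(om)
    mean(vapply(1:3, function(s) mantel_r(om, s), 0)), 0)
  expect_gte(cor(means, omegas, method = "spearman"), 0)
  expect_gt(means[3], means[1])
})

test_that("stronger dispersal decay steepens the geographic distance decay", {
  slope_of <- function(lambda, seed) {
    ds <- simulate_communities(small_cfg(seed = seed, assembly_weight = 0,
                                         dispersal_decay = lambda,
                                         reads_per_sample = 1000))
    md <- ds$metadata
    bc <- bray_curtis(ds$otu_table)
    geo <- haversine_matrix(data.frame(site_id = md$sample_id,
                                       latitude = md$latitude,
                                       longitude = md$longitude))
    ddr_fit(similarity(bc), geo, n_perm = 9, seed = seed)$slope
  }
  lambdas <- c(0, 0.002, 0.005)
  means <- vapply(lambdas, function(l)
    mean(vapply(1:3, function(s) slope_of(l, s), 0)), 0)
  expect_gte(cor(abs(means), lambdas, method = "spearman"), 0)
  expect_gt(abs(means[3]), abs(means[1]))
})

test_that("datasets round-trip through the on-disk bundle", {
  ds <- simulate_communities(small_cfg(seed = 41))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  expect_identical(read_otu_table(file.path(dir, "otu_table.tsv")),
                   ds$otu_table)
  tax <- utils::read.delim(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$otu_id, ds$taxonomy$otu_id)
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$seed, 41)
})
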