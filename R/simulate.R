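# Synthetic metacommunity generator with a known assembly regime.
#
# Expected relative abundance of species s at site i:
#   p_i(s)  propto  A_s * ( w * exp(-(E_i - mu_s)^2 / (2 sigma^2))
#                           + (1 - w) * K_i(s) )
# where A_s is the regional (metacommunity) relative abundance, E_i the
# site's environmental gradient value, mu_s the species' niche optimum,
# and K_i(s) a dispersal-limited lognormal drift field whose spatial
# autocorrelation between sites decays as exp(-lambda * d_km). w = 1 is
# pure species sorting (deterministic niche assembly); w = 0 is neutral
# sampling of the regional pool under dispersal limitation, and with
# lambda = 0 every site shares one drift realization so communities differ
# only by multinomial read noise. Replicate plots within a site share the
# site expectation and get independent multinomial draws.

# Approximate regional centres matching the packaged site tables
.region_centres <- data.frame(
  region = c("SJ", "CB", "LK", "GK"),
  latitude = c(47.6, 42.35, 48.5, 52.0),
  longitude = c(133.4, 126.4, 129.3, 123.3)
)

#' Build a validated simulation configuration
#'
#' Defaults mirror the scale of a regional peatland survey: 15 sites with 3
#' replicate plots each, 500 species, 5000 reads per sample, sampled in two
#' media (soil and water).
#'
#' @param n_sites number of sites (>= 2).
#' @param replicates_per_site replicate plots per site and medium.
#' @param n_species size of the regional species pool.
#' @param guild_fraction proportion of species carrying an FeOB/FeRB genus.
#' @param assembly_weight `w` in \[0, 1\]: 1 = pure deterministic species
#'   sorting along the gradient, 0 = pure dispersal-limited neutral sampling.
#' @param niche_breadth `sigma` (> 0), in sd units of the standardized
#'   environmental gradient.
#' @param dispersal_decay `lambda` (>= 0), per km; autocorrelation of the
#'   drift field between sites is `exp(-lambda * d_km)`.
#' @param drift_sd lognormal sd of the neutral drift field.
#' @param reads_per_sample sequencing depth (multinomial trials).
#' @param env_spatial_correlation `rho` in \[0, 1\]: the gradient is
#'   `rho * scaled latitude + (1 - rho) * noise`, so `rho` controls
#'   spatial-environmental collinearity.
#' @param subthreshold_fraction fraction of guild species whose best-hit
#'   similarity is drawn at or below the 97% identity threshold (exercises
#'   the guild filter).
#' @param media which sample media to generate.
#' @param region_layout optional data.frame with columns `site_id`,
#'   `region`, `peatland_type` assigning sites to the four regions and
#'   three peatland types; default round-robin.
#' @param seed integer RNG seed; same seed and config give a bit-identical
#'   dataset.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 15L,
                              replicates_per_site = 3L,
                              n_species = 500L,
                              guild_fraction = 0.15,
                              assembly_weight = 0.5,
                              niche_breadth = 1,
                              dispersal_decay = 0.005,
                              drift_sd = 2,
                              reads_per_sample = 5000L,
                              env_spatial_correlation = 0.7,
                              subthreshold_fraction = 0.2,
                              media = c("soil", "water"),
                              region_layout = NULL,
                              seed = 1L) {
  stopifnot(n_sites >= 2, replicates_per_site >= 1, n_species >= 2,
            guild_fraction >= 0, guild_fraction <= 1,
            assembly_weight >= 0, assembly_weight <= 1,
            niche_breadth > 0, dispersal_decay >= 0, drift_sd >= 0,
            reads_per_sample >= 1,
            env_spatial_correlation >= 0, env_spatial_correlation <= 1,
            subthreshold_fraction >= 0, subthreshold_fraction <= 1,
            length(media) >= 1, all(media %in% c("soil", "water")))
  if (is.null(region_layout)) {
    region_layout <- data.frame(
      site_id = sprintf("S%02d", seq_len(n_sites)),
      region = rep_len(.regions, n_sites),
      peatland_type = rep_len(rep(.peat_types, each = 1L), n_sites)
    )
  } else {
    stopifnot(all(c("site_id", "region", "peatland_type") %in%
                    names(region_layout)),
              nrow(region_layout) == n_sites,
              all(region_layout$region %in% .regions),
              all(region_layout$peatland_type %in% .peat_types))
  }
  cfg <- list(n_sites = as.integer(n_sites),
              replicates_per_site = as.integer(replicates_per_site),
              n_species = as.integer(n_species),
              guild_fraction = guild_fraction,
              assembly_weight = assembly_weight,
              niche_breadth = niche_breadth,
              dispersal_decay = dispersal_decay,
              drift_sd = drift_sd,
              reads_per_sample = as.integer(reads_per_sample),
              env_spatial_correlation = env_spatial_correlation,
              subthreshold_fraction = subthreshold_fraction,
              media = media,
              region_layout = region_layout,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate site coordinates and an environmental gradient
#'
#' Sites scatter around the four regional centres (so a 15-site landscape
#' spans the same extent as the packaged tables). The gradient is
#' `rho * z(latitude) + (1 - rho) * noise`, rescaled to unit sd, so
#' `env_spatial_correlation` = 1 ties the gradient to latitude and 0
#' decouples it from space.
#'
#' @param config a `simulation_config`.
#' @return data.frame: `site_id`, `region`, `peatland_type`, `latitude`,
#'   `longitude`, `env`.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  .simulate_landscape_impl(config)
}

.simulate_landscape_impl <- function(config) {
  lay <- config$region_layout
  ctr <- .region_centres[match(lay$region, .region_centres$region), ]
  lat <- ctr$latitude + stats::runif(config$n_sites, -0.5, 0.5)
  lon <- ctr$longitude + stats::runif(config$n_sites, -0.5, 0.5)
  zlat <- as.numeric(scale(lat))
  if (all(zlat == zlat[1L]) || anyNA(zlat)) zlat <- rep(0, config$n_sites)
  rho <- config$env_spatial_correlation
  env <- rho * zlat + (1 - rho) * stats::rnorm(config$n_sites)
  s <- stats::sd(env)
  if (s > 0) env <- env / s
  data.frame(site_id = lay$site_id, region = lay$region,
             peatland_type = lay$peatland_type,
             latitude = lat, longitude = lon, env = env)
}

#' Simulate the regional species pool
#'
#' Each species gets a niche optimum on the gradient, a lognormal regional
#' relative abundance (normalized to sum 1), a genus label (a
#' `guild_fraction` share drawn from the FeOB/FeRB reference) and a best-hit
#' similarity score; `subthreshold_fraction` of guild species score at or
#' below 97% so the guild filter has something to reject.
#'
#' @param config a `simulation_config`.
#' @param reference genus -> guild reference; default packaged.
#' @return data.frame: `otu_id`, `genus`, `best_hit_similarity`,
#'   `niche_optimum`, `regional_abundance`.
#' @export
simulate_metacommunity <- function(config, reference = load_guild_reference()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  .simulate_metacommunity_impl(config, reference)
}

.simulate_metacommunity_impl <- function(config, reference) {
  n <- config$n_species
  abund <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  abund <- abund / sum(abund)
  mu <- stats::runif(n, -2, 2)
  n_guild <- round(config$guild_fraction * n)
  if (config$guild_fraction > 0 && n_guild < 1L) {
    warning("guild_fraction * n_species < 1; no guild species generated")
    n_guild <- 0L
  }
  genus <- rep("Unclassified", n)
  sim_score <- stats::runif(n, 85, 100)
  if (n_guild > 0L) {
    idx <- sample.int(n, n_guild)
    genus[idx] <- sample(names(reference), n_guild, replace = TRUE)
    below <- stats::runif(n_guild) < config$subthreshold_fraction
    sim_score[idx] <- ifelse(below,
                             stats::runif(n_guild, 90, 97),
                             stats::runif(n_guild, 97.05, 100))
  }
  data.frame(otu_id = sprintf("OTU%04d", seq_len(n)),
             genus = genus,
             best_hit_similarity = round(sim_score, 2),
             niche_optimum = mu,
             regional_abundance = abund)
}

# Spatially autocorrelated lognormal drift field: sites x species matrix,
# corr(z_i, z_j) = exp(-lambda * d_km(i, j)).
.drift_field <- function(dist_km, n_species, lambda, drift_sd) {
  n <- nrow(dist_km)
  if (drift_sd == 0) return(matrix(1, n, n_species))
  if (lambda == 0) {
    z <- matrix(stats::rnorm(n_species), n, n_species, byrow = TRUE)
  } else {
    C <- exp(-lambda * dist_km)
    diag(C) <- diag(C) + 1e-8
    L <- t(chol(C))
    z <- L %*% matrix(stats::rnorm(n * n_species), n, n_species)
  }
  exp(drift_sd * z - drift_sd^2 / 2)
}

#' Simulate a full community dataset
#'
#' Runs the landscape and species-pool generators, builds per-site expected
#' compositions from the niche/neutral mixture, and draws per-sample counts
#' multinomially at `reads_per_sample` trials. Each medium gets an
#' independent drift-field realization on the same landscape and species
#' pool. Deterministic under `config$seed`.
#'
#' @param config a `simulation_config`.
#' @param reference genus -> guild reference; default packaged.
#' @return list of class `synthetic_dataset`: `otu_table` (samples x OTUs
#'   integer matrix), `taxonomy`, `metadata` (one row per sample), `truth`
#'   (config, landscape, species pool, per-site expectations).
#' @export
simulate_communities <- function(config, reference = load_guild_reference()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  landscape <- .simulate_landscape_impl(config)
  set.seed(config$seed + 1L)
  pool <- .simulate_metacommunity_impl(config, reference)
  set.seed(config$seed + 2L)

  dist_km <- haversine_matrix(landscape)
  w <- config$assembly_weight
  sig <- config$niche_breadth
  niche <- exp(-outer(landscape$env, pool$niche_optimum, "-")^2 / (2 * sig^2))
  if (!is.finite(sig)) niche[] <- 1

  counts_list <- list()
  meta_list <- list()
  expectations <- list()
  for (med in config$media) {
    K <- .drift_field(dist_km, config$n_species,
                      config$dispersal_decay, config$drift_sd)
    p <- t(pool$regional_abundance * t(w * niche + (1 - w) * K))
    p <- p / rowSums(p)
    expectations[[med]] <- p
    for (i in seq_len(config$n_sites)) {
      for (r in seq_len(config$replicates_per_site)) {
        sid <- sprintf("%s_%s_r%d", landscape$site_id[i], med, r)
        counts_list[[sid]] <- as.integer(
          stats::rmultinom(1, config$reads_per_sample, p[i, ]))
        meta_list[[sid]] <- data.frame(
          sample_id = sid, site_id = landscape$site_id[i],
          region = landscape$region[i],
          peatland_type = landscape$peatland_type[i],
          medium = med, replicate = r,
          latitude = landscape$latitude[i],
          longitude = landscape$longitude[i],
          env = landscape$env[i])
      }
    }
  }
  counts <- do.call(rbind, counts_list)
  colnames(counts) <- pool$otu_id
  metadata <- do.call(rbind, meta_list)
  rownames(metadata) <- NULL
  out <- list(otu_table = counts,
              taxonomy = pool[c("otu_id", "genus", "best_hit_similarity")],
              metadata = metadata,
              truth = list(config = config, landscape = landscape,
                           species_pool = pool,
                           expected_composition = expectations))
  class(out) <- "synthetic_dataset"
  out
}

#' Write a synthetic dataset to a directory
#'
#' Writes `otu_table.tsv`, `taxonomy.tsv`, `metadata.tsv` and `truth.yaml`
#' (the generating configuration).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$otu_table, file.path(dir, "otu_table.tsv"))
  utils::write.table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$truth$config
  cfg$region_layout <- as.list(cfg$region_layout)
  yaml::write_yaml(unclass(cfg), file.path(dir, "truth.yaml"))
  invisible(dir)
}
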