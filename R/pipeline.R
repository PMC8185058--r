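# End-to-end orchestration: simulate or load inputs, filter the guild
# community, compute diversity, distances, permutation statistics and the
# assembly report, and write a reproducible results bundle with a hashed
# manifest.

#' Cross-file input validation
#'
#' Checks that every OTU in the count table has a taxonomy row, every
#' sample has a metadata row, and (when geographic analyses are requested)
#' that coordinates are present. Produces a report rather than failing;
#' [run_pipeline()] refuses to run on any issue.
#'
#' @param otu OTU count matrix, samples in rows.
#' @param taxonomy data.frame with `otu_id`, `genus`, `best_hit_similarity`.
#' @param metadata data.frame with `sample_id` (plus `latitude`/`longitude`
#'   if geographic analyses are requested).
#' @param require_coordinates flag coordinate-less samples as issues.
#' @return character vector of issues (empty when consistent).
#' @export
validate_inputs <- function(otu, taxonomy, metadata,
                            require_coordinates = FALSE) {
  issues <- character()
  orphan <- setdiff(colnames(otu), taxonomy$otu_id)
  if (length(orphan))
    issues <- c(issues, paste0("OTU without taxonomy row: ", orphan))
  nometa <- setdiff(rownames(otu), metadata$sample_id)
  if (length(nometa))
    issues <- c(issues, paste0("sample without metadata row: ", nometa))
  if (require_coordinates) {
    if (!all(c("latitude", "longitude") %in% names(metadata))) {
      issues <- c(issues, "metadata lacks latitude/longitude columns")
    } else {
      bad <- metadata$sample_id[is.na(metadata$latitude) |
                                  is.na(metadata$longitude)]
      bad <- intersect(bad, rownames(otu))
      if (length(bad))
        issues <- c(issues, paste0("sample missing coordinates: ", bad))
    }
  }
  issues
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain inputs — either a simulation config (`simulation`
#' entry) or paths to `otu`, `taxonomy`, `metadata` TSVs; (2) validate
#' cross-file consistency; (3) classify OTUs and subset the iron-cycling
#' guild community; (4) per-sample alpha diversity plus ANOVA by region and
#' peatland type; (5) per-medium Bray-Curtis, geographic and environmental
#' distance matrices; (6) Mantel and distance-decay statistics (community
#' vs geography and vs environment), ANOSIM and PERMANOVA by region and
#' type; (7) the observed-vs-null assembly report. All outputs are TSVs in
#' `out_dir`; a `manifest.tsv` lists every file with its MD5 hash, and the
#' effective configuration is echoed to `config.yaml`. Identical config and
#' seed give identical hashes.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `simulation` (list of [simulation_config()] arguments) or `inputs`
#'   (list with `otu`, `taxonomy`, `metadata` paths); optional
#'   `guild_threshold` (97), `strict` (TRUE), `env_variables`, `strata`,
#'   `n_perm` (999), `n_iter` (999), `alpha` (0.05), `seed` (1), and
#'   `out_dir` (required).
#' @return invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(guild_threshold = 97, strict = TRUE,
                   env_variables = NULL,
                   strata = c("region", "peatland_type"),
                   n_perm = 999L, n_iter = 999L, alpha = 0.05, seed = 1L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(name, sprintf("done in %.2fs", as.numeric(Sys.time() - t0, "secs")))
    r
  }
  files <- character()

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$simulation)) {
    ds <- stage("simulate", {
      sim_args <- config$simulation
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      simulate_communities(do.call(simulation_config, sim_args))
    })
    otu <- ds$otu_table; taxonomy <- ds$taxonomy; metadata <- ds$metadata
  } else if (!is.null(config$inputs)) {
    otu <- stage("read_otu", read_otu_table(config$inputs$otu))
    taxonomy <- stage("read_taxonomy",
                      utils::read.delim(config$inputs$taxonomy,
                                        check.names = FALSE))
    metadata <- stage("read_metadata",
                      utils::read.delim(config$inputs$metadata,
                                        check.names = FALSE))
  } else {
    stop("config needs either a 'simulation' entry or 'inputs' paths")
  }
  for (col in c("sample_id", "medium"))
    if (is.null(metadata[[col]]))
      stop("pipeline stage 'validate' failed: metadata is missing column '",
           col, "'", call. = FALSE)
  issues <- stage("validate",
                  validate_inputs(otu, taxonomy, metadata,
                                  require_coordinates = TRUE))
  if (length(issues))
    stop("pipeline stage 'validate' failed:\n  ",
         paste(issues, collapse = "\n  "), call. = FALSE)
  say("inputs", sprintf("%d samples x %d OTUs", nrow(otu), ncol(otu)))

  # --- guild filter ---------------------------------------------------
  assignments <- stage("classify", classify_otus(
    taxonomy, threshold = config$guild_threshold, strict = config$strict))
  guild_tab <- stage("subset", subset_by_guild(otu, assignments,
                                               "iron_cycling"))
  say("guild", sprintf("%d of %d OTUs retained as iron-cycling",
                       ncol(guild_tab), ncol(otu)))
  files["guild_assignments.tsv"] <-
    .write_tsv(assignments, file.path(out_dir, "guild_assignments.tsv"))
  files["guild_abundance.tsv"] <-
    .write_tsv(guild_relative_abundance(otu, assignments),
               file.path(out_dir, "guild_abundance.tsv"))

  # --- alpha diversity ------------------------------------------------
  alpha <- stage("alpha", {
    a <- alpha_diversity(guild_tab)
    merge(a, metadata, by = "sample_id", sort = FALSE)
  })
  files["alpha_diversity.tsv"] <-
    .write_tsv(alpha[c("sample_id", "medium", "region", "peatland_type",
                       "shannon", "simpson", "goods_coverage")],
               file.path(out_dir, "alpha_diversity.tsv"))
  anova_rows <- list()
  for (med in unique(alpha$medium)) {
    sub <- alpha[alpha$medium == med, ]
    for (col in intersect(config$strata, names(sub))) {
      for (idx in c("shannon", "simpson", "goods_coverage")) {
        ok <- nlevels(droplevels(factor(sub[[col]]))) >= 2L &&
          all(table(sub[[col]]) >= 2L)
        if (!ok) next
        fit <- one_way_anova(sub[[idx]], sub[[col]])
        anova_rows[[paste(med, col, idx)]] <- data.frame(
          medium = med, stratum = col, index = idx,
          F = fit$F, p = fit$p)
      }
    }
  }
  files["alpha_anova.tsv"] <-
    .write_tsv(do.call(rbind, anova_rows), file.path(out_dir, "alpha_anova.tsv"))

  # --- per-medium distances and statistics ----------------------------
  stat_rows <- list()
  for (med in unique(metadata$medium)) {
    ids <- metadata$sample_id[metadata$medium == med]
    ids <- intersect(rownames(guild_tab), ids)
    sub_meta <- metadata[match(ids, metadata$sample_id), ]
    sub_tab <- guild_tab[ids, , drop = FALSE]
    sub_tab <- sub_tab[rowSums(sub_tab) > 0, , drop = FALSE]
    if (nrow(sub_tab) < 4L) {
      say("distances", "medium ", med, ": fewer than 4 usable samples, skipped")
      next
    }
    sub_meta <- sub_meta[match(rownames(sub_tab), sub_meta$sample_id), ]
    bc <- stage(paste0("bray_", med), bray_curtis(sub_tab))
    geo <- stage(paste0("geo_", med), {
      g <- haversine_matrix(data.frame(site_id = sub_meta$sample_id,
                                       latitude = sub_meta$latitude,
                                       longitude = sub_meta$longitude))
      g
    })
    env_vars <- config$env_variables
    if (is.null(env_vars))
      env_vars <- intersect(c("env", .soil_vars, .water_vars), names(sub_meta))
    envd <- stage(paste0("env_", med), {
      use_vars <- intersect(env_vars, names(sub_meta))
      env_df <- data.frame(site_id = sub_meta$sample_id,
                           sub_meta[use_vars], check.names = FALSE)
      # the simulated gradient is already standardized and can be negative
      lv <- if (identical(use_vars, "env")) character(0) else NULL
      env_distance(env_df, variables = use_vars, log_vars = lv)
    })
    files[paste0("bray_curtis_", med, ".tsv")] <-
      .write_matrix_tsv(bc, file.path(out_dir, paste0("bray_curtis_", med, ".tsv")))
    files[paste0("geographic_", med, ".tsv")] <-
      .write_matrix_tsv(geo, file.path(out_dir, paste0("geographic_", med, ".tsv")))
    files[paste0("environmental_", med, ".tsv")] <-
      .write_matrix_tsv(envd, file.path(out_dir, paste0("environmental_", med, ".tsv")))

    sim <- similarity(bc)
    man_geo <- mantel_test(bc, geo, n_perm = config$n_perm,
                           seed = .stratum_seed(config$seed,
                                                paste0("mantel_geo_", med)))
    man_env <- mantel_test(bc, envd, n_perm = config$n_perm,
                           seed = .stratum_seed(config$seed,
                                                paste0("mantel_env_", med)))
    ddr_geo <- ddr_fit(sim, geo, n_perm = config$n_perm,
                       seed = .stratum_seed(config$seed,
                                            paste0("ddr_geo_", med)))
    ddr_env <- ddr_fit(sim, envd, n_perm = config$n_perm,
                       seed = .stratum_seed(config$seed,
                                            paste0("ddr_env_", med)))
    stat_rows[[paste0(med, "_mantel_geo")]] <- data.frame(
      medium = med, test = "mantel", predictor = "geographic",
      statistic = man_geo$r, slope = NA, r_squared = NA, p = man_geo$p)
    stat_rows[[paste0(med, "_mantel_env")]] <- data.frame(
      medium = med, test = "mantel", predictor = "environmental",
      statistic = man_env$r, slope = NA, r_squared = NA, p = man_env$p)
    stat_rows[[paste0(med, "_ddr_geo")]] <- data.frame(
      medium = med, test = "ddr", predictor = "geographic",
      statistic = NA, slope = ddr_geo$slope, r_squared = ddr_geo$r_squared,
      p = ddr_geo$p)
    stat_rows[[paste0(med, "_ddr_env")]] <- data.frame(
      medium = med, test = "ddr", predictor = "environmental",
      statistic = NA, slope = ddr_env$slope, r_squared = ddr_env$r_squared,
      p = ddr_env$p)
    for (col in intersect(config$strata, names(sub_meta))) {
      grp <- factor(sub_meta[[col]])
      if (nlevels(droplevels(grp)) < 2L || any(table(grp) < 2L)) next
      an <- anosim_test(bc, grp, n_perm = config$n_perm,
                        seed = .stratum_seed(config$seed,
                                             paste0("anosim_", med, col)))
      pm <- permanova_test(bc, grp, n_perm = config$n_perm,
                           seed = .stratum_seed(config$seed,
                                                paste0("permanova_", med, col)))
      stat_rows[[paste0(med, "_anosim_", col)]] <- data.frame(
        medium = med, test = "anosim", predictor = col,
        statistic = an$R, slope = NA, r_squared = NA, p = an$p)
      stat_rows[[paste0(med, "_permanova_", col)]] <- data.frame(
        medium = med, test = "permanova", predictor = col,
        statistic = pm$F, slope = NA, r_squared = NA, p = pm$p)
    }
  }
  files["beta_statistics.tsv"] <-
    .write_tsv(do.call(rbind, stat_rows),
               file.path(out_dir, "beta_statistics.tsv"))

  # --- assembly report ------------------------------------------------
  report <- stage("assembly", assembly_report(
    guild_tab, metadata, strata = config$strata,
    n_iter = config$n_iter, n_perm = config$n_perm,
    alpha = config$alpha, seed = config$seed))
  files["assembly_report.tsv"] <-
    .write_tsv(report, file.path(out_dir, "assembly_report.tsv"))

  # --- manifest -------------------------------------------------------
  echo <- config
  echo$out_dir <- NULL   # analysis config only; identical runs hash identically
  echo$strata <- as.list(echo$strata)
  yaml::write_yaml(echo, file.path(out_dir, "config.yaml"))
  files["config.yaml"] <- file.path(out_dir, "config.yaml")
  manifest <- data.frame(file = names(files),
                         md5 = unname(tools::md5sum(unlist(files))))
  files["manifest.tsv"] <-
    .write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  say("done", sprintf("%d files written to %s", length(files), out_dir))
  invisible(list(otu_table = otu, guild_table = guild_tab,
                 assignments = assignments, alpha = alpha,
                 beta_statistics = do.call(rbind, stat_rows),
                 assembly_report = report, manifest = manifest,
                 out_dir = out_dir))
}

#' Distance matrices for the packaged site tables
#'
#' Even without community data, the packaged soil and water tables support
#' the spatial/environmental side of the analysis: this computes the
#' geographic (Haversine km) and standardized environmental Euclidean
#' distance matrices for the 15 soil or 18 water sites.
#'
#' @param source `"table1_soil"` or `"table2_water"`.
#' @return list with `env_table`, `geographic`, `environmental`.
#' @export
fixture_distances <- function(source = c("table1_soil", "table2_water")) {
  source <- match.arg(source)
  tab <- load_env_table(source)
  list(env_table = tab,
       geographic = haversine_matrix(tab),
       environmental = env_distance(tab))
}
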