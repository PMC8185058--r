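# Identification of potential iron redox cycling bacteria from genus
# annotation plus best-hit similarity evidence, and guild-wise subsetting
# of OTU tables.

#' Classify OTUs into iron-cycling guilds
#'
#' An OTU is assigned a guild iff its genus is in the reference AND its
#' best-hit similarity to a verified FeOB/FeRB sequence passes the
#' threshold (strictly greater than 97% by default). Everything else —
#' unknown genus, failing similarity, or missing similarity evidence — is
#' `none`.
#'
#' @param taxonomy data.frame with columns `otu_id`, `genus`,
#'   `best_hit_similarity` (percent in \[0, 100\]).
#' @param reference genus -> guild map from [load_guild_reference()].
#' @param threshold percent identity threshold (default 97).
#' @param strict if `TRUE` (default) require similarity strictly above the
#'   threshold; if `FALSE`, at or above.
#' @return data.frame `otu_id`, `genus`, `best_hit_similarity`, `guild`
#'   (`"FeOB"`, `"FeRB"` or `"none"`).
#' @export
classify_otus <- function(taxonomy, reference = load_guild_reference(),
                          threshold = 97, strict = TRUE) {
  stopifnot(all(c("otu_id", "genus", "best_hit_similarity") %in%
                  names(taxonomy)))
  sim <- taxonomy$best_hit_similarity
  bad <- !is.na(sim) & (sim < 0 | sim > 100)
  if (any(bad))
    stop("best_hit_similarity outside [0, 100] for OTU ",
         taxonomy$otu_id[bad][1L])
  guild <- unname(reference[as.character(taxonomy$genus)])
  guild[is.na(guild)] <- "none"
  passes <- if (strict) sim > threshold else sim >= threshold
  missing_sim <- is.na(sim) & guild != "none"
  if (any(missing_sim)) {
    warning("missing similarity for ", sum(missing_sim),
            " guild-genus OTU(s); assigned 'none'")
  }
  passes[is.na(passes)] <- FALSE
  guild[!passes] <- "none"
  data.frame(otu_id = taxonomy$otu_id, genus = taxonomy$genus,
             best_hit_similarity = sim, guild = guild)
}

#' Subset an OTU table by guild
#'
#' Keeps exactly the OTUs assigned to `guild` (or to any non-`none` guild
#' with `guild = "iron_cycling"`); samples and counts are unchanged. An
#' empty result is returned as a zero-column table with a warning, not an
#' error.
#'
#' @param table OTU count matrix, samples in rows.
#' @param assignments output of [classify_otus()] covering all OTUs.
#' @param guild `"FeOB"`, `"FeRB"`, `"none"` or `"iron_cycling"` (FeOB +
#'   FeRB).
#' @return OTU count matrix restricted to the guild's OTUs.
#' @export
subset_by_guild <- function(table, assignments,
                            guild = c("iron_cycling", "FeOB", "FeRB", "none")) {
  guild <- match.arg(guild)
  table <- as.matrix(table)
  missing <- setdiff(colnames(table), assignments$otu_id)
  if (length(missing))
    stop("assignments do not cover OTU(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  g <- assignments$guild[match(colnames(table), assignments$otu_id)]
  keep <- if (guild == "iron_cycling") g %in% c("FeOB", "FeRB") else g == guild
  if (!any(keep))
    warning("no OTUs assigned to guild '", guild, "'; returning empty table")
  table[, keep, drop = FALSE]
}

#' Per-sample guild relative abundance
#'
#' Fraction of each sample's reads in FeOB, FeRB and unassigned OTUs; the
#' three fractions sum to 1. Zero-read samples are excluded with a warning.
#'
#' @inheritParams subset_by_guild
#' @return data.frame `sample_id`, `FeOB`, `FeRB`, `none`.
#' @export
guild_relative_abundance <- function(table, assignments) {
  table <- as.matrix(table)
  totals <- rowSums(table)
  if (any(totals == 0)) {
    warning("excluding zero-read sample(s): ",
            paste(rownames(table)[totals == 0], collapse = ", "))
    table <- table[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  g <- assignments$guild[match(colnames(table), assignments$otu_id)]
  if (anyNA(g))
    stop("assignments do not cover all OTUs in the table")
  frac <- function(which) rowSums(table[, g == which, drop = FALSE]) / totals
  data.frame(sample_id = rownames(table),
             FeOB = frac("FeOB"), FeRB = frac("FeRB"), none = frac("none"),
             row.names = NULL)
}
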