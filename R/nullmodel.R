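# Abundance-based null model for community assembly, the standardized
# effect size of beta diversity, and the observed-vs-null classification of
# assembly as deterministic or stochastic.
#
# Null scheme ("abundance-based", richness and depth preserving): for each
# sample, (1) keep its species richness and read total exactly; (2) draw
# that many OTU identities, without replacement, with probability
# proportional to each OTU's occupancy frequency across samples; (3) give
# each drawn OTU one read, then allocate the remaining reads multinomially
# with probability proportional to the OTUs' regional relative abundances.
# Alternative schemes can be plugged in via the `scheme` function argument.

.null_scheme_abundance <- function(counts) {
  occ <- colMeans(counts > 0)
  regional <- colSums(counts) / sum(counts)
  n_otus <- ncol(counts)
  function(sample_counts) {
    s <- sum(sample_counts > 0)
    n_reads <- sum(sample_counts)
    if (s > sum(occ > 0))
      stop("sample richness exceeds the number of occupied OTUs in the pool")
    out <- integer(n_otus)
    if (s == 0L) return(out)
    ids <- sample.int(n_otus, s, replace = FALSE, prob = occ)
    out[ids] <- 1L
    extra <- n_reads - s
    if (extra > 0L) {
      w <- regional[ids]
      if (sum(w) <= 0) w <- rep(1, s)
      out[ids] <- out[ids] + as.integer(stats::rmultinom(1, extra, w))
    }
    out
  }
}

#' Generate null communities
#'
#' Randomized versions of an OTU table preserving, for every sample, its
#' exact species richness and read total, with OTU identities drawn by
#' occupancy and reads allocated by regional abundance (see the scheme
#' description above). Reproducible under `seed`.
#'
#' @param table OTU count matrix, samples in rows.
#' @param n_iter number of null tables.
#' @param seed optional RNG seed.
#' @param scheme a function `counts -> (sample_counts -> null_sample)`;
#'   defaults to the abundance-based scheme.
#' @return list of `n_iter` null count matrices with the same dimnames.
#' @export
generate_null_communities <- function(table, n_iter = 999, seed = NULL,
                                      scheme = .null_scheme_abundance) {
  table <- as.matrix(table)
  if (nrow(table) < 1L || ncol(table) < 1L) stop("empty OTU table")
  draw <- scheme(table)
  .with_seed(seed, {
    lapply(seq_len(n_iter), function(k) {
      null <- t(apply(table, 1L, draw))
      dimnames(null) <- dimnames(table)
      null
    })
  })
}

#' Standardized effect size of beta diversity
#'
#' \eqn{SES = (\beta_{obs} - \overline{\beta_{null}}) / sd(\beta_{null})},
#' with the sample (n-1) standard deviation and the sign retained.
#' Magnitudes near zero indicate that observed beta diversity is
#' indistinguishable from the stochastic null expectation.
#'
#' @param observed_beta observed mean pairwise dissimilarity.
#' @param null_betas per-iteration null mean pairwise dissimilarities
#'   (>= 2 values with positive sd).
#' @return the SES value.
#' @export
ses <- function(observed_beta, null_betas) {
  if (length(null_betas) < 2L) stop("need at least two null values")
  s <- stats::sd(null_betas)
  if (s == 0) stop("null sd is zero; SES undefined")
  (observed_beta - mean(null_betas)) / s
}

#' Test observed communities against the null expectation
#'
#' For a group of samples: computes the observed pairwise Bray-Curtis
#' dissimilarities, generates `n_iter` null communities and their pairwise
#' dissimilarities, and summarizes (a) mean observed and mean null-expected
#' similarity (1 - dissimilarity), (b) a two-group PERMANOVA pseudo-F
#' comparing the observed sample set against one null-community realization
#' on their pooled Bray-Curtis matrix, with significance by sample-label
#' permutation, (c) the SES of mean beta diversity, and (d) the assembly
#' classification: `Determinism` iff `p < alpha`, i.e. the observed
#' community structure is distinguishable from the stochastic null, else
#' `Stochasticity`.
#'
#' The two-group PERMANOVA operationalization — observed communities as one
#' group, a null realization as the other, pooled distance matrix — is this
#' package's documented construction of the per-stratum F; it compares the
#' position of the observed community cloud against the null cloud, so
#' communities that differ from their null expectation only by sampling
#' noise (coincident clouds) yield F near 0 however tight the observed
#' cloud is. It is isolated here so alternative constructions can be
#' swapped in.
#'
#' The null communities are assembled from the regional species pool: OTU
#' occupancy frequencies and regional relative abundances are taken over
#' ALL samples of `table` (e.g. every sample of a medium), while only the
#' `group`'s samples are randomized and tested. A stratum whose communities
#' are environmentally filtered to a subset of the regional pool therefore
#' sits away from its null cloud; a stratum assembled by random sampling
#' from the pool coincides with it.
#'
#' @param table OTU count matrix, samples in rows; all of its samples
#'   define the regional pool for the null model.
#' @param group optional character vector of sample ids to test
#'   (default: all samples of `table`).
#' @param n_iter null-model iterations (default 999).
#' @param n_perm label permutations for the F test.
#' @param alpha significance level for the classification (default 0.05).
#' @param seed optional RNG seed.
#' @param label name to report for the group.
#' @return list of class `null_model_result`: `group`, `n_samples`,
#'   `mean_observed_similarity`, `mean_null_similarity`, `F`, `p`, `SES`,
#'   `classification`, `n_iter`.
#' @export
observed_vs_null_test <- function(table, group = NULL, n_iter = 999,
                                  n_perm = 999, alpha = 0.05, seed = NULL,
                                  label = "all") {
  table <- as.matrix(table)
  if (is.null(group)) group <- rownames(table)
  missing <- setdiff(group, rownames(table))
  if (length(missing))
    stop("sample(s) not in table: ", paste(missing, collapse = ", "))
  sub <- table[group, , drop = FALSE]
  n <- nrow(sub)
  if (n < 3L) stop("need at least 3 samples in the group")
  if (any(rowSums(sub) == 0)) stop("zero-read sample(s) in group")

  obs_d <- lower_pairs(bray_curtis(sub))

  res <- .with_seed(seed, {
    null_means <- numeric(n_iter)
    draw <- .null_scheme_abundance(table)
    first_null <- NULL
    for (k in seq_len(n_iter)) {
      null_tab <- t(apply(sub, 1L, draw))
      if (k == 1L) first_null <- null_tab
      null_means[k] <- mean(lower_pairs(bray_curtis(null_tab)))
    }
    rownames(first_null) <- paste0("null_", rownames(sub))
    pooled <- rbind(sub, first_null)
    pool_d <- bray_curtis(pooled)
    grp <- rep(c("observed", "null"), each = n)
    pf <- permanova_test(pool_d, grp, n_perm = n_perm)

    list(group = label, n_samples = n,
         mean_observed_similarity = 1 - mean(obs_d),
         mean_null_similarity = 1 - mean(null_means),
         F = pf$F, p = pf$p,
         SES = ses(mean(obs_d), null_means),
         classification = if (pf$p < alpha) "Determinism" else "Stochasticity",
         n_iter = n_iter)
  })
  structure(res, class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(
    "%s (n = %d): obs sim %.3f, null sim %.3f, F = %.3f, p = %.4g, SES = %.3f -> %s\n",
    x$group, x$n_samples, x$mean_observed_similarity,
    x$mean_null_similarity, x$F, x$p, x$SES, x$classification))
  invisible(x)
}

# stable per-stratum seed offset so adding strata does not perturb others
.stratum_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 100003L
  as.integer((seed + h) %% .Machine$integer.max)
}

#' Assembly report across strata
#'
#' Runs [observed_vs_null_test()] for every stratum (medium crossed with
#' region and/or peatland type) and returns one row per stratum: the mean
#' observed and null-expected similarity, F, p, SES and the
#' deterministic/stochastic classification. Strata with fewer than 3
#' samples yield an NA row with a warning. Each stratum's RNG seed is
#' derived from the run seed and the stratum name, so results are
#' reproducible and insensitive to stratum order.
#'
#' @param table OTU count matrix (typically the iron-cycling guild subset).
#' @param metadata data.frame with `sample_id`, `medium`, and the stratum
#'   columns.
#' @param strata metadata columns to stratify by within each medium.
#' @inheritParams observed_vs_null_test
#' @return data.frame with columns `stratum`, `mean_observed_similarity`,
#'   `mean_null_similarity`, `F`, `p`, `SES`, `classification`; `stratum`
#'   is `"<medium>|<column>|<level>"`.
#' @export
assembly_report <- function(table, metadata,
                            strata = c("region", "peatland_type"),
                            n_iter = 999, n_perm = 999, alpha = 0.05,
                            seed = NULL) {
  stopifnot(all(c("sample_id", "medium") %in% names(metadata)),
            all(strata %in% names(metadata)))
  table <- as.matrix(table)
  rows <- list()
  for (med in unique(metadata$medium)) {
    med_ids <- intersect(metadata$sample_id[metadata$medium == med],
                         rownames(table))
    med_tab <- table[med_ids, , drop = FALSE]
    med_tab <- med_tab[rowSums(med_tab) > 0, , drop = FALSE]
    for (col in strata) {
      levels_here <- unique(metadata[[col]][metadata$medium == med])
      for (lev in levels_here) {
        key <- paste(med, col, lev, sep = "|")
        ids <- metadata$sample_id[metadata$medium == med &
                                    metadata[[col]] == lev]
        ids <- intersect(ids, rownames(med_tab))
        if (length(ids) < 3L) {
          warning("stratum ", key, " has fewer than 3 samples; NA row emitted")
          rows[[key]] <- data.frame(
            stratum = key, mean_observed_similarity = NA_real_,
            mean_null_similarity = NA_real_, F = NA_real_, p = NA_real_,
            SES = NA_real_, classification = NA_character_)
          next
        }
        r <- observed_vs_null_test(med_tab, group = ids, n_iter = n_iter,
                                   n_perm = n_perm, alpha = alpha,
                                   seed = .stratum_seed(seed, key),
                                   label = key)
        rows[[key]] <- data.frame(
          stratum = key,
          mean_observed_similarity = r$mean_observed_similarity,
          mean_null_similarity = r$mean_null_similarity,
          F = r$F, p = r$p, SES = r$SES,
          classification = r$classification)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
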