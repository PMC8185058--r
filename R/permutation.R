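# Matrix- and label-permutation tests on distance matrices. All tests share
# the same conventions: sampled p-values are (1 + #{extreme}) / (1 + n_perm),
# so p >= 1/(n_perm + 1); when the full permutation group is no larger than
# n_perm the tests enumerate it exhaustively and p is the exact proportion
# of permutations (identity included) at least as extreme as observed.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

# all n! permutations of 1..n as rows (n <= 8 guard upstream)
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

.check_labels <- function(d1, d2) {
  if (is.null(rownames(d1)) || is.null(rownames(d2)) ||
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices must carry identical labels in the same order")
}

# iterate a statistic over permutations; returns c(stat, p, n_perm_used, exact)
.permutation_p <- function(n, n_perm, seed, stat_fn, two_sided) {
  obs <- stat_fn(seq_len(n))
  use_exact <- factorial(n) <= n_perm && n <= 8
  cmp <- if (two_sided) function(x) abs(x) >= abs(obs) - 1e-12
         else function(x) x >= obs - 1e-12
  if (use_exact) {
    perms <- .all_perms(n)
    stats <- apply(perms, 1L, stat_fn)
    p <- mean(cmp(stats))
    list(stat = obs, p = p, n_perm = nrow(perms), exact = TRUE)
  } else {
    hits <- .with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(k) cmp(stat_fn(sample.int(n))),
                 logical(1)))
    })
    list(stat = obs, p = (1 + hits) / (1 + n_perm),
         n_perm = n_perm, exact = FALSE)
  }
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorized off-diagonal entries; significance
#' by jointly permuting rows and columns of the second matrix. The p-value
#' is two-sided on |r|.
#'
#' @param d1,d2 labelled symmetric distance matrices over the same samples.
#' @param n_perm number of permutations (default 999). If the full
#'   permutation group is at most this size, it is enumerated exactly.
#' @param seed optional RNG seed for the permutation draw.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  .check_labels(d1, d2)
  n <- nrow(d1)
  if (n < 4L) stop("Mantel test needs at least 4 samples")
  lt <- which(lower.tri(d1), arr.ind = TRUE)
  v1 <- d1[lt]
  if (stats::sd(v1) == 0 || stats::sd(d2[lt]) == 0)
    stop("zero-variance distance matrix")
  stat_fn <- function(idx) stats::cor(v1, d2[cbind(idx[lt[, 1L]], idx[lt[, 2L]])])
  res <- .permutation_p(n, n_perm, seed, stat_fn, two_sided = TRUE)
  structure(list(r = res$stat, p = res$p, n_perm = res$n_perm,
                 exact = res$exact),
            class = "mantel_result")
}

#' Distance-decay regression
#'
#' Ordinary least squares of pairwise community similarity on pairwise
#' distance (geographic or environmental). Because pairs sharing a sample
#' are not independent, the slope's significance comes from the same
#' matrix-permutation scheme as the Mantel test (two-sided), not from the
#' OLS t statistic.
#'
#' @param similarity square labelled similarity matrix (e.g.
#'   `similarity(bray_curtis(x))`).
#' @param distance labelled distance matrix over the same samples.
#' @inheritParams mantel_test
#' @return list of class `ddr_result`: `slope`, `intercept`, `r_squared`,
#'   `p`, `n_perm`, `exact`.
#' @export
ddr_fit <- function(similarity, distance, n_perm = 999, seed = NULL) {
  s <- as.matrix(similarity); d <- as.matrix(distance)
  .check_labels(s, d)
  n <- nrow(s)
  if (n < 4L) stop("distance-decay fit needs at least 4 samples")
  lt <- which(lower.tri(s), arr.ind = TRUE)
  y <- s[lt]; x <- d[lt]
  if (stats::sd(x) == 0) stop("zero-variance predictor (constant distances)")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  if (stats::sd(y) == 0) {
    res <- list(p = 1, n_perm = 0L, exact = FALSE)
  } else {
    stat_fn <- function(idx)
      stats::cor(y, d[cbind(idx[lt[, 1L]], idx[lt[, 2L]])])
    res <- .permutation_p(n, n_perm, seed, stat_fn, two_sided = TRUE)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p = res$p, n_perm = res$n_perm, exact = res$exact),
            class = "ddr_result")
}

#' Analysis of similarities (ANOSIM)
#'
#' \eqn{R = (\bar r_B - \bar r_W) / (n(n-1)/4)} with ranks over all pairs
#' (ties averaged); significance by group-label permutation (one-sided,
#' large R).
#'
#' @param d labelled distance matrix.
#' @param grouping factor-like group labels, one per sample; every group
#'   must have at least 2 members.
#' @inheritParams mantel_test
#' @return list of class `anosim_result`: `R`, `p`, `n_perm`, `exact`.
#' @export
anosim_test <- function(d, grouping, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) stop("one group label per sample required")
  if (nlevels(droplevels(grouping)) < 2L) stop("need at least two groups")
  if (any(table(grouping) < 2L)) stop("singleton group not allowed")
  lt <- which(lower.tri(d), arr.ind = TRUE)
  rk <- rank(d[lt])
  denom <- n * (n - 1) / 4
  g <- as.integer(grouping)
  stat_fn <- function(idx) {
    gi <- g[idx]
    within <- gi[lt[, 1L]] == gi[lt[, 2L]]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  res <- .permutation_p(n, n_perm, seed, stat_fn, two_sided = FALSE)
  structure(list(R = res$stat, p = res$p, n_perm = res$n_perm,
                 exact = res$exact),
            class = "anosim_result")
}

# pseudo-F from squared pairwise distances and integer group labels
.permanova_F <- function(d2_pairs, pair_i, pair_j, g, sizes, n) {
  a <- length(sizes)
  ss_total <- sum(d2_pairs) / n
  gi <- g[pair_i]; gj <- g[pair_j]
  within <- gi == gj
  ss_within <- sum(d2_pairs[within] / sizes[gi[within]])
  ss_between <- ss_total - ss_within
  if (ss_within <= 1e-12 * max(ss_total, 1))
    return(if (ss_between > 1e-12 * max(ss_total, 1)) Inf else 0)
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Pseudo-F from partitioned squared distances:
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / N}, \eqn{SS_W = \sum_g \sum_{i<j \in g}
#' d_{ij}^2 / n_g}, \eqn{F = (SS_B/(a-1)) / (SS_W/(N-a))}; significance by
#' group-label permutation (one-sided, large F). On Euclidean distances
#' from univariate data the pseudo-F equals the classical one-way ANOVA F.
#'
#' @inheritParams anosim_test
#' @return list of class `permanova_result`: `F`, `p`, `df`, `n_perm`,
#'   `exact`.
#' @export
permanova_test <- function(d, grouping, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) stop("one group label per sample required")
  grouping <- droplevels(grouping)
  a <- nlevels(grouping)
  if (a < 2L) stop("need at least two groups")
  if (any(table(grouping) < 2L)) stop("singleton group not allowed")
  if (n - a < 1L) stop("degenerate residual degrees of freedom")
  lt <- which(lower.tri(d), arr.ind = TRUE)
  d2 <- d[lt]^2
  g <- as.integer(grouping)
  sizes <- as.numeric(table(g))
  stat_fn <- function(idx)
    .permanova_F(d2, lt[, 1L], lt[, 2L], g[idx], sizes, n)
  res <- .permutation_p(n, n_perm, seed, stat_fn, two_sided = FALSE)
  structure(list(F = res$stat, p = res$p,
                 df = c(between = a - 1L, within = n - a),
                 n_perm = res$n_perm, exact = res$exact),
            class = "permanova_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, if (x$exact) "exact" else "sampled", x$n_perm))
  invisible(x)
}

#' @export
print.ddr_result <- function(x, ...) {
  cat(sprintf(
    "Distance-decay: slope = %.4g, intercept = %.4g, R2 = %.3f, p = %.4g\n",
    x$slope, x$intercept, x$r_squared, x$p))
  invisible(x)
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$R, x$p, if (x$exact) "exact" else "sampled", x$n_perm))
  invisible(x)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F(%d, %d) = %.4f, p = %.4g (%s, %d permutations)\n",
              x$df[1L], x$df[2L], x$F, x$p,
              if (x$exact) "exact" else "sampled", x$n_perm))
  invisible(x)
}
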