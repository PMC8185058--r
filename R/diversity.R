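# Alpha diversity indices and the omnibus group test used to compare them
# across regions and peatland types.

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log p_i} over observed species, natural log by
#' default (the convention of the common amplicon toolchains).
#'
#' @param counts non-negative numeric vector of species counts.
#' @param base logarithm base.
#' @return the index (0 for a single species).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (all(counts == 0)) stop("all-zero sample")
  if (any(counts < 0)) stop("negative counts")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Simpson index (finite-sample probability of identity)
#'
#' \eqn{D = \sum_i n_i (n_i - 1) / (N (N - 1))}: the probability that two
#' reads drawn without replacement are the same species. Smaller values
#' mean more diverse communities; 1 for a single species. Variants are
#' available: `"complement"` gives \eqn{1 - D}, `"inverse"` gives
#' \eqn{1 / D}.
#'
#' @param counts non-negative numeric vector with total >= 2.
#' @param variant which form of the index to return.
#' @return the index.
#' @export
simpson <- function(counts, variant = c("identity", "complement", "inverse")) {
  variant <- match.arg(variant)
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n < 2) stop("Simpson index needs a total of at least 2 reads")
  d <- sum(counts * (counts - 1)) / (n * (n - 1))
  switch(variant, identity = d, complement = 1 - d, inverse = 1 / d)
}

#' Good's coverage
#'
#' \eqn{1 - F_1 / N}, with \eqn{F_1} the number of singleton species: the
#' estimated fraction of the community represented in the sample.
#'
#' @param counts non-negative numeric vector with positive total.
#' @return coverage in \[0, 1\].
#' @export
goods_coverage <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n <= 0) stop("all-zero sample")
  1 - sum(counts == 1) / n
}

#' Per-sample alpha diversity table
#'
#' @param table OTU count matrix, samples in rows.
#' @return data.frame `sample_id`, `shannon`, `simpson`, `goods_coverage`.
#' @export
alpha_diversity <- function(table) {
  table <- as.matrix(table)
  data.frame(sample_id = rownames(table),
             shannon = apply(table, 1, shannon),
             simpson = apply(table, 1, simpson),
             goods_coverage = apply(table, 1, goods_coverage),
             row.names = NULL)
}

#' One-way ANOVA on diversity indices
#'
#' Classical between/within mean-square F with (a - 1, N - a) degrees of
#' freedom (equal variances assumed), computed by [stats::oneway.test()].
#'
#' @param groups either a list of numeric vectors (one per group) or a
#'   numeric vector (with `group` giving the labels).
#' @param group optional grouping factor when `groups` is a vector.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups, group = NULL) {
  if (!is.null(group)) {
    values <- as.numeric(groups)
    group <- as.factor(group)
  } else {
    stopifnot(is.list(groups))
    values <- unlist(groups, use.names = FALSE)
    group <- factor(rep(seq_along(groups), lengths(groups)))
  }
  sizes <- table(group)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 2L)) stop("each group needs at least two values")
  wvar <- sum(vapply(split(values, group), function(x)
    sum((x - mean(x))^2), 0))
  if (wvar == 0) stop("zero within-group variance in every group")
  fit <- stats::oneway.test(values ~ group, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df_between = unname(fit$parameter[1L]),
       df_within = unname(fit$parameter[2L]))
}
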