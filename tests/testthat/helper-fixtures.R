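# Shared generators and independent brute-force oracles. Oracles are
# deliberately naive (double loops, full enumeration) and never call the
# package functions they check.

rand_otu <- function(n_samples, n_otus, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda = runif(1, 2, max_count / 2)),
              n_samples, n_otus)
  # ensure every sample has a positive total
  m[, 1] <- m[, 1] + 1L
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("OTU", seq_len(n_otus)))
  storage.mode(m) <- "integer"
  m
}

rand_taxonomy <- function(otu_ids, seed = 1) {
  set.seed(seed)
  ref <- load_guild_reference()
  data.frame(otu_id = otu_ids,
             genus = sample(c(names(ref), "Bacillus", "Nitrospira"),
                            length(otu_ids), replace = TRUE),
             best_hit_similarity = round(runif(length(otu_ids), 90, 100), 2))
}

# --- oracles ---------------------------------------------------------

bray_brute <- function(u, v) sum(abs(u - v)) / sum(u + v)

euclid_brute <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  d
}

anova_F_brute <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  msb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0)) / (k - 1)
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (n - k)
  msb / msw
}

haversine_brute <- function(lat1, lon1, lat2, lon2, r = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# full enumeration of permutations by successive insertion, structurally
# independent of the package's recursion
perms_brute <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_brute(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

permanova_F_brute <- function(d, labels) {
  n <- nrow(d)
  ss_tot <- sum(d[lower.tri(d)]^2) / n
  ss_w <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    sub <- d[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(labels))
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

anosim_R_brute <- function(d, labels) {
  n <- nrow(d)
  pairs <- which(lower.tri(d), arr.ind = TRUE)
  rk <- rank(d[pairs])
  within <- labels[pairs[, 1]] == labels[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}
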