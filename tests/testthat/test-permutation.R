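test_that("Mantel r is exact under affine relations and p matches enumeration", {
  m <- rand_otu(6, 15, seed = 21)
  d1 <- bray_curtis(m)
  d2 <- 2 * unclass(as.matrix(d1))
  dimnames(d2) <- dimnames(d1)
  expect_equal(mantel_test(d1, d2, n_perm = 99)$r, 1.0)

  # n = 4: full enumeration of the 24 relabelings equals a brute-force oracle
  set.seed(31)
  a <- matrix(runif(16), 4); a <- a + t(a); diag(a) <- 0
  b <- matrix(runif(16), 4); b <- b + t(b); diag(b) <- 0
  dimnames(a) <- dimnames(b) <- list(paste0("s", 1:4), paste0("s", 1:4))
  got <- mantel_test(a, b, n_perm = 999)
  expect_true(got$exact)
  lt <- lower.tri(a)
  r_obs <- cor(a[lt], b[lt])
  rs <- vapply(perms_brute(4), function(p) cor(a[lt], b[p, p][lt]), 0)
  expect_equal(got$r, r_obs)
  expect_equal(got$p, mean(abs(rs) >= abs(r_obs) - 1e-12))

  bad <- b
  rownames(bad) <- colnames(bad) <- paste0("x", 1:4)
  expect_error(mantel_test(a, bad), "labels")
})

test_that("Mantel agrees with an independent implementation on the statistic", {
  m <- rand_otu(12, 30, seed = 22)
  d1 <- bray_curtis(m)
  set.seed(1)
  coords <- data.frame(site_id = rownames(m), latitude = runif(12, 40, 50),
                       longitude = runif(12, 120, 130))
  d2 <- haversine_matrix(coords)
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("distance-decay regression recovers exact linear relations", {
  set.seed(41)
  n <- 8
  d <- matrix(runif(n * n, 10, 500), n); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  s <- 0.9 - 0.001 * d
  diag(s) <- 1
  fit <- ddr_fit(s, d, n_perm = 99, seed = 2)
  expect_equal(fit$slope, -0.001, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  s0 <- matrix(0.5, n, n, dimnames = dimnames(d))
  diag(s0) <- 1
  fit0 <- ddr_fit(s0, d, n_perm = 99)
  expect_equal(fit0$slope, 0)
  const_d <- matrix(1, n, n, dimnames = dimnames(d)); diag(const_d) <- 0
  expect_error(ddr_fit(s, const_d), "zero-variance predictor")
})

test_that("ANOSIM hits its closed-form extremes and exact enumeration", {
  labs <- rep(c("a", "b"), each = 3)
  flat <- matrix(1, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  diag(flat) <- 0
  expect_equal(anosim_test(flat, labs, n_perm = 99)$R, 0)

  sep <- matrix(1, 6, 6)
  sep[1:3, 1:3] <- 0.1
  sep[4:6, 4:6] <- 0.1
  diag(sep) <- 0
  dimnames(sep) <- dimnames(flat)
  expect_equal(anosim_test(sep, labs, n_perm = 99)$R, 1)

  set.seed(51)
  d <- matrix(runif(36), 6); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- dimnames(flat)
  got <- anosim_test(d, labs, n_perm = 999)
  expect_true(got$exact)
  r_all <- vapply(perms_brute(6),
                  function(p) anosim_R_brute(d, labs[p]), 0)
  expect_equal(got$R, anosim_R_brute(d, labs))
  expect_equal(got$p, mean(r_all >= got$R - 1e-12))
  ref <- suppressWarnings(vegan::anosim(as.dist(d), labs, permutations = 9))
  expect_equal(got$R, unname(ref$statistic), tolerance = 1e-10)

  expect_error(anosim_test(d, c("a", "a", "a", "a", "a", "b")), "singleton")
})

test_that("PERMANOVA matches enumeration, ANOVA, and an independent implementation", {
  labs <- rep(c("a", "b"), each = 3)
  set.seed(61)
  d <- matrix(runif(36, 0.2, 1), 6); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  got <- permanova_test(d, labs, n_perm = 999)
  expect_true(got$exact)
  f_all <- vapply(perms_brute(6),
                  function(p) permanova_F_brute(d, labs[p]), 0)
  expect_equal(got$F, permanova_F_brute(d, labs))
  expect_equal(got$p, mean(f_all >= got$F - 1e-12))

  # identical samples: all distances zero -> F degenerate at 0, p = 1
  z <- matrix(0, 6, 6, dimnames = dimnames(d))
  expect_equal(permanova_test(z, labs, n_perm = 99)$p, 1)

  # univariate Euclidean pseudo-F equals the classical ANOVA F
  for (s in 1:5) {
    set.seed(s)
    y <- rnorm(12)
    g <- rep(c("a", "b", "c"), each = 4)
    dy <- as.matrix(dist(y))
    dimnames(dy) <- list(paste0("s", 1:12), paste0("s", 1:12))
    expect_equal(permanova_test(dy, g, n_perm = 9)$F,
                 one_way_anova(split(y, g))$F, tolerance = 1e-8)
  }

  # pseudo-F agrees with an independent implementation
  m <- rand_otu(10, 20, seed = 62)
  bc <- bray_curtis(m)
  g10 <- rep(c("a", "b"), each = 5)
  ours <- permanova_test(bc, g10, n_perm = 99, seed = 3)
  ref <- vegan::adonis2(as.dist(bc) ~ g10, permutations = 9)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-10)
})

test_that("sampled permutation p-values respect their lower bound", {
  m <- rand_otu(10, 25, seed = 71)
  d1 <- bray_curtis(m)
  d2 <- bray_curtis(m[, sample(ncol(m))] + rand_otu(10, 25, seed = 72))
  g <- rep(c("a", "b"), each = 5)
  for (np in c(19, 99)) {
    expect_gte(mantel_test(d1, d2, n_perm = np, seed = 1)$p, 1 / (np + 1))
    expect_gte(anosim_test(d1, g, n_perm = np, seed = 1)$p, 1 / (np + 1))
    expect_gte(permanova_test(d1, g, n_perm = np, seed = 1)$p, 1 / (np + 1))
  }
})
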