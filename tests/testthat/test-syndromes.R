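vp_table <- function(y, species, individual) {
  tibble::tibble(species = species, individual_id = individual, m = y)
}

test_that("species-only differences put 100% of variance at the species level", {
  d <- vp_table(rep(c(1, 2, 3), each = 6),
                rep(c("s1", "s2", "s3"), each = 6),
                rep(sprintf("i%d", 1:9), each = 2))
  vp <- variance_partition(d, metrics = "m")
  expect_equal(vp$pct_species, 100)
  expect_equal(vp$pct_individual, 0)
})

test_that("equal species means put ~0% at the species level", {
  set.seed(80)
  ind_eff <- rnorm(10)
  d <- vp_table(rep(ind_eff, each = 5) + rnorm(50, 0, 1e-6),
                rep(c("s1", "s2"), each = 25),
                rep(sprintf("i%d", 1:10), each = 5))
  # recenter so species means are exactly equal
  d$m[d$species == "s1"] <- d$m[d$species == "s1"] -
    mean(d$m[d$species == "s1"])
  d$m[d$species == "s2"] <- d$m[d$species == "s2"] -
    mean(d$m[d$species == "s2"])
  vp <- variance_partition(d, metrics = "m")
  expect_lt(vp$pct_species, 1e-6)
})

test_that("nested SS decomposition matches a brute-force computation", {
  set.seed(81)
  species <- rep(c("s1", "s2", "s3"), times = c(12, 16, 8))
  individual <- paste0(species, "_", rep(c(1, 2, 3, 4), times = 9)[1:36])
  y <- rnorm(36, ave(seq_len(36), species), 2)
  d <- vp_table(y, species, individual)
  vp <- variance_partition(d, metrics = "m")
  # brute-force sums of squares
  gm <- mean(y)
  sp_mean <- ave(y, species)
  ind_mean <- ave(y, individual)
  ss_sp <- sum((sp_mean - gm)^2)
  ss_ind <- sum((ind_mean - sp_mean)^2)
  ss_tot <- sum((y - gm)^2)
  expect_equal(vp$pct_species, 100 * ss_sp / ss_tot, tolerance = 1e-9)
  expect_equal(vp$pct_individual, 100 * ss_ind / ss_tot, tolerance = 1e-9)
  # F against the individual-within-species mean square
  df_sp <- 2; df_ind <- length(unique(individual)) - 3
  expect_equal(vp$statistic, (ss_sp / df_sp) / (ss_ind / df_ind),
               tolerance = 1e-9)
  expect_equal(vp$df1, df_sp)
  expect_equal(vp$df2, df_ind)
})

test_that("variance percentages are invariant to adding a constant", {
  set.seed(82)
  d <- vp_table(rnorm(24, rep(1:4, each = 6)),
                rep(c("s1", "s2"), each = 12),
                rep(sprintf("i%d", 1:8), each = 3))
  v1 <- variance_partition(d, metrics = "m")
  d$m <- d$m + 1000
  v2 <- variance_partition(d, metrics = "m")
  expect_equal(v1$pct_species, v2$pct_species, tolerance = 1e-6)
  expect_equal(v1$pct_individual, v2$pct_individual, tolerance = 1e-6)
})

test_that("single species or zero variance raise informative errors", {
  d <- vp_table(rnorm(10), rep("s1", 10), sprintf("i%d", 1:10))
  expect_error(variance_partition(d, metrics = "m"),
               class = "msms_config_error")
  d2 <- vp_table(rep(1, 10), rep(c("s1", "s2"), 5), sprintf("i%d", 1:10))
  expect_error(variance_partition(d2, metrics = "m"),
               class = "msms_degenerate_data")
})

pca_table <- function(n = 10, p = 4, seed = 83) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  d <- tibble::as_tibble(setNames(as.data.frame(X), paste0("m", 1:p)))
  d$species <- rep(c("s1", "s2"), length.out = n)
  d$individual_id <- sprintf("i%d", 1:n)
  d
}

test_that("rank-1 metric tables load entirely on the first component", {
  d <- pca_table(12, 1)
  d$m2 <- 2 * d$m1; d$m3 <- -0.5 * d$m1
  sp <- pca_syndromes(d, metrics = c("m1", "m2", "m3"), log_metrics = NULL)
  expect_equal(sp$pct_variance[1], 100, tolerance = 1e-9)
  expect_equal(sum(sp$eigenvalues), 3, tolerance = 1e-9)
})

test_that("eigenvalues sum to the number of metrics (correlation PCA)", {
  d <- pca_table(20, 5)
  sp <- pca_syndromes(d, metrics = paste0("m", 1:5), log_metrics = NULL)
  expect_equal(sum(sp$eigenvalues), 5, tolerance = 1e-12)
  # scores orthogonal across components
  S <- as.matrix(sp$scores[, paste0("PC", 1:5)])
  G <- crossprod(S)
  expect_equal(G[lower.tri(G)], rep(0, 10), tolerance = 1e-8)
})

test_that("loadings match an independent eigensolver oracle up to sign", {
  d <- pca_table(10, 4, seed = 84)
  sp <- pca_syndromes(d, metrics = paste0("m", 1:4), log_metrics = NULL)
  pr <- prcomp(d[, paste0("m", 1:4)], center = TRUE, scale. = TRUE)
  for (j in 1:4) {
    expect_equal(unname(abs(sp$loadings[, j])),
                 abs(unname(pr$rotation[, j])), tolerance = 1e-8)
    expect_equal(abs(sp$eigenvalues[j]), unname(pr$sdev[j]^2),
                 tolerance = 1e-8)
  }
  # deterministic sign: dominant metric of each component loads positive
  for (j in 1:4) expect_gt(sp$loadings[which.max(abs(sp$loadings[, j])), j], 0)
})

test_that("PCA scores are invariant to affine rescaling of inputs", {
  d <- pca_table(15, 3, seed = 85)
  s1 <- pca_syndromes(d, metrics = paste0("m", 1:3), log_metrics = NULL)
  d2 <- d
  d2$m1 <- 100 * d2$m1 - 7
  d2$m3 <- 0.01 * d2$m3 + 2
  s2 <- pca_syndromes(d2, metrics = paste0("m", 1:3), log_metrics = NULL)
  expect_equal(s2$scores$PC1, s1$scores$PC1, tolerance = 1e-9)
  expect_equal(s2$eigenvalues, s1$eigenvalues, tolerance = 1e-12)
})

test_that("constant metrics are dropped with a warning; log transform applies", {
  d <- pca_table(10, 3, seed = 86)
  d$m4 <- 5
  expect_warning(sp <- pca_syndromes(d, metrics = paste0("m", 1:4),
                                     log_metrics = NULL), "zero-variance")
  expect_equal(length(sp$metrics), 3)
  # log transform: exp(m1) logged back is m1; the duplicated columns load
  # identically on every informative (nonzero-eigenvalue) component
  d2 <- pca_table(10, 2, seed = 87)
  d2$straightness <- exp(d2$m1)
  s_log <- pca_syndromes(d2, metrics = c("m1", "m2", "straightness"))
  keep <- s_log$eigenvalues > 1e-8
  expect_equal(unname(s_log$loadings["straightness", keep]),
               unname(s_log$loadings["m1", keep]), tolerance = 1e-8)
})

test_that("well-separated score blobs are recovered by Ward clustering", {
  set.seed(88)
  centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
  truth <- rep(1:3, each = 8)
  X <- centers[truth, ] + matrix(rnorm(48, 0, 0.5), 24, 2)
  d <- tibble::tibble(m1 = X[, 1], m2 = X[, 2],
                      m3 = X[, 1] + rnorm(24, 0, 0.3),
                      species = "s1", individual_id = sprintf("i%d", 1:24))
  sp <- pca_syndromes(d, metrics = c("m1", "m2", "m3"), log_metrics = NULL)
  cl <- cluster_individuals(sp, k = 3)
  tab <- table(truth, cl$assignments$cluster)
  expect_equal(sum(apply(tab, 1, max)), 24)  # perfect recovery
  expect_gt(cl$mean_silhouette, 0.5)
})

test_that("k = n-1 yields singletons; duplicate rows co-cluster; bad k errors", {
  d <- pca_table(8, 3, seed = 89)
  d[8, c("m1", "m2", "m3")] <- d[7, c("m1", "m2", "m3")]
  sp <- pca_syndromes(d, metrics = paste0("m", 1:3), log_metrics = NULL)
  cl <- cluster_individuals(sp, k = 7)
  expect_true(any(table(cl$assignments$cluster) == 1))
  expect_equal(cl$assignments$cluster[7], cl$assignments$cluster[8])
  expect_error(cluster_individuals(sp, k = 1), class = "msms_config_error")
  expect_error(cluster_individuals(sp, k = 8), class = "msms_config_error")
})
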