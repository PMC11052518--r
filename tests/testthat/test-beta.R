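test_that("dissimilarities reproduce boundary cases and hand sums", {
  x <- c(10, 0, 5)
  expect_equal(bray_curtis(x, x), 0)
  expect_equal(bray_curtis(c(3, 0), c(0, 9)), 1)
  expect_equal(bray_curtis(c(10, 0, 5), c(5, 5, 5)), 1 / 3)
  expect_equal(jaccard_binary(c(2, 1, 9), c(5, 3, 1)), 0)
  expect_equal(jaccard_binary(c(1, 0), c(0, 1)), 1)
  # supports {a,b,c} vs {b,c,d}: 1 - 2/4
  expect_equal(jaccard_binary(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(jaccard_quant(c(2, 2), c(1, 4)), 1 - 3 / 6)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("distance_matrix is symmetric, zero-diagonal, matches loops", {
  sim <- simulate_community(community_design(
    species = "A", seasons = "spring", gut_parts = "whole",
    samples_per_cell = 10, n_asvs = 40, depth_meanlog = log(800),
    depth_sdlog = 0, seed = 2))
  for (m in c("bray_curtis", "jaccard")) {
    D <- distance_matrix(sim$table, m)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, ncol(D)))
    expect_true(all(D >= 0 & D <= 1))
    fun <- if (m == "bray_curtis") bray_curtis else jaccard_binary
    for (i in 1:9) for (j in (i + 1):10)
      expect_equal(D[i, j], fun(sim$table[, i], sim$table[, j]))
  }
  one <- distance_matrix(toy_table(matrix(c(1, 2), 2, 1)))
  expect_equal(dim(one), c(1, 1))
  expect_equal(one[1, 1], 0)
})

test_that("distance matrices agree with vegan::vegdist", {
  skip_if_not_installed("vegan")
  sim <- simulate_community(community_design(
    species = "A", seasons = "spring", gut_parts = "whole",
    samples_per_cell = 8, n_asvs = 50, depth_meanlog = log(600),
    depth_sdlog = 0, seed = 4))
  comm <- t(unclass(sim$table))
  expect_equal(unname(distance_matrix(sim$table, "bray_curtis")),
               unname(as.matrix(vegan::vegdist(comm, "bray"))),
               ignore_attr = TRUE)
  expect_equal(unname(distance_matrix(sim$table, "jaccard")),
               unname(as.matrix(vegan::vegdist(comm, "jaccard",
                                               binary = TRUE))),
               ignore_attr = TRUE)
  expect_equal(unname(distance_matrix(sim$table, "jaccard_quant")),
               unname(as.matrix(vegan::vegdist(comm, "jaccard"))),
               ignore_attr = TRUE)
})

test_that("NMDS embeds exactly embeddable configurations at ~zero stress", {
  # three equidistant points form an equilateral triangle in the plane
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  r3 <- nmds(D3, k = 2, n_starts = 5, seed = 1)
  expect_lt(r3$stress, 1e-6)
  # four points drawn in the plane
  set.seed(2)
  X <- matrix(rnorm(8), 4, 2)
  D4 <- as.matrix(dist(X))
  dimnames(D4) <- list(letters[1:4], letters[1:4])
  r4 <- nmds(D4, k = 2, n_starts = 5, seed = 1)
  expect_lt(r4$stress, 1e-3)
  expect_error(nmds(D3, k = 3), "more samples")
})

test_that("NMDS stress is non-increasing within every start", {
  sim <- simulate_community(community_design(
    species = c("A", "B"), seasons = "spring", gut_parts = "whole",
    samples_per_cell = 6, n_asvs = 60, depth_meanlog = log(900),
    depth_sdlog = 0, seed = 13))
  D <- distance_matrix(sim$table, "bray_curtis")
  r <- nmds(D, k = 2, n_starts = 8, seed = 3)
  for (tr in r$stress_trace)
    expect_true(all(diff(tr) <= 1e-12))
  expect_equal(r$stress, min(r$per_start_stress))
  expect_equal(dim(r$points), c(ncol(D), 2))
  # centred and principal-axis rotated
  expect_equal(unname(colMeans(r$points)), c(0, 0), tolerance = 1e-8)
})

test_that("PERMANOVA matches the loop oracle and vegan::adonis2", {
  sim <- simulate_community(community_design(
    species = c("A", "B"), seasons = "spring", gut_parts = "whole",
    samples_per_cell = 8, n_asvs = 80, seed = 3,
    depth_meanlog = log(3000), depth_sdlog = 0))
  D <- distance_matrix(sim$table, "bray_curtis")
  g <- sim$metadata$species[match(colnames(sim$table),
                                  sim$metadata$sample_id)]
  pa <- permanova(D, g, n_perm = 199, seed = 1)
  expect_equal(pa$pseudo_F, permanova_f_oracle(D, g))
  expect_gte(pa$p_perm, 1 / 200)
  expect_true(pa$R2 >= 0 && pa$R2 <= 1)
  if (requireNamespace("vegan", quietly = TRUE)) {
    ad <- vegan::adonis2(stats::as.dist(D) ~ g, permutations = 99)
    expect_equal(pa$pseudo_F, ad$F[1])
    expect_equal(pa$R2, ad$R2[1])
  }
  expect_error(permanova(D, rep("A", length(g))), "two groups")
})

test_that("exhaustive PERMANOVA and MRPP equal full-enumeration oracles", {
  set.seed(9)
  Y <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(Y))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  g <- rep(c("a", "b"), each = 3)
  pa <- permanova(D, g, exhaustive = TRUE)
  expect_equal(pa$n_perm, 20)            # C(6,3) distinct assignments
  expect_equal(pa$p_perm, perm_p_oracle(D, g, permanova_f_oracle))
  mr <- mrpp(D, g, exhaustive = TRUE)
  expect_equal(mr$delta_observed, mrpp_delta_oracle(D, g))
  expect_equal(mr$p_perm,
               perm_p_oracle(D, g, mrpp_delta_oracle, lower = TRUE))
  expect_equal(mr$A, 1 - mr$delta_observed / mr$delta_expected)
})

test_that("MRPP matches vegan's delta and detects planted separation", {
  skip_if_not_installed("vegan")
  sim <- simulate_community(community_design(
    species = "A", seasons = "spring",
    gut_parts = c("foregut", "hindgut"), samples_per_cell = 10,
    n_asvs = 80, species_effect = 0, season_effect = 0,
    gutpart_effect = 2, depth_meanlog = log(2000), depth_sdlog = 0,
    seed = 6))
  D <- distance_matrix(sim$table, "bray_curtis")
  g <- sim$metadata$gut_part[match(colnames(sim$table),
                                   sim$metadata$sample_id)]
  mr <- mrpp(D, g, n_perm = 999, seed = 2)
  vm <- vegan::mrpp(stats::as.dist(D), g, permutations = 99)
  expect_equal(mr$delta_observed, vm$delta)
  expect_gt(mr$A, 0)
  expect_equal(mr$p_perm, 1 / 1000)      # minimal attainable p
})

test_that("null labels give A near zero and uniform-ish p", {
  set.seed(31)
  as <- numeric(20)
  for (i in 1:20) {
    Y <- matrix(rnorm(32), 16, 2)
    D <- as.matrix(dist(Y))
    dimnames(D) <- list(paste0("s", 1:16), paste0("s", 1:16))
    g <- rep(c("a", "b"), each = 8)
    as[i] <- mrpp(D, g, n_perm = 99, seed = i)$A
  }
  expect_lt(abs(median(as)), 0.05)
})

test_that("duplicated-then-relabelled samples are not declared distinct", {
  set.seed(17)
  base <- matrix(rpois(60, 8), 10, 6,
                 dimnames = list(paste0("a", 1:10), paste0("s", 1:6)))
  tab <- asv_table(cbind(base, `colnames<-`(base, paste0("t", 1:6))))
  D <- distance_matrix(tab, "bray_curtis")
  g <- rep(c("g1", "g2"), each = 6)
  set.seed(1)
  # the two groups are the same six samples relabelled: no real signal
  expect_gt(permanova(D, g, n_perm = 199, seed = 3)$p_perm, 0.05)
})
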