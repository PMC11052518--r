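test_that("prevalence filter applies the strict more-than-half rule", {
  # asv1 in 3/6 samples (exactly half): dropped; asv2 in 4/6: kept
  m <- toy_table(rbind(c(1, 1, 1, 0, 0, 0),
                       c(1, 1, 1, 1, 0, 0),
                       c(5, 5, 5, 5, 5, 5)))
  filt <- prevalence_filter(m)
  expect_setequal(rownames(filt), c("asv2", "asv3"))
  # brute-force presence-count oracle on a random table
  set.seed(1)
  big <- toy_table(matrix(rbinom(300, 1, 0.4) * rpois(300, 5), 30, 10))
  f2 <- prevalence_filter(big)
  keep <- apply(unclass(big), 1, function(r) sum(r > 0) > 5)
  expect_setequal(rownames(f2), rownames(big)[keep])
  expect_error(prevalence_filter(toy_table(matrix(1, 2, 3))),
               "at least 4 samples")
  empty <- toy_table(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  expect_error(prevalence_filter(empty), "empty")
})

test_that("Spearman matrix is exact on monotone pairs and tied data", {
  m <- toy_table(rbind(c(1, 5, 9, 12, 20, 44),
                       c(2, 6, 11, 30, 31, 90),   # monotone with row 1
                       c(9, 2, 7, 1, 4, 3)))
  R <- spearman_matrix(m)
  expect_equal(R["asv1", "asv2"], 1)
  # invariant under per-ASV monotone transforms
  m2 <- unclass(m); m2[1, ] <- m2[1, ]^3; m2[3, ] <- m2[3, ]^2
  expect_equal(unname(spearman_matrix(asv_table(m2))["asv1", "asv3"]),
               unname(R["asv1", "asv3"]), tolerance = 1e-12)
  # tie-laden case against the rank-then-Pearson oracle
  a <- c(3, 3, 0, 7, 7, 1); b <- c(2, 2, 2, 9, 1, 1)
  tied <- toy_table(rbind(a, b, c(1, 2, 3, 4, 5, 6)))
  Rt <- spearman_matrix(tied)
  expect_equal(unname(Rt[1, 2]), cor(rank(a), rank(b)))
  # zero-variance ASVs excluded with a warning
  cst <- toy_table(rbind(c(1, 2, 3, 4), c(5, 5, 5, 5)))
  expect_warning(Rc <- spearman_matrix(rbind(unclass(cst),
                                             asv3 = c(2, 1, 9, 4))),
                 "zero-variance")
  expect_false("asv2" %in% rownames(Rc))
  expect_error(spearman_matrix(toy_table(matrix(1:6, 2, 3))), "4 samples")
})

test_that("NNSD discriminator separates GOE from Poisson spectra", {
  set.seed(11)
  goe_rej <- 0; iid_acc <- 0
  for (i in 1:20) {
    ev <- eigen(rgoe(150), symmetric = TRUE, only.values = TRUE)$values
    if (nnsd_poisson_gof(ev)$p_poisson < 0.05) goe_rej <- goe_rej + 1
    if (nnsd_poisson_gof(sort(runif(150)))$p_poisson >= 0.05)
      iid_acc <- iid_acc + 1
  }
  expect_gte(goe_rej, 18)
  expect_gte(iid_acc, 18)
  # too few eigenvalues is flagged, not silently tested
  expect_false(nnsd_poisson_gof(rnorm(10))$evaluable)
})

test_that("RMT scan picks a low threshold for structureless correlations", {
  sim <- simulate_correlated_counts(planted_network_design(
    rho = 0, n_blocks = 3, block_size = 20, n_samples = 25, seed = 3))
  R <- spearman_matrix(sim$table)
  scan <- rmt_threshold(R)
  expect_lte(scan$chosen_threshold, 0.45)
  expect_true(scan$chosen_threshold %in% scan$scan$threshold)
  expect_true(all(diff(scan$scan$threshold) > 0))
})

test_that("RMT-thresholded pipeline separates strong planted blocks", {
  sim <- simulate_correlated_counts(planted_network_design(seed = 1))
  net <- conet(sim$table)
  tr <- sim$truth
  ari <- adjusted_rand_index(net$membership[tr$asv_id],
                             tr$block)
  expect_gte(ari, 0.9)
  # edge count shrinks (weakly) as the threshold rises
  R <- spearman_matrix(sim$table)
  counts <- vapply(seq(0.3, 0.9, 0.1), function(t)
    sum(abs(R[upper.tri(R)]) >= t), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("build_network reproduces the brute-force edge set", {
  set.seed(5)
  n <- 12
  R <- matrix(runif(n * n, -1, 1), n, n)
  R <- (R + t(R)) / 2; diag(R) <- 1
  dimnames(R) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  net <- build_network(R, 0.5)
  got <- with(net$edges, sort(paste(pmin(node1, node2),
                                    pmax(node1, node2))))
  want <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (abs(R[i, j]) >= 0.5)
      want <- c(want, paste(sprintf("v%02d", i), sprintf("v%02d", j)))
  expect_identical(got, sort(want))
  expect_true(all(abs(net$edges$rho) >= 0.5))
  expect_identical(unique(net$edges$sign[net$edges$rho < 0]), "-")
  expect_error(build_network(R, 0.999), "no edges")
  # threshold ~0 gives the complete graph
  full <- build_network(R, 1e-9)
  expect_equal(nrow(full$edges), n * (n - 1) / 2)
})

test_that("module detection handles cliques and disjoint components", {
  R <- diag(6)
  blocks <- list(1:3, 4:6)
  for (b in blocks) for (i in b) for (j in b) if (i != j) R[i, j] <- 0.9
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  net <- detect_modules(build_network(R, 0.5))
  expect_equal(net$n_modules, 2)
  expect_length(unique(net$membership[paste0("v", 1:3)]), 1)
  expect_length(unique(net$membership[paste0("v", 4:6)]), 1)
  # single clique is one module; repeated runs identical
  R1 <- matrix(0.8, 4, 4); diag(R1) <- 1
  dimnames(R1) <- list(letters[1:4], letters[1:4])
  n1 <- detect_modules(build_network(R1, 0.5))
  expect_equal(n1$n_modules, 1)
  expect_identical(detect_modules(build_network(R1, 0.5))$membership,
                   n1$membership)
})

test_that("greedy modularity is bounded by the exhaustive optimum", {
  set.seed(23)
  checked <- 0
  tot_q <- 0; tot_best <- 0
  for (g in 1:50) {
    n <- sample(6:8, 1)
    net <- random_conet(n, 0.35, seed = 100 + g)
    net <- detect_modules(net)
    q_greedy <- igraph::modularity(net$graph,
                                   net$membership[igraph::V(net$graph)$name])
    edges <- as.matrix(net$edges[, c("node1", "node2")])
    nodes <- net$nodes
    best <- -Inf
    for (p in all_set_partitions(length(nodes))) {
      memb <- stats::setNames(p, nodes)
      best <- max(best, modularity_oracle(edges, memb))
    }
    # never exceeds the exhaustive optimum (per graph)
    expect_lte(q_greedy, best + 1e-9)
    if (best > 1e-9) {
      tot_q <- tot_q + q_greedy
      tot_best <- tot_best + best
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
  # achieves at least 90% of the attainable modularity over the sweep
  expect_gte(tot_q / tot_best, 0.9)
})

test_that("network statistics reproduce closed forms and oracles", {
  # complete graph K4
  R <- matrix(0.9, 4, 4); diag(R) <- 1
  dimnames(R) <- list(letters[1:4], letters[1:4])
  k4 <- detect_modules(build_network(R, 0.5))
  s4 <- network_stats(k4)
  expect_equal(s4$avgCC, 1)
  expect_equal(s4$GD, 1)
  expect_equal(s4$M, 0)                  # single module has Q = 0
  expect_equal(s4$n_nodes, 4); expect_equal(s4$n_links, 6)
  # path a-b-c
  Rp <- diag(3); Rp[1, 2] <- Rp[2, 1] <- 0.9; Rp[2, 3] <- Rp[3, 2] <- 0.9
  dimnames(Rp) <- list(letters[1:3], letters[1:3])
  pth <- detect_modules(build_network(Rp, 0.5))
  sp <- network_stats(pth)
  expect_equal(sp$avgCC, 0)
  expect_equal(sp$GD, 4 / 3)
  # two disjoint triangles with the 2-module partition: M = 0.5
  Rt <- diag(6)
  for (b in list(1:3, 4:6)) for (i in b) for (j in b)
    if (i != j) Rt[i, j] <- 0.9
  dimnames(Rt) <- list(paste0("v", 1:6), paste0("v", 1:6))
  tri <- detect_modules(build_network(Rt, 0.5))
  expect_equal(network_stats(tri)$M, 0.5)
})

test_that("average path distance matches Floyd-Warshall on random graphs", {
  for (s in 1:5) {
    net <- detect_modules(random_conet(sample(10:20, 1), 0.2,
                                       seed = 400 + s))
    adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
    d <- fw_distances(adj)
    vals <- d[upper.tri(d)]
    expect_equal(network_stats(net)$GD, mean(vals[is.finite(vals)]))
  }
})

test_that("network stats recomputed from the exported edge list agree", {
  sim <- simulate_correlated_counts(planted_network_design(seed = 4))
  net <- conet(sim$table)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(net$edges, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  edges <- utils::read.table(f, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  R2 <- diag(length(net$nodes))
  dimnames(R2) <- list(net$nodes, net$nodes)
  for (r in seq_len(nrow(edges)))
    R2[edges$node1[r], edges$node2[r]] <-
      R2[edges$node2[r], edges$node1[r]] <- edges$rho[r]
  net2 <- detect_modules(build_network(R2, net$threshold))
  expect_identical(network_stats(net2), network_stats(net))
})

test_that("Zi/Pi follow the participation formulas exactly", {
  # two K4 cliques joined by one bridge edge
  R <- diag(8)
  for (b in list(1:4, 5:8)) for (i in b) for (j in b)
    if (i != j) R[i, j] <- 0.9
  R[4, 5] <- R[5, 4] <- 0.9
  dimnames(R) <- list(paste0("v", 1:8), paste0("v", 1:8))
  net <- detect_modules(build_network(R, 0.5))
  topo <- zi_pi(net)
  # node v1: all links inside its module
  expect_equal(topo$Pi[topo$node == "v1"], 0)
  # bridge node v4: degree 4, three links in, one out
  expect_equal(topo$Pi[topo$node == "v4"], 1 - (3 / 4)^2 - (1 / 4)^2)
  # per-node link partition: sum over modules equals degree
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  memb <- net$membership[rownames(adj)]
  for (v in topo$node) {
    kim <- tapply(adj[v, ], memb, sum)
    expect_equal(sum(kim), topo$degree[topo$node == v])
  }
  # synthetic degree-4 node with 2 links in each of 2 modules: Pi = 0.5
  Rb <- diag(7)
  for (b in list(1:3, 4:6)) for (i in b) for (j in b)
    if (i != j) Rb[i, j] <- 0.9
  Rb[7, c(1, 2, 4, 5)] <- Rb[c(1, 2, 4, 5), 7] <- 0.9
  dimnames(Rb) <- list(paste0("v", 1:7), paste0("v", 1:7))
  nb <- detect_modules(build_network(Rb, 0.5))
  tb <- zi_pi(nb)
  if (nb$n_modules == 2)
    expect_equal(tb$Pi[tb$node == "v7"], 0.5)
})

test_that("keystone classification follows the printed truth table", {
  grid <- data.frame(
    node = paste0("n", 1:6),
    Zi = c(3.0, 1.0, 2.5, 5.0, 0.0, 2.6),
    Pi = c(0.10, 0.70, 0.62, 0.80, 0.62, 0.62))
  out <- classify_nodes(grid)
  expect_equal(out$category,
               c("module_hub", "connector", "peripheral", "network_hub",
                 "peripheral", "module_hub"))
  expect_equal(out$keystone,
               c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
})
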