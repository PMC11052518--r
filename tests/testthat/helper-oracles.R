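# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use different computational routes
# (explicit loops, pairwise counting, exhaustive enumeration) from the
# code they check.

# small labelled count matrix builder
toy_table <- function(counts, asv = NULL, samp = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- asv %||% paste0("asv", seq_len(nrow(counts)))
  colnames(counts) <- samp %||% paste0("s", seq_len(ncol(counts)))
  asv_table(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# all set partitions of n elements as membership vectors (restricted
# growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(memb, next_id) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (m in seq_len(next_id))
      rec(c(memb, m), next_id + (m == next_id))
  }
  rec(integer(0), 1L)
  out
}

# Newman modularity from an edge list, direct formula
modularity_oracle <- function(edges, memb) {
  m <- nrow(edges)
  deg <- table(factor(c(edges[, 1], edges[, 2]), levels = names(memb)))
  same <- memb[edges[, 1]] == memb[edges[, 2]]
  q <- sum(same) / m
  for (mod in unique(memb)) {
    dm <- sum(deg[names(memb)[memb == mod]])
    q <- q - (dm / (2 * m))^2
  }
  q
}

# exact two-sided Mann-Whitney p by enumerating group assignments and
# counting pairwise wins (not via rank sums)
mwu_oracle <- function(a, b) {
  pool <- c(a, b)
  n <- length(a); m <- length(b)
  u_of <- function(av, bv) {
    u <- 0
    for (x in av) for (y in bv) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  u_obs <- u_of(a, b)
  center <- n * m / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2L, function(ix) u_of(pool[ix], pool[-ix]))
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# loop-based PERMANOVA pseudo-F (explicit pair loops)
permanova_f_oracle <- function(D, groups) {
  n <- length(groups)
  a <- length(unique(groups))
  sst <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    sst <- sst + D[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    s <- 0
    if (ng > 1)
      for (ii in seq_len(ng - 1)) for (jj in seq.int(ii + 1, ng))
        s <- s + D[idx[ii], idx[jj]]^2
    ssw <- ssw + s / ng
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# loop-based MRPP delta
mrpp_delta_oracle <- function(D, groups) {
  n <- length(groups)
  delta <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng < 2) next
    s <- 0
    for (ii in seq_len(ng - 1)) for (jj in seq.int(ii + 1, ng))
      s <- s + D[idx[ii], idx[jj]]
    delta <- delta + (ng / n) * s / (ng * (ng - 1) / 2)
  }
  delta
}

# exhaustive two-group permutation p-values via combn over positions of
# the first group (independent of the package's multiset enumerator)
perm_p_oracle <- function(D, groups, stat_fun, lower = FALSE) {
  levs <- unique(groups)
  stopifnot(length(levs) == 2)
  n <- length(groups)
  k <- sum(groups == levs[1])
  obs <- stat_fun(D, groups)
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2L, function(ix) {
    g <- rep(levs[2], n)
    g[ix] <- levs[1]
    stat_fun(D, g)
  })
  if (lower) mean(stats <= obs + 1e-9) else mean(stats >= obs - 1e-9)
}

# random labelled simple graph as an edge data.frame + conet object
random_conet <- function(n, p, seed) {
  set.seed(seed)
  labs <- sprintf("n%02d", seq_len(n))
  R <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    if (runif(1) < p) R[i, j] <- R[j, i] <- runif(1, 0.6, 0.9)
  diag(R) <- 1
  if (all(R[upper.tri(R)] == 0)) R[1, 2] <- R[2, 1] <- 0.7
  build_network(R, 0.5)
}
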