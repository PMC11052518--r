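#' Prevalence filter for network construction
#'
#' Retains only the ASVs that appear (nonzero count) in strictly more
#' than `fraction` of the group's samples — with the default 0.5 this is
#' the "more than half" rule, so an ASV present in exactly half the
#' samples is dropped. A group with fewer than 4 samples is refused: no
#' meaningful co-occurrence network can be estimated from it.
#'
#' @param table an [asv_table()] restricted to the group of interest.
#' @param fraction prevalence fraction that must be strictly exceeded.
#' @return filtered [asv_table()].
#' @export
prevalence_filter <- function(table, fraction = 0.5) {
  x <- unclass_table(table)
  if (ncol(x) < 4) stop("need at least 4 samples to build a network")
  prev <- rowSums(x > 0)
  keep <- prev > fraction * ncol(x)
  if (!any(keep))
    stop("no ASV present in more than ", round(100 * fraction),
         "% of samples; network would be empty")
  asv_table(x[keep, , drop = FALSE])
}

#' Spearman correlation matrix between ASVs
#'
#' Pairwise Spearman rank correlation (average ranks for ties) across
#' samples. ASVs with zero variance across samples carry no rank
#' information and are excluded with a warning.
#'
#' @param table an [asv_table()] with at least 4 samples.
#' @return symmetric correlation matrix with unit diagonal and ASV ids as
#'   dimnames.
#' @export
spearman_matrix <- function(table) {
  x <- unclass_table(table)
  if (ncol(x) < 4) stop("need at least 4 samples for correlations")
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance ASV(s): ",
            paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 variable ASVs")
  R <- stats::cor(t(x), method = "spearman")
  diag(R) <- 1
  R
}

#' Sample a Gaussian orthogonal ensemble (GOE) matrix
#'
#' Random real symmetric matrix with independent N(0,1) off-diagonal and
#' N(0,2) diagonal entries: the null model whose eigenvalue spacings
#' follow the Wigner surmise rather than the Poisson law. Used to
#' validate the spacing-distribution discriminator behind the RMT
#' threshold choice.
#'
#' @param n matrix dimension.
#' @return an `n x n` symmetric matrix.
#' @export
rgoe <- function(n) {
  a <- matrix(stats::rnorm(n * n), n, n)
  (a + t(a)) / sqrt(2)
}

#' Nearest-neighbour spacing test against the Poisson law
#'
#' Tests whether the nearest-neighbour spacing distribution (NNSD) of a
#' spectrum is consistent with the Poisson law \eqn{e^{-d}} expected of
#' uncorrelated eigenvalues. Eigenvalues are deduplicated (within 1e-8),
#' the spectrum is unfolded by fitting the empirical cumulative
#' eigenvalue count with a cubic smoothing spline and mapping eigenvalues
#' through it, spacings are rescaled to unit mean, and a chi-square
#' goodness-of-fit against the exponential distribution is computed on
#' `ceiling(sqrt(n_spacings))` equal-probability bins. Small p-values
#' indicate level repulsion (GOE/Wigner statistics, i.e. a noise-bearing
#' matrix); non-rejection indicates Poisson statistics.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @param unfold_df degrees of freedom of the unfolding spline.
#' @param min_spacings minimum spacings required to evaluate the test.
#' @return list: `evaluable`, `n_spacings`, `statistic`, `df`,
#'   `p_poisson`.
#' @export
nnsd_poisson_gof <- function(eigenvalues, unfold_df = 10,
                             min_spacings = 20) {
  lam <- sort(eigenvalues[is.finite(eigenvalues)])
  if (length(lam) > 1)
    lam <- lam[c(TRUE, diff(lam) > 1e-8)]
  if (length(lam) < max(min_spacings + 1L, 8L))
    return(list(evaluable = FALSE, n_spacings = max(length(lam) - 1L, 0L),
                statistic = NA_real_, df = NA_integer_,
                p_poisson = NA_real_))
  dfree <- max(4, min(unfold_df, length(lam) - 2L))
  ss <- stats::smooth.spline(lam, seq_along(lam), df = dfree)
  unfolded <- sort(stats::predict(ss, lam)$y)
  sp <- diff(unfolded)
  sp <- sp[is.finite(sp) & sp >= 0]
  if (length(sp) < min_spacings || mean(sp) <= 0)
    return(list(evaluable = FALSE, n_spacings = length(sp),
                statistic = NA_real_, df = NA_integer_,
                p_poisson = NA_real_))
  sp <- sp / mean(sp)
  nb <- ceiling(sqrt(length(sp)))
  breaks <- stats::qexp(seq(0, 1, length.out = nb + 1L))
  breaks[nb + 1L] <- Inf
  obs <- tabulate(findInterval(sp, breaks, rightmost.closed = TRUE),
                  nbins = nb)
  expected <- length(sp) / nb
  statistic <- sum((obs - expected)^2 / expected)
  dfb <- nb - 1L
  list(evaluable = TRUE, n_spacings = length(sp), statistic = statistic,
       df = dfb, p_poisson = stats::pchisq(statistic, dfb,
                                           lower.tail = FALSE))
}

#' RMT-based correlation threshold scan
#'
#' Scans candidate thresholds over the correlation matrix. At each
#' candidate `t`, correlations with `|r| < t` are zeroed (diagonal kept),
#' rows without any off-diagonal entry are dropped, and the eigenvalue
#' nearest-neighbour spacing distribution of the resulting matrix is
#' tested against the Poisson law with [nnsd_poisson_gof()]. The chosen
#' threshold is the smallest candidate whose Poisson fit is not rejected
#' at `alpha` *and* that stays unrejected for the next `stability`
#' scanned candidates — the point where random (GOE-like) structure has
#' been stripped away. Candidates with fewer than `min_spacings` spacings
#' are marked unevaluable and cannot anchor or extend the stability
#' window.
#'
#' @param R symmetric correlation matrix from at least 10 ASVs.
#' @param thresholds ascending candidate thresholds.
#' @param alpha significance level of the Poisson goodness-of-fit.
#' @param stability number of subsequent candidates that must also be
#'   unrejected.
#' @param unfold_df,min_spacings passed to [nnsd_poisson_gof()].
#' @return object of class `"rmt_scan"`: `scan` (data.frame with one row
#'   per candidate: `threshold`, `n_nodes`, `n_edges`, `n_spacings`,
#'   `statistic`, `p_poisson`, `evaluable`), `chosen_threshold`,
#'   `rationale`, and the settings.
#' @export
rmt_threshold <- function(R, thresholds = seq(0.30, 0.99, by = 0.01),
                          alpha = 0.05, stability = 2L, unfold_df = 10,
                          min_spacings = 20L) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R))
  if (nrow(R) < 10) stop("RMT scan needs a correlation matrix of >= 10 ASVs")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("`thresholds` must be strictly increasing")
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    t_ <- thresholds[i]
    A <- R
    A[abs(A) < t_] <- 0
    diag(A) <- 1
    off <- abs(A) > 0
    diag(off) <- FALSE
    keep <- rowSums(off) > 0
    n_edges <- sum(off) / 2
    if (sum(keep) >= 2) {
      Ak <- A[keep, keep, drop = FALSE]
      ev <- eigen(Ak, symmetric = TRUE, only.values = TRUE)$values
      g <- nnsd_poisson_gof(ev, unfold_df = unfold_df,
                            min_spacings = min_spacings)
    } else {
      g <- list(evaluable = FALSE, n_spacings = 0L, statistic = NA_real_,
                df = NA_integer_, p_poisson = NA_real_)
    }
    rows[[i]] <- data.frame(threshold = t_, n_nodes = sum(keep),
                            n_edges = n_edges,
                            n_spacings = g$n_spacings,
                            statistic = g$statistic,
                            p_poisson = g$p_poisson,
                            evaluable = g$evaluable)
  }
  scan <- do.call(rbind, rows)
  ok <- scan$evaluable & !is.na(scan$p_poisson) & scan$p_poisson >= alpha
  chosen <- NA_real_
  for (i in seq_along(thresholds)) {
    win <- seq.int(i, min(i + stability, length(thresholds)))
    if (all(ok[win])) {
      chosen <- thresholds[i]
      break
    }
  }
  if (is.na(chosen))
    stop("no scanned threshold passes the Poisson spacing criterion with ",
         "a stable window; inspect the scan and supply a manual threshold")
  structure(list(scan = scan, chosen_threshold = chosen,
                 rationale = "smallest stable Poisson-consistent threshold",
                 alpha = alpha, stability = as.integer(stability),
                 unfold_df = unfold_df,
                 min_spacings = as.integer(min_spacings)),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  ev <- x$scan[x$scan$evaluable, , drop = FALSE]
  cat("RMT threshold scan: ", nrow(x$scan), " candidates (",
      nrow(ev), " evaluable); chosen threshold = ",
      x$chosen_threshold, "\n", sep = "")
  i <- match(x$chosen_threshold, x$scan$threshold)
  cat(sprintf("  at choice: %d nodes, %d edges, Poisson GOF p = %.3f\n",
              x$scan$n_nodes[i], x$scan$n_edges[i], x$scan$p_poisson[i]))
  invisible(x)
}

#' @export
plot.rmt_scan <- function(x, ...) {
  plot(x$scan$threshold, x$scan$p_poisson, type = "b", pch = 19,
       xlab = "candidate threshold", ylab = "Poisson GOF p-value", ...)
  graphics::abline(h = x$alpha, lty = 2)
  graphics::abline(v = x$chosen_threshold, col = 2)
  invisible(x)
}

#' Build a co-occurrence network from a correlation matrix
#'
#' Forms the undirected simple graph whose edges are ASV pairs with
#' `|r| >= threshold`; each edge stores the correlation and its sign.
#' Isolated nodes are removed.
#'
#' @param R symmetric correlation matrix with ASV labels.
#' @param threshold edge threshold in (0, 1].
#' @return object of class `"conet"` (modules unset): `graph` (igraph),
#'   `edges` (data.frame `node1`, `node2`, `rho`, `sign`), `nodes`,
#'   `threshold`.
#' @export
build_network <- function(R, threshold) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R), threshold > 0, threshold <= 1)
  labs <- rownames(R)
  if (is.null(labs)) labs <- paste0("n", seq_len(nrow(R)))
  idx <- which(abs(R) >= threshold & upper.tri(R), arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("threshold ", threshold, " leaves no edges; network is empty")
  edges <- data.frame(node1 = labs[idx[, 1L]], node2 = labs[idx[, 2L]],
                      rho = R[idx],
                      sign = ifelse(R[idx] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = g, edges = edges,
                 nodes = igraph::V(g)$name,
                 threshold = threshold, membership = NULL),
            class = "conet")
}

# deterministic single-node local moves: repeatedly move each node (in
# ascending label order) to the neighbouring module that most increases
# modularity, until no strictly improving move remains
refine_partition <- function(g, memb) {
  m <- igraph::ecount(g)
  if (m == 0) return(memb)
  nodes <- sort(igraph::V(g)$name)
  deg <- igraph::degree(g)
  nbrs <- lapply(igraph::adjacent_vertices(g, nodes), names)
  names(nbrs) <- nodes
  dsum <- tapply(deg[names(memb)], memb, sum)
  repeat {
    improved <- FALSE
    for (v in nodes) {
      a <- memb[[v]]
      kvc <- table(memb[nbrs[[v]]])
      kva <- if (as.character(a) %in% names(kvc))
        kvc[[as.character(a)]] else 0
      cand <- sort(as.integer(setdiff(names(kvc), as.character(a))))
      best_dq <- 1e-12; best_b <- NA_integer_
      for (b in cand) {
        kvb <- kvc[[as.character(b)]]
        dq <- (kvb - kva) / m -
          deg[[v]] * (dsum[[as.character(b)]] -
                        dsum[[as.character(a)]] + deg[[v]]) / (2 * m^2)
        if (dq > best_dq) {
          best_dq <- dq
          best_b <- b
        }
      }
      if (!is.na(best_b)) {
        dsum[[as.character(a)]] <- dsum[[as.character(a)]] - deg[[v]]
        dsum[[as.character(best_b)]] <-
          dsum[[as.character(best_b)]] + deg[[v]]
        memb[[v]] <- best_b
        improved <- TRUE
      }
    }
    if (!improved) {
      # try whole-module merges (agglomerative step on the refined
      # partition); resume local moves after an accepted merge
      em <- igraph::ends(g, igraph::E(g))
      mods <- sort(unique(memb))
      best_dq <- 1e-12; pair <- NULL
      for (ai in seq_along(mods)) {
        a_ <- mods[ai]
        for (b_ in mods[-seq_len(ai)]) {
          e_ab <- sum((memb[em[, 1]] == a_ & memb[em[, 2]] == b_) |
                        (memb[em[, 1]] == b_ & memb[em[, 2]] == a_))
          dq <- e_ab / m -
            dsum[[as.character(a_)]] * dsum[[as.character(b_)]] /
            (2 * m^2)
          if (dq > best_dq) {
            best_dq <- dq
            pair <- c(a_, b_)
          }
        }
      }
      if (is.null(pair)) break
      memb[memb == pair[2]] <- pair[1]
      dsum[[as.character(pair[1])]] <- dsum[[as.character(pair[1])]] +
        dsum[[as.character(pair[2])]]
      dsum[[as.character(pair[2])]] <- 0
    }
  }
  memb
}

#' Detect modules by greedy modularity maximisation
#'
#' Partitions the network with the agglomerative
#' Clauset-Newman-Moore greedy modularity algorithm
#' ([igraph::cluster_fast_greedy()]) on the unweighted graph, cutting the
#' merge path at its modularity maximum, then applies a deterministic
#' local refinement (single-node moves in ascending node-label order,
#' accepted only when they strictly increase modularity) that repairs the
#' small-graph resolution artifacts of pure agglomeration. Module ids are
#' relabelled in ascending order of each module's smallest node label, so
#' repeated runs give identical partitions.
#'
#' @param net a `"conet"` from [build_network()].
#' @return the network with `membership` (named module id per node) and
#'   `n_modules` filled in.
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "conet"))
  g <- igraph::simplify(net$graph)
  fg <- igraph::cluster_fast_greedy(g, weights = NULL)
  # cut the merge path at its modularity maximum ourselves: membership()
  # can return a sub-optimal cut when the maximum sits at the final merge
  steps <- which.max(fg$modularity) - 1L
  memb <- igraph::cut_at(fg, steps = steps)
  names(memb) <- igraph::V(g)$name
  # refine from three deterministic initial partitions (the greedy cut,
  # all-singletons, all-in-one) and keep the highest-modularity result
  nn <- igraph::vcount(g)
  starts <- list(memb,
                 stats::setNames(seq_len(nn), igraph::V(g)$name),
                 stats::setNames(rep(1L, nn), igraph::V(g)$name))
  cands <- lapply(starts, function(s) refine_partition(g, s))
  qs <- vapply(cands, function(s)
    igraph::modularity(g, s[igraph::V(g)$name]), 0)
  memb <- cands[[which.max(qs)]]
  first <- tapply(names(memb), as.integer(memb), min)
  relabel <- match(as.character(memb), names(first)[order(first)])
  memb <- stats::setNames(relabel, names(memb))
  net$membership <- memb[net$nodes]
  net$n_modules <- max(relabel)
  net
}

#' Network summary statistics
#'
#' Node and link counts, mean local clustering coefficient (nodes of
#' degree < 2 contribute 0), average shortest-path distance over node
#' pairs within the same connected component, and Newman modularity Q of
#' the stored partition.
#'
#' @param net a `"conet"` with modules detected.
#' @return data.frame with one row: `n_nodes`, `n_links`, `avgCC`, `GD`,
#'   `M`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "conet"))
  if (is.null(net$membership))
    stop("detect modules before computing network statistics")
  g <- net$graph
  cc <- igraph::transitivity(g, type = "local")
  cc[is.na(cc)] <- 0
  sp <- igraph::distances(g)
  vals <- sp[upper.tri(sp)]
  vals <- vals[is.finite(vals)]
  gd <- if (length(vals)) mean(vals) else NA_real_
  data.frame(n_nodes = igraph::vcount(g), n_links = igraph::ecount(g),
             avgCC = mean(cc), GD = gd,
             M = igraph::modularity(g, net$membership[
               igraph::V(g)$name]))
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' For each node, `Zi` is the z-score of its number of links into its own
#' module, standardised over that module's members (a module whose
#' members all have identical within-degree, or a singleton module, gives
#' Zi = 0); `Pi = 1 - sum_m (k_im / k_i)^2` measures how evenly the
#' node's links spread across modules (0 = all links inside one module).
#'
#' @param net a `"conet"` with modules detected.
#' @return data.frame: `node`, `module`, `degree`, `k_within`, `Zi`,
#'   `Pi`.
#' @export
zi_pi <- function(net) {
  stopifnot(inherits(net, "conet"))
  if (is.null(net$membership)) stop("detect modules first")
  g <- net$graph
  nodes <- igraph::V(g)$name
  memb <- net$membership[nodes]
  k <- igraph::degree(g)
  if (any(k == 0)) {
    warning("excluding ", sum(k == 0), " isolated node(s)")
  }
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  mods <- sort(unique(memb))
  # k_im: links of node i into module m
  kim <- vapply(mods, function(m)
    rowSums(adj[, memb == m, drop = FALSE]), numeric(length(nodes)))
  kim <- matrix(kim, nrow = length(nodes),
                dimnames = list(nodes, mods))
  k_within <- kim[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    sel <- memb == m
    mu <- mean(k_within[sel])
    s <- stats::sd(k_within[sel])
    zi[sel] <- if (is.na(s) || s == 0) 0 else (k_within[sel] - mu) / s
  }
  pi_ <- 1 - rowSums((kim / k)^2)
  out <- data.frame(node = nodes, module = unname(memb),
                    degree = unname(k), k_within = unname(k_within),
                    Zi = unname(zi), Pi = unname(pi_),
                    stringsAsFactors = FALSE)
  out[out$degree > 0, , drop = FALSE]
}

#' Classify nodes into topological roles and flag keystone taxa
#'
#' Four-way classification on the (Zi, Pi) plane with the conventional
#' cutoffs: peripherals (Zi <= 2.5 and Pi <= 0.62), connectors
#' (Zi <= 2.5, Pi > 0.62), module hubs (Zi > 2.5, Pi <= 0.62) and network
#' hubs (Zi > 2.5, Pi > 0.62). Boundary values fall on the "<=" side.
#' Every non-peripheral node (connectors, module hubs, network hubs) is
#' flagged as a keystone taxon.
#'
#' @param topology data.frame from [zi_pi()].
#' @param zi_cut,pi_cut classification cutoffs.
#' @return the input with `category` and logical `keystone` columns.
#' @export
classify_nodes <- function(topology, zi_cut = 2.5, pi_cut = 0.62) {
  stopifnot(all(c("Zi", "Pi") %in% colnames(topology)))
  hi_z <- topology$Zi > zi_cut
  hi_p <- topology$Pi > pi_cut
  topology$category <- ifelse(!hi_z & !hi_p, "peripheral",
                       ifelse(!hi_z & hi_p, "connector",
                       ifelse(hi_z & !hi_p, "module_hub", "network_hub")))
  topology$keystone <- topology$category != "peripheral"
  topology
}

#' Fit a co-occurrence network to an ASV table
#'
#' One-call molecular ecological network analysis: prevalence filter,
#' Spearman correlation, RMT-based threshold choice (or a manual
#' threshold), graph construction, greedy module detection, network
#' summary statistics, and Zi/Pi keystone classification.
#'
#' @param table an [asv_table()] restricted to the sample group of
#'   interest (e.g. one host species, pooling seasons and gut parts).
#' @param prevalence prevalence fraction for [prevalence_filter()].
#' @param thresholds,alpha,stability,unfold_df,min_spacings RMT scan
#'   settings, see [rmt_threshold()].
#' @param threshold optional manual correlation threshold; skips the RMT
#'   scan.
#' @return object of class `"conet"` with `edges`, `membership`,
#'   `n_modules`, `stats` (see [network_stats()]), `topology` (Zi/Pi and
#'   categories), `rmt` (the scan, or `NULL` if manual), `threshold`.
#' @examples
#' sim <- simulate_correlated_counts(planted_network_design(seed = 42))
#' net <- conet(sim$table)
#' net
#' @export
conet <- function(table, prevalence = 0.5,
                  thresholds = seq(0.30, 0.99, by = 0.01), alpha = 0.05,
                  stability = 2L, unfold_df = 10, min_spacings = 20L,
                  threshold = NULL) {
  filt <- prevalence_filter(table, fraction = prevalence)
  R <- spearman_matrix(filt)
  scan <- NULL
  if (is.null(threshold)) {
    scan <- rmt_threshold(R, thresholds = thresholds, alpha = alpha,
                          stability = stability, unfold_df = unfold_df,
                          min_spacings = min_spacings)
    threshold <- scan$chosen_threshold
  }
  net <- build_network(R, threshold)
  net <- detect_modules(net)
  net$stats <- network_stats(net)
  net$topology <- classify_nodes(zi_pi(net))
  net$rmt <- scan
  net$call <- match.call()
  net
}

#' @export
print.conet <- function(x, ...) {
  cat("Co-occurrence network (|Spearman rho| >= ", x$threshold, ")\n",
      sep = "")
  cat("  ", length(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (!is.null(x$n_modules)) paste0(", ", x$n_modules, " modules"),
      "\n", sep = "")
  if (!is.null(x$stats))
    cat(sprintf("  avgCC = %.3f  GD = %.3f  M = %.3f\n",
                x$stats$avgCC, x$stats$GD, x$stats$M))
  if (!is.null(x$topology)) {
    ks <- x$topology$node[x$topology$keystone]
    cat("  keystone taxa: ",
        if (length(ks)) paste(ks, collapse = ", ") else "none", "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.conet <- function(object, ...) {
  print(object)
  if (!is.null(object$topology)) {
    cat("\nNode categories:\n")
    print(table(object$topology$category))
  }
  if (!is.null(object$rmt)) {
    cat("\n")
    print(object$rmt)
  }
  invisible(object)
}

#' @export
plot.conet <- function(x, ...) {
  g <- x$graph
  col <- if (!is.null(x$membership))
    x$membership[igraph::V(g)$name] else 1L
  plot(g, vertex.color = col, vertex.size = 6, vertex.label = NA, ...)
  invisible(x)
}

#' Export a co-occurrence network to GraphML
#'
#' Writes the graph with per-edge correlation and sign and per-node
#' module, Zi, Pi and category attributes, readable by Gephi or
#' Cytoscape.
#'
#' @param net a `"conet"`.
#' @param path output file path.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "conet"))
  g <- net$graph
  igraph::E(g)$rho <- net$edges$rho
  igraph::E(g)$sign <- net$edges$sign
  if (!is.null(net$membership))
    igraph::V(g)$module <- unname(net$membership[igraph::V(g)$name])
  if (!is.null(net$topology)) {
    m <- match(igraph::V(g)$name, net$topology$node)
    igraph::V(g)$Zi <- net$topology$Zi[m]
    igraph::V(g)$Pi <- net$topology$Pi[m]
    igraph::V(g)$category <- net$topology$category[m]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
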