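#' Bray-Curtis dissimilarity between two samples
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; 0 for identical
#' samples, 1 for samples with disjoint taxon support.
#'
#' @param x,y non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both samples are all-zero")
  sum(abs(x - y)) / tot
}

#' Binary Jaccard dissimilarity between two samples
#'
#' Presence/absence form: 1 minus shared taxa over total observed taxa.
#'
#' @inheritParams bray_curtis
#' @export
jaccard_binary <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  px <- x > 0; py <- y > 0
  u <- sum(px | py)
  if (u == 0) stop("both samples are all-zero")
  1 - sum(px & py) / u
}

#' Quantitative (Ruzicka) Jaccard dissimilarity
#'
#' Abundance-weighted Jaccard: \eqn{1 - \sum \min(x,y) / \sum \max(x,y)}.
#' Provided as an alternative to the binary form.
#'
#' @inheritParams bray_curtis
#' @export
jaccard_quant <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  mx <- sum(pmax(x, y))
  if (mx == 0) stop("both samples are all-zero")
  1 - sum(pmin(x, y)) / mx
}

#' Pairwise sample dissimilarity matrix
#'
#' @param table an [asv_table()] (or any non-negative matrix with sample
#'   columns).
#' @param metric `"bray_curtis"` (default), `"jaccard"` (binary
#'   presence/absence) or `"jaccard_quant"` (Ruzicka).
#' @return symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
distance_matrix <- function(table,
                            metric = c("bray_curtis", "jaccard",
                                       "jaccard_quant")) {
  metric <- match.arg(metric)
  fun <- switch(metric, bray_curtis = bray_curtis,
                jaccard = jaccard_binary, jaccard_quant = jaccard_quant)
  x <- unclass_table(table)
  n <- ncol(x)
  D <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  if (n > 1)
    for (i in seq_len(n - 1L))
      for (j in seq.int(i + 1L, n)) {
        D[i, j] <- D[j, i] <- fun(x[, i], x[, j])
      }
  attr(D, "metric") <- metric
  D
}

check_dist <- function(D) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal not zero")
  if (any(D < 0)) stop("negative distances")
  D
}

# all distinct arrangements of a label multiset, one per column
enumerate_assignments <- function(groups) {
  groups <- as.character(groups)
  levs <- unique(groups)
  counts <- table(factor(groups, levels = levs))
  n <- length(groups)
  rec <- function(free, li) {
    if (li == length(levs))
      return(matrix(free, ncol = 1L))
    k <- counts[[li]]
    picks <- utils::combn(length(free), k)
    out <- vector("list", ncol(picks))
    for (c_ in seq_len(ncol(picks))) {
      chosen <- free[picks[, c_]]
      rest <- rec(free[-picks[, c_]], li + 1L)
      out[[c_]] <- rbind(matrix(chosen, nrow = k, ncol = ncol(rest)), rest)
    }
    do.call(cbind, out)
  }
  # rec returns, per column, the positions receiving levels in order
  pos <- rec(seq_len(n), 1L)
  lab <- rep(levs, counts)
  apply(pos, 2L, function(p) {
    g <- character(n)
    g[p] <- lab
    g
  })
}

permanova_ss <- function(d2, groups, levs) {
  n <- length(groups)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (lv in levs) {
    idx <- which(groups == lv)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, within = ss_within)
}

check_grouping <- function(D, groups) {
  if (length(groups) != nrow(D))
    stop("groups length must match distance matrix")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (sum(tab >= 2) < 2) stop("need at least two groups with n >= 2")
  as.character(groups)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared dissimilarities into between- and within-group
#' components, forms the pseudo-F ratio
#' \eqn{F = [SS_B/(a-1)] / [SS_W/(N-a)]}, and assesses it by whole-label
#' permutation. The reported p uses the add-one smoothing bound
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (n_{perm} + 1)}, so
#' \eqn{p \ge 1/(n_{perm}+1)} always. With `exhaustive = TRUE` all
#' distinct label arrangements are enumerated instead and p is the exact
#' proportion (including the observed arrangement).
#'
#' @param D symmetric dissimilarity matrix (zero diagonal).
#' @param groups group label per sample (>= 2 groups; at least two with
#'   n >= 2).
#' @param n_perm number of random permutations.
#' @param seed RNG seed, recorded in the result.
#' @param exhaustive enumerate all distinct arrangements instead of
#'   sampling (only sensible for small N).
#' @return object of class `"permanova_result"`: `pseudo_F`, `R2`, `p_perm`,
#'   `n_perm`, `seed`, `df`, sums of squares.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = 1L,
                      exhaustive = FALSE) {
  D <- check_dist(D)
  groups <- check_grouping(D, groups)
  levs <- unique(groups)
  a <- length(levs)
  n <- length(groups)
  d2 <- D^2
  f_of <- function(g) {
    ss <- permanova_ss(d2, g, levs)
    ssb <- ss[["total"]] - ss[["within"]]
    (ssb / (a - 1)) / (ss[["within"]] / (n - a))
  }
  ss <- permanova_ss(d2, groups, levs)
  ssb <- ss[["total"]] - ss[["within"]]
  f_obs <- (ssb / (a - 1)) / (ss[["within"]] / (n - a))
  eps <- 1e-12
  if (exhaustive) {
    arr <- enumerate_assignments(groups)
    f_all <- apply(arr, 2L, f_of)
    p <- mean(f_all >= f_obs - eps)
    n_used <- ncol(arr)
  } else {
    set.seed(seed)
    f_perm <- replicate(n_perm, f_of(sample(groups)))
    p <- (1 + sum(f_perm >= f_obs - eps)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(pseudo_F = f_obs, R2 = ssb / ss[["total"]], p_perm = p,
                 n_perm = n_used, seed = as.integer(seed),
                 exhaustive = exhaustive,
                 df = c(between = a - 1L, within = n - a),
                 ss = c(between = unname(ssb),
                        within = unname(ss[["within"]]),
                        total = unname(ss[["total"]]))),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (one-way, ",
      if (x$exhaustive) "exhaustive enumeration" else
        paste0(x$n_perm, " permutations"),
      ")\n", sep = "")
  cat(sprintf("  pseudo-F = %.4f  R2 = %.4f  p = %.4g\n",
              x$pseudo_F, x$R2, x$p_perm))
  invisible(x)
}

#' Multi-response permutation procedure (MRPP)
#'
#' Computes the weighted mean within-group dissimilarity
#' \eqn{\delta = \sum_g w_g \bar d_g} with \eqn{w_g = n_g / N}, its
#' permutation expectation, the chance-corrected within-group agreement
#' \eqn{A = 1 - \delta / E(\delta)}, and a permutation p-value for small
#' \eqn{\delta} (cohesive groups), with add-one smoothing. A is 0 when
#' groups are no more cohesive than chance and approaches 1 for perfect
#' within-group homogeneity.
#'
#' @inheritParams permanova
#' @return object of class `"mrpp_result"`: `delta_observed`, `delta_expected`,
#'   `A`, `p_perm`, `n_perm`, `seed`.
#' @export
mrpp <- function(D, groups, n_perm = 999, seed = 1L, exhaustive = FALSE) {
  D <- check_dist(D)
  groups <- check_grouping(D, groups)
  levs <- unique(groups)
  n <- length(groups)
  delta_of <- function(g) {
    d <- 0
    for (lv in levs) {
      idx <- which(g == lv)
      ng <- length(idx)
      if (ng > 1)
        d <- d + (ng / n) * sum(D[idx, idx]) / (ng * (ng - 1))
    }
    d
  }
  delta_obs <- delta_of(groups)
  eps <- 1e-12
  if (exhaustive) {
    arr <- enumerate_assignments(groups)
    deltas <- apply(arr, 2L, delta_of)
    p <- mean(deltas <= delta_obs + eps)
    delta_exp <- mean(deltas)
    n_used <- ncol(arr)
  } else {
    set.seed(seed)
    deltas <- replicate(n_perm, delta_of(sample(groups)))
    p <- (1 + sum(deltas <= delta_obs + eps)) / (n_perm + 1)
    delta_exp <- mean(deltas)
    n_used <- n_perm
  }
  structure(list(delta_observed = delta_obs, delta_expected = delta_exp,
                 A = 1 - delta_obs / delta_exp, p_perm = p,
                 n_perm = n_used, seed = as.integer(seed),
                 exhaustive = exhaustive),
            class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat("MRPP (", if (x$exhaustive) "exhaustive enumeration" else
    paste0(x$n_perm, " permutations"), ")\n", sep = "")
  cat(sprintf("  delta = %.4f  E(delta) = %.4f  A = %.4f  p = %.4g\n",
              x$delta_observed, x$delta_expected, x$A, x$p_perm))
  invisible(x)
}
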