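check_counts <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero count vector")
  counts
}

#' Shannon diversity index
#'
#' Entropy \eqn{H = -\sum p_i \log p_i} over taxa with positive counts,
#' in natural-log units (nats) by default.
#'
#' @param counts non-negative count (or abundance) vector.
#' @param base logarithm base; default `exp(1)`.
#' @return Shannon index; 0 for a single-taxon sample, at most
#'   `log(richness, base)`.
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Inverse Simpson index
#'
#' \eqn{1 / \sum p_i^2}: the effective number of equally abundant taxa.
#' Ranges from 1 (one dominant taxon) to the observed richness (perfectly
#' even community).
#'
#' @inheritParams shannon
#' @export
inverse_simpson <- function(counts) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  1 / sum(p^2)
}

#' Observed richness
#'
#' Number of taxa with a positive count.
#'
#' @inheritParams shannon
#' @export
observed_richness <- function(counts) {
  counts <- check_counts(counts)
  sum(counts > 0)
}

#' Bias-corrected Chao1 richness estimator
#'
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} where \eqn{F_1} and
#' \eqn{F_2} are the numbers of singletons and doubletons. The
#' bias-corrected form never divides by zero when doubletons are absent.
#' Requires integer counts (e.g. rarefied reads): the estimator is
#' meaningless on relative abundances. Unlike Shannon or inverse Simpson
#' it is not invariant under count rescaling.
#'
#' @inheritParams shannon
#' @return estimated richness, always \eqn{\ge} observed richness.
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  if (any(counts != round(counts)))
    stop("chao1 requires integer counts (singleton/doubleton based)")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha-diversity table
#'
#' Computes Shannon, inverse Simpson, observed richness and Chao1 for
#' every sample column of an ASV table. Best run on a rarefied table so
#' that richness-sensitive indices are comparable across samples.
#'
#' @param table an [asv_table()].
#' @param base logarithm base for Shannon.
#' @return data.frame with columns `sample_id`, `shannon`, `inv_simpson`,
#'   `observed`, `chao1`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  x <- unclass_table(table)
  data.frame(
    sample_id = colnames(x),
    shannon = apply(x, 2L, shannon, base = base),
    inv_simpson = apply(x, 2L, inverse_simpson),
    observed = apply(x, 2L, observed_richness),
    chao1 = apply(x, 2L, chao1),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ranks/U statistic shared by exact and approximate paths
mwu_u1 <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test (exact or normal approximation)
#'
#' Rank-sum test for a difference between two independent groups, with
#' average ranks for ties. The exact two-sided p-value is computed by
#' complete enumeration of all \eqn{\binom{n+m}{n}} group assignments of
#' the pooled values, as the probability of a U at least as far from its
#' null mean \eqn{nm/2} as observed. `mode = "auto"` enumerates whenever
#' \eqn{\binom{n+m}{n} \le 20000} and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return list with `U` (the smaller of the two U statistics, SPSS
#'   convention), `U1` (first group's U), `p` (two-sided), and `method`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(a) < 1 || length(b) < 1) stop("empty group")
  n <- length(a); m <- length(b)
  u1 <- mwu_u1(a, b)
  u <- min(u1, n * m - u1)
  n_arr <- choose(n + m, n)
  do_exact <- switch(mode,
                     exact = TRUE,
                     approx = FALSE,
                     auto = n_arr <= 20000)
  if (do_exact) {
    pool <- c(a, b)
    r <- rank(pool)
    center <- n * m / 2
    dev_obs <- abs(u1 - center)
    combos <- utils::combn(n + m, n)
    offs <- n * (n + 1) / 2
    us <- colSums(matrix(r[combos], nrow = n)) - offs
    p <- sum(abs(us - center) >= dev_obs - 1e-9) / ncol(combos)
    method <- "exact enumeration"
  } else {
    N <- n + m
    ties <- table(c(a, b))
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1   # all values tied: no evidence either way
    } else {
      z <- (abs(u1 - n * m / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(U = u, U1 = u1, p = p, method = method)
}

#' Pairwise group comparisons of alpha-diversity indices
#'
#' Mann-Whitney U tests between every pair of levels of a metadata
#' factor, for each alpha-diversity index, with significance stars.
#' Following common practice in descriptive community surveys the
#' p-values are unadjusted by default; set `adjust = "holm"` for a
#' family-wise correction across the comparisons of each index.
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param metadata a [sample_metadata()].
#' @param factor_name one of `"species"`, `"season"`, `"gut_part"`.
#' @param mode passed to [mann_whitney()].
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame: `group1`, `group2`, `index`, `U`, `p`, `stars`.
#' @export
alpha_compare <- function(alpha, metadata,
                          factor_name = c("species", "season", "gut_part"),
                          mode = "auto", adjust = c("none", "holm")) {
  factor_name <- match.arg(factor_name)
  adjust <- match.arg(adjust)
  md <- metadata[match(alpha$sample_id, metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  groups <- md[[factor_name]]
  levs <- sort(unique(groups))
  if (length(levs) < 2) stop("need >= 2 groups to compare")
  idx_cols <- c("shannon", "inv_simpson", "observed", "chao1")
  rows <- list()
  for (ix in idx_cols) {
    for (i in seq_len(length(levs) - 1L)) {
      for (j in seq.int(i + 1L, length(levs))) {
        va <- alpha[[ix]][groups == levs[i]]
        vb <- alpha[[ix]][groups == levs[j]]
        mw <- mann_whitney(va, vb, mode = mode)
        rows[[length(rows) + 1L]] <-
          data.frame(group1 = levs[i], group2 = levs[j], index = ix,
                     U = mw$U, p = mw$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm")
    for (ix in idx_cols) {
      sel <- out$index == ix
      out$p[sel] <- stats::p.adjust(out$p[sel], method = "holm")
    }
  out$stars <- p_stars(out$p)
  rownames(out) <- NULL
  out
}
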