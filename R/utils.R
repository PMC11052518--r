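softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[] <- 1   # numerically degenerate draw; fall back to uniform
  g / sum(g)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 the expectation under random labeling.
#' Used to score recovery of planted correlation blocks by module
#' detection.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return the adjusted Rand index, a number \eqn{\le} 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)        # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Significance stars for p-values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

# seeds derived from a master seed stay valid 32-bit integers
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
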