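# isotonic (monotone non-decreasing) fit of config distances against the
# rank order of the dissimilarities; Kruskal's primary tie treatment:
# within a block of tied dissimilarities the fitted values may take any
# order, so block members are pre-sorted by current distance.
monotone_fit <- function(d_target, dv) {
  o <- order(d_target, dv)
  fit <- stats::isoreg(dv[o])$yf
  out <- numeric(length(dv))
  out[o] <- fit
  out
}

stress1 <- function(dv, dhat) {
  sqrt(sum((dv - dhat)^2) / sum(dv^2))
}

# lower-triangle (column-major) distances of configuration rows
config_dist <- function(X) {
  as.vector(stats::dist(X))
}

nmds_one_start <- function(X, d0, max_iter, tol) {
  n <- nrow(X)
  lt <- lower.tri(matrix(0, n, n))
  trace <- numeric(0)
  dv <- config_dist(X)
  dhat <- monotone_fit(d0, dv)
  s <- stress1(dv, dhat)
  for (iter in seq_len(max_iter)) {
    trace[iter] <- s
    if (s < 1e-12) break
    Dm <- matrix(0, n, n); Dm[lt] <- dv; Dm <- Dm + t(Dm)
    Dh <- matrix(0, n, n); Dh[lt] <- dhat; Dh <- Dh + t(Dh)
    sstar <- sum((dv - dhat)^2)
    tstar <- sum(dv^2)
    C <- (Dm - Dh) / sstar - Dm / tstar
    W <- ifelse(Dm > 0, C / Dm, 0)
    diag(W) <- 0
    G <- s * (rowSums(W) * X - W %*% X)
    gn <- sqrt(sum(G^2))
    if (gn < 1e-14) break
    alpha <- 0.2 * sqrt(sum(X^2) + 1e-12) / gn
    improved <- FALSE
    for (h in seq_len(30)) {
      Xt <- X - alpha * G
      dvt <- config_dist(Xt)
      dht <- monotone_fit(d0, dvt)
      st <- stress1(dvt, dht)
      if (st <= s) {
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
    X <- Xt; dv <- dvt; dhat <- dht
    if (s - st < tol) {
      s <- st
      trace[iter + 1L] <- s
      break
    }
    s <- st
  }
  list(X = X, stress = s, trace = trace)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds samples in `k` dimensions so that configuration distances
#' preserve the rank order of the input dissimilarities. The fit
#' alternates isotonic regression (pool-adjacent-violators over the rank
#' order of `D`, primary tie treatment) with gradient descent on
#' Kruskal's stress-1 \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}}, using
#' a backtracking line search so that stress is non-increasing at every
#' accepted step. One start uses classical metric scaling
#' ([stats::cmdscale()]); the remaining starts are random Gaussian
#' configurations. The best configuration is centred and rotated to its
#' principal axes.
#'
#' @param D symmetric dissimilarity matrix.
#' @param k embedding dimension (`n >= k + 1` required).
#' @param n_starts number of starts including the metric-scaling start.
#' @param max_iter iteration cap per start.
#' @param tol stop when the per-iteration stress decrease falls below
#'   this.
#' @param seed RNG seed for the random starts.
#' @return object of class `"nmds_result"`: `points` (samples x k),
#'   `stress`, `per_start_stress`, `stress_trace` (list, one vector per
#'   start; each non-increasing), `best_start`, `converged`, `seed`.
#' @export
nmds <- function(D, k = 2L, n_starts = 20L, max_iter = 300L, tol = 1e-6,
                 seed = 1L) {
  D <- check_dist(D)
  n <- nrow(D)
  if (n <= k) stop("need more samples (", n, ") than dimensions (", k, ")")
  d0 <- D[lower.tri(D)]
  if (all(d0 == 0)) stop("all dissimilarities are zero")
  set.seed(seed)
  starts <- vector("list", n_starts)
  cm <- tryCatch(stats::cmdscale(D, k = k), error = function(e) NULL)
  if (!is.null(cm)) {
    if (ncol(cm) < k)
      cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
    starts[[1L]] <- cm
  } else {
    starts[[1L]] <- matrix(stats::rnorm(n * k), n, k)
  }
  for (i in seq_len(n_starts)[-1L])
    starts[[i]] <- matrix(stats::rnorm(n * k), n, k)

  fits <- lapply(starts, nmds_one_start, d0 = d0, max_iter = max_iter,
                 tol = tol)
  stresses <- vapply(fits, `[[`, 0, "stress")
  best <- which.min(stresses)
  X <- fits[[best]]$X
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- X %*% sv$v
  dimnames(X) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  structure(list(points = X, stress = stresses[best],
                 per_start_stress = stresses,
                 stress_trace = lapply(fits, `[[`, "trace"),
                 best_start = best,
                 converged = length(fits[[best]]$trace) < max_iter,
                 n_starts = n_starts, k = k, seed = as.integer(seed)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("NMDS: ", nrow(x$points), " samples in ", x$k, " dimensions; ",
      "stress-1 = ", format(x$stress, digits = 6),
      " (best of ", x$n_starts, " starts)\n", sep = "")
  invisible(x)
}

#' @export
plot.nmds_result <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  plot(x$points[, 1L], x$points[, 2L], col = col, pch = 19,
       xlab = "NMDS1", ylab = "NMDS2",
       main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}
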