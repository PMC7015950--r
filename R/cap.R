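# Canonical analysis of principal coordinates (CAP): constrained ordination
# maximizing separation of a-priori groups on the first m PCoA axes, with m
# chosen by leave-one-out allocation success of a nearest-centroid
# classifier, and a trace statistic tested by permutation of group labels.

#' Canonical analysis of principal coordinates
#'
#' PCoA axes are computed from the distance matrix; if `m` is not given it
#' is chosen in `1..min(n - 2, rank)` to maximize leave-one-out allocation
#' success of a nearest-centroid classifier on the first `m` axes (smallest
#' `m` on ties). Canonical axes come from the eigen-analysis of the group
#' projection of the orthonormal PCoA axes `Q_m` (eigenvalues are squared
#' canonical correlations); the trace statistic `tr(Q_m' H Q_m)` is tested
#' by permuting group labels.
#'
#' @param d A `dist_matrix` (or symmetric matrix / `dist`).
#' @param groups Factor/character vector of group labels (named by sample or
#'   in distance order); >= 2 levels, each with >= 2 samples.
#' @param m Number of PCoA axes to use (default: automatic).
#' @param n_perm Permutations for the trace test.
#' @param seed Integer seed.
#' @return A `cap_result`: `m`, `allocation_success`, `allocation_table`,
#'   `canonical_axes` (sample scores), `canonical_eigenvalues` (squared
#'   canonical correlations), `trace`, `p`, `m_search` (success by m).
#' @export
cap <- function(d, groups, m = NULL, n_perm = 999L, seed = 1L) {
  if (!inherits(d, "dist_matrix")) d <- dist_matrix(d)
  n <- length(d$sample_ids)
  if (!is.null(names(groups))) groups <- groups[d$sample_ids]
  if (length(groups) != n || anyNA(groups)) .stopf("every sample needs a group label")
  g <- factor(as.character(groups))
  sizes <- table(g)
  if (nlevels(g) < 2L) .stopf("CAP needs >= 2 groups")
  if (any(sizes < 2L))
    .stopf("group(s) with a single sample: %s",
           paste(names(sizes)[sizes < 2L], collapse = ", "))

  ord <- pcoa(d)
  scores <- ord$coordinates             # eigenvectors scaled by sqrt(lambda)
  rank <- ncol(scores)
  m_max <- min(n - 2L, rank)

  loo_success <- function(mm) {
    sc <- scores[, seq_len(mm), drop = FALSE]
    mean(.loo_alloc(sc, g) == g)
  }

  if (is.null(m)) {
    succ <- vapply(seq_len(m_max), loo_success, numeric(1L))
    m <- which.max(succ)               # smallest m on ties
    m_search <- data.frame(m = seq_len(m_max), allocation_success = succ)
    success <- succ[m]
  } else {
    m <- as.integer(m)
    if (m < 1L || m > m_max) .stopf("m must lie in [1, %d]", m_max)
    success <- loo_success(m)
    m_search <- data.frame(m = m, allocation_success = success)
  }

  Q <- ord$vectors[, seq_len(m), drop = FALSE]  # orthonormal
  Hg <- .hat(stats::model.matrix(~ 0 + g))$H
  M <- crossprod(Q, Hg %*% Q)
  ce <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_can <- min(nlevels(g) - 1L, m)
  can_val <- pmax(0, pmin(1, ce$values[seq_len(n_can)]))
  can_axes <- Q %*% ce$vectors[, seq_len(n_can), drop = FALSE]
  rownames(can_axes) <- d$sample_ids
  colnames(can_axes) <- paste0("CAP", seq_len(n_can))
  trace_obs <- sum(diag(M))

  p <- NA_real_
  if (n_perm > 0L) {
    p <- with_substream(seed, "cap", {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        gp <- g[sample.int(n)]
        Hp <- .hat(stats::model.matrix(~ 0 + gp))$H
        if (sum(diag(crossprod(Q, Hp %*% Q))) >= trace_obs - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
  }

  alloc <- table(observed = g, allocated = .loo_alloc(scores[, seq_len(m), drop = FALSE], g))
  structure(list(m = m, allocation_success = success, allocation_table = alloc,
                 canonical_axes = can_axes, canonical_eigenvalues = can_val,
                 trace = trace_obs, p = p, n_perm = n_perm, m_search = m_search),
            class = "cap_result")
}

# leave-one-out nearest-centroid allocation labels
.loo_alloc <- function(sc, g) {
  n <- nrow(sc)
  out <- character(n)
  for (i in seq_len(n)) {
    cent <- vapply(levels(g), function(lv) {
      as.numeric(colMeans(sc[setdiff(which(g == lv), i), , drop = FALSE]))
    }, numeric(ncol(sc)))
    cent <- matrix(cent, nrow = ncol(sc))   # axes x groups, even for 1 axis
    d2 <- colSums((cent - as.numeric(sc[i, ]))^2)
    out[i] <- levels(g)[which.min(d2)]
  }
  factor(out, levels = levels(g))
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP: m = %d axes, LOO allocation success %.1f%%, trace %.4g, p = %s\n",
              x$m, 100 * x$allocation_success, x$trace,
              format(x$p, digits = 4L)))
  invisible(x)
}
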