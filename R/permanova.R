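# Multifactorial / nested PERMANOVA on a distance matrix, from first
# principles (McArdle-Anderson trace partition of the Gower-centred matrix).
# Sums of squares: Type I (sequential) or Type III (marginal). Significance
# by permutation of residuals under a reduced model (Freedman-Lane applied
# to the Gower matrix); permutations for a nested term are restricted to
# the levels of its parent factor.

# Parse a term such as "genotype" or "genotype(species)" (A within B).
.parse_term <- function(term) {
  m <- regmatches(term, regexec("^\\s*([^()\\s]+)\\s*(\\(\\s*([^()\\s]+)\\s*\\))?\\s*$",
                                term, perl = TRUE))[[1L]]
  if (!length(m)) .stopf("cannot parse model term '%s'", term)
  list(label = trimws(term), factor = m[2L],
       parent = if (nzchar(m[4L])) m[4L] else NA_character_)
}

# Hat matrix of a design, via QR; returns H and the design's rank.
.hat <- function(X) {
  qr_ <- qr(X)
  r <- qr_$rank
  Q <- qr.Q(qr_)[, seq_len(r), drop = FALSE]
  list(H = tcrossprod(Q), rank = r)
}

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squares `tr(G)` of the Gower-centred matrix
#' `G` over an ordered list of factors. For cumulative-design hat matrices
#' `H_1..H_j`, Type I (sequential) `SS_j = tr(H_j G) - tr(H_{j-1} G)`;
#' Type III (marginal) `SS_j = tr(H_full G) - tr(H_{-j} G)`. The pseudo-F
#' for every term uses the residual mean square as denominator. P-values
#' come from permutation of residuals under the reduced model: with
#' `H_red` the reduced-model hat matrix, `G* = H_red G H_red + P R P'`
#' where `R = (I - H_red) G (I - H_red)` and `P` permutes rows and columns
#' by the same permutation; the p-value is `(1 + #(F* >= F)) / (1 + n_perm)`.
#' Terms written `"A(B)"` are nested (A within B): their design columns are
#' the dummies of A, and their permutations are restricted to within the
#' levels of B.
#'
#' @param d A `dist_matrix` (or symmetric matrix / `dist`).
#' @param meta Data frame of sample factors (rows matched to the distance
#'   matrix sample ids via a `sample_id` column if present, else by order).
#' @param terms Ordered character vector of model terms, e.g.
#'   `c("fraction", "ancestry", "species(ancestry)", "genotype(species)")`.
#' @param n_perm Number of permutations (9999 by default; 0 skips the
#'   permutation test and returns `NA` p-values).
#' @param seed Integer seed; each term gets its own substream.
#' @param ss_type `"I"` (sequential) or `"III"` (marginal).
#' @return A `permanova_result`: data.frame `table` with one row per term
#'   plus Residual and Total (columns term, df, SS, MS, pseudoF, p,
#'   n_perm), and fields `ss_type`, `total_ss`.
#' @export
permanova <- function(d, meta, terms, n_perm = 9999L, seed = 1L,
                      ss_type = c("I", "III")) {
  ss_type <- match.arg(ss_type)
  if (!inherits(d, "dist_matrix")) d <- dist_matrix(d)
  n <- length(d$sample_ids)
  meta <- as.data.frame(meta)
  if ("sample_id" %in% names(meta)) {
    idx <- match(d$sample_ids, meta$sample_id)
    if (anyNA(idx))
      .stopf("distance sample(s) absent from metadata: %s",
             paste(d$sample_ids[is.na(idx)], collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
  } else if (nrow(meta) != n) {
    .stopf("metadata rows (%d) do not match samples (%d)", nrow(meta), n)
  }
  # canonical sample order: the permutation stream, and hence the p-value,
  # cannot depend on the order in which samples arrive
  ord <- order(d$sample_ids)
  d <- dist_matrix(d$d[ord, ord])
  meta <- meta[ord, , drop = FALSE]
  parsed <- lapply(terms, .parse_term)
  for (p in parsed) {
    if (!p$factor %in% names(meta)) .stopf("unknown factor '%s'", p$factor)
    if (!is.na(p$parent) && !p$parent %in% names(meta))
      .stopf("unknown nesting parent '%s'", p$parent)
  }
  G <- gower_center(d)
  total_ss <- sum(diag(G))

  # cumulative designs and hat matrices
  dummies <- lapply(parsed, function(p)
    stats::model.matrix(~ 0 + f, data.frame(f = factor(meta[[p$factor]]))))
  k <- length(parsed)
  X <- matrix(1, n, 1L)
  hats <- vector("list", k + 1L)
  hats[[1L]] <- .hat(X)
  for (j in seq_len(k)) {
    X <- cbind(X, dummies[[j]])
    hats[[j + 1L]] <- .hat(X)
    if (hats[[j + 1L]]$rank == hats[[j]]$rank)
      .stopf("term '%s' is aliased with earlier terms (adds no rank)",
             parsed[[j]]$label)
  }
  rank_full <- hats[[k + 1L]]$rank
  df_res <- n - rank_full
  if (df_res <= 0L) .stopf("saturated model: no residual degrees of freedom")
  H_full <- hats[[k + 1L]]$H
  ss_res <- total_ss - sum(H_full * G)
  ms_res <- ss_res / df_res

  # leave-one-out hat matrices for Type III
  if (ss_type == "III") {
    hats_drop <- lapply(seq_len(k), function(j) {
      Xj <- do.call(cbind, c(list(matrix(1, n, 1L)), dummies[-j]))
      .hat(Xj)
    })
  }

  df <- SS <- Fobs <- pval <- numeric(k)
  for (j in seq_len(k)) {
    if (ss_type == "I") {
      df[j] <- hats[[j + 1L]]$rank - hats[[j]]$rank
      SS[j] <- sum(hats[[j + 1L]]$H * G) - sum(hats[[j]]$H * G)
      H_red <- hats[[j]]$H
    } else {
      df[j] <- rank_full - hats_drop[[j]]$rank
      if (df[j] == 0L)
        .stopf("term '%s' is aliased under Type III (no marginal rank)",
               parsed[[j]]$label)
      SS[j] <- sum(H_full * G) - sum(hats_drop[[j]]$H * G)
      H_red <- hats_drop[[j]]$H
    }
    Fobs[j] <- (SS[j] / df[j]) / ms_res

    if (n_perm > 0L) {
      strata <- if (!is.na(parsed[[j]]$parent)) factor(meta[[parsed[[j]]$parent]]) else NULL
      pval[j] <- with_substream(seed, paste0("permanova:", parsed[[j]]$label), {
        .fl_perm_p(G, H_red,
                   H_num_hi = if (ss_type == "I") hats[[j + 1L]]$H else H_full,
                   H_num_lo = H_red, H_full = H_full,
                   df_j = df[j], df_res = df_res, F_obs = Fobs[j],
                   n_perm = n_perm, strata = strata)
      })
    } else pval[j] <- NA_real_
  }

  tab <- data.frame(
    term = c(vapply(parsed, `[[`, character(1L), "label"), "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(SS, ss_res, total_ss),
    MS = c(SS / df, ms_res, NA_real_),
    pseudoF = c(Fobs, NA_real_, NA_real_),
    p = c(pval, NA_real_, NA_real_),
    n_perm = c(rep(if (n_perm > 0L) n_perm else NA_integer_, k), NA_integer_, NA_integer_),
    stringsAsFactors = FALSE)
  structure(list(table = tab, ss_type = ss_type, total_ss = total_ss),
            class = "permanova_result")
}

# Freedman-Lane permutation p-value for one term.
.fl_perm_p <- function(G, H_red, H_num_hi, H_num_lo, H_full,
                       df_j, df_res, F_obs, n_perm, strata = NULL) {
  n <- nrow(G)
  fitted <- H_red %*% G %*% H_red
  IH <- diag(n) - H_red
  R <- IH %*% G %*% IH
  # constant parts of the traces
  c_hi <- sum(H_num_hi * fitted); c_lo <- sum(H_num_lo * fitted)
  c_full <- sum(H_full * fitted); c_tot <- sum(diag(fitted))
  perm_one <- function(pi_) {
    Rp <- R[pi_, pi_]
    ss_num <- (c_hi + sum(H_num_hi * Rp)) - (c_lo + sum(H_num_lo * Rp))
    ss_res <- (c_tot + sum(diag(Rp))) - (c_full + sum(H_full * Rp))
    (ss_num / df_j) / (ss_res / df_res)
  }
  draw_perm <- if (is.null(strata)) {
    function() sample.int(n)
  } else {
    idx_by <- split(seq_len(n), strata)
    function() {
      pi_ <- seq_len(n)
      for (ix in idx_by) if (length(ix) > 1L) pi_[ix] <- ix[sample.int(length(ix))]
      pi_
    }
  }
  hits <- 0L
  tol <- abs(F_obs) * 1e-8 + 1e-12
  for (b in seq_len(n_perm)) {
    if (perm_one(draw_perm()) >= F_obs - tol) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (Type %s SS, residual-permutation p)\n", x$ss_type))
  tab <- x$table
  tab$SS <- signif(tab$SS, 6L); tab$MS <- signif(tab$MS, 6L)
  tab$pseudoF <- signif(tab$pseudoF, 4L)
  print(tab, row.names = FALSE)
  invisible(x)
}
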