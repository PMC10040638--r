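#' Permutational multivariate analysis of variance (perMANOVA)
#'
#' Partitions a dissimilarity matrix by the metadata terms via the
#' Gower-centred inner-product matrix `G = -1/2 C D^2 C`. Each term is
#' tested marginally (its sum of squares is the drop from the full model
#' hat projection to the model without the term), with a pseudo-F against
#' the full-model residual and a permutation p-value obtained by freely
#' permuting sample labels. For a single term this reduces to the classic
#' one-factor partition and term plus residual R-squared sum to one.
#'
#' @param dist square dissimilarity matrix (or `dist`).
#' @param metadata data.frame aligned to the rows of `dist`.
#' @param terms character vector of metadata columns (factors or numeric).
#' @param n_perm number of permutations, or `"exact"` to enumerate all
#'   row permutations (n <= 8).
#' @param seed integer seed for the permutation stream.
#' @return data.frame of class `crc_permanova` with one row per term plus
#'   `Residual` and `Total`: `df`, `SS`, `R2`, `F`, `p`.
#' @export
permanova <- function(dist, metadata, terms, n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  n <- nrow(d)
  assert_that(all(terms %in% names(metadata)),
              "every term must be a metadata column")
  mf <- metadata[, terms, drop = FALSE]
  assert_that(all(complete.cases(mf)), "terms must have no missing values")
  for (t in terms) {
    if (!is.numeric(mf[[t]])) {
      mf[[t]] <- factor(mf[[t]])
      tab <- table(mf[[t]])
      assert_that(nlevels(mf[[t]]) >= 2,
                  paste0("term '", t, "' needs >= 2 levels"))
      if (any(tab < 2)) {
        stop("term '", t, "' has singleton level(s): ",
             paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
      }
    }
  }
  G <- gower_center(d)
  ss_total <- sum(diag(G))

  X_full <- model.matrix(stats::reformulate(terms), data = mf)
  asg <- attr(X_full, "assign")
  H_full <- hat_matrix(X_full)
  rank_full <- attr(H_full, "rank")
  df_res <- n - rank_full
  assert_that(df_res > 0, "no residual degrees of freedom")

  H_red <- list(); df_term <- numeric(length(terms))
  for (i in seq_along(terms)) {
    keep <- asg != i
    H_red[[i]] <- hat_matrix(X_full[, keep, drop = FALSE])
    df_term[i] <- rank_full - attr(H_red[[i]], "rank")
  }

  stat <- function(Gp) {
    ss_res <- sum(diag(Gp)) - sum(H_full * Gp)
    ss_t <- vapply(seq_along(terms), function(i) {
      sum(H_full * Gp) - sum(H_red[[i]] * Gp)
    }, numeric(1))
    (ss_t / df_term) / (ss_res / df_res)
  }
  obs_ss_res <- ss_total - sum(H_full * G)
  obs_ss <- vapply(seq_along(terms), function(i) {
    sum(H_full * G) - sum(H_red[[i]] * G)
  }, numeric(1))
  obs_F <- (obs_ss / df_term) / (obs_ss_res / df_res)

  if (identical(n_perm, "exact")) {
    perms <- all_permutations(n)
    Fs <- apply(perms, 1, function(p) stat(G[p, p]))
    Fs <- matrix(Fs, nrow = length(terms))
    pval <- rowMeans(Fs >= obs_F - 1e-12)
    n_perm_used <- nrow(perms)
  } else {
    set.seed(seed)
    count <- rep(0L, length(terms))
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      count <- count + (stat(G[p, p]) >= obs_F - 1e-12)
    }
    pval <- (1 + count) / (1 + n_perm)
    n_perm_used <- n_perm
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_term, df_res, n - 1),
    SS = c(obs_ss, obs_ss_res, ss_total),
    R2 = c(obs_ss, obs_ss_res, ss_total) / ss_total,
    F = c(obs_F, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm_used
  class(out) <- c("crc_permanova", "data.frame")
  out
}

gower_center <- function(d) {
  n <- nrow(d)
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

hat_matrix <- function(X) {
  qrx <- qr(X)
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  H <- tcrossprod(Q)
  attr(H, "rank") <- qrx$rank
  H
}

#' Pairwise perMANOVA between all group pairs
#'
#' Runs [permanova()] on every pair of group levels' sub-matrix and
#' adjusts the raw permutation p-values by Benjamini-Hochberg across the
#' pairs. Pairs with fewer than two samples on either side are skipped
#' with a warning.
#'
#' @inheritParams permanova
#' @param group_col metadata column with the grouping factor.
#' @return data.frame with `group1`, `group2`, `R2`, `F`, `p`, `p_adj`.
#' @export
pairwise_permanova <- function(dist, metadata, group_col = "group",
                               n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  groups <- as.character(metadata[[group_col]])
  levels <- intersect(CRC_GROUPS, unique(groups))
  if (length(levels) == 0) levels <- unique(groups)
  pairs <- combn(levels, 2)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sel <- groups %in% c(g1, g2)
    if (sum(groups == g1) < 2 || sum(groups == g2) < 2) {
      warning("skipping pair ", g1, " vs ", g2, ": fewer than 2 samples a side",
              call. = FALSE)
      next
    }
    sub <- permanova(d[sel, sel, drop = FALSE],
                     data.frame(group = groups[sel]),
                     terms = "group", n_perm = n_perm,
                     seed = derive_seed(seed, k))
    rows[[length(rows) + 1]] <- data.frame(
      group1 = g1, group2 = g2, R2 = sub$R2[1], F = sub$F[1], p = sub$p[1],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
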