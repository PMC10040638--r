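#' Shannon diversity
#'
#' `H = -sum(p * log(p))` over nonzero proportions, natural log.
#'
#' @param profile samples x taxa matrix of relative abundances (rows sum
#'   to 1).
#' @return named numeric vector of per-sample diversities.
#' @export
shannon <- function(profile) {
  assert_that(all(profile >= 0), "relative abundances must be non-negative")
  assert_that(all(abs(rowSums(profile) - 1) < 1e-6),
              "profile rows must sum to 1; use to_relative() first")
  apply(profile, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum|x - y| / sum(x + y)`, bounded in `[0, 1]`.
#'
#' @param profile samples x taxa non-negative abundance matrix.
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(profile) {
  assert_that(all(profile >= 0), "abundances must be non-negative")
  zero <- rowSums(profile) == 0
  if (sum(zero) >= 2) {
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(rownames(profile)[zero], collapse = ", "), call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(profile, method = "bray"))
  diag(d) <- 0
  d
}

#' Average variation degree (AVD) of community stability
#'
#' Within each group, every taxon with positive within-group standard
#' deviation is z-scored; a sample's AVD is the mean absolute z-score over
#' those taxa. Lower AVD indicates a more stable (more homogeneous)
#' community. Group means are compared by one-way ANOVA with Tukey HSD
#' compact letters at alpha = 0.05.
#'
#' @param profile samples x taxa relative-abundance matrix.
#' @param metadata sample metadata aligned to rows.
#' @param group_col metadata column holding the grouping factor.
#' @return list of class `crc_avd`: `samples` (per-sample data.frame with
#'   `avd` and a `no_variation` flag), `groups` (mean, sd, letter), and
#'   `anova_p`.
#' @export
avd <- function(profile, metadata, group_col = "group") {
  groups <- metadata[[group_col]]
  tab <- table(groups)
  assert_that(all(tab >= 2), paste("group(s) of size 1:",
              paste(names(tab)[tab < 2], collapse = ", ")))
  per_sample <- data.frame(sample_id = rownames(profile), group = groups,
                           avd = NA_real_, no_variation = FALSE,
                           stringsAsFactors = FALSE)
  for (g in names(tab)) {
    sel <- groups == g
    x <- profile[sel, , drop = FALSE]
    mu <- colMeans(x)
    sdev <- apply(x, 2, sd)
    use <- sdev > 0
    if (!any(use)) {
      per_sample$avd[sel] <- 0
      per_sample$no_variation[sel] <- TRUE
      next
    }
    z <- abs(sweep(sweep(x[, use, drop = FALSE], 2, mu[use]), 2, sdev[use], "/"))
    per_sample$avd[sel] <- rowMeans(z)
  }
  grp_stats <- do.call(rbind, lapply(names(tab), function(g) {
    v <- per_sample$avd[per_sample$group == g]
    data.frame(group = g, mean = mean(v), sd = sd(v), n = length(v))
  }))
  if (nrow(grp_stats) >= 2) {
    fit <- aov(avd ~ group, data = per_sample)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$group
    sig <- matrix(FALSE, nrow(grp_stats), nrow(grp_stats),
                  dimnames = list(grp_stats$group, grp_stats$group))
    for (k in rownames(tk)) {
      pair <- strsplit(k, "-", fixed = TRUE)[[1]]
      sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- tk[k, "p adj"] < 0.05
    }
    means <- setNames(grp_stats$mean, grp_stats$group)
    grp_stats$letter <- letter_display(sig, means)[grp_stats$group]
  } else {
    p <- NA_real_
    grp_stats$letter <- "a"
  }
  structure(list(samples = per_sample, groups = grp_stats, anova_p = p),
            class = "crc_avd")
}

#' Group-presence intersection counts (UpSet-style)
#'
#' A taxon is present in a group if it is nonzero in at least one of the
#' group's samples. Every taxon that is nonzero somewhere is assigned to
#' exactly one of the `2^k - 1` presence patterns.
#'
#' @param counts samples x taxa count matrix.
#' @param metadata sample metadata aligned to rows.
#' @param group_col grouping column.
#' @return data.frame with `pattern` (group labels joined by `&`),
#'   `degree` and `count`, sorted by degree then count.
#' @export
upset_counts <- function(counts, metadata, group_col = "group") {
  groups <- metadata[[group_col]]
  levels <- intersect(CRC_GROUPS, unique(groups))
  if (length(levels) == 0) levels <- unique(groups)
  pres <- sapply(levels, function(g) {
    colSums(counts[groups == g, , drop = FALSE] > 0) > 0
  })
  nonzero <- rowSums(pres) > 0
  pattern <- apply(pres[nonzero, , drop = FALSE], 1, function(r) {
    paste(levels[r], collapse = "&")
  })
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$degree, -out$count), , drop = FALSE]
}

#' Specificity-occupancy (SPEC-OCCU) specialist analysis
#'
#' Within each group the `top_n` taxa by mean relative abundance are
#' scored: specificity of taxon i in group g is its group-mean relative
#' abundance divided by the sum of its group means over all groups;
#' occupancy is the fraction of the group's samples in which it occurs.
#' Specialists satisfy specificity >= 0.5 and occupancy >= 0.5.
#'
#' @param counts samples x taxa count matrix (converted internally to
#'   relative abundances).
#' @param metadata sample metadata aligned to rows.
#' @param group_col grouping column.
#' @param top_n taxa retained per group (default 500).
#' @return data.frame with `taxon_id`, `group`, `specificity`, `occupancy`,
#'   `specialist`.
#' @export
spec_occu <- function(counts, metadata, group_col = "group", top_n = 500) {
  assert_that(top_n >= 1, "top_n must be >= 1")
  groups <- metadata[[group_col]]
  levels <- intersect(CRC_GROUPS, unique(groups))
  if (length(levels) == 0) levels <- unique(groups)
  rel <- to_relative(counts)
  mu <- sapply(levels, function(g) colMeans(rel[groups == g, , drop = FALSE]))
  total <- rowSums(mu)
  specificity <- mu / ifelse(total > 0, total, 1)
  if (top_n > ncol(counts)) {
    message("spec_occu: only ", ncol(counts), " taxa available (top_n = ",
            top_n, "); using all")
    top_n <- ncol(counts)
  }
  out <- do.call(rbind, lapply(levels, function(g) {
    sel_taxa <- order(mu[, g], decreasing = TRUE)[seq_len(top_n)]
    occ <- colMeans(counts[groups == g, sel_taxa, drop = FALSE] > 0)
    data.frame(taxon_id = colnames(counts)[sel_taxa], group = g,
               specificity = specificity[sel_taxa, g], occupancy = occ,
               stringsAsFactors = FALSE)
  }))
  out$specialist <- out$specificity >= 0.5 & out$occupancy >= 0.5
  rownames(out) <- NULL
  out
}

#' Groupwise differential abundance
#'
#' Rank-based test per taxon (Kruskal-Wallis; Wilcoxon rank-sum when the
#' factor has two levels) with Benjamini-Hochberg correction across taxa.
#' For two-group contrasts, direction is the sign of the median difference
#' (level 2 minus level 1). Constant taxa get p = 1 and a flag.
#'
#' @param profile samples x taxa relative-abundance matrix.
#' @param metadata sample metadata aligned to rows.
#' @param group_col grouping column.
#' @return data.frame with `taxon_id`, `statistic`, `p`, `p_adj`,
#'   `direction`, `constant`.
#' @export
differential_abundance <- function(profile, metadata, group_col = "group") {
  groups <- factor(metadata[[group_col]])
  assert_that(nlevels(groups) >= 2, "need at least two groups")
  two <- nlevels(groups) == 2
  res <- lapply(seq_len(ncol(profile)), function(i) {
    x <- profile[, i]
    if (length(unique(x)) == 1) {
      return(data.frame(statistic = NA_real_, p = 1, direction = 0L,
                        constant = TRUE))
    }
    if (two) {
      a <- x[groups == levels(groups)[1]]
      b <- x[groups == levels(groups)[2]]
      ht <- suppressWarnings(wilcox.test(a, b))
      dir <- sign(median(b) - median(a))
    } else {
      ht <- kruskal.test(x, groups)
      dir <- 0L
    }
    data.frame(statistic = unname(ht$statistic), p = ht$p.value,
               direction = dir, constant = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(taxon_id = colnames(profile), out)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("taxon_id", "statistic", "p", "p_adj", "direction", "constant")]
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' Principal-coordinate decomposition of the distance matrix (axes with
#' non-positive eigenvalues dropped), optionally residualized on a
#' conditioning factor, followed by linear discriminant analysis of the
#' grouping factor on the leading m axes. m is chosen to maximize
#' leave-one-out classification success (smallest m on ties).
#'
#' @param dist square dissimilarity matrix.
#' @param metadata sample metadata aligned to rows.
#' @param group_col grouping column.
#' @param condition_col optional metadata column regressed out of the
#'   principal coordinates before discrimination.
#' @param max_axes upper bound on m (default: all positive axes up to
#'   n - number of groups).
#' @return list of class `crc_cap`: `scores` (canonical axes), `m`,
#'   `loo_success`, `group`.
#' @export
cap_ordination <- function(dist, metadata, group_col = "group",
                           condition_col = NULL, max_axes = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  assert_that(n >= 3, "need at least 3 samples")
  groups <- factor(metadata[[group_col]])
  # cmdscale warns when k exceeds the positive rank; rank is handled below
  pco <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  pos <- which(pco$eig > sqrt(.Machine$double.eps))
  dropped <- sum(pco$eig < -sqrt(.Machine$double.eps))
  if (dropped > 0) {
    message("cap_ordination: dropped ", dropped, " negative eigenvalue axes")
  }
  axes <- pco$points[, seq_len(min(length(pos), ncol(pco$points))), drop = FALSE]
  assert_that(ncol(axes) >= 1, "degenerate distance matrix (rank 0)")
  if (!is.null(condition_col)) {
    cond <- model.matrix(~., data = metadata[, condition_col, drop = FALSE])
    axes <- stats::resid(stats::lm.fit(cond, axes))
  }
  cap <- min(max_axes %||% (n - nlevels(groups) - 1), ncol(axes))
  cap <- max(cap, 1)
  success <- vapply(seq_len(cap), function(m) {
    fit <- try(suppressWarnings(
      MASS::lda(axes[, seq_len(m), drop = FALSE], grouping = groups, CV = TRUE)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    mean(fit$class == groups, na.rm = TRUE)
  }, numeric(1))
  assert_that(any(!is.na(success)), "discriminant analysis failed on all m")
  m <- which.max(success)  # first maximum = smallest m on ties
  fit <- suppressWarnings(MASS::lda(axes[, seq_len(m), drop = FALSE],
                                    grouping = groups))
  scores <- predict(fit, axes[, seq_len(m), drop = FALSE])$x
  rownames(scores) <- rownames(d)
  structure(list(scores = scores, m = m, loo_success = success[m],
                 loo_curve = success, group = groups),
            class = "crc_cap")
}
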