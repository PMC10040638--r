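#' @keywords internal
#' @noRd
NULL

# Groups are reported in this fixed order everywhere; ties in the classifier
# break in this order too.
CRC_GROUPS <- c("T1", "T2", "T3", "T4", "BP")

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

# Deterministic sub-seed derivation so that one top-level seed drives every
# stage without reuse. Constants from a standard LCG; result stays < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + 12345 * as.numeric(k)) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Counts matrix convention: samples in rows, taxa in columns (vegan-style).
validate_counts <- function(counts) {
  assert_that(is.matrix(counts) && is.numeric(counts),
              "counts must be a numeric matrix (samples x taxa)")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must have sample row names and taxon column names")
  assert_that(!anyDuplicated(rownames(counts)), "duplicate sample ids in counts")
  assert_that(!anyDuplicated(colnames(counts)), "duplicate taxon ids in counts")
  assert_that(all(counts >= 0), "counts must be non-negative")
  invisible(counts)
}

validate_metadata <- function(metadata) {
  assert_that(is.data.frame(metadata), "metadata must be a data.frame")
  needed <- c("sample_id", "group", "age", "gender")
  missing <- setdiff(needed, names(metadata))
  assert_that(length(missing) == 0,
              paste("metadata lacks column(s):", paste(missing, collapse = ", ")))
  bad <- !metadata$group %in% CRC_GROUPS
  if (any(bad)) {
    stop("invalid group label(s) in metadata row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(metadata$group[bad]), collapse = ", "),
         " (allowed: ", paste(CRC_GROUPS, collapse = ", "), ")", call. = FALSE)
  }
  assert_that(all(metadata$age >= 0 & metadata$age <= 120),
              "ages outside plausible range [0, 120]")
  invisible(metadata)
}

# Compact letter display from a symmetric logical "significantly different"
# matrix, insert-and-absorb over groups sorted by decreasing mean.
letter_display <- function(sig, means) {
  groups <- names(means)[order(-means)]
  sets <- list(groups[1])
  for (g in groups[-1]) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (!any(sig[g, sets[[i]]])) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      # open a new letter containing g plus every earlier group compatible with it
      comp <- groups[seq_len(match(g, groups) - 1)]
      sets[[length(sets) + 1]] <- c(comp[!sig[g, comp]], g)
    }
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]))
        keep[i] <- FALSE
    }
  }
  sets <- sets[keep]
  out <- setNames(rep("", length(means)), names(means))
  for (i in seq_along(sets)) {
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  }
  out
}

# All permutations of 1..n (n small), for exact permutation tests.
all_permutations <- function(n) {
  assert_that(n <= 8, "exact enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}
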