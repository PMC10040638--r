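# Shared fixtures and independent oracles, built in code at test time.

# small cohort for fast end-to-end checks
small_cohort <- function(seed = 1, n_taxa = 300,
                         n_per_group = c(BP = 10, T1 = 6, T2 = 6, T3 = 6, T4 = 6),
                         rarefy_depth = 2000, depth_mean = 12000,
                         depth_sd = 3000, ...) {
  generate_cohort(simulation_config(
    n_per_group = n_per_group, n_taxa = n_taxa, rarefy_depth = rarefy_depth,
    depth_mean = depth_mean, depth_sd = depth_sd, seed = seed, ...))
}

# counts matrix with named dims from a plain matrix
label_counts <- function(m, prefix_s = "S", prefix_t = "t") {
  rownames(m) <- paste0(prefix_s, seq_len(nrow(m)))
  colnames(m) <- paste0(prefix_t, seq_len(ncol(m)))
  m
}

# Independent one-factor perMANOVA oracle from the classic pairwise-distance
# sums-of-squares identity (no Gower matrix, no hat projections).
permanova_oracle_F <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- length(unique(groups))
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# exact two-group permutation p by enumerating all distinct assignments
permanova_oracle_exact_p <- function(d, groups) {
  n <- length(groups)
  k <- sum(groups == unique(groups)[1])
  obs <- permanova_oracle_F(d, groups)
  assignments <- combn(n, k)
  fs <- apply(assignments, 2, function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    permanova_oracle_F(d, g)
  })
  mean(fs >= obs - 1e-12)
}

# brute-force normalized betweenness by BFS shortest-path enumeration
betweenness_oracle <- function(edges, nodes) {
  adj <- setNames(lapply(nodes, function(x) character(0)), nodes)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges$node_a[k]; b <- edges$node_b[k]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  paths_through <- setNames(numeric(length(nodes)), nodes)
  all_simple_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (nb in adj[[last]]) if (!nb %in% path) walk(c(path, nb))
    }
    walk(from)
    out
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      paths <- all_simple_paths(nodes[i], nodes[j])
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        inner <- setdiff(p, c(nodes[i], nodes[j]))
        for (v in inner) paths_through[v] <- paths_through[v] + 1 / length(shortest)
      }
    }
  }
  n <- length(nodes)
  paths_through / ((n - 1) * (n - 2) / 2)
}

# build a crc_network object directly from an edge list (for toy tests)
toy_network <- function(nodes, edge_pairs) {
  edges <- if (length(edge_pairs) > 0) {
    data.frame(node_a = vapply(edge_pairs, `[`, "", 1),
               node_b = vapply(edge_pairs, `[`, "", 2),
               weight = 1, p_adj = 0.01, stringsAsFactors = FALSE)
  } else {
    data.frame(node_a = character(0), node_b = character(0),
               weight = numeric(0), p_adj = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(min_prevalence = 0, rho_threshold = 0.6,
                                   alpha = 0.05, max_taxa = Inf)),
            class = "crc_network")
}

write_toy_tables <- function(dir, counts, metadata, taxonomy) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_df <- data.frame(taxon_id = colnames(counts), t(counts),
                          check.names = FALSE)
  write.table(counts_df, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}
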