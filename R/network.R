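#' Build a within-group co-occurrence network
#'
#' Computes pairwise Spearman associations among the retained taxa of one
#' group's relative-abundance profile and keeps edges with `|rho| >=
#' rho_threshold` whose Benjamini-Hochberg adjusted p-values (t
#' approximation) fall at or below `alpha`. Taxa below the prevalence
#' cutoff are dropped; to keep the multiple-testing burden of the pair
#' space tractable the network is restricted to the `max_taxa` most
#' abundant retained taxa, the usual practice for amplicon co-occurrence
#' analysis.
#'
#' @param profile samples x taxa relative-abundance matrix for one group.
#' @param min_prevalence minimum fraction of samples in which a taxon is
#'   nonzero.
#' @param rho_threshold minimum absolute Spearman correlation for an edge.
#' @param alpha BH-adjusted significance cutoff for an edge.
#' @param max_taxa cap on network size (most abundant retained taxa).
#' @return list of class `crc_network`: `nodes` (taxon ids), `edges`
#'   (data.frame `node_a`, `node_b`, `weight`, `p_adj`), and the
#'   thresholds used.
#' @export
build_network <- function(profile, min_prevalence = 0.3, rho_threshold = 0.6,
                         alpha = 0.05, max_taxa = 200) {
  n <- nrow(profile)
  assert_that(n >= 5, "need >= 5 samples for association estimates")
  prevalence <- colMeans(profile > 0)
  keep <- prevalence >= min_prevalence
  prof <- profile[, keep, drop = FALSE]
  if (ncol(prof) > max_taxa) {
    top <- order(colMeans(prof), decreasing = TRUE)[seq_len(max_taxa)]
    prof <- prof[, sort(top), drop = FALSE]
  }
  nodes <- colnames(prof)
  p_taxa <- length(nodes)
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      weight = numeric(0), p_adj = numeric(0))
  if (p_taxa >= 2) {
    rho <- suppressWarnings(cor(prof, method = "spearman"))
    # t approximation for the Spearman null, BH across the pair space
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    praw <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    ut <- upper.tri(rho)
    padj <- praw
    padj[ut] <- p.adjust(praw[ut], method = "BH")
    hit <- which(ut & abs(rho) >= rho_threshold & padj <= alpha & !is.na(rho),
                 arr.ind = TRUE)
    if (nrow(hit) > 0) {
      edges <- data.frame(node_a = nodes[hit[, 1]], node_b = nodes[hit[, 2]],
                          weight = rho[hit], p_adj = padj[hit],
                          stringsAsFactors = FALSE)
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(min_prevalence = min_prevalence,
                                   rho_threshold = rho_threshold,
                                   alpha = alpha, max_taxa = max_taxa)),
            class = "crc_network")
}

as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes), name = network$nodes)
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(g, rbind(network$edges$node_a, network$edges$node_b))
  }
  g
}

neighbor_sets <- function(network) {
  out <- setNames(vector("list", length(network$nodes)), network$nodes)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (nrow(network$edges) > 0) {
    for (k in seq_len(nrow(network$edges))) {
      a <- network$edges$node_a[k]; b <- network$edges$node_b[k]
      out[[a]] <- c(out[[a]], b)
      out[[b]] <- c(out[[b]], a)
    }
  }
  out
}

#' Common sub-network of a control and a case network
#'
#' The common node set is the intersection of the two networks' node
#' sets; the edges each network induces on that set are reported
#' separately. Nodes outside the intersection that are adjacent to it are
#' flagged as direct interactors.
#'
#' @param control,case `crc_network` objects.
#' @return list: `nodes`, `edges_control`, `edges_case`,
#'   `adjacent_control`, `adjacent_case`.
#' @export
common_subnetwork <- function(control, case) {
  nodes <- intersect(control$nodes, case$nodes)
  if (length(nodes) == 0) {
    warning("empty common node set", call. = FALSE)
  }
  induced <- function(net) {
    e <- net$edges
    e[e$node_a %in% nodes & e$node_b %in% nodes, , drop = FALSE]
  }
  adjacent <- function(net) {
    e <- net$edges
    touch <- e$node_a %in% nodes | e$node_b %in% nodes
    setdiff(unique(c(e$node_a[touch], e$node_b[touch])), nodes)
  }
  list(nodes = nodes,
       edges_control = induced(control), edges_case = induced(case),
       adjacent_control = adjacent(control), adjacent_case = adjacent(case))
}

#' Neighbour-shift (NESH-style) rewiring scores
#'
#' For a node with neighbour sets A (control) and B (case):
#' `score = (1 - |A∩B| / |A∪B|) + |B \\ A| / |A∪B|`, i.e. Jaccard
#' dissimilarity of the neighbourhoods plus the case-gained fraction.
#' Bounded in `[0, 2]`; 0 when the union is empty or the neighbourhood is
#' unchanged.
#'
#' @param control,case `crc_network` objects.
#' @param nodes node ids, each present in both networks.
#' @return named numeric vector of scores.
#' @export
nesh_scores <- function(control, case, nodes = NULL) {
  nodes <- nodes %||% intersect(control$nodes, case$nodes)
  absent <- setdiff(nodes, intersect(control$nodes, case$nodes))
  assert_that(length(absent) == 0,
              paste("node(s) absent from a network:",
                    paste(absent, collapse = ", ")))
  nb_c <- neighbor_sets(control)
  nb_t <- neighbor_sets(case)
  vapply(nodes, function(v) {
    A <- nb_c[[v]]; B <- nb_t[[v]]
    u <- union(A, B)
    if (length(u) == 0) return(0)
    (1 - length(intersect(A, B)) / length(u)) + length(setdiff(B, A)) / length(u)
  }, numeric(1))
}

#' Betweenness change between control and case networks
#'
#' Normalized shortest-path betweenness of each node within its full
#' group network (unweighted; the edge threshold already encodes
#' association strength).
#'
#' @param control,case `crc_network` objects.
#' @param nodes node ids present in both networks (default: intersection).
#' @return data.frame `taxon_id`, `betweenness_control`,
#'   `betweenness_case`, `increased`.
#' @export
betweenness_change <- function(control, case, nodes = NULL) {
  nodes <- nodes %||% intersect(control$nodes, case$nodes)
  bw <- function(net) {
    g <- as_igraph(net)
    b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
    setNames(as.numeric(b), igraph::V(g)$name)
  }
  b_c <- bw(control)[nodes]
  b_t <- bw(case)[nodes]
  data.frame(taxon_id = nodes,
             betweenness_control = unname(b_c),
             betweenness_case = unname(b_t),
             increased = unname(b_t > b_c),
             stringsAsFactors = FALSE)
}

#' Flag driver taxa from rewiring scores and betweenness shifts
#'
#' A node is a driver when its neighbour-shift score reaches the given
#' quantile of the common-node scores and its betweenness increased from
#' control to case. Community ids (greedy modularity on the case
#' network) are attached for reporting.
#'
#' @param control,case `crc_network` objects.
#' @param score_quantile quantile of the score distribution used as the
#'   driver threshold (default 0.90).
#' @return data.frame of class `crc_drivers` with per-node scores,
#'   betweenness, community and the `driver` flag.
#' @export
identify_drivers <- function(control, case, score_quantile = 0.90) {
  common <- common_subnetwork(control, case)
  nodes <- common$nodes
  assert_that(length(nodes) >= 1, "no common nodes to score")
  scores <- nesh_scores(control, case, nodes)
  bw <- betweenness_change(control, case, nodes)
  thr <- quantile(scores, score_quantile, names = FALSE, type = 7)
  g_case <- as_igraph(case)
  comm <- tryCatch(igraph::membership(igraph::cluster_fast_greedy(g_case)),
                   error = function(e) setNames(seq_along(case$nodes),
                                                case$nodes))
  nb_c <- neighbor_sets(control); nb_t <- neighbor_sets(case)
  out <- data.frame(
    taxon_id = nodes,
    degree_control = lengths(nb_c[nodes]),
    degree_case = lengths(nb_t[nodes]),
    nesh_score = unname(scores),
    betweenness_control = bw$betweenness_control,
    betweenness_case = bw$betweenness_case,
    community = as.integer(comm[nodes]),
    stringsAsFactors = FALSE)
  out$driver <- out$nesh_score >= thr & bw$increased
  attr(out, "score_threshold") <- thr
  class(out) <- c("crc_drivers", "data.frame")
  out
}

#' End-to-end driver screen between two groups
#'
#' Builds the control- and case-group co-occurrence networks from a
#' relative-abundance profile and flags drivers via [identify_drivers()].
#'
#' @param profile samples x taxa relative-abundance matrix.
#' @param metadata sample metadata aligned to rows.
#' @param control_group,case_group group labels (defaults BP and T1).
#' @param group_col grouping column.
#' @param score_quantile passed to [identify_drivers()].
#' @param ... passed to [build_network()].
#' @return the `crc_drivers` data.frame, with the two networks attached
#'   as attributes `control_network` and `case_network`.
#' @export
network_drivers <- function(profile, metadata, control_group = "BP",
                            case_group = "T1", group_col = "group",
                            score_quantile = 0.90, ...) {
  groups <- metadata[[group_col]]
  ctrl <- build_network(profile[groups == control_group, , drop = FALSE], ...)
  case <- build_network(profile[groups == case_group, , drop = FALSE], ...)
  out <- identify_drivers(ctrl, case, score_quantile = score_quantile)
  attr(out, "control_network") <- ctrl
  attr(out, "case_network") <- case
  out
}

#' Write a network as an edge-list TSV
#'
#' @param network a `crc_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
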