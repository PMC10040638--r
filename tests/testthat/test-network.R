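test_that("edges appear for perfect rank correlation and vanish for none", {
  set.seed(2)
  base <- sort(rexp(12)) + 1
  prof <- label_counts(cbind(base, base * 2, rexp(12) + 1))
  net <- build_network(prof, min_prevalence = 0, rho_threshold = 0.6,
                       alpha = 0.05)
  hit <- net$edges[net$edges$node_a == "t1" & net$edges$node_b == "t2", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$weight, 1)
  # thresholds off -> complete graph on retained taxa
  prof2 <- label_counts(matrix(rexp(12 * 5) + 1, 12, 5))
  full <- build_network(prof2, min_prevalence = 0, rho_threshold = 0,
                        alpha = 1)
  expect_equal(nrow(full$edges), choose(5, 2))
  expect_error(build_network(prof2[1:4, ]), ">= 5 samples")
})

test_that("false-edge count among independent taxa stays within the FDR budget", {
  total_edges <- 0
  for (s in 1:40) {
    set.seed(400 + s)
    prof <- label_counts(matrix(rexp(15 * 30), 15, 30))
    net <- build_network(prof, min_prevalence = 0, rho_threshold = 0,
                         alpha = 0.05)
    total_edges <- total_edges + nrow(net$edges)
  }
  # BH at alpha = 0.05 over 435 independent pairs x 40 replicates
  expect_lt(total_edges, 0.05 * choose(30, 2) * 40)
})

test_that("common sub-network takes node intersections and induced edges", {
  a <- toy_network(c("x", "y", "z", "q"),
                   list(c("x", "y"), c("y", "z"), c("z", "q")))
  b <- toy_network(c("x", "y", "z", "r"),
                   list(c("x", "z"), c("x", "r")))
  cs <- common_subnetwork(a, b)
  expect_setequal(cs$nodes, c("x", "y", "z"))
  expect_equal(nrow(cs$edges_control), 2)  # x-y, y-z induced from a
  expect_equal(nrow(cs$edges_case), 1)     # x-z induced from b
  expect_identical(cs$adjacent_control, "q")
  expect_identical(cs$adjacent_case, "r")
  expect_equal(common_subnetwork(a, a)$nodes, a$nodes)
  disjoint <- toy_network(c("m", "n"), list(c("m", "n")))
  expect_warning(empty <- common_subnetwork(a, disjoint), "empty")
  expect_length(empty$nodes, 0)
})

test_that("neighbour-shift scores match direct set arithmetic", {
  ctrl <- toy_network(c("v", "x", "y", "z"), list(c("v", "x"), c("v", "y")))
  case_same <- ctrl
  expect_equal(unname(nesh_scores(ctrl, case_same, "v")), 0)
  # A empty, B = {x, y} -> 1 + 1 = 2
  ctrl0 <- toy_network(c("v", "x", "y"), list())
  case2 <- toy_network(c("v", "x", "y"), list(c("v", "x"), c("v", "y")))
  expect_equal(unname(nesh_scores(ctrl0, case2, "v")), 2)
  # A = {x, y}, B = {y, z} -> (1 - 1/3) + 1/3 = 1
  caseyz <- toy_network(c("v", "x", "y", "z"), list(c("v", "y"), c("v", "z")))
  expect_equal(unname(nesh_scores(ctrl, caseyz, "v")), 1)
  # isolated on both sides -> 0; bounds
  expect_equal(unname(nesh_scores(ctrl0, toy_network(c("v", "x", "y"), list()), "v")), 0)
  expect_error(nesh_scores(ctrl, toy_network("w", list()), "v"), "absent")
})

test_that("neighbour-shift score is monotone in case-gained neighbours and label-invariant", {
  # |A ∪ B| fixed at 4; growing |B \ A| never lowers the score
  scores <- vapply(0:2, function(k) {
    A <- c("a", "b")
    B <- c(c("a", "b")[seq_len(2 - k)], c("c", "d")[seq_len(k)])
    u <- union(A, B)
    (1 - length(intersect(A, B)) / length(u)) + length(setdiff(B, A)) / length(u)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  ctrl <- toy_network(c("v", "x", "y"), list(c("v", "x")))
  case <- toy_network(c("v", "x", "y"), list(c("v", "y")))
  relabel <- function(net) {
    net$nodes <- sub("^v$", "vv", net$nodes)
    net$edges$node_a <- sub("^v$", "vv", net$edges$node_a)
    net$edges$node_b <- sub("^v$", "vv", net$edges$node_b)
    net
  }
  expect_equal(unname(nesh_scores(ctrl, case, "v")),
               unname(nesh_scores(relabel(ctrl), relabel(case), "vv")))
})

test_that("betweenness matches brute-force path enumeration on toys", {
  # path graph a-b-c: centre has normalized betweenness 1
  path3 <- toy_network(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  bw <- betweenness_change(path3, path3)
  expect_equal(bw$betweenness_control[bw$taxon_id == "b"], 1)
  expect_equal(bw$betweenness_control[bw$taxon_id == "a"], 0)
  # isolated node
  iso <- toy_network(c("a", "b", "c"), list(c("a", "b")))
  expect_equal(betweenness_change(iso, iso)$betweenness_control[3], 0)
  # 5-node toy vs exhaustive enumeration
  edges5 <- list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"), c("c", "e"))
  net5 <- toy_network(letters[1:5], edges5)
  got <- betweenness_change(net5, net5)
  oracle <- betweenness_oracle(net5$edges, letters[1:5])
  expect_equal(setNames(got$betweenness_control, got$taxon_id), oracle,
               tolerance = 1e-12)
})

test_that("driver flags require both rewiring and increased betweenness", {
  ctrl <- toy_network(letters[1:4], list(c("a", "b")))
  # identical topology: all scores zero, no drivers
  same <- identify_drivers(ctrl, ctrl)
  expect_true(all(same$nesh_score == 0))
  expect_false(any(same$driver))
  # rewired but with no betweenness increase -> no drivers
  case <- toy_network(letters[1:4], list(c("a", "c")))
  res <- identify_drivers(ctrl, case)
  expect_false(any(res$driver))
  # a case-only bridge gains both score and betweenness
  case2 <- toy_network(letters[1:4],
                       list(c("a", "b"), c("b", "c"), c("c", "d"), c("b", "d")))
  res2 <- identify_drivers(ctrl, case2, score_quantile = 0.25)
  expect_true(res2$driver[res2$taxon_id == "b"])
  # quantile zero flags every node with increased betweenness
  res3 <- identify_drivers(ctrl, case2, score_quantile = 0)
  expect_identical(res3$driver, res3$betweenness_case > res3$betweenness_control)
})

test_that("planted rewiring is recovered end to end", {
  cfg <- simulation_config(n_per_group = c(BP = 45, T1 = 30), seed = 77)
  co <- generate_cohort(cfg)
  cnt <- rarefy_counts(filter_taxa(co$counts, co$taxonomy), seed = 78)
  rel <- to_relative(cnt)
  md <- co$metadata[match(rownames(cnt), co$metadata$sample_id), ]
  drv <- network_drivers(rel, md)
  flagged <- drv$taxon_id[drv$driver]
  expect_gte(length(intersect(flagged, co$truth$driver_taxa)), 10)
  # every planted taxon gains at least one new common-subnetwork neighbour
  planted <- drv[drv$taxon_id %in% co$truth$driver_taxa, ]
  expect_true(all(planted$degree_case >= 1))
  # planted taxa sit above the 75th percentile of the score distribution
  thr <- quantile(drv$nesh_score, 0.75)
  expect_true(mean(planted$nesh_score >= thr) >= 0.9)
})
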