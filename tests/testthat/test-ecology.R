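test_that("Shannon diversity matches closed forms and vegan", {
  prof <- label_counts(rbind(rep(1 / 8, 8), c(1, rep(0, 7))))
  h <- shannon(prof)
  expect_equal(unname(h[1]), log(8))
  expect_equal(unname(h[2]), 0)
  set.seed(4)
  rnd <- to_relative(label_counts(matrix(rpois(200, 10) + 1, 10, 20)))
  expect_equal(unname(shannon(rnd)), unname(vegan::diversity(rnd)))
})

test_that("Bray-Curtis attains its bounds and a hand-computed toy", {
  prof <- label_counts(rbind(c(1, 2, 3), c(1, 2, 3), c(0, 0, 6)))
  d <- bray_curtis(prof)
  expect_equal(d["S1", "S2"], 0)
  disjoint <- label_counts(rbind(c(1, 0), c(0, 1)))
  expect_equal(bray_curtis(disjoint)["S1", "S2"], 1)
  # hand arithmetic: x = (1,2,3), y = (0,0,6): sum|x-y| = 1+2+3 = 6; sum = 12
  expect_equal(d["S1", "S3"], 6 / 12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  zeros <- label_counts(rbind(c(0, 0), c(0, 0), c(1, 1)))
  expect_error(bray_curtis(zeros), "all-zero")
})

test_that("AVD handles degenerate groups, scale invariance, and the Gaussian limit", {
  md <- data.frame(sample_id = paste0("S", 1:8),
                   group = rep(c("BP", "T1"), each = 4),
                   age = 50, gender = "male")
  # identical samples within BP: no-variation flag and AVD 0
  prof <- label_counts(rbind(matrix(0.25, 4, 4),
                             to_relative(matrix(rpois(16, 9) + 1, 4, 4))))
  res <- avd(prof, md)
  expect_true(all(res$samples$no_variation[1:4]))
  expect_equal(res$samples$avd[1:4], rep(0, 4))
  # multiplying one taxon by a constant leaves AVD unchanged
  prof2 <- label_counts(matrix(rexp(32), 8, 4))
  scaled <- prof2
  scaled[, 2] <- scaled[, 2] * 37
  expect_equal(avd(prof2, md)$samples$avd, avd(scaled, md)$samples$avd)
  # E|Z| limit on a large Gaussian fixture
  set.seed(8)
  gauss <- label_counts(matrix(rnorm(200 * 10000), 200, 10000))
  md_big <- data.frame(sample_id = rownames(gauss), group = "BP",
                       age = 50, gender = "male")
  res_big <- avd(gauss, md_big)
  expect_lt(abs(mean(res_big$samples$avd) - sqrt(2 / pi)), 0.01)
})

test_that("AVD group comparison produces letters and errors on singletons", {
  set.seed(21)
  md <- data.frame(sample_id = paste0("S", 1:30),
                   group = rep(c("BP", "T1", "T2"), each = 10),
                   age = 50, gender = "male")
  prof <- label_counts(matrix(rexp(30 * 50), 30, 50))
  res <- avd(prof, md)
  expect_equal(nrow(res$groups), 3)
  expect_true(all(nchar(res$groups$letter) >= 1))
  expect_equal(res$groups$mean[res$groups$group == "BP"],
               mean(res$samples$avd[md$group == "BP"]))
  md_bad <- md; md_bad$group[1:10] <- c("BP", rep("T3", 9))
  expect_error(avd(prof, md_bad), "size 1")
})

test_that("UpSet patterns partition the nonzero taxa", {
  counts <- label_counts(matrix(c(1, 0, 1,
                                  0, 0, 1), 2, 3, byrow = TRUE))
  md <- data.frame(sample_id = c("S1", "S2"), group = c("T1", "T2"),
                   age = 50, gender = "male")
  res <- upset_counts(counts, md)
  expect_equal(res$count[res$pattern == "T1"], 1)
  expect_equal(res$count[res$pattern == "T1&T2"], 1)
  expect_equal(sum(res$count), 2)  # t2 is nowhere nonzero
  co <- small_cohort(seed = 17)
  res2 <- upset_counts(co$counts, co$metadata)
  expect_equal(sum(res2$count), sum(colSums(co$counts) > 0))
})

test_that("specificity and occupancy obey their normalizations", {
  counts <- label_counts(matrix(c(4, 0, 2,
                                  6, 0, 0,
                                  0, 3, 1,
                                  0, 5, 1), 4, 3, byrow = TRUE))
  md <- data.frame(sample_id = paste0("S", 1:4),
                   group = c("T1", "T1", "T2", "T2"), age = 50, gender = "male")
  res <- suppressMessages(spec_occu(counts, md, top_n = 3))
  t1_only <- res[res$taxon_id == "t1" & res$group == "T1", ]
  expect_equal(t1_only$specificity, 1)  # nonzero only in T1 samples
  expect_equal(t1_only$occupancy, 1)    # present in every T1 sample
  expect_true(t1_only$specialist)
  # specificities of a taxon sum to one across groups
  sums <- tapply(res$specificity, res$taxon_id, sum)
  expect_true(all(abs(sums[c("t1", "t3")] - 1) < 1e-9))
  # stability under sample reordering
  perm <- c(3, 1, 4, 2)
  res_perm <- suppressMessages(spec_occu(counts[perm, ], md[perm, ], top_n = 3))
  key <- function(x) x[order(x$taxon_id, x$group), c("specificity", "occupancy")]
  expect_equal(key(res_perm), key(res), ignore_attr = TRUE)
})

test_that("differential abundance is calibrated under the null and powered", {
  md <- data.frame(sample_id = paste0("S", 1:40),
                   group = rep(c("BP", "T1"), each = 20), age = 50, gender = "m")
  set.seed(31)
  rejections <- 0; tests <- 0
  for (r in 1:20) {
    prof <- label_counts(matrix(rexp(40 * 25), 40, 25))
    res <- differential_abundance(prof, md)
    rejections <- rejections + sum(res$p < 0.05)
    tests <- tests + nrow(res)
  }
  rate <- rejections / tests
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / tests) + 0.01)
  # planted 4-fold enrichment detected with power > 0.8
  power_hits <- vapply(1:50, function(r) {
    set.seed(1000 + r)
    prof <- label_counts(matrix(rlnorm(40 * 10), 40, 10))
    prof[md$group == "T1", 1] <- prof[md$group == "T1", 1] * 4
    res <- differential_abundance(to_relative(prof), md)
    res$p[res$taxon_id == "t1"] < 0.05
  }, logical(1))
  expect_gt(mean(power_hits), 0.8)
  # constant taxon flagged with p = 1; BH never lowers p
  prof <- label_counts(matrix(rexp(40 * 5), 40, 5))
  prof[, 3] <- 1
  res <- differential_abundance(prof, md)
  expect_true(res$constant[3] && res$p[3] == 1)
  expect_true(all(res$p_adj >= res$p - 1e-12))
})

test_that("CAP separates separable clusters and is order-invariant", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, 0), 15, 4), matrix(rnorm(60, 6), 15, 4))
  rownames(x) <- paste0("S", 1:30)
  md <- data.frame(sample_id = rownames(x), group = rep(c("a", "b"), each = 15),
                   age = 50, gender = "m")
  d <- as.matrix(dist(x))
  dimnames(d) <- list(rownames(x), rownames(x))
  cap <- cap_ordination(d, md)
  expect_equal(cap$loo_success, 1)
  # permuted labels give near-chance success
  set.seed(6)
  null_succ <- vapply(1:10, function(i) {
    md2 <- md; md2$group <- sample(md2$group)
    cap_ordination(d, md2)$loo_success
  }, numeric(1))
  expect_lt(mean(null_succ), 0.75)
  # input order invariance (up to axis sign)
  perm <- sample(30)
  cap2 <- cap_ordination(d[perm, perm], md[perm, ])
  a <- cap$scores[rownames(cap2$scores), 1]
  expect_gt(abs(cor(a, cap2$scores[, 1])), 0.999)
  # conditioning on the grouping itself removes the separable signal
  md$batch <- md$group
  cap3 <- cap_ordination(d, md, condition_col = "batch")
  expect_lt(cap3$loo_success, cap$loo_success)
})
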