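test_that("stratified split reproduces the 67/28 design and is deterministic", {
  co <- generate_cohort(simulation_config(n_taxa = 10, n_age_taxa = 1,
                                          n_stage_taxa = 1, n_driver_taxa = 1,
                                          seed = 2))
  md <- co$metadata
  sp <- split_cohort(md, seed = 4)
  expect_length(sp$train, 67)
  expect_length(sp$test, 28)
  grp <- md$group[match(sp$train, md$sample_id)]
  expect_equal(sum(grp == "BP"), 32)
  expect_equal(sum(md$group[match(sp$test, md$sample_id)] == "BP"), 13)
  expect_setequal(c(sp$train, sp$test), md$sample_id)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_cohort(md, seed = 4), sp)
  expect_false(identical(split_cohort(md, seed = 5), sp))
})

test_that("confusion arithmetic reproduces the published per-rank accuracies", {
  audit <- audit_published_confusions()
  printed <- c(phylum = 62.1, class = 64.2, order = 64.2, family = 66.3,
               asv = 87.4)
  for (r in names(printed)) {
    row <- audit[audit$rank == r, ]
    expect_equal(row$computed_overall, printed[[r]])
    expect_true(row$consistent)
  }
  # the genus block's printed accuracy cannot be reproduced from its entries
  genus <- audit[audit$rank == "genus", ]
  expect_false(genus$consistent)
  expect_equal(genus$computed_overall, round(100 * 60 / 95, 1))
  # ASV block details: control sensitivity, stage-T1 accuracy, false negatives
  asv <- audit[audit$rank == "asv", ]
  expect_equal(asv$bp_sensitivity, 97.8)
  expect_equal(asv$t1_accuracy, 88.9)
  expect_equal(asv$false_negatives, 0)
})

test_that("accuracy_from_confusion handles identity and degenerate inputs", {
  m <- diag(3L) * 5L
  dimnames(m) <- list(c("T1", "T2", "BP"), c("T1", "T2", "BP"))
  acc <- accuracy_from_confusion(m)
  expect_equal(acc$overall, 1)
  expect_equal(unname(acc$per_class), rep(1, 3))
  expect_equal(acc$false_negatives, 0)
  expect_error(accuracy_from_confusion(matrix(0L, 2, 2)), "empty")
  expect_error(accuracy_from_confusion(matrix(1L, 2, 3)), "square")
})

test_that("vote cutoff, ties and low-confidence flags follow the fixed class order", {
  votes <- rbind(c(0.6, 0.2, 0.1, 0.05, 0.05),
                 c(0.2, 0.2, 0.2, 0.2, 0.2),
                 c(0.1, 0.4, 0.4, 0.05, 0.05))
  colnames(votes) <- c("T1", "T2", "T3", "T4", "BP")
  calls <- crcstage:::votes_to_calls(votes, colnames(votes), 0.5)
  expect_equal(calls$diagnosed, c("T1", "T1", "T2"))  # ties -> first in order
  expect_equal(calls$low_confidence, c(FALSE, TRUE, TRUE))
})

test_that("screens honour the exclusion contract and diagnosis is consistent", {
  co <- small_cohort(seed = 23, n_taxa = 120)
  rel <- to_relative(rarefy_counts(co$counts, depth = 2000, seed = 1))
  md <- co$metadata[match(rownames(rel), co$metadata$sample_id), ]
  excluded <- colnames(rel)[1:20]
  scr <- suppressWarnings(stage_screen(rel, md$group, excluded = excluded,
                                       top_k = 10, seed = 1))
  expect_length(intersect(scr$selected, excluded), 0)
  expect_lte(length(scr$selected), 10)
  model <- fit_stage_model(rel, md$group, scr$selected, excluded = excluded,
                           seed = 1, ntree = 300)
  diag <- diagnose(model, rel, observed = md$group)
  expect_equal(sum(diag$confusion), nrow(rel))
  expect_equal(diag$accuracy$overall,
               sum(diag(diag$confusion)) / sum(diag$confusion))
  expect_equal(mean(diag$calls$correct), diag$accuracy$overall)
  # a model cannot be built on excluded features
  expect_error(fit_stage_model(rel, md$group, excluded[1:3],
                               excluded = excluded), "overlap")
  # features absent from a new profile are zero-filled with a message
  expect_message(diagnose(model, rel[, -match(scr$selected[1], colnames(rel))]),
                 "zero-filling")
})

test_that("age screen needs variation and reports a selected minimal set", {
  co <- generate_cohort(simulation_config(n_per_group = c(BP = 30),
                                          n_taxa = 150, seed = 31,
                                          rarefy_depth = 1500,
                                          depth_mean = 9000, depth_sd = 2000))
  rel <- to_relative(rarefy_counts(co$counts, depth = 1500, seed = 2))
  md <- co$metadata[match(rownames(rel), co$metadata$sample_id), ]
  scr <- age_screen(rel, md$age, n_rep = 1, seed = 1, ntree = 300)
  expect_true(all(scr$selected %in% colnames(rel)))
  expect_equal(scr$cv$size[1], 1)
  expect_true(all(diff(scr$cv$size) > 0))
  expect_lte(length(scr$selected), ncol(rel))
  expect_error(age_screen(rel, rep(50, nrow(rel))), "constant")
})

test_that("cohort-wide diagnosis merges out-of-bag and test votes", {
  co <- small_cohort(seed = 37, n_taxa = 150)
  rel <- to_relative(rarefy_counts(co$counts, depth = 2000, seed = 3))
  md <- co$metadata[match(rownames(rel), co$metadata$sample_id), ]
  sp <- split_cohort(md, seed = 3)
  grp_train <- md$group[match(sp$train, md$sample_id)]
  scr <- suppressWarnings(stage_screen(rel[sp$train, ], grp_train,
                                       top_k = 10, seed = 3))
  model <- fit_stage_model(rel[sp$train, ], grp_train, scr$selected,
                           seed = 3, ntree = 300)
  rep <- diagnose_cohort(model, rel, md, sp$test)
  expect_equal(sum(rep$all$confusion), nrow(rel))
  expect_equal(sum(rep$test$confusion), length(sp$test))
  expect_identical(rep$all$calls$sample_id, md$sample_id)
})

test_that("bias audit flags degenerate reports and computes both tests", {
  md <- data.frame(sample_id = paste0("S", 1:20),
                   group = "BP", age = c(30:39, 60:69),
                   gender = rep(c("male", "female"), 10))
  calls <- data.frame(sample_id = md$sample_id,
                      correct = rep(c(TRUE, FALSE), each = 10))
  res <- audit_bias(calls, md)
  expect_equal(res$test, c("age_wilcoxon", "gender_fisher"))
  expect_false(any(res$degenerate))
  expect_true(all(res$p_adj >= res$p - 1e-12, na.rm = TRUE))
  # hand-built contingency: ages 30-39 correct vs 60-69 false separates fully
  expect_lt(res$p[1], 0.01)
  all_ok <- data.frame(sample_id = md$sample_id, correct = TRUE)
  expect_true(all(audit_bias(all_ok, md)$degenerate))
})

test_that("age-independent errors give calibrated bias p-values", {
  set.seed(12)
  ps <- replicate(100, {
    md <- data.frame(sample_id = paste0("S", 1:30), group = "BP",
                     age = sample(21:89, 30, TRUE),
                     gender = sample(c("male", "female"), 30, TRUE))
    calls <- data.frame(sample_id = md$sample_id,
                        correct = sample(c(TRUE, FALSE), 30, TRUE, c(0.8, 0.2)))
    if (all(calls$correct) || !any(calls$correct)) NA_real_
    else audit_bias(calls, md)$p[1]
  })
  rate <- mean(ps < 0.05, na.rm = TRUE)
  expect_lt(rate, 0.12)
})

test_that("rank sweep prefers the rank carrying the planted signal", {
  co <- small_cohort(seed = 41, n_taxa = 200,
                     n_per_group = c(BP = 14, T1 = 8, T2 = 8, T3 = 8, T4 = 8),
                     stage_effect = 3)
  cnt <- rarefy_counts(filter_taxa(co$counts, co$taxonomy), depth = 2000,
                       seed = 4)
  md <- co$metadata[match(rownames(cnt), co$metadata$sample_id), ]
  sw <- suppressWarnings(rank_sweep(cnt, co$taxonomy, md,
                                    ranks = c("phylum", "asv"),
                                    exclude_age = FALSE, top_k = 15,
                                    seed = 5, ntree = 300))
  expect_equal(nrow(sw$table), 2)
  expect_true(all(sw$table$accuracy_all >= 0 & sw$table$accuracy_all <= 1))
  # effects are planted at ASV resolution, so the finer rank must win
  expect_equal(sw$chosen_rank, "asv")
  rep <- sw$per_rank$asv$report$all
  expect_equal(sum(rep$confusion), nrow(cnt))
})
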