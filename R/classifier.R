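#' Stratified train/test split of a cohort
#'
#' Draws a per-group stratified split; with the default fraction a
#' 95-sample cohort (45 BP, 9/13/22/6 tumors) yields 67 training and 28
#' test samples with 32/13 of the BP controls. Deterministic given the
#' seed.
#'
#' @param metadata sample metadata (`sample_id`, `group`).
#' @param train_fraction fraction of each group assigned to training.
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_cohort <- function(metadata, train_fraction = 67 / 95, seed = 1L) {
  tab <- table(metadata$group)
  assert_that(all(tab >= 2), paste("group(s) with < 2 samples:",
              paste(names(tab)[tab < 2], collapse = ", ")))
  set.seed(seed)
  train <- character(0)
  for (g in names(tab)) {
    ids <- metadata$sample_id[metadata$group == g]
    k <- min(max(round(length(ids) * train_fraction), 1), length(ids) - 1)
    train <- c(train, sample(ids, k))
  }
  list(train = sort(train), test = sort(setdiff(metadata$sample_id, train)))
}

make_folds <- function(n, n_folds, strata = NULL) {
  if (is.null(strata)) {
    sample(rep_len(seq_len(n_folds), n))
  } else {
    fold <- integer(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  }
}

halving_sizes <- function(p) {
  sizes <- p
  while (sizes[length(sizes)] > 1) {
    sizes <- c(sizes, ceiling(sizes[length(sizes)] / 2))
  }
  unique(sizes)
}

ranger_fit <- function(x, y, seed, ntree = 1000, probability = FALSE,
                       importance = "none") {
  classification <- is.factor(y)
  # sqrt(p) candidate features per split (the ranger default for both task
  # types); a large regression mtry lets the strongest of several correlated
  # informative features mask its weaker siblings out of the importance
  mtry <- max(1, floor(sqrt(ncol(x))))
  # inverse-class-frequency split weights: the cohort is heavily imbalanced
  # (45 controls vs 6 T4) and unweighted splitting lets the control class
  # dominate; class weights (rather than case weights) keep out-of-bag
  # coverage of the small classes intact for permutation importance
  cw <- if (classification) {
    w <- 1 / table(y)
    as.numeric(w / sum(w) * nlevels(y))
  } else NULL
  ranger::ranger(x = x, y = y, num.trees = ntree, mtry = mtry,
                 importance = importance, probability = probability,
                 class.weights = cw, seed = seed, num.threads = 1,
                 respect.unordered.factors = TRUE)
}

#' Screen age-discriminatory features on control samples
#'
#' Random-forest regression of host age on feature relative abundances
#' with permutation ("mean decrease accuracy" style) importance.
#' Cross-validated RMSE is traced over nested top-feature subsets whose
#' sizes halve from all features down to one; the selected minimal set is
#' the smallest size attaining the minimum of the CV curve.
#'
#' @param profile samples x features relative-abundance matrix (control
#'   training samples).
#' @param ages numeric host ages aligned to rows.
#' @param n_folds cross-validation folds (default 10; reduced with a
#'   warning when samples are scarce).
#' @param n_rep repetitions of the cross-validation with fresh fold
#'   assignments; the curve averages over all repetitions.
#' @param seed integer seed.
#' @param ntree trees per forest.
#' @return list of class `crc_screen`: `ranking` (features by decreasing
#'   importance), `cv` (data.frame `size`, `error`, `se`), `selected`
#'   (feature ids), `cv_r` and `cv_r2` (out-of-fold Pearson r and R^2 at
#'   the selected size).
#' @export
age_screen <- function(profile, ages, n_folds = 10, n_rep = 3, seed = 1L,
                       ntree = 1000) {
  assert_that(length(unique(ages)) > 1, "host age is constant")
  n <- nrow(profile)
  assert_that(n >= 4, "too few samples to screen")
  if (n < n_folds) {
    warning("reducing folds to ", n, call. = FALSE)
    n_folds <- n
  }
  x <- as.data.frame(profile)
  rf <- ranger_fit(x, ages, seed = derive_seed(seed, 1), ntree = ntree,
                   importance = "permutation")
  imp <- rf$variable.importance
  ranking <- colnames(profile)[order(imp, decreasing = TRUE)]
  sizes <- halving_sizes(ncol(profile))
  cv_err <- matrix(NA_real_, length(sizes), n_folds * n_rep)
  oof <- matrix(NA_real_, length(sizes), n)
  for (r in seq_len(n_rep)) {
    set.seed(derive_seed(seed, 2 + r))
    fold <- make_folds(n, n_folds)
    for (si in seq_along(sizes)) {
      feats <- ranking[seq_len(sizes[si])]
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        fit <- ranger_fit(x[tr, feats, drop = FALSE], ages[tr],
                          seed = derive_seed(seed, 1000 * r + 100 * si + f),
                          ntree = 500)
        pred <- predict(fit, x[!tr, feats, drop = FALSE],
                        num.threads = 1)$predictions
        oof[si, !tr] <- pred
        cv_err[si, (r - 1) * n_folds + f] <- sqrt(mean((pred - ages[!tr])^2))
      }
    }
  }
  err <- rowMeans(cv_err)
  se <- apply(cv_err, 1, sd) / sqrt(ncol(cv_err))
  ord <- order(sizes)
  # minimal set = the curve minimum (smallest size on ties); a one-SE band
  # is wider than the curve's whole range at these fold sizes and would
  # collapse the selection to near-singleton sets
  sel_size <- min(sizes[err <= min(err) + 1e-12])
  sel_idx <- match(sel_size, sizes)
  resid_var <- mean((oof[sel_idx, ] - ages)^2)
  structure(list(
    ranking = ranking,
    importance = sort(imp, decreasing = TRUE),
    cv = data.frame(size = sizes[ord], error = err[ord], se = se[ord]),
    selected = ranking[seq_len(sel_size)],
    cv_r = suppressWarnings(cor(oof[sel_idx, ], ages)),
    cv_r2 = 1 - resid_var / mean((ages - mean(ages))^2)),
    class = "crc_screen")
}

#' Screen stage-discriminatory features
#'
#' Random-forest classification of the group label on feature relative
#' abundances after removing an exclusion set (typically the
#' age-discriminatory features). Features are ranked by permutation
#' importance; the top `top_k` are returned, with an optional
#' cross-validated accuracy curve over halving subset sizes.
#'
#' @param profile samples x features relative-abundance matrix (training
#'   samples).
#' @param groups group labels aligned to rows.
#' @param excluded feature ids removed before fitting.
#' @param top_k number of features returned (default 15).
#' @param n_folds folds for the optional CV curve.
#' @param compute_cv logical; skip the curve for speed when `FALSE`.
#' @param seed integer seed.
#' @param ntree trees per forest.
#' @return list of class `crc_screen`: `ranking`, `selected` (the top
#'   `top_k`), `cv` (or `NULL`).
#' @export
stage_screen <- function(profile, groups, excluded = character(0),
                         top_k = 15, n_folds = 10, compute_cv = FALSE,
                         seed = 1L, ntree = 1000) {
  keep <- setdiff(colnames(profile), excluded)
  assert_that(length(keep) >= 1, "all features excluded")
  x <- as.data.frame(profile[, keep, drop = FALSE])
  y <- factor(groups, levels = intersect(CRC_GROUPS, unique(groups)))
  tab <- table(y)
  if (any(tab < n_folds)) {
    n_folds <- max(2, min(tab))
    warning("smallest class has ", min(tab), " members; using ", n_folds,
            " folds", call. = FALSE)
  }
  rf <- ranger_fit(x, y, seed = derive_seed(seed, 1), ntree = ntree,
                   importance = "permutation")
  imp <- rf$variable.importance
  ranking <- keep[order(imp, decreasing = TRUE)]
  top_k <- min(top_k, length(ranking))
  cv <- NULL
  if (compute_cv) {
    sizes <- halving_sizes(length(keep))
    set.seed(derive_seed(seed, 2))
    fold <- make_folds(length(y), n_folds, strata = as.character(y))
    acc <- matrix(NA_real_, length(sizes), n_folds)
    for (si in seq_along(sizes)) {
      feats <- ranking[seq_len(sizes[si])]
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        fit <- ranger_fit(x[tr, feats, drop = FALSE], droplevels(y[tr]),
                          seed = derive_seed(seed, 100 * si + f), ntree = 500)
        pred <- predict(fit, x[!tr, feats, drop = FALSE],
                        num.threads = 1)$predictions
        acc[si, f] <- mean(as.character(pred) == as.character(y[!tr]))
      }
    }
    ord <- order(sizes)
    cv <- data.frame(size = sizes[ord], accuracy = rowMeans(acc)[ord],
                     se = (apply(acc, 1, sd) / sqrt(n_folds))[ord])
  }
  structure(list(ranking = ranking,
                 importance = sort(imp, decreasing = TRUE),
                 selected = ranking[seq_len(top_k)], cv = cv),
            class = "crc_screen")
}

#' Fit the final stage-diagnosis forest
#'
#' Probability forest over the selected discriminatory features. Class
#' order is fixed as T1, T2, T3, T4, BP for vote reporting and
#' tie-breaking.
#'
#' @param profile samples x features relative-abundance matrix (training
#'   samples).
#' @param groups group labels aligned to rows.
#' @param features final feature list (must be disjoint from `excluded`).
#' @param excluded age-discriminatory exclusion set, kept for the model
#'   record.
#' @param rank taxonomic rank of the features (metadata only).
#' @param vote_cutoff vote fraction required for a confident call.
#' @param seed integer seed.
#' @param ntree trees.
#' @return list of class `crc_stage_model`.
#' @export
fit_stage_model <- function(profile, groups, features,
                            excluded = character(0), rank = "asv",
                            vote_cutoff = 0.5, seed = 1L, ntree = 1000) {
  assert_that(length(intersect(features, excluded)) == 0,
              "final features overlap the exclusion set")
  assert_that(vote_cutoff > 0 && vote_cutoff <= 1,
              "vote_cutoff must lie in (0, 1]")
  assert_that(all(features %in% colnames(profile)),
              "features missing from the training profile")
  y <- factor(groups, levels = intersect(CRC_GROUPS, unique(groups)))
  forest <- ranger_fit(as.data.frame(profile[, features, drop = FALSE]), y,
                       seed = derive_seed(seed, 3), ntree = ntree,
                       probability = TRUE)
  oob <- forest$predictions
  rownames(oob) <- rownames(profile)
  structure(list(features = features, excluded = excluded, rank = rank,
                 vote_cutoff = vote_cutoff, classes = levels(y),
                 forest = forest, oob_votes = oob,
                 train_groups = setNames(as.character(y), rownames(profile))),
            class = "crc_stage_model")
}

votes_to_calls <- function(votes, classes, cutoff) {
  votes <- votes[, classes, drop = FALSE]
  call_idx <- integer(nrow(votes))
  low <- logical(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    v <- votes[i, ]
    hit <- which(v >= cutoff)
    if (length(hit) > 0) {
      call_idx[i] <- hit[1]
    } else {
      call_idx[i] <- which.max(v)  # first max in fixed class order on ties
      low[i] <- TRUE
    }
  }
  data.frame(diagnosed = classes[call_idx], max_vote = apply(votes, 1, max),
             low_confidence = low, stringsAsFactors = FALSE)
}

#' Diagnose samples with a fitted stage model
#'
#' Per sample, the forest's class vote fractions are computed; the
#' diagnosed class is the one reaching the vote cutoff, otherwise the
#' majority class flagged low-confidence (ties break in the fixed class
#' order T1, T2, T3, T4, BP). Features absent from the profile are
#' zero-filled with a message. When observed groups are supplied, a
#' confusion matrix and accuracy summary are attached.
#'
#' @param model a `crc_stage_model`.
#' @param profile samples x features relative-abundance matrix.
#' @param observed optional observed group labels aligned to rows.
#' @return list of class `crc_diagnosis`: `calls` (per-sample
#'   data.frame), `votes`, and — given `observed` — `confusion`,
#'   `accuracy` (see [accuracy_from_confusion()]).
#' @export
diagnose <- function(model, profile, observed = NULL) {
  assert_that(inherits(model, "crc_stage_model"), "model must be a crc_stage_model")
  assert_that(nrow(profile) >= 1, "empty input profile")
  missing <- setdiff(model$features, colnames(profile))
  if (length(missing) > 0) {
    message("zero-filling ", length(missing), " feature(s) absent from input")
    fill <- matrix(0, nrow(profile), length(missing),
                   dimnames = list(rownames(profile), missing))
    profile <- cbind(profile, fill)
  }
  votes <- predict(model$forest,
                   as.data.frame(profile[, model$features, drop = FALSE]),
                   num.threads = 1)$predictions
  rownames(votes) <- rownames(profile)
  calls <- votes_to_calls(votes, model$classes, model$vote_cutoff)
  calls <- cbind(sample_id = rownames(profile), calls)
  out <- list(calls = calls, votes = votes)
  if (!is.null(observed)) {
    out <- c(out, confusion_summary(observed, calls$diagnosed, model$classes))
    out$calls$observed <- as.character(observed)
    out$calls$correct <- out$calls$observed == out$calls$diagnosed
  }
  structure(out, class = "crc_diagnosis")
}

confusion_summary <- function(observed, diagnosed, classes) {
  confusion <- table(factor(observed, levels = classes),
                     factor(diagnosed, levels = classes))
  confusion <- matrix(as.integer(confusion), length(classes),
                      dimnames = list(classes, classes))
  list(confusion = confusion, accuracy = accuracy_from_confusion(confusion))
}

#' Cohort-wide diagnosis from out-of-bag and test votes
#'
#' Training samples are diagnosed from their out-of-bag votes and test
#' samples from ordinary votes, so that the confusion matrix covers all
#' samples, alongside a pure test-set report.
#'
#' @param model a `crc_stage_model`.
#' @param profile full-cohort samples x features relative-abundance matrix.
#' @param metadata sample metadata.
#' @param test_ids sample ids held out from training.
#' @return list with `all` and `test`, each a `crc_diagnosis`-style list.
#' @export
diagnose_cohort <- function(model, profile, metadata, test_ids) {
  train_ids <- rownames(model$oob_votes)
  test <- diagnose(model, profile[test_ids, , drop = FALSE],
                   observed = metadata$group[match(test_ids, metadata$sample_id)])
  oob_calls <- votes_to_calls(model$oob_votes, model$classes, model$vote_cutoff)
  oob_calls <- cbind(sample_id = train_ids, oob_calls)
  oob_calls$observed <- unname(model$train_groups[train_ids])
  oob_calls$correct <- oob_calls$observed == oob_calls$diagnosed
  calls_all <- rbind(oob_calls, test$calls)
  calls_all <- calls_all[match(metadata$sample_id, calls_all$sample_id), ]
  rownames(calls_all) <- NULL
  all <- c(list(calls = calls_all),
           confusion_summary(calls_all$observed, calls_all$diagnosed,
                             model$classes))
  list(all = structure(all, class = "crc_diagnosis"), test = test)
}

#' Full screen-fit-diagnose cycle at several taxonomic ranks
#'
#' For each rank the ASV table is collapsed, the age screen is learned on
#' the control (BP) training samples, the exclusion set removed, stage
#' features screened, the final forest fitted, and the whole cohort
#' diagnosed ([diagnose_cohort()]). The chosen rank maximizes overall
#' accuracy, with ties resolved toward the finer rank.
#'
#' @param counts samples x ASV count matrix (already filtered/rarefied).
#' @param taxonomy taxonomy data.frame.
#' @param metadata sample metadata.
#' @param ranks ranks to sweep (coarse to fine).
#' @param train_fraction,seed passed to [split_cohort()].
#' @param top_k stage-discriminatory features per rank.
#' @param exclude_age if `FALSE`, skip the age screen (the no-exclusion
#'   variant used for the deconfounding contrast).
#' @param ntree trees per forest.
#' @return list of class `crc_rank_sweep`: `per_rank` (each with
#'   `screen_age`, `screen_stage`, `model`, `report`), `table`
#'   (accuracy per rank), `chosen_rank`, `split`.
#' @export
rank_sweep <- function(counts, taxonomy, metadata,
                       ranks = c("phylum", "class", "order", "family",
                                 "genus", "asv"),
                       train_fraction = 67 / 95, top_k = 15,
                       exclude_age = TRUE, seed = 1L, ntree = 1000) {
  split <- split_cohort(metadata, train_fraction, seed = derive_seed(seed, 11))
  per_rank <- list()
  for (r in ranks) {
    collapsed <- collapse_rank(counts, taxonomy, r)
    rel <- to_relative(collapsed)
    train <- split$train
    grp_train <- metadata$group[match(train, metadata$sample_id)]
    excluded <- character(0)
    screen_age <- NULL
    if (exclude_age) {
      bp_train <- train[grp_train == "BP"]
      screen_age <- age_screen(rel[bp_train, , drop = FALSE],
                               metadata$age[match(bp_train, metadata$sample_id)],
                               seed = derive_seed(seed, 21), ntree = ntree)
      excluded <- screen_age$selected
    }
    screen_stage <- stage_screen(rel[train, , drop = FALSE], grp_train,
                                 excluded = excluded, top_k = top_k,
                                 seed = derive_seed(seed, 31), ntree = ntree)
    model <- fit_stage_model(rel[train, , drop = FALSE], grp_train,
                             features = screen_stage$selected,
                             excluded = excluded, rank = r,
                             seed = derive_seed(seed, 41), ntree = ntree)
    report <- diagnose_cohort(model, rel, metadata, split$test)
    per_rank[[r]] <- list(screen_age = screen_age, screen_stage = screen_stage,
                          model = model, report = report)
  }
  tab <- data.frame(
    rank = ranks,
    accuracy_all = vapply(per_rank, function(x) x$report$all$accuracy$overall,
                          numeric(1)),
    accuracy_test = vapply(per_rank, function(x) x$report$test$accuracy$overall,
                           numeric(1)),
    stringsAsFactors = FALSE)
  chosen <- ranks[1]
  for (r in ranks) {
    if (tab$accuracy_all[tab$rank == r] >= tab$accuracy_all[tab$rank == chosen])
      chosen <- r  # >= prefers the finer rank on ties (ranks ordered coarse->fine)
  }
  structure(list(per_rank = per_rank, table = tab, chosen_rank = chosen,
                 split = split),
            class = "crc_rank_sweep")
}

#' Audit diagnosis errors for age and gender bias
#'
#' Wilcoxon rank-sum test of host age between correctly and falsely
#' diagnosed samples and Fisher's exact test of gender against
#' correctness, BH-adjusted across the two tests. Degenerate reports
#' (no errors, or no correct calls) are flagged instead of tested.
#'
#' @param calls per-sample calls data.frame with `sample_id` and
#'   `correct` (from [diagnose()] with observed labels).
#' @param metadata sample metadata with `age` and `gender`.
#' @return data.frame with `test`, `statistic`, `p`, `p_adj`,
#'   `degenerate`.
#' @export
audit_bias <- function(calls, metadata) {
  m <- metadata[match(calls$sample_id, metadata$sample_id), ]
  correct <- calls$correct
  if (all(correct) || !any(correct)) {
    return(data.frame(test = c("age_wilcoxon", "gender_fisher"),
                      statistic = NA_real_, p = NA_real_, p_adj = NA_real_,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(m$age[correct], m$age[!correct]))
  gtab <- table(factor(m$gender), factor(correct, levels = c(FALSE, TRUE)))
  if (nrow(gtab) >= 2) {
    ft <- fisher.test(gtab)
    ft_stat <- if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_
    ft_p <- ft$p.value
  } else {
    ft_stat <- NA_real_
    ft_p <- NA_real_
  }
  out <- data.frame(test = c("age_wilcoxon", "gender_fisher"),
                    statistic = c(unname(wt$statistic), ft_stat),
                    p = c(wt$p.value, ft_p), degenerate = FALSE,
                    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("test", "statistic", "p", "p_adj", "degenerate")]
}
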