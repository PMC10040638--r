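# Parameter registry: defaults plus a domain check per key, by section.
config_schema <- function() {
  num <- function(lo, hi) function(x) is.numeric(x) && length(x) == 1 &&
    x >= lo && x <= hi
  int <- function(lo, hi) function(x) num(lo, hi)(x) && x == round(x)
  list(
    seed = list(default = 1L, check = int(0, 2^31 - 1),
                msg = "integer in [0, 2^31)"),
    simulate = list(
      n_taxa = list(default = 2000L, check = int(1, 1e6), msg = "positive integer"),
      stage_effect = list(default = 2.0, check = num(0, 20), msg = "in [0, 20]"),
      age_effect = list(default = 0.03, check = num(0, 1), msg = "in [0, 1]"),
      rewire_strength = list(default = 0.8, check = num(0, 1), msg = "in [0, 1]"),
      overdispersion = list(default = 1000, check = num(1e-6, 1e9),
                            msg = "positive"),
      depth_mean = list(default = 81710, check = num(1, 1e9), msg = "positive"),
      depth_sd = list(default = 47466, check = num(0, 1e9), msg = "non-negative")),
    preprocess = list(
      rarefy_depth = list(default = 14221L, check = int(1, 1e9),
                          msg = "positive integer"),
      min_samples = list(default = 3L, check = int(1, 1e6),
                         msg = "integer >= 1")),
    ecology = list(
      n_perm = list(default = 999L, check = int(1, 1e7), msg = "integer >= 1"),
      top_n = list(default = 500L, check = int(1, 1e7), msg = "integer >= 1")),
    drivers = list(
      min_prevalence = list(default = 0.3, check = num(0, 1), msg = "in [0, 1]"),
      rho_threshold = list(default = 0.6, check = num(0, 1), msg = "in [0, 1]"),
      alpha = list(default = 0.05, check = num(0, 1), msg = "in (0, 1]"),
      max_taxa = list(default = 200L, check = int(2, 1e6), msg = "integer >= 2"),
      score_quantile = list(default = 0.9, check = num(0, 1), msg = "in [0, 1]")),
    stage_model = list(
      ranks = list(default = c("phylum", "class", "order", "family",
                               "genus", "asv"),
                   check = function(x) is.character(x) &&
                     all(x %in% c("phylum", "class", "order", "family",
                                  "genus", "asv")),
                   msg = "subset of phylum/class/order/family/genus/asv"),
      top_k = list(default = 15L, check = int(1, 1e4), msg = "integer >= 1"),
      train_fraction = list(default = 67 / 95, check = num(0.05, 0.95),
                            msg = "in [0.05, 0.95]"),
      ntree = list(default = 1000L, check = int(10, 1e6), msg = "integer >= 10"))
  )
}

#' Deterministic hash of a canonicalized configuration
#'
#' @param config a plain list.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = 12)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent nested list), rejects
#' unknown keys, type- and range-checks every parameter, and fills
#' defaults. All problems are reported together in one error.
#'
#' @param config path to a YAML file, a nested list, or `NULL` for all
#'   defaults.
#' @return a validated list of class `crc_run_config`, with a
#'   `config_hash` attribute.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    assert_that(file.exists(config), paste("config file not found:", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  assert_that(is.list(config), "config must be a list or YAML file")
  schema <- config_schema()
  errors <- character(0)
  out <- list()
  unknown_top <- setdiff(names(config), names(schema))
  if (length(unknown_top) > 0) {
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown_top, collapse = ", ")))
  }
  for (section in names(schema)) {
    spec <- schema[[section]]
    if (!is.list(spec$default) && !is.null(spec$check)) {  # scalar top-level key
      val <- config[[section]] %||% spec$default
      if (!spec$check(val)) {
        errors <- c(errors, paste0(section, ": must be ", spec$msg))
      }
      out[[section]] <- val
      next
    }
    given <- config[[section]] %||% list()
    unknown <- setdiff(names(given), names(spec))
    if (length(unknown) > 0) {
      errors <- c(errors, paste0(section, ": unknown key(s): ",
                                 paste(unknown, collapse = ", ")))
    }
    out[[section]] <- list()
    for (key in names(spec)) {
      val <- given[[key]] %||% spec[[key]]$default
      if (!spec[[key]]$check(val)) {
        errors <- c(errors, paste0(section, ".", key, ": must be ",
                                   spec[[key]]$msg))
      }
      out[[section]][[key]] <- val
    }
  }
  if (length(errors) > 0) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  attr(out, "config_hash") <- config_hash(out)
  class(out) <- "crc_run_config"
  out
}

write_tsv <- function(x, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    x <- data.frame(setNames(list(rownames(x)), rownames_col),
                    as.data.frame(x), check.names = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess (filter, rarefy) -> ecology (diversity,
#' perMANOVA, AVD, UpSet, SPEC-OCCU, differential abundance) -> driver
#' screen (BP vs T1) -> stage-model rank sweep, writing every table as
#' TSV under `out_dir` plus a consolidated `report.json`. A completed run
#' directory with an identical config hash is left untouched unless
#' `force = TRUE`. Every random draw derives from the single config seed.
#'
#' @param config a [validate_config()] result, a YAML path, or `NULL`.
#' @param out_dir output directory.
#' @param force rerun even if a matching completed run exists.
#' @return invisibly, the consolidated report list.
#' @export
run_pipeline <- function(config = NULL, out_dir, force = FALSE) {
  cfg <- if (inherits(config, "crc_run_config")) config else validate_config(config)
  hash <- attr(cfg, "config_hash")
  report_path <- file.path(out_dir, "report.json")
  if (!force && file.exists(report_path)) {
    prev <- jsonlite::read_json(report_path)
    if (identical(prev$config_hash, hash)) {
      message("run up to date (config hash ", hash, "); use force = TRUE to rerun")
      return(invisible(prev))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  report <- list(config_hash = hash)

  sim_cfg <- simulation_config(
    n_taxa = cfg$simulate$n_taxa, stage_effect = cfg$simulate$stage_effect,
    age_effect = cfg$simulate$age_effect,
    rewire_strength = cfg$simulate$rewire_strength,
    overdispersion = cfg$simulate$overdispersion,
    depth_mean = cfg$simulate$depth_mean, depth_sd = cfg$simulate$depth_sd,
    rarefy_depth = cfg$preprocess$rarefy_depth, seed = derive_seed(seed, 1))
  cohort <- generate_cohort(sim_cfg)
  write_cohort(cohort, file.path(out_dir, "cohort"))

  counts <- filter_taxa(cohort$counts, cohort$taxonomy,
                        min_samples = cfg$preprocess$min_samples)
  report$n_taxa_raw <- ncol(cohort$counts)
  report$n_taxa_filtered <- ncol(counts)
  message("filter_taxa: ", ncol(cohort$counts), " -> ", ncol(counts), " taxa")
  counts <- rarefy_counts(counts, depth = cfg$preprocess$rarefy_depth,
                          seed = derive_seed(seed, 2))
  metadata <- cohort$metadata[match(rownames(counts),
                                    cohort$metadata$sample_id), ]
  report$n_samples <- nrow(counts)
  rel <- to_relative(counts)

  div <- shannon(rel)
  write_tsv(data.frame(sample_id = names(div), shannon = div),
            file.path(out_dir, "diversity.tsv"))
  d <- bray_curtis(rel)
  write_tsv(d, file.path(out_dir, "bray_curtis.tsv"), "sample_id")
  pm <- permanova(d, metadata, terms = c("group", "age", "gender"),
                  n_perm = cfg$ecology$n_perm, seed = derive_seed(seed, 3))
  write_tsv(as.data.frame(pm), file.path(out_dir, "permanova.tsv"))
  report$permanova <- setNames(as.list(pm$R2[1:3]), pm$term[1:3])
  pw <- pairwise_permanova(d, metadata, n_perm = cfg$ecology$n_perm,
                           seed = derive_seed(seed, 4))
  write_tsv(pw, file.path(out_dir, "pairwise_permanova.tsv"))
  stab <- avd(rel, metadata)
  write_tsv(stab$groups, file.path(out_dir, "avd.tsv"))
  report$avd <- setNames(as.list(stab$groups$mean), stab$groups$group)
  ups <- upset_counts(counts, metadata)
  write_tsv(ups, file.path(out_dir, "upset.tsv"))
  all_pattern <- paste(intersect(CRC_GROUPS, unique(metadata$group)),
                       collapse = "&")
  shared <- ups$count[ups$pattern == all_pattern]
  report$shared_taxa_pct <- if (length(shared) == 1)
    shared_fraction(shared, sum(ups$count)) else 0
  so <- spec_occu(counts, metadata, top_n = cfg$ecology$top_n)
  write_tsv(so, file.path(out_dir, "spec_occu.tsv"))
  report$n_specialists <- sum(so$specialist)
  da <- differential_abundance(rel, metadata)
  write_tsv(da, file.path(out_dir, "differential_abundance.tsv"))

  drv <- tryCatch(
    network_drivers(rel, metadata,
                    min_prevalence = cfg$drivers$min_prevalence,
                    rho_threshold = cfg$drivers$rho_threshold,
                    alpha = cfg$drivers$alpha, max_taxa = cfg$drivers$max_taxa,
                    score_quantile = cfg$drivers$score_quantile),
    error = function(e) {
      message("driver screen skipped: ", conditionMessage(e))
      NULL
    })
  if (!is.null(drv)) {
    write_tsv(as.data.frame(drv), file.path(out_dir, "drivers.tsv"))
    report$n_drivers <- sum(drv$driver)
  }

  sweep <- rank_sweep(counts, cohort$taxonomy, metadata,
                      ranks = cfg$stage_model$ranks,
                      train_fraction = cfg$stage_model$train_fraction,
                      top_k = cfg$stage_model$top_k,
                      ntree = cfg$stage_model$ntree,
                      seed = derive_seed(seed, 5))
  write_tsv(sweep$table, file.path(out_dir, "rank_sweep.tsv"))
  chosen <- sweep$per_rank[[sweep$chosen_rank]]
  write_tsv(chosen$report$all$confusion, file.path(out_dir, "confusion.tsv"),
            "observed")
  bias <- audit_bias(chosen$report$all$calls, metadata)
  write_tsv(bias, file.path(out_dir, "bias_audit.tsv"))
  report$chosen_rank <- sweep$chosen_rank
  report$overall_accuracy <- chosen$report$all$accuracy$overall
  report$false_negatives <- chosen$report$all$accuracy$false_negatives
  report$rank_sweep <- setNames(as.list(sweep$table$accuracy_all),
                                sweep$table$rank)

  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
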