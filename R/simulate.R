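#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: a 95-sample
#' cohort (45 benign polyps, tumors 9/13/22/6 across stages T1-T4), host ages
#' 21-89 with a 70/95 male fraction, sequencing depths of 81710 +/- 47466
#' reads, and planted age-associated, stage-discriminatory and
#' network-rewired taxa whose identities are returned as ground truth.
#'
#' @param n_per_group named integer vector of samples per group.
#' @param n_taxa number of ASVs simulated before filtering.
#' @param age_range two-element numeric, youngest and oldest host age (years).
#' @param male_fraction probability that a subject is male.
#' @param n_age_taxa,n_stage_taxa,n_driver_taxa numbers of planted taxa with,
#'   respectively, an age trend, a stage effect, and case-group co-occurrence
#'   rewiring. The three sets are disjoint.
#' @param stage_effect magnitude of the planted stage effect, log2 fold change.
#' @param age_effect slope of log relative abundance per year of host age.
#' @param rewire_strength loading of the shared latent factor planted in the
#'   case group (T1), in log units per factor standard deviation.
#' @param depth_mean,depth_sd mean and sd of per-sample sequencing depth
#'   (reads); depths are truncated below at `2 * rarefy_depth`.
#' @param rarefy_depth target even depth used downstream.
#' @param overdispersion Dirichlet concentration scale; smaller values give
#'   stronger taxon-level overdispersion around the expected composition.
#' @param baseline_sigma sd of the log-normal baseline abundance profile.
#' @param age_by_group optional named list of per-group age ranges, used to
#'   emulate an age-stage confounded cohort; default `NULL` draws every
#'   group's ages from `age_range`.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return an object of class `crc_sim_config` (a validated list).
#' @export
simulation_config <- function(n_per_group = c(BP = 45, T1 = 9, T2 = 13, T3 = 22, T4 = 6),
                              n_taxa = 2000,
                              age_range = c(21, 89),
                              male_fraction = 70 / 95,
                              n_age_taxa = 9,
                              n_stage_taxa = 15,
                              n_driver_taxa = 13,
                              stage_effect = 2.0,
                              age_effect = 0.03,
                              rewire_strength = 0.8,
                              depth_mean = 81710,
                              depth_sd = 47466,
                              rarefy_depth = 14221,
                              overdispersion = 1000,
                              baseline_sigma = 1.5,
                              age_by_group = NULL,
                              seed = 1L) {
  cfg <- list(n_per_group = n_per_group, n_taxa = as.integer(n_taxa),
              age_range = age_range, male_fraction = male_fraction,
              n_age_taxa = as.integer(n_age_taxa),
              n_stage_taxa = as.integer(n_stage_taxa),
              n_driver_taxa = as.integer(n_driver_taxa),
              stage_effect = stage_effect, age_effect = age_effect,
              rewire_strength = rewire_strength,
              depth_mean = depth_mean, depth_sd = depth_sd,
              rarefy_depth = as.integer(rarefy_depth),
              overdispersion = overdispersion,
              baseline_sigma = baseline_sigma,
              age_by_group = age_by_group,
              seed = as.integer(seed))
  assert_that(length(cfg$n_per_group) >= 1 && all(cfg$n_per_group >= 1),
              "n_per_group must hold positive counts")
  assert_that(!is.null(names(cfg$n_per_group)) &&
                all(names(cfg$n_per_group) %in% CRC_GROUPS),
              "n_per_group names must be among BP, T1, T2, T3, T4")
  assert_that(cfg$n_taxa >= 1, "n_taxa must be positive")
  assert_that(cfg$n_age_taxa + cfg$n_stage_taxa + cfg$n_driver_taxa <= cfg$n_taxa,
              "planted taxa exceed n_taxa")
  assert_that(length(cfg$age_range) == 2 && cfg$age_range[1] < cfg$age_range[2],
              "age_range must be [min, max] with min < max")
  assert_that(cfg$male_fraction >= 0 && cfg$male_fraction <= 1,
              "male_fraction must lie in [0, 1]")
  assert_that(cfg$rewire_strength >= 0 && cfg$rewire_strength <= 1,
              "rewire_strength must lie in [0, 1]")
  assert_that(cfg$rarefy_depth >= 1 && cfg$depth_mean > 0 && cfg$depth_sd >= 0,
              "depth parameters must be positive")
  assert_that(cfg$overdispersion > 0, "overdispersion must be positive")
  class(cfg) <- "crc_sim_config"
  cfg
}

# SILVA-style phylum pool; Firmicutes + Bacteroidota + Proteobacteria carry
# ~75% of the mass in expectation (assignment is independent of abundance).
PHYLUM_POOL <- c(Firmicutes = 0.35, Bacteroidota = 0.25, Proteobacteria = 0.15,
                 Actinobacteriota = 0.08, Fusobacteriota = 0.06,
                 Campylobacterota = 0.04, Verrucomicrobiota = 0.04,
                 Desulfobacterota = 0.03)

# Nested synthetic taxonomy: ~3 ASVs per genus, 3 genera per family, 3
# families per order, 3 orders per class, 2 classes merged per phylum draw.
simulate_taxonomy <- function(n_taxa) {
  idx <- seq_len(n_taxa) - 1L
  genus  <- idx %/% 3L
  family <- genus %/% 3L
  ord    <- family %/% 3L
  clas   <- ord %/% 3L
  phy_of_class <- sample(names(PHYLUM_POOL), max(clas) + 1L, replace = TRUE,
                         prob = PHYLUM_POOL)
  phylum <- phy_of_class[clas + 1L]
  # a fraction of ASVs lack species (40%) or genus (10%) assignment
  sp_known <- runif(n_taxa) > 0.4
  ge_known <- runif(n_taxa) > 0.1
  lineage <- paste0("d__Bacteria; p__", phylum,
                    "; c__", phylum, "_c", clas,
                    "; o__o", ord,
                    "; f__f", family,
                    "; g__", ifelse(ge_known, paste0("g", genus), ""),
                    "; s__", ifelse(sp_known & ge_known,
                                    paste0("g", genus, "_s", idx), ""))
  data.frame(taxon_id = sprintf("ASV%04d", seq_len(n_taxa)),
             lineage = lineage, stringsAsFactors = FALSE)
}

#' Plant a linear age trend into an abundance profile
#'
#' For each planted taxon, log abundance shifts linearly with host age
#' centred at the cohort mean age; other taxa are untouched. The profile is
#' not renormalized here — callers convert to proportions afterwards.
#'
#' @param profile numeric matrix, samples x taxa, positive abundances.
#' @param metadata sample metadata with an `age` column aligned to rows.
#' @param taxa character vector of planted taxon ids (columns of `profile`).
#' @param slope change in log abundance per year.
#' @return the modified profile matrix.
#' @export
plant_age_effect <- function(profile, metadata, taxa, slope) {
  missing <- setdiff(taxa, colnames(profile))
  assert_that(length(missing) == 0,
              paste("unknown taxon id(s):", paste(missing, collapse = ", ")))
  if (length(taxa) == 0 || slope == 0) return(profile)
  centred <- metadata$age - mean(metadata$age)
  profile[, taxa] <- profile[, taxa, drop = FALSE] * exp(slope * centred)
  profile
}

#' Plant case-group co-occurrence rewiring into an abundance profile
#'
#' Within the case group only, planted taxa share a common latent log-normal
#' factor, inducing positive pairwise correlation absent in the control
#' group. Each taxon responds to the factor with its own sensitivity —
#' loadings are spread evenly over `[0.65, 1] * strength` — as taxa react
#' to a shared environmental driver to different degrees. Marginal means
#' are preserved to first order by the usual log-normal mean correction.
#'
#' @param profile numeric matrix, samples x taxa, positive abundances.
#' @param metadata sample metadata with a `group` column aligned to rows.
#' @param taxa planted taxon ids.
#' @param strength top latent-factor loading in `[0, 1]` (log units per
#'   factor sd).
#' @param case_group group label receiving the factor (default `"T1"`).
#' @return the modified profile matrix.
#' @export
plant_network_rewiring <- function(profile, metadata, taxa, strength,
                                   case_group = "T1") {
  assert_that(strength >= 0 && strength <= 1, "strength must lie in [0, 1]")
  missing <- setdiff(taxa, colnames(profile))
  assert_that(length(missing) == 0,
              paste("unknown taxon id(s):", paste(missing, collapse = ", ")))
  if (length(taxa) == 0 || strength == 0) return(profile)
  case <- which(metadata$group == case_group)
  if (length(case) == 0) return(profile)
  z <- rnorm(length(case))
  if (length(case) >= 2) {
    # standardize the realized factor so the planted correlation structure
    # does not drift with the luck of a small case-group draw
    z <- (z - mean(z)) / sd(z)
  }
  loading <- strength * seq(0.65, 1, length.out = length(taxa))
  shift <- exp(outer(z, loading) - rep(loading^2 / 2, each = length(case)))
  profile[case, taxa] <- profile[case, taxa, drop = FALSE] * shift
  profile
}

#' Generate a synthetic tumor-microbiome cohort with ground truth
#'
#' Draws sample metadata (group, age, gender), a nested SILVA-style
#' taxonomy, and an ASV count table from a Dirichlet-multinomial around a
#' log-normal baseline composition modified by three planted effects:
#' age-trending taxa, stage-discriminatory taxa (half monotone across
#' T1-T4, half single-stage spikes), and taxa rewired into a shared latent
#' factor in the case group. Per-sample depths are truncated-normal draws.
#'
#' @param config a [simulation_config()] object.
#' @return a list of class `crc_cohort` with elements `counts` (samples x
#'   taxa integer matrix), `metadata` (data.frame), `taxonomy` (data.frame),
#'   and `truth` (list with `age_taxa`, `stage_taxa`, `stage_fc` log2
#'   fold-change matrix, `driver_taxa`, and the `config`).
#' @export
generate_cohort <- function(config = simulation_config()) {
  assert_that(inherits(config, "crc_sim_config"),
              "config must come from simulation_config()")
  set.seed(config$seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  ages <- numeric(n)
  for (g in unique(groups)) {
    rng <- (config$age_by_group[[g]] %||% config$age_range)
    sel <- groups == g
    ages[sel] <- sample(seq(rng[1], rng[2]), sum(sel), replace = TRUE)
  }
  metadata <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    age = ages,
    gender = ifelse(runif(n) < config$male_fraction, "male", "female"),
    stringsAsFactors = FALSE)
  validate_metadata(metadata)

  taxonomy <- simulate_taxonomy(config$n_taxa)
  log_base <- rnorm(config$n_taxa, 0, config$baseline_sigma)
  names(log_base) <- taxonomy$taxon_id

  # Planted sets, disjoint, chosen among abundant taxa so that effects are
  # detectable at amplicon depth: drivers from the top of the baseline
  # (co-occurrence needs low sampling noise), stage and age taxa below them.
  # Drivers sit at the top of the baseline (co-occurrence detection needs low
  # sampling noise); stage taxa are abundant; age taxa sit at moderate
  # abundance where single-taxon noise is high, so age information is spread
  # across the set rather than concentrated in one or two proxies.
  ord <- order(log_base, decreasing = TRUE)
  ids <- taxonomy$taxon_id
  band <- function(a, b) {
    a <- min(a, config$n_taxa)
    b <- min(b, config$n_taxa)
    ids[ord[seq(min(a, b), b)]]
  }
  pick <- function(pool, k, taken) {
    pool <- setdiff(pool, taken)
    # tiny simulations may not fit the preferred abundance band; fall back
    # to any remaining taxa
    if (length(pool) < k) pool <- unique(c(pool, setdiff(ids, taken)))
    sample(pool, k)
  }
  driver_taxa <- ids[ord[pmin(seq_len(config$n_driver_taxa) + 2L,
                              config$n_taxa)]]
  driver_taxa <- unique(driver_taxa)
  if (length(driver_taxa) < config$n_driver_taxa) {
    driver_taxa <- c(driver_taxa,
                     pick(ids, config$n_driver_taxa - length(driver_taxa),
                          driver_taxa))
  }
  age_taxa <- pick(band(40, 100), config$n_age_taxa, driver_taxa)
  stage_taxa <- pick(band(20, 220), config$n_stage_taxa,
                     c(driver_taxa, age_taxa))

  profile <- matrix(exp(log_base), nrow = n, ncol = config$n_taxa,
                    byrow = TRUE, dimnames = list(metadata$sample_id, ids))

  # Stage effects (log2 fold change vs BP): first half monotone across
  # T1->T4 with alternating sign (taxa that progressively bloom or deplete
  # along severity), second half spiked at initiation (T1), the stage where
  # transiently recruited taxa appear.
  stage_fc <- matrix(0, length(stage_taxa), 4,
                     dimnames = list(stage_taxa, c("T1", "T2", "T3", "T4")))
  n_mono <- ceiling(length(stage_taxa) / 2)
  ramp <- seq(0.8, 2, length.out = 4) / 2
  for (i in seq_along(stage_taxa)) {
    if (i <= n_mono) {
      sign <- if (i %% 2 == 0) -1 else 1
      stage_fc[i, ] <- sign * config$stage_effect * ramp
    } else {
      stage_fc[i, "T1"] <- config$stage_effect
    }
  }
  for (g in c("T1", "T2", "T3", "T4")) {
    sel <- metadata$group == g
    if (any(sel)) {
      profile[sel, stage_taxa] <- profile[sel, stage_taxa, drop = FALSE] *
        matrix(2^stage_fc[, g], sum(sel), length(stage_taxa), byrow = TRUE)
    }
  }

  # taxon-specific age responses: magnitudes spread around the configured
  # slope, directions alternating (taxa both wax and wane with host age)
  age_slopes <- config$age_effect *
    seq(0.85, 1.15, length.out = max(length(age_taxa), 1)) *
    rep_len(c(1, -1), length(age_taxa))
  for (i in seq_along(age_taxa)) {
    profile <- plant_age_effect(profile, metadata, age_taxa[i], age_slopes[i])
  }
  profile <- plant_network_rewiring(profile, metadata, driver_taxa,
                                    config$rewire_strength)

  # depths: truncated normal, floor at 2x rarefaction depth
  floor_depth <- 2 * config$rarefy_depth
  depths <- round(rnorm(n, config$depth_mean, config$depth_sd))
  while (any(bad <- depths < floor_depth)) {
    depths[bad] <- round(rnorm(sum(bad), config$depth_mean, config$depth_sd))
  }

  counts <- matrix(0L, n, config$n_taxa, dimnames = dimnames(profile))
  conc <- config$overdispersion
  for (j in seq_len(n)) {
    p <- profile[j, ] / sum(profile[j, ])
    gam <- rgamma(config$n_taxa, shape = conc * p, rate = 1)
    if (sum(gam) == 0) gam <- p
    counts[j, ] <- as.integer(rmultinom(1, depths[j], gam / sum(gam)))
  }

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy,
                 truth = list(age_taxa = age_taxa,
                              age_slopes = setNames(age_slopes, age_taxa),
                              stage_taxa = stage_taxa,
                              stage_fc = stage_fc, driver_taxa = driver_taxa,
                              config = config)),
            class = "crc_cohort")
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `counts.tsv` (rows = ASVs, columns = samples), `metadata.tsv`,
#' `taxonomy.tsv` (SILVA-style semicolon lineages) and `ground_truth.json`.
#' Each TSV carries a `# config_hash:` header line for provenance.
#'
#' @param cohort a `crc_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "crc_cohort"), "cohort must be a crc_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(cohort$truth$config))
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_tsv_hashed <- function(df, path, row_label) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# config_hash: ", hash), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts_df <- data.frame(taxon_id = colnames(cohort$counts),
                          t(cohort$counts), check.names = FALSE)
  write_tsv_hashed(counts_df, paths["counts"])
  write_tsv_hashed(cohort$metadata, paths["metadata"])
  write_tsv_hashed(cohort$taxonomy, paths["taxonomy"])
  truth <- cohort$truth
  truth$stage_fc <- as.data.frame(truth$stage_fc)
  truth$config <- unclass(truth$config)
  truth$config_hash <- hash
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
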