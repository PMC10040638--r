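#' Read the three input tables
#'
#' Reads an ASV count table (TSV, rows = taxa, columns = samples, first
#' column `taxon_id`), a sample metadata table (`sample_id`, `group`,
#' `age`, `gender`) and a taxonomy table (`taxon_id`, `lineage`). Sample
#' sets of counts and metadata are reconciled by intersection (mismatches
#' warned about), as are the taxon sets of counts and taxonomy. Lines
#' starting with `#` are ignored.
#'
#' @param counts_path,metadata_path,taxonomy_path file paths.
#' @return list with `counts` (samples x taxa integer matrix), `metadata`,
#'   `taxonomy`.
#' @export
read_tables <- function(counts_path, metadata_path, taxonomy_path) {
  for (p in c(counts_path, metadata_path, taxonomy_path)) {
    assert_that(file.exists(p), paste("file not found:", p))
  }
  raw <- read.delim(counts_path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  assert_that(ncol(raw) >= 2, "count table needs a taxon id column and samples")
  taxa <- as.character(raw[[1]])
  assert_that(!anyDuplicated(taxa), "duplicate taxon ids in count table")
  counts <- t(as.matrix(raw[, -1, drop = FALSE]))
  colnames(counts) <- taxa
  storage.mode(counts) <- "integer"
  assert_that(!anyDuplicated(rownames(counts)), "duplicate sample ids in count table")

  metadata <- read.delim(metadata_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  validate_metadata(metadata)
  assert_that(!anyDuplicated(metadata$sample_id), "duplicate sample ids in metadata")

  taxonomy <- read.delim(taxonomy_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  assert_that(all(c("taxon_id", "lineage") %in% names(taxonomy)),
              "taxonomy table needs taxon_id and lineage columns")
  assert_that(!anyDuplicated(taxonomy$taxon_id), "duplicate taxon ids in taxonomy")

  shared_samples <- intersect(rownames(counts), metadata$sample_id)
  assert_that(length(shared_samples) > 0,
              "no samples shared between counts and metadata")
  dropped <- setdiff(union(rownames(counts), metadata$sample_id), shared_samples)
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " sample(s) absent from one table: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  shared_taxa <- intersect(colnames(counts), taxonomy$taxon_id)
  assert_that(length(shared_taxa) > 0,
              "no taxa shared between counts and taxonomy")
  dropped_t <- setdiff(union(colnames(counts), taxonomy$taxon_id), shared_taxa)
  if (length(dropped_t) > 0) {
    warning("dropping ", length(dropped_t), " taxon id(s) absent from one table",
            call. = FALSE)
  }
  counts <- counts[shared_samples, shared_taxa, drop = FALSE]
  metadata <- metadata[match(shared_samples, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  taxonomy <- taxonomy[match(shared_taxa, taxonomy$taxon_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  list(counts = validate_counts(counts), metadata = metadata,
       taxonomy = taxonomy)
}

# split "d__Bacteria; p__X; ..." into a 7-column matrix of bare rank names
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";")
  mat <- matrix("", length(lineage), 7,
                dimnames = list(NULL, TAXONOMIC_RANKS))
  for (i in seq_along(parts)) {
    tokens <- trimws(parts[[i]])
    tokens <- sub("^[a-z]__", "", tokens)
    mat[i, seq_len(min(7, length(tokens)))] <- tokens[seq_len(min(7, length(tokens)))]
  }
  mat
}

#' Taxonomy- and prevalence-based ASV filtering
#'
#' Removes taxa whose lineage contains any excluded token (case-insensitive
#' match on individual rank fields, any rank) — by default Mitochondria,
#' Chloroplast, Archaea and Eukaryota — and taxa detected in fewer than
#' `min_samples` samples. The sample set is unchanged. Detection in exactly
#' `min_samples` samples retains the taxon (the threshold is inclusive).
#'
#' @param counts samples x taxa count matrix.
#' @param taxonomy taxonomy data.frame (`taxon_id`, `lineage`).
#' @param min_samples minimum number of samples with nonzero counts.
#' @param excluded_lineages character vector of lineage tokens to exclude.
#' @return the filtered count matrix.
#' @export
filter_taxa <- function(counts, taxonomy, min_samples = 3,
                        excluded_lineages = c("Mitochondria", "Chloroplast",
                                              "Archaea", "Eukaryota")) {
  validate_counts(counts)
  assert_that(min_samples >= 1, "min_samples must be >= 1")
  lin <- taxonomy$lineage[match(colnames(counts), taxonomy$taxon_id)]
  ranks <- parse_lineage(ifelse(is.na(lin), "", lin))
  excluded <- rep(FALSE, ncol(counts))
  for (token in excluded_lineages) {
    hit <- rowSums(matrix(grepl(token, ranks, ignore.case = TRUE),
                          nrow = nrow(ranks))) > 0
    excluded <- excluded | hit
  }
  prevalence <- colSums(counts > 0)
  keep <- !excluded & prevalence >= min_samples
  if (!any(keep)) {
    message("filter_taxa: no taxa retained")
  }
  counts[, keep, drop = FALSE]
}

#' Rarefy samples to an even depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric
#' draw) to exactly `depth` reads. Samples whose totals fall below the
#' depth are dropped with a warning. Deterministic for a given seed.
#'
#' @param counts samples x taxa count matrix.
#' @param depth target depth (reads).
#' @param seed integer seed.
#' @return rarefied count matrix; every row sums to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 14221, seed = 1L) {
  validate_counts(counts)
  assert_that(depth >= 1, "depth must be >= 1")
  totals <- rowSums(counts)
  keep <- totals >= depth
  assert_that(any(keep), "all samples fall below the rarefaction depth")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[!keep], collapse = ", "), call. = FALSE)
  }
  counts <- counts[keep, , drop = FALSE]
  set.seed(seed)
  # rrarefy's input heuristics warn on legitimate large counts; inputs are
  # already validated as integer counts at or above the target depth
  out <- suppressWarnings(vegan::rrarefy(counts, depth))
  storage.mode(out) <- "integer"
  out
}

#' Convert counts to relative abundances
#'
#' @param counts samples x taxa non-negative matrix; every sample total
#'   must be positive.
#' @return matrix of the same shape whose rows each sum to 1.
#' @export
to_relative <- function(counts) {
  totals <- rowSums(counts)
  bad <- totals <= 0
  if (any(bad)) {
    stop("sample(s) with zero total: ",
         paste(rownames(counts)[bad], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 1, totals, "/")
}

#' Collapse a count table to a higher taxonomic rank
#'
#' Sums counts over taxa sharing the lineage prefix up to `rank`. Taxa
#' unassigned at that rank are pooled into an explicit `unassigned@rank`
#' bin, so per-sample totals are conserved exactly.
#'
#' @param counts samples x taxa count matrix (taxa = ASVs).
#' @param taxonomy taxonomy data.frame.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, or `"asv"` (identity).
#' @return samples x collapsed-taxa matrix; columns named by lineage prefix.
#' @export
collapse_rank <- function(counts, taxonomy, rank) {
  rank <- match.arg(tolower(rank), c("phylum", "class", "order", "family",
                                     "genus", "asv"))
  if (rank == "asv") return(counts)
  validate_counts(counts)
  depth_idx <- match(rank, TAXONOMIC_RANKS)
  lin <- taxonomy$lineage[match(colnames(counts), taxonomy$taxon_id)]
  ranks <- parse_lineage(ifelse(is.na(lin), "", lin))
  assigned <- ranks[, depth_idx] != ""
  label <- apply(ranks[, seq_len(depth_idx), drop = FALSE], 1,
                 paste, collapse = ";")
  label[!assigned] <- paste0("unassigned@", rank)
  groups <- factor(label, levels = unique(label))
  out <- t(rowsum(t(counts), groups))
  storage.mode(out) <- storage.mode(counts)
  out
}
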