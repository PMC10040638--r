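#' Accuracy summaries from a confusion matrix
#'
#' Overall accuracy is the trace over the total; per-class accuracy is
#' each diagonal entry over its row (observed-class) sum. For cohorts
#' with a control class, the count of case samples diagnosed as control
#' (false negatives in the cancer-warning sense) is reported.
#'
#' @param matrix square confusion matrix of non-negative integers,
#'   observed classes in rows, diagnosed classes in columns, identical
#'   row/column order.
#' @param control class label treated as the control for the
#'   false-negative audit (default `"BP"`; ignored if absent).
#' @return list: `overall` (proportion), `per_class` (named vector),
#'   `n`, `false_negatives` (NA when no control class).
#' @export
accuracy_from_confusion <- function(matrix, control = "BP") {
  m <- as.matrix(matrix)
  assert_that(nrow(m) == ncol(m), "confusion matrix must be square")
  assert_that(all(m >= 0) && all(m == round(m)),
              "confusion entries must be non-negative integers")
  total <- sum(m)
  assert_that(total > 0, "confusion matrix is empty")
  per_class <- diag(m) / rowSums(m)
  names(per_class) <- rownames(m)
  fn <- NA_integer_
  if (!is.null(rownames(m)) && control %in% rownames(m)) {
    case_rows <- setdiff(rownames(m), control)
    fn <- sum(m[case_rows, control])
  }
  list(overall = sum(diag(m)) / total, per_class = per_class,
       n = total, false_negatives = fn)
}

#' Published stage-diagnosis confusion matrices
#'
#' The six per-rank 5x5 confusion matrices of the published diagnosis
#' model (observed rows, diagnosed columns, order T1, T2, T3, T4, BP),
#' together with each block's printed overall accuracy (percent). These
#' are inputs for arithmetic audits: [audit_published_confusions()]
#' recomputes each block's accuracy and flags blocks whose printed value
#' disagrees with their own entries.
#'
#' @return named list of lists, one per rank (`phylum` ... `genus`,
#'   `asv`), each with `matrix` and `printed_overall` (percent).
#' @export
published_confusions <- function() {
  lv <- c("T1", "T2", "T3", "T4", "BP")
  block <- function(v, printed) {
    list(matrix = matrix(as.integer(v), 5, 5, byrow = TRUE,
                         dimnames = list(lv, lv)),
         printed_overall = printed)
  }
  list(
    phylum = block(c(3, 1, 2, 3, 0,
                     0, 1, 8, 0, 4,
                     1, 3, 12, 1, 5,
                     1, 3, 2, 0, 0,
                     0, 0, 2, 0, 43), 62.1),
    class = block(c(2, 2, 1, 0, 4,
                    1, 2, 6, 0, 4,
                    2, 4, 11, 1, 4,
                    0, 2, 3, 1, 0,
                    0, 0, 0, 0, 45), 64.2),
    order = block(c(1, 3, 2, 0, 3,
                    0, 0, 10, 0, 3,
                    1, 2, 14, 0, 5,
                    2, 0, 2, 1, 1,
                    0, 0, 0, 0, 45), 64.2),
    family = block(c(0, 1, 2, 4, 2,
                     0, 2, 8, 0, 3,
                     1, 2, 14, 0, 5,
                     0, 4, 0, 2, 0,
                     0, 0, 0, 0, 45), 66.3),
    genus = block(c(1, 0, 2, 5, 1,
                    0, 0, 11, 0, 2,
                    1, 3, 16, 0, 2,
                    0, 0, 2, 0, 4,
                    0, 0, 2, 0, 43), 70.6),
    asv = block(c(8, 0, 1, 0, 0,
                  1, 8, 4, 0, 0,
                  0, 2, 17, 3, 0,
                  0, 0, 0, 6, 0,
                  0, 0, 1, 0, 44), 87.4)
  )
}

#' Audit the published confusion blocks
#'
#' Recomputes each published block's overall accuracy from its entries
#' via [accuracy_from_confusion()] and compares it with the printed value
#' at the printed precision (one decimal, percent). Blocks whose printed
#' accuracy cannot be reproduced from their own entries are flagged
#' inconsistent.
#'
#' @return data.frame with `rank`, `computed_overall` (percent),
#'   `printed_overall`, `consistent`, `bp_sensitivity`, `t1_accuracy`,
#'   `false_negatives`.
#' @export
audit_published_confusions <- function() {
  blocks <- published_confusions()
  out <- do.call(rbind, lapply(names(blocks), function(r) {
    b <- blocks[[r]]
    acc <- accuracy_from_confusion(b$matrix)
    computed <- round(100 * acc$overall, 1)
    data.frame(rank = r,
               computed_overall = computed,
               printed_overall = b$printed_overall,
               consistent = abs(computed - b$printed_overall) < 0.05 + 1e-9,
               bp_sensitivity = round(100 * acc$per_class[["BP"]], 1),
               t1_accuracy = round(100 * acc$per_class[["T1"]], 1),
               false_negatives = acc$false_negatives,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Shared-taxon percentage
#'
#' Fraction (percent) of taxa falling in the all-groups intersection of
#' an UpSet partition, e.g. the taxa detected in every study group.
#'
#' @param n_shared taxa present in all groups.
#' @param n_total all nonzero taxa.
#' @return percentage, rounded to two decimals.
#' @export
shared_fraction <- function(n_shared, n_total) {
  assert_that(n_total > 0 && n_shared >= 0 && n_shared <= n_total,
              "need 0 <= n_shared <= n_total, n_total > 0")
  round(100 * n_shared / n_total, 2)
}
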