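# Confidence scoring of ISG proteome candidates.
#
# Each location keyword is scored by how well it separates curated true
# positives from trial negatives; a protein's confidence combines its
# keyword score sums with the number of proteomes it appears in.

#' Build a keyword score table
#'
#' For every keyword observed in the catalog, tabulates the fraction of
#' labelled positives and of labelled negatives carrying it, and assigns
#' `score = fraction_of_positives - fraction_of_negatives`.  Keywords that
#' mark contaminant compartments (e.g. "mitochondrion", "nucleus") thereby
#' receive negative scores.
#'
#' @param catalog An [annotation_catalog()].
#' @param labels A [labelled_set()].
#' @param flavour `"location"` to score each protein's own annotations,
#'   `"interactor"` to score the annotations of its interactors.
#' @return A data frame (class `loc_score_table`) with columns `keyword`,
#'   `frac_pos`, `frac_neg`, `score`, and attribute `flavour`.
#' @export
build_score_table <- function(catalog, labels, flavour = c("location", "interactor")) {
  flavour <- match.arg(flavour)
  if (length(labels$positives) == 0 || length(labels$negatives) == 0) {
    stop("both positives and negatives are required to build a score table")
  }
  ann <- if (flavour == "location") catalog$locations else catalog$interactor_locations
  keywords <- sort(unique(unlist(c(catalog$locations, catalog$interactor_locations))))
  carries <- function(ids, kw) {
    mean(vapply(ann[ids], function(v) kw %in% v, logical(1)))
  }
  frac_pos <- vapply(keywords, function(kw) carries(labels$positives, kw), numeric(1))
  frac_neg <- vapply(keywords, function(kw) carries(labels$negatives, kw), numeric(1))
  out <- data.frame(
    keyword = keywords, frac_pos = frac_pos, frac_neg = frac_neg,
    score = frac_pos - frac_neg, stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "flavour") <- flavour
  class(out) <- c("loc_score_table", class(out))
  out
}

.keyword_sum <- function(keywords, table) {
  if (length(keywords) == 0) return(0)
  s <- table$score[match(keywords, table$keyword)]
  sum(s, na.rm = TRUE)
}

#' Confidence weights
#'
#' Nonnegative weights applied to the location and interactor-location
#' keyword score sums.  The trained defaults are 12 and 1.
#'
#' @param w_loc,w_intloc Nonnegative numbers.
#' @return Object of class `confidence_weights`.
#' @export
confidence_weights <- function(w_loc = 12, w_intloc = 1) {
  stopifnot(w_loc >= 0, w_intloc >= 0)
  structure(list(w_loc = w_loc, w_intloc = w_intloc), class = "confidence_weights")
}

#' Confidence scores for all catalog proteins
#'
#' The raw score of protein p is
#' `N_proteome(p) * (w_loc * sum LocScore + w_intloc * sum IntLocScore)`,
#' summed over p's own location annotations and over the annotations of its
#' interactors (each interactor contributing its keyword set once).  Raw
#' scores are min-max normalised over the scored roster to `[0, 1]`.
#'
#' @param catalog An [annotation_catalog()].
#' @param loc_table,intloc_table Score tables from [build_score_table()]
#'   with flavours `"location"` and `"interactor"`.
#' @param weights A [confidence_weights()].
#' @return Data frame with columns `protein_id`, `value` (normalised score),
#'   `raw`, `n_proteome`, `loc_sum`, `intloc_sum`, ordered as the catalog.
#' @export
confidence_scores <- function(catalog, loc_table, intloc_table,
                              weights = confidence_weights()) {
  ids <- catalog_ids(catalog)
  loc_sum <- vapply(catalog$locations, .keyword_sum, numeric(1), table = loc_table)
  intloc_sum <- vapply(catalog$interactor_locations, .keyword_sum, numeric(1),
                       table = intloc_table)
  np <- n_proteome(catalog)
  raw <- np * (weights$w_loc * loc_sum + weights$w_intloc * intloc_sum)
  rng <- range(raw)
  value <- if (diff(rng) == 0) rep(0, length(raw)) else (raw - rng[1]) / diff(rng)
  data.frame(
    protein_id = ids, value = unname(value), raw = unname(raw),
    n_proteome = unname(np), loc_sum = unname(loc_sum),
    intloc_sum = unname(intloc_sum), stringsAsFactors = FALSE
  )
}

#' Confidence score of a single protein
#'
#' @inheritParams confidence_scores
#' @param protein_id A protein id present in the catalog.
#' @return One-row data frame as in [confidence_scores()].
#' @export
confidence <- function(protein_id, catalog, loc_table, intloc_table,
                       weights = confidence_weights()) {
  if (!protein_id %in% catalog_ids(catalog)) {
    stop("protein '", protein_id, "' absent from catalog")
  }
  sc <- confidence_scores(catalog, loc_table, intloc_table, weights)
  sc[sc$protein_id == protein_id, , drop = FALSE]
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param values Numeric scores.
#' @param labels Logical (or 0/1) vector, `TRUE` for positives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(values, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sweep confidence weights for the best ROC value
#'
#' Rescores the catalog at every grid point and returns the weights
#' maximising the ROC AUC of the confidence values against the labels.
#' Ties are broken towards the smallest `w_loc`, then smallest `w_intloc`.
#'
#' @param catalog An [annotation_catalog()].
#' @param labels A [labelled_set()].
#' @param grid Data frame (or matrix) with columns `w_loc`, `w_intloc`.
#' @return A [confidence_weights()] with attributes `auc` (best AUC) and
#'   `sweep` (per-point AUC table).
#' @export
sweep_weights <- function(catalog, labels, grid) {
  grid <- as.data.frame(grid)
  stopifnot(nrow(grid) >= 1, all(c("w_loc", "w_intloc") %in% names(grid)))
  loc_tab <- build_score_table(catalog, labels, "location")
  int_tab <- build_score_table(catalog, labels, "interactor")
  lab <- catalog_ids(catalog) %in% labels$positives
  aucs <- vapply(seq_len(nrow(grid)), function(i) {
    w <- confidence_weights(grid$w_loc[i], grid$w_intloc[i])
    sc <- confidence_scores(catalog, loc_tab, int_tab, w)
    roc_auc(sc$value, lab)
  }, numeric(1))
  ord <- order(-aucs, grid$w_loc, grid$w_intloc)
  best <- ord[1]
  out <- confidence_weights(grid$w_loc[best], grid$w_intloc[best])
  attr(out, "auc") <- aucs[best]
  attr(out, "sweep") <- cbind(grid, auc = aucs)
  out
}

#' Rank proteins and flag candidates for manual review
#'
#' Sorts by confidence value (descending; ties broken by protein id) and
#' flags every protein whose value exceeds `threshold` or that is present
#' in at least `min_proteomes` proteomes.
#'
#' @param scores Data frame from [confidence_scores()].
#' @param threshold Confidence cutoff; the comparison is strict (default
#'   0.333).
#' @param min_proteomes Minimum proteome count for flagging (default 2).
#' @return `scores` reordered, with an added logical column `flagged`.
#' @export
rank_and_flag <- function(scores, threshold = 0.333, min_proteomes = 2) {
  stopifnot(all(c("protein_id", "value", "n_proteome") %in% names(scores)))
  out <- scores[order(-scores$value, scores$protein_id), , drop = FALSE]
  out$flagged <- out$value > threshold | out$n_proteome >= min_proteomes
  rownames(out) <- NULL
  out
}

#' Write a ranked score table as TSV
#'
#' @param ranked Data frame from [rank_and_flag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(ranked, path) {
  cols <- c("protein_id", "value", "n_proteome", "loc_sum", "intloc_sum", "flagged")
  utils::write.table(ranked[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
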