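# Annotation catalogs: per-protein localisation keywords, interactor
# localisation keywords and proteome memberships.  This is the evidence
# base for confidence scoring of ISG proteome candidates.

#' Construct an annotation catalog
#'
#' @param locations Named list: protein id -> character vector of location
#'   keywords (a set; duplicates are removed).
#' @param interactor_locations Named list: protein id -> character vector of
#'   location keywords contributed by the protein's interactors.  Each
#'   interactor contributes its keyword set once, so the same keyword may
#'   appear with multiplicity (a multiset); multiplicity is preserved.
#' @param proteomes Named list: protein id -> character vector of proteome
#'   identifiers the protein was observed in.  Every protein must belong to
#'   at least one proteome.
#' @param proteome_roster Character vector of valid proteome identifiers
#'   (default three studies, `"P1" "P2" "P3"`).
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(locations, interactor_locations, proteomes,
                               proteome_roster = c("P1", "P2", "P3")) {
  ids <- names(proteomes)
  if (is.null(ids) || anyDuplicated(ids)) stop("proteomes must be uniquely named by protein id")
  n_mem <- lengths(proteomes)
  if (any(n_mem < 1)) stop("every protein needs at least one proteome membership")
  bad <- setdiff(unique(unlist(proteomes)), proteome_roster)
  if (length(bad)) stop("unknown proteome id(s): ", paste(bad, collapse = ", "))
  fill <- function(x) {
    x <- x[intersect(names(x), ids)]
    miss <- setdiff(ids, names(x))
    x[miss] <- list(character(0))
    x[ids]
  }
  structure(
    list(
      locations = lapply(fill(locations), unique),
      interactor_locations = fill(interactor_locations),
      proteomes = lapply(proteomes, unique),
      proteome_roster = proteome_roster
    ),
    class = "annotation_catalog"
  )
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog:", length(x$proteomes), "proteins,",
      length(unique(unlist(x$locations))), "location keywords,",
      length(x$proteome_roster), "proteomes\n")
  invisible(x)
}

#' Protein ids in a catalog
#' @param catalog An `annotation_catalog`.
#' @return Character vector of protein ids.
#' @export
catalog_ids <- function(catalog) names(catalog$proteomes)

#' Number of proteomes containing each protein
#' @param catalog An `annotation_catalog`.
#' @return Named integer vector.
#' @export
n_proteome <- function(catalog) lengths(catalog$proteomes)

#' Construct a labelled training set
#'
#' Curated true positives and trial negatives used to train the keyword
#' score tables.  The two sides must be disjoint and jointly cover the
#' catalog roster.
#'
#' @param positives,negatives Character vectors of protein ids.
#' @param catalog An `annotation_catalog` the labels refer to.
#' @return An object of class `labelled_set`.
#' @export
labelled_set <- function(positives, negatives, catalog) {
  if (length(intersect(positives, negatives))) stop("positives and negatives overlap")
  roster <- catalog_ids(catalog)
  if (!setequal(union(positives, negatives), roster)) {
    stop("labels must partition the catalog roster")
  }
  structure(list(positives = positives, negatives = negatives), class = "labelled_set")
}

#' Read an annotation catalog from delimited text
#'
#' Expects a tab-separated file with columns `protein_id`, `locations`,
#' `interactor_locations`, `proteomes`; the last three are `;`-separated
#' keyword/identifier lists (empty string for none).
#'
#' @param path File path.
#' @param proteome_roster Valid proteome identifiers.
#' @return An `annotation_catalog`.
#' @export
read_catalog_tsv <- function(path, proteome_roster = c("P1", "P2", "P3")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_id", "locations", "interactor_locations", "proteomes")
  if (!all(need %in% names(df))) {
    stop("catalog file must have columns: ", paste(need, collapse = ", "))
  }
  split_field <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  annotation_catalog(
    locations = stats::setNames(split_field(df$locations), df$protein_id),
    interactor_locations = stats::setNames(split_field(df$interactor_locations), df$protein_id),
    proteomes = stats::setNames(split_field(df$proteomes), df$protein_id),
    proteome_roster = proteome_roster
  )
}

#' Write an annotation catalog to delimited text
#'
#' Inverse of [read_catalog_tsv()].
#'
#' @param catalog An `annotation_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  join <- function(x) vapply(x, paste, character(1), collapse = ";")
  df <- data.frame(
    protein_id = catalog_ids(catalog),
    locations = join(catalog$locations),
    interactor_locations = join(catalog$interactor_locations),
    proteomes = join(catalog$proteomes),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
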