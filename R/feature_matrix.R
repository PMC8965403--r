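#' @useDynLib lingstab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom ape read.tree
NULL

FEATURE_STATES <- c("present", "absent", "missing")

#' Closed category vocabularies for the feature catalogue
#'
#' The three annotation axes of the feature catalogue are validated against
#' closed sets: 14 functional categories, 5 language domains and 10 part of
#' speech values.
#'
#' @return Named list with character vectors `functional_category`, `domain`
#'   and `part_of_speech`.
#' @export
catalog_vocabularies <- function() {
  list(
    functional_category = c(
      "argument marking (core)", "argument marking (non-core)", "deixis",
      "derivation", "interrogation", "modification", "negation",
      "phonological distinctiveness", "possession", "quantification",
      "TAME+", "valency", "word order", "other"
    ),
    domain = c("phonological shape", "word", "nominal phrase", "clause",
               "other"),
    part_of_speech = c("adjective", "article", "demonstrative", "noun",
                       "noun/pronoun", "particle", "pronoun", "verb",
                       "other", "not assignable")
  )
}

#' Construct a binary feature matrix
#'
#' A `feature_matrix` holds a taxa-by-features grid over the three states
#' `present`, `absent` and `missing` (missing is explicit, never
#' blank-as-absent), together with a family label per taxon.
#'
#' @param values Character matrix with rownames = taxa, colnames = features,
#'   entries in `c("present", "absent", "missing")`.
#' @param families Named character vector mapping every taxon to its family.
#' @return Object of class `feature_matrix` with elements `values`, `taxa`,
#'   `features`, `families`.
#' @export
feature_matrix <- function(values, families) {
  if (!is.matrix(values) || !is.character(values))
    stop("'values' must be a character matrix")
  taxa <- rownames(values)
  features <- colnames(values)
  if (is.null(taxa) || is.null(features))
    stop("'values' must have row (taxon) and column (feature) names")
  if (anyDuplicated(taxa))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyDuplicated(features))
    stop("duplicate feature identifiers: ",
         paste(unique(features[duplicated(features)]), collapse = ", "))
  bad <- which(matrix(!(values %in% FEATURE_STATES), nrow(values)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid value '%s' at taxon '%s', feature '%s'",
                 values[bad[1, 1], bad[1, 2]],
                 taxa[bad[1, 1]], features[bad[1, 2]]))
  if (is.null(names(families)) || !all(taxa %in% names(families)))
    stop("'families' must be a named vector covering every taxon")
  families <- families[taxa]
  if (anyNA(families)) stop("missing family label")
  structure(list(values = values, taxa = taxa, features = features,
                 families = families),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d taxa x %d features, %d families\n",
              length(x$taxa), length(x$features),
              length(unique(x$families))))
  tab <- table(factor(x$values, levels = FEATURE_STATES))
  cat(sprintf("  cells: %d present, %d absent, %d missing\n",
              tab[["present"]], tab[["absent"]], tab[["missing"]]))
  invisible(x)
}

#' Read a binary feature matrix from delimited text
#'
#' The file has taxa in rows and features in columns, with mandatory columns
#' `taxon` and `family`. Cell tokens map 1 -> present, 0 -> absent,
#' ? -> missing by default; the mapping is configurable so that dialects
#' (e.g. `NA` for missing) can be read.
#'
#' @param path File path.
#' @param sep Field delimiter (default `,`).
#' @param tokens Named character vector giving the input token for each of
#'   `present`, `absent`, `missing`. Several tokens per state are allowed by
#'   repeating names.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, sep = ",",
                                tokens = c(present = "1", absent = "0",
                                           missing = "?")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "\"")
  if (!all(c("taxon", "family") %in% names(df)))
    stop("matrix file must have 'taxon' and 'family' columns")
  feat_cols <- names(df)[!names(df) %in% c("taxon", "family")]
  if (length(feat_cols) == 0) stop("no feature columns found")
  if (anyDuplicated(feat_cols))
    stop("duplicate feature identifiers: ",
         paste(unique(feat_cols[duplicated(feat_cols)]), collapse = ", "))
  vals <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(vals) <- df$taxon
  map <- stats::setNames(names(tokens), tokens)
  unknown <- which(matrix(!(vals %in% names(map)), nrow(vals)),
                   arr.ind = TRUE)
  if (nrow(unknown) > 0)
    stop(sprintf("unknown token '%s' at taxon '%s', feature '%s'",
                 vals[unknown[1, 1], unknown[1, 2]],
                 df$taxon[unknown[1, 1]], feat_cols[unknown[1, 2]]))
  mapped <- matrix(map[vals], nrow = nrow(vals),
                   dimnames = dimnames(vals))
  feature_matrix(mapped, stats::setNames(df$family, df$taxon))
}

#' Write a feature matrix as delimited text
#'
#' Inverse of [read_feature_matrix()]; `read_feature_matrix(write...)` is the
#' identity.
#'
#' @inheritParams read_feature_matrix
#' @param x A `feature_matrix`.
#' @export
write_feature_matrix <- function(x, path, sep = ",",
                                 tokens = c(present = "1", absent = "0",
                                            missing = "?")) {
  stopifnot(inherits(x, "feature_matrix"))
  inv <- tokens[FEATURE_STATES]
  out <- matrix(inv[x$values], nrow = nrow(x$values),
                dimnames = dimnames(x$values))
  df <- data.frame(taxon = x$taxa, family = unname(x$families),
                   out, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop features never coded present
#'
#' Features whose every cell is `absent` or `missing` carry no information
#' for a presence/absence analysis and are excluded; features with only
#' `present` and `missing` cells are retained.
#'
#' @param x A `feature_matrix`.
#' @return List with `matrix` (the filtered `feature_matrix`, feature order
#'   preserved) and `removed` (character vector of dropped feature ids).
#' @export
drop_never_present <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  has_present <- apply(x$values == "present", 2, any)
  removed <- x$features[!has_present]
  kept <- x$values[, has_present, drop = FALSE]
  list(matrix = feature_matrix(kept, x$families), removed = removed)
}

#' Coverage (non-missing) counts per feature and per taxon
#'
#' @param x A `feature_matrix`.
#' @param majority_fraction Fraction of taxa defining the "codable for a
#'   majority" threshold (default 0.5).
#' @return List with `per_feature` (named integer vector of taxa with
#'   non-missing values per feature), `per_taxon` (non-missing features per
#'   taxon), `n_features_majority` (features non-missing in more than
#'   `majority_fraction` of taxa) and `prop_features_majority`.
#' @export
coverage_stats <- function(x, majority_fraction = 0.5) {
  stopifnot(inherits(x, "feature_matrix"))
  nonmiss <- x$values != "missing"
  per_feature <- colSums(nonmiss)
  per_taxon <- rowSums(nonmiss)
  n_maj <- sum(per_feature > majority_fraction * length(x$taxa))
  list(per_feature = per_feature, per_taxon = per_taxon,
       n_features_majority = n_maj,
       prop_features_majority = n_maj / length(x$features))
}

#' Read and validate the feature catalogue
#'
#' Delimited text with columns `feature`, `functional_category`, `domain`,
#' `part_of_speech`; values are validated against the closed vocabularies of
#' [catalog_vocabularies()].
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @param features Optional character vector of feature ids that must each
#'   have exactly one catalogue row (typically the matrix's features).
#' @return `data.frame` with the four columns, one row per feature.
#' @export
read_feature_catalog <- function(path, sep = ",", features = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"")
  need <- c("feature", "functional_category", "domain", "part_of_speech")
  if (!all(need %in% names(df)))
    stop("catalogue must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$feature))
    stop("duplicate catalogue entries for: ",
         paste(unique(df$feature[duplicated(df$feature)]), collapse = ", "))
  vocab <- catalog_vocabularies()
  for (axis in names(vocab)) {
    bad <- setdiff(unique(df[[axis]]), vocab[[axis]])
    if (length(bad) > 0)
      stop(sprintf("invalid %s value(s): %s", axis,
                   paste(bad, collapse = ", ")))
  }
  if (!is.null(features)) {
    miss <- setdiff(features, df$feature)
    if (length(miss) > 0)
      stop("features without catalogue entry: ",
           paste(miss, collapse = ", "))
    df <- df[match(features, df$feature), ]
    rownames(df) <- NULL
  }
  df
}

#' Numeric view of a feature's tip values
#'
#' @param x A `feature_matrix`.
#' @param feature Feature id.
#' @return Named numeric vector over taxa: 1 = present, 0 = absent,
#'   NA = missing.
#' @export
feature_values <- function(x, feature) {
  stopifnot(inherits(x, "feature_matrix"))
  if (!feature %in% x$features) stop("unknown feature: ", feature)
  v <- x$values[, feature]
  out <- ifelse(v == "present", 1, ifelse(v == "absent", 0, NA_real_))
  stats::setNames(out, x$taxa)
}
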