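# Sample identity reconciliation: alias resolution via the crosswalk,
# intersection of omics and clinical sample sets, clinical feature filtering
# and label extraction.

#' Rewrite a table's sample IDs to stable individual IDs
#'
#' Each sample ID in `table` is looked up in `alias_column` of the crosswalk
#' and replaced by the corresponding `individual_id` (e.g. the methylation
#' alias PT-M5AF resolves to individual R1822146). Samples whose alias is
#' absent from the map are dropped with a message.
#'
#' @param table An [omics_table].
#' @param id_map A `sample_id_map` from [read_sample_id_map()].
#' @param alias_column Which alias namespace the table's sample IDs live in.
#'   `"individual_id"` acts as the identity map.
#' @return The table with `sample_ids` rewritten, possibly fewer samples.
#' @export
resolve_aliases <- function(table, id_map, alias_column) {
  stopifnot(inherits(table, "omics_table"))
  if (!alias_column %in% colnames(id_map)) {
    stop("alias column '", alias_column, "' not in sample map")
  }
  lut <- id_map$individual_id
  names(lut) <- id_map[[alias_column]]
  lut <- lut[!is.na(names(lut))]
  hit <- table$sample_ids %in% names(lut)
  if (!any(hit)) stop("no sample of the table maps through '", alias_column, "'")
  if (any(!hit)) {
    message(sum(!hit), " sample(s) without a crosswalk entry dropped: ",
            paste(utils::head(table$sample_ids[!hit], 5L), collapse = ", "))
  }
  new_ids <- unname(lut[table$sample_ids[hit]])
  if (anyDuplicated(new_ids)) {
    stop("ambiguous aliases: multiple table samples resolve to individual(s) ",
         paste(unique(new_ids[duplicated(new_ids)]), collapse = ", "))
  }
  omics_table(table$values[, hit, drop = FALSE], table$kind,
              table$row_namespace, row_ids = table$row_ids,
              sample_ids = new_ids)
}

#' Restrict all tables to the common sample set
#'
#' Intersects the sample sets of every omics table and the clinical table,
#' orders the intersection lexicographically, and reindexes every table to
#' that ordered set. M is the intersection size.
#'
#' @param tables Named list of [omics_table]s sharing the individual-ID
#'   namespace.
#' @param clinical A `clinical_table`, or NULL to intersect omics only.
#' @return List with `tables` (reindexed), `clinical` (reindexed or NULL),
#'   `samples` (ordered common IDs) and `M`.
#' @export
align_samples <- function(tables, clinical = NULL) {
  stopifnot(length(tables) >= 1L)
  common <- Reduce(intersect, lapply(tables, function(t) t$sample_ids))
  if (!is.null(clinical)) common <- intersect(common, clinical$sample_id)
  if (!length(common)) stop("empty sample intersection across tables")
  common <- sort_c(common)
  tables <- lapply(tables, function(t) {
    idx <- match(common, t$sample_ids)
    omics_table(t$values[, idx, drop = FALSE], t$kind, t$row_namespace,
                row_ids = t$row_ids, sample_ids = common)
  })
  if (!is.null(clinical)) {
    clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
    rownames(clinical) <- NULL
    class(clinical) <- c("clinical_table", "data.frame")
  }
  list(tables = tables, clinical = clinical, samples = common,
       M = length(common))
}

#' Drop clinical features with too many missing values
#'
#' A feature is dropped when its missing fraction strictly exceeds
#' `max_missing_fraction` (default 0.30, i.e. the ">30% missing" rule).
#'
#' @param clinical A `clinical_table`.
#' @param max_missing_fraction Proportion in \[0, 1\].
#' @return The clinical table with offending feature columns removed.
#' @export
filter_clinical_features <- function(clinical, max_missing_fraction = 0.30) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  feats <- setdiff(colnames(clinical), "sample_id")
  frac <- vapply(feats, function(f) mean(is.na(clinical[[f]])), 0)
  drop <- feats[frac > max_missing_fraction]
  if (length(drop) == length(feats) && length(feats)) {
    warning("all clinical features dropped by missingness filter")
  }
  out <- clinical[, c("sample_id", setdiff(feats, drop)), drop = FALSE]
  class(out) <- c("clinical_table", "data.frame")
  attr(out, "dropped_features") <- drop
  out
}

#' Extract class labels from a clinical column
#'
#' Maps observed values of `label_column` to 0-based class indices in the
#' order given by `class_map`. Samples with a missing label are excluded and
#' reported; an observed value outside `class_map` is an error.
#'
#' @param clinical A `clinical_table`.
#' @param label_column Name of the clinical column used as the label.
#' @param class_map Character vector of category values; index = position - 1.
#' @return A `label_vector` data frame (`sample_id`, `label`) with attributes
#'   `class_map` and `label_name`; C = `length(class_map)`.
#' @export
extract_labels <- function(clinical, label_column, class_map) {
  if (!label_column %in% colnames(clinical)) {
    stop("label column '", label_column, "' not in clinical table")
  }
  raw <- clinical[[label_column]]
  obs <- !is.na(raw)
  unseen <- setdiff(unique(raw[obs]), as.character(class_map))
  if (length(unseen)) {
    stop("label values outside class_map: ", paste(unseen, collapse = ", "))
  }
  if (any(!obs)) {
    message(sum(!obs), " sample(s) with missing '", label_column,
            "' label excluded")
  }
  out <- data.frame(sample_id = clinical$sample_id[obs],
                    label = match(raw[obs], as.character(class_map)) - 1L,
                    stringsAsFactors = FALSE)
  attr(out, "class_map") <- as.character(class_map)
  attr(out, "label_name") <- label_column
  class(out) <- c("label_vector", "data.frame")
  out
}
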