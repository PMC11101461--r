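#' Construct an omics layer
#'
#' An `omics_matrix` couples one layer's feature-by-patient value matrix with
#' per-feature metadata (chromosome, mapped gene symbols, multimap flag). It is
#' the unit the preprocessing filters and the SNF affinity step consume.
#'
#' @param values numeric matrix, features in rows, patients in columns; both
#'   dimensions must be named with unique IDs. Methylation beta values live in
#'   \[0, 1\] (NA allowed before filtering); expression layers are nonnegative.
#' @param layer one of `"methylation"`, `"mrna"`, `"mirna"`.
#' @param feature_meta tibble with columns `feature_id`, `chromosome`,
#'   `gene_symbol` (`;`-separated symbols, may be empty) and `multimap`
#'   (logical). Defaults to autosomal, unannotated, single-mapping features.
#'
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, layer = c("methylation", "mrna", "mirna"),
                         feature_meta = NULL) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x patients)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have feature rownames and patient colnames")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate feature IDs")
  if (anyDuplicated(colnames(values))) abort("duplicate patient IDs")
  if (is.null(feature_meta)) {
    feature_meta <- tibble(
      feature_id = rownames(values),
      chromosome = "chr1",
      gene_symbol = "",
      multimap = FALSE
    )
  }
  feature_meta <- as_tibble(feature_meta)
  need <- c("feature_id", "chromosome", "gene_symbol", "multimap")
  if (!all(need %in% names(feature_meta))) {
    abort(paste("feature_meta must contain:", paste(need, collapse = ", ")))
  }
  if (!setequal(feature_meta$feature_id, rownames(values)) ||
      nrow(feature_meta) != nrow(values)) {
    abort("feature_meta rows must match matrix features one-to-one")
  }
  feature_meta <- feature_meta[match(rownames(values), feature_meta$feature_id), ]
  structure(
    list(layer = layer, values = values, feature_meta = feature_meta),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> layer=%s: %d features x %d patients (%d NA values)\n",
    x$layer, nrow(x$values), ncol(x$values), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

patient_ids <- function(x) colnames(x$values)
feature_ids <- function(x) rownames(x$values)
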