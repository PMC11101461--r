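#' Methylation sample quality control by mean detection p-value
#'
#' A sample passes if its mean detection p-value is strictly below the cutoff
#' (default 0.005, the array QC rule for whole-sample screening).
#'
#' @param x methylation [omics_matrix()] (used for patient IDs / layer check).
#' @param detection_p named numeric vector of per-sample mean detection
#'   p-values, one per patient column.
#' @param cutoff strict upper threshold.
#' @return tibble with `patient_id`, `mean_detection_p`, `pass`.
#' @export
qc_detection <- function(x, detection_p, cutoff = 0.005) {
  if (x$layer != "methylation") abort("detection QC applies to the methylation layer")
  if (length(detection_p) != ncol(x$values)) {
    abort("one detection p-value per sample required")
  }
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
    abort("detection p-values must lie in [0, 1]")
  }
  tibble(
    patient_id = patient_ids(x),
    mean_detection_p = unname(detection_p),
    pass = unname(detection_p < cutoff)
  )
}

#' Feature-level quality filters with accounting
#'
#' Removes, in a fixed order: (1) features with any NA value; (2) multimapped
#' reporters; (3) features on chromosome X or Y (methylation and mRNA layers
#' only — miRNA annotations are left alone); (4) features that are zero across
#' all samples (all layers). The report tallies each step so
#' `before - sum(removed) = after` reconciles exactly.
#'
#' @param x an [omics_matrix()].
#' @return list with `matrix` (filtered [omics_matrix()]) and `report`
#'   (a `filter_report` tibble: `step`, `removed`, `remaining`).
#' @export
filter_features <- function(x) {
  vals <- x$values
  meta <- x$feature_meta
  before <- nrow(vals)
  steps <- tibble(step = character(0), removed = integer(0), remaining = integer(0))
  drop_step <- function(name, bad) {
    steps <<- bind_rows(steps, tibble(
      step = name, removed = sum(bad), remaining = as.integer(nrow(vals) - sum(bad))
    ))
    vals <<- vals[!bad, , drop = FALSE]
    meta <<- meta[!bad, , drop = FALSE]
  }
  drop_step("na", rowSums(is.na(vals)) > 0)
  drop_step("multimap", meta$multimap)
  sex <- if (x$layer %in% c("methylation", "mrna")) {
    meta$chromosome %in% c("chrX", "chrY", "X", "Y")
  } else {
    rep(FALSE, nrow(vals))
  }
  drop_step("sex_chromosome", sex)
  drop_step("all_zero", rowSums(vals != 0) == 0)
  if (nrow(vals) == 0) abort("all features removed: over-filtering")
  report <- structure(
    bind_cols(tibble(layer = x$layer), steps,
              tibble(before = before, after = nrow(vals))),
    class = c("filter_report", class(steps))
  )
  list(matrix = omics_matrix(vals, x$layer, meta), report = report)
}

#' Convert FPKM to TPM
#'
#' Per patient column, `TPM = FPKM / colSum(FPKM) * 1e6`; every column of the
#' result sums to one million, making expression comparable across samples.
#'
#' @param x mRNA [omics_matrix()] with nonnegative values.
#' @return an [omics_matrix()] of TPM values.
#' @export
fpkm_to_tpm <- function(x) {
  if (any(x$values < 0, na.rm = TRUE)) abort("FPKM values must be nonnegative")
  cs <- colSums(x$values)
  if (any(cs <= 0)) abort("every patient column must have a positive sum")
  out <- sweep(x$values, 2, cs, "/") * 1e6
  omics_matrix(out, x$layer, x$feature_meta)
}

#' Min-max normalize each feature across patients
#'
#' Rescales every feature row to \[0, 1\] via `(x - min) / (max - min)`.
#' Constant rows map to all zeros (the documented degenerate convention,
#' preserving feature accounting instead of dropping them).
#'
#' @param x an [omics_matrix()] with no remaining NA values.
#' @return normalized [omics_matrix()].
#' @export
minmax_normalize <- function(x) {
  if (anyNA(x$values)) abort("NA values must be filtered before normalization")
  rmin <- apply(x$values, 1, min)
  rmax <- apply(x$values, 1, max)
  rng <- rmax - rmin
  out <- (x$values - rmin) / ifelse(rng == 0, 1, rng)
  out[rng == 0, ] <- 0
  omics_matrix(out, x$layer, x$feature_meta)
}

#' Full preprocessing of one layer
#'
#' Applies [filter_features()], then [fpkm_to_tpm()] for the mRNA layer, then
#' [minmax_normalize()].
#'
#' @param x an [omics_matrix()].
#' @return list with `matrix` and `report` (as in [filter_features()]).
#' @export
preprocess_layer <- function(x) {
  f <- filter_features(x)
  m <- f$matrix
  if (m$layer == "mrna") m <- fpkm_to_tpm(m)
  list(matrix = minmax_normalize(m), report = f$report)
}

#' Write a filter report as JSON
#'
#' @param report a `filter_report` (or a list of them, one per layer).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  if (inherits(report, "filter_report")) report <- list(report)
  jsonlite::write_json(lapply(report, as.data.frame), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
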