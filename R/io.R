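#' Write a cohort to delimited text files
#'
#' Layers are written as TSV with features in rows (first column `feature_id`)
#' and one column per patient; the annotation as
#' `reporter_id` / `gene_symbol` (`;`-separated) / `chromosome`; the clinical
#' table as `patient_id` / `os_time_days` / `os_event` / `inss_stage`; and the
#' interaction tables (if supplied) with their full annotation columns.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param tables optional [generate_interaction_tables()] result.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, tables = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$layers)) {
    write_omics_tsv(cohort$layers[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  readr::write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(
    cohort$clinical[c("patient_id", "os_time_days", "os_event", "inss_stage")],
    file.path(dir, "clinical.tsv")
  )
  if (!is.null(tables)) {
    readr::write_tsv(tables$tf_mirna, file.path(dir, "tf_mirna.tsv"))
    readr::write_tsv(tables$mirna_target, file.path(dir, "mirna_target.tsv"))
  }
  invisible(dir)
}

#' Write one omics layer as TSV
#'
#' @param x an [omics_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_omics_tsv <- function(x, path) {
  df <- bind_cols(tibble(feature_id = feature_ids(x)), as_tibble(x$values))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read one omics layer from TSV
#'
#' Expects features in rows, a `feature_id` first column and one column per
#' patient. Feature metadata is joined from an annotation table when given;
#' unannotated features default to autosomal single-mapping.
#'
#' @param path TSV file as written by [write_omics_tsv()].
#' @param layer layer label.
#' @param annotation optional annotation tibble
#'   (`reporter_id`, `gene_symbol`, `chromosome`).
#' @param multimap_ids optional character vector of multimapped reporter IDs.
#' @return an [omics_matrix()].
#' @export
read_omics_tsv <- function(path, layer, annotation = NULL, multimap_ids = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  vals <- as.matrix(df[-1])
  rownames(vals) <- df$feature_id
  meta <- NULL
  if (!is.null(annotation)) {
    idx <- match(df$feature_id, annotation$reporter_id)
    meta <- tibble(
      feature_id = df$feature_id,
      chromosome = ifelse(is.na(idx), "chr1", annotation$chromosome[idx]),
      gene_symbol = ifelse(is.na(idx), "", annotation$gene_symbol[idx]),
      multimap = df$feature_id %in% (multimap_ids %||% character(0))
    )
  }
  omics_matrix(vals, layer, meta)
}

#' Read interaction tables from TSV
#'
#' @param tf_mirna_path,mirna_target_path TSV files with columns
#'   `source`, `target`, `kind`, `sign`, `evidence`, `context`.
#' @return list with `tf_mirna` and `mirna_target` tibbles.
#' @export
read_interaction_tsv <- function(tf_mirna_path, mirna_target_path) {
  list(
    tf_mirna = readr::read_tsv(tf_mirna_path, show_col_types = FALSE, progress = FALSE),
    mirna_target = readr::read_tsv(mirna_target_path, show_col_types = FALSE, progress = FALSE)
  )
}
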