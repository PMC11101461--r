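#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run with defaults mirroring the
#' framework's choices: SNF at `t = 15, k = 20, alpha = 0.5`, cluster counts
#' 2..7 scored by the quality ratio, top-10% feature selection, 10 hubs, and
#' a 0.25-SD dichotomization band.
#'
#' @param spec a [cohort_spec()] describing the synthetic cohort to generate
#'   (or `NULL` when `cohort` is supplied to [run_pipeline()] directly).
#' @param params [snf_params()].
#' @param c_range candidate cluster counts.
#' @param top_fraction feature-selection fraction.
#' @param n_hubs hub count reported from the MCC ranking.
#' @param delta dichotomization width in SDs.
#' @param seed seed for clustering and ranking.
#' @param nstart_cluster,nstart_rank k-means restarts for the fused model
#'   selection and the per-feature rSNF runs.
#' @param diagnostics if `TRUE`, compute the fusion-iteration convergence
#'   curve (relative spectral-norm changes over a `t` sweep).
#' @param t_grid grid for the diagnostic sweep.
#' @param out_dir optional directory for artifacts (TSV tables, JSON summary,
#'   SIF/GraphML network, filter report).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(spec = cohort_spec(),
                            params = snf_params(),
                            c_range = 2:7,
                            top_fraction = 0.10,
                            n_hubs = 10,
                            delta = 0.25,
                            seed = 1L,
                            nstart_cluster = 50,
                            nstart_rank = 20,
                            diagnostics = FALSE,
                            t_grid = 2:30,
                            out_dir = NULL) {
  if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must be in (0, 1]")
  if (n_hubs < 1) abort("n_hubs must be positive")
  if (delta < 0) abort("delta must be nonnegative")
  structure(list(
    spec = spec, params = params, c_range = c_range,
    top_fraction = top_fraction, n_hubs = n_hubs, delta = delta,
    seed = as.integer(seed), nstart_cluster = nstart_cluster,
    nstart_rank = nstart_rank, diagnostics = diagnostics, t_grid = t_grid,
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the multi-omics biomarker-discovery pipeline end to end
#'
#' Preprocess each layer -> per-layer affinity -> SNF fusion -> cluster-count
#' selection by the quality ratio -> rSNF feature ranking per layer ->
#' top-fraction selection and gene mapping -> essential-gene intersection ->
#' regulatory-network construction and MCC hub ranking -> per-hub survival
#' (KM / log-rank), stage-association (chi-square) and stage-4-vs-other ROC
#' validation.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-built [generate_cohort()] cohort (otherwise
#'   generated from `config$spec`).
#' @param tables optionally, pre-built interaction tables (otherwise generated
#'   from the cohort).
#' @return a `pipeline_report` list: `filter_reports`, `fused`, `selection`,
#'   `rankings`, `top_sets`, `essential`, `network`, `hubs`, `validation`,
#'   `convergence` (when requested), `truth_recovery` and `summary` (a
#'   machine-readable list mirroring the JSON artifact).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL, tables = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)), parent = e)
    })
  }

  cohort <- cohort %||% stage("simulate", generate_cohort(config$spec))
  tables <- tables %||% stage("simulate", generate_interaction_tables(cohort, cohort$spec))

  pre <- stage("preprocess", lapply(cohort$layers, preprocess_layer))
  mats <- lapply(pre, `[[`, "matrix")
  reports <- lapply(pre, `[[`, "report")

  aff <- stage("fuse", lapply(mats, affinity_matrix, params = config$params))
  fused <- stage("fuse", snf_fuse(aff, config$params))

  conv <- NULL
  if (isTRUE(config$diagnostics)) {
    conv <- stage("fuse", convergence_curve(aff, config$t_grid, "t", config$params))
  }

  sel <- stage("cluster", select_n_clusters(
    fused, config$c_range, seed = config$seed, nstart = config$nstart_cluster
  ))

  rankings <- stage("rank", lapply(mats, function(m) {
    rank_features(m, sel$labels, sel$c_star, config$params,
                  seed = config$seed, nstart = config$nstart_rank)
  }))
  top_sets <- lapply(rankings, select_top_fraction, fraction = config$top_fraction)

  methyl_genes <- stage("rank", map_features_to_genes(top_sets$methylation, cohort$annotation))
  mrna_genes <- stage("rank", map_features_to_genes(top_sets$mrna, cohort$annotation))
  essential <- stage("rank", essential_genes(methyl_genes, mrna_genes))
  highrank_mirnas <- top_sets$mirna$feature_id

  recs <- stage("network", filter_interactions(
    interaction_records(tables), highrank_mirnas, essential
  ))
  net <- stage("network", build_network(recs))
  hubs <- if (nrow(net$nodes) > 0) {
    top_hubs(stage("network", mcc_scores(net)), config$n_hubs)
  } else {
    tibble(node = character(0), role = character(0), mcc = numeric(0),
           degree = numeric(0), rank = integer(0))
  }

  validation <- stage("validate", validate_hubs(
    hubs, mats, cohort$clinical, config$delta
  ))

  recovery <- truth_recovery(cohort, top_sets, tables, hubs)

  summary <- list(
    n_patients = length(cohort$true_subtype),
    c_star = sel$c_star,
    q_profile = as.data.frame(sel$profile),
    nmi_vs_truth = nmi(sel$labels, cohort$true_subtype),
    n_selected = vapply(top_sets, nrow, integer(1)),
    n_methyl_genes = length(methyl_genes),
    n_mrna_genes = length(mrna_genes),
    n_essential_genes = length(essential),
    network_nodes = nrow(net$nodes),
    network_edges = nrow(net$edges),
    hubs = as.data.frame(hubs),
    validation = as.data.frame(validation),
    truth_recovery = recovery
  )

  report <- structure(list(
    cohort = cohort, tables = tables, filter_reports = reports,
    preprocessed = mats, fused = fused, selection = sel,
    rankings = rankings, top_sets = top_sets,
    methyl_genes = methyl_genes, mrna_genes = mrna_genes,
    essential = essential, network = net, hubs = hubs,
    validation = validation, convergence = conv, summary = summary
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Per-hub validation against survival, stage, and a stage-4-vs-other ROC.
validate_hubs <- function(hubs, mats, clinical, delta) {
  expr_of <- function(node, role) {
    m <- if (role == "miRNA") mats$mirna else mats$mrna
    if (node %in% rownames(m$values)) m$values[node, ] else NULL
  }
  rows <- purrr::pmap(list(hubs$node, hubs$role), function(node, role) {
    v <- expr_of(node, role)
    if (is.null(v)) return(NULL)
    res <- validate_biomarker(v, clinical, delta = delta)
    case <- clinical$inss_stage == "4"
    auc <- if (any(case) && any(!case)) {
      roc_auc(unname(v[clinical$patient_id]), case)$auc
    } else {
      NA_real_
    }
    bind_cols(tibble(node = node, role = role), res, tibble(auc_stage4 = auc))
  })
  bind_rows(purrr::compact(rows))
}

# Bookkeeping against the generator's planted truth (synthetic cohorts only).
truth_recovery <- function(cohort, top_sets, tables, hubs) {
  rec <- function(layer) {
    planted <- cohort$truth[[layer]]
    if (length(planted) == 0) return(NA_real_)
    mean(planted %in% top_sets[[layer]]$feature_id)
  }
  list(
    informative_in_top = c(
      methylation = rec("methylation"),
      mrna = rec("mrna"),
      mirna = rec("mirna")
    ),
    hub_tf = tables$truth$hub_tf,
    hub_tf_rank = if (!is.na(tables$truth$hub_tf) && nrow(hubs) > 0 &&
                      tables$truth$hub_tf %in% hubs$node) {
      hubs$rank[hubs$node == tables$truth$hub_tf]
    } else {
      NA_integer_
    }
  )
}

#' Write pipeline artifacts to a directory
#'
#' Emits the feature rankings, hub table and validation table as TSV, the
#' network as SIF and GraphML, the filter report as JSON, and a
#' machine-readable `summary.json`.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$rankings)) {
    readr::write_tsv(report$rankings[[nm]], file.path(dir, paste0("ranking_", nm, ".tsv")))
  }
  readr::write_tsv(report$hubs, file.path(dir, "hubs.tsv"))
  readr::write_tsv(report$validation, file.path(dir, "validation.tsv"))
  if (nrow(report$network$edges) > 0) {
    write_sif(report$network, file.path(dir, "network.sif"))
    write_graphml(report$network, file.path(dir, "network.graphml"))
  }
  write_filter_report(report$filter_reports, file.path(dir, "filter_report.json"))
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    paste0("<pipeline_report>\n  c* = %d (NMI vs truth %.3f)\n",
           "  essential genes: %d; network: %d nodes / %d edges\n",
           "  top hub: %s (MCC %g)\n"),
    x$summary$c_star, x$summary$nmi_vs_truth, x$summary$n_essential_genes,
    x$summary$network_nodes, x$summary$network_edges,
    if (nrow(x$hubs) > 0) x$hubs$node[1] else "<none>",
    if (nrow(x$hubs) > 0) x$hubs$mcc[1] else NA
  ))
  invisible(x)
}
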