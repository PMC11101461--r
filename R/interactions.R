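#' Generate synthetic TF-miRNA and miRNA-target interaction tables
#'
#' Emulates extracts from curated interaction databases: TF->miRNA records
#' carry a regulation sign (`activation`, `repression`, or generic
#' `regulation`), an evidence class (`level2`, `literature`, `other`) and a
#' cell-line context (`tumor`, `normal`); miRNA->gene records carry the same
#' annotation columns. A designated hub TF and hub miRNA are planted with many
#' high-confidence tumor-context edges confined to the cohort's informative
#' features, so they survive the downstream filters and dominate the maximal
#' clique centrality ranking; background edges are spread over random nodes
#' with mixed annotations so every filter branch is exercised.
#'
#' @param cohort a [generate_cohort()] result.
#' @param spec the [cohort_spec()] used for the cohort (supplies the seed;
#'   interactions use `seed + 1`).
#' @param n_tf number of genes designated as transcription factors.
#' @param n_background_tf_mirna,n_background_mirna_target background edge
#'   counts.
#' @param planted_hubs if `FALSE`, no hub is planted and degrees are
#'   approximately exchangeable.
#' @param hub_tf_degree,hub_mirna_degree out-degrees of the planted hub TF and
#'   planted hub miRNA.
#'
#' @return list with tibbles `tf_mirna` (`source`, `target`, `kind`, `sign`,
#'   `evidence`, `context`) and `mirna_target` (same columns), plus `truth`
#'   (`hub_tf`, `hub_mirna`, `tf_pool`).
#' @export
generate_interaction_tables <- function(cohort, spec,
                                        n_tf = 15,
                                        n_background_tf_mirna = 120,
                                        n_background_mirna_target = 200,
                                        planted_hubs = TRUE,
                                        hub_tf_degree = 12,
                                        hub_mirna_degree = 15) {
  stopifnot(inherits(cohort, "multi_omics_cohort"))
  withr::with_seed(spec$seed + 1L, {
    inf_genes <- cohort$truth$shared_informative_genes %||%
      cohort$truth$informative_genes
    inf_mirs <- cohort$truth$mirna
    all_genes <- feature_ids(cohort$layers$mrna)
    all_mirs <- feature_ids(cohort$layers$mirna)

    # TFs: half drawn from informative genes (essential by construction),
    # half from the background
    n_tf_inf <- min(ceiling(n_tf / 2), length(inf_genes))
    tf_pool <- c(
      sample(inf_genes, n_tf_inf),
      sample(setdiff(all_genes, inf_genes), n_tf - n_tf_inf)
    )

    signs <- c("activation", "repression", "regulation")
    evid <- c("level2", "literature", "other")
    ctx <- c("tumor", "normal")

    rand_annot <- function(k) {
      tibble(
        sign = sample(signs, k, replace = TRUE),
        evidence = sample(evid, k, replace = TRUE, prob = c(0.4, 0.4, 0.2)),
        context = sample(ctx, k, replace = TRUE, prob = c(0.75, 0.25))
      )
    }

    tf_mirna <- bind_cols(
      tibble(
        source = sample(tf_pool, n_background_tf_mirna, replace = TRUE),
        target = sample(all_mirs, n_background_tf_mirna, replace = TRUE),
        kind = "tf_mirna"
      ),
      rand_annot(n_background_tf_mirna)
    )
    mirna_target <- bind_cols(
      tibble(
        source = sample(all_mirs, n_background_mirna_target, replace = TRUE),
        target = sample(all_genes, n_background_mirna_target, replace = TRUE),
        kind = "mirna_target"
      ),
      rand_annot(n_background_mirna_target)
    )

    hub_tf <- NA_character_
    hub_mirna <- NA_character_
    if (planted_hubs) {
      hub_tf <- tf_pool[1]  # informative gene -> lands in the essential set
      hub_targets <- sample(inf_mirs, min(hub_tf_degree, length(inf_mirs)))
      tf_mirna <- bind_rows(tf_mirna, tibble(
        source = hub_tf, target = hub_targets, kind = "tf_mirna",
        sign = sample(c("activation", "repression"), length(hub_targets), replace = TRUE),
        evidence = "level2", context = "tumor"
      ))
      hub_mirna <- sample(setdiff(inf_mirs, hub_targets[1]), 1)
      hub_genes <- sample(inf_genes, min(hub_mirna_degree, length(inf_genes)))
      mirna_target <- bind_rows(mirna_target, tibble(
        source = hub_mirna, target = hub_genes, kind = "mirna_target",
        sign = "repression", evidence = "literature", context = "tumor"
      ))
      # the hub miRNA is also regulated by the hub TF: ties the two hubs
      tf_mirna <- bind_rows(tf_mirna, tibble(
        source = hub_tf, target = hub_mirna, kind = "tf_mirna",
        sign = "activation", evidence = "level2", context = "tumor"
      ))
    }

    list(
      tf_mirna = distinct(tf_mirna, .data$source, .data$target, .keep_all = TRUE),
      mirna_target = distinct(mirna_target, .data$source, .data$target, .keep_all = TRUE),
      truth = list(hub_tf = hub_tf, hub_mirna = hub_mirna, tf_pool = tf_pool)
    )
  })
}

#' Bind the two interaction tables into one record set
#'
#' @param tables a [generate_interaction_tables()] result or a list with
#'   `tf_mirna` / `mirna_target` tibbles.
#' @return single tibble of interaction records.
#' @export
interaction_records <- function(tables) {
  bind_rows(tables$tf_mirna, tables$mirna_target)
}
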