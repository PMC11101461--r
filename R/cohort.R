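#' Specify a synthetic multi-omics cohort
#'
#' Defines the ground-truth structure of a simulated neuroblastoma-like cohort:
#' patient count, latent subtypes and their mixing proportions, per-layer
#' feature counts, the fraction of subtype-informative features, the mean shift
#' separating subtypes, the rates of defective features the preprocessing
#' filters must catch, and the clinical model linking subtype to survival and
#' INSS stage.
#'
#' Defaults mirror the cohort the pipeline is designed around: 99 patients in
#' four latent subtypes with layer sizes scaled to desk size (2000 methylation
#' reporters, 2000 genes, 500 miRNAs), 10% informative features per layer, a
#' 3-standard-deviation subtype shift, and defect rates dominated by the ~20%
#' NA rate typical of 450K methylation arrays.
#'
#' `informative_fraction` is taken relative to the layer's clean
#' (non-defective) features: planted signal features are always well measured,
#' so the planted count is commensurate with a post-filter top-fraction
#' selection of the same fraction.
#'
#' @param n_patients number of patients.
#' @param n_subtypes number of latent disease subtypes.
#' @param subtype_proportions probability vector over subtypes (sums to 1).
#' @param n_features named vector of feature counts for `methylation`, `mrna`,
#'   `mirna`.
#' @param informative_fraction fraction (per layer, recycled) of clean features
#'   carrying subtype signal.
#' @param effect_size mean shift between subtypes in units of `noise_sd`, on
#'   the latent (pre-link) scale.
#' @param noise_sd within-subtype latent standard deviation.
#' @param frac_na fraction of methylation features given NA entries.
#' @param frac_multimapped fraction of methylation reporters flagged as
#'   mapping to multiple sites.
#' @param frac_sex_chrom fraction of methylation and mRNA features annotated to
#'   chromosome X or Y.
#' @param frac_all_zero fraction of features (all layers) that are zero across
#'   every sample.
#' @param subtype_hazard_ratios positive hazard multipliers, one per subtype;
#'   default spaces them geometrically from 1 to 4.
#' @param censoring_rate target fraction of censored patients under uniform
#'   administrative censoring.
#' @param stage_distribution_per_subtype matrix (subtype x INSS stage) of
#'   probabilities, rows summing to 1; default skews high-hazard subtypes
#'   toward stage 4.
#' @param seed integer seed; the whole cohort is reproducible from it.
#'
#' @return a validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 99,
                        n_subtypes = 4,
                        subtype_proportions = rep(1 / n_subtypes, n_subtypes),
                        n_features = c(methylation = 2000, mrna = 2000, mirna = 500),
                        informative_fraction = 0.10,
                        effect_size = 3,
                        noise_sd = 1,
                        frac_na = 0.20,
                        frac_multimapped = 0.05,
                        frac_sex_chrom = 0.03,
                        frac_all_zero = 0.02,
                        subtype_hazard_ratios = exp(seq(0, log(4), length.out = n_subtypes)),
                        censoring_rate = 0.40,
                        stage_distribution_per_subtype = default_stage_distribution(n_subtypes),
                        seed = 1L) {
  if (n_patients < 1 || n_subtypes < 1) abort("counts must be positive")
  if (n_subtypes > n_patients) abort("n_subtypes cannot exceed n_patients")
  check_prob_vector(subtype_proportions, "subtype_proportions")
  if (length(subtype_proportions) != n_subtypes) {
    abort("subtype_proportions must have one entry per subtype")
  }
  layers <- c("methylation", "mrna", "mirna")
  if (!all(layers %in% names(n_features)) || any(n_features[layers] < 1)) {
    abort("n_features must name positive methylation/mrna/mirna counts")
  }
  informative_fraction <- rep_len(informative_fraction, 3)
  names(informative_fraction) <- layers
  for (f in informative_fraction) check_fraction(f, "informative_fraction")
  check_fraction(frac_na, "frac_na")
  check_fraction(frac_multimapped, "frac_multimapped")
  check_fraction(frac_sex_chrom, "frac_sex_chrom")
  check_fraction(frac_all_zero, "frac_all_zero")
  if (frac_na + frac_multimapped + frac_sex_chrom + frac_all_zero >= 1) {
    abort("defect fractions must sum to less than 1")
  }
  check_fraction(censoring_rate, "censoring_rate")
  if (any(subtype_hazard_ratios <= 0) ||
      length(subtype_hazard_ratios) != n_subtypes) {
    abort("subtype_hazard_ratios must be positive, one per subtype")
  }
  sdist <- as.matrix(stage_distribution_per_subtype)
  if (nrow(sdist) != n_subtypes) {
    abort("stage_distribution_per_subtype needs one row per subtype")
  }
  for (i in seq_len(nrow(sdist))) check_prob_vector(sdist[i, ], "stage distribution row")
  if (is.null(colnames(sdist))) colnames(sdist) <- c("1", "2", "3", "4", "4S")[seq_len(ncol(sdist))]
  if (effect_size < 0 || noise_sd <= 0) abort("effect_size >= 0 and noise_sd > 0 required")

  structure(list(
    n_patients = as.integer(n_patients),
    n_subtypes = as.integer(n_subtypes),
    subtype_proportions = subtype_proportions,
    n_features = n_features[layers],
    informative_fraction = informative_fraction,
    effect_size = effect_size,
    noise_sd = noise_sd,
    frac_na = frac_na,
    frac_multimapped = frac_multimapped,
    frac_sex_chrom = frac_sex_chrom,
    frac_all_zero = frac_all_zero,
    subtype_hazard_ratios = subtype_hazard_ratios,
    censoring_rate = censoring_rate,
    stage_distribution = sdist,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default per-subtype INSS stage distribution
#'
#' Probabilities over stages 1, 2, 3, 4, 4S; subtypes later in hazard order are
#' weighted toward stage 4, mimicking the stage/risk gradient of real cohorts.
#'
#' @param n_subtypes number of subtypes (rows).
#' @return matrix with one row per subtype summing to 1.
#' @export
default_stage_distribution <- function(n_subtypes) {
  w <- if (n_subtypes == 1) 0.5 else seq(0, 1, length.out = n_subtypes)
  t(vapply(w, function(x) {
    p <- c(
      `1` = 0.35 * (1 - x) + 0.05 * x,
      `2` = 0.25 * (1 - x) + 0.10 * x,
      `3` = 0.20 * (1 - x) + 0.15 * x,
      `4` = 0.10 * (1 - x) + 0.65 * x,
      `4S` = 0.10 * (1 - x) + 0.05 * x
    )
    p / sum(p)
  }, numeric(5)))
}

# Deterministic subtype assignment: integer counts from the proportions
# (largest-remainder rounding), then a shuffle.
assign_subtypes <- function(n, proportions) {
  k <- length(proportions)
  counts <- floor(n * proportions)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * proportions - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  if (any(counts == 0)) counts[counts == 0] <- 1L  # every subtype represented
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  sample(rep(seq_len(k), counts))
}

# One layer's latent signal matrix: feature baselines + noise, with each
# informative feature shifted by effect_size * noise_sd in one random subtype.
latent_layer <- function(m, n, subtype, informative_idx, effect_size, noise_sd) {
  mu <- rnorm(m)
  x <- matrix(rnorm(m * n, sd = noise_sd), m, n) + mu
  if (length(informative_idx) > 0 && effect_size > 0) {
    k <- max(subtype)
    up_in <- sample(seq_len(k), length(informative_idx), replace = TRUE)
    for (i in seq_along(informative_idx)) {
      cols <- subtype == up_in[i]
      x[informative_idx[i], cols] <- x[informative_idx[i], cols] +
        effect_size * noise_sd
    }
  }
  x
}

# Pick disjoint defect index sets for a layer.
pick_defects <- function(m, fracs) {
  counts <- vapply(fracs, function(f) as.integer(round(f * m)), integer(1))
  pool <- sample.int(m)
  out <- list()
  off <- 0L
  for (nm in names(counts)) {
    out[[nm]] <- sort(pool[seq_len(counts[[nm]]) + off])
    if (counts[[nm]] == 0L) out[[nm]] <- integer(0)
    off <- off + counts[[nm]]
  }
  out
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws three feature-by-patient layers (methylation beta values via a
#' sigmoid-transformed Gaussian, mRNA FPKM-like and miRNA expression values as
#' log-normals), plants subtype-informative features, injects defective
#' features (NA, multimapped, sex-chromosome, all-zero) at the specified rates,
#' and draws per-patient survival (exponential baseline with subtype hazard
#' ratios, uniform administrative censoring) and INSS stage.
#'
#' Informative methylation reporters are annotated to the same gene symbols as
#' informative mRNA features, so an essential-gene intersection exists by
#' construction; the mapping is recorded in `truth`.
#'
#' @param spec a [cohort_spec()].
#' @return a `multi_omics_cohort`: list with `layers` (three [omics_matrix()]
#'   objects sharing patient order), `true_subtype`, `clinical` tibble
#'   (`patient_id`, `os_time_days`, `os_event`, `inss_stage`), `annotation`
#'   tibble (`reporter_id`, `gene_symbol`, `chromosome`), and `truth` (planted
#'   informative feature IDs per layer plus the shared informative genes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  pid <- sprintf("PT%03d", seq_len(n))
  subtype <- assign_subtypes(n, spec$subtype_proportions)
  names(subtype) <- pid

  gene_ids <- sprintf("GENE%04d", seq_len(spec$n_features[["mrna"]]))
  mir_ids <- sprintf("hsa-mir-%04d", seq_len(spec$n_features[["mirna"]]))
  cpg_ids <- sprintf("cg%07d", seq_len(spec$n_features[["methylation"]]))

  # --- mRNA layer (defects: sex chromosome, all-zero) -----------------------
  m_rna <- spec$n_features[["mrna"]]
  rna_def <- pick_defects(m_rna, c(sex = spec$frac_sex_chrom, zero = spec$frac_all_zero))
  rna_clean <- setdiff(seq_len(m_rna), unlist(rna_def))
  n_inf_rna <- round(spec$informative_fraction[["mrna"]] * length(rna_clean))
  rna_inf <- sort(sample(rna_clean, n_inf_rna))
  rna_lat <- latent_layer(m_rna, n, subtype, rna_inf, spec$effect_size, spec$noise_sd)
  rna_val <- exp(rna_lat)  # FPKM-like log-normal
  rna_val[rna_def$zero, ] <- 0
  dimnames(rna_val) <- list(gene_ids, pid)
  rna_chr <- sample(paste0("chr", 1:22), m_rna, replace = TRUE)
  rna_chr[rna_def$sex] <- sample(c("chrX", "chrY"), length(rna_def$sex), replace = TRUE)
  rna_meta <- tibble(
    feature_id = gene_ids, chromosome = rna_chr,
    gene_symbol = gene_ids, multimap = FALSE
  )

  # --- methylation layer (defects: NA, multimap, sex, all-zero) -------------
  m_me <- spec$n_features[["methylation"]]
  me_def <- pick_defects(m_me, c(
    na = spec$frac_na, multimap = spec$frac_multimapped,
    sex = spec$frac_sex_chrom, zero = spec$frac_all_zero
  ))
  me_clean <- setdiff(seq_len(m_me), unlist(me_def))
  n_inf_me <- round(spec$informative_fraction[["methylation"]] * length(me_clean))
  me_inf <- sort(sample(me_clean, n_inf_me))
  me_lat <- latent_layer(m_me, n, subtype, me_inf, spec$effect_size, spec$noise_sd)
  me_val <- plogis(me_lat)  # beta values in (0, 1)
  me_val[me_def$zero, ] <- 0
  for (i in me_def$na) {
    k_na <- max(1L, rbinom(1, n, 0.1))
    me_val[i, sample.int(n, k_na)] <- NA_real_
  }
  dimnames(me_val) <- list(cpg_ids, pid)
  me_chr <- sample(paste0("chr", 1:22), m_me, replace = TRUE)
  me_chr[me_def$sex] <- sample(c("chrX", "chrY"), length(me_def$sex), replace = TRUE)
  # informative reporters map onto the informative genes (cycled); the rest
  # onto random genes, with ~5% left unannotated
  me_gene <- gene_ids[sample.int(m_rna, m_me, replace = TRUE)]
  me_gene[me_inf] <- gene_ids[rna_inf][((seq_along(me_inf) - 1L) %% length(rna_inf)) + 1L]
  me_gene[setdiff(which(runif(m_me) < 0.05), me_inf)] <- ""
  me_meta <- tibble(
    feature_id = cpg_ids, chromosome = me_chr,
    gene_symbol = me_gene, multimap = FALSE
  )
  me_meta$multimap[me_def$multimap] <- TRUE

  # --- miRNA layer (defects: all-zero only) ---------------------------------
  m_mi <- spec$n_features[["mirna"]]
  mi_def <- pick_defects(m_mi, c(zero = spec$frac_all_zero))
  mi_clean <- setdiff(seq_len(m_mi), mi_def$zero)
  n_inf_mi <- round(spec$informative_fraction[["mirna"]] * length(mi_clean))
  mi_inf <- sort(sample(mi_clean, n_inf_mi))
  mi_lat <- latent_layer(m_mi, n, subtype, mi_inf, spec$effect_size, spec$noise_sd)
  mi_val <- exp(mi_lat)
  mi_val[mi_def$zero, ] <- 0
  dimnames(mi_val) <- list(mir_ids, pid)
  mi_meta <- tibble(
    feature_id = mir_ids,
    chromosome = sample(paste0("chr", 1:22), m_mi, replace = TRUE),
    gene_symbol = "", multimap = FALSE
  )

  clinical <- draw_clinical(pid, subtype, spec)

  annotation <- bind_rows(
    tibble(reporter_id = cpg_ids, gene_symbol = me_gene, chromosome = me_chr),
    tibble(reporter_id = gene_ids, gene_symbol = gene_ids, chromosome = rna_chr)
  )

  structure(list(
    layers = list(
      methylation = omics_matrix(me_val, "methylation", me_meta),
      mrna = omics_matrix(rna_val, "mrna", rna_meta),
      mirna = omics_matrix(mi_val, "mirna", mi_meta)
    ),
    true_subtype = subtype,
    clinical = clinical,
    annotation = annotation,
    truth = list(
      methylation = cpg_ids[me_inf],
      mrna = gene_ids[rna_inf],
      mirna = mir_ids[mi_inf],
      informative_genes = gene_ids[rna_inf],
      shared_informative_genes = sort(unique(me_gene[me_inf]))
    ),
    spec = spec
  ), class = "multi_omics_cohort")
}

# Exponential survival with subtype hazard ratios; uniform censoring horizon
# calibrated by root-finding so the expected censored fraction matches spec.
draw_clinical <- function(pid, subtype, spec) {
  lambda0 <- log(2) / 1500  # baseline median survival 1500 days
  rate <- lambda0 * spec$subtype_hazard_ratios[subtype]
  t_event <- rexp(length(pid), rate)
  if (spec$censoring_rate <= 0) {
    os_time <- t_event
    os_event <- rep(1L, length(pid))
  } else {
    mix_rates <- lambda0 * spec$subtype_hazard_ratios
    mix_w <- spec$subtype_proportions
    cens_frac <- function(tau) {
      sum(mix_w * (1 - exp(-mix_rates * tau)) / (mix_rates * tau)) -
        spec$censoring_rate
    }
    tau <- stats::uniroot(cens_frac, c(1e-6, 1e7))$root
    cens <- runif(length(pid), 0, tau)
    os_time <- pmin(t_event, cens)
    os_event <- as.integer(t_event <= cens)
  }
  stages <- colnames(spec$stage_distribution)
  stage <- vapply(subtype, function(s) {
    sample(stages, 1, prob = spec$stage_distribution[s, ])
  }, character(1))
  tibble(
    patient_id = pid,
    os_time_days = os_time,
    os_event = os_event,
    inss_stage = stage,
    true_subtype = unname(subtype)
  )
}

#' @export
print.multi_omics_cohort <- function(x, ...) {
  cat(sprintf(
    "<multi_omics_cohort> %d patients, %d subtypes; layers: %s\n",
    length(x$true_subtype), x$spec$n_subtypes,
    paste(sprintf("%s (%d)", names(x$layers),
                  vapply(x$layers, function(l) nrow(l$values), integer(1))),
          collapse = ", ")
  ))
  invisible(x)
}
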