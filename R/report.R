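#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square with `df = (r - 1)(c - 1)` and an
#' upper-tail p-value; used for example to compare smoking-status
#' distributions between case and control co-twins.
#'
#' @param tab Matrix of nonnegative integer counts, at least 2 x 2.
#'
#' @return List with `chi2`, `df`, `p`.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_input("table must have at least 2 rows and 2 columns")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_input("table must contain nonnegative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_input("table has a zero marginal; the test is undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Cohort descriptives in the style of a clinical Table 1
#'
#' Per-group sample counts, percentage female, mean (SD) age, the smoking
#' contingency table with its Pearson chi-square p-value, and — when a
#' composition estimate is supplied — mean cell fractions per group with
#' Welch t-test p-values.
#'
#' @param sample_sheet Sample sheet (see [generate_twin_cohort()]).
#' @param composition Optional samples x cell types fraction matrix.
#'
#' @return List with `n_case`, `n_control`, `pct_female_case`,
#'   `pct_female_control`, `age` (data frame), `smoking` (list: table, p;
#'   p is NA when a marginal is zero or a group has fewer than 2 levels),
#'   and optionally `cells` (data frame from [compare_composition()]).
#' @export
cohort_summary <- function(sample_sheet, composition = NULL) {
  case <- sample_sheet$status == "case"
  out <- list(
    n_case = sum(case), n_control = sum(!case),
    pct_female_case = 100 * mean(sample_sheet$sex[case] == "F"),
    pct_female_control = 100 * mean(sample_sheet$sex[!case] == "F"),
    age = data.frame(
      group = c("case", "control"),
      mean = c(mean(sample_sheet$age[case]), mean(sample_sheet$age[!case])),
      sd = c(stats::sd(sample_sheet$age[case]),
             stats::sd(sample_sheet$age[!case])),
      stringsAsFactors = FALSE))
  smk <- table(ifelse(case, "case", "control"),
               factor(sample_sheet$smoking,
                      levels = c("current", "past", "never")))
  p_smk <- if (any(colSums(smk) == 0) || any(rowSums(smk) == 0) ||
               nrow(smk) < 2L) NA_real_
           else contingency_test(smk[, colSums(smk) > 0, drop = FALSE])$p
  out$smoking <- list(table = smk, p = p_smk)
  if (!is.null(composition)) {
    out$cells <- compare_composition(composition, sample_sheet)
  }
  out
}

#' Default pipeline configuration
#'
#' @param seed Global seed fanned out to per-stage seeds (stage k uses
#'   `seed + 11 * k`; see the per-stage functions).
#' @param ... Overrides for the synthetic generator (passed to
#'   [synthetic_config()]) or top-level settings: `n_independent`,
#'   `normalize`, `dvp_q_thresh`, `dvp_p_thresh`, `n_gene_sets`,
#'   `genes_per_set`, `enrich_draws`, `gene_sets`, `known_genes`,
#'   `external_probes`, `external_genes`.
#'
#' @return Configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed),
              synthetic = list(n_pairs = 79L, n_probes = 2000L,
                               frac_dmp = 0, frac_dvp = 0.005,
                               delta_beta = 0.05, var_inflation = 4),
              n_independent = 156L, normalize = TRUE,
              dvp_q_thresh = 0.001, dvp_p_thresh = 0.05,
              n_gene_sets = 20L, genes_per_set = 40L,
              enrich_draws = 1000L,
              gene_sets = NULL, known_genes = NULL,
              external_probes = NULL, external_genes = NULL)
  dots <- list(...)
  syn_fields <- names(formals(synthetic_config))
  for (nm in names(dots)) {
    if (nm %in% syn_fields) cfg$synthetic[[nm]] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Run the full twin-cohort analysis pipeline
#'
#' Executes, in order: synthetic cohort generation, probe QC filtering,
#' optional probe-type normalisation and M transformation, cell-fraction
#' estimation and group comparison, PCA covariate screening, differential
#' methylation testing (pair random effect), differential variability
#' detection (iEVORA-style), feature enrichment and bias-adjusted
#' gene-set testing of the DVP signature, independent-cohort signature
#' assessment, overlap tests against any supplied external signatures,
#' cohort descriptives, and truth-recovery scoring against the generator's
#' truth table. Fully deterministic given the configuration.
#'
#' @param config Configuration list from [default_pipeline_config()], or a
#'   path to a YAML file with the same structure.
#' @param outdir Optional directory; when given, all result tables are
#'   written there as TSV/CSV/JSON via [write_result_bundle()].
#'
#' @return A list of class `result_bundle` with elements `qc_report`,
#'   `dmp`, `dvp`, `dvp_summary`, `composition`, `composition_compare`,
#'   `pc_screen`, `enrichment`, `gene_set_results`, `overlap`,
#'   `signature`, `cohort`, `truth_recovery`, `annotation`, `sample_sheet`,
#'   `beta_qc`, `beta_independent`, `truth`, `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed)
  syn <- do.call(synthetic_config,
                 c(config$synthetic, list(seed = seed + 11L)))

  ann <- generate_probe_annotation(syn$n_probes, seed = seed + 22L)
  ref <- generate_cell_reference(
    ann, n_celltypes = syn$n_celltypes, seed = seed + 33L,
    n_markers_per_type = min(100L, syn$n_probes %/% (2L * syn$n_celltypes)))
  cohort <- generate_twin_cohort(syn, ann, cell_reference = ref)
  sheet <- cohort$sample_sheet

  qc <- filter_probes(cohort$beta, ann,
                      detection_p = cohort$intensities$detection_p,
                      bead_count = cohort$intensities$bead_count,
                      m_int = cohort$intensities$m_int,
                      u_int = cohort$intensities$u_int)
  beta_qc <- qc$beta
  if (isTRUE(config$normalize)) {
    beta_qc <- normalize_type_bias(beta_qc, ann)
  }
  ann_qc <- ann[ann$IlmnID %in% rownames(beta_qc), , drop = FALSE]
  m_qc <- beta_to_m(beta_qc)

  markers <- intersect(select_discriminating_probes(ref),
                       rownames(beta_qc))
  comp <- estimate_cell_fractions(beta_qc, ref, probes = markers)
  comp_cmp <- compare_composition(comp, sheet)

  factors <- data.frame(sheet[, c("age", "sex", "smoking", "cohort",
                                  "chip", "position")],
                        comp, check.names = TRUE)
  pcs <- pca_covariate_screen(m_qc, factors, n_pcs = 10)
  covs <- intersect(pcs$selected,
                    c("age", "sex", "smoking", "cohort", "chip"))

  dmp <- fit_dmp_model(beta_qc, sheet, covariates = covs,
                       annotation = ann)
  dvp <- ievora(beta_qc, sheet, q_thresh = config$dvp_q_thresh,
                p_thresh = config$dvp_p_thresh, annotation = ann)
  dvp_sum <- summarize_dvp_directionality(dvp)

  enrichment <- NULL
  gene_set_results <- NULL
  gene_sets <- config$gene_sets
  if (is.character(gene_sets) && length(gene_sets) == 1L) {
    gene_sets <- read_gmt(gene_sets)
  }
  if (is.null(gene_sets)) {
    universe <- map_probes_to_genes(ann_qc$IlmnID, ann_qc)
    gene_sets <- with_seed(seed + 44L, {
      stats::setNames(
        lapply(seq_len(config$n_gene_sets), function(i) {
          sample(universe, min(config$genes_per_set, length(universe)))
        }),
        sprintf("SET%03d", seq_len(config$n_gene_sets)))
    })
  }
  if (nrow(dvp) > 0L) {
    enrichment <- feature_enrichment(dvp$probe_id, ann_qc,
                                     n_draws = config$enrich_draws,
                                     seed = seed + 55L)
    gene_set_results <- probe_bias_gene_test(dvp$probe_id, ann_qc,
                                             gene_sets)
  }

  beta_ind <- generate_independent_cohort(syn, ann,
                                          n_samples = config$n_independent,
                                          seed = seed + 66L,
                                          cell_reference = ref)
  signature <- if (nrow(dvp) > 0L) {
    variability_signature_assessment(
      dvp,
      beta_qc[, sheet$status == "case", drop = FALSE],
      beta_qc[, sheet$status == "control", drop = FALSE],
      beta_ind[rownames(beta_qc), , drop = FALSE])
  } else NULL

  overlap <- list()
  if (!is.null(config$external_probes) && nrow(dvp) > 0L) {
    ext <- intersect(config$external_probes, rownames(beta_qc))
    overlap$probe_permutation <- probe_overlap_permutation(
      dvp$probe_id, ext, rownames(beta_qc), seed = seed + 77L)
  }
  if (!is.null(config$external_genes) && nrow(dvp) > 0L) {
    universe <- map_probes_to_genes(ann_qc$IlmnID, ann_qc)
    overlap$gene_hypergeometric <- gene_overlap_test(
      map_probes_to_genes(dvp$probe_id, ann_qc),
      intersect(config$external_genes, universe), universe)
  }
  known <- NULL
  if (!is.null(config$known_genes) && nrow(dvp) > 0L) {
    known <- annotate_known_loci(dvp, ann, config$known_genes)
  }

  truth <- cohort$truth
  truth_qc <- truth[truth$probe_id %in% rownames(beta_qc), ]
  called <- truth_qc$probe_id %in% dvp$probe_id
  tp <- sum(called & truth_qc$is_dvp)
  recovery <- list(
    n_true_dvp_qc = sum(truth_qc$is_dvp),
    n_called = sum(called), n_true_positive = tp,
    sensitivity = if (sum(truth_qc$is_dvp) > 0)
      tp / sum(truth_qc$is_dvp) else NA_real_,
    empirical_fdr = if (sum(called) > 0)
      (sum(called) - tp) / sum(called) else 0)

  bundle <- structure(list(
    qc_report = qc$report, dmp = dmp, dvp = dvp, dvp_summary = dvp_sum,
    composition = comp, composition_compare = comp_cmp,
    pc_screen = pcs, enrichment = enrichment,
    gene_set_results = gene_set_results, overlap = overlap,
    known_loci = known, signature = signature,
    cohort = cohort_summary(sheet, comp),
    truth_recovery = recovery, annotation = ann, sample_sheet = sheet,
    beta_qc = beta_qc, beta_independent = beta_ind, truth = truth,
    config = config), class = "result_bundle")
  if (!is.null(outdir)) write_result_bundle(bundle, outdir)
  bundle
}

#' Write the result bundle to disk
#'
#' Emits all pipeline tables as UTF-8 text: beta matrices as TSV, sample
#' sheet as CSV, DMP/DVP/enrichment/composition tables as TSV, QC report
#' and summaries as JSON. Output is byte-identical across reruns of the
#' same configuration.
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_result_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  write_beta_tsv(bundle$beta_qc, fp("beta_qc.tsv"))
  write_sample_sheet_csv(bundle$sample_sheet, fp("sample_sheet.csv"))
  write_table_tsv(bundle$annotation, fp("annotation.tsv"))
  write_table_tsv(bundle$truth, fp("truth.tsv"))
  write_table_tsv(bundle$dmp, fp("dmp.tsv"))
  write_table_tsv(bundle$dvp, fp("dvp.tsv"))
  comp <- data.frame(sample_id = rownames(bundle$composition),
                     bundle$composition, check.names = FALSE)
  write_table_tsv(comp, fp("composition.csv"))
  write_table_tsv(bundle$composition_compare, fp("composition_compare.tsv"))
  if (!is.null(bundle$enrichment)) {
    write_table_tsv(bundle$enrichment, fp("feature_enrichment.tsv"))
  }
  if (!is.null(bundle$gene_set_results)) {
    write_table_tsv(bundle$gene_set_results, fp("gene_set_results.tsv"))
  }
  jsonlite::write_json(
    list(qc = unclass(bundle$qc_report),
         dvp_summary = bundle$dvp_summary,
         truth_recovery = bundle$truth_recovery),
    fp("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
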