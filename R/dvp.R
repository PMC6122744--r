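#' Two-group Bartlett test of variance homogeneity
#'
#' Classical Bartlett statistic for two groups with a chi-square(1)
#' p-value. Sample variances are floored at `1e-12` so that constant
#' groups do not produce infinities.
#'
#' @param x,y Numeric vectors, each of length >= 2; at least one group
#'   must have nonzero variance.
#'
#' @return List with `statistic` and `p`.
#' @export
bartlett_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop_input("each group needs at least 2 values")
  v1 <- max(stats::var(x), 1e-12)
  v2 <- max(stats::var(y), 1e-12)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop_input("both groups have zero variance")
  }
  n <- n1 + n2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
  num <- (n - 2) * log(sp2) - (n1 - 1) * log(v1) - (n2 - 1) * log(v2)
  corr <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (n - 2)) / 3
  stat <- num / corr
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Vectorised two-group Bartlett statistic over matrix rows.
bartlett_rows <- function(v1, v2, n1, n2) {
  v1 <- pmax(v1, 1e-12); v2 <- pmax(v2, 1e-12)
  n <- n1 + n2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
  num <- (n - 2) * log(sp2) - (n1 - 1) * log(v1) - (n2 - 1) * log(v2)
  corr <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (n - 2)) / 3
  num / corr
}

#' Differential-variability detection (iEVORA-style two-stage procedure)
#'
#' Calls differentially variable positions in two stages: (1) a per-probe
#' two-group Bartlett test whose p-values are BH-adjusted across all
#' probes, gated at `q_thresh`; (2) a two-sided Welch t-test on group
#' means over the retained probes, gated at `p_thresh` and used to rank
#' the calls (ascending t-test p). The t-test gate regularises the
#' variance test, suppressing single-outlier false positives. Each call is
#' labelled with its hypervariable group (the group with the larger sample
#' variance) and the direction of the mean trend.
#'
#' @param beta QC-passed beta-value matrix (probes x samples).
#' @param sample_sheet Sample sheet with `sample_id` and `status`
#'   (case/control); at least 3 samples per group.
#' @param q_thresh BH q-value threshold for the Bartlett stage.
#' @param p_thresh p-value threshold for the t-test stage.
#' @param annotation Optional probe annotation to join.
#'
#' @return A data frame (DVP table) with one row per call, ranked by
#'   t-test p (ties broken by Bartlett p, then probe ID): `probe_id`,
#'   `bartlett_stat`, `p_bartlett`, `q_bartlett`, `t_stat`, `p_ttest`,
#'   `var_case`, `var_control`, `mean_case`, `mean_control`,
#'   `hypervariable_group` (case/control), `trend` (hypo_in_case /
#'   hyper_in_case), `rank`. The full-genome Bartlett p-value vector is
#'   attached as attribute `p_bartlett_all` (named by probe).
#' @export
ievora <- function(beta, sample_sheet, q_thresh = 0.001, p_thresh = 0.05,
                   annotation = NULL) {
  status <- sample_sheet$status[match(colnames(beta),
                                      sample_sheet$sample_id)]
  if (anyNA(status)) stop_input("every sample must appear in the sheet")
  case <- status == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 3L || n2 < 3L) stop_input("need at least 3 samples per group")

  bc <- beta[, case, drop = FALSE]
  bn <- beta[, !case, drop = FALSE]
  v1 <- row_vars(bc); v2 <- row_vars(bn)
  m1 <- rowMeans(bc); m2 <- rowMeans(bn)

  bstat <- bartlett_rows(v1, v2, n1, n2)
  p_bt <- stats::pchisq(bstat, df = 1, lower.tail = FALSE)
  names(p_bt) <- rownames(beta)
  q_bt <- bh_adjust(p_bt)

  # Welch t on means (vectorised).
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(pmax(se2, 1e-24))
  df_w <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p_tt <- 2 * stats::pt(abs(tstat), df_w, lower.tail = FALSE)

  keep <- which(q_bt < q_thresh & p_tt < p_thresh)
  out <- data.frame(
    probe_id = rownames(beta)[keep],
    bartlett_stat = bstat[keep], p_bartlett = unname(p_bt[keep]),
    q_bartlett = unname(q_bt[keep]),
    t_stat = tstat[keep], p_ttest = p_tt[keep],
    var_case = v1[keep], var_control = v2[keep],
    mean_case = m1[keep], mean_control = m2[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  out$hypervariable_group <- ifelse(out$var_case > out$var_control,
                                    "case", "control")
  out$trend <- ifelse(out$mean_case < out$mean_control,
                      "hypo_in_case", "hyper_in_case")
  ord <- order(out$p_ttest, out$p_bartlett, out$probe_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(annotation) && nrow(out) > 0L) {
    j <- match(out$probe_id, annotation$IlmnID)
    out$CHR <- annotation$CHR[j]
    out$UCSC_RefGene_Name <- annotation$UCSC_RefGene_Name[j]
    out$UCSC_RefGene_Group <- annotation$UCSC_RefGene_Group[j]
  }
  rownames(out) <- NULL
  attr(out, "p_bartlett_all") <- p_bt
  attr(out, "thresholds") <- c(q_thresh = q_thresh, p_thresh = p_thresh)
  out
}

#' Directionality summary of a DVP table
#'
#' Partitions the calls by hypervariable group and counts, within each
#' partition, how many show a trend towards hypomethylation in the
#' hypervariable group (for case-hypervariable probes: case mean below
#' control mean; for control-hypervariable probes: control mean below case
#' mean).
#'
#' @param dvp A DVP table from [ievora()] (may be empty).
#'
#' @return Named list: `n_total`, `n_hyper_case`, `n_hyper_control`,
#'   `n_hypo_in_hypervariable_case`, `n_hypo_in_hypervariable_control`.
#' @export
summarize_dvp_directionality <- function(dvp) {
  if (nrow(dvp) == 0L) {
    return(list(n_total = 0L, n_hyper_case = 0L, n_hyper_control = 0L,
                n_hypo_in_hypervariable_case = 0L,
                n_hypo_in_hypervariable_control = 0L))
  }
  hc <- dvp$hypervariable_group == "case"
  list(n_total = nrow(dvp),
       n_hyper_case = sum(hc),
       n_hyper_control = sum(!hc),
       n_hypo_in_hypervariable_case = sum(hc & dvp$trend == "hypo_in_case"),
       n_hypo_in_hypervariable_control =
         sum(!hc & dvp$trend == "hyper_in_case"))
}
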