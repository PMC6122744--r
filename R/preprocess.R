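#' Compute beta values from methylated/unmethylated intensities
#'
#' Applies the platform convention `beta = M / (M + U + offset)` with the
#' standard offset of 100, yielding values in `[0, 1)`.
#'
#' @param m_int,u_int Nonnegative intensity matrices (probes x samples),
#'   aligned on probes and samples.
#' @param offset Stabilising offset added to the denominator.
#'
#' @return A beta-value matrix with the dimnames of `m_int`.
#' @export
compute_beta <- function(m_int, u_int, offset = 100) {
  check_aligned(m_int, u_int, "u_int")
  if (any(m_int < 0) || any(u_int < 0)) {
    stop_input("intensities must be nonnegative")
  }
  m_int / (m_int + u_int + offset)
}

#' Filter probes by detection p-value, annotation flags and bead counts
#'
#' Removes probes that (i) fail the detection p-value rule at `detp`
#' (default 0.01), (ii) map to the sex chromosomes, (iii) carry a SNP
#' within two base pairs of the interrogated CpG, (iv) are flagged
#' cross-reactive, or (v) have a bead count below `bead_min` (default 3) in
#' at least `bead_frac` (default 5%) of samples. The detection rule is
#' configurable: `"any"` (strictest reading — removed if any sample fails)
#' or `"fraction"` (removed if at least `detp_frac` of samples fail).
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param annotation Probe annotation covering the rows of `beta`.
#' @param detection_p Optional detection p-value matrix aligned with `beta`.
#' @param bead_count Optional bead-count matrix aligned with `beta`.
#' @param detp Detection p-value threshold; a probe-sample measurement
#'   fails when its detection p is `>= detp`.
#' @param detp_rule Either `"any"` or `"fraction"`.
#' @param detp_frac Failing-sample fraction for `detp_rule = "fraction"`.
#' @param bead_min Minimum acceptable bead count.
#' @param bead_frac Fraction of samples at which low bead counts remove a
#'   probe.
#' @param m_int,u_int Optional intensity matrices; when given, per-sample
#'   median log2 intensities are recorded in the QC report.
#'
#' @return A list with `beta` (the filtered matrix) and `report`, a
#'   `qc_report` list itemising removed-probe counts per reason
#'   (overlaps counted in every reason they trigger), the total removed,
#'   and the retained probe count.
#' @export
filter_probes <- function(beta, annotation, detection_p = NULL,
                          bead_count = NULL, detp = 0.01,
                          detp_rule = c("any", "fraction"), detp_frac = 0.05,
                          bead_min = 3, bead_frac = 0.05,
                          m_int = NULL, u_int = NULL) {
  detp_rule <- match.arg(detp_rule)
  probes <- rownames(beta)
  if (is.null(probes)) stop_input("beta must have probe rownames")
  ann <- annotation[match(probes, annotation$IlmnID), , drop = FALSE]
  if (anyNA(ann$IlmnID)) {
    stop_input("annotation does not cover all probes in the beta matrix")
  }
  n_samp <- ncol(beta)

  fail_detp <- rep(FALSE, nrow(beta))
  if (!is.null(detection_p)) {
    check_aligned(beta, detection_p, "detection_p")
    nfail <- rowSums(detection_p >= detp)
    fail_detp <- if (detp_rule == "any") nfail >= 1L
                 else nfail >= detp_frac * n_samp
  }
  fail_sex <- ann$CHR %in% c("X", "Y")
  fail_snp <- as.logical(ann$SNP_within_2bp)
  fail_xr <- as.logical(ann$Cross_reactive)
  fail_bead <- rep(FALSE, nrow(beta))
  if (!is.null(bead_count)) {
    check_aligned(beta, bead_count, "bead_count")
    nlow <- rowSums(bead_count < bead_min)
    fail_bead <- nlow >= ceiling(bead_frac * n_samp)
  }

  removed <- fail_detp | fail_sex | fail_snp | fail_xr | fail_bead
  report <- list(
    n_input = nrow(beta),
    n_detection_p = sum(fail_detp),
    n_sex_chromosome = sum(fail_sex),
    n_snp_within_2bp = sum(fail_snp),
    n_cross_reactive = sum(fail_xr),
    n_low_bead_count = sum(fail_bead),
    n_removed = sum(removed),
    n_retained = sum(!removed),
    detp_rule = detp_rule)
  if (!is.null(m_int) && !is.null(u_int)) {
    report$median_log2_m_int <- apply(log2(m_int + 1), 2, stats::median)
    report$median_log2_u_int <- apply(log2(u_int + 1), 2, stats::median)
  }
  class(report) <- "qc_report"
  list(beta = beta[!removed, , drop = FALSE], report = report)
}

#' Probe-type quantile normalisation
#'
#' Reduces the distributional difference between Infinium type I and type
#' II probes within each sample: the empirical quantile functions of the
#' two probe types are averaged and both types are quantile-mapped onto the
#' average. Ranks within each type are preserved (the map is monotone), and
#' when the two types already share a distribution the data are a fixed
#' point of the map.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param annotation Probe annotation providing `Infinium_Design_Type`.
#'
#' @return The normalised beta matrix. If either probe type has fewer than
#'   10 probes the input is returned unchanged with a warning.
#' @export
normalize_type_bias <- function(beta, annotation) {
  ann <- annotation[match(rownames(beta), annotation$IlmnID), , drop = FALSE]
  is_one <- ann$Infinium_Design_Type == "I"
  if (sum(is_one) < 10L || sum(!is_one) < 10L) {
    warning("fewer than 10 probes in a design type; normalisation skipped")
    return(beta)
  }
  out <- beta
  for (s in seq_len(ncol(beta))) {
    x1 <- beta[is_one, s]
    x2 <- beta[!is_one, s]
    # Plotting positions (r - 0.5)/n with type-5 quantiles make each value
    # its own quantile, so identical type distributions map to themselves.
    p1 <- (rank(x1, ties.method = "average") - 0.5) / length(x1)
    p2 <- (rank(x2, ties.method = "average") - 0.5) / length(x2)
    avg_q <- function(p) {
      (stats::quantile(x1, p, type = 5, names = FALSE) +
         stats::quantile(x2, p, type = 5, names = FALSE)) / 2
    }
    out[is_one, s] <- avg_q(p1)
    out[!is_one, s] <- avg_q(p2)
  }
  out
}

#' Logit (M-value) transform of beta values
#'
#' Computes `M = log2(beta / (1 - beta))` after clipping beta into
#' `[epsilon, 1 - epsilon]`, so the result is always finite.
#'
#' @param beta Beta-value matrix or vector in `[0, 1]`.
#' @param epsilon Clipping bound.
#'
#' @return M values with the shape and dimnames of the input.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop_input("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Inverse logit transform of M values
#'
#' @param m M-value matrix or vector.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) 1 / (1 + 2^(-m))

#' Screen covariates against principal components of the methylome
#'
#' Runs a sample-space PCA on row-centred M values and tests each candidate
#' factor against each of the leading components: one-way ANOVA for
#' categorical factors, a Pearson correlation test for continuous ones.
#' Factors associated (p < `alpha`) with any of the first four components
#' are flagged for inclusion as model covariates.
#'
#' @param m M-value matrix (probes x samples).
#' @param factors Data frame of per-sample candidate factors (rows aligned
#'   with the columns of `m`); typically sample-sheet columns plus
#'   estimated cell fractions.
#' @param n_pcs Number of components to retain (capped by the data rank).
#' @param alpha Association threshold for covariate selection.
#'
#' @return A list of class `pc_association` with `variance_explained`,
#'   `p_values` (factors x PCs), `selected` (character vector of factor
#'   names), `scores` (samples x PCs) and `notes` (skipped factors).
#' @export
pca_covariate_screen <- function(m, factors, n_pcs = 20, alpha = 0.05) {
  if (ncol(m) < 3L) stop_input("need at least 3 samples for PCA")
  if (nrow(factors) != ncol(m)) {
    stop_input("factors must have one row per sample")
  }
  mc <- m - rowMeans(m)
  pc <- stats::prcomp(t(mc), center = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  ve <- pc$sdev[seq_len(n_pcs)]^2 / sum(pc$sdev^2)

  notes <- character(0)
  pvals <- matrix(NA_real_, ncol(factors), n_pcs,
                  dimnames = list(colnames(factors),
                                  paste0("PC", seq_len(n_pcs))))
  for (f in seq_len(ncol(factors))) {
    x <- factors[[f]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      notes <- c(notes, sprintf("factor '%s' is constant; skipped",
                                colnames(factors)[f]))
      next
    }
    for (j in seq_len(n_pcs)) {
      pvals[f, j] <- if (is.numeric(x)) {
        stats::cor.test(x, scores[, j])$p.value
      } else {
        stats::anova(stats::lm(scores[, j] ~ factor(x)))[1, "Pr(>F)"]
      }
    }
  }
  lead <- seq_len(min(4L, n_pcs))
  sel_rows <- apply(pvals[, lead, drop = FALSE], 1,
                    function(p) any(p < alpha, na.rm = TRUE))
  structure(list(variance_explained = ve, p_values = pvals,
                 selected = rownames(pvals)[sel_rows],
                 scores = scores, notes = notes),
            class = "pc_association")
}

#' MDS of the most variable probes with a group-separation score
#'
#' Classical multidimensional scaling of the Euclidean sample distances
#' over the `k` most variable probes, with a silhouette-style separation
#' statistic for a candidate grouping (for example treatment use): the mean
#' silhouette width of the labels in the 2-D embedding. Values near 0 mean
#' the grouping does not structure the methylome; values above 0.5 indicate
#' clear separation.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param group_labels Per-sample labels (length `ncol(beta)`, at least two
#'   groups).
#' @param k Number of most-variable probes to use.
#'
#' @return A list with `coordinates` (samples x 2), `separation` (mean
#'   silhouette width) and `probes` (the probes used).
#' @export
mds_top_variable <- function(beta, group_labels, k = 1000) {
  if (k < 2) stop_input("k must be at least 2")
  k <- min(k, nrow(beta))
  if (length(group_labels) != ncol(beta)) {
    stop_input("group_labels must match the number of samples")
  }
  top <- order(row_vars(beta), decreasing = TRUE)[seq_len(k)]
  d <- stats::dist(t(beta[top, , drop = FALSE]))
  xy <- stats::cmdscale(d, k = 2)
  rownames(xy) <- colnames(beta)
  list(coordinates = xy,
       separation = silhouette_mean(xy, group_labels),
       probes = rownames(beta)[top])
}

# Mean silhouette width of labelled points in a Euclidean embedding.
silhouette_mean <- function(xy, labels) {
  labels <- as.character(labels)
  dd <- as.matrix(stats::dist(xy))
  n <- nrow(dd)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(dd[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(dd[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
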