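#' Select cell-type-discriminating probes from a reference panel
#'
#' For each cell type, probes are ranked by the standardised one-vs-rest
#' mean gap `|mean(type) - mean(others)| / (sd across types + eps)` and the
#' top `n_per_type` per type are pooled (deduplicated).
#'
#' @param reference Probes x cell types reference beta matrix (>= 2 types).
#' @param n_per_type Number of probes requested per cell type.
#'
#' @return Character vector of selected probe IDs. If fewer candidates
#'   exist than requested, all are returned with a warning; identical
#'   reference columns trigger a degeneracy warning.
#' @export
select_discriminating_probes <- function(reference, n_per_type = 100L) {
  if (ncol(reference) < 2L) stop_input("reference needs at least 2 cell types")
  if (is.null(rownames(reference))) stop_input("reference needs probe rownames")
  k <- ncol(reference)
  row_sd <- sqrt(row_vars(reference))
  if (all(row_sd < 1e-12)) {
    warning("reference columns are identical; probe selection is degenerate")
  }
  n_take <- min(n_per_type, nrow(reference))
  if (n_take < n_per_type) {
    warning("fewer candidate probes than requested; returning all available")
  }
  sel <- character(0)
  for (t in seq_len(k)) {
    gap <- abs(reference[, t] - rowMeans(reference[, -t, drop = FALSE]))
    stat <- gap / (row_sd + 1e-12)
    sel <- c(sel, rownames(reference)[order(stat,
                                            decreasing = TRUE)[seq_len(n_take)]])
  }
  unique(sel)
}

#' Estimate cell-type fractions by constrained projection
#'
#' Houseman-style reference-based deconvolution: each sample's beta profile
#' over a discriminating probe subset is regressed on the reference panel
#' under a nonnegativity constraint (`min ||beta_s - R w||^2, w >= 0`,
#' solved by Lawson-Hanson NNLS), and the weights are renormalised to sum
#' to one.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param reference Probes x cell types reference beta matrix.
#' @param probes Probe subset to use; defaults to all probes shared by
#'   `beta` and `reference`.
#'
#' @return Samples x cell types matrix of estimated fractions (rows sum
#'   to 1).
#' @export
estimate_cell_fractions <- function(beta, reference, probes = NULL) {
  if (is.null(probes)) {
    probes <- intersect(rownames(beta), rownames(reference))
  }
  if (length(probes) < ncol(reference)) {
    stop_input("probe subset is empty or smaller than the number of cell ",
               "types; cannot estimate fractions")
  }
  if (!all(probes %in% rownames(beta)) ||
      !all(probes %in% rownames(reference))) {
    stop_input("probe subset must be present in both beta and reference")
  }
  r <- reference[probes, , drop = FALSE]
  b <- beta[probes, , drop = FALSE]
  out <- matrix(NA_real_, ncol(b), ncol(r),
                dimnames = list(colnames(b), colnames(r)))
  for (s in seq_len(ncol(b))) {
    w <- pracma::lsqnonneg(r, b[, s])$x
    if (sum(w) <= 0) stop_input("degenerate solution for sample ",
                                colnames(b)[s])
    out[s, ] <- w / sum(w)
  }
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and
#' a two-sided p-value. When both groups have zero variance and equal
#' means the conventional `t = 0, p = 1` is returned; zero variance in
#' both groups with unequal means is an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#'
#' @return List with `t`, `df` and `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_input("each group needs at least 2 observations")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop_input("both groups have zero variance with different means")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Compare estimated cell composition between case and control groups
#'
#' Welch t-test per cell type on the estimated fractions; any cell type
#' with p < 0.05 is flagged as a potential confounder.
#'
#' @param composition Samples x cell types fraction matrix, as from
#'   [estimate_cell_fractions()].
#' @param sample_sheet Sample sheet with `sample_id` and `status`
#'   (case/control) covering all rows of `composition`.
#'
#' @return Data frame with one row per cell type: `cell_type`,
#'   `mean_case`, `mean_control`, `p`, `confounder`.
#' @export
compare_composition <- function(composition, sample_sheet) {
  status <- sample_sheet$status[match(rownames(composition),
                                      sample_sheet$sample_id)]
  if (anyNA(status)) stop_input("every composition sample must be labelled")
  case <- status == "case"
  if (!any(case) || all(case)) stop_input("both groups must be nonempty")
  res <- lapply(colnames(composition), function(ct) {
    xc <- composition[case, ct]; xn <- composition[!case, ct]
    p <- if (stats::var(xc) == 0 && stats::var(xn) == 0 &&
             isTRUE(all.equal(mean(xc), mean(xn)))) 1
         else welch_t_test(xc, xn)$p
    data.frame(cell_type = ct, mean_case = mean(xc),
               mean_control = mean(xn), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$confounder <- out$p < 0.05
  out
}
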