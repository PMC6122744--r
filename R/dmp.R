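#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone in p rank, capped at 1), via
#' `stats::p.adjust(method = "BH")` after input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_input("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-probe group means and case-control difference
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param sample_sheet Sample sheet with `sample_id` and `status`.
#'
#' @return Data frame: `probe_id`, `mean_beta_control`, `mean_beta_case`,
#'   `diff` (= case - control).
#' @export
summarize_group_means <- function(beta, sample_sheet) {
  status <- sample_sheet$status[match(colnames(beta),
                                      sample_sheet$sample_id)]
  if (anyNA(status)) stop_input("every sample must appear in the sheet")
  case <- status == "case"
  if (!any(case) || all(case)) stop_input("both groups must be nonempty")
  mc <- rowMeans(beta[, case, drop = FALSE])
  mn <- rowMeans(beta[, !case, drop = FALSE])
  data.frame(probe_id = rownames(beta), mean_beta_control = mn,
             mean_beta_case = mc, diff = mc - mn,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Covariates without within-pair variation carry no information about the
# within-pair disease contrast; they are dropped with a note.
drop_pair_constant <- function(covariates, data) {
  keep <- character(0)
  for (cv in covariates) {
    x <- data[[cv]]
    within_var <- tapply(as.numeric(factor(x)), data$pair_id,
                         function(v) length(unique(v)) > 1L)
    if (any(within_var)) keep <- c(keep, cv)
    else message("covariate '", cv,
                 "' is constant within pairs; dropped from the DMP model")
  }
  keep
}

#' Differential methylation testing with a sibling-pair random effect
#'
#' Fits, per probe, a linear mixed model of methylation on disease status
#' plus optional fixed covariates with a pair-level random intercept
#' (REML), and reports the two-sided p-value for the disease coefficient
#' with Satterthwaite degrees of freedom. On balanced discordant pairs
#' without covariates this reproduces the paired t-test. Non-convergent
#' fits fall back to least squares with fixed pair intercepts and are
#' flagged.
#'
#' @param beta Methylation matrix (probes x samples); beta values by
#'   default, M values if the caller transformed them.
#' @param sample_sheet Sample sheet with `sample_id`, `pair_id`, `status`;
#'   every pair must have exactly one case and one control.
#' @param covariates Character vector of sample-sheet column names to
#'   include as fixed covariates (typically from
#'   [pca_covariate_screen()]). Covariates constant within all pairs are
#'   dropped with a note.
#' @param annotation Optional probe annotation to join (chromosome, gene,
#'   feature).
#' @param fdr_threshold FDR level recorded as an attribute.
#'
#' @return A data frame (DMP table) sorted by p: `probe_id`,
#'   `mean_beta_control`, `mean_beta_case`, `diff`, `estimate`, `p`, `q`,
#'   `fallback`, plus annotation columns when supplied.
#' @export
fit_dmp_model <- function(beta, sample_sheet, covariates = character(0),
                          annotation = NULL, fdr_threshold = 0.05) {
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ,
                        drop = FALSE]
  if (anyNA(sheet$sample_id)) {
    stop_input("every beta column must appear in the sample sheet")
  }
  tab <- table(sheet$pair_id, sheet$status)
  if (ncol(tab) != 2L || any(tab != 1L)) {
    stop_input("each pair must contribute exactly one case and one control")
  }
  covariates <- drop_pair_constant(covariates, sheet)

  dat <- data.frame(status = factor(sheet$status,
                                    levels = c("control", "case")),
                    pair_id = factor(sheet$pair_id))
  for (cv in covariates) dat[[cv]] <- sheet[[cv]]
  rhs <- paste(c("status", covariates, "(1 | pair_id)"), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  fb_fml <- stats::as.formula(paste("y ~",
    paste(c("status", covariates, "pair_id"), collapse = " + ")))
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "ignore")
  case <- dat$status == "case"
  ctrl_of_pair <- match(dat$pair_id[case], dat$pair_id[!case])

  n <- nrow(beta)
  est <- p <- rep(NA_real_, n)
  fallback <- rep(FALSE, n)
  for (i in seq_len(n)) {
    dat$y <- beta[i, ]
    co <- tryCatch({
      lf <- lme4::lFormula(fml, data = dat, REML = TRUE, control = ctrl)
      dfun <- do.call(lme4::mkLmerDevfun, lf)
      theta <- if (length(covariates) == 0L) {
        # Balanced paired design: the REML variance components have a
        # closed form via within-pair differences and pair sums, so the
        # optimiser is skipped and theta is exact.
        yc <- dat$y[case]; yn <- dat$y[!case][ctrl_of_pair]
        d <- yc - yn; s <- yc + yn
        npair <- length(d)
        s2e <- sum((d - mean(d))^2) / (2 * (npair - 1))
        s2a <- max(0, (sum((s - mean(s))^2) / (npair - 1) - 2 * s2e) / 4)
        sqrt(s2a / max(s2e, 1e-300))
      } else {
        op0 <- lme4::optimizeLmer(dfun, optimizer = "bobyqa",
                                  control = list())
        stats::optimize(dfun, c(max(0, op0$par - 0.2), op0$par + 0.2),
                        tol = 1e-12)$minimum
      }
      fval <- dfun(theta)
      mm <- lme4::mkMerMod(environment(dfun),
                           list(par = theta, fval = fval, conv = 0L,
                                feval = 1L),
                           lf$reTrms, fr = lf$fr)
      mm@call <- as.call(list(quote(lme4::lmer), fml,
                              data = quote(dat), REML = TRUE))
      mt <- lmerTest::as_lmerModLmerTest(mm)
      stats::coef(summary(mt))["statuscase", c("Estimate", "Pr(>|t|)")]
    }, error = function(e) NULL)
    if (is.null(co) || anyNA(co)) {
      lfit <- stats::lm(fb_fml, data = dat)
      sc <- stats::coef(summary(lfit))
      co <- sc["statuscase", c("Estimate", "Pr(>|t|)")]
      fallback[i] <- TRUE
    }
    est[i] <- co[1]; p[i] <- co[2]
  }

  gm <- summarize_group_means(beta, sheet)
  out <- data.frame(probe_id = rownames(beta),
                    mean_beta_control = gm$mean_beta_control,
                    mean_beta_case = gm$mean_beta_case,
                    diff = gm$diff, estimate = est, p = p,
                    q = bh_adjust(p), fallback = fallback,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    j <- match(out$probe_id, annotation$IlmnID)
    out$CHR <- annotation$CHR[j]
    out$UCSC_RefGene_Name <- annotation$UCSC_RefGene_Name[j]
    out$UCSC_RefGene_Group <- annotation$UCSC_RefGene_Group[j]
  }
  out <- out[order(out$p, out$probe_id), ]
  rownames(out) <- NULL
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Power of the paired (within-twin-pair) test for a mean methylation shift
#'
#' Two-sided paired t-test power via the noncentral t distribution: the
#' probability that a mean beta difference of `delta_beta` between
#' discordant co-twins is detected at level `alpha` with `n_pairs` pairs,
#' given the standard deviation `sd_d` of within-pair beta differences.
#'
#' @param n_pairs Number of twin pairs (>= 2).
#' @param delta_beta True mean within-pair methylation difference.
#' @param sd_d Standard deviation of within-pair differences (> 0).
#' @param alpha Two-sided significance level.
#'
#' @return Power in `[0, 1]`.
#' @export
ewas_power <- function(n_pairs, delta_beta, sd_d, alpha = 0.05) {
  if (n_pairs < 2L) stop_input("n_pairs must be at least 2")
  if (sd_d <= 0) stop_input("sd_d must be positive")
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0, 1)")
  df <- n_pairs - 1
  ncp <- delta_beta / (sd_d / sqrt(n_pairs))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}
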