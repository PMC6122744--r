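#' Configuration for the synthetic twin-cohort generator
#'
#' Builds and validates the parameter set describing a simulated
#' disease-discordant monozygotic twin methylation study. The defaults mirror
#' a 79-pair whole-blood 450K-style cohort drawn from two recruitment waves:
#' 86% female pairs, six blood cell types with granulocytes dominant, and
#' chip-level batch structure with both twins of a pair on the same chip.
#'
#' @param n_pairs Number of twin pairs (each contributes one case and one
#'   control sample).
#' @param n_probes Number of array probes.
#' @param frac_dmp Fraction of probes carrying an injected mean shift
#'   (differentially methylated positions).
#' @param frac_dvp Fraction of probes carrying an injected variance
#'   inflation (differentially variable positions).
#' @param delta_beta Mean-shift effect size on the beta scale for injected
#'   DMPs.
#' @param var_inflation Multiplicative variance factor (on the M scale) for
#'   the hypervariable group at injected DVPs; must be positive.
#' @param rho Intra-pair correlation of M values, in (0, 1).
#' @param n_celltypes Number of cell types in the simulated mixtures.
#' @param dirichlet_alpha Concentration parameter scaling the Dirichlet
#'   draw of per-sample cell-mixing weights.
#' @param n_chips Number of BeadChip batches; pairs are assigned to chips
#'   round-robin so that co-twins always share a chip.
#' @param seed Integer seed from which all per-stage seeds are derived.
#' @param sigma_m Baseline per-probe total standard deviation on the M
#'   scale (pair effect plus individual residual).
#' @param female_fraction Fraction of female twin pairs.
#' @param dvp_case_prob Probability that an injected DVP is hypervariable in
#'   the case group (the remainder are hypervariable in controls).
#' @param dvp_shift_sd Magnitude, in units of the probe's baseline M-scale
#'   standard deviation, of the mean trend accompanying each injected DVP
#'   in its hypervariable group (hypervariability in real methylomes
#'   co-occurs with a directional mean trend of roughly this size).
#' @param dvp_hypo_prob Probability that the accompanying DVP mean shift is
#'   towards hypomethylation in the hypervariable group.
#' @param frac_fail_detp Fraction of probes with failing detection p values.
#' @param frac_low_bead Fraction of probes with low bead counts in more than
#'   5% of samples.
#' @param chip_sd Standard deviation of the M-scale chip (batch) offset.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 79L,
                             n_probes = 20000L,
                             frac_dmp = 0.01,
                             frac_dvp = 0.005,
                             delta_beta = 0.05,
                             var_inflation = 4,
                             rho = 0.8,
                             n_celltypes = 6L,
                             dirichlet_alpha = 5,
                             n_chips = 8L,
                             seed = 1L,
                             sigma_m = 0.25,
                             female_fraction = 0.86,
                             dvp_case_prob = 0.65,
                             dvp_shift_sd = 0.9,
                             dvp_hypo_prob = 0.74,
                             frac_fail_detp = 0.005,
                             frac_low_bead = 0.005,
                             chip_sd = 0.1) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_probes = as.integer(n_probes),
              frac_dmp = frac_dmp, frac_dvp = frac_dvp,
              delta_beta = delta_beta, var_inflation = var_inflation,
              rho = rho, n_celltypes = as.integer(n_celltypes),
              dirichlet_alpha = dirichlet_alpha, n_chips = as.integer(n_chips),
              seed = as.integer(seed), sigma_m = sigma_m,
              female_fraction = female_fraction, dvp_case_prob = dvp_case_prob,
              dvp_shift_sd = dvp_shift_sd, dvp_hypo_prob = dvp_hypo_prob,
              frac_fail_detp = frac_fail_detp, frac_low_bead = frac_low_bead,
              chip_sd = chip_sd)
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_pairs < 2L) stop_input("n_pairs must be at least 2")
  if (cfg$n_probes < 10L) stop_input("n_probes must be at least 10")
  if (cfg$frac_dmp < 0 || cfg$frac_dvp < 0 ||
      cfg$frac_dmp + cfg$frac_dvp > 1) {
    stop_input("frac_dmp and frac_dvp must be nonnegative with sum <= 1")
  }
  if (cfg$var_inflation <= 0) stop_input("var_inflation must be positive")
  if (cfg$rho <= 0 || cfg$rho >= 1) stop_input("rho must lie in (0, 1)")
  if (cfg$n_celltypes < 2L) stop_input("n_celltypes must be at least 2")
  if (cfg$dirichlet_alpha <= 0) stop_input("dirichlet_alpha must be positive")
  if (cfg$sigma_m <= 0) stop_input("sigma_m must be positive")
  invisible(cfg)
}

#' Generate a manifest-style probe annotation table
#'
#' Creates per-probe metadata mimicking the HumanMethylation450 manifest:
#' chromosome (about 2% of probes on X/Y), genomic position, Infinium probe
#' chemistry, CpG-island relation, gene symbol(s) with a heavy-tailed
#' probes-per-gene distribution (exercising probe-number bias in gene-set
#' tests), gene feature, and flags for SNPs within 2 bp of the interrogated
#' CpG and for cross-reactive probes.
#'
#' @param n_probes Number of probes (at least 10).
#' @param seed Integer seed; the same seed reproduces the annotation exactly.
#'
#' @return A data frame with manifest-like columns `IlmnID`, `CHR`,
#'   `MAPINFO`, `Infinium_Design_Type`, `Relation_to_UCSC_CpG_Island`,
#'   `UCSC_RefGene_Name` (semicolon-delimited for multi-gene probes, empty
#'   for intergenic), `UCSC_RefGene_Group`, `SNP_within_2bp`,
#'   `Cross_reactive`.
#' @export
generate_probe_annotation <- function(n_probes, seed = 1L) {
  if (!is.numeric(n_probes) || n_probes < 10L) {
    stop_input("n_probes must be a positive count of at least 10")
  }
  n_probes <- as.integer(n_probes)
  with_seed(seed, {
    ids <- sprintf("cg%08d", sort(sample.int(99999999L, n_probes)))
    autos <- sample(as.character(1:22), n_probes, replace = TRUE)
    sex_idx <- which(stats::runif(n_probes) < 0.02)
    chr <- autos
    chr[sex_idx] <- sample(c("X", "Y"), length(sex_idx),
                           replace = TRUE, prob = c(0.8, 0.2))
    pos <- sample.int(240000000L, n_probes, replace = TRUE)
    type <- sample(c("I", "II"), n_probes, replace = TRUE, prob = c(0.28, 0.72))
    island <- sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                       "OpenSea"),
                     n_probes, replace = TRUE,
                     prob = c(0.31, 0.12, 0.10, 0.05, 0.05, 0.37))

    # Probe-to-gene assignment with a Pareto-weighted gene popularity so a
    # few genes accumulate tens to hundreds of probes while most get 1-3.
    n_genes <- max(2L, as.integer(round(n_probes / 4)))
    gene_pool <- sprintf("GENE%05d", seq_len(n_genes))
    w <- pmin(stats::runif(n_genes)^(-1.1), 800)
    intergenic <- stats::runif(n_probes) < 0.12
    gene1 <- rep("", n_probes)
    gene1[!intergenic] <- sample(gene_pool, sum(!intergenic),
                                 replace = TRUE, prob = w)
    second <- !intergenic & stats::runif(n_probes) < 0.05
    gene2 <- rep("", n_probes)
    gene2[second] <- sample(gene_pool, sum(second), replace = TRUE, prob = w)
    gene <- gene1
    keep2 <- second & gene2 != gene1
    gene[keep2] <- paste(gene1[keep2], gene2[keep2], sep = ";")

    feature <- rep("", n_probes)
    feature[!intergenic] <- sample(
      c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR"),
      sum(!intergenic), replace = TRUE,
      prob = c(0.14, 0.10, 0.10, 0.06, 0.48, 0.12))

    data.frame(
      IlmnID = ids, CHR = chr, MAPINFO = pos,
      Infinium_Design_Type = type,
      Relation_to_UCSC_CpG_Island = island,
      UCSC_RefGene_Name = gene,
      UCSC_RefGene_Group = feature,
      SNP_within_2bp = stats::runif(n_probes) < 0.01,
      Cross_reactive = stats::runif(n_probes) < 0.015,
      stringsAsFactors = FALSE)
  })
}

# Deterministic per-probe baseline model shared by the twin cohort and the
# independent cohort: a three-component (low/mid/high) beta mixture mapped
# to the M scale, mildly heterogeneous per-probe noise SDs, and cell-type
# M-scale offsets on a 10% subset of probes.
baseline_probe_params <- function(cfg, annotation) {
  n <- cfg$n_probes
  with_seed(cfg$seed + 1000L, {
    comp <- sample.int(3L, n, replace = TRUE, prob = c(0.35, 0.2, 0.45))
    mu_beta <- numeric(n)
    mu_beta[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 14)
    mu_beta[comp == 2L] <- stats::rbeta(sum(comp == 2L), 10, 10)
    mu_beta[comp == 3L] <- stats::rbeta(sum(comp == 3L), 14, 2)
    mu_beta <- pmin(pmax(mu_beta, 0.01), 0.99)
    sigma <- cfg$sigma_m * exp(stats::rnorm(n, 0, 0.2))
    cell_probe <- stats::runif(n) < 0.10
    cell_offsets <- matrix(0, n, cfg$n_celltypes)
    cell_offsets[cell_probe, ] <- stats::rnorm(sum(cell_probe) *
                                                 cfg$n_celltypes, 0, 1)
    list(mu_m = log2(mu_beta / (1 - mu_beta)), sigma = sigma,
         cell_offsets = cell_offsets)
  })
}

# Blood-like base mixing proportions; granulocytes dominate whole blood.
cell_base_props <- function(k) {
  if (k == 6L) {
    c(CD8T = 0.05, CD4T = 0.20, NK = 0.06, Bcell = 0.05,
      Mono = 0.07, Gran = 0.57)
  } else {
    p <- rev(seq_len(k))
    stats::setNames(p / sum(p), paste0("CT", seq_len(k)))
  }
}

#' Simulate a disease-discordant twin methylation cohort
#'
#' Draws a probes-by-samples beta matrix for `n_pairs` monozygotic twin
#' pairs, one case and one control per pair, with known injected effects.
#' Pair effects and noise are modelled on the M (logit) scale and mapped
#' back to beta values, so all values stay inside `[0, 1]`. Injected DMPs
#' shift the case-group beta by `delta_beta`; injected DVPs inflate the
#' total M-scale variance of one group (the hypervariable group, cases
#' with probability `dvp_case_prob`) by the factor `var_inflation` and add
#' an M-scale mean trend of `dvp_shift_sd` baseline standard deviations in
#' that group, towards hypomethylation with probability `dvp_hypo_prob`.
#' Per-sample
#' Dirichlet cell-mixing weights perturb a cell-sensitive probe subset and
#' chip batch offsets are added on the M scale. Methylated/unmethylated
#' intensities satisfying `beta = M/(M + U + 100)` exactly, a detection
#' p-value layer and a bead-count layer are emitted alongside.
#'
#' @param config A [synthetic_config()] object.
#' @param annotation Probe annotation with `config$n_probes` rows, as from
#'   [generate_probe_annotation()].
#' @param cell_reference Optional reference panel from
#'   [generate_cell_reference()]. When supplied, the baseline of its
#'   designated marker probes is replaced per sample by the logit of the
#'   mixed reference profile `R w`, so reference-based deconvolution of
#'   the emitted betas recovers the true mixing weights; marker probes are
#'   then also excluded from effect injection.
#'
#' @return A list with elements `beta` (probes x samples matrix),
#'   `intensities` (list of `m_int`, `u_int`, `detection_p`, `bead_count`
#'   matrices aligned with `beta`), `sample_sheet` (data frame: sample_id,
#'   pair_id, status, age, sex, smoking, cohort, chip, position),
#'   `truth` (data frame: probe_id, is_dmp, is_dvp,
#'   dvp_hypervariable_group, true_delta, true_v) and `cell_fractions`
#'   (samples x cell types matrix of true mixing weights).
#' @export
generate_twin_cohort <- function(config, annotation, cell_reference = NULL) {
  validate_synthetic_config(config)
  if (nrow(annotation) != config$n_probes) {
    stop_input("annotation must have config$n_probes rows")
  }
  cfg <- config
  n <- cfg$n_probes
  np <- cfg$n_pairs
  ns <- 2L * np
  base <- baseline_probe_params(cfg, annotation)
  probes <- annotation$IlmnID

  with_seed(cfg$seed + 2000L, {
    pair_id <- sprintf("P%03d", seq_len(np))
    sample_id <- as.vector(rbind(paste0(pair_id, "_case"),
                                 paste0(pair_id, "_ctrl")))
    status <- rep(c("case", "control"), np)
    pair_of_sample <- rep(pair_id, each = 2L)

    age <- rep(pmin(pmax(stats::rnorm(np, 54.2, 12.2), 18), 90), each = 2L)
    sex <- rep(ifelse(stats::runif(np) < cfg$female_fraction, "F", "M"),
               each = 2L)
    smoking <- sample(c("current", "past", "never"), ns, replace = TRUE,
                      prob = c(0.17, 0.31, 0.52))
    cohort <- rep(ifelse(stats::runif(np) < 62 / 79, "cohort1", "cohort2"),
                  each = 2L)
    chip <- rep(sprintf("chip%02d", ((seq_len(np) - 1L) %% cfg$n_chips) + 1L),
                each = 2L)
    position <- sprintf("R%02dC01", ((seq_len(ns) - 1L) %% 12L) + 1L)
    sheet <- data.frame(sample_id = sample_id, pair_id = pair_of_sample,
                        status = status, age = round(age, 1), sex = sex,
                        smoking = smoking, cohort = cohort, chip = chip,
                        position = position, stringsAsFactors = FALSE)

    # Truth: disjoint DMP / DVP probe sets. Effects are injected at
    # intermediately methylated probes (baseline mean in [0.15, 0.85]):
    # mean shifts need headroom and methylation variability is only
    # expressible away from the fully (un)methylated boundaries.
    n_dmp <- as.integer(round(cfg$frac_dmp * n))
    n_dvp <- as.integer(round(cfg$frac_dvp * n))
    mu_beta <- 1 / (1 + 2^(-base$mu_m))
    eligible <- which(mu_beta >= 0.2 & mu_beta <= 0.8)
    if (!is.null(cell_reference)) {
      eligible <- setdiff(eligible,
                          match(attr(cell_reference, "marker_probes"),
                                probes))
    }
    if (length(eligible) < n_dmp + n_dvp) {
      stop_input("too few intermediately methylated probes for the ",
                 "requested effect fractions")
    }
    flagged <- sample(eligible, n_dmp + n_dvp)
    dmp_idx <- flagged[seq_len(n_dmp)]
    dvp_idx <- flagged[n_dmp + seq_len(n_dvp)]
    dvp_group <- character(0)
    if (n_dvp > 0L) {
      dvp_group <- ifelse(stats::runif(n_dvp) < cfg$dvp_case_prob,
                          "case", "control")
    }
    dvp_sign <- numeric(0)
    if (n_dvp > 0L) {
      dvp_sign <- ifelse(stats::runif(n_dvp) < cfg$dvp_hypo_prob, -1, 1)
    }
    truth <- data.frame(probe_id = probes,
                        is_dmp = FALSE, is_dvp = FALSE,
                        dvp_hypervariable_group = "",
                        true_delta = 0, true_v = 1,
                        true_dvp_delta = 0,
                        stringsAsFactors = FALSE)
    truth$is_dmp[dmp_idx] <- TRUE
    truth$true_delta[dmp_idx] <- cfg$delta_beta
    truth$is_dvp[dvp_idx] <- TRUE
    truth$dvp_hypervariable_group[dvp_idx] <- dvp_group
    truth$true_v[dvp_idx] <- cfg$var_inflation

    # M-scale signal: baseline + pair effect + individual residual.
    sd_pair <- base$sigma * sqrt(cfg$rho)
    sd_ind <- base$sigma * sqrt(1 - cfg$rho)
    pair_eff <- matrix(stats::rnorm(n * np), n, np) * sd_pair
    m <- base$mu_m + pair_eff[, rep(seq_len(np), each = 2L)] +
      matrix(stats::rnorm(n * ns), n, ns) * sd_ind
    # DVP injection: the hypervariable group's total M-scale variance is
    # inflated to v * sigma^2 by adding independent noise with variance
    # (v - 1) * sigma^2 on top of the shared pair structure, and its mean
    # is shifted by dvp_shift_sd * sigma (direction per dvp_sign).
    if (n_dvp > 0L) {
      # The inflation targets the observed per-probe group variance, so
      # the chip-batch and cell-mixture components are included. The
      # cell-mixture variance of offset' w under Dirichlet(a0 * p) is
      # (sum p_k off_k^2 - (sum p_k off_k)^2) / (a0 + 1).
      props <- cell_base_props(cfg$n_celltypes)
      a0 <- cfg$dirichlet_alpha * cfg$n_celltypes
      off <- base$cell_offsets[dvp_idx, , drop = FALSE]
      cell_var <- (off^2 %*% props - (off %*% props)^2) / (a0 + 1)
      tot_sd <- sqrt(base$sigma[dvp_idx]^2 + cfg$chip_sd^2 +
                       as.vector(cell_var))
      extra_sd <- tot_sd * sqrt(max(cfg$var_inflation - 1, 0))
      shift <- dvp_sign * cfg$dvp_shift_sd * tot_sd
      truth$true_dvp_delta[dvp_idx] <- shift
      case_cols <- which(status == "case")
      ctrl_cols <- which(status == "control")
      for (j in seq_len(n_dvp)) {
        cols <- if (dvp_group[j] == "case") case_cols else ctrl_cols
        m[dvp_idx[j], cols] <- m[dvp_idx[j], cols] + shift[j] +
          stats::rnorm(length(cols), 0, extra_sd[j])
      }
    }

    # Cell mixtures: per-sample Dirichlet weights move cell-sensitive
    # probes by the weight-centred reference offsets.
    props <- cell_base_props(cfg$n_celltypes)
    wts <- rdirichlet(ns, cfg$dirichlet_alpha * cfg$n_celltypes * props)
    colnames(wts) <- names(props)
    rownames(wts) <- sample_id
    m <- m + base$cell_offsets %*% t(wts - rep(props, each = ns))

    # With a reference panel, marker-probe baselines are the logit of the
    # per-sample mixture of reference profiles (pair/noise terms kept).
    if (!is.null(cell_reference)) {
      mk <- match(attr(cell_reference, "marker_probes"), probes)
      mix <- cell_reference[mk, , drop = FALSE] %*% t(wts)
      mix <- pmin(pmax(mix, 1e-4), 1 - 1e-4)
      m[mk, ] <- m[mk, ] - base$mu_m[mk] + log2(mix / (1 - mix))
    }

    # Chip batch offsets (shared by all samples on a chip).
    chip_levels <- sort(unique(chip))
    chip_off <- stats::rnorm(length(chip_levels), 0, cfg$chip_sd)
    m <- m + matrix(chip_off[match(chip, chip_levels)], n, ns, byrow = TRUE)

    beta <- 1 / (1 + 2^(-m))
    if (n_dmp > 0L) {
      beta[dmp_idx, status == "case"] <-
        beta[dmp_idx, status == "case"] + cfg$delta_beta
    }
    beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)
    dimnames(beta) <- list(probes, sample_id)

    # Intensities: U = (1 - beta) * S, M = beta * (U + 100) / (1 - beta),
    # which reproduces beta = M / (M + U + 100) exactly.
    s_tot <- matrix(stats::rlnorm(n * ns, log(3000), 0.3), n, ns)
    u_int <- (1 - beta) * s_tot
    m_int <- beta * (u_int + 100) / (1 - beta)
    dimnames(u_int) <- dimnames(m_int) <- dimnames(beta)

    detection_p <- matrix(stats::runif(n * ns, 0, 0.005), n, ns,
                          dimnames = dimnames(beta))
    n_fail <- as.integer(round(cfg$frac_fail_detp * n))
    if (n_fail > 0L) {
      fail_idx <- sample.int(n, n_fail)
      detection_p[fail_idx, ] <- stats::runif(n_fail * ns, 0.011, 0.6)
    }
    bead_count <- matrix(3L + stats::rpois(n * ns, 11), n, ns,
                         dimnames = dimnames(beta))
    n_low <- as.integer(round(cfg$frac_low_bead * n))
    if (n_low > 0L) {
      low_idx <- sample.int(n, n_low)
      n_aff <- as.integer(ceiling(0.08 * ns))
      for (i in low_idx) {
        cols <- sample.int(ns, n_aff)
        bead_count[i, cols] <- stats::rpois(n_aff, 1)
      }
    }

    list(beta = beta,
         intensities = list(m_int = m_int, u_int = u_int,
                            detection_p = detection_p,
                            bead_count = bead_count),
         sample_sheet = sheet, truth = truth, cell_fractions = wts,
         config = cfg)
  })
}

#' Generate a purified-cell reference methylome panel
#'
#' Builds a reference beta matrix (probes x cell types) with, for each cell
#' type, a designated block of strongly discriminating probes whose beta
#' values differ from all other types by at least 0.5 — the substrate for
#' reference-based (Houseman-style) deconvolution. With six cell types the
#' columns are named for the standard blood panel: CD8T, CD4T, NK, Bcell,
#' Mono, Gran.
#'
#' @param annotation Probe annotation table.
#' @param n_celltypes Number of cell types (at least 2).
#' @param seed Integer seed.
#' @param n_markers_per_type Number of discriminating probes per cell type.
#'
#' @return A probes x cell types beta matrix with attribute
#'   `marker_probes` (character vector of designated discriminating probes).
#' @export
generate_cell_reference <- function(annotation, n_celltypes = 6L, seed = 1L,
                                    n_markers_per_type = 100L) {
  if (n_celltypes < 2L) stop_input("n_celltypes must be at least 2")
  n <- nrow(annotation)
  k <- as.integer(n_celltypes)
  if (n < k * n_markers_per_type) {
    stop_input("annotation has too few probes for the requested markers")
  }
  with_seed(seed + 3000L, {
    base <- stats::rbeta(n, 0.8, 0.8)
    ref <- matrix(rep(base, k), n, k) +
      matrix(stats::rnorm(n * k, 0, 0.02), n, k)
    marker_idx <- sample.int(n, k * n_markers_per_type)
    marks <- split(marker_idx, rep(seq_len(k), each = n_markers_per_type))
    for (t in seq_len(k)) {
      idx <- marks[[t]]
      hi <- idx[seq_len(length(idx) %/% 2)]   # hypermethylated in type t
      lo <- setdiff(idx, hi)                  # hypomethylated in type t
      ref[hi, ] <- 0.15
      ref[hi, t] <- 0.90
      ref[lo, ] <- 0.90
      ref[lo, t] <- 0.15
    }
    ref <- pmin(pmax(ref, 0.01), 0.99)
    rownames(ref) <- annotation$IlmnID
    colnames(ref) <- names(cell_base_props(k))
    attr(ref, "marker_probes") <- annotation$IlmnID[marker_idx]
    ref
  })
}

#' Simulate an independent healthy reference cohort
#'
#' Draws unpaired healthy samples from the same per-probe baseline model as
#' the twin cohort (same mixture means, noise scales and cell-sensitive
#' probes for a given `config`), with no disease effects and no pair
#' structure. Used to assess whether a variability signature found in the
#' twin cohort is present in the general population.
#'
#' @param config A [synthetic_config()] object (its seed pins the shared
#'   baseline).
#' @param annotation Probe annotation with `config$n_probes` rows.
#' @param n_samples Number of samples (at least 2); 156 mirrors a typical
#'   population-reference subset.
#' @param seed Integer seed for the cohort-specific draws.
#' @param cell_reference Optional reference panel, treated as in
#'   [generate_twin_cohort()].
#'
#' @return A probes x samples beta matrix.
#' @export
generate_independent_cohort <- function(config, annotation,
                                        n_samples = 156L, seed = 1L,
                                        cell_reference = NULL) {
  validate_synthetic_config(config)
  if (nrow(annotation) != config$n_probes) {
    stop_input("annotation must have config$n_probes rows")
  }
  if (n_samples < 2L) stop_input("n_samples must be at least 2")
  cfg <- config
  n <- cfg$n_probes
  ns <- as.integer(n_samples)
  base <- baseline_probe_params(cfg, annotation)
  with_seed(seed + 4000L, {
    m <- base$mu_m + matrix(stats::rnorm(n * ns), n, ns) * base$sigma
    props <- cell_base_props(cfg$n_celltypes)
    wts <- rdirichlet(ns, cfg$dirichlet_alpha * cfg$n_celltypes * props)
    m <- m + base$cell_offsets %*% t(wts - rep(props, each = ns))
    if (!is.null(cell_reference)) {
      mk <- match(attr(cell_reference, "marker_probes"),
                  annotation$IlmnID)
      mix <- cell_reference[mk, , drop = FALSE] %*% t(wts)
      mix <- pmin(pmax(mix, 1e-4), 1 - 1e-4)
      m[mk, ] <- m[mk, ] - base$mu_m[mk] + log2(mix / (1 - mix))
    }
    beta <- 1 / (1 + 2^(-m))
    beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)
    dimnames(beta) <- list(annotation$IlmnID,
                           sprintf("IND%03d", seq_len(ns)))
    beta
  })
}
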