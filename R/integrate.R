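#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least the actual overlap between
#' two sets drawn from a common gene universe (the phyper test).
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of the gene universe.
#'
#' @return List of class `overlap_result`: `overlap`, `n_a`, `n_b`,
#'   `n_universe`, `p`, `method = "hypergeometric"`.
#' @export
gene_overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop_input("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_b),
                     length(universe) - length(set_b),
                     length(set_a), lower.tail = FALSE)
  structure(list(overlap = k, n_a = length(set_a), n_b = length(set_b),
                 n_universe = length(universe), p = p,
                 method = "hypergeometric"),
            class = "overlap_result")
}

#' Permutation test for probe-set overlap
#'
#' The observed overlap between a target probe set and a fixed external
#' set is compared with the overlaps of `n_perm` uniform random draws of
#' `|target|` probes from the background;
#' `p = (1 + #perm overlaps >= observed) / (n_perm + 1)`. Only the target
#' set is randomised — the external signature is conditioned on as
#' published.
#'
#' @param target_probes,external_probes Probe ID vectors, both subsets of
#'   `background`.
#' @param background Character vector of QC-passed probe IDs.
#' @param n_perm Number of permutations (a warning is issued below 100).
#' @param seed Integer seed (recorded in the result).
#'
#' @return List of class `overlap_result`: `overlap`, `n_target`,
#'   `n_external`, `n_background`, `p`, `n_perm`, `seed`,
#'   `method = "permutation"`.
#' @export
probe_overlap_permutation <- function(target_probes, external_probes,
                                      background, n_perm = 10000,
                                      seed = 1L) {
  target_probes <- unique(target_probes)
  external_probes <- unique(external_probes)
  background <- unique(background)
  if (!all(target_probes %in% background) ||
      !all(external_probes %in% background)) {
    stop_input("both probe sets must be subsets of the background")
  }
  if (n_perm < 100) warning("fewer than 100 permutations; p is unstable")
  obs <- length(intersect(target_probes, external_probes))
  in_ext <- background %in% external_probes
  n_t <- length(target_probes)
  hits <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(in_ext[sample.int(length(background), n_t)]),
           numeric(1))
  })
  p <- (1 + sum(hits >= obs)) / (n_perm + 1)
  structure(list(overlap = obs, n_target = n_t,
                 n_external = length(external_probes),
                 n_background = length(background), p = p,
                 n_perm = n_perm, seed = as.integer(seed),
                 method = "permutation"),
            class = "overlap_result")
}

#' Annotate a DVP table against a known-susceptibility gene list
#'
#' Intersects the genes carrying at least one DVP with a list of known
#' disease-associated genes and reports per-gene DVP probe counts.
#'
#' @param dvp DVP table from [ievora()].
#' @param annotation Probe annotation.
#' @param known_genes Nonempty character vector of gene symbols.
#'
#' @return Data frame `gene`, `n_dvp` (DVP probes mapping to the gene),
#'   sorted by decreasing count; zero rows when no listed gene carries a
#'   DVP.
#' @export
annotate_known_loci <- function(dvp, annotation, known_genes) {
  if (length(known_genes) == 0L) stop_input("known gene list is empty")
  empty <- data.frame(gene = character(0), n_dvp = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(dvp) == 0L) return(empty)
  g <- annotation$UCSC_RefGene_Name[match(dvp$probe_id, annotation$IlmnID)]
  per_probe <- lapply(strsplit(g, ";", fixed = TRUE),
                      function(v) unique(v[v != ""]))
  hits <- unlist(lapply(per_probe, function(v) v[v %in% known_genes]))
  if (length(hits) == 0L) return(empty)
  tab <- sort(table(hits), decreasing = TRUE)
  data.frame(gene = names(tab), n_dvp = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variance and range of a variability signature across cohorts
#'
#' For every probe in a DVP signature, computes the sample variance and
#' the range (max - min) of beta values in the case twins, the control
#' twins and an independent cohort, stratified by the direction of
#' hypervariability. Per-stratum, per-group quartiles of both statistics
#' are aggregated — the contract being that probes hypervariable in cases
#' should show their largest variance and range in the case group, and
#' comparable, lower values in controls and the independent population.
#'
#' @param dvp DVP table from [ievora()].
#' @param beta_case,beta_control,beta_independent Beta matrices (probes x
#'   samples) for the three groups. Probes missing from any matrix are
#'   excluded with a warning.
#'
#' @return List of class `signature_summary` with `per_probe` (data frame:
#'   probe_id, stratum, variance and range per group) and `aggregate`
#'   (data frame of quartiles per stratum x group x statistic).
#' @export
variability_signature_assessment <- function(dvp, beta_case, beta_control,
                                             beta_independent) {
  probes <- dvp$probe_id
  present <- probes %in% rownames(beta_case) &
    probes %in% rownames(beta_control) &
    probes %in% rownames(beta_independent)
  if (any(!present)) {
    warning(sum(!present), " DVP probe(s) missing from a matrix; excluded: ",
            paste(utils::head(probes[!present], 5), collapse = ", "))
  }
  probes <- probes[present]
  stratum <- ifelse(
    dvp$hypervariable_group[present] == "case",
    "hypervariable_in_case", "hypervariable_in_control")

  stat_block <- function(mat) {
    m <- mat[probes, , drop = FALSE]
    list(variance = row_vars(m),
         range = apply(m, 1, function(x) max(x) - min(x)))
  }
  gc <- stat_block(beta_case)
  gn <- stat_block(beta_control)
  gi <- stat_block(beta_independent)
  per_probe <- data.frame(
    probe_id = probes, stratum = stratum,
    var_case = gc$variance, var_control = gn$variance,
    var_independent = gi$variance,
    range_case = gc$range, range_control = gn$range,
    range_independent = gi$range,
    row.names = NULL, stringsAsFactors = FALSE)

  agg <- list()
  for (st in unique(stratum)) {
    sub <- per_probe[per_probe$stratum == st, ]
    for (grp in c("case", "control", "independent")) {
      for (what in c("var", "range")) {
        qs <- stats::quantile(sub[[paste(what, grp, sep = "_")]],
                              c(0.25, 0.5, 0.75))
        agg[[length(agg) + 1L]] <- data.frame(
          stratum = st, group = grp, statistic = what,
          q25 = qs[1], q50 = qs[2], q75 = qs[3],
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(per_probe = per_probe,
                 aggregate = do.call(rbind, agg)),
            class = "signature_summary")
}
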