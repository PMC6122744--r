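#' CpG feature enrichment by repeated random sampling
#'
#' Compares the annotation-category composition of a target probe set
#' (for example a DVP signature) with `n_draws` uniform random draws of
#' the same size from the QC-passed background. For each category level
#' the empirical enrichment p-value is
#' `(1 + #draws with count >= observed) / (n_draws + 1)`, and the
#' depletion p-value uses `<=`; both one-sided p-values are reported.
#'
#' @param target_probes Character vector of probe IDs (subset of the
#'   background).
#' @param annotation Background probe annotation (the QC-passed probes).
#' @param n_draws Number of random draws.
#' @param seed Integer seed.
#' @param categories Annotation columns to tabulate; empty strings are
#'   relabelled `"intergenic"`.
#'
#' @return Data frame with `family`, `category`, `observed`, `expected`,
#'   `fold`, `p_enriched`, `p_depleted`, `p` (the one-sided p matching
#'   `direction`), `direction`.
#' @export
feature_enrichment <- function(target_probes, annotation, n_draws = 1000,
                               seed = 1L,
                               categories = c("Relation_to_UCSC_CpG_Island",
                                              "UCSC_RefGene_Group")) {
  bg <- annotation$IlmnID
  if (length(target_probes) > length(bg)) {
    stop_input("target set is larger than the background")
  }
  if (!all(target_probes %in% bg)) {
    stop_input("target probes must be a subset of the background annotation")
  }
  n_t <- length(target_probes)
  t_idx <- match(target_probes, bg)

  cat_mats <- lapply(categories, function(cc) {
    v <- annotation[[cc]]
    v[v == ""] <- "intergenic"
    factor(v)
  })
  names(cat_mats) <- categories

  # One shared set of draws across category families.
  draw_counts <- with_seed(seed, {
    lapply(seq_len(n_draws), function(i) sample.int(length(bg), n_t))
  })

  out <- list()
  for (cc in categories) {
    f <- cat_mats[[cc]]
    lev <- levels(f)
    obs <- table(f[t_idx])
    cnt <- vapply(draw_counts, function(ix) as.vector(table(f[ix])),
                  numeric(length(lev)))
    if (length(lev) == 1L) cnt <- matrix(cnt, nrow = 1L)
    expd <- rowMeans(cnt)
    for (l in seq_along(lev)) {
      o <- as.vector(obs[lev[l]])
      p_enr <- (1 + sum(cnt[l, ] >= o)) / (n_draws + 1)
      p_dep <- (1 + sum(cnt[l, ] <= o)) / (n_draws + 1)
      fold <- if (expd[l] > 0) o / expd[l] else NA_real_
      dir <- if (!is.na(fold) && fold < 1) "depleted" else "enriched"
      out[[length(out) + 1L]] <- data.frame(
        family = cc, category = lev[l], observed = o,
        expected = expd[l], fold = fold,
        p_enriched = p_enr, p_depleted = p_dep,
        p = if (dir == "enriched") p_enr else p_dep,
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map probes to their annotated gene symbols
#'
#' Splits semicolon-delimited multi-gene annotations, removes duplicates,
#' and drops intergenic probes (empty annotation).
#'
#' @param probes Character vector of probe IDs.
#' @param annotation Probe annotation with `IlmnID` and
#'   `UCSC_RefGene_Name`.
#'
#' @return Character vector of unique gene symbols.
#' @export
map_probes_to_genes <- function(probes, annotation) {
  g <- annotation$UCSC_RefGene_Name[match(probes, annotation$IlmnID)]
  if (anyNA(g)) stop_input("annotation does not cover all probes")
  genes <- unlist(strsplit(g[g != ""], ";", fixed = TRUE))
  unique(genes[genes != ""])
}

# Wallenius noncentral hypergeometric pmf by numerical integration:
# P(X = x) for x in-set successes when n items are drawn without
# replacement from m1 in-set items (weight w) and m2 out-of-set items
# (weight 1).
wallenius_pmf <- function(x, n, m1, m2, w) {
  d <- w * (m1 - x) + (m2 - (n - x))
  if (d <= 0) d <- 1e-12
  f <- function(t) {
    r <- rep(1, length(t))
    if (x > 0) r <- r * (1 - t^(w / d))^x
    if (n - x > 0) r <- r * (1 - t^(1 / d))^(n - x)
    r
  }
  val <- stats::integrate(f, 0, 1, rel.tol = 1e-10,
                          subdivisions = 500L)$value
  exp(lchoose(m1, x) + lchoose(m2, n - x)) * val
}

# Upper-tail P(X >= x_obs) of the Wallenius distribution.
wallenius_tail <- function(x_obs, n, m1, m2, w) {
  if (abs(w - 1) < 1e-9) {
    return(stats::phyper(x_obs - 1, m1, m2, n, lower.tail = FALSE))
  }
  xs <- seq(max(x_obs, max(0, n - m2)), min(n, m1))
  if (length(xs) == 0L) return(0)
  min(1, sum(vapply(xs, wallenius_pmf, numeric(1),
                    n = n, m1 = m1, m2 = m2, w = w)))
}

#' Probe-number-bias-adjusted gene-set over-representation test
#'
#' Methylation arrays carry unequal numbers of probes per gene, so genes
#' with many probes are more likely to be "selected" by any probe-level
#' signature. This test estimates each gene's selection propensity as a
#' monotone (isotonic-regression) function of its probe count, summarises
#' the bias of each gene set as the odds
#' `mean weight inside set / mean weight outside`, and computes the
#' over-representation p-value from the upper tail of the Wallenius
#' noncentral hypergeometric distribution with those odds. With constant
#' probe counts the odds are 1 and the test reduces exactly to the central
#' hypergeometric. Results are ranked by p with no FDR correction across
#' sets (gene sets are not independent).
#'
#' @param selected_probes Probe IDs of the signature (for example DVPs).
#' @param annotation Probe annotation defining the gene universe.
#' @param gene_sets Named list of character vectors of gene symbols.
#'
#' @return Data frame: `set`, `n_set`, `n_selected_in_set`, `odds`, `p`,
#'   ranked by p. Empty sets (no genes in the universe) are skipped with
#'   a note.
#' @export
probe_bias_gene_test <- function(selected_probes, annotation, gene_sets) {
  # Gene universe and probe counts (multi-gene probes count once per gene).
  all_genes <- unlist(strsplit(
    annotation$UCSC_RefGene_Name[annotation$UCSC_RefGene_Name != ""],
    ";", fixed = TRUE))
  all_genes <- all_genes[all_genes != ""]
  counts <- table(all_genes)
  universe <- names(counts)
  n_probes_gene <- as.vector(counts)

  sel_genes <- map_probes_to_genes(selected_probes, annotation)
  sel <- as.numeric(universe %in% sel_genes)
  n_sel <- sum(sel)
  if (n_sel == 0L) stop_input("no selected probes map to genes")

  # Monotone bias curve: isotonic regression of the selection indicator on
  # probe count, floored so no gene has zero weight.
  ord <- order(n_probes_gene)
  iso <- stats::isoreg(n_probes_gene[ord], sel[ord])
  wgt <- numeric(length(universe))
  wgt[ord] <- iso$yf
  wgt <- pmax(wgt, 1e-6)

  res <- list()
  for (nm in names(gene_sets)) {
    in_set <- universe %in% gene_sets[[nm]]
    m1 <- sum(in_set)
    if (m1 == 0L) {
      message("gene set '", nm, "' has no genes in the universe; skipped")
      next
    }
    x_obs <- sum(sel == 1 & in_set)
    odds <- if (m1 == length(universe)) 1
            else mean(wgt[in_set]) / mean(wgt[!in_set])
    p <- wallenius_tail(x_obs, n = n_sel, m1 = m1,
                        m2 = length(universe) - m1, w = odds)
    res[[length(res) + 1L]] <- data.frame(
      set = nm, n_set = m1, n_selected_in_set = x_obs,
      odds = odds, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited GMT format: set name, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
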