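make_flat_annotation <- function(n, island = NULL, gene = NULL,
                                 feature = NULL) {
  data.frame(
    IlmnID = sprintf("cg%05d", seq_len(n)),
    CHR = "1", MAPINFO = seq_len(n),
    Infinium_Design_Type = "II",
    Relation_to_UCSC_CpG_Island =
      if (is.null(island)) "OpenSea" else island,
    UCSC_RefGene_Name = if (is.null(gene)) "" else gene,
    UCSC_RefGene_Group = if (is.null(feature)) "" else feature,
    SNP_within_2bp = FALSE, Cross_reactive = FALSE,
    stringsAsFactors = FALSE)
}

test_that("feature enrichment is exact at its degenerate extremes", {
  ann <- make_flat_annotation(
    300, island = rep(c("Island", "OpenSea"), c(30, 270)))
  # target = background: fold 1 and p 1 everywhere
  full <- feature_enrichment(ann$IlmnID, ann, n_draws = 200, seed = 1)
  isl <- full[full$family == "Relation_to_UCSC_CpG_Island", ]
  expect_true(all(abs(isl$fold - 1) < 1e-12))
  expect_true(all(isl$p == 1))

  # target = exactly the Island probes: minimal attainable p
  res <- feature_enrichment(ann$IlmnID[1:30], ann, n_draws = 500, seed = 2)
  row <- res[res$category == "Island", ]
  expect_equal(row$observed, 30)
  expect_equal(row$p_enriched, 1 / 501)
  expect_identical(row$direction, "enriched")
  expect_error(feature_enrichment(c(ann$IlmnID, "cgX"), ann), "larger")
  expect_error(feature_enrichment(c(ann$IlmnID[1:5], "cgX"), ann), "subset")
})

test_that("empirical enrichment p converges to the hypergeometric tail", {
  ann <- make_flat_annotation(
    200, island = rep(c("Island", "OpenSea"), c(60, 140)))
  set.seed(3)
  target <- sample(ann$IlmnID, 50)
  obs <- sum(target %in% ann$IlmnID[1:60])
  res <- feature_enrichment(target, ann, n_draws = 10000, seed = 4)
  row <- res[res$category == "Island", ]
  exact <- stats::phyper(obs - 1, 60, 140, 50, lower.tail = FALSE)
  expect_equal(row$p_enriched, exact, tolerance = 0.02)

  # over seeds, mean fold for a uniform random target is about 1
  folds <- vapply(1:10, function(s) {
    tg <- with(list(), {set.seed(100 + s); sample(ann$IlmnID, 50)})
    r <- feature_enrichment(tg, ann, n_draws = 100, seed = s)
    r$fold[r$category == "Island"]
  }, numeric(1))
  expect_equal(mean(folds), 1, tolerance = 0.15)
})

test_that("probe-to-gene mapping splits, deduplicates and drops intergenic", {
  ann <- make_flat_annotation(4, gene = c("A;B;A", "", "B", "C"))
  expect_setequal(map_probes_to_genes(ann$IlmnID[1], ann), c("A", "B"))
  expect_length(map_probes_to_genes(ann$IlmnID[2], ann), 0)
  all_g <- map_probes_to_genes(ann$IlmnID, ann)
  per <- unique(unlist(lapply(ann$IlmnID, map_probes_to_genes, ann)))
  expect_setequal(all_g, per)
})

test_that("Wallenius tail matches enumeration and the central special case", {
  # sequential biased-urn enumeration oracle, weight w for in-set items
  urn_tail <- function(x_obs, n, m1, m2, w) {
    total <- new.env()
    recur <- function(ri, ro, k, pr, x) {
      if (k == 0) {
        key <- as.character(x)
        assign(key, mget(key, envir = total, ifnotfound = 0)[[1]] + pr,
               envir = total)
        return(invisible())
      }
      z <- ri * w + ro
      if (ri > 0) recur(ri - 1, ro, k - 1, pr * ri * w / z, x + 1)
      if (ro > 0) recur(ri, ro - 1, k - 1, pr * ro / z, x)
    }
    recur(m1, m2, n, 1, 0)
    sum(vapply(x_obs:n, function(x) {
      mget(as.character(x), envir = total, ifnotfound = 0)[[1]]
    }, numeric(1)))
  }
  for (w in c(0.5, 2, 3.7)) {
    for (x in 0:3) {
      expect_equal(twinvar:::wallenius_tail(x, 3, 4, 3, w),
                   urn_tail(x, 3, 4, 3, w), tolerance = 1e-9)
    }
  }
  # odds 1 reduces to the central hypergeometric: draw 5 of 10-in-set/20
  expect_equal(twinvar:::wallenius_tail(5, 5, 10, 10, 1),
               1 / choose(20, 5) * choose(10, 5), tolerance = 1e-12)
})

test_that("gene-set test reduces to phyper with constant probe counts", {
  # every gene has exactly 2 probes, so the bias weight is constant
  genes <- sprintf("G%03d", 1:60)
  ann <- make_flat_annotation(120, gene = rep(genes, each = 2))
  sel_probes <- ann$IlmnID[ann$UCSC_RefGene_Name %in% genes[1:15]]
  sets <- list(hit = genes[1:20], miss = genes[41:60])
  res <- probe_bias_gene_test(sel_probes, ann, sets)
  x <- sum(genes[1:15] %in% sets$hit)
  exact <- stats::phyper(x - 1, 20, 40, 15, lower.tail = FALSE)
  expect_equal(res$p[res$set == "hit"], exact, tolerance = 1e-6)
  expect_equal(res$odds[res$set == "hit"], 1, tolerance = 1e-9)
})

test_that("probe-count bias inflates unadjusted significance", {
  # 10 'large' genes with 30 probes each, 90 small genes with 1 probe
  genes <- c(rep(sprintf("BIG%02d", 1:10), each = 30),
             sprintf("SMALL%02d", 1:90))
  ann <- make_flat_annotation(length(genes), gene = genes)
  set.seed(9)
  # selection purely proportional to probe count: sample probes uniformly
  sel_probes <- sample(ann$IlmnID, 60)
  big_set <- list(big = sprintf("BIG%02d", 1:10))
  res <- probe_bias_gene_test(sel_probes, ann, big_set)
  sel_genes <- map_probes_to_genes(sel_probes, ann)
  x <- sum(sel_genes %in% big_set$big)
  p_central <- stats::phyper(x - 1, 10, 90, length(sel_genes),
                             lower.tail = FALSE)
  # the bias-adjusted p must not overstate the evidence
  expect_gt(res$p, p_central)
})

test_that("GMT files round-trip and agree with the fgsea reader", {
  sets <- list(alpha = c("A", "B", "C"), beta = c("B", "D"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back, sets)
  skip_if_not_installed("fgsea")
  expect_identical(lapply(fgsea::gmtPathways(path), identity), sets)
})
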