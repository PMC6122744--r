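test_that("hypergeometric overlap test matches combinatorial counts", {
  universe <- sprintf("G%02d", 1:10)
  a <- universe[1:5]; b <- universe[1:5]
  res <- gene_overlap_test(a, b, universe)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

  disj <- gene_overlap_test(universe[1:3], universe[4:6], universe)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$p, 1)

  # A subset of B: tail at the maximal attainable overlap, by enumeration
  sub <- gene_overlap_test(universe[1:2], universe[1:6], universe)
  # P(overlap >= 2) drawing 2 from 10 with 6 marked = C(6,2)/C(10,2)
  expect_equal(sub$p, choose(6, 2) / choose(10, 2), tolerance = 1e-12)
  expect_error(gene_overlap_test(c(a, "ZZ"), b, universe), "subsets")
})

test_that("permutation overlap p behaves at the extremes and converges", {
  bg <- sprintf("cg%04d", 1:1000)
  # external set = background: every draw overlaps fully
  full <- probe_overlap_permutation(bg[1:50], bg, bg, n_perm = 200, seed = 1)
  expect_equal(full$p, 1)

  # target identical to a tiny external set in a large background
  ident <- probe_overlap_permutation(bg[1:5], bg[1:5], bg,
                                     n_perm = 999, seed = 2)
  expect_equal(ident$p, 1 / 1000)

  # convergence to the hypergeometric tail on a 1000-probe toy
  ext <- bg[1:100]
  tgt <- bg[c(1:20, 501:580)]
  perm <- probe_overlap_permutation(tgt, ext, bg, n_perm = 10000, seed = 3)
  exact <- stats::phyper(perm$overlap - 1, 100, 900, 100,
                         lower.tail = FALSE)
  expect_equal(perm$p, exact, tolerance = 0.02)
  expect_equal(perm$seed, 3L)
  expect_warning(probe_overlap_permutation(bg[1:5], bg[1:5], bg,
                                           n_perm = 50, seed = 1),
                 "permutations")
  expect_error(probe_overlap_permutation(c(bg[1:3], "x"), bg[1:5], bg),
               "background")
})

test_that("known-locus annotation counts DVP probes per listed gene", {
  ann <- data.frame(
    IlmnID = sprintf("cg%02d", 1:6),
    CHR = "1", MAPINFO = 1:6, Infinium_Design_Type = "II",
    Relation_to_UCSC_CpG_Island = "OpenSea",
    UCSC_RefGene_Name = c("JAZF1", "JAZF1", "BLK", "OTHER", "", "CLNK;BLK"),
    UCSC_RefGene_Group = "Body",
    SNP_within_2bp = FALSE, Cross_reactive = FALSE,
    stringsAsFactors = FALSE)
  dvp <- data.frame(probe_id = sprintf("cg%02d", c(1, 2, 3, 4, 6)),
                    stringsAsFactors = FALSE)
  known <- c("JAZF1", "BLK", "CLNK", "NFKBIE", "ICOSLG")
  res <- annotate_known_loci(dvp, ann, known)
  expect_equal(res$n_dvp[res$gene == "JAZF1"], 2)
  expect_equal(res$n_dvp[res$gene == "BLK"], 2)
  expect_equal(res$n_dvp[res$gene == "CLNK"], 1)
  expect_false("OTHER" %in% res$gene)
  expect_lte(sum(res$n_dvp), 2 * nrow(dvp))

  empty <- annotate_known_loci(dvp[0, , drop = FALSE], ann, known)
  expect_equal(nrow(empty), 0)
  expect_error(annotate_known_loci(dvp, ann, character(0)), "empty")
})

test_that("signature assessment computes variance/range per cohort", {
  probes <- c("cg01", "cg02")
  dvp <- data.frame(probe_id = probes,
                    hypervariable_group = c("case", "control"),
                    stringsAsFactors = FALSE)
  mk <- function(vals) {
    matrix(vals, 2, 3, byrow = TRUE,
           dimnames = list(probes, c("s1", "s2", "s3")))
  }
  bc <- mk(c(0.2, 0.5, 0.9, 0.4, 0.4, 0.4))
  bn <- mk(c(0.3, 0.3, 0.3, 0.4, 0.4, 0.4))
  bi <- mk(c(0.25, 0.25, 0.25, 0.4, 0.4, 0.4))
  res <- variability_signature_assessment(dvp, bc, bn, bi)
  pp <- res$per_probe
  expect_equal(pp$range_case[pp$probe_id == "cg01"], 0.7)
  expect_equal(pp$var_control[pp$probe_id == "cg01"], 0)
  expect_equal(pp$range_independent[pp$probe_id == "cg02"], 0)
  expect_true(all(res$aggregate$q25 <= res$aggregate$q75))

  # missing probes are excluded with a warning
  expect_warning(
    variability_signature_assessment(dvp, bc[1, , drop = FALSE], bn, bi),
    "excluded")
})

test_that("case-hypervariable strata show their variance in the cases", {
  cfg <- synthetic_config(n_pairs = 40, n_probes = 4000, frac_dmp = 0,
                          frac_dvp = 0.01, var_inflation = 4,
                          dvp_case_prob = 1, seed = 41)
  ann <- generate_probe_annotation(4000, seed = 41)
  co <- generate_twin_cohort(cfg, ann)
  ind <- generate_independent_cohort(cfg, ann, n_samples = 60, seed = 42)
  truth_dvp <- co$truth[co$truth$is_dvp, ]
  dvp <- data.frame(probe_id = truth_dvp$probe_id,
                    hypervariable_group = truth_dvp$dvp_hypervariable_group,
                    stringsAsFactors = FALSE)
  case <- co$sample_sheet$status == "case"
  res <- variability_signature_assessment(
    dvp, co$beta[, case], co$beta[, !case], ind)
  agg <- res$aggregate
  med <- function(grp) {
    agg$q50[agg$stratum == "hypervariable_in_case" &
              agg$group == grp & agg$statistic == "var"]
  }
  expect_gt(med("case"), med("control"))
  expect_gt(med("case"), med("independent"))
})
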