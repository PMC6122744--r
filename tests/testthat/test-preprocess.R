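test_that("filter_probes removes one probe per defect class", {
  toy <- make_qc_toy(n_clean = 5, n_samples = 40)
  out <- filter_probes(toy$beta, toy$annotation,
                       detection_p = toy$detection_p,
                       bead_count = toy$bead_count)
  expect_equal(out$report$n_retained, 5)
  expect_equal(out$report$n_sex_chromosome, 1)
  expect_equal(out$report$n_snp_within_2bp, 1)
  expect_equal(out$report$n_cross_reactive, 1)
  expect_equal(out$report$n_detection_p, 1)
  expect_equal(out$report$n_low_bead_count, 1)
  expect_equal(out$report$n_removed, 5)
  expect_equal(nrow(out$beta), out$report$n_retained)

  # idempotence: filtering the filtered matrix changes nothing
  again <- filter_probes(out$beta, toy$annotation)
  expect_identical(again$beta, out$beta)

  # all-clean input is returned unchanged
  clean <- filter_probes(toy$beta[6:10, ], toy$annotation)
  expect_identical(clean$beta, toy$beta[6:10, ])
})

test_that("bead-count rule triggers exactly at the 5% boundary", {
  toy <- make_qc_toy(n_clean = 5, n_samples = 40)
  k <- ceiling(0.05 * 40)   # = 2 failing samples trips the rule
  bead <- matrix(10L, 10, 40, dimnames = dimnames(toy$beta))
  bead[6, seq_len(k)] <- 2L
  bead[7, seq_len(k - 1)] <- 2L
  out <- filter_probes(toy$beta[6:10, ], toy$annotation,
                       bead_count = bead[6:10, ])
  expect_false("cg00000006" %in% rownames(out$beta))
  expect_true("cg00000007" %in% rownames(out$beta))
})

test_that("detection-p rule supports any-sample and fraction readings", {
  toy <- make_qc_toy(n_clean = 5, n_samples = 40)
  out_any <- filter_probes(toy$beta, toy$annotation,
                           detection_p = toy$detection_p)
  expect_equal(out_any$report$n_detection_p, 1)
  # single failing sample (2.5% of 40) is below the 5% fraction threshold
  out_frac <- filter_probes(toy$beta, toy$annotation,
                            detection_p = toy$detection_p,
                            detp_rule = "fraction")
  expect_equal(out_frac$report$n_detection_p, 0)
})

test_that("compute_beta applies the offset convention", {
  m <- matrix(c(900, 0), 1, 2, dimnames = list("cg1", c("a", "b")))
  u <- matrix(c(0, 0), 1, 2, dimnames = dimnames(m))
  b <- compute_beta(m, u)
  expect_equal(b[1, 1], 0.9)
  expect_equal(b[1, 2], 0)
  expect_error(compute_beta(-m, u), "nonnegative")
})

test_that("beta/M transforms are exact, monotone and mutually inverse", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(1), log2((1 - 1e-6) / 1e-6))
  b <- seq(0.01, 0.99, by = 0.01)
  m <- beta_to_m(b)
  expect_true(all(diff(m) > 0))
  expect_equal(m_to_beta(m), b, tolerance = 1e-12)
  expect_error(beta_to_m(1.2), "0, 1")
})

test_that("probe-type normalisation fixes equal distributions and shrinks KS", {
  ids <- sprintf("cg%08d", 1:60)
  ann <- data.frame(IlmnID = ids,
                    Infinium_Design_Type = rep(c("I", "II"), each = 30),
                    stringsAsFactors = FALSE)
  vals <- seq(0.05, 0.95, length.out = 30)
  beta_same <- matrix(c(vals, vals), 60, 2,
                      dimnames = list(ids, c("s1", "s2")))
  out <- normalize_type_bias(beta_same, ann)
  expect_lt(max(abs(out - beta_same)), 1e-9)

  # shifted type II: the between-type KS distance must decrease
  set.seed(1)
  b1 <- runif(30, 0.2, 0.8)
  b2 <- pmin(runif(30, 0.2, 0.8) + 0.1, 0.99)
  beta_shift <- matrix(c(b1, b2), 60, 1, dimnames = list(ids, "s1"))
  norm <- normalize_type_bias(beta_shift, ann)
  ks_pre <- suppressWarnings(
    stats::ks.test(beta_shift[1:30, 1], beta_shift[31:60, 1]))$statistic
  ks_post <- suppressWarnings(
    stats::ks.test(norm[1:30, 1], norm[31:60, 1]))$statistic
  expect_lt(ks_post, ks_pre)
  # ranks within each type are preserved
  expect_identical(order(norm[1:30, 1]), order(beta_shift[1:30, 1]))
  expect_identical(order(norm[31:60, 1]), order(beta_shift[31:60, 1]))
})

test_that("PCA screen finds self-associated factors and stays calibrated", {
  set.seed(2)
  m <- matrix(rnorm(200 * 30), 200, 30,
              dimnames = list(sprintf("cg%03d", 1:200),
                              sprintf("s%02d", 1:30)))
  m[1:50, 1:15] <- m[1:50, 1:15] + 2   # structure driving PC1
  pre <- pca_covariate_screen(m, data.frame(dummy = rnorm(30)), n_pcs = 5)
  factors <- data.frame(self = pre$scores[, 1], noise = rnorm(30))
  scr <- pca_covariate_screen(m, factors, n_pcs = 5)
  expect_lt(scr$p_values["self", "PC1"], 1e-10)
  expect_true("self" %in% scr$selected)
  expect_true(all(diff(scr$variance_explained) <= 1e-12))

  # constant factor is skipped with a note
  scr2 <- pca_covariate_screen(m, data.frame(const = rep(1, 30)), n_pcs = 3)
  expect_match(scr2$notes, "constant")

  # a pure-noise factor attains p < 0.05 at roughly the nominal rate
  hits <- 0; total <- 0
  set.seed(3)
  for (r in 1:60) {
    sc <- pca_covariate_screen(m, data.frame(noise = rnorm(30)), n_pcs = 4)
    hits <- hits + sum(sc$p_values < 0.05)
    total <- total + length(sc$p_values)
  }
  expect_gt(hits / total, 0.005)
  expect_lt(hits / total, 0.15)
})

test_that("MDS separates constructed clusters and not random labels", {
  set.seed(4)
  base <- matrix(runif(300 * 24, 0.2, 0.8), 300, 24,
                 dimnames = list(sprintf("cg%03d", 1:300),
                                 sprintf("s%02d", 1:24)))
  base[1:50, 1:12] <- base[1:50, 1:12] + 0.5
  groups <- rep(c("a", "b"), each = 12)
  res <- mds_top_variable(base, groups, k = 100)
  expect_gt(res$separation, 0.5)

  rand <- mds_top_variable(base, sample(groups), k = 100)
  expect_lt(abs(rand$separation), 0.25)
  expect_error(mds_top_variable(base, groups, k = 1), "at least 2")

  # cross-check the in-package silhouette against cluster::silhouette
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(factor(groups)),
                             stats::dist(res$coordinates))
  expect_equal(res$separation, mean(sil[, "sil_width"]), tolerance = 1e-8)
})
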