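test_that("BH adjustment matches hand computations and edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  q <- bh_adjust(c(0.9, 0.01, 0.5))
  expect_true(all(q >= c(0.9, 0.01, 0.5)))
})

test_that("BH agrees with a brute-force step-up oracle on random vectors", {
  set.seed(7)
  for (r in 1:20) {
    p <- runif(50)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("group mean summary reproduces a published-style worked example", {
  sheet <- make_pair_sheet(2)
  beta <- matrix(c(0.800, 0.763, 0.800, 0.763,   # case/ctrl alternating
                   0.5, 0.5, 0.5, 0.5,
                   0, 0, 1, 1),
                 3, 4, byrow = TRUE,
                 dimnames = list(c("cgA", "cgB", "cgC"), sheet$sample_id))
  gm <- summarize_group_means(beta, sheet)
  expect_equal(gm$mean_beta_control[1], 0.763)
  expect_equal(gm$mean_beta_case[1], 0.800)
  expect_equal(gm$diff[1], 0.037)
  expect_equal(gm$diff[2], 0)
  expect_equal(gm$mean_beta_case[3], 0.5)
  expect_equal(gm$diff[3], 0)
})

test_that("mixed model without covariates reproduces the paired t-test", {
  cfg <- synthetic_config(n_pairs = 30, n_probes = 80, frac_dmp = 0.05,
                          frac_dvp = 0, seed = 13)
  ann <- generate_probe_annotation(80, seed = 13)
  co <- generate_twin_cohort(cfg, ann)
  sheet <- co$sample_sheet
  dmp <- fit_dmp_model(co$beta, sheet)
  expect_true(all(dmp$q >= dmp$p))
  expect_equal(dmp$diff, dmp$mean_beta_case - dmp$mean_beta_control,
               tolerance = 1e-12)

  case <- sheet$status == "case"
  map <- match(sheet$pair_id[!case], sheet$pair_id[case])
  for (pid in dmp$probe_id[c(1, 40, 80)]) {
    y <- co$beta[pid, ]
    d <- y[case][map] - y[!case]
    tt <- stats::t.test(d)
    expect_equal(dmp$p[dmp$probe_id == pid], tt$p.value, tolerance = 1e-8)
    expect_equal(dmp$estimate[dmp$probe_id == pid], mean(d),
                 tolerance = 1e-6)
  }
})

test_that("mixed model is invariant to column order and label swapping", {
  cfg <- synthetic_config(n_pairs = 15, n_probes = 20, frac_dmp = 0.1,
                          frac_dvp = 0, seed = 17)
  ann <- generate_probe_annotation(20, seed = 17)
  co <- generate_twin_cohort(cfg, ann)
  sheet <- co$sample_sheet
  base <- fit_dmp_model(co$beta, sheet)

  perm <- sample(ncol(co$beta))
  shuffled <- fit_dmp_model(co$beta[, perm], sheet)
  expect_equal(base$p, shuffled$p, tolerance = 1e-10)

  flipped_sheet <- sheet
  flipped_sheet$status <- ifelse(sheet$status == "case", "control", "case")
  flipped <- fit_dmp_model(co$beta, flipped_sheet)
  j <- match(base$probe_id, flipped$probe_id)
  expect_equal(base$estimate, -flipped$estimate[j], tolerance = 1e-8)
  expect_equal(base$p, flipped$p[j], tolerance = 1e-8)
})

test_that("a strong injected mean shift reaches FDR significance", {
  # delta = 0.1 against within-pair residual SD 0.03 at 79 pairs
  set.seed(19)
  sheet <- make_pair_sheet(79)
  n <- 200
  beta <- matrix(0.5 + rep(rnorm(79 * n, 0, 0.03), each = 2) +
                   rnorm(2 * 79 * n, 0, 0.03),
                 n, 158, byrow = TRUE,
                 dimnames = list(sprintf("cg%03d", 1:n), sheet$sample_id))
  beta[1, sheet$status == "case"] <- beta[1, sheet$status == "case"] + 0.1
  beta <- pmin(pmax(beta, 0), 1)
  dmp <- fit_dmp_model(beta, sheet)
  expect_lt(dmp$q[dmp$probe_id == "cg001"], 0.05)
  expect_equal(dmp$probe_id[1], "cg001")
})

test_that("non-discordant pairs and unknown samples are rejected", {
  sheet <- make_pair_sheet(5)
  beta <- matrix(0.5, 2, 10,
                 dimnames = list(c("a", "b"), sheet$sample_id))
  bad <- sheet
  bad$status[2] <- "case"
  expect_error(fit_dmp_model(beta, bad), "one case and one control")
})

test_that("paired power is exact at the null, saturates, and inverts", {
  expect_equal(ewas_power(79, 0, sd_d = 0.05), 0.05, tolerance = 1e-10)
  expect_gt(ewas_power(79, 0.5, sd_d = 0.05), 0.999)
  expect_error(ewas_power(79, 0.04, sd_d = 0), "sd_d")

  # sd at which power for delta = 0.04 crosses 80% at n = 79
  f <- function(s) ewas_power(79, 0.04, sd_d = s) - 0.8
  s80 <- stats::uniroot(f, c(0.01, 1), tol = 1e-10)$root
  expect_equal(ewas_power(79, 0.04, sd_d = s80), 0.8, tolerance = 1e-6)
  # simulation oracle at that sd
  set.seed(23)
  hits <- mean(replicate(2000, {
    stats::t.test(rnorm(79, 0.04, s80))$p.value < 0.05
  }))
  expect_equal(hits, 0.8, tolerance = 0.04)
  # power decreases with noise
  expect_gt(ewas_power(79, 0.04, s80 * 0.8), 0.8)
  expect_lt(ewas_power(79, 0.04, s80 * 1.2), 0.8)
})
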