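# Shared fixture builders; everything is generated in code at test time.

# A tiny aligned beta/detection/bead fixture with one probe per QC defect
# class and `n_clean` clean probes.
make_qc_toy <- function(n_clean = 5, n_samples = 40) {
  n <- n_clean + 5
  ids <- sprintf("cg%08d", seq_len(n))
  ann <- data.frame(
    IlmnID = ids,
    CHR = c("X", rep("7", n - 1)),
    MAPINFO = seq_len(n) * 1000L,
    Infinium_Design_Type = rep(c("I", "II"), length.out = n),
    Relation_to_UCSC_CpG_Island = "OpenSea",
    UCSC_RefGene_Name = "GENE1",
    UCSC_RefGene_Group = "Body",
    SNP_within_2bp = c(FALSE, TRUE, rep(FALSE, n - 2)),
    Cross_reactive = c(FALSE, FALSE, TRUE, rep(FALSE, n - 3)),
    stringsAsFactors = FALSE)
  beta <- matrix(0.5, n, n_samples,
                 dimnames = list(ids, sprintf("S%02d", seq_len(n_samples))))
  detp <- matrix(0.001, n, n_samples, dimnames = dimnames(beta))
  detp[4, 1] <- 0.02                      # detection failure, one sample
  bead <- matrix(10L, n, n_samples, dimnames = dimnames(beta))
  k <- ceiling(0.05 * n_samples)
  bead[5, seq_len(k)] <- 2L               # low bead count in >= 5% samples
  list(beta = beta, annotation = ann, detection_p = detp,
       bead_count = bead)
}

# A balanced discordant-pair sample sheet.
make_pair_sheet <- function(n_pairs) {
  pair <- sprintf("P%03d", seq_len(n_pairs))
  data.frame(
    sample_id = as.vector(rbind(paste0(pair, "_case"),
                                paste0(pair, "_ctrl"))),
    pair_id = rep(pair, each = 2),
    status = rep(c("case", "control"), n_pairs),
    age = rep(50, 2 * n_pairs),
    sex = "F", smoking = "never", cohort = "cohort1",
    chip = "chip01", position = "R01C01",
    stringsAsFactors = FALSE)
}

# Independent step-up BH oracle: q_i = min over ranks j >= rank(i) of
# n * p_(j) / j, capped at 1 (computed by explicit search, not cummin).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    ri <- which(o == i)
    cand <- vapply(ri:n, function(j) n * p[o[j]] / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}
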