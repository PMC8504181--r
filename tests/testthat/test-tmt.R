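test_that("reference-channel normalization aligns runs and is idempotent", {
  # single run: unchanged
  rt1 <- make_reporter_fixture()
  expect_equal(normalize_reference_channels(rt1)$intensity, rt1$intensity)

  # run B = 2x run A: B shifted by -1 in log2, medians equal
  rtA <- make_reporter_fixture(run_id = "runA")
  rtB <- rtA
  rtB$run_id <- "runB"
  rtB$psm_id <- sub("psm", "psmB", rtB$psm_id)
  rtB$intensity <- 2 * rtB$intensity
  out <- normalize_reference_channels(rbind(rtA, rtB))
  expect_equal(out$intensity[out$run_id == "runB"],
               rtA$intensity, tolerance = 1e-12)

  # arbitrary 2-run table: reference medians equal after transform; idempotent
  set.seed(3)
  rtA <- make_reporter_fixture(profile = rnorm(9, 10), run_id = "runA")
  rtB <- make_reporter_fixture(profile = rnorm(9, 12), run_id = "runB")
  rtB$psm_id <- sub("psm", "psmB", rtB$psm_id)
  out <- normalize_reference_channels(rbind(rtA, rtB))
  med <- tapply(seq_len(nrow(out)), out$run_id, function(i) {
    sub <- out[i, ]
    median(log2(sub$intensity[sub$condition == "APEX_TTX"]))
  })
  expect_lt(abs(med[["runA"]] - med[["runB"]]), 1e-9)
  again <- normalize_reference_channels(out)
  expect_equal(again$intensity, out$intensity, tolerance = 1e-12)

  # within-run ratios are preserved exactly
  rb <- out$intensity[out$run_id == "runB"]
  expect_equal(rb / rb[1], rtB$intensity / rtB$intensity[1], tolerance = 1e-12)

  # run without reference channels errors, naming the run
  rtC <- rtA[rtA$condition != "APEX_TTX", ]
  rtC$run_id <- "runC"
  expect_error(normalize_reference_channels(rbind(rtA, rtC)), "runC")
})

test_that("downstream calls are invariant to per-run intensity rescaling", {
  set.seed(11)
  sim <- simulate_tmt_psms(tmt_sim_config(n_proteins = 40), seed = 5)
  rt <- sim$reporter_table
  rt2 <- rt
  rt2$intensity <- rt2$intensity * 7.3  # one run: constant rescale
  r1 <- tmt_enrich(rt)
  r2 <- tmt_enrich(rt2)
  expect_equal(r1$enriched, r2$enriched)
  expect_equal(r1$control_results$log2FC, r2$control_results$log2FC,
               tolerance = 1e-9)
})

test_that("protein summarization by median polish behaves as specified", {
  # one PSM: profile equals that PSM's log2 intensities
  prof <- c(10, 11, 9, 12, 10.5, 9.5, 11.5, 10, 12.5)
  rt <- make_reporter_fixture(profile = prof, n_psm = 1)
  pam <- summarize_protein_medpolish(rt)
  got <- pam$log2_abundance["P1", ]
  layout <- tmt9_layout()
  key <- paste(layout$condition, layout$replicate, sep = ".")
  expect_equal(unname(got[key]), prof, tolerance = 1e-10)

  # PSM offsets (additive rows) do not move the column profile differences
  rt2 <- make_reporter_fixture(profile = prof, n_psm = 3,
                               psm_offsets = c(-1, 0, 2))
  pam2 <- summarize_protein_medpolish(rt2)
  got2 <- pam2$log2_abundance["P1", key]
  expect_equal(unname(diff(got2)), diff(prof), tolerance = 1e-9)

  # a protein with no observed intensity is omitted with a warning
  rt3 <- make_reporter_fixture(n_psm = 1)
  rt_na <- make_reporter_fixture(n_psm = 1, protein_id = "P2")
  rt_na$intensity <- NA_real_
  expect_warning(pam3 <- summarize_protein_medpolish(rbind(rt3, rt_na)), "P2")
  expect_equal(rownames(pam3$log2_abundance), "P1")
})

test_that("shared peptides are dropped before summarization", {
  rt <- make_reporter_fixture(n_psm = 2)
  shared <- make_reporter_fixture(n_psm = 1, protein_id = "P2")
  shared$peptide_id <- "P1_pep1"  # now maps to P1 and P2
  both <- rbind(rt, shared)
  both$peptide_id[both$protein_id == "P1" & both$peptide_id == "P1_pep1"] <-
    "P1_pep1"
  kept <- drop_shared_peptides(both)
  expect_false("P1_pep1" %in% kept$peptide_id)
  expect_true("P1_pep2" %in% kept$peptide_id)
})

test_that("pooled-variance contrast matches the t-distribution oracle", {
  layout <- tmt9_layout()
  samples <- data.frame(sample_id = paste(layout$condition, layout$replicate,
                                          sep = "."),
                        condition = layout$condition,
                        replicate = layout$replicate)
  ab <- matrix(NA_real_, nrow = 2, ncol = 9,
               dimnames = list(c("PA", "PB"), samples$sample_id))
  # PA: identical groups -> log2FC 0, p 1
  ab["PA", samples$condition == "APEX_BIC"] <- c(5, 6, 7)
  ab["PA", samples$condition == "APEX_TTX"] <- c(5, 6, 7)
  # PB: a = {1,2,3}, b = {4,5,6} -> log2FC -3, pooled t with df 4
  ab["PB", samples$condition == "APEX_BIC"] <- c(1, 2, 3)
  ab["PB", samples$condition == "APEX_TTX"] <- c(4, 5, 6)
  pam <- structure(list(log2_abundance = ab, samples = samples),
                   class = "protein_abundance")
  res <- contrast_test(pam, "APEX_BIC", "APEX_TTX")
  pa <- res[res$protein_id == "PA", ]
  expect_equal(pa$log2FC, 0)
  expect_equal(pa$p, 1)
  pb <- res[res$protein_id == "PB", ]
  expect_equal(pb$log2FC, -3)
  t_oracle <- -3 / sqrt(1 * (1 / 3 + 1 / 3))  # pooled sd is exactly 1
  expect_equal(pb$p, 2 * pt(-abs(t_oracle), df = 4), tolerance = 1e-12)
  expect_equal(pb$p, 0.021, tolerance = 0.05)

  # a group with < 2 observed values makes the protein untestable
  ab["PB", samples$condition == "APEX_TTX"] <- c(4, NA, NA)
  pam$log2_abundance <- ab
  res <- contrast_test(pam, "APEX_BIC", "APEX_TTX")
  expect_false(res$testable[res$protein_id == "PB"])
  expect_true(is.na(res$p[res$protein_id == "PB"]))
})

test_that("BH adjustment matches the hand-computed step-up example and oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, method = "BH"), rep(0.04, 4))
  set.seed(99)
  for (k in 1:20) {
    pv <- runif(sample(3:30, 1))
    expect_equal(p.adjust(pv, method = "BH"), bh_stepup_oracle(pv),
                 tolerance = 1e-12)
  }
})

test_that("enrichment and activity gates use strict inequalities", {
  res <- data.frame(protein_id = c("A", "B", "C"),
                    log2FC = c(3.5, 3.0, 5.0),
                    p = c(0.001, 0.001, 0.02),
                    adj_p = c(0.01, 0.01, 0.06),
                    testable = TRUE)
  expect_equal(call_enriched_above_control(res), "A")

  act <- data.frame(protein_id = c("A", "B", "C", "D"),
                    log2FC = c(0.6, -0.6, 0.5, 0.7),
                    p = c(0.01, 0.01, 0.001, 0.05),
                    adj_p = NA_real_,
                    testable = TRUE)
  calls <- call_activity_regulated(act, enriched = c("A", "B", "C", "D"))
  expect_equal(calls$activity_direction[calls$protein_id == "A"], "BIC_UP")
  expect_equal(calls$activity_direction[calls$protein_id == "B"], "TTX_UP")
  expect_equal(calls$activity_direction[calls$protein_id == "C"], "NONE")
  expect_equal(calls$activity_direction[calls$protein_id == "D"], "NONE")

  # the gate is evaluated only on the enriched set
  calls2 <- call_activity_regulated(act, enriched = "A")
  expect_equal(calls2$protein_id, "A")
})

test_that("term-fraction curve counts annotated ids among list prefixes", {
  ids <- paste0("p", 1:10)
  ann_all <- data.frame(id = ids, term = "nucleus")
  expect_equal(term_fraction_curve(ids, ann_all, "nucleus", c(2, 5, 10))$fraction,
               c(1, 1, 1))
  ann_none <- data.frame(id = ids, term = "membrane")
  expect_equal(term_fraction_curve(ids, ann_none, "nucleus", c(5, 10))$fraction,
               c(0, 0))
  # 4 annotated ids, 2 of them in the top 5: direct count gives 2/5 and 4/10
  ann <- data.frame(id = c("p1", "p3", "p6", "p9"), term = "nucleus")
  curve <- term_fraction_curve(ids, ann, "nucleus", c(5, 10))
  expect_equal(curve$fraction, c(2 / 5, 4 / 10))
  expect_error(term_fraction_curve(ids, ann, "nucleus", 11), "cutoffs")
})
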