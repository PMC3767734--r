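test_that("configuration invariants are enforced", {
  expect_error(sim_config(marker_prevalence = 1.2), "probabilities")
  expect_error(sim_config(baseline_event_risk = 0.5, risk_ratio = 3),
               "<= 1")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(planted_set_size = 100, n_genes = 50),
               "exceeds n_genes")
})

test_that("every generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 31, n_genes = 200, planted_set_size = 10,
                    promoter_length = 600)
  e1 <- gen_expression(cfg)
  e2 <- gen_expression(cfg)
  expect_identical(e1$dataset$values, e2$dataset$values)
  expect_identical(e1$planted$members, e2$planted$members)

  p1 <- gen_promoters(cfg, "TTAATNATTAAC", e1$planted$members[1:2],
                      gene_ids = e1$planted$members[1:4],
                      window = c(-250L, 250L))
  p2 <- gen_promoters(cfg, "TTAATNATTAAC", e1$planted$members[1:2],
                      gene_ids = e1$planted$members[1:4],
                      window = c(-250L, 250L))
  expect_identical(vapply(p1$promoters, `[[`, "", "sequence"),
                   vapply(p2$promoters, `[[`, "", "sequence"))
  expect_identical(p1$truth, p2$truth)

  expect_identical(gen_cohort(cfg), gen_cohort(cfg))
  expect_identical(gen_ct_table(cfg), gen_ct_table(cfg))
  b1 <- gen_bisulfite_samples(cfg)
  b2 <- gen_bisulfite_samples(cfg)
  expect_identical(b1$reads, b2$reads)
})

test_that("planted genes carry the configured shift within the CLT bound", {
  cfg <- sim_config(seed = 11, n_genes = 1000, planted_set_size = 50,
                    effect_size = 2, noise_sd = 1, n_per_class = 10)
  sim <- gen_expression(cfg)
  v <- sim$dataset$values[sim$planted$members, ]
  diff_means <- rowMeans(v[, sim$dataset$labels == "induced"]) -
    rowMeans(v[, sim$dataset$labels == "control"])
  expect_lt(abs(mean(diff_means) - 2), 2 / sqrt(50 * 5))
})

test_that("with zero effect the planted genes are exchangeable with background", {
  n_sig <- 0L
  for (s in 1:100) {
    cfg <- sim_config(seed = s, n_genes = 150, planted_set_size = 15,
                      effect_size = 0, noise_sd = 1, n_per_class = 5)
    sim <- gen_expression(cfg)
    v <- sim$dataset$values[sim$planted$members, ]
    a <- colMeans(v[, sim$dataset$labels == "induced"])
    b <- colMeans(v[, sim$dataset$labels == "control"])
    p <- t.test(a, b)$p.value
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_gte(100L - n_sig, 95L)
})

test_that("background promoters are motif-free and planted promoters are hit", {
  cfg <- sim_config(seed = 3, promoter_length = 800)
  sim <- gen_promoters(cfg, "WRGTTAATNATTAACNNN", character(0),
                       gene_ids = sprintf("bg%02d", 1:20),
                       window = c(-350L, 350L))
  hits <- vapply(sim$promoters, function(p) {
    nrow(match_iupac("WRGTTAATNATTAACNNN", p$sequence))
  }, 0L)
  expect_true(all(hits == 0L))

  sim2 <- gen_promoters(cfg, "WRGTTAATNATTAACNNN", "g7",
                        gene_ids = c("g7", "g8"), window = c(-350L, 350L))
  g7 <- sim2$promoters[[1]]
  expect_gte(nrow(match_iupac("WRGTTAATNATTAACNNN", g7$sequence)), 1L)
  expect_error(gen_promoters(cfg, strrep("N", 900), "g1",
                             gene_ids = "g1", window = c(-350L, 350L)),
               "longer than the scan window")
})

test_that("cohort generation recovers the configured risk ratio at large n", {
  cfg <- sim_config(seed = 2, marker_prevalence = 0.5,
                    baseline_event_risk = 0.15, risk_ratio = 3)
  cohort <- gen_cohort(cfg, n = 10000)
  rr <- relative_risk(cohort_to_table(cohort))$risk_ratio
  expect_gt(rr, 2.7)
  expect_lt(rr, 3.3)
})

test_that("a zero Ct shift yields non-significant group differences", {
  n_ns <- 0L
  for (s in 1:100) {
    cfg <- sim_config(seed = s, ct_shift = 0,
                      n_ct_per_group = c(a = 5L, b = 5L))
    tab <- gen_ct_table(cfg)
    lv <- delta_ct(tab, "GAPDH", tab$sample_id[tab$group == "b"][1])
    cmp <- compare_ct_groups(lv)
    if (cmp$p_value[cmp$gene_id == "F2"] > 0.05) n_ns <- n_ns + 1L
  }
  expect_gte(n_ns, 90L)
})

test_that("generated artifacts pass the package's own readers", {
  cfg <- sim_config(seed = 47, n_genes = 50, planted_set_size = 5)
  sim <- gen_expression(cfg)
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".txt")
  write_expression(sim$dataset, mp, lp)
  expect_equal(read_expression(mp, lp)$values, sim$dataset$values)

  ctp <- withr::local_tempfile(fileext = ".tsv")
  ct <- gen_ct_table(cfg)
  write_ct_table(ct, ctp)
  back <- read_ct_table(ctp)
  expect_identical(back$detected, ct$detected)
  expect_equal(back$ct, ct$ct, tolerance = 1e-8)

  bis <- gen_bisulfite_samples(cfg)
  fp <- withr::local_tempfile(fileext = ".fa")
  write_fasta_records(bis$reads, fp)
  expect_identical(read_fasta_records(fp), bis$reads)
})
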