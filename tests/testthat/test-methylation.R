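# a miniature amplicon: C-free primer footprints around the 10 bp region
# "ATCGATCGAA" with CpG cytosines at region offsets 2 and 6
mini_amplicon <- function(interior = "ATCGATCGAA") {
  amplicon_reference(
    sequence = paste0("GGAAGGAAGG", interior, "TTGGTTGGTT"),
    primer_fwd = "GGAAGGAAGG",
    primer_rev = "AACCAACCAA"
  )
}

test_that("bisulfite conversion protects only methylated CpG cytosines", {
  expect_equal(bisulfite_convert("ACGT", FALSE), "ATGT")
  expect_equal(bisulfite_convert("ACGT", TRUE), "ACGT")
  expect_equal(bisulfite_convert("ACGTCCGG", c(FALSE, FALSE)), "ATGTTTGG")
  expect_equal(bisulfite_convert("ACGTCCGG", c(FALSE, TRUE)), "ATGTTCGG")
  expect_error(bisulfite_convert("ACGT", c(TRUE, TRUE)), "CpG")
})

test_that("the published primer pair validates on the synthetic 191 bp amplicon", {
  ref <- synthetic_hnf1b_amplicon()
  v <- validate_primers(ref)
  expect_equal(v$amplicon_length, 191L)
  expect_equal(ref$amplicon_length, 191L)
  expect_length(ref$scored_cpgs, 16L)
  expect_equal(diff(ref$scored_region), 147L)
  # every recorded CpG really is a CG dinucleotide
  for (pos in ref$cpg_positions) {
    expect_equal(substring(ref$sequence, pos + 1, pos + 2), "CG")
  }
})

test_that("a primer overlapping a CpG without degeneracy fails on one template", {
  # literal C at the CpG: matches the methylated template only
  expect_error(
    amplicon_reference(
      sequence = paste0("GGGGTCGAGTTCGATATTAAGT",
                        strrep("ACGTACTAT", 16), strrep("T", 3),
                        "AGGTGGATCGGATGTTTAGGTA"),
      primer_fwd = "GGGGTCGAGTTCGATATTAAGT",
      primer_rev = "TACCTAAACATCCRATCCACCT"),
    "unmethylated converted template")
  # primer absent entirely
  expect_error(
    amplicon_reference(
      sequence = paste0("GGAAGGAAGG", "ATCGATCGAA", "TTGGTTGGTT"),
      primer_fwd = "TTTTAAAATTTT",
      primer_rev = "AACCAACCAA"),
    "forward primer does not match")
})

test_that("per-site calls follow the C/T/Y code", {
  ref <- mini_amplicon()
  expect_equal(ref$scored_region, c(10L, 20L))
  calls <- call_methylation(ref, "ATCGATCGAA", "s1")
  expect_equal(as.character(calls$call), rep("methylated", 2))
  calls <- call_methylation(ref, "ATTGATTGAA", "s2")
  expect_equal(as.character(calls$call), rep("unmethylated", 2))
  calls <- call_methylation(ref, "ATCGATTGAA", "s3")
  expect_equal(as.character(calls$call), c("methylated", "unmethylated"))
  m <- methylation_call_matrix(calls)
  expect_equal(unname(m$fractions), 0.5)
  calls <- call_methylation(ref, "ATYGATTGAA", "s4")
  expect_equal(as.character(calls$call), c("partial", "unmethylated"))
  m <- methylation_call_matrix(calls)
  expect_equal(unname(m$fractions), 0.5)  # partial counts as methylation
})

test_that("unconverted non-CpG cytosines and mismatches reject the read", {
  # interior with a non-CpG C at offset 4: genomic ACGTCTTTAA
  ref <- mini_amplicon("ACGTCTTTAA")
  expect_equal(length(ref$scored_cpgs), 1L)
  ok <- call_methylation(ref, "ACGTTTTTAA", "s1")  # converted correctly
  expect_equal(as.character(ok$call), "methylated")
  expect_error(call_methylation(ref, "ACGTCTTTAA", "s1"),
               "conversion-failure")
  expect_error(call_methylation(ref, "ACGTTTTTAG", "s1"), "mismatch")
  expect_error(call_methylation(ref, "ACGT", "s1"), "length")
})

test_that("simulate -> convert -> call recovers the truth exactly on clean reads", {
  ref <- synthetic_hnf1b_amplicon()
  set.seed(33)
  for (rep in 1:30) {
    flags <- runif(length(ref$cpg_positions)) < runif(1)
    conv <- bisulfite_convert(ref$sequence, flags)
    read <- substring(conv, ref$scored_region[1] + 1, ref$scored_region[2])
    calls <- call_methylation(ref, read, "s")
    truth <- flags[ref$cpg_positions %in% ref$scored_cpgs]
    expect_identical(as.character(calls$call),
                     ifelse(truth, "methylated", "unmethylated"))
  }
})

test_that("extreme group probabilities give all-or-none calls downstream", {
  cfg <- sim_config(seed = 5, methylation_prob_per_group = c(hi = 1, lo = 0))
  sim <- gen_bisulfite_samples(cfg)
  ref <- synthetic_hnf1b_amplicon()
  calls <- do.call(rbind, lapply(names(sim$reads), function(s) {
    call_methylation(ref, sim$reads[[s]], s)
  }))
  m <- methylation_call_matrix(calls)
  expect_true(all(m$fractions[sim$groups$sample_id[sim$groups$group == "hi"]] == 1))
  expect_true(all(m$fractions[sim$groups$sample_id[sim$groups$group == "lo"]] == 0))
})

test_that("recovered mean fraction is within 3 binomial SE of the generating probability", {
  cfg <- sim_config(seed = 101,
                    methylation_prob_per_group = c(g1 = 0.5, g2 = 0.5),
                    n_bisulfite_per_group = 10L)   # 16 sites x 20 samples
  sim <- gen_bisulfite_samples(cfg)
  ref <- synthetic_hnf1b_amplicon()
  calls <- do.call(rbind, lapply(names(sim$reads), function(s) {
    call_methylation(ref, sim$reads[[s]], s)
  }))
  m <- methylation_call_matrix(calls)
  se <- sqrt(0.5 * 0.5 / (16 * 20))
  expect_lt(abs(mean(m$fractions) - 0.5), 3 * se)
})

test_that("group comparison handles separation and identity by convention", {
  sep <- compare_methylation_groups(c(1, 1, 1, 1, 0, 0, 0, 0),
                                    rep(c("a", "b"), each = 4))
  expect_true(sep$separated)
  expect_lte(sep$p_value, .Machine$double.xmin)
  same <- compare_methylation_groups(rep(0.5, 8), rep(c("a", "b"), each = 4))
  expect_equal(same$p_value, 1)
  # agrees with the closed-form equal-variance t on regular data
  x <- c(0.9, 0.95, 0.8, 1, 0.1, 0, 0.2, 0.15)
  g <- rep(c("a", "b"), each = 4)
  got <- compare_methylation_groups(x, g)
  ref_t <- t.test(x[1:4], x[5:8], var.equal = TRUE)
  expect_equal(got$p_value, ref_t$p.value, tolerance = 1e-12)
})

test_that("null group comparison p-values are uniform", {
  set.seed(55)
  ps <- vapply(1:500, function(i) {
    x <- rnorm(10)
    compare_methylation_groups(x, rep(c("a", "b"), each = 5))$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
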