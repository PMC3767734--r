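test_that("the HNF1 consensus matches an instantiation with every code class", {
  hits <- match_iupac("WRGTTAATNATTAACNNN", "AAGTTAATCATTAACGGG")
  expect_equal(hits$start, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$match, "AAGTTAATCATTAACGGG")
})

test_that("pattern N matches every base; sequence N matches only pattern N", {
  expect_equal(nrow(match_iupac("N", "ACGT", both_strands = FALSE)), 4L)
  # W = A/T must not swallow an ambiguous sequence base
  expect_equal(nrow(match_iupac("WWWW", "ANAT", both_strands = FALSE)), 0L)
  expect_equal(nrow(match_iupac("ANAT", "ANAT", both_strands = FALSE)), 1L)
  expect_error(match_iupac("AXGT", "ACGT"), "invalid IUPAC")
})

test_that("scan equals the character-by-character oracle on random cases", {
  set.seed(11)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
  for (case in 1:100) {
    pat <- paste(sample(codes, sample(4:8, 1), replace = TRUE), collapse = "")
    seqlen <- sample(30:200, 1)
    sq <- paste(sample(c("A", "C", "G", "T"), seqlen, replace = TRUE),
                collapse = "")
    got <- match_iupac(pat, sq, both_strands = FALSE)
    expect_identical(got$start, oracle_scan(pat, sq))
    # both strands: union of forward oracle and reverse-complement oracle
    both <- match_iupac(pat, sq, both_strands = TRUE)
    exp_starts <- sort(union(oracle_scan(pat, sq),
                             oracle_scan(oracle_revcomp(pat), sq)))
    expect_identical(both$start, as.integer(exp_starts))
  }
})

test_that("strand symmetry: both-strand hit count is invariant under reverse complement", {
  set.seed(5)
  for (case in 1:25) {
    sq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
    pat <- "GTTAATNATTAAC"
    n1 <- nrow(match_iupac(pat, sq, both_strands = TRUE))
    n2 <- nrow(match_iupac(pat, reverse_complement(sq), both_strands = TRUE))
    expect_equal(n1, n2)
  }
})

test_that("background hit rate matches the closed-form product within Monte Carlo error", {
  set.seed(19)
  pat <- "RYCGNA"  # tractable rate: 2/4 * 2/4 * 1/16 * 1/4 * 1 * 1/4
  L <- 2000L
  n_seq <- 300L
  hits <- vapply(seq_len(n_seq), function(i) {
    sq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
    nrow(match_iupac(pat, sq, both_strands = FALSE))
  }, 0L)
  expected <- expected_background_hits(pat, L)
  expect_equal(expected, (L - 6 + 1) * (2 / 4) * (2 / 4) * (1 / 4)^3)
  total_exp <- n_seq * expected
  expect_lt(abs(sum(hits) - total_exp), 4 * sqrt(total_exp))
})

test_that("predict_targets applies the full-extent window rule", {
  # motif instantiation straddles the window end: excluded
  inst <- "AAGTTAATCATTAACGGG"
  pad <- function(n) paste(rep("T", n), collapse = "")
  # window [-10, +10) around TSS at 50 in a 100 bp promoter
  sq <- paste0(pad(55), inst, pad(100 - 55 - nchar(inst)))
  pw <- promoter_window("gStraddle", sq, 50L, window = c(-10L, 10L))
  inside <- paste0(pad(42), inst, pad(100 - 42 - nchar(inst)))
  pw_in <- promoter_window("gInside", inside, 50L, window = c(-10L, 10L))
  all_n <- promoter_window("gN", paste(rep("N", 100), collapse = ""), 50L,
                           window = c(-10L, 10L))
  got <- predict_targets(list(pw, pw_in, all_n), "WRGTTAATNATTAACNNN")
  expect_identical(got$members, "gInside")
  expect_equal(unname(attr(got, "hit_counts")),
               c(0L, 1L, 0L))
})

test_that("bases outside the window never change predictions", {
  inst <- "AAGTTAATCATTAACGGG"
  core <- paste0(strrep("T", 42), inst, strrep("T", 40))
  pw1 <- promoter_window("g", core, 50L, window = c(-10L, 10L))
  decorated <- paste0("GGGG", sub("^TTTT", "", sub("TTTT$", "", core)), "CCCC")
  pw2 <- promoter_window("g", decorated, 50L, window = c(-10L, 10L))
  h1 <- attr(predict_targets(list(pw1), "WRGTTAATNATTAACNNN"), "hits")
  h2 <- attr(predict_targets(list(pw2), "WRGTTAATNATTAACNNN"), "hits")
  expect_identical(h1, h2)
})

test_that("predicted targets equal the planted set on generator truth", {
  cfg <- sim_config(seed = 21, promoter_length = 1000)
  planted <- c("gA", "gB", "gC")
  sim <- gen_promoters(cfg, "WRGTTAATNATTAACNNN", planted,
                       gene_ids = c(planted, sprintf("bg%02d", 1:30)),
                       window = c(-400L, 400L))
  got <- predict_targets(sim$promoters, "WRGTTAATNATTAACNNN")
  expect_setequal(got$members, planted)
  # recorded offsets point at real instantiations
  hits <- attr(got, "hits")
  for (i in seq_len(nrow(sim$truth))) {
    expect_true(any(hits$gene_id == sim$truth$gene_id[i] &
                      hits$start == sim$truth$motif_start[i]))
  }
})

test_that("promoter windows and patterns are validated", {
  expect_error(promoter_window("g", "ACGT", 2L, window = c(-10L, 10L)),
               "exceeds sequence bounds")
  expect_error(motif_pattern("ACG"), "length >= 4")
  expect_error(motif_pattern("ACGX"), "invalid IUPAC")
  expect_error(predict_targets(list(), "ACGT"), "empty promoter list")
})
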