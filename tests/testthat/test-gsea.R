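make_ranked <- function(scores, ids = sprintf("g%03d", seq_along(scores))) {
  ranked_list(ids, scores)
}

test_that("signal-to-noise applies the floored-sd formula", {
  m <- rbind(
    gA = c(2, 2, 2, 1, 1, 1),     # sd 0 both classes -> floors 0.4 and 0.2
    gB = c(5, 5, 5, 5, 5, 5),     # identical, mean != 0 -> score 0
    gC = c(0, 0, 0, 0, 0, 0)      # all zero -> floors 0.2 -> score 0
  )
  colnames(m) <- paste0("s", 1:6)
  ds <- expression_dataset(m, rep(c("A", "B"), each = 3))
  r <- suppressWarnings(signal_to_noise(ds))
  scores <- setNames(r$score, r$gene_id)
  expect_equal(unname(scores["gA"]), 1 / 0.6, tolerance = 1e-12)
  expect_equal(unname(scores["gB"]), 0)
  expect_equal(unname(scores["gC"]), 0)
})

test_that("swapping class labels negates scores and reverses the order", {
  set.seed(3)
  m <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  ds <- expression_dataset(m, rep(c("A", "B"), each = 4))
  ra <- signal_to_noise(ds, class_a = "A")
  rb <- signal_to_noise(ds, class_a = "B")
  sa <- setNames(ra$score, ra$gene_id)
  expect_equal(unname(sa[rb$gene_id]), -rb$score, tolerance = 1e-12)
  expect_identical(rb$gene_id, rev(ra$gene_id))
})

test_that("prefix and suffix sets reach the extreme enrichment scores at p = 0", {
  r <- make_ranked(10:1)
  prefix <- enrichment_score(r, r$gene_id[1:5], weight_exponent = 0)
  expect_equal(prefix$es, 1)
  expect_equal(prefix$peak_index, 4L)
  suffix <- enrichment_score(r, r$gene_id[6:10], weight_exponent = 0)
  expect_equal(suffix$es, -1)
  expect_error(enrichment_score(r, c("absent1", "absent2")),
               "not represented")
})

test_that("enrichment score equals brute-force oracles on random small instances", {
  set.seed(23)
  for (case in 1:200) {
    N <- sample(6:12, 1)
    k <- sample(2:4, 1)
    scores <- round(rnorm(N), 3)
    r <- make_ranked(scores)
    members <- sample(r$gene_id, k)
    in_set <- r$gene_id %in% members
    p <- sample(c(0, 1, 2), 1)
    got <- enrichment_score(r, members, weight_exponent = p)
    if (p == 0) {
      exp0 <- oracle_es_p0(in_set)
      expect_equal(got$es, exp0$es, tolerance = 1e-12)
      expect_equal(got$peak_index, exp0$peak_index)
    }
    expf <- oracle_es(r$score, in_set, p)
    expect_equal(got$es, expf$es, tolerance = 1e-10)
    # conservation and boundedness
    expect_equal(got$running_sum[N], 0, tolerance = 1e-12)
    expect_lte(abs(got$es), 1 + 1e-12)
  }
})

test_that("weighted enrichment score agrees with an external implementation", {
  set.seed(31)
  for (case in 1:50) {
    N <- sample(20:60, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    r <- ranked_list(sprintf("g%03d", 1:N), scores)
    idx <- sort(sample(N, sample(3:8, 1)))
    got <- enrichment_score(r, r$gene_id[idx], weight_exponent = 1)
    ext <- fgsea::calcGseaStat(setNames(r$score, r$gene_id), idx,
                               gseaParam = 1)
    expect_equal(got$es, ext, tolerance = 1e-8)
  }
})

test_that("ES is invariant under monotone score transforms at p = 0 and negates on reversal", {
  set.seed(13)
  scores <- rnorm(30)
  r <- make_ranked(scores)
  members <- sample(r$gene_id, 6)
  base <- enrichment_score(r, members, weight_exponent = 0)
  r2 <- ranked_list(r$gene_id, exp(r$score))  # strictly monotone transform
  expect_equal(enrichment_score(r2, members, weight_exponent = 0)$es, base$es)
  rev_r <- ranked_list(r$gene_id, -r$score)
  expect_equal(enrichment_score(rev_r, members, weight_exponent = 0)$es,
               -base$es, tolerance = 1e-12)
})

test_that("gene-set permutation p-value hits the plus-one floor for a planted prefix", {
  set.seed(1)
  r <- make_ranked(seq(5, -5, length.out = 1000),
                   ids = sprintf("g%04d", 1:1000))
  prefix <- r$gene_id[1:20]
  res <- permutation_null(r, prefix, mode = "gene_set", n_perm = 99,
                          seed = 17)
  expect_equal(res$es, 1, tolerance = 1e-6)
  # no random 20-gene subset reaches ES 1.0, so p is the plus-one floor
  n_pos <- sum(res$null_es >= 0)
  expect_equal(res$p_nominal, 1 / (n_pos + 1))
  expect_lte(res$p_nominal, 0.02)
})

test_that("single-permutation p-value is capped at 1 when the null wins", {
  r <- make_ranked(rnorm(50))
  set.seed(2)
  members <- sample(r$gene_id, 5)
  ps <- vapply(1:30, function(s) {
    permutation_null(r, members, mode = "gene_set", n_perm = 1,
                     seed = s)$p_nominal
  }, 0)
  expect_true(all(ps %in% c(0.5, 1)))
  expect_true(any(ps == 1))
})

test_that("phenotype permutation enumerates all assignments for small designs", {
  set.seed(4)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  ds <- expression_dataset(m, rep(c("A", "B"), each = 3))
  res <- suppressWarnings(
    permutation_null(ds, rownames(m)[1:3], mode = "phenotype",
                     n_perm = 100, seed = 9))
  expect_length(res$null_es, choose(6, 3))  # exact enumeration
  expect_gt(res$p_nominal, 0)
  expect_lte(res$p_nominal, 1)
})

test_that("NES normalization identities hold", {
  # every null ES equal to the observed ES -> NES exactly 1
  res <- list(s1 = list(es = 0.5, null_es = rep(0.5, 20), p_nominal = 0.5))
  tab <- nes_and_fdr(res)
  expect_equal(tab$nes, 1)
  # null strictly below the observed -> q = 0
  res2 <- list(s1 = list(es = 0.9, null_es = runif(50, 0.1, 0.4),
                         p_nominal = 0.02))
  expect_equal(nes_and_fdr(res2)$fdr_q, 0)
})

test_that("planted sets rank ahead of null sets by FDR", {
  set.seed(6)
  cfg <- sim_config(seed = 77, n_genes = 1000, planted_set_size = 40,
                    effect_size = 2, noise_sd = 1)
  sim <- gen_expression(cfg)
  genes <- rownames(sim$dataset$values)
  planted_sets <- lapply(1:5, function(i) {
    gene_set(sprintf("planted%02d", i),
             sample(sim$planted$members, 20))
  })
  null_sets <- lapply(1:15, function(i) {
    gene_set(sprintf("null%02d", i), sample(genes, 20))
  })
  coll <- gene_set_collection(c(planted_sets, null_sets))
  res <- run_gsea(sim$dataset, coll, mode = "gene_set", n_perm = 199,
                  seed = 123)
  top5 <- res$table$set_name[order(res$table$fdr_q,
                                   -abs(res$table$nes))][1:5]
  expect_setequal(top5, sprintf("planted%02d", 1:5))
  # q monotone non-increasing in |NES| within the positive sign class
  pos <- res$table[res$table$nes >= 0, ]
  ord <- order(-abs(pos$nes))
  expect_true(all(diff(pos$fdr_q[ord]) >= -1e-12))
})

test_that("leading edge matches its defining scan on random instances", {
  set.seed(8)
  for (case in 1:100) {
    N <- sample(8:20, 1)
    r <- make_ranked(rnorm(N))
    members <- sample(r$gene_id, sample(2:5, 1))
    es <- enrichment_score(r, members, weight_exponent = 1)
    le <- leading_edge(r, gene_set("s", members), es)
    in_set <- r$gene_id %in% members
    expect_identical(
      le$members,
      oracle_leading_edge(r$gene_id, in_set, es$es, es$peak_index))
    expect_true(all(le$members %in% members))
  }
  # prefix set with es = 1: leading edge is the whole set
  r <- make_ranked(10:1)
  es <- enrichment_score(r, r$gene_id[1:4], weight_exponent = 0)
  expect_setequal(leading_edge(r, r$gene_id[1:4], es)$members, r$gene_id[1:4])
  # a member ranked strictly after a positive peak is excluded
  members <- c(r$gene_id[1:3], r$gene_id[9])
  es2 <- enrichment_score(r, members, weight_exponent = 0)
  le2 <- leading_edge(r, members, es2)
  expect_false(r$gene_id[9] %in% le2$members)
})
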