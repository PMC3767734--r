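# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: the motif oracle compares
# characters one by one, the enrichment-score oracle at p = 0 walks the list
# in integer arithmetic, and the count-based oracles enumerate supports with
# exact binomial coefficients or log-factorials.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

# character-by-character single-strand scan
oracle_scan <- function(pattern, sequence) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(sequence, "")[[1]]
  w <- length(pc)
  starts <- integer(0)
  if (length(sc) < w) return(starts)
  for (s in 0:(length(sc) - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(sc[s + j] %in% IUPAC_SETS[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# unweighted (p = 0) enrichment score in pure integer arithmetic: scale the
# running sum by k * (N - k) so every step is an integer
oracle_es_p0 <- function(in_set) {
  N <- length(in_set)
  k <- sum(in_set)
  stopifnot(k > 0, k < N)
  run <- cumsum(ifelse(in_set, N - k, -k))
  hi <- max(run)
  lo <- min(run)
  peak <- if (hi >= -lo) which(run == hi)[1] else which(run == lo)[1]
  list(es = run[peak] / (k * (N - k)), peak_index = peak - 1L)
}

# weighted enrichment score recomputed step by step, independently coded
oracle_es <- function(scores, in_set, p) {
  N <- length(in_set)
  k <- sum(in_set)
  nr <- sum(abs(scores[in_set])^p)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (in_set[i]) {
      cur + (if (nr > 0) abs(scores[i])^p / nr else 1 / k)
    } else {
      cur - 1 / (N - k)
    }
    run[i] <- cur
  }
  hi <- max(run)
  lo <- min(run)
  peak <- if (hi >= -lo - 1e-12) which(run == hi)[1] else which(run == lo)[1]
  list(es = run[peak], peak_index = peak - 1L)
}

# leading edge by direct definition
oracle_leading_edge <- function(gene_ids, in_set, es, peak_index) {
  rank0 <- seq_along(gene_ids) - 1L
  keep <- if (es >= 0) in_set & rank0 <= peak_index else
    in_set & rank0 >= peak_index
  gene_ids[keep]
}

# hypergeometric upper tail by full enumeration with exact binomial
# coefficients (exact in double precision for N <= 30)
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# two-sided Fisher p by enumerating the support, point probabilities from
# log-factorials
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  row1 <- a + b
  col2 <- b + d
  pt <- function(x) {
    # P(table with x events among marker-negatives), margins fixed
    exp(lfactorial(row1) + lfactorial(n - row1) + lfactorial(col2) +
          lfactorial(n - col2) - lfactorial(n) - lfactorial(x) -
          lfactorial(row1 - x) - lfactorial(col2 - x) -
          lfactorial(n - row1 - col2 + x))
  }
  support <- max(0, row1 + col2 - n):min(row1, col2)
  probs <- vapply(support, pt, 0)
  sum(probs[probs <= pt(b) * (1 + 1e-7)])
}

# random valid gene-set collection for round-trip properties
random_collection <- function(n_sets, pool = sprintf("G%03d", 1:60)) {
  sets <- lapply(seq_len(n_sets), function(i) {
    gene_set(sprintf("S%02d", i), sample(pool, sample(2:10, 1)),
             description = paste("set", i))
  })
  gene_set_collection(sets)
}
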