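# Gene set enrichment analysis, implemented from scratch: signal-to-noise
# ranking with floored standard deviations, the weighted Kolmogorov-Smirnov
# running-sum enrichment score, permutation nulls (gene-set or phenotype
# mode), normalized enrichment scores with an FDR estimate from the null
# tail fractions, and leading-edge extraction.
#
# Conventions: ranked lists are ordered by score descending with ties broken
# by gene id ascending; p-values use the plus-one convention within the
# same-sign null subsample; weight exponent defaults to 1.

#' Signal-to-noise ranking metric
#'
#' Per gene, `(meanA - meanB) / (sdA' + sdB')`, where each class standard
#' deviation is floored at `0.2 * |class mean|`, and at 0.2 when that floor is
#' itself zero. Class A is the first label in order of appearance (override
#' with `class_a`). Genes are returned in ranked order: score descending,
#' ties broken by gene id ascending.
#'
#' @param dataset An [expression_dataset].
#' @param class_a Label to treat as class A (default: first observed label).
#' @return A `ranked_list`: data.frame with columns `gene_id`, `score`,
#'   ordered as above.
#' @export
signal_to_noise <- function(dataset, class_a = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  classes <- dataset$classes
  class_a <- class_a %||% classes[[1]]
  if (!class_a %in% classes) stop("unknown class label: ", class_a)
  class_b <- setdiff(classes, class_a)
  ia <- dataset$labels == class_a
  ib <- dataset$labels == class_b
  if (sum(ia) < 3L || sum(ib) < 3L) {
    log_warning("fewer than 3 samples in a class; signal-to-noise is unstable")
  }
  va <- dataset$values[, ia, drop = FALSE]
  vb <- dataset$values[, ib, drop = FALSE]
  ma <- rowMeans(va)
  mb <- rowMeans(vb)
  sa <- if (ncol(va) > 1L) apply(va, 1L, stats::sd) else rep(0, nrow(va))
  sb <- if (ncol(vb) > 1L) apply(vb, 1L, stats::sd) else rep(0, nrow(vb))
  floor_sd <- function(s, m) {
    lo <- 0.2 * abs(m)
    lo[lo == 0] <- 0.2
    pmax(s, lo)
  }
  score <- (ma - mb) / (floor_sd(sa, ma) + floor_sd(sb, mb))
  ranked_list(rownames(dataset$values), score)
}

#' Construct a ranked gene list
#'
#' @param gene_ids Unique gene identifiers.
#' @param scores Numeric ranking metric, one per gene.
#' @return A `ranked_list` data.frame ordered by score descending, gene id
#'   ascending on ties.
#' @export
ranked_list <- function(gene_ids, scores) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("ranked list gene ids must be unique")
  stopifnot(length(gene_ids) == length(scores), is.numeric(scores))
  ord <- order(-scores, gene_ids, method = "radix")
  structure(
    data.frame(gene_id = gene_ids[ord], score = as.numeric(scores)[ord],
               stringsAsFactors = FALSE),
    class = c("ranked_list", "data.frame")
  )
}

#' Running-sum enrichment score
#'
#' Walking down the ranked list, set members increment the running sum by
#' `|score|^p` normalized over in-set genes and non-members decrement it by
#' `1/(N - k)`. The enrichment score is the deviation of maximal magnitude,
#' with its sign; the sum telescopes back to zero at the end of the list.
#' When every in-set `|score|^p` is zero (possible at `p > 0` with all-zero
#' scores) hit increments fall back to the uniform `1/k`. On an exact tie
#' between the positive and negative extremes the positive one is reported.
#'
#' @param ranked A `ranked_list`.
#' @param set A [gene_set] (or character vector of members).
#' @param weight_exponent Weight `p >= 0`; default 1 (`p = 0` gives the
#'   classic unweighted Kolmogorov-Smirnov statistic).
#' @return List with `es`, `peak_index` (0-based rank of the maximal
#'   deviation) and `running_sum` (length-N numeric).
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"), weight_exponent >= 0)
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)
  inset <- ranked$gene_id %in% members
  k <- sum(inset)
  if (k == 0L) stop("set not represented in the ranked universe")
  n <- nrow(ranked)
  w <- abs(ranked$score)^weight_exponent
  w[!inset] <- 0
  nr <- sum(w)
  inc <- if (nr > 0) w / nr else as.numeric(inset) / k
  dec <- if (n > k) 1 / (n - k) else 0
  steps <- inc
  steps[!inset] <- -dec
  running <- cumsum(steps)
  hi <- max(running)
  lo <- min(running)
  # sign tie-break: a positive extreme wins an exact-magnitude tie (the
  # tolerance only absorbs float noise; genuine gaps exceed 1/(k(N-k)))
  if (hi >= -lo - 1e-12) {
    peak <- which(running == hi)[[1]]
  } else {
    peak <- which(running == lo)[[1]]
  }
  list(es = running[[peak]], peak_index = peak - 1L, running_sum = running)
}

# Fast enrichment score from sorted hit positions (1-based ranks) and their
# unnormalized weights; used by the gene-set permutation loop. The running
# sum's positive extrema sit at hits and negative extrema just before hits,
# so only 2k candidates need inspection.
.es_from_positions <- function(pos, w, n) {
  k <- length(pos)
  if (k == 0L) stop("no hit positions")
  if (n == k) return(1)
  nr <- sum(w)
  cw <- if (nr > 0) cumsum(w) / nr else seq_len(k) / k
  dec <- 1 / (n - k)
  at_hit <- cw - (pos - seq_len(k)) * dec
  before_hit <- c(0, cw[-k]) - (pos - seq_len(k)) * dec
  hi <- max(at_hit)
  lo <- min(before_hit)
  if (hi >= -lo) hi else lo
}

#' Permutation null and nominal p-value for one gene set
#'
#' In `gene_set` mode, the null draws uniform random subsets of the same size
#' from the ranked universe (the mode for designs with too few samples to
#' permute phenotypes). In `phenotype` mode, class labels are permuted and
#' the ranking metric recomputed per permutation; all distinct label
#' assignments are enumerated when there are at most `n_perm` of them
#' (an exact test), otherwise distinct assignments are sampled.
#'
#' The nominal p is the plus-one-corrected fraction of same-sign null scores
#' at least as extreme as the observed: `(#{|ES_null| >= |ES|} + 1) /
#' (n_same_sign + 1)`.
#'
#' @param x A `ranked_list` (`gene_set` mode) or [expression_dataset]
#'   (`phenotype` mode).
#' @param set A [gene_set] or character vector.
#' @param mode `"gene_set"` or `"phenotype"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed for the permutation stream.
#' @param weight_exponent Weight `p` passed to [enrichment_score()].
#' @return List with `es`, `peak_index`, `p_nominal`, `null_es` (numeric
#'   vector), `mode`, `set_size`.
#' @export
permutation_null <- function(x, set, mode = c("gene_set", "phenotype"),
                             n_perm = 1000L, seed = NULL,
                             weight_exponent = 1) {
  mode <- match.arg(mode)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)

  if (mode == "gene_set") {
    stopifnot(inherits(x, "ranked_list"))
    ranked <- x
    obs <- enrichment_score(ranked, members, weight_exponent)
    n <- nrow(ranked)
    k <- sum(ranked$gene_id %in% members)
    wall <- abs(ranked$score)^weight_exponent
    null_es <- vapply(seq_len(n_perm), function(b) {
      pos <- sort.int(sample.int(n, k))
      .es_from_positions(pos, wall[pos], n)
    }, 0)
  } else {
    stopifnot(inherits(x, "expression_dataset"))
    ranked <- signal_to_noise(x)
    obs <- enrichment_score(ranked, members, weight_exponent)
    assignments <- .label_assignments(x$labels, n_perm)
    null_es <- vapply(assignments, function(lab) {
      perm <- x
      perm$labels <- lab
      r <- signal_to_noise(perm, class_a = x$classes[[1]])
      enrichment_score(r, members, weight_exponent)$es
    }, 0)
  }

  if (obs$es >= 0) {
    same <- null_es[null_es >= 0]
    p <- (sum(same >= obs$es) + 1) / (length(same) + 1)
  } else {
    same <- null_es[null_es < 0]
    p <- (sum(same <= obs$es) + 1) / (length(same) + 1)
  }
  list(es = obs$es, peak_index = obs$peak_index, p_nominal = p,
       null_es = null_es, mode = mode,
       set_size = sum(ranked$gene_id %in% members))
}

# distinct two-class label assignments: exhaustive when feasible, otherwise
# sampled without replacement (deduplicated shuffles)
.label_assignments <- function(labels, n_perm) {
  n <- length(labels)
  classes <- unique(labels)
  na <- sum(labels == classes[[1]])
  total <- choose(n, na)
  if (total <= n_perm) {
    combs <- utils::combn(n, na, simplify = FALSE)
    return(lapply(combs, function(idx) {
      lab <- rep(classes[[2]], n)
      lab[idx] <- classes[[1]]
      lab
    }))
  }
  seen <- new.env(hash = TRUE)
  out <- vector("list", n_perm)
  got <- 0L
  while (got < n_perm) {
    idx <- sort.int(sample.int(n, na))
    key <- paste(idx, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    got <- got + 1L
    lab <- rep(classes[[2]], n)
    lab[idx] <- classes[[1]]
    out[[got]] <- lab
  }
  out
}

#' Normalized enrichment scores and FDR q-values
#'
#' Each observed ES is divided by the mean magnitude of its same-sign null
#' scores; the per-set nulls are normalized the same way. The FDR q for a set
#' is the ratio of the same-sign normalized-null tail fraction to the
#' observed tail fraction at that set's |NES|, clipped to [0, 1] and made
#' monotone non-increasing in |NES| within each sign class.
#'
#' @param results List as returned by [permutation_null()], one per set
#'   (needs fields `es` and `null_es`); names are set names.
#' @return data.frame with `set_name`, `es`, `nes`, `p_nominal`, `fdr_q`.
#'   Sets with no same-sign nulls get `NA` NES and q, with a warning.
#' @export
nes_and_fdr <- function(results) {
  stopifnot(is.list(results), length(results) > 0L)
  nms <- names(results) %||% paste0("set", seq_along(results))
  es <- vapply(results, `[[`, 0, "es")
  normalize <- function(vals, null) {
    pos_mean <- mean(null[null >= 0])
    neg_mean <- mean(abs(null[null < 0]))
    ifelse(vals >= 0, vals / pos_mean, vals / neg_mean)
  }
  nes <- numeric(length(results))
  null_nes <- vector("list", length(results))
  for (i in seq_along(results)) {
    null <- results[[i]]$null_es
    nes[[i]] <- normalize(es[[i]], null)[[1]]
    null_nes[[i]] <- normalize(null, null)
  }
  if (any(!is.finite(nes))) {
    log_warning("NES undefined for set(s) with no same-sign null scores: ",
                paste(nms[!is.finite(nes)], collapse = ", "))
    nes[!is.finite(nes)] <- NA_real_
  }
  all_null <- unlist(null_nes)
  all_null <- all_null[is.finite(all_null)]
  q <- rep(NA_real_, length(nes))
  for (sign_pos in c(TRUE, FALSE)) {
    idx <- which(!is.na(nes) & if (sign_pos) nes >= 0 else nes < 0)
    if (length(idx) == 0L) next
    nullside <- if (sign_pos) all_null[all_null >= 0] else all_null[all_null < 0]
    obs_side <- nes[idx]
    raw <- vapply(obs_side, function(v) {
      tail_null <- if (sign_pos) mean(nullside >= v) else mean(nullside <= v)
      tail_obs <- if (sign_pos) mean(obs_side >= v) else mean(obs_side <= v)
      min(1, tail_null / tail_obs)
    }, 0)
    # a looser |NES| threshold with a smaller ratio also covers stronger sets
    ord <- order(-abs(obs_side))
    raw[ord] <- rev(cummin(rev(raw[ord])))
    q[idx] <- raw
  }
  p <- vapply(results, function(r) r$p_nominal %||% NA_real_, 0)
  data.frame(set_name = nms, es = es, nes = nes, p_nominal = p, fdr_q = q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Leading-edge subset of a gene set
#'
#' For a positive enrichment score, the set members at ranks at or before the
#' running-sum peak (the genes driving the enrichment); for a negative score,
#' the members at or after the peak.
#'
#' @param ranked A `ranked_list`.
#' @param set A [gene_set] or character vector.
#' @param es_result Result of [enrichment_score()] (or any list with `es` and
#'   `peak_index`).
#' @return A [gene_set] named `<set>_leading_edge`, members in ranked order.
#' @export
leading_edge <- function(ranked, set, es_result) {
  stopifnot(inherits(ranked, "ranked_list"))
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)
  set_name <- if (inherits(set, "gene_set")) set$name else "set"
  rank0 <- seq_len(nrow(ranked)) - 1L
  inset <- ranked$gene_id %in% members
  keep <- if (es_result$es >= 0) {
    inset & rank0 <= es_result$peak_index
  } else {
    inset & rank0 >= es_result$peak_index
  }
  if (!any(keep)) stop("empty leading edge")
  gene_set(paste0(set_name, "_leading_edge"), ranked$gene_id[keep],
           description = "leading-edge subset")
}

#' Run GSEA for a collection of gene sets
#'
#' Convenience wrapper: ranks (if given a dataset), computes per-set
#' enrichment, permutation p-values, NES/FDR, and leading edges.
#'
#' @param x An [expression_dataset] or `ranked_list`.
#' @param collection A [gene_set_collection].
#' @param mode Permutation mode, `"gene_set"` (default) or `"phenotype"`
#'   (requires a dataset).
#' @param n_perm Permutations per set.
#' @param seed Integer seed.
#' @param weight_exponent Weight `p` (default 1).
#' @param min_size Sets with fewer represented members are dropped with a
#'   warning (default 2).
#' @return List with `table` (the [nes_and_fdr()] data.frame plus set sizes
#'   and peak indices), `leading_edges` (named list of [gene_set]), and
#'   `ranked` (the ranked list used).
#' @export
run_gsea <- function(x, collection, mode = c("gene_set", "phenotype"),
                     n_perm = 1000L, seed = NULL, weight_exponent = 1,
                     min_size = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "gene_set_collection"))
  ranked <- if (inherits(x, "ranked_list")) x else signal_to_noise(x)
  if (mode == "phenotype" && !inherits(x, "expression_dataset")) {
    stop("phenotype mode requires an expression_dataset")
  }
  sizes <- vapply(collection$sets,
                  function(s) sum(ranked$gene_id %in% s$members), 0L)
  drop <- sizes < min_size
  if (any(drop)) {
    log_warning("dropping ", sum(drop), " set(s) with fewer than ", min_size,
                " represented members")
  }
  sets <- collection$sets[!drop]
  if (length(sets) == 0L) stop("no set is represented in the ranked universe")
  if (!is.null(seed)) set.seed(seed)
  results <- lapply(sets, function(s) {
    permutation_null(if (mode == "gene_set") ranked else x, s, mode = mode,
                     n_perm = n_perm, weight_exponent = weight_exponent)
  })
  tab <- nes_and_fdr(results)
  tab$size <- vapply(results, `[[`, 0L, "set_size")
  tab$peak_index <- vapply(results, `[[`, 0L, "peak_index")
  edges <- lapply(names(sets), function(nm) {
    leading_edge(ranked, sets[[nm]],
                 list(es = results[[nm]]$es,
                      peak_index = results[[nm]]$peak_index))
  })
  names(edges) <- names(sets)
  tab$leading_edge_size <- vapply(edges, function(e) length(e$members), 0L)
  tab <- tab[order(tab$p_nominal, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, leading_edges = edges, ranked = ranked,
                 mode = mode, n_perm = n_perm),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("<gsea_result> ", nrow(x$table), " sets, ", x$mode,
      " permutation (n_perm = ", x$n_perm, ")\n", sep = "")
  print(utils::head(x$table, 10L))
  invisible(x)
}
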