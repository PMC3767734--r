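# Over-representation of a query gene list (typically a leading edge) against
# a curated collection: exact hypergeometric upper tail per set, BH FDR
# across tested sets, top-k reporting with the p < 0.01 / q < 0.25 defaults.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for the overlap `X` between a query of size `n` and a set of
#' size `K` drawn from a universe of size `N`.
#'
#' @param k Observed overlap.
#' @param K Set size.
#' @param n Query size.
#' @param N Universe size.
#' @return The exact tail probability.
#' @examples
#' hypergeom_upper_tail(2, 5, 2, 10) # 10/45
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N <= 0 || K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: k=", k, " K=", K, " n=", n, " N=", N)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Rank curated sets by over-representation of a query
#'
#' Query genes outside the universe are dropped with a warning; each
#' collection set is intersected with the universe before testing. BH
#' q-values are computed across all tested sets; the report is sorted by
#' nominal p ascending (ties broken by set name) and filtered at the default
#' thresholds p < 0.01 and q < 0.25 before taking the top `top_k` rows.
#'
#' @param query A [gene_set] or character vector of query genes.
#' @param collection A [gene_set_collection].
#' @param universe A [gene_set] or character vector defining the gene
#'   universe (an explicit input: the choice of universe changes every
#'   p-value and defaults differ between tools).
#' @param top_k Number of rows to report (default 10).
#' @param p_max,q_max Filter thresholds (defaults 0.01 and 0.25); set to 1 to
#'   disable.
#' @return data.frame of the top rows with columns `set_name`, `k_overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p_nominal`, `fdr_q`,
#'   `members` (comma-joined overlap). The full unfiltered table is attached
#'   as attribute `full`.
#' @export
rank_overlaps <- function(query, collection, universe, top_k = 10L,
                          p_max = 0.01, q_max = 0.25) {
  qm <- if (inherits(query, "gene_set")) query$members else as.character(query)
  um <- if (inherits(universe, "gene_set")) universe$members else
    as.character(universe)
  um <- unique(um)
  if (length(um) == 0L) stop("empty universe")
  stopifnot(inherits(collection, "gene_set_collection"))
  outside <- setdiff(qm, um)
  if (length(outside) > 0L) {
    log_warning("dropping ", length(outside),
                " query gene(s) outside the universe")
    qm <- intersect(qm, um)
  }
  if (length(qm) == 0L) stop("query has no genes in the universe")
  rows <- lapply(collection$sets, function(s) {
    sm <- intersect(s$members, um)
    if (length(sm) == 0L) return(NULL)
    ov <- intersect(qm, sm)
    data.frame(
      set_name = s$name, k_overlap = length(ov), set_size = length(sm),
      query_size = length(qm), universe_size = length(um),
      p_nominal = hypergeom_upper_tail(length(ov), length(sm), length(qm),
                                       length(um)),
      members = paste(ov, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stop("no collection set intersects the universe")
  tab <- do.call(rbind, rows)
  tab$fdr_q <- stats::p.adjust(tab$p_nominal, method = "BH")
  tab <- tab[order(tab$p_nominal, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  out <- tab[tab$p_nominal < p_max & tab$fdr_q < q_max, , drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  attr(out, "full") <- tab
  out
}
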