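# Exact 2x2 association statistics for binary-marker / binary-event cohorts:
# two-sided Fisher exact test under the minimum-likelihood convention, the
# relative risk as a ratio of event proportions (not an odds ratio), and
# cohort tabulation / pooling. Table orientation is fixed throughout:
# marker in rows (negative first), event in columns (no-event first).

#' Construct a 2x2 marker-by-event table
#'
#' @param a Marker-negative, no-event count.
#' @param b Marker-negative, event count.
#' @param c Marker-positive, no-event count.
#' @param d Marker-positive, event count.
#' @return An object of class `cohort_2x2`.
#' @examples
#' cohort_2x2(14, 3, 10, 11)
#' @export
cohort_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("table total must be positive")
  structure(as.list(counts), class = "cohort_2x2")
}

#' @export
print.cohort_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2L, byrow = TRUE,
              dimnames = list(c("marker-neg", "marker-pos"),
                              c("no event", "event")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.cohort_2x2 <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), 2L, byrow = TRUE,
         dimnames = list(c("marker-neg", "marker-pos"),
                         c("no event", "event")))
}

#' Two-sided Fisher exact test (minimum-likelihood convention)
#'
#' With the margins fixed, sums the hypergeometric probabilities of every
#' table whose point probability is at most that of the observed table (a
#' relative tolerance of 1e-7 guards floating-point ties) — the two-sided
#' convention of the dominant statistical software.
#'
#' @param table A [cohort_2x2].
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(cohort_2x2(14, 3, 10, 11)) # 0.043
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(inherits(table, "cohort_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  row1 <- a + b          # marker-negative total
  col2 <- b + d          # event total
  # x = event count among marker-negatives; hypergeometric over the support
  lo <- max(0L, row1 - (n - col2))
  hi <- min(row1, col2)
  support <- lo:hi
  probs <- stats::dhyper(support, col2, n - col2, row1)
  p_obs <- stats::dhyper(b, col2, n - col2, row1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Relative risk and per-group event proportions
#'
#' The ratio of event proportions, marker-positive over marker-negative.
#' Returned at full precision; reports conventionally print one decimal.
#' A zero marker-negative event count leaves the ratio undefined (`NA`,
#' flagged) rather than applying a continuity correction.
#'
#' @param table A [cohort_2x2].
#' @return List with `risk_ratio`, `p_event_pos`, `p_event_neg`,
#'   `p_marker_pos` (marker prevalence), `p_event` (overall event rate),
#'   `defined` (logical).
#' @examples
#' relative_risk(cohort_2x2(14, 3, 10, 11))$risk_ratio # 2.97
#' @export
relative_risk <- function(table) {
  stopifnot(inherits(table, "cohort_2x2"))
  n_neg <- table$a + table$b
  n_pos <- table$c + table$d
  if (n_neg == 0 || n_pos == 0) stop("both marker groups must be non-empty")
  p_neg <- table$b / n_neg
  p_pos <- table$d / n_pos
  n <- n_neg + n_pos
  defined <- p_neg > 0
  if (!defined) {
    log_warning("zero events in the marker-negative group; ",
                "relative risk undefined")
  }
  list(risk_ratio = if (defined) p_pos / p_neg else NA_real_,
       p_event_pos = p_pos, p_event_neg = p_neg,
       p_marker_pos = n_pos / n, p_event = (table$b + table$d) / n,
       defined = defined)
}

#' Tabulate a cohort of (marker, event) records
#'
#' Records with marker outside `pos`/`neg` or event outside `yes`/`no`
#' (including NA) are excluded with a logged count.
#'
#' @param records data.frame with columns `marker` and `event`.
#' @return A [cohort_2x2].
#' @export
cohort_to_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("marker", "event") %in% names(records)))
  if (nrow(records) == 0L) stop("empty cohort")
  ok <- records$marker %in% c("pos", "neg") & records$event %in% c("yes", "no")
  if (any(!ok)) {
    log_warning("excluding ", sum(!ok),
                " record(s) with unknown marker or event status")
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records with known marker and event")
  cohort_2x2(
    a = sum(records$marker == "neg" & records$event == "no"),
    b = sum(records$marker == "neg" & records$event == "yes"),
    c = sum(records$marker == "pos" & records$event == "no"),
    d = sum(records$marker == "pos" & records$event == "yes")
  )
}

#' Pool 2x2 cohorts cellwise
#'
#' @param tables Non-empty list of [cohort_2x2] objects.
#' @return A [cohort_2x2] of cellwise sums.
#' @examples
#' pool_cohorts(list(cohort_2x2(14, 3, 10, 11), cohort_2x2(40, 6, 42, 15)))
#' @export
pool_cohorts <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L) {
    stop("need a non-empty list of cohort_2x2 tables")
  }
  ok <- vapply(tables, inherits, TRUE, what = "cohort_2x2")
  if (!all(ok)) stop("all elements must be cohort_2x2 objects")
  cohort_2x2(
    a = sum(vapply(tables, `[[`, 0, "a")),
    b = sum(vapply(tables, `[[`, 0, "b")),
    c = sum(vapply(tables, `[[`, 0, "c")),
    d = sum(vapply(tables, `[[`, 0, "d"))
  )
}

#' Full association summary for one 2x2 table
#'
#' @param table A [cohort_2x2].
#' @return List with the Fisher two-sided `p_value`, the [relative_risk()]
#'   fields, and the counts.
#' @export
assoc_test <- function(table) {
  rr <- relative_risk(table)
  c(list(p_value = fisher_exact_two_sided(table)), rr,
    list(counts = unlist(table[c("a", "b", "c", "d")])))
}
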