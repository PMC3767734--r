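# Transcription-factor target prediction by degenerate-consensus scanning of
# promoter windows around the TSS. The scan is exhaustive (overlapping hits
# reported), double-stranded by default, and conservative about ambiguity: an
# N in the subject sequence matches only the pattern code N, never A/C/G/T
# classes. Coordinates are 0-based; windows are half-open intervals relative
# to the TSS on the transcribed strand, default [-2000, +2000).

#' Construct an IUPAC motif pattern
#'
#' @param pattern Consensus string over the IUPAC alphabet, length >= 4.
#' @param label Free-text label.
#' @return An object of class `motif_pattern`.
#' @examples
#' motif_pattern("WRGTTAATNATTAACNNN", label = "HNF1 consensus")
#' @export
motif_pattern <- function(pattern, label = "") {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  }
  if (nchar(pattern) < 4L) stop("pattern must have length >= 4")
  structure(list(pattern = pattern, label = label), class = "motif_pattern")
}

# IUPAC consensus -> regex. A subject N is only allowed where the pattern says
# N; every other code expands to its exact base class.
.iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    bases <- IUPAC_CODES[[ch]]
    if (ch == "N") bases <- c(bases, "N")
    if (length(bases) == 1L) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Find all occurrences of an IUPAC motif in a sequence
#'
#' Reports every (possibly overlapping) occurrence. With `both_strands` the
#' reverse strand is scanned by matching the reverse-complemented pattern on
#' the forward sequence; minus-strand hits carry the forward-strand position
#' of their leftmost matched base. A hit present on both strands at the same
#' position (self-complementary instantiation) is reported once, as `+`.
#'
#' @param pattern A [motif_pattern] or IUPAC string.
#' @param sequence DNA string over A, C, G, T, N.
#' @param both_strands Scan both strands (default `TRUE`).
#' @return data.frame with columns `start` (0-based), `strand`, `match`.
#' @export
match_iupac <- function(pattern, sequence, both_strands = TRUE) {
  if (!inherits(pattern, "motif_pattern")) {
    # bare strings of any length are accepted here; the length >= 4
    # invariant binds motif_pattern objects used for target prediction
    pattern <- toupper(pattern)
    bad <- setdiff(strsplit(pattern, "", fixed = TRUE)[[1]],
                   names(IUPAC_CODES))
    if (length(bad) > 0L) {
      stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
    }
    pattern <- structure(list(pattern = pattern, label = ""),
                         class = "motif_pattern")
  }
  sequence <- validate_dna(sequence)
  hits <- .scan_one(pattern$pattern, sequence, "+")
  if (both_strands) {
    rc <- reverse_complement(pattern$pattern)
    minus <- .scan_one(rc, sequence, "-")
    hits <- rbind(hits, minus)
    # dedupe identical (start, extent) hits, keeping the + strand call
    hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
    dup <- duplicated(hits$start)
    hits <- hits[!dup, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits[order(hits$start), , drop = FALSE]
}

.scan_one <- function(consensus, sequence, strand) {
  w <- nchar(consensus)
  rx <- paste0("(?=", .iupac_regex(consensus), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[[1]] == -1L) {
    return(data.frame(start = integer(0), strand = character(0),
                      match = character(0), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  data.frame(
    start = starts,
    strand = rep(strand, length(starts)),
    match = substring(sequence, starts + 1L, starts + w),
    stringsAsFactors = FALSE
  )
}

#' Construct a promoter window
#'
#' A promoter sequence with the TSS position recorded, and the scan window
#' given as a half-open interval in base pairs relative to the TSS (0-based;
#' default `c(-2000, 2000)`). The window must be contained in the sequence.
#'
#' @param gene_id Gene identifier.
#' @param sequence Promoter DNA.
#' @param tss_offset 0-based position of the TSS within `sequence`.
#' @param window Length-2 integer vector `c(from, to)` relative to the TSS.
#' @return An object of class `promoter_window`.
#' @export
promoter_window <- function(gene_id, sequence, tss_offset,
                            window = c(-2000L, 2000L)) {
  sequence <- validate_dna(sequence, what = paste0("promoter '", gene_id, "'"))
  stopifnot(length(window) == 2L, window[[1]] < window[[2]])
  lo <- tss_offset + window[[1]]
  hi <- tss_offset + window[[2]]
  if (lo < 0L || hi > nchar(sequence)) {
    stop("window [", window[[1]], ",", window[[2]], ") around TSS at ",
         tss_offset, " exceeds sequence bounds for gene '", gene_id, "'")
  }
  structure(
    list(gene_id = gene_id, sequence = sequence,
         tss_offset = as.integer(tss_offset), window = as.integer(window)),
    class = "promoter_window"
  )
}

#' Predict transcription-factor targets by promoter motif scan
#'
#' A gene is predicted as a target iff at least one motif occurrence lies with
#' its full extent inside the gene's promoter window. Hits are deduplicated
#' per gene; per-gene hit counts and hit coordinates (relative to the TSS) are
#' attached to the result.
#'
#' @param promoters List of [promoter_window] objects.
#' @param pattern A [motif_pattern] or IUPAC string.
#' @param both_strands Scan both strands (default `TRUE`).
#' @return A [gene_set] of predicted targets, with attributes `hits` (a
#'   data.frame of gene_id, start relative to TSS, strand, match) and
#'   `hit_counts` (named integer vector over all scanned genes).
#' @export
predict_targets <- function(promoters, pattern, both_strands = TRUE) {
  if (length(promoters) == 0L) stop("empty promoter list")
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  ok <- vapply(promoters, inherits, TRUE, what = "promoter_window")
  if (!all(ok)) stop("all promoters must be promoter_window objects")
  w <- nchar(pattern$pattern)
  all_hits <- lapply(promoters, function(p) {
    lo <- p$tss_offset + p$window[[1]]
    hi <- p$tss_offset + p$window[[2]]
    if (hi - lo < w) {
      return(data.frame(gene_id = character(0), start = integer(0),
                        strand = character(0), match = character(0),
                        stringsAsFactors = FALSE))
    }
    # scanning the window subsequence enforces the full-extent rule and makes
    # the result independent of bases outside the window
    sub <- substring(p$sequence, lo + 1L, hi)
    h <- match_iupac(pattern, sub, both_strands = both_strands)
    if (nrow(h) == 0L) {
      return(data.frame(gene_id = character(0), start = integer(0),
                        strand = character(0), match = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(gene_id = p$gene_id, start = h$start + p$window[[1]],
               strand = h$strand, match = h$match, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, all_hits)
  gene_ids <- vapply(promoters, `[[`, "", "gene_id")
  counts <- table(factor(hits$gene_id, levels = gene_ids))
  hit_counts <- stats::setNames(as.integer(counts), gene_ids)
  targets <- gene_ids[hit_counts > 0L]
  if (length(targets) == 0L) {
    stop("no promoter contains the motif; no targets predicted")
  }
  out <- gene_set("predicted_targets", targets,
                  description = paste0("promoter scan for ", pattern$pattern))
  attr(out, "hits") <- hits
  attr(out, "hit_counts") <- hit_counts
  out
}

#' Expected background hit rate for an IUPAC motif
#'
#' Closed-form expected number of matches per strand of an i.i.d. uniform
#' A/C/G/T sequence of length `L`: `(L - w + 1)` positions times the product
#' of per-position match probabilities `|class|/4`.
#'
#' @param pattern A [motif_pattern] or IUPAC string.
#' @param length_bp Sequence length `L`.
#' @return Expected hit count (single strand).
#' @export
expected_background_hits <- function(pattern, length_bp) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  chars <- strsplit(pattern$pattern, "", fixed = TRUE)[[1]]
  p_match <- prod(vapply(chars, function(ch) length(IUPAC_CODES[[ch]]) / 4, 0))
  max(0L, length_bp - length(chars) + 1L) * p_match
}
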