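#' @keywords internal
"_PACKAGE"

# Shared small helpers. Sequence utilities live here because motif scanning,
# methylation and the simulators all need them.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of a DNA or IUPAC string
#'
#' Complements every symbol through the IUPAC complement table (so degenerate
#' codes map to their complementary classes, e.g. R to Y) and reverses.
#'
#' @param x A single character string over the IUPAC alphabet.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("WRGTTAAT")
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_COMPLEMENT))
  if (length(bad) > 0L) {
    stop("invalid nucleotide code(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

# validate a sequence over {A,C,G,T,N}; returns the uppercased string
validate_dna <- function(x, what = "sequence", allow_n = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  alphabet <- if (allow_n) DNA_ALPHABET else setdiff(DNA_ALPHABET, "N")
  chars <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, alphabet)
  if (length(bad) > 0L) {
    stop(what, " contains illegal character(s): ", paste(bad, collapse = ", "))
  }
  x
}

# warning with a consistent prefix so filter/dedup actions are greppable in logs
log_warning <- function(...) warning(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the inputs, seeds and parameter values of a run as a two-column TSV
#' (key, value), deliberately free of timestamps so that reruns are
#' byte-identical.
#'
#' @param entries Named list of scalar values.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(entries, path) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  df <- data.frame(
    key = names(entries),
    value = vapply(entries, function(v) paste(format(v), collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
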