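# Readers and writers for the interchange formats every stage touches:
# GMT gene-set collections, GCT/TSV expression matrices, CLS/TSV two-class
# labels, and FASTA. Parsing is strict: malformed input stops with the line
# number, silent coercions are never performed, and every dedup/filter action
# is surfaced as a warning with counts.

#' Construct a gene set
#'
#' A named, ordered collection of unique gene identifiers. Member order is
#' preserved for reporting but the semantics are those of a set; duplicate
#' identifiers are collapsed (first occurrence kept) with a warning.
#'
#' @param name Non-empty set name.
#' @param members Character vector of gene identifiers, non-empty.
#' @param description Free-text description.
#' @return An object of class `gene_set` with fields `name`, `description`,
#'   `members`.
#' @examples
#' gene_set("clotting", c("F2", "FGA", "FGB"))
#' @export
gene_set <- function(name, members, description = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) stop("gene set name must be non-empty")
  members <- as.character(members)
  if (length(members) == 0L) stop("gene set '", name, "' has no members")
  if (anyDuplicated(members)) {
    n_dup <- sum(duplicated(members))
    members <- members[!duplicated(members)]
    log_warning("gene set '", name, "': collapsed ", n_dup,
                " duplicate member id(s)")
  }
  structure(
    list(name = name, description = as.character(description)[1L],
         members = members),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, " (", length(x$members), " genes)\n", sep = "")
  shown <- utils::head(x$members, 8L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$members) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Construct a gene set collection
#'
#' @param sets List of [gene_set] objects with unique names.
#' @param source_label Free-text provenance label.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source_label = "") {
  stopifnot(is.list(sets))
  ok <- vapply(sets, inherits, TRUE, what = "gene_set")
  if (!all(ok)) stop("all elements must be gene_set objects")
  nms <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  structure(list(sets = sets, source_label = source_label),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " sets",
      if (nzchar(x$source_label)) paste0(" [", x$source_label, "]"), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then one or more member identifiers,
#' tab-separated (the de facto MSigDB format). Duplicate members within a line
#' are collapsed with a warning; a duplicate set name across lines is an error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields, ",
           "got ", length(fields))
    }
    sets[[i]] <- gene_set(fields[[1]], fields[-(1:2)],
                          description = fields[[2]])
  }
  gene_set_collection(sets, source_label = basename(path))
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s) {
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a two-class expression dataset
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); log2-scale intensities.
#' @param labels Character/factor of class labels, one per sample; exactly two
#'   distinct values. The first label in order of appearance is class A for
#'   the ranking metric.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)) ||
      any(!nzchar(rownames(values)))) {
    stop("values must have unique, non-empty gene-id rownames")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique sample-id colnames")
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop("label count (", length(labels), ") does not match sample count (",
         ncol(values), ")")
  }
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("exactly two distinct class labels required, got ", length(classes))
  }
  if (any(is.na(values))) stop("expression values contain NA")
  structure(
    list(values = values, labels = labels, classes = classes),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples; classes: ", paste(x$classes, collapse = " vs "), " (",
      paste(tabulate(factor(x$labels, x$classes)), collapse = "/"), ")\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix with two-class labels
#'
#' The matrix may be GCT v1.2 (`#1.2` header, dimension line, Name/Description
#' columns) or plain TSV (first column gene id, header row of sample ids,
#' decimal point only). Labels may be CLS (two-class) or plain text with one
#' label per line / whitespace-separated.
#'
#' @param matrix_path Path to the expression matrix.
#' @param labels_path Path to the class labels.
#' @return An [expression_dataset].
#' @export
read_expression <- function(matrix_path, labels_path) {
  if (!file.exists(matrix_path)) stop("file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("file not found: ", labels_path)
  first <- readLines(matrix_path, n = 1L, warn = FALSE)
  if (identical(substr(first, 1, 4), "#1.2")) {
    values <- .read_gct(matrix_path)
  } else {
    values <- .read_matrix_tsv(matrix_path)
  }
  labels <- .read_labels(labels_path, n_samples = ncol(values))
  expression_dataset(values, labels)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) stop("expression TSV needs a gene-id column plus samples")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression cell in ", path)
  rownames(m) <- ids
  m
}

.read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("truncated GCT file: ", path)
  dims <- suppressWarnings(as.integer(strsplit(lines[[2]], "\t")[[1]][1:2]))
  if (any(is.na(dims))) stop("malformed GCT dimension line")
  df <- utils::read.table(text = lines[-(1:2)], sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("GCT needs Name, Description and sample columns")
  if (nrow(df) != dims[[1]]) {
    stop("GCT declares ", dims[[1]], " genes but contains ", nrow(df), " rows")
  }
  if (ncol(df) - 2L != dims[[2]]) {
    stop("GCT declares ", dims[[2]], " samples but contains ", ncol(df) - 2L)
  }
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression cell in ", path)
  rownames(m) <- as.character(df[[1]])
  m
}

.read_labels <- function(path, n_samples) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) >= 3L && grepl("^\\s*\\d+\\s+\\d+\\s+\\d+\\s*$",
                                   lines[[1]])) {
    # CLS: "<n> <k> 1" / "# nameA nameB" / assignment row
    hdr <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
    if (hdr[[2]] != 2L) stop("CLS file declares ", hdr[[2]],
                             " classes; exactly 2 required")
    class_names <- strsplit(trimws(sub("^#", "", lines[[2]])), "\\s+")[[1]]
    assign <- strsplit(trimws(lines[[3]]), "\\s+")[[1]]
    if (length(assign) != n_samples) {
      stop("CLS assigns ", length(assign), " samples; matrix has ", n_samples)
    }
    if (all(assign %in% c("0", "1")) && length(class_names) == 2L) {
      return(class_names[as.integer(assign) + 1L])
    }
    return(assign)
  }
  labels <- unlist(strsplit(trimws(lines), "\\s+"))
  if (length(labels) != n_samples) {
    stop("label file assigns ", length(labels), " samples; matrix has ",
         n_samples)
  }
  labels
}

#' Write an expression dataset as TSV matrix + label file
#'
#' @param dataset An [expression_dataset].
#' @param matrix_path,labels_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = rownames(dataset$values), dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(dataset$labels, labels_path)
  invisible(matrix_path)
}

#' Read FASTA records as a named character vector
#'
#' Sequences are uppercased and validated over the alphabet A, C, G, T, N.
#' Duplicate record ids, empty files and illegal characters are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids, file
#'   order preserved).
#' @export
read_fasta_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(recs))
  for (i in seq_along(seqs)) {
    seqs[[i]] <- validate_dna(seqs[[i]], what = paste0("record '", ids[[i]], "'"))
  }
  names(seqs) <- ids
  seqs
}

#' Write named sequences as FASTA
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta_records <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}
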