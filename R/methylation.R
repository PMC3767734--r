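# Bisulfite amplicon methylation analysis, top strand only: in-silico
# conversion (unmethylated C reads as T, methylated CpG C protected),
# validation of degenerate primers against both fully-methylated and
# fully-unmethylated converted templates, per-CpG calling from ungapped
# Sanger-style reads with a conversion-failure guard, per-sample methylated
# fractions, and an equal-variance two-sample t comparison between groups.

#' In-silico bisulfite conversion of the top strand
#'
#' Every cytosine converts to thymine except CpG cytosines flagged as
#' methylated. Non-CpG cytosines always convert.
#'
#' @param sequence DNA string.
#' @param methylated Logical vector, one flag per CpG cytosine of `sequence`
#'   in left-to-right order (as returned by [cpg_positions()]).
#' @return The converted sequence.
#' @examples
#' bisulfite_convert("ACGTCCGG", c(FALSE, TRUE)) # "ATGTTCGG"
#' @export
bisulfite_convert <- function(sequence, methylated) {
  sequence <- validate_dna(sequence)
  cpg <- cpg_positions(sequence)
  if (length(methylated) != length(cpg)) {
    stop("methylation state covers ", length(methylated),
         " position(s) but the sequence has ", length(cpg),
         " CpG cytosine(s)")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_c <- chars == "C"
  protect <- rep(FALSE, length(chars))
  if (length(cpg) > 0L) protect[cpg + 1L] <- as.logical(methylated)
  chars[is_c & !protect] <- "T"
  paste(chars, collapse = "")
}

#' 0-based positions of CpG cytosines
#'
#' @param sequence DNA string.
#' @return Integer vector of 0-based positions of each C immediately followed
#'   by G.
#' @export
cpg_positions <- function(sequence) {
  sequence <- validate_dna(sequence)
  m <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1]]
  if (m[[1]] == -1L) integer(0) else as.integer(m) - 1L
}

#' Construct a bisulfite amplicon reference
#'
#' Stores the genomic (pre-conversion) top-strand amplicon, its primers, and
#' the scored region (the interior between the primer footprints, where CpG
#' sites are called). The constructor runs [validate_primers()], so a primer
#' pair that fails on either the fully-methylated or the fully-unmethylated
#' converted template is rejected at construction.
#'
#' @param sequence Genomic top-strand amplicon (no N).
#' @param primer_fwd,primer_rev IUPAC primer strings (reverse primer given
#'   5'->3' on the bottom strand, as synthesized); no N allowed in primers.
#' @return An object of class `amplicon_reference` with fields `sequence`,
#'   `cpg_positions` (all CpGs), `scored_region` (half-open 0-based
#'   interval), `scored_cpgs` (CpGs inside it), `primer_fwd`, `primer_rev`,
#'   `amplicon_length`.
#' @export
amplicon_reference <- function(sequence, primer_fwd, primer_rev) {
  sequence <- validate_dna(sequence, allow_n = FALSE)
  primer_fwd <- toupper(primer_fwd)
  primer_rev <- toupper(primer_rev)
  for (p in c(primer_fwd, primer_rev)) {
    chars <- unique(strsplit(p, "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, setdiff(names(IUPAC_CODES), "N"))
    if (length(bad) > 0L) {
      stop("primer contains disallowed code(s): ", paste(bad, collapse = ", "))
    }
  }
  ref <- structure(
    list(sequence = sequence, cpg_positions = cpg_positions(sequence),
         primer_fwd = primer_fwd, primer_rev = primer_rev),
    class = "amplicon_reference"
  )
  v <- validate_primers(ref)
  ref$scored_region <- v$scored_region
  ref$amplicon_length <- v$amplicon_length
  ref$scored_cpgs <- ref$cpg_positions[
    ref$cpg_positions >= v$scored_region[[1]] &
      ref$cpg_positions < v$scored_region[[2]]]
  ref
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("<amplicon_reference> ", x$amplicon_length, " bp, ",
      length(x$scored_cpgs), " scorable CpG site(s) in scored region [",
      x$scored_region[[1]], ",", x$scored_region[[2]], ")\n", sep = "")
  invisible(x)
}

#' Validate a bisulfite primer pair against both converted templates
#'
#' Confirms that the forward primer and the reverse-complement of the reverse
#' primer each match at exactly one position on both the fully-methylated and
#' the fully-unmethylated bisulfite-converted top strand, at the same
#' coordinates (the degeneracy requirement: a primer overlapping a CpG must
#' carry Y, or R on the bottom strand, at that cytosine).
#'
#' @param reference An `amplicon_reference` (or a bare list with `sequence`,
#'   `primer_fwd`, `primer_rev`, `cpg_positions`).
#' @return List with `fwd_start`, `rev_end` (0-based, half-open),
#'   `scored_region`, `amplicon_length`.
#' @export
validate_primers <- function(reference) {
  seqs <- list(
    methylated = bisulfite_convert(
      reference$sequence, rep(TRUE, length(reference$cpg_positions))),
    unmethylated = bisulfite_convert(
      reference$sequence, rep(FALSE, length(reference$cpg_positions)))
  )
  locate <- function(primer, what) {
    starts <- lapply(names(seqs), function(tmpl) {
      h <- .scan_one(primer, seqs[[tmpl]], "+")
      if (nrow(h) == 0L) {
        stop(what, " primer does not match the ", tmpl,
             " converted template")
      }
      if (nrow(h) > 1L) {
        stop(what, " primer matches the ", tmpl,
             " converted template at ", nrow(h), " positions")
      }
      h$start[[1]]
    })
    if (starts[[1]] != starts[[2]]) {
      stop(what, " primer footprint differs between methylated and ",
           "unmethylated templates")
    }
    starts[[1]]
  }
  fwd_start <- locate(reference$primer_fwd, "forward")
  rev_rc <- reverse_complement(reference$primer_rev)
  rev_start <- locate(rev_rc, "reverse")
  fwd_end <- fwd_start + nchar(reference$primer_fwd)
  rev_end <- rev_start + nchar(rev_rc)
  if (fwd_end >= rev_start) stop("primer footprints overlap or are inverted")
  list(fwd_start = fwd_start, rev_end = rev_end,
       scored_region = c(fwd_end, rev_start),
       amplicon_length = rev_end - fwd_start)
}

#' Call per-CpG methylation from one bisulfite read
#'
#' The read must be an ungapped sequence of exactly the scored region. At
#' each CpG cytosine: C calls methylated, T unmethylated, Y (mixed trace
#' peak, partial methylation) partial, anything else no_call. Every non-CpG
#' reference cytosine must read T; each residual C counts as a bisulfite
#' conversion failure, and a failure rate above `max_failure_rate` rejects
#' the read. Mismatches at non-cytosine positions also reject the read
#' (indels and sequencing artefacts are upstream concerns).
#'
#' @param reference An `amplicon_reference`.
#' @param read Read sequence over A, C, G, T, N, Y; same length as the scored
#'   region.
#' @param sample_id Sample identifier attached to the calls.
#' @param max_failure_rate Maximum tolerated conversion-failure rate
#'   (default 0.01).
#' @return data.frame with `sample_id`, `site` (1-based site index), `position`
#'   (0-based on the amplicon), `call` (factor: methylated, partial,
#'   unmethylated, no_call).
#' @export
call_methylation <- function(reference, read, sample_id = "sample",
                             max_failure_rate = 0.01) {
  stopifnot(inherits(reference, "amplicon_reference"))
  read <- toupper(read)
  bad <- setdiff(unique(strsplit(read, "", fixed = TRUE)[[1]]),
                 c(DNA_ALPHABET, "Y"))
  if (length(bad) > 0L) {
    stop("read contains illegal character(s): ", paste(bad, collapse = ", "))
  }
  region <- reference$scored_region
  region_len <- region[[2]] - region[[1]]
  if (nchar(read) != region_len) {
    stop("read length ", nchar(read), " does not match scored region length ",
         region_len)
  }
  ref_region <- substring(reference$sequence, region[[1]] + 1L, region[[2]])
  ref_chars <- strsplit(ref_region, "", fixed = TRUE)[[1]]
  read_chars <- strsplit(read, "", fixed = TRUE)[[1]]
  cpg_local <- reference$scored_cpgs - region[[1]]
  is_cpg_c <- rep(FALSE, region_len)
  is_cpg_c[cpg_local + 1L] <- TRUE
  non_cpg_c <- which(ref_chars == "C" & !is_cpg_c)
  failures <- sum(read_chars[non_cpg_c] == "C")
  if (length(non_cpg_c) > 0L &&
      failures / length(non_cpg_c) > max_failure_rate) {
    stop("read rejected: ", failures, "/", length(non_cpg_c),
         " unconverted non-CpG cytosine(s) exceeds the conversion-failure ",
         "threshold of ", max_failure_rate)
  }
  other <- which(ref_chars != "C")
  mism <- read_chars[other] != ref_chars[other]
  if (any(mism)) {
    stop("read rejected: ", sum(mism),
         " mismatch(es) at non-cytosine position(s), first at region offset ",
         other[which(mism)[[1]]] - 1L)
  }
  call_base <- read_chars[cpg_local + 1L]
  call <- ifelse(call_base == "C", "methylated",
                 ifelse(call_base == "T", "unmethylated",
                        ifelse(call_base == "Y", "partial", "no_call")))
  data.frame(
    sample_id = sample_id, site = seq_along(cpg_local),
    position = reference$scored_cpgs,
    call = factor(call, levels = c("methylated", "partial", "unmethylated",
                                   "no_call")),
    stringsAsFactors = FALSE
  )
}

#' Assemble a methylation call matrix with per-sample fractions
#'
#' Partial methylation counts as presence of methylation in the fraction
#' (matching the binary filled/empty rendering of amplicon summaries);
#' no_call sites drop out of the denominator.
#'
#' @param calls data.frame of stacked [call_methylation()] results.
#' @return An object of class `methylation_call_matrix`: list with `calls`
#'   (samples x sites character matrix) and `fractions` (named numeric).
#' @export
methylation_call_matrix <- function(calls) {
  stopifnot(all(c("sample_id", "site", "call") %in% names(calls)))
  samples <- unique(calls$sample_id)
  sites <- sort(unique(calls$site))
  m <- matrix(NA_character_, length(samples), length(sites),
              dimnames = list(samples, paste0("site", sites)))
  for (i in seq_len(nrow(calls))) {
    m[calls$sample_id[[i]], paste0("site", calls$site[[i]])] <-
      as.character(calls$call[[i]])
  }
  frac <- apply(m, 1L, function(row) {
    scored <- row[!is.na(row) & row != "no_call"]
    if (length(scored) == 0L) return(NA_real_)
    sum(scored %in% c("methylated", "partial")) / length(scored)
  })
  structure(list(calls = m, fractions = frac),
            class = "methylation_call_matrix")
}

#' @export
print.methylation_call_matrix <- function(x, ...) {
  cat("<methylation_call_matrix> ", nrow(x$calls), " sample(s) x ",
      ncol(x$calls), " site(s)\n", sep = "")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Text rendering of per-sample methylation profiles
#'
#' One row per sample: filled boxes for methylated or partially methylated
#' sites, empty boxes for unmethylated, dots for no-calls.
#'
#' @param x A `methylation_call_matrix`.
#' @return Character vector (one line per sample), invisibly; also printed.
#' @export
methylation_profile_text <- function(x) {
  stopifnot(inherits(x, "methylation_call_matrix"))
  glyph <- c(methylated = "■", partial = "■",
             unmethylated = "□", no_call = ".")
  lines <- vapply(rownames(x$calls), function(s) {
    paste0(format(s, width = 12L), " ",
           paste(glyph[x$calls[s, ]], collapse = ""))
  }, "")
  cat(lines, sep = "\n")
  invisible(unname(lines))
}

#' Compare per-sample methylated fractions between two groups
#'
#' Equal-variance two-sample t-test on the fractions (the standard comparison
#' for small amplicon cohorts). Degenerate inputs follow fixed conventions:
#' identical groups with zero pooled variance give p = 1; complete separation
#' with zero pooled variance gives the smallest representable p with a
#' `separated` flag.
#'
#' @param fractions Named numeric vector of per-sample fractions.
#' @param groups Character/factor of group labels aligned with `fractions`;
#'   exactly two groups, each with >= 2 samples.
#' @return List with `group_means`, `t`, `df`, `p_value`, `separated`.
#' @export
compare_methylation_groups <- function(fractions, groups) {
  groups <- as.character(groups)
  stopifnot(length(fractions) == length(groups))
  gl <- unique(groups)
  if (length(gl) != 2L) stop("exactly two groups required")
  a <- fractions[groups == gl[[1]]]
  b <- fractions[groups == gl[[2]]]
  if (length(a) < 2L || length(b) < 2L) stop(">= 2 samples per group required")
  na <- length(a); nb <- length(b)
  means <- c(mean(a), mean(b))
  names(means) <- gl
  sp2 <- (sum((a - means[[1]])^2) + sum((b - means[[2]])^2)) / (na + nb - 2)
  df <- na + nb - 2
  if (sp2 == 0) {
    if (means[[1]] == means[[2]]) {
      return(list(group_means = means, t = 0, df = df, p_value = 1,
                  separated = FALSE))
    }
    return(list(group_means = means, t = sign(means[[1]] - means[[2]]) * Inf,
                df = df, p_value = .Machine$double.xmin, separated = TRUE))
  }
  tstat <- (means[[1]] - means[[2]]) / sqrt(sp2 * (1 / na + 1 / nb))
  list(group_means = means, t = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df), separated = FALSE)
}

#' Synthetic bisulfite amplicon built to the published primer design
#'
#' Constructs a deterministic, fully synthetic 191 bp amplicon whose ends are
#' the genomic footprints implied by the degenerate primer pair
#' `GGGGTYGAGTTYGATATTAAGT` / `TACCTAAACATCCRATCCACCT` (each Y/R sits on a
#' CpG cytosine, so the primers tolerate both methylation states after
#' conversion) and whose interior is a 147 bp scored region carrying
#' `n_sites` CpG dinucleotides plus non-CpG cytosines that exercise the
#' conversion check. This is a synthetic stand-in for the real amplicon
#' sequence, which is not bundled; only the primer design and site count are
#' reproduced.
#'
#' @param n_sites Number of scorable CpG sites in the interior (default 16).
#' @param interior_length Length of the scored region in bp (default 147; the
#'   published amplicon length of 191 minus two 22-mer primers).
#' @return An `amplicon_reference`.
#' @export
synthetic_hnf1b_amplicon <- function(n_sites = 16L, interior_length = 147L) {
  fwd_genomic <- "GGGGTCGAGTTCGATATTAAGT"   # Y positions restored to CpG C
  rev_genomic <- "AGGTGGATCGGATGTTTAGGTA"   # revcomp of rev primer, R -> CpG C
  unit <- "ACGTACTAT"                        # one CpG + one non-CpG C per unit
  if (n_sites < 1L) stop("need at least one CpG site")
  if (interior_length < n_sites * nchar(unit)) {
    stop("interior_length too small for ", n_sites, " sites")
  }
  pad <- interior_length - n_sites * nchar(unit)
  interior <- paste0(paste(rep(unit, n_sites), collapse = ""),
                     paste(rep("T", pad), collapse = ""))
  amplicon_reference(
    sequence = paste0(fwd_genomic, interior, rev_genomic),
    primer_fwd = "GGGGTYGAGTTYGATATTAAGT",
    primer_rev = "TACCTAAACATCCRATCCACCT"
  )
}
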