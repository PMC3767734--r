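# Relative transcript quantification by the delta-delta-Ct method (assumed
# amplification efficiency 2.0) with exact Mann-Whitney group comparison.

#' Delta-delta-Ct relative quantification
#'
#' Per sample and target gene, `delta_ct = Ct_target - Ct_reference_gene`;
#' the log2 relative level versus the reference sample is
#' `-(delta_ct_sample - delta_ct_reference_sample)` (so the reference
#' sample's own level is 0 for every gene, and adding a constant to every Ct
#' of a sample changes nothing). Samples whose reference gene is missing or
#' undetected are dropped with a warning. Undetected target measurements are
#' imputed to the smallest detectable level observed for that gene and
#' flagged.
#'
#' @param table A `ct_table` data.frame (columns `sample_id`, `group`,
#'   `gene_id`, `ct`, `detected`).
#' @param reference_gene Reference (housekeeping) gene id.
#' @param reference_sample Sample id all levels are expressed against.
#' @return data.frame with `sample_id`, `group`, `gene_id`, `log2_level`,
#'   `imputed`.
#' @export
delta_ct <- function(table, reference_gene, reference_sample) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "group", "gene_id", "ct") %in% names(table)))
  if (is.null(table$detected)) table$detected <- !is.na(table$ct)
  ref_rows <- table[table$gene_id == reference_gene, , drop = FALSE]
  ref_ct <- stats::setNames(ref_rows$ct, ref_rows$sample_id)
  ref_ok <- stats::setNames(ref_rows$detected, ref_rows$sample_id)
  samples <- unique(table$sample_id)
  usable <- samples[samples %in% names(ref_ct) & ref_ok[samples] %in% TRUE]
  dropped <- setdiff(samples, usable)
  if (length(dropped) > 0L) {
    log_warning("dropping ", length(dropped),
                " sample(s) without a detected reference gene: ",
                paste(dropped, collapse = ", "))
  }
  if (!reference_sample %in% usable) {
    stop("reference sample '", reference_sample,
         "' is missing or lacks a detected reference gene")
  }
  targets <- table[table$gene_id != reference_gene &
                     table$sample_id %in% usable, , drop = FALSE]
  out <- NULL
  for (tg in unique(targets$gene_id)) {
    sub <- targets[targets$gene_id == tg, , drop = FALSE]
    ref_row <- sub[sub$sample_id == reference_sample, , drop = FALSE]
    if (nrow(ref_row) == 0L || !isTRUE(ref_row$detected[[1]])) {
      stop("reference sample '", reference_sample,
           "' has no detected measurement for target '", tg, "'")
    }
    dct_ref <- ref_row$ct[[1]] - ref_ct[[reference_sample]]
    dct <- sub$ct - ref_ct[sub$sample_id]
    level <- -(dct - dct_ref)
    imputed <- !sub$detected
    if (any(imputed)) {
      detected_levels <- level[!imputed]
      if (length(detected_levels) == 0L) {
        stop("target '", tg, "' undetected in every sample")
      }
      level[imputed] <- min(detected_levels)
    }
    out <- rbind(out, data.frame(
      sample_id = sub$sample_id, group = sub$group, gene_id = tg,
      log2_level = level, imputed = imputed, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test (exact by enumeration for small samples)
#'
#' `U` counts pairs where a group-A value exceeds a group-B value, ties
#' contributing 1/2. For `nA + nB <= threshold` (default 13, so that a
#' 6-versus-7 design is tested exactly) the two-sided p
#' is exact: all label assignments are enumerated and
#' `p = P(|U - nA nB / 2| >= |U_obs - nA nB / 2|)`, which handles ties by
#' construction. Larger samples use the normal approximation with tie
#' correction and continuity correction. If all values are identical across
#' both groups, p = 1.
#'
#' @param group_a,group_b Numeric vectors, non-empty.
#' @param exact_threshold Total sample size at or below which the exact test
#'   is used (default 13).
#' @return List with `U` (for group A), `p_value`, `method` (`"exact"` or
#'   `"normal"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
mann_whitney <- function(group_a, group_b, exact_threshold = 13L) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(U = na * nb / 2, p_value = 1,
                method = if (na + nb <= exact_threshold) "exact" else "normal"))
  }
  u_stat <- function(idx_a) {
    va <- pooled[idx_a]
    vb <- pooled[-idx_a]
    sum(outer(va, vb, function(x, y) (x > y) + 0.5 * (x == y)))
  }
  u_obs <- u_stat(seq_len(na))
  mu <- na * nb / 2
  if (na + nb <= exact_threshold) {
    combs <- utils::combn(na + nb, na, simplify = FALSE)
    u_all <- vapply(combs, u_stat, 0)
    # tolerance guards half-integer U against floating error
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(U = u_obs, p_value = p, method = "exact"))
  }
  n <- na + nb
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_term)
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = u_obs, p_value = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

#' Per-gene group comparison of relative levels
#'
#' Applies [mann_whitney()] to the log2 levels of each target gene between
#' the two groups of a [delta_ct()] result.
#'
#' @param levels data.frame from [delta_ct()].
#' @param include_imputed Include imputed (undetected) points (default TRUE,
#'   matching the plotted convention of setting them to the smallest
#'   detectable level).
#' @return data.frame with `gene_id`, `group_a`, `group_b`, `median_diff`
#'   (median log2 level, group A minus group B), `U`, `p_value`, `method`.
#' @export
compare_ct_groups <- function(levels, include_imputed = TRUE) {
  stopifnot(all(c("gene_id", "group", "log2_level") %in% names(levels)))
  if (!include_imputed) levels <- levels[!levels$imputed, , drop = FALSE]
  gl <- unique(levels$group)
  if (length(gl) != 2L) stop("exactly two groups required")
  out <- NULL
  for (tg in unique(levels$gene_id)) {
    sub <- levels[levels$gene_id == tg, , drop = FALSE]
    va <- sub$log2_level[sub$group == gl[[1]]]
    vb <- sub$log2_level[sub$group == gl[[2]]]
    mw <- mann_whitney(va, vb)
    out <- rbind(out, data.frame(
      gene_id = tg, group_a = gl[[1]], group_b = gl[[2]],
      median_diff = stats::median(va) - stats::median(vb),
      U = mw$U, p_value = mw$p_value, method = mw$method,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
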