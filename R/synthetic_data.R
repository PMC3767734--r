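# Simulators that produce inputs with the statistical structure each pipeline
# stage assumes: a two-class expression matrix with a planted up-shifted gene
# set, promoters with planted IUPAC motif instantiations (and motif-free
# background, by rejection), a bisulfite amplicon cohort with per-group CpG
# methylation probabilities, Ct tables with a group-level shift, and
# binary-marker/binary-event cohorts with a specified relative risk.
#
# Every generator is a pure function of the configuration: one global seed,
# from which each generator derives its own substream seed as
# (64 * seed + k) mod (2^31 - 1) with a fixed k per generator, so adding a
# generator never perturbs the draws of another.

.SUBSTREAMS <- c(expression = 1L, promoters = 2L, bisulfite = 3L,
                 cohort = 4L, qpcr = 5L, collection = 6L)

.substream_seed <- function(seed, stream) {
  k <- .SUBSTREAMS[[stream]]
  as.integer((64 * (as.numeric(seed) %% 33554432) + k) %% (2^31 - 1))
}

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data module. The
#' defaults are the study conditions the pipeline is designed around: a
#' two-class induction design with 10 samples per class, a planted target
#' set of 50 genes among 5000 shifted by +2 log2 units over unit Gaussian
#' noise; 4 kb promoters; an 8-sample bisulfite cohort with heavily
#' methylated versus nearly unmethylated groups (4 + 4); a 38-patient cohort
#' with 55% marker prevalence, 18% baseline event risk and a 3-fold risk
#' ratio; and a qPCR design of 6 versus 7 samples with a -3 cycle shift.
#'
#' @param seed Integer master seed.
#' @param n_genes,n_per_class,effect_size,noise_sd,planted_set_size
#'   Expression-design parameters (log2 scale; `noise_sd` is the Gaussian SD).
#' @param promoter_length Promoter length in bp (TSS at the midpoint).
#' @param gc_content Background base composition (0.5 = uniform).
#' @param methylation_prob_per_group Named per-group probability that a CpG
#'   site is methylated.
#' @param n_bisulfite_per_group Samples per methylation group.
#' @param cohort_size,marker_prevalence,baseline_event_risk,risk_ratio
#'   Cohort-design parameters; `risk_ratio * baseline_event_risk` must be
#'   <= 1.
#' @param ct_shift Shift in target-gene delta-Ct for the first qPCR group
#'   (cycles; negative means higher expression).
#' @param ct_noise_sd Per-measurement Ct noise SD (cycles).
#' @param n_ct_per_group Named samples per qPCR group.
#' @param ct_detect_limit Ct above which a measurement is undetected ("ND").
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 5000L, n_per_class = 10L,
                       effect_size = 2, noise_sd = 1,
                       planted_set_size = 50L,
                       promoter_length = 4000L, gc_content = 0.5,
                       methylation_prob_per_group = c(serous = 0.9,
                                                      clear_cell = 0.05),
                       n_bisulfite_per_group = 4L,
                       cohort_size = 38L, marker_prevalence = 0.55,
                       baseline_event_risk = 0.18, risk_ratio = 3,
                       ct_shift = -3, ct_noise_sd = 0.5,
                       n_ct_per_group = c(clear_cell = 6L, serous = 7L),
                       ct_detect_limit = 35) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_per_class = as.integer(n_per_class),
              effect_size = effect_size, noise_sd = noise_sd,
              planted_set_size = as.integer(planted_set_size),
              promoter_length = as.integer(promoter_length),
              gc_content = gc_content,
              methylation_prob_per_group = methylation_prob_per_group,
              n_bisulfite_per_group = as.integer(n_bisulfite_per_group),
              cohort_size = as.integer(cohort_size),
              marker_prevalence = marker_prevalence,
              baseline_event_risk = baseline_event_risk,
              risk_ratio = risk_ratio, ct_shift = ct_shift,
              ct_noise_sd = ct_noise_sd,
              n_ct_per_group = n_ct_per_group,
              ct_detect_limit = ct_detect_limit)
  probs <- c(cfg$marker_prevalence, cfg$baseline_event_risk, cfg$gc_content,
             cfg$methylation_prob_per_group)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$risk_ratio * cfg$baseline_event_risk > 1) {
    stop("risk_ratio * baseline_event_risk must be <= 1")
  }
  counts <- c(cfg$n_genes, cfg$n_per_class, cfg$planted_set_size,
              cfg$promoter_length, cfg$cohort_size,
              cfg$n_bisulfite_per_group, cfg$n_ct_per_group)
  if (any(counts <= 0L)) stop("counts must be positive")
  if (cfg$noise_sd < 0 || cfg$ct_noise_sd < 0) stop("noise SDs must be >= 0")
  if (cfg$planted_set_size > cfg$n_genes) {
    stop("planted_set_size exceeds n_genes")
  }
  if (length(cfg$methylation_prob_per_group) != 2L ||
      is.null(names(cfg$methylation_prob_per_group))) {
    stop("methylation_prob_per_group must be a named length-2 vector")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-class expression dataset with a planted target set
#'
#' Background values are Normal(0, `noise_sd`); the planted genes get an
#' additional `effect_size` shift in the "induced" class. Class labels are
#' `induced` then `control`, so the induced class is class A of the ranking
#' metric and the planted set is enriched at the top of the list.
#'
#' @param config A [sim_config].
#' @return List with `dataset` (an [expression_dataset]) and `planted`
#'   (a [gene_set] of the shifted genes).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "expression"))
  ng <- config$n_genes
  np <- config$n_per_class
  gene_ids <- sprintf("g%05d", seq_len(ng))
  values <- matrix(stats::rnorm(ng * 2L * np, sd = config$noise_sd), ng,
                   2L * np)
  planted_idx <- sort.int(sample.int(ng, config$planted_set_size))
  values[planted_idx, seq_len(np)] <-
    values[planted_idx, seq_len(np)] + config$effect_size
  rownames(values) <- gene_ids
  colnames(values) <- c(sprintf("induced_%02d", seq_len(np)),
                        sprintf("control_%02d", seq_len(np)))
  labels <- rep(c("induced", "control"), each = np)
  list(dataset = expression_dataset(values, labels),
       planted = gene_set("planted_targets", gene_ids[planted_idx],
                          description = "genes shifted in the induced class"))
}

#' Simulate promoters with planted motif instantiations
#'
#' Background promoters are i.i.d. draws (uniform by default, GC-biasable via
#' `gc_content`) regenerated until they are motif-free on both strands, so
#' the planted genes are exactly the genes whose promoters contain the motif.
#' Each planted gene receives one instantiation of the IUPAC pattern (each
#' degenerate position sampled uniformly from its class) at a uniform offset
#' with full extent inside the scan window.
#'
#' @param config A [sim_config].
#' @param motif A [motif_pattern] or IUPAC string.
#' @param planted_gene_ids Gene ids to plant the motif into (may be empty).
#' @param gene_ids All gene ids to build promoters for; defaults to the
#'   planted ids plus enough background genes to reach 50.
#' @param window Scan window relative to the TSS, default `c(-2000, 2000)`.
#' @return List with `promoters` (list of [promoter_window]), `tss`
#'   (data.frame gene_id, tss_offset) and `truth` (data.frame gene_id,
#'   motif_start relative to the TSS, instantiation).
#' @export
gen_promoters <- function(config, motif, planted_gene_ids,
                          gene_ids = NULL, window = c(-2000L, 2000L)) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(motif, "motif_pattern")) motif <- motif_pattern(motif)
  w <- nchar(motif$pattern)
  len <- config$promoter_length
  if (w >= window[[2]] - window[[1]] || w > len) {
    stop("motif is longer than the scan window")
  }
  if (is.null(gene_ids)) {
    n_bg <- max(0L, 50L - length(planted_gene_ids))
    gene_ids <- c(planted_gene_ids, sprintf("bg%04d", seq_len(n_bg)))
  }
  if (!all(planted_gene_ids %in% gene_ids)) {
    stop("planted ids must be a subset of gene_ids")
  }
  set.seed(.substream_seed(config$seed, "promoters"))
  tss_offset <- len %/% 2L
  lo <- max(0L, tss_offset + window[[1]])
  hi <- min(len, tss_offset + window[[2]])
  base_probs <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
                  G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  draw_background <- function() {
    for (attempt in seq_len(100L)) {
      s <- paste(sample(names(base_probs), len, replace = TRUE,
                        prob = base_probs), collapse = "")
      if (nrow(match_iupac(motif, s, both_strands = TRUE)) == 0L) return(s)
    }
    stop("could not draw a motif-free background promoter in 100 attempts")
  }
  instantiate <- function() {
    paste(vapply(strsplit(motif$pattern, "", fixed = TRUE)[[1]], function(ch) {
      cls <- IUPAC_CODES[[ch]]
      cls[[sample.int(length(cls), 1L)]]
    }, ""), collapse = "")
  }
  promoters <- vector("list", length(gene_ids))
  truth <- data.frame(gene_id = character(0), motif_start = integer(0),
                      instantiation = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(gene_ids)) {
    gid <- gene_ids[[i]]
    s <- draw_background()
    if (gid %in% planted_gene_ids) {
      inst <- instantiate()
      start_abs <- lo + sample.int(hi - lo - w + 1L, 1L) - 1L
      s <- paste0(substring(s, 1L, start_abs),
                  inst, substring(s, start_abs + w + 1L, len))
      truth <- rbind(truth, data.frame(
        gene_id = gid, motif_start = start_abs - tss_offset,
        instantiation = inst, stringsAsFactors = FALSE))
    }
    promoters[[i]] <- promoter_window(gid, s, tss_offset, window = window)
  }
  tss <- data.frame(gene_id = gene_ids, tss_offset = tss_offset,
                    stringsAsFactors = FALSE)
  list(promoters = promoters, tss = tss, truth = truth)
}

#' Simulate a bisulfite amplicon cohort
#'
#' For each sample, every CpG of the amplicon is methylated independently
#' with its group's probability; the read is the bisulfite conversion of the
#' realized template, trimmed to the scored region.
#'
#' @param config A [sim_config] (fields `methylation_prob_per_group`,
#'   `n_bisulfite_per_group`).
#' @param amplicon_ref An `amplicon_reference` (default:
#'   [synthetic_hnf1b_amplicon()]).
#' @return List with `reads` (named character vector), `groups` (data.frame
#'   sample_id, group) and `truth` (data.frame sample_id, site, methylated
#'   for the scorable sites).
#' @export
gen_bisulfite_samples <- function(config,
                                  amplicon_ref = synthetic_hnf1b_amplicon()) {
  stopifnot(inherits(config, "sim_config"),
            inherits(amplicon_ref, "amplicon_reference"))
  set.seed(.substream_seed(config$seed, "bisulfite"))
  probs <- config$methylation_prob_per_group
  n <- config$n_bisulfite_per_group
  region <- amplicon_ref$scored_region
  scored_idx <- which(amplicon_ref$cpg_positions %in% amplicon_ref$scored_cpgs)
  reads <- character(0)
  groups <- data.frame(sample_id = character(0), group = character(0),
                       stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = character(0), site = integer(0),
                      methylated = logical(0), stringsAsFactors = FALSE)
  for (g in names(probs)) {
    for (i in seq_len(n)) {
      sid <- sprintf("%s_%02d", g, i)
      flags <- stats::runif(length(amplicon_ref$cpg_positions)) < probs[[g]]
      conv <- bisulfite_convert(amplicon_ref$sequence, flags)
      reads[[sid]] <- substring(conv, region[[1]] + 1L, region[[2]])
      groups <- rbind(groups, data.frame(sample_id = sid, group = g,
                                         stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        sample_id = sid, site = seq_along(scored_idx),
        methylated = flags[scored_idx], stringsAsFactors = FALSE))
    }
  }
  list(reads = reads, groups = groups, truth = truth)
}

#' Simulate a binary-marker / binary-event cohort
#'
#' Marker status is Bernoulli(`marker_prevalence`); the event risk is
#' `baseline_event_risk` for marker-negative and `baseline_event_risk *
#' risk_ratio` for marker-positive patients.
#'
#' @param config A [sim_config].
#' @param n Cohort size override (default `config$cohort_size`).
#' @return data.frame with `id`, `marker` (`pos`/`neg`), `event` (`yes`/`no`).
#' @export
gen_cohort <- function(config, n = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "cohort"))
  n <- as.integer(n %||% config$cohort_size)
  marker <- ifelse(stats::runif(n) < config$marker_prevalence, "pos", "neg")
  risk <- ifelse(marker == "pos",
                 config$baseline_event_risk * config$risk_ratio,
                 config$baseline_event_risk)
  event <- ifelse(stats::runif(n) < risk, "yes", "no")
  data.frame(id = sprintf("P%05d", seq_len(n)), marker = marker,
             event = event, stringsAsFactors = FALSE)
}

#' Simulate a qPCR Ct table
#'
#' The reference gene cycles around 20; each target gene has a baseline
#' delta-Ct, shifted by `ct_shift` in the first group. Measurements above the
#' detection limit are emitted as undetected (the `ND` sentinel in TSV form).
#'
#' @param config A [sim_config].
#' @param target_genes Target gene ids (default F2, FGA, FGB).
#' @param reference_gene Reference gene id (default GAPDH).
#' @param base_delta_ct Named baseline delta-Ct per target in the second
#'   (unshifted) group; defaults to 8 cycles each.
#' @return A `ct_table` data.frame: `sample_id`, `group`, `gene_id`, `ct`
#'   (NA when undetected), `detected`.
#' @export
gen_ct_table <- function(config, target_genes = c("F2", "FGA", "FGB"),
                         reference_gene = "GAPDH", base_delta_ct = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "qpcr"))
  if (is.null(base_delta_ct)) {
    base_delta_ct <- stats::setNames(rep(8, length(target_genes)),
                                     target_genes)
  }
  groups <- names(config$n_ct_per_group)
  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    for (i in seq_len(config$n_ct_per_group[[g]])) {
      sid <- sprintf("%s_%02d", g, i)
      ct_ref <- stats::rnorm(1L, 20, 0.2)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = g, gene_id = reference_gene,
        ct = ct_ref, stringsAsFactors = FALSE)
      for (tg in target_genes) {
        shift <- if (gi == 1L) config$ct_shift else 0
        ct <- ct_ref + base_delta_ct[[tg]] + shift +
          stats::rnorm(1L, 0, config$ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene_id = tg, ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$detected <- tab$ct <= config$ct_detect_limit
  tab$ct[!tab$detected] <- NA_real_
  class(tab) <- c("ct_table", "data.frame")
  tab
}

#' Simulate a curated collection with planted overlapping sets
#'
#' Builds `n_planted` sets that genuinely overlap the query (half of each
#' set, at least 3 genes, drawn from the query) plus `n_random` sets drawn
#' uniformly from the universe, for exercising over-representation ranking
#' on known ground truth.
#'
#' @param config A [sim_config] (seed only).
#' @param query Character vector of query genes.
#' @param universe Character vector of universe genes (superset of query).
#' @param n_planted,n_random Set counts.
#' @param set_size Size of every generated set.
#' @return List with `collection` (a [gene_set_collection]) and
#'   `planted_names` (character).
#' @export
gen_overlap_collection <- function(config, query, universe, n_planted = 3L,
                                   n_random = 100L, set_size = 20L) {
  stopifnot(inherits(config, "sim_config"), all(query %in% universe))
  set.seed(.substream_seed(config$seed, "collection"))
  k_in <- max(3L, set_size %/% 2L)
  sets <- vector("list", n_planted + n_random)
  for (i in seq_len(n_planted)) {
    inq <- sample(query, min(k_in, length(query)))
    rest <- sample(setdiff(universe, inq), set_size - length(inq))
    sets[[i]] <- gene_set(sprintf("planted_set_%02d", i), c(inq, rest))
  }
  for (i in seq_len(n_random)) {
    sets[[n_planted + i]] <- gene_set(sprintf("random_set_%03d", i),
                                      sample(universe, set_size))
  }
  list(collection = gene_set_collection(sets, source_label = "synthetic"),
       planted_names = sprintf("planted_set_%02d", seq_len(n_planted)))
}

#' Write a Ct table as TSV (undetected as "ND")
#'
#' @param table A `ct_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ct_table <- function(table, path) {
  out <- as.data.frame(table)[, c("sample_id", "group", "gene_id", "ct")]
  out$ct <- ifelse(is.na(out$ct), "ND", format(out$ct, digits = 10))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Ct table TSV written by [write_ct_table()]
#'
#' @param path Input path.
#' @return A `ct_table` data.frame with NA for the `ND` sentinel.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character"))
  stopifnot(all(c("sample_id", "group", "gene_id", "ct") %in% names(df)))
  detected <- df$ct != "ND"
  ct <- suppressWarnings(as.numeric(df$ct))
  if (any(is.na(ct) & detected)) stop("non-numeric Ct value that is not 'ND'")
  df$ct <- ct
  df$detected <- detected
  class(df) <- c("ct_table", "data.frame")
  df
}
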