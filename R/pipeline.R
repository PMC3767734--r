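# End-to-end orchestration on synthetic inputs: simulate every scenario,
# then chain motif target prediction, enrichment, leading-edge overlap,
# methylation, qPCR and association statistics, with every stage writing
# plain-text outputs and a manifest free of timestamps so reruns are
# byte-identical.

#' Default pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed (drives the simulation config).
#' @param stages Character vector of stages to run, in dependency order;
#'   subset of `c("simulate", "targets", "gsea", "overlap", "methylation",
#'   "qpcr", "assoc")`.
#' @param motif IUPAC consensus scanned by the target-prediction stage.
#' @param n_perm GSEA permutations.
#' @param weight_exponent GSEA weight.
#' @param perm_mode GSEA permutation mode.
#' @param overlap_p_max,overlap_q_max Over-representation report filters.
#' @param sim Optional [sim_config] override (its seed wins).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            stages = c("simulate", "targets", "gsea",
                                       "overlap", "methylation", "qpcr",
                                       "assoc"),
                            motif = "WRGTTAATNATTAACNNN",
                            n_perm = 999L, weight_exponent = 1,
                            perm_mode = "gene_set",
                            overlap_p_max = 0.01, overlap_q_max = 0.25,
                            sim = NULL) {
  known <- c("simulate", "targets", "gsea", "overlap", "methylation",
             "qpcr", "assoc")
  if (length(stages) > 0L && !all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed), stages = stages,
         motif = motif, n_perm = as.integer(n_perm),
         weight_exponent = weight_exponent, perm_mode = perm_mode,
         overlap_p_max = overlap_p_max, overlap_q_max = overlap_q_max,
         sim = sim %||% sim_config(seed = seed)),
    class = "pipeline_config"
  )
}

#' Run the integrative pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order, each stage consuming the
#' files of its predecessors from `outdir`. With every stage enabled the
#' chain is: simulate all scenarios; predict targets from the promoter scan;
#' test the predicted set for enrichment in the induction contrast and
#' extract its leading edge; rank curated-set overlaps of the leading edge;
#' call methylation and compare groups; quantify transcripts and compare
#' groups; tabulate the cohort and compute Fisher p / relative risk. With no
#' stages enabled an empty report is written and the run succeeds.
#'
#' @param config A [pipeline_config] (or a path to a YAML file with its
#'   fields).
#' @return Named list of per-stage results, invisibly; files under
#'   `config$outdir`, including `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfg_list)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  on <- function(stage) stage %in% config$stages
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("stage '", stage, "': required input not found: ", path)
    }
    path
  }
  out <- list()
  manifest <- list(seed = config$seed, motif = config$motif,
                   n_perm = config$n_perm,
                   weight_exponent = config$weight_exponent,
                   perm_mode = config$perm_mode,
                   stages = paste(config$stages, collapse = ","))
  p <- function(...) file.path(config$outdir, ...)

  if (on("simulate")) {
    sim <- config$sim
    expr <- gen_expression(sim)
    write_expression(expr$dataset, p("expression.tsv"), p("labels.txt"))
    write_gmt(gene_set_collection(list(expr$planted)), p("planted.gmt"))
    half <- sim$promoter_length %/% 2L
    prom <- gen_promoters(sim, config$motif,
                          planted_gene_ids = utils::head(
                            expr$planted$members, 25L),
                          window = c(-half, sim$promoter_length - half))
    write_fasta_records(
      stats::setNames(vapply(prom$promoters, `[[`, "", "sequence"),
                      vapply(prom$promoters, `[[`, "", "gene_id")),
      p("promoters.fa"))
    utils::write.table(prom$tss, p("tss.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(prom$truth, p("promoter_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bis <- gen_bisulfite_samples(sim)
    write_fasta_records(bis$reads, p("bisulfite_reads.fa"))
    utils::write.table(bis$groups, p("bisulfite_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bis$truth, p("bisulfite_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_ct_table(gen_ct_table(sim), p("ct.tsv"))
    utils::write.table(gen_cohort(sim, n = sim$cohort_size), p("cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$simulate <- list(planted = expr$planted,
                         promoter_truth = prom$truth)
    manifest$n_genes <- sim$n_genes
    manifest$planted_set_size <- sim$planted_set_size
  }

  if (on("targets")) {
    seqs <- read_fasta_records(need(p("promoters.fa"), "targets"))
    tss <- utils::read.table(need(p("tss.tsv"), "targets"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    promoters <- lapply(seq_along(seqs), function(i) {
      gid <- names(seqs)[[i]]
      off <- tss$tss_offset[match(gid, tss$gene_id)]
      # scan the full recorded promoter as the window
      promoter_window(gid, seqs[[i]], off,
                      window = c(-off, nchar(seqs[[i]]) - off))
    })
    targets <- predict_targets(promoters, config$motif)
    write_gmt(gene_set_collection(list(targets)), p("predicted_targets.gmt"))
    utils::write.table(attr(targets, "hits"), p("motif_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$targets <- targets
    manifest$n_predicted_targets <- length(targets$members)
  }

  if (on("gsea")) {
    ds <- read_expression(need(p("expression.tsv"), "gsea"),
                          need(p("labels.txt"), "gsea"))
    coll <- read_gmt(need(p("predicted_targets.gmt"), "gsea"))
    res <- run_gsea(ds, coll, mode = config$perm_mode,
                    n_perm = config$n_perm, seed = config$seed,
                    weight_exponent = config$weight_exponent)
    utils::write.table(res$table, p("gsea_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gmt(gene_set_collection(unname(res$leading_edges)),
              p("leading_edge.gmt"))
    out$gsea <- res
    manifest$gsea_top_p <- res$table$p_nominal[[1]]
  }

  if (on("overlap")) {
    le <- read_gmt(need(p("leading_edge.gmt"), "overlap"))
    ds <- read_expression(need(p("expression.tsv"), "overlap"),
                          need(p("labels.txt"), "overlap"))
    universe <- rownames(ds$values)
    query <- le$sets[[1]]
    coll <- gen_overlap_collection(config$sim, query$members, universe)
    top <- rank_overlaps(query, coll$collection, universe,
                         p_max = config$overlap_p_max,
                         q_max = config$overlap_q_max)
    utils::write.table(attr(top, "full"), p("overlap_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$overlap <- list(top = top, planted_names = coll$planted_names)
    manifest$n_overlap_hits <- nrow(top)
  }

  if (on("methylation")) {
    ref <- synthetic_hnf1b_amplicon()
    reads <- read_fasta_records(need(p("bisulfite_reads.fa"), "methylation"))
    groups <- utils::read.table(need(p("bisulfite_groups.tsv"), "methylation"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    calls <- do.call(rbind, lapply(names(reads), function(sid) {
      call_methylation(ref, reads[[sid]], sample_id = sid)
    }))
    mat <- methylation_call_matrix(calls)
    cmp <- compare_methylation_groups(
      mat$fractions[groups$sample_id],
      groups$group)
    utils::write.table(
      data.frame(sample_id = rownames(mat$calls), mat$calls,
                 fraction = mat$fractions, stringsAsFactors = FALSE),
      p("methylation_calls.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    out$methylation <- list(matrix = mat, comparison = cmp)
    manifest$methylation_p <- cmp$p_value
  }

  if (on("qpcr")) {
    ct <- read_ct_table(need(p("ct.tsv"), "qpcr"))
    ref_sample <- ct$sample_id[ct$group == utils::tail(unique(ct$group),
                                                       1L)][[1]]
    levels <- delta_ct(ct, reference_gene = "GAPDH",
                       reference_sample = ref_sample)
    cmp <- compare_ct_groups(levels)
    utils::write.table(levels, p("qpcr_levels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cmp, p("qpcr_comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$qpcr <- list(levels = levels, comparison = cmp)
    manifest$qpcr_min_p <- min(cmp$p_value)
  }

  if (on("assoc")) {
    cohort <- utils::read.table(need(p("cohort.tsv"), "assoc"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
    tab <- cohort_to_table(cohort)
    res <- assoc_test(tab)
    utils::write.table(
      data.frame(a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                 risk_ratio = res$risk_ratio, fisher_p = res$p_value),
      p("assoc_results.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    out$assoc <- res
    manifest$assoc_p <- res$p_value
  }

  write_manifest(manifest, p("manifest.tsv"))
  invisible(out)
}
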