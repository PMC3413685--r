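# End-to-end orchestration: simulate -> filter -> assemble (several k) ->
# homologue-keyed merge -> coverage/completeness -> enzyme annotation ->
# reports, under one declarative configuration with fixed seeds.

#' Pipeline configuration
#'
#' Collects every stage threshold in one place, at its standard default:
#' quality window 25-of-35 above Q30; homology alignment length > 60 aa at
#' E < 1e-5; known-mRNA validation identity > 95% with > 80% of the isotig
#' aligned; target-site scans at identity > 90%; the k sweep over odd
#' 21..41 anchored at base k = 31.
#'
#' @param sim a [sim_config()] describing the synthetic input data.
#' @param k_values odd k values to assemble at.
#' @param base_k anchor k for homologue-keyed merging; must be in
#'   `k_values`.
#' @param min_count,max_paths assembler settings (see [extract_contigs()],
#'   [build_isotigs()]).
#' @param min_isotig_len minimum isotig length for the reported set
#'   (default 100).
#' @param min_aa,max_e homology thresholds.
#' @param mrna_identity,mrna_cov known-mRNA validation thresholds.
#' @param targetsite_identity translated-scan identity threshold.
#' @param quality list with `window`, `min_good`, `min_q`.
#' @param adapters adapter list for the content filter.
#' @param protein_identity identity of the simulated protein database to
#'   the true translations.
#' @param coverage target read fold-coverage handed to the simulator.
#' @param read_mode "sampled" or "tiled" (see [simulate_reads()]).
#' @param n_known_mrnas how many true transcripts are withheld as "known
#'   mRNAs" for the validation stage.
#' @param target_scan logical: run the translated target-site scan against
#'   diverged reference-gene copies.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            k_values = seq(21L, 41L, by = 2L),
                            base_k = 31L,
                            min_count = 1L, max_paths = 16L,
                            min_isotig_len = 100L,
                            min_aa = 60L, max_e = 1e-5,
                            mrna_identity = 0.95, mrna_cov = 0.80,
                            targetsite_identity = 0.90,
                            quality = list(window = 35L, min_good = 25L,
                                           min_q = 30L),
                            adapters = NULL,
                            protein_identity = 0.90,
                            coverage = 30, read_mode = "sampled",
                            n_known_mrnas = 10L,
                            target_scan = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  k_values <- as.integer(k_values)
  base_k <- as.integer(base_k)
  if (any(k_values %% 2L == 0L)) stop("all k values must be odd")
  if (!base_k %in% k_values)
    stop("base_k = ", base_k, " is not among k_values")
  for (nm in c("mrna_identity", "mrna_cov", "targetsite_identity")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(nm, " must lie in [0,1]")
  }
  if (min_aa < 0 || max_e <= 0) stop("invalid homology thresholds")
  stopifnot(all(c("window", "min_good", "min_q") %in% names(quality)))
  cfg <- list(sim = sim, k_values = k_values, base_k = base_k,
              min_count = as.integer(min_count),
              max_paths = as.integer(max_paths),
              min_isotig_len = as.integer(min_isotig_len),
              min_aa = min_aa, max_e = max_e,
              mrna_identity = mrna_identity, mrna_cov = mrna_cov,
              targetsite_identity = targetsite_identity,
              quality = quality,
              adapters = adapters %||% sim$adapter,
              protein_identity = protein_identity,
              coverage = coverage, read_mode = read_mode,
              n_known_mrnas = as.integer(n_known_mrnas),
              target_scan = isTRUE(target_scan))
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a transcriptome, protein/enzyme databases and paired reads;
#' filters the reads; assembles at every configured k; merges the per-k
#' isotig sets by homologue novelty; maps reads back for coverage; computes
#' completeness and its binned summary; predicts EC groups with motif
#' confirmation, deduplicates by coverage and collapses isotigs into
#' putative genes; and validates against withheld known mRNAs.  All stage
#' outputs are written under `out_dir` along with a machine-readable
#' manifest; reruns with the same configuration produce identical
#' manifests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(thresholds = config[setdiff(names(config), "sim")],
                   sim = unclass(config$sim), counts = list())
  # --- simulate ------------------------------------------------------------
  tx <- .stage("simulate", generate_transcriptome(config$sim))
  prot_db <- .stage("simulate", build_protein_db(
    tx, target_identity = config$protein_identity,
    seed = config$sim$seed + 2L))
  truth <- attr(prot_db, "truth")
  pairs <- .stage("simulate", simulate_reads(
    tx, config$sim, coverage = config$coverage, mode = config$read_mode))
  set.seed(config$sim$seed + 3L)
  known_idx <- sample(nrow(tx), min(config$n_known_mrnas, nrow(tx)))
  known <- stats::setNames(tx$sequence[known_idx], tx$isoform_id[known_idx])
  write_fasta(stats::setNames(tx$sequence, tx$isoform_id),
              file.path(out_dir, "transcripts.fa"), type = "DNA")
  write_fasta(prot_db, file.path(out_dir, "proteins.fa"), type = "AA")
  write_read_pairs(pairs, file.path(out_dir, "reads"))
  utils::write.table(as.data.frame(tx)[, c("gene_id", "isoform_id",
                                           "expression", "ec")],
                     file.path(out_dir, "truth_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$n_genes <- length(unique(tx$gene_id))
  manifest$counts$n_transcripts <- nrow(tx)
  manifest$counts$n_read_pairs <- nrow(pairs)
  # --- filter --------------------------------------------------------------
  fl <- .stage("readqc", filter_read_pairs(
    pairs, adapters = config$adapters,
    window = config$quality$window, min_good = config$quality$min_good,
    min_q = config$quality$min_q))
  .write_kv_tsv(list(
    n_input = fl$report$n_input, n_retained = fl$report$n_retained,
    n_paired_retained = fl$report$n_paired_retained,
    n_single_retained = fl$report$n_single_retained,
    total_retained_length = fl$report$total_retained_length),
    file.path(out_dir, "qc_report.tsv"))
  manifest$counts$reads_input <- fl$report$n_input
  manifest$counts$reads_retained <- fl$report$n_retained
  manifest$counts$reads_paired <- fl$report$n_paired_retained
  manifest$counts$reads_single <- fl$report$n_single_retained
  asm_reads <- c(fl$pairs$bases1, fl$pairs$bases2, fl$singles$bases)
  asm_reads <- asm_reads[grepl("^[ACGT]+$", asm_reads)]
  # --- assemble at each k --------------------------------------------------
  per_k <- list()
  all_assign <- list()
  idx_cache <- NULL
  for (k in config$k_values) {
    iso_k <- .stage(paste0("assemble_k", k), {
      g <- build_graph(asm_reads, k)
      ctg <- extract_contigs(g, min_count = config$min_count)
      bi <- build_isotigs(g, ctg, max_paths = config$max_paths)
      bi$isotigs[bi$isotigs$length >= config$min_isotig_len, , drop = FALSE]
    })
    per_k[[as.character(k)]] <- iso_k
    write_fasta(stats::setNames(iso_k$sequence, iso_k$isotig_id),
                file.path(out_dir, sprintf("isotigs.k%d.fa", k)),
                type = "DNA")
    st <- assembly_stats(iso_k$sequence)
    utils::write.table(st, file.path(out_dir, sprintf("stats.k%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    all_assign[[as.character(k)]] <- .stage(
      paste0("homology_k", k),
      assign_homologues(iso_k, prot_db,
                        min_aa = config$min_aa, max_e = config$max_e))
  }
  assignments <- do.call(rbind, all_assign)
  rownames(assignments) <- NULL
  # --- merge ---------------------------------------------------------------
  mg <- .stage("merge", merge_multi_k(per_k, assignments,
                                      base_k = config$base_k))
  merged <- mg$isotigs
  write_fasta(stats::setNames(merged$sequence, merged$isotig_id),
              file.path(out_dir, "isotigs.merged.fa"), type = "DNA")
  utils::write.table(mg$tally, file.path(out_dir, "merge_tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$isotigs_per_k <-
    stats::setNames(as.list(vapply(per_k, nrow, 0L)), names(per_k))
  manifest$counts$isotigs_merged <- nrow(merged)
  # --- coverage + completeness --------------------------------------------
  cov <- .stage("metrics", map_reads(merged, asm_reads))
  merged_assign <- assignments[assignments$isotig_id %in% merged$isotig_id, ]
  ct <- completeness_table(merged_assign, prot_db, coverage_profiles = cov)
  bins <- if (nrow(ct)) completeness_coverage_bins(ct) else NULL
  utils::write.table(cov$profiles, file.path(out_dir, "coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ct, file.path(out_dir, "completeness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bins))
    utils::write.table(bins, file.path(out_dir, "completeness_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$isotigs_with_homologue <- nrow(merged_assign)
  # --- enzyme annotation ---------------------------------------------------
  enz_truth <- truth[!is.na(truth$ec), , drop = FALSE]
  preds <- NULL
  if (nrow(enz_truth)) {
    edb <- enzyme_db(prot_db[enz_truth$protein_id], enz_truth$ec)
    write_enzyme_db(edb, file.path(out_dir, "enzymes.fa"))
    preds <- .stage("annotate", predict_ec_batch(
      merged, edb, min_aa = config$min_aa, max_e = config$max_e))
    covs <- stats::setNames(cov$profiles$mean_depth,
                            cov$profiles$isotig_id)
    preds <- dedupe_by_coverage(preds, covs)
    fam <- c("1.14.14.1" = "P450", "2.5.1.18" = "GST",
             "3.1.1.1" = "COE", "3.1.1.7" = "AChE")
    cg <- collapse_genes(preds, covs, families = fam)
    utils::write.table(preds, file.path(out_dir, "ec_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cg$tally, file.path(out_dir, "gene_tally.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$ec_predictions <- nrow(preds)
    manifest$counts$putative_enzyme_genes <-
      if (nrow(cg$clusters)) nrow(cg$clusters) else 0L
  }
  # --- validation ----------------------------------------------------------
  val <- .stage("validate", validate_against_known(
    merged, known, min_identity = config$mrna_identity,
    min_cov = config$mrna_cov))
  utils::write.table(val, file.path(out_dir, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$validated_pairs <- nrow(val)
  # --- optional target-site scan ------------------------------------------
  if (config$target_scan) {
    refs <- build_reference_genes(
      tx, gene_ids = utils::head(unique(tx$gene_id), 5L),
      target_identity = 0.97, seed = config$sim$seed + 4L)
    scan <- .stage("target_scan", translated_scan(
      merged, refs, min_identity = config$targetsite_identity))
    utils::write.table(scan, file.path(out_dir, "target_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$target_site_hits <- sum(scan$passes)
  }
  # --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$files <- stats::setNames(
    as.list(unname(tools::md5sum(file.path(out_dir, files)))), files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
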