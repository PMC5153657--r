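#' Simulate a study and write it to disk
#'
#' Runs [simulate_study()] and writes genome FASTA, gene-model GTF, paired
#' FASTQ per library, the truth tables, the effective config and a library
#' manifest into `out_dir` (created if missing).
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return The `sim_study`, invisibly; file layout: `genome.fa`,
#'   `genes.gtf`, `fastq/<library>_[12].fastq`, `truth/`, `manifest.tsv`,
#'   `config.json`.
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(file.path(out_dir, "fastq"), showWarnings = FALSE,
             recursive = TRUE)
  study <- simulate_study(cfg)
  write_genome_fasta(study$bundle, file.path(out_dir, "genome.fa"))
  write_gtf(study$bundle, file.path(out_dir, "genes.gtf"))
  write_truth(study$truth, file.path(out_dir, "truth"))
  write_sim_config(cfg, file.path(out_dir, "config.json"))
  manifest <- study$design %>%
    mutate(fastq1 = file.path("fastq", paste0(.data$library_id, "_1.fastq")),
           fastq2 = file.path("fastq", paste0(.data$library_id, "_2.fastq")))
  for (lib in names(study$reads)) {
    write_fastq_pairs(study$reads[[lib]],
                      file.path(out_dir, "fastq", lib))
  }
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(study)
}

#' Load a simulated study directory back into memory
#'
#' @param dir Directory written by [run_simulate()].
#' @return A `sim_study` (without per-read truth reconstruction beyond the
#'   truth tables).
#' @export
load_study <- function(dir) {
  bundle <- read_genome_bundle(file.path(dir, "genome.fa"),
                               file.path(dir, "genes.gtf"))
  truth <- read_truth(file.path(dir, "truth"))
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              col_types = readr::cols(), progress = FALSE)
  reads <- purrr::pmap(manifest, function(library_id, fastq1, fastq2, ...) {
    read_fastq_pairs(file.path(dir, fastq1), file.path(dir, fastq2))
  })
  names(reads) <- manifest$library_id
  structure(list(bundle = bundle, circs = truth$circs, truth = truth,
                 reads = reads,
                 design = manifest %>%
                   select("library_id", "tissue", "age", "replicate"),
                 config = read_sim_config(file.path(dir, "config.json"))),
            class = "sim_study")
}

#' Run the full circRNA pipeline on a study
#'
#' Detection, annotation merging, multi-gene filtering, scaffold
#' quantification with duplicate removal, per-tissue expression filtering,
#' TPM/FPKM normalization, old-vs-young differential tests, global shift
#' tests, circular/linear independence, feature classification, PCA,
#' optional microRNA seed-site scanning, and a summary written as JSON.
#' Stages write their tables into `out_dir`; with `overwrite = FALSE` a
#' directory whose `summary.json` already exists is returned as-is (per-run
#' no-op).
#'
#' @param study A `sim_study` (from [simulate_study()] or [load_study()]).
#' @param out_dir Output directory (created).
#' @param known Optional known circRNA annotation tibble (BED-like) merged
#'   with de novo calls.
#' @param min_reads,anchor_length,max_mismatches Detection parameters.
#' @param flank,score_threshold,min_overhang Quantification parameters.
#' @param fc_cutoff,alpha Differential-expression parameters. All defaults
#'   are the study-faithful values (6-read minimum, 20 nt anchors, 100 nt
#'   flanks, score threshold -15, 1.5-fold cutoff, alpha 0.05).
#' @param mirna Scan retained circRNA loci for seed sites using the
#'   packaged family list.
#' @param overwrite Recompute even if `summary.json` exists.
#' @return A `circ_results` list (components named as written to disk),
#'   invisibly `summary` holds the summary list.
#' @export
run_all <- function(study, out_dir, known = NULL, min_reads = 6L,
                    anchor_length = 20L, max_mismatches = 2L, flank = 100L,
                    score_threshold = -15, min_overhang = 10L,
                    fc_cutoff = 1.5, alpha = 0.05, mirna = FALSE,
                    overwrite = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(out_dir, "summary.json")
  if (!overwrite && file.exists(summary_path)) {
    inform("run_all: summary.json present, skipping (overwrite = FALSE)")
    return(invisible(jsonlite::read_json(summary_path)))
  }
  bundle <- study$bundle
  design <- study$design

  # 1. de novo detection ----------------------------------------------------
  det <- detect_circrnas(study$reads, bundle, min_reads = min_reads,
                         anchor_length = anchor_length,
                         max_mismatches = max_mismatches)
  write_junctions_bed(det$junctions, file.path(out_dir, "denovo.bed"))
  readr::write_tsv(det$lib_stats, file.path(out_dir, "lib_stats.tsv"))

  # 2. merge annotations, multi-gene filter ---------------------------------
  merged <- merge_annotations(known = known, denovo = det$junctions)
  mg <- multigene_filter(merged, bundle)
  ann <- mg$kept
  readr::write_tsv(mg$removed, file.path(out_dir, "multigene_removed.tsv"))
  readr::write_tsv(ann, file.path(out_dir, "annotation.tsv"))

  results <- list(detection = det, annotation = ann,
                  multigene_removed = mg$removed)
  summary <- list(
    n_denovo_junctions = nrow(det$junctions),
    n_multigene_removed = nrow(mg$removed),
    n_annotated = nrow(ann))

  if (nrow(ann) > 0) {
    # 3. scaffolds & quantification ------------------------------------------
    scaffolds <- build_scaffolds(ann, bundle, flank = flank)
    n_linear <- setNames(det$lib_stats$n_linear, det$lib_stats$library_id)
    quant <- quantify_junctions(study$reads, scaffolds, design, n_linear,
                                score_threshold = score_threshold,
                                min_overhang = min_overhang)
    readr::write_tsv(quant$matrix$counts, file.path(out_dir, "counts.tsv"))
    readr::write_tsv(quant$matrix$lib_totals,
                     file.path(out_dir, "lib_totals.tsv"))

    # 4. expression filter, TPM, DE, shift ------------------------------------
    ef <- expression_filter(quant$matrix, min_total = min_reads,
                            strict = FALSE)
    readr::write_tsv(ef$membership, file.path(out_dir, "membership.tsv"))
    tpm <- circ_tpm(quant$matrix)
    readr::write_tsv(tpm$values, file.path(out_dir, "tpm.tsv"))
    fpkm <- gene_fpkm(det$linear_hits, bundle, design)
    readr::write_tsv(fpkm$values, file.path(out_dir, "fpkm.tsv"))
    host_map <- ann %>% select("circ_id", gene_id = "host_gene")

    per_tissue <- list()
    for (ts in unique(design$tissue)) {
      retained <- ef$membership %>%
        filter(.data$tissue == ts, .data$retained)
      tpm_ts <- tpm
      tpm_ts$values <- tpm$values %>%
        semi_join(retained, by = c(feature_id = "circ_id"))
      if (nrow(tpm_ts$values) == 0) next
      de <- differential(tpm_ts, ts, fc_cutoff = fc_cutoff, alpha = alpha,
                         correct = "none")
      shift <- global_shift(tpm_ts, ts)
      lde <- differential(fpkm, ts, fc_cutoff = fc_cutoff, alpha = alpha,
                          correct = "BH")
      indep <- circ_linear_independence(de, lde, host_map,
                                        circ_expr = tpm_ts,
                                        linear_expr = fpkm, tissue = ts)
      readr::write_tsv(as_tibble(de),
                       file.path(out_dir, paste0("de_circ_", ts, ".tsv")))
      readr::write_tsv(as_tibble(lde),
                       file.path(out_dir, paste0("de_linear_", ts, ".tsv")))
      readr::write_tsv(indep$density,
                       file.path(out_dir, paste0("independence_", ts,
                                                 ".tsv")))
      per_tissue[[ts]] <- list(de = de, linear_de = lde, shift = shift,
                               independence = indep)
      summary[[paste0("n_retained_", ts)]] <- nrow(retained)
      summary[[paste0("n_up_", ts)]] <- sum(de$status == "up")
      summary[[paste0("n_down_", ts)]] <- sum(de$status == "down")
      summary[[paste0("global_shift_p_", ts)]] <- shift$p_value
      summary[[paste0("coup_fraction_", ts)]] <- indep$overlap_fraction
    }

    # 5. features, overlap, PCA ----------------------------------------------
    feats <- circ_features(ann, bundle)
    readr::write_tsv(feats, file.path(out_dir, "features.tsv"))
    overlap <- tissue_overlap(ef$membership)
    readr::write_tsv(overlap, file.path(out_dir, "tissue_overlap.tsv"))
    pca <- pca_expression(tpm)
    summary$n_all_tissues <-
      overlap$count[overlap$n_tissues == max(overlap$n_tissues)][1]
    summary$pc1_variance <- pca$variance_fraction[1]

    mir <- NULL
    if (mirna) {
      fams <- read_mir_families()
      mir <- purrr::map(seq_len(nrow(ann)),
                        ~scan_circ_sites(ann[.x, ], bundle, fams)) %>%
        list_rbind()
      readr::write_tsv(mir, file.path(out_dir, "mir_sites.tsv"))
      readr::write_tsv(top_families(mir),
                       file.path(out_dir, "mir_top_families.tsv"))
      summary$n_circ_with_sites <- n_distinct(mir$circ_id)
    }

    results <- c(results, list(
      scaffolds = scaffolds, matrix = quant$matrix,
      alignments = quant$alignments, membership = ef$membership,
      tpm = tpm, fpkm = fpkm, per_tissue = per_tissue, features = feats,
      overlap = overlap, pca = pca, mir_sites = mir))
  }

  summary <- purrr::map(summary, function(x) {
    if (is.numeric(x) && length(x) == 1 && !is.finite(x)) NA else x
  })
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  results$summary <- summary
  class(results) <- "circ_results"
  invisible(results)
}

#' Human-readable study report
#'
#' Renders the `summary.json` of a results directory as markdown text.
#'
#' @param results_dir Directory written by [run_all()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
report <- function(results_dir) {
  path <- file.path(results_dir, "summary.json")
  if (!file.exists(path)) {
    abort(sprintf("no summary.json under '%s' (run run_all() first)", path))
  }
  s <- jsonlite::read_json(path)
  digest <- unname(tools::md5sum(path))
  ver <- as.character(utils::packageVersion("circaging"))
  lines <- c(
    "# circRNA aging study report",
    sprintf("- circaging %s; summary digest %s", ver, digest),
    sprintf("- de novo junctions: %s; multi-gene removed: %s; annotated: %s",
            s$n_denovo_junctions, s$n_multigene_removed, s$n_annotated))
  for (key in grep("^n_retained_", names(s), value = TRUE)) {
    ts <- sub("^n_retained_", "", key)
    lines <- c(lines, sprintf(
      "- %s: %s retained; %s up / %s down; global shift P = %.3g; co-up fraction %.3f",
      ts, s[[key]], s[[paste0("n_up_", ts)]], s[[paste0("n_down_", ts)]],
      as.numeric(s[[paste0("global_shift_p_", ts)]] %||% NA),
      as.numeric(s[[paste0("coup_fraction_", ts)]] %||% NA)))
  }
  if (!is.null(s$n_all_tissues)) {
    lines <- c(lines, sprintf("- circRNAs retained in all tissues: %s",
                              s$n_all_tissues))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
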