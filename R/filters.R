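#' Per-tissue expression filter
#'
#' A circRNA is retained for a tissue when its summed deduplicated junction
#' count across that tissue's libraries reaches `min_total` (default 6 over
#' the 6 libraries of a two-age triplicate design -- a minimum average of
#' one read per biological replicate). There is no per-library requirement.
#'
#' @param mat A `junction_count_matrix`.
#' @param min_total Minimum tissue-summed count (default 6).
#' @param strict If `TRUE` (default), error when a tissue does not have
#'   exactly 6 libraries; if `FALSE`, the threshold is scaled
#'   proportionally to the tissue's library count
#'   (`min_total / 6 * n_libraries`).
#' @return List: `matrix` (counts restricted to circRNAs retained in at
#'   least one tissue) and `membership` (tibble `tissue`, `circ_id`,
#'   `total`, `retained`).
#' @export
expression_filter <- function(mat, min_total = 6L, strict = TRUE) {
  libs <- mat$design %>% count(.data$tissue, name = "n_libs")
  if (strict && any(libs$n_libs != 6)) {
    abort(paste0("expression_filter: tissues without exactly 6 libraries: ",
                 paste(libs$tissue[libs$n_libs != 6], collapse = ", "),
                 " (use strict = FALSE for a proportional threshold)"))
  }
  thresholds <- libs %>%
    mutate(threshold = if (strict) min_total
           else min_total / 6 * .data$n_libs)
  membership <- mat$counts %>%
    left_join(mat$design %>% select("library_id", "tissue"),
              by = "library_id") %>%
    group_by(.data$tissue, .data$circ_id) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    left_join(thresholds %>% select("tissue", "threshold"), by = "tissue") %>%
    mutate(retained = .data$total >= .data$threshold) %>%
    select("tissue", "circ_id", "total", "retained")
  keep <- membership %>% filter(.data$retained) %>%
    distinct(.data$circ_id)
  filtered <- mat
  filtered$counts <- mat$counts %>% semi_join(keep, by = "circ_id")
  list(matrix = filtered, membership = membership)
}

#' Flag and remove multi-gene spanning junctions
#'
#' A junction is flagged multi-gene when its start lies in an exon of one
#' gene and its end in an exon of a *different* gene with no gene containing
#' both -- the signature of paralog-pair mapping artifacts (tandem genes
#' with near-identical exons), which sequencing shows to be linear-spliced,
#' not back-spliced. Flagged loci are removed from the annotation.
#' Junctions with both boundaries in one gene keep that gene as host;
#' junctions overlapping no exon at either boundary are kept with host
#' `"intergenic"`.
#'
#' @param circs Annotation tibble (`circ_id`, `chrom`, `start`, `end`,
#'   `strand`, ...).
#' @param bundle A `genome_bundle`.
#' @return List: `kept` (annotation with `host_gene` column), `removed`
#'   (flagged multi-gene loci with `start_genes`, `end_genes`).
#' @export
multigene_filter <- function(circs, bundle) {
  genes_at <- function(chrom, pos) {
    hit <- bundle$exons %>%
      filter(.data$chrom == !!chrom, .data$start <= pos, .data$end > pos)
    unique(hit$gene_id)
  }
  rows <- purrr::pmap(
    list(circs$chrom, circs$start, circs$end),
    function(chrom, start, end) {
      gs <- genes_at(chrom, start)
      ge <- genes_at(chrom, end - 1L)
      common <- intersect(gs, ge)
      multi <- length(gs) > 0 && length(ge) > 0 && length(common) == 0
      host <- if (length(common)) common[1]
              else if (length(gs)) gs[1]
              else if (length(ge)) ge[1]
              else "intergenic"
      tibble(host_gene = host, multi_gene = multi,
             start_genes = paste(gs, collapse = ","),
             end_genes = paste(ge, collapse = ","))
    }) %>% list_rbind()
  ann <- bind_cols(circs, rows)
  list(kept = ann %>% filter(!.data$multi_gene) %>%
         select(-"multi_gene", -"start_genes", -"end_genes"),
       removed = ann %>% filter(.data$multi_gene) %>% select(-"multi_gene"))
}
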