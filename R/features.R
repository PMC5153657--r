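# Host transcript used for feature classification: among transcripts of the
# host gene, the one with the longest CDS (ties by transcript_id).
host_transcript <- function(bundle, gene_id) {
  tx <- bundle$transcripts %>%
    filter(.data$gene_id == !!gene_id) %>%
    mutate(cds_len = coalesce(.data$cds_tend - .data$cds_tstart, 0L)) %>%
    arrange(desc(.data$cds_len), .data$transcript_id)
  if (nrow(tx) == 0) return(NULL)
  tx[1, ]
}

tx_region_of <- function(tpos, cds_tstart, cds_tend) {
  case_when(is.na(tpos) ~ NA_character_,
            tpos < cds_tstart ~ "5'UTR",
            tpos < cds_tend ~ "CDS",
            TRUE ~ "3'UTR")
}

#' Classify the genomic region of a circRNA
#'
#' Locates the circle's first and last bases relative to the host
#' transcript's 5'UTR / CDS / 3'UTR partition (first/last in transcript
#' orientation). A circle with no gene overlap is `intergenic`; a circle
#' overlapping a gene whose boundary bases fall outside annotated exons is
#' `other`.
#'
#' @param circ One-row tibble (`chrom`, `start`, `end`, `strand`,
#'   `host_gene`).
#' @param bundle A `genome_bundle`.
#' @return A category string, one of `CDS-CDS`, `5'UTR-CDS`, `CDS-3'UTR`,
#'   `5'UTR-5'UTR`, `3'UTR-3'UTR`, `5'UTR-3'UTR`, `intergenic`, `other`.
#' @export
classify_region <- function(circ, bundle) {
  if (is.na(circ$host_gene) || circ$host_gene == "intergenic") {
    return("intergenic")
  }
  tx <- host_transcript(bundle, circ$host_gene)
  if (is.null(tx) || is.na(tx$cds_tstart)) return("other")
  gfirst <- if (circ$strand == "+") circ$start else circ$end - 1L
  glast <- if (circ$strand == "+") circ$end - 1L else circ$start
  t1 <- genomic_to_tx(bundle, tx$transcript_id, gfirst)
  t2 <- genomic_to_tx(bundle, tx$transcript_id, glast)
  r1 <- tx_region_of(t1, tx$cds_tstart, tx$cds_tend)
  r2 <- tx_region_of(t2, tx$cds_tstart, tx$cds_tend)
  if (is.na(r1) || is.na(r2)) return("other")
  paste0(r1, "-", r2)
}

#' Splice-accepting exon index of a circRNA
#'
#' 1-based index, in transcript (strand-aware) order, of the host exon
#' whose boundary coincides with the circle's acceptor edge: the exon
#' starting at `start` for plus-strand circles, the exon ending at `end`
#' for minus-strand circles. When no exon boundary matches exactly, the
#' nearest exon containing the acceptor edge is returned with
#' `exact = FALSE`.
#'
#' @param circ One-row tibble (`chrom`, `start`, `end`, `strand`,
#'   `host_gene`).
#' @param bundle A `genome_bundle`.
#' @return List `index` (integer or `NA`), `exact` (logical).
#' @export
acceptor_exon_index <- function(circ, bundle) {
  tx <- host_transcript(bundle, circ$host_gene)
  if (is.null(tx)) return(list(index = NA_integer_, exact = FALSE))
  ex <- tx_exons(bundle, tx$transcript_id)
  if (circ$strand == "+") {
    hit <- ex$exon_rank[ex$start == circ$start]
    pos <- circ$start
  } else {
    hit <- ex$exon_rank[ex$end == circ$end]
    pos <- circ$end - 1L
  }
  if (length(hit)) return(list(index = as.integer(hit[1]), exact = TRUE))
  cont <- ex$exon_rank[ex$start <= pos & ex$end > pos]
  if (length(cont)) return(list(index = as.integer(cont[1]), exact = FALSE))
  dist <- pmin(abs(ex$start - pos), abs(ex$end - 1L - pos))
  list(index = as.integer(ex$exon_rank[which.min(dist)]), exact = FALSE)
}

#' Number of host-transcript exons fully inside a circRNA
#'
#' @param circ One-row tibble (`chrom`, `start`, `end`, `host_gene`).
#' @param bundle A `genome_bundle`.
#' @return Integer count of exons with `[start, end)` contained in the
#'   circle's span.
#' @export
exons_within <- function(circ, bundle) {
  tx <- host_transcript(bundle, circ$host_gene)
  if (is.null(tx)) return(NA_integer_)
  ex <- tx_exons(bundle, tx$transcript_id)
  sum(ex$start >= circ$start & ex$end <= circ$end)
}

#' Per-circRNA genomic feature table
#'
#' Applies [classify_region()], [acceptor_exon_index()] and
#' [exons_within()] to an annotated (multigene-filtered) circRNA set.
#'
#' @param circs Annotation tibble with `host_gene` (see
#'   [multigene_filter()]).
#' @param bundle A `genome_bundle`.
#' @return Tibble `circ_id`, `host_gene`, `category`, `acceptor_index`,
#'   `acceptor_exact`, `n_exons_within`, `host_exon_count`.
#' @export
circ_features <- function(circs, bundle) {
  purrr::map(seq_len(nrow(circs)), function(i) {
    circ <- circs[i, ]
    genic <- !is.na(circ$host_gene) && circ$host_gene != "intergenic"
    acc <- if (genic) acceptor_exon_index(circ, bundle)
           else list(index = NA_integer_, exact = NA)
    tx <- if (genic) host_transcript(bundle, circ$host_gene) else NULL
    tibble(circ_id = circ$circ_id, host_gene = circ$host_gene,
           category = classify_region(circ, bundle),
           acceptor_index = acc$index, acceptor_exact = acc$exact,
           n_exons_within = if (genic) exons_within(circ, bundle)
                            else NA_integer_,
           host_exon_count = if (genic) tx$n_exons else NA_integer_)
  }) %>% list_rbind()
}

#' Circles per host gene
#'
#' @param circs Annotation tibble with `host_gene`.
#' @return Tibble `gene_id`, `n_circles`, genic circles only, descending.
#' @export
per_gene_counts <- function(circs) {
  circs %>%
    filter(!is.na(.data$host_gene), .data$host_gene != "intergenic") %>%
    count(gene_id = .data$host_gene, name = "n_circles") %>%
    arrange(desc(.data$n_circles), .data$gene_id)
}

#' Cross-tissue overlap (Venn region) counts
#'
#' All `2^k - 1` exclusive region counts of the k-set Venn diagram of
#' per-tissue retained circRNA sets.
#'
#' @param membership Tibble `tissue`, `circ_id`, `retained` from
#'   [expression_filter()], or a named list of circ id vectors.
#' @return Tibble `tissues` (comma-joined region label), `n_tissues`,
#'   `count`; counts sum to the union size.
#' @export
tissue_overlap <- function(membership) {
  sets <- if (is.data.frame(membership)) {
    membership %>%
      filter(.data$retained) %>%
      group_by(.data$tissue) %>%
      summarise(ids = list(unique(.data$circ_id)), .groups = "drop") %>%
      (function(d) setNames(d$ids, d$tissue))
  } else membership
  tiss <- sort(names(sets))
  all_ids <- unique(unlist(sets))
  inset <- purrr::map(sets[tiss], ~all_ids %in% .x)
  key <- purrr::map_chr(seq_along(all_ids), function(i) {
    paste(tiss[purrr::map_lgl(inset, ~.x[i])], collapse = ",")
  })
  combos <- unlist(purrr::map(seq_along(tiss), function(k) {
    utils::combn(tiss, k, paste, collapse = ",", simplify = FALSE)
  }))
  tibble(tissues = combos) %>%
    mutate(n_tissues = stringr::str_count(.data$tissues, ",") + 1L,
           count = purrr::map_int(.data$tissues,
                                  ~sum(key == .x))) %>%
    arrange(desc(.data$n_tissues), .data$tissues)
}
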