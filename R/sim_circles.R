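#' Assign true circRNAs to genes
#'
#' Draws `n_circ_genes` host genes (needing at least three exons, so that the
#' acceptor can avoid exon 1 and the donor can avoid the terminal exon, both
#' of which lack the flanking splice signal a back-splice requires) and one
#' circle per host; `n_multi_circ_genes` of them receive a second, distinct
#' circle. The splice-accepting exon index is drawn from
#' `cfg$acceptor_index_probs` (mode at exon 2 by default); the donor exon is
#' drawn uniformly between the acceptor and the penultimate exon. Member
#' exons are the contiguous acceptor..donor block of the host transcript.
#'
#' Age regulation: `age_effect$fraction_up` of circles are designated
#' up-regulated (multiplier `fold_up` at the old age in `affected_tissues`)
#' and `fraction_down` down-regulated, disjointly.
#'
#' @param bundle A `genome_bundle`.
#' @param cfg A [sim_config()].
#' @return A tibble of true circRNAs: `circ_id`, `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open genomic bounds of
#'   the member-exon block), `acceptor_rank`, `donor_rank`, `n_exons_circ`,
#'   `rel_abundance`, `direction` (`up`/`down`/`none`) and `fold`.
#' @export
assign_circrnas <- function(bundle, cfg) {
  with_substream(cfg$seed, "circles", {
    empty_circs <- tibble(
      circ_id = character(0), gene_id = character(0),
      transcript_id = character(0), chrom = character(0),
      strand = character(0), start = integer(0), end = integer(0),
      acceptor_rank = integer(0), donor_rank = integer(0),
      n_exons_circ = integer(0), rel_abundance = double(0),
      direction = character(0), fold = double(0))
    if (cfg$n_circ_genes == 0) return(empty_circs)
    eligible <- bundle$transcripts %>% filter(.data$n_exons >= 3)
    if (nrow(eligible) < cfg$n_circ_genes) {
      abort(sprintf(
        "requested %d circRNA host genes but only %d genes have >= 3 exons",
        cfg$n_circ_genes, nrow(eligible)))
    }
    hosts <- eligible %>% slice_sample(n = cfg$n_circ_genes)
    n_multi <- min(cfg$n_multi_circ_genes, sum(hosts$n_exons >= 4))
    host_rows <- bind_rows(hosts,
                           hosts %>% filter(.data$n_exons >= 4) %>%
                             head(n_multi))

    # enumerate valid (acceptor, donor) pairs -- acceptor weighted by the
    # configured index distribution, donor uniform from acceptor to the
    # penultimate exon -- and sample one not already used on this host
    draw_circle <- function(tx_row, forbid = NULL) {
      n_ex <- tx_row$n_exons
      probs <- cfg$acceptor_index_probs
      idx <- seq_along(probs)
      ok <- idx <= n_ex - 1 & probs > 0
      if (!any(ok)) { ok <- idx <= n_ex - 1; probs <- rep(1, length(idx)) }
      pairs <- purrr::map(idx[ok], function(a) {
        tibble(a = a, d = a:(n_ex - 1L),
               w = probs[a] / (n_ex - a))
      }) %>% list_rbind()
      if (!is.null(forbid)) {
        pairs <- pairs %>% anti_join(forbid, by = c("a", "d"))
      }
      if (nrow(pairs) == 0) {
        abort("could not draw a distinct second circle on host gene")
      }
      i <- sample.int(nrow(pairs), 1, prob = pairs$w)
      c(a = pairs$a[i], d = pairs$d[i])
    }

    made <- list()
    seen <- list()
    for (i in seq_len(nrow(host_rows))) {
      tx_row <- host_rows[i, ]
      forbid <- seen[[tx_row$transcript_id]]
      ad <- draw_circle(tx_row, forbid)
      seen[[tx_row$transcript_id]] <-
        bind_rows(forbid, tibble(a = ad[["a"]], d = ad[["d"]]))
      ex <- tx_exons(bundle, tx_row$transcript_id) %>%
        filter(.data$exon_rank >= ad[["a"]], .data$exon_rank <= ad[["d"]])
      made[[i]] <- tibble(
        gene_id = tx_row$gene_id, transcript_id = tx_row$transcript_id,
        chrom = tx_row$chrom, strand = tx_row$strand,
        start = min(ex$start), end = max(ex$end),
        acceptor_rank = ad[["a"]], donor_rank = ad[["d"]],
        n_exons_circ = nrow(ex))
    }
    circs <- list_rbind(made) %>%
      arrange(.data$chrom, .data$start, .data$end) %>%
      mutate(circ_id = sprintf("circ%04d", row_number()), .before = 1)

    n <- nrow(circs)
    circs$rel_abundance <- rlnorm(n, cfg$base_abundance$meanlog,
                                  cfg$base_abundance$sdlog)
    n_up <- round(cfg$age_effect$fraction_up * n)
    n_down <- round(cfg$age_effect$fraction_down * n)
    pick <- sample(seq_len(n), min(n, n_up + n_down))
    circs$direction <- "none"
    circs$fold <- 1
    if (n_up > 0) {
      circs$direction[pick[seq_len(n_up)]] <- "up"
      circs$fold[pick[seq_len(n_up)]] <- cfg$age_effect$fold_up
    }
    if (n_down > 0 && length(pick) > n_up) {
      dn <- pick[(n_up + 1):length(pick)]
      circs$direction[dn] <- "down"
      circs$fold[dn] <- 1 / cfg$age_effect$fold_down
    }
    circs
  })
}

# Spliced circle sequence (member exons concatenated, transcript
# orientation). The back-spliced junction sits between the last and first
# base of the returned string.
circle_seq <- function(bundle, circ) {
  ex <- tx_exons(bundle, circ$transcript_id) %>%
    filter(.data$exon_rank >= circ$acceptor_rank,
           .data$exon_rank <= circ$donor_rank) %>%
    arrange(.data$start)
  s <- paste(subseq0(bundle$seqs[[circ$chrom]], ex$start, ex$end),
             collapse = "")
  if (circ$strand == "-") revcomp(s) else s
}

#' Append a tandem-duplicated gene pair to a genome bundle
#'
#' Creates an analog of paralogous gene pairs with near-identical exon
#' sequence (such as the C4a/C4b complement genes) by copying one gene's
#' genomic span immediately downstream of itself under a new gene id. A
#' putative junction whose two boundaries fall in exons of the two copies is
#' the multi-gene artifact [multigene_filter()] is designed to remove.
#'
#' @param bundle A `genome_bundle`.
#' @param gene_id Gene to duplicate (defaults to the first gene with >= 2
#'   exons).
#' @param gap Intergenic gap between the copies (nt).
#' @return The augmented `genome_bundle`; the copy is named
#'   `<gene_id>_dup` (transcript `<transcript_id>_dup`).
#' @export
add_duplicated_gene <- function(bundle, gene_id = NULL, gap = 500L) {
  if (is.null(gene_id)) {
    gene_id <- (bundle$transcripts %>% filter(.data$n_exons >= 2) %>%
                  slice(1))$gene_id
  }
  g <- bundle$genes %>% filter(.data$gene_id == !!gene_id)
  if (nrow(g) != 1) abort(sprintf("gene '%s' not found", gene_id))
  shift <- (g$end - g$start) + as.integer(gap)
  chrom_len <- stringr::str_length(bundle$seqs[[g$chrom]])
  if (g$end + shift > chrom_len) {
    abort("chromosome too short to append the duplicated gene copy")
  }
  # copy the genomic span (exons + introns, signals included)
  span_seq <- subseq0(bundle$seqs[[g$chrom]], g$start, g$end)
  stringr::str_sub(bundle$seqs[[g$chrom]], g$start + shift + 1,
                   g$end + shift) <- span_seq
  new_gene <- g %>% mutate(gene_id = paste0(gene_id, "_dup"),
                           start = .data$start + shift,
                           end = .data$end + shift)
  new_exons <- bundle$exons %>%
    filter(.data$gene_id == !!gene_id) %>%
    mutate(gene_id = paste0(.data$gene_id, "_dup"),
           transcript_id = paste0(.data$transcript_id, "_dup"),
           start = .data$start + shift, end = .data$end + shift)
  new_tx <- bundle$transcripts %>%
    filter(.data$gene_id == !!gene_id) %>%
    mutate(gene_id = paste0(.data$gene_id, "_dup"),
           transcript_id = paste0(.data$transcript_id, "_dup"))
  bundle$genes <- bind_rows(bundle$genes, new_gene)
  bundle$exons <- bind_rows(bundle$exons, new_exons)
  bundle$transcripts <- bind_rows(bundle$transcripts, new_tx)
  bundle
}
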