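#' Generate a toy genome with spliced gene models
#'
#' Places `n_genes` multi-exon protein-coding genes on random chromosomes.
#' Intergenic and exonic sequence is sampled uniformly over A/C/G/T from the
#' seeded generator; every intron carries canonical splice dinucleotides in
#' genomic orientation (GT..AG for plus-strand genes, CT..AC for minus-strand
#' genes), which is what out-of-order breakpoint resolution keys on.
#'
#' All coordinates in the returned bundle are 0-based half-open (BED
#' convention); GTF import/export converts at the boundary.
#'
#' @param cfg A [sim_config()] object.
#' @return A `genome_bundle`: list with `seqs` (named character vector of
#'   chromosome sequences), `genes`, `transcripts` and `exons` tibbles.
#'   Each gene carries one transcript whose CDS is an internal interval of
#'   the spliced transcript, so 5'UTR/CDS/3'UTR partitions are derivable.
#' @examples
#' bundle <- generate_genome(sim_config(seed = 1, n_genes = 5,
#'                                      n_chromosomes = 1,
#'                                      chrom_length = 50000L))
#' bundle$genes
#' @export
generate_genome <- function(cfg) {
  validate_sim_config(cfg)
  with_substream(cfg$seed, "genome", {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    n <- cfg$n_genes

    gene_specs <- purrr::map(seq_len(n), function(i) {
      n_ex <- sample_range(cfg$exons_per_gene[1], cfg$exons_per_gene[2])
      ex_len <- sample_range(cfg$exon_length[1], cfg$exon_length[2], n_ex)
      in_len <- if (n_ex > 1) {
        sample_range(cfg$intron_length[1], cfg$intron_length[2], n_ex - 1)
      } else integer(0)
      list(n_ex = n_ex, ex_len = ex_len, in_len = in_len,
           strand = sample(c("+", "-"), 1),
           span = sum(ex_len) + sum(in_len))
    })

    # sequential placement with random intergenic gaps
    cursor <- setNames(rep(0L, length(chroms)), chroms)
    placements <- vector("list", n)
    for (i in seq_len(n)) {
      gs <- gene_specs[[i]]
      gap <- sample_range(cfg$intergenic_length[1], cfg$intergenic_length[2])
      placed <- FALSE
      for (ch in chroms) {
        start <- cursor[[ch]] + gap
        if (start + gs$span + 10L <= cfg$chrom_length) {
          placements[[i]] <- list(chrom = ch, start = start)
          cursor[[ch]] <- start + gs$span
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "chromosomes too short: cannot place gene %d of %d (span %d nt)",
          i, n, gs$span))
      }
    }

    exons <- purrr::imap(gene_specs, function(gs, i) {
      pl <- placements[[i]]
      starts <- pl$start + cumsum(c(0L, head(gs$ex_len, -1) + gs$in_len))
      genomic_rank <- seq_len(gs$n_ex)
      rank <- if (gs$strand == "+") genomic_rank else rev(genomic_rank)
      tibble(gene_id = sprintf("gene%03d", i),
             transcript_id = sprintf("tx%03d", i),
             exon_rank = rank, start = as.integer(starts),
             end = as.integer(starts + gs$ex_len))
    }) %>% list_rbind()

    genes <- purrr::imap(gene_specs, function(gs, i) {
      pl <- placements[[i]]
      tibble(gene_id = sprintf("gene%03d", i), chrom = pl$chrom,
             strand = gs$strand, start = as.integer(pl$start),
             end = as.integer(pl$start + gs$span))
    }) %>% list_rbind()

    exons <- exons %>%
      left_join(genes %>% select("gene_id", "chrom", "strand"),
                by = "gene_id") %>%
      select("gene_id", "transcript_id", "chrom", "strand", "exon_rank",
             "start", "end")

    # chromosome sequences, then intron splice signals planted in place
    seqs <- setNames(random_dna(rep(cfg$chrom_length, length(chroms))),
                     chroms)
    for (i in seq_len(n)) {
      gs <- gene_specs[[i]]
      if (gs$n_ex < 2) next
      ex <- exons %>%
        filter(.data$gene_id == sprintf("gene%03d", i)) %>%
        arrange(.data$start)
      ch <- ex$chrom[1]
      istart <- ex$end[-nrow(ex)]
      iend <- ex$start[-1]
      don <- if (gs$strand == "+") "GT" else "CT"
      acc <- if (gs$strand == "+") "AG" else "AC"
      for (j in seq_along(istart)) {
        stringr::str_sub(seqs[[ch]], istart[j] + 1, istart[j] + 2) <- don
        stringr::str_sub(seqs[[ch]], iend[j] - 1, iend[j]) <- acc
      }
    }

    # CDS as an internal interval of the spliced transcript: the flanks
    # become 5' and 3' UTR
    transcripts <- exons %>%
      group_by(.data$transcript_id, .data$gene_id, .data$chrom,
               .data$strand) %>%
      summarise(n_exons = n(), tx_len = sum(.data$end - .data$start),
                .groups = "drop") %>%
      mutate(cds_tstart = as.integer(floor(0.15 * .data$tx_len)),
             cds_tend = as.integer(floor(0.85 * .data$tx_len)))

    bundle <- structure(
      list(seqs = seqs, genes = genes, transcripts = transcripts,
           exons = exons),
      class = "genome_bundle")
    bundle
  })
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d chromosome(s), %d gene(s), %d exon(s)\n",
              length(x$seqs), nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

# ---- coordinate helpers ----------------------------------------------------

# Exons of one transcript in transcript (5'->3') order.
tx_exons <- function(bundle, transcript_id) {
  bundle$exons %>%
    filter(.data$transcript_id == !!transcript_id) %>%
    arrange(.data$exon_rank)
}

#' Mature transcript sequences
#'
#' Splices each transcript's exons and reverse-complements minus-strand
#' transcripts, yielding mature (intron-free) sequences in 5'->3'
#' orientation.
#'
#' @param bundle A `genome_bundle`.
#' @return Named character vector, one element per transcript.
#' @export
transcript_seqs <- function(bundle) {
  sp <- bundle$exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id, .data$chrom, .data$strand) %>%
    summarise(seq = paste(subseq0(bundle$seqs[[.data$chrom[1]]],
                                  .data$start, .data$end), collapse = ""),
              .groups = "drop")
  out <- ifelse(sp$strand == "-", revcomp(sp$seq), sp$seq)
  setNames(out, sp$transcript_id)
}

# Map a genomic position (0-based) to a transcript coordinate (0-based
# within the spliced transcript); NA when the position is intronic or
# outside the transcript.
genomic_to_tx <- function(bundle, transcript_id, gpos) {
  ex <- tx_exons(bundle, transcript_id)
  offs <- cumsum(c(0L, ex$end - ex$start))
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(gpos) & gpos >= ex$start[i] & gpos < ex$end[i]
    if (!any(hit)) next
    out[hit] <- if (ex$strand[1] == "+") {
      offs[i] + (gpos[hit] - ex$start[i])
    } else {
      offs[i] + (ex$end[i] - 1L - gpos[hit])
    }
  }
  as.integer(out)
}

# Exon-union length per gene (nt of genomic sequence covered by exons).
gene_exon_union <- function(bundle) {
  bundle$exons %>%
    group_by(.data$gene_id) %>%
    summarise(union_len = {
      ir <- IRanges::reduce(IRanges::IRanges(start = .data$start + 1L,
                                             end = .data$end))
      sum(IRanges::width(ir))
    }, .groups = "drop")
}

# ---- FASTA / GTF I/O -------------------------------------------------------

#' Write and read the toy genome as FASTA
#'
#' @param bundle A `genome_bundle`.
#' @param path Output FASTA path (60-column wrapped).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(bundle, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$seqs), path,
                              width = 60)
  invisible(path)
}

# Genomic CDS intervals of a transcript (0-based half-open tibble), mapped
# from its transcript-coordinate CDS interval through the exon chain.
cds_genomic_intervals <- function(bundle, transcript_id) {
  tx <- bundle$transcripts %>%
    filter(.data$transcript_id == !!transcript_id)
  ex <- tx_exons(bundle, transcript_id)
  offs <- cumsum(c(0L, ex$end - ex$start))
  t0 <- tx$cds_tstart
  t1 <- tx$cds_tend
  out <- list()
  for (i in seq_len(nrow(ex))) {
    a <- max(t0, offs[i]); b <- min(t1, offs[i + 1])
    if (a >= b) next
    if (ex$strand[1] == "+") {
      out[[length(out) + 1]] <- tibble(start = ex$start[i] + (a - offs[i]),
                                       end = ex$start[i] + (b - offs[i]))
    } else {
      out[[length(out) + 1]] <- tibble(start = ex$end[i] - (b - offs[i]),
                                       end = ex$end[i] - (a - offs[i]))
    }
  }
  if (!length(out)) return(tibble(start = integer(0), end = integer(0)))
  list_rbind(out) %>% arrange(.data$start)
}

#' Export gene models as GTF
#'
#' Emits gene, transcript, exon and CDS features (1-based inclusive, per the
#' GTF standard) through \pkg{rtracklayer}.
#'
#' @param bundle A `genome_bundle`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(bundle, path) {
  rows <- list()
  rows$gene <- bundle$genes %>%
    transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
              strand = .data$strand, type = "gene", gene_id = .data$gene_id,
              transcript_id = NA_character_, exon_rank = NA_integer_)
  rows$tx <- bundle$exons %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom,
             .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    mutate(type = "transcript", exon_rank = NA_integer_)
  rows$exon <- bundle$exons %>%
    mutate(type = "exon") %>%
    select("chrom", "start", "end", "strand", "type", "gene_id",
           "transcript_id", "exon_rank")
  rows$cds <- bundle$transcripts %>%
    mutate(ivl = purrr::map(.data$transcript_id,
                            ~cds_genomic_intervals(bundle, .x))) %>%
    tidyr::unnest("ivl") %>%
    transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
              strand = .data$strand, type = "CDS", gene_id = .data$gene_id,
              transcript_id = .data$transcript_id,
              exon_rank = NA_integer_)
  feat <- list_rbind(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start + 1L, end = feat$end),
    strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$gene_id <- feat$gene_id
  S4Vectors::mcols(gr)$transcript_id <- feat$transcript_id
  S4Vectors::mcols(gr)$exon_number <- feat$exon_rank
  S4Vectors::mcols(gr)$phase <- ifelse(feat$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Load a genome bundle from FASTA + GTF
#'
#' Inverse of [write_genome_fasta()] / [write_gtf()]; reconstructs the
#' 0-based half-open tibbles, including the transcript-coordinate CDS
#' interval, from standard files.
#'
#' @param fasta Genome FASTA path.
#' @param gtf Gene-model GTF path.
#' @return A `genome_bundle`.
#' @export
read_genome_bundle <- function(fasta, gtf) {
  dss <- Biostrings::readDNAStringSet(fasta)
  names(dss) <- sub("\\s.*$", "", names(dss))
  seqs <- setNames(as.character(dss), names(dss))
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  df <- df %>%
    mutate(chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           start0 = .data$start - 1L, end0 = .data$end)
  genes <- df %>%
    filter(.data$type == "gene") %>%
    transmute(gene_id = .data$gene_id, chrom = .data$chrom,
              strand = .data$strand, start = as.integer(.data$start0),
              end = as.integer(.data$end0))
  exons <- df %>%
    filter(.data$type == "exon") %>%
    transmute(gene_id = .data$gene_id, transcript_id = .data$transcript_id,
              chrom = .data$chrom, strand = .data$strand,
              exon_rank = as.integer(.data$exon_number),
              start = as.integer(.data$start0),
              end = as.integer(.data$end0))
  if (all(is.na(exons$exon_rank))) {
    exons <- exons %>%
      group_by(.data$transcript_id) %>%
      arrange(.data$start, .by_group = TRUE) %>%
      mutate(exon_rank = if (.data$strand[1] == "+") row_number()
             else rev(row_number())) %>%
      ungroup()
  }
  transcripts <- exons %>%
    group_by(.data$transcript_id, .data$gene_id, .data$chrom,
             .data$strand) %>%
    summarise(n_exons = n(), tx_len = sum(.data$end - .data$start),
              .groups = "drop")
  cds <- df %>% filter(.data$type == "CDS")
  if (nrow(cds)) {
    bundle0 <- structure(list(seqs = seqs, genes = genes,
                              transcripts = transcripts, exons = exons),
                         class = "genome_bundle")
    cds_tx <- cds %>%
      group_by(.data$transcript_id) %>%
      summarise(gmin = min(.data$start0), gmax = max(.data$end0),
                .groups = "drop") %>%
      mutate(
        t_a = purrr::map2_int(.data$transcript_id, .data$gmin,
                              ~genomic_to_tx(bundle0, .x, .y)),
        t_b = purrr::map2_int(.data$transcript_id, .data$gmax - 1L,
                              ~genomic_to_tx(bundle0, .x, .y)),
        cds_tstart = pmin(.data$t_a, .data$t_b),
        cds_tend = pmax(.data$t_a, .data$t_b) + 1L) %>%
      select("transcript_id", "cds_tstart", "cds_tend")
    transcripts <- transcripts %>% left_join(cds_tx, by = "transcript_id")
  } else {
    transcripts <- transcripts %>%
      mutate(cds_tstart = NA_integer_, cds_tend = NA_integer_)
  }
  structure(list(seqs = seqs, genes = genes, transcripts = transcripts,
                 exons = exons),
            class = "genome_bundle")
}
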