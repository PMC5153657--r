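# ---- indexes ---------------------------------------------------------------

#' Build a k-mer read-matching index
#'
#' Wraps the compiled seeded matcher. With `transcripts = TRUE` the spliced
#' transcriptome is appended (targets named `tx|<transcript_id>`) so that
#' reads from mature linear transcripts that cross forward splice junctions
#' still count as linearly aligned.
#'
#' @param bundle A `genome_bundle`.
#' @param k Seed / anchor length (default 20).
#' @param transcripts Include mature transcript sequences as targets.
#' @return A `read_index` (list: `xp` external pointer, `targets`,
#'   `lengths`, `is_genome`, `k`).
#' @export
build_read_index <- function(bundle, k = 20L, transcripts = TRUE) {
  seqs <- bundle$seqs
  is_genome <- rep(TRUE, length(seqs))
  if (transcripts) {
    txs <- transcript_seqs(bundle)
    names(txs) <- paste0("tx|", names(txs))
    seqs <- c(seqs, txs)
    is_genome <- c(is_genome, rep(FALSE, length(txs)))
  }
  xp <- kmer_index_build(seqs, as.integer(k))
  structure(list(xp = xp, targets = names(seqs),
                 lengths = stringr::str_length(seqs),
                 is_genome = is_genome, k = as.integer(k)),
            class = "read_index")
}

#' Remove linearly aligning reads
#'
#' A mate is linearly aligned when it has at least one end-to-end placement
#' (either strand, at most `max_mismatches` substitutions, no indels) on the
#' genome or on a spliced transcript. Only the mates with no such placement
#' -- the candidate pool for back-splice discovery -- are returned.
#'
#' @param reads Tibble with `read_id`, `seq` (one row per mate; mates are
#'   processed independently).
#' @param bundle A `genome_bundle`.
#' @param max_mismatches Substitution budget (default 2).
#' @param index Optional prebuilt [build_read_index()] (with transcripts).
#' @return List: `unaligned` (tibble `read_id`, `seq`), `n_aligned` (count
#'   of linearly aligned mates, the later TPM denominator contribution),
#'   `hits` (best placement per aligned mate: `read_id`, `target`, `pos`,
#'   `strand`, `mm`).
#' @export
linear_filter <- function(reads, bundle, max_mismatches = 2L, index = NULL) {
  if (nrow(reads) == 0) {
    inform("linear_filter: empty input")
    return(list(unaligned = reads, n_aligned = 0L,
                hits = tibble(read_id = character(0), target = character(0),
                              pos = integer(0), strand = character(0),
                              mm = integer(0))))
  }
  if (is.null(index)) index <- build_read_index(bundle, transcripts = TRUE)
  res <- kmer_match_reads(index$xp, reads$seq, as.integer(max_mismatches),
                          TRUE, 16L)
  aligned <- res$n_hits > 0
  hits <- as_tibble(res$hits) %>%
    group_by(.data$read) %>%
    slice_min(.data$mm, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    transmute(read_id = reads$read_id[.data$read],
              target = index$targets[.data$seq], pos = .data$pos,
              strand = ifelse(.data$strand == 0, "+", "-"), mm = .data$mm)
  list(unaligned = reads[!aligned, , drop = FALSE],
       n_aligned = sum(aligned), hits = hits)
}

# ---- anchors & breakpoints -------------------------------------------------

#' Split a read into terminal anchors
#'
#' @param read Character vector of read sequences.
#' @param anchor_length Anchor length (nt).
#' @return Tibble `head`, `tail` (`NA` rows for reads shorter than two
#'   anchors, which the caller should skip and count).
#' @export
split_anchors <- function(read, anchor_length = 20L) {
  L <- stringr::str_length(read)
  ok <- L >= 2L * anchor_length
  tibble(
    head = ifelse(ok, stringr::str_sub(read, 1, anchor_length), NA),
    tail = ifelse(ok, stringr::str_sub(read, L - anchor_length + 1, L), NA))
}

# Splice-signal test for a candidate junction [start, end) on `chrom`:
# plus-strand circles require genomic GT immediately after `end` and AG
# immediately before `start`; minus-strand circles the genomic
# complements (CT after `end`, AC before `start`).
junction_signal <- function(seq, start, end) {
  don <- subseq0(seq, end, end + 2L)
  acc <- subseq0(seq, start - 2L, start)
  if (don == "GT" && acc == "AG") return("+")
  if (don == "CT" && acc == "AC") return("-")
  NA_character_
}

#' Resolve a back-splice breakpoint from out-of-order anchor hits
#'
#' Given a read whose two terminal anchors align uniquely, on the same
#' chromosome, with the tail anchor upstream of the head anchor
#' (out-of-order relative to the genome), scans every split position for
#' the unique breakpoint flanked by splice signals and within the mismatch
#' budget. Reads whose best breakpoint is tied between two positions are
#' rejected as ambiguous rather than arbitrarily assigned.
#'
#' @param head_hits,tail_hits Tibbles of genomic anchor hits (`chrom`,
#'   `pos`, `strand`, with `strand` `"+"` for a forward match of the anchor
#'   and `"-"` for a match of its reverse complement), e.g. from
#'   [anchor_hits()].
#' @param read The full read sequence.
#' @param bundle A `genome_bundle`.
#' @param anchor_length,max_mismatches,max_span Detector parameters; a
#'   junction wider than `max_span` nt is never emitted.
#' @return A list: `junction` (one-row tibble `chrom`, `start`, `end`,
#'   `strand`, `mismatches` or `NULL`) and `status` (`"junction"`,
#'   `"none"`, or `"ambiguous"`).
#' @export
resolve_breakpoint <- function(head_hits, tail_hits, read, bundle,
                               anchor_length = 20L, max_mismatches = 2L,
                               max_span = 1000000L) {
  k <- anchor_length
  L <- stringr::str_length(read)
  if (L < 2L * k) return(list(junction = NULL, status = "none"))
  try_orient <- function(seq, h_hits, t_hits) {
    if (nrow(h_hits) != 1 || nrow(t_hits) != 1) return(NULL)
    if (h_hits$chrom != t_hits$chrom) return(NULL)
    h <- h_hits$pos; t0 <- t_hits$pos - (L - k)
    if (!(t_hits$pos < h)) return(NULL)          # must be out-of-order
    chrom <- h_hits$chrom
    g <- bundle$seqs[[chrom]]
    glen <- stringr::str_length(g)
    if (t0 < 2L || h + L + 2L > glen) return(NULL)
    G1 <- subseq0(g, h, h + L)
    G2 <- subseq0(g, t0, t0 + L)
    r <- utf8ToInt(seq)
    m1 <- cumsum(c(0L, r != utf8ToInt(G1)))
    m2c <- c(0L, cumsum(r != utf8ToInt(G2)))
    tot2 <- m2c[L + 1L]
    cand <- list()
    for (s in k:(L - k)) {
      mm <- m1[s + 1L] + (tot2 - m2c[s + 1L])
      if (mm > max_mismatches) next
      A <- t0 + s; E <- h + s
      if (E - A > max_span) next
      sig <- junction_signal(g, A, E)
      if (is.na(sig)) next
      cand[[length(cand) + 1]] <- tibble(chrom = chrom, start = A, end = E,
                                         strand = sig, mismatches = mm)
    }
    if (!length(cand)) return("none")
    cand <- list_rbind(cand) %>% arrange(.data$mismatches)
    if (nrow(cand) >= 2 && cand$mismatches[2] == cand$mismatches[1]) {
      return("ambiguous")
    }
    cand[1, ]
  }

  pick <- function(hits, strand) hits[hits$strand == strand, , drop = FALSE]
  out_plus <- try_orient(read, pick(head_hits, "+"), pick(tail_hits, "+"))
  out_minus <- try_orient(revcomp(read), pick(tail_hits, "-"),
                          pick(head_hits, "-"))
  outs <- list(out_plus, out_minus)
  if (any(vapply(outs, identical, logical(1), "ambiguous"))) {
    return(list(junction = NULL, status = "ambiguous"))
  }
  js <- purrr::keep(outs, is.data.frame)
  if (length(js) == 0) return(list(junction = NULL, status = "none"))
  if (length(js) == 2) return(list(junction = NULL, status = "ambiguous"))
  list(junction = js[[1]], status = "junction")
}

#' Exact genomic hits of fixed-length anchors
#'
#' @param anchors Character vector of anchor sequences (length = index k).
#' @param index A genome-only [build_read_index()].
#' @return Tibble `anchor` (input position), `chrom`, `pos`, `strand`.
#' @export
anchor_hits <- function(anchors, index) {
  df <- as_tibble(kmer_anchor_hits(index$xp, anchors))
  df %>%
    filter(index$is_genome[.data$seq]) %>%
    transmute(anchor = .data$anchor, chrom = index$targets[.data$seq],
              pos = .data$pos, strand = ifelse(.data$strand == 0, "+", "-"))
}

#' Call back-spliced junctions across libraries
#'
#' Resolves every non-linearly-aligning mate to a candidate junction and
#' aggregates by exact (chrom, start, end, strand). Support counts distinct
#' junction reads: mates with identical sequence at the same junction (PCR
#' duplicates) collapse to one. Junctions with support below `min_reads`
#' are dropped.
#'
#' @param unaligned_by_lib Named list (library id -> tibble `read_id`,
#'   `seq`) of mates surviving [linear_filter()].
#' @param bundle A `genome_bundle`.
#' @param min_reads Minimum distinct junction reads (default 6, one per
#'   library of a two-age triplicate tissue design).
#' @param anchor_length,max_mismatches,max_span Passed to
#'   [resolve_breakpoint()].
#' @return A tibble of junctions (`chrom`, `start`, `end`, `strand`,
#'   `name`, `support`, `donor_signal`, `acceptor_signal`,
#'   `breakpoint_mismatches`), coordinate-sorted, with attributes
#'   `read_evidence` (per-read table incl. library) and `stats`
#'   (ambiguous / unresolved counters).
#' @export
call_junctions <- function(unaligned_by_lib, bundle, min_reads = 6L,
                           anchor_length = 20L, max_mismatches = 2L,
                           max_span = 1000000L) {
  stopifnot(min_reads >= 1)
  gidx <- build_read_index(bundle, k = anchor_length, transcripts = FALSE)
  ev <- list()
  n_ambig <- 0L; n_short <- 0L
  for (lib in names(unaligned_by_lib)) {
    reads <- unaligned_by_lib[[lib]]
    if (!nrow(reads)) next
    anc <- split_anchors(reads$seq, anchor_length)
    short <- is.na(anc$head)
    n_short <- n_short + sum(short)
    if (all(short)) next
    reads <- reads[!short, , drop = FALSE]; anc <- anc[!short, , drop = FALSE]
    h_all <- anchor_hits(anc$head, gidx)
    t_all <- anchor_hits(anc$tail, gidx)
    h_split <- split(h_all, factor(h_all$anchor, levels = seq_len(nrow(reads))))
    t_split <- split(t_all, factor(t_all$anchor, levels = seq_len(nrow(reads))))
    for (i in seq_len(nrow(reads))) {
      hh <- h_split[[i]]; tt <- t_split[[i]]
      if (nrow(hh) == 0 || nrow(tt) == 0) next
      res <- resolve_breakpoint(hh, tt, reads$seq[i], bundle,
                                anchor_length, max_mismatches, max_span)
      if (res$status == "ambiguous") n_ambig <- n_ambig + 1L
      if (res$status != "junction") next
      ev[[length(ev) + 1]] <- res$junction %>%
        mutate(library_id = lib, read_id = reads$read_id[i],
               seq = reads$seq[i])
    }
  }
  if (!length(ev)) {
    out <- tibble(chrom = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  name = character(0), support = integer(0),
                  donor_signal = character(0), acceptor_signal = character(0),
                  breakpoint_mismatches = integer(0))
    attr(out, "read_evidence") <- tibble()
    attr(out, "stats") <- list(ambiguous = n_ambig, too_short = n_short)
    return(out)
  }
  evidence <- list_rbind(ev)
  out <- evidence %>%
    distinct(.data$chrom, .data$start, .data$end, .data$strand, .data$seq,
             .keep_all = TRUE) %>%
    group_by(.data$chrom, .data$start, .data$end, .data$strand) %>%
    summarise(support = n(),
              breakpoint_mismatches = min(.data$mismatches),
              .groups = "drop") %>%
    filter(.data$support >= min_reads) %>%
    arrange(.data$chrom, .data$start, .data$end) %>%
    mutate(name = sprintf("novel_circ_%04d", row_number()),
           donor_signal = ifelse(.data$strand == "+", "GT", "CT"),
           acceptor_signal = ifelse(.data$strand == "+", "AG", "AC")) %>%
    select("chrom", "start", "end", "strand", "name", "support",
           "donor_signal", "acceptor_signal", "breakpoint_mismatches")
  attr(out, "read_evidence") <- evidence
  attr(out, "stats") <- list(ambiguous = n_ambig, too_short = n_short)
  out
}

#' De novo circRNA detection over a set of libraries
#'
#' Convenience wrapper: linear-filters each library's mates against genome
#' and spliced transcriptome, then calls junctions across libraries.
#'
#' @param reads_by_lib Named list (library id -> tibble `name`, `seq1`,
#'   `seq2`) as produced by [simulate_library()] or [read_fastq_pairs()].
#' @param bundle A `genome_bundle`.
#' @param min_reads,anchor_length,max_mismatches,max_span See
#'   [call_junctions()].
#' @return List: `junctions` (see [call_junctions()]), `lib_stats` (tibble
#'   `library_id`, `n_mates`, `n_linear`, `n_unaligned`), `linear_hits`
#'   (named list of per-library best linear placements, reused for FPKM).
#' @export
detect_circrnas <- function(reads_by_lib, bundle, min_reads = 6L,
                            anchor_length = 20L, max_mismatches = 2L,
                            max_span = 1000000L) {
  index <- build_read_index(bundle, transcripts = TRUE)
  unaligned <- list(); stats <- list(); linear_hits <- list()
  for (lib in names(reads_by_lib)) {
    rl <- reads_long(reads_by_lib[[lib]])
    lf <- linear_filter(rl, bundle, max_mismatches, index)
    unaligned[[lib]] <- lf$unaligned
    linear_hits[[lib]] <- lf$hits
    stats[[lib]] <- tibble(library_id = lib, n_mates = nrow(rl),
                           n_linear = lf$n_aligned,
                           n_unaligned = nrow(lf$unaligned))
  }
  junctions <- call_junctions(unaligned, bundle, min_reads, anchor_length,
                              max_mismatches, max_span)
  list(junctions = junctions, lib_stats = list_rbind(stats),
       linear_hits = linear_hits)
}

#' Write junctions as BED6
#'
#' @param junctions Junction tibble ([call_junctions()] or merged
#'   annotations with `chrom`, `start`, `end`, `name`, `support`/`score`,
#'   `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  score <- junctions$support %||% junctions$score %||% rep(0L, nrow(junctions))
  readr::write_tsv(
    tibble(chrom = junctions$chrom, start = junctions$start,
           end = junctions$end, name = junctions$name, score = score,
           strand = junctions$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 circRNA annotation
#'
#' @param path BED6 file (0-based half-open).
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_junctions_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                  col_types = "ciicic", progress = FALSE)
}
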