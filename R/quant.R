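#' Merge known and de novo circRNA annotations
#'
#' De-duplicates on exact (chrom, start, end, strand); a junction present in
#' both inputs gets `source = "both"` and keeps the known name.
#'
#' @param known Tibble with `chrom`, `start`, `end`, `strand` and optional
#'   `name` (e.g. from [read_junctions_bed()]); may be `NULL`.
#' @param denovo Junction tibble from [call_junctions()]; may be `NULL`.
#' @return Annotation tibble `circ_id`, `chrom`, `start`, `end`, `strand`,
#'   `source`.
#' @export
merge_annotations <- function(known = NULL, denovo = NULL) {
  norm <- function(x, src) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    tibble(circ_id = x$name %||% NA_character_, chrom = x$chrom,
           start = as.integer(x$start), end = as.integer(x$end),
           strand = x$strand, source = src)
  }
  all <- bind_rows(norm(known, "known"), norm(denovo, "de novo"))
  if (is.null(all) || nrow(all) == 0) {
    abort("merge_annotations: no annotations supplied")
  }
  all %>%
    group_by(.data$chrom, .data$start, .data$end, .data$strand) %>%
    summarise(circ_id = first(.data$circ_id[!is.na(.data$circ_id)]),
              source = if (n_distinct(.data$source) > 1) "both"
                       else first(.data$source),
              .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$end) %>%
    mutate(circ_id = ifelse(is.na(.data$circ_id),
                            sprintf("circ_novel_%04d", row_number()),
                            .data$circ_id)) %>%
    select("circ_id", "chrom", "start", "end", "strand", "source")
}

#' Build back-splice junction scaffolds
#'
#' For each junction, concatenates the last `min(flank, span)` genomic nt
#' before `end` (donor side) with the first `min(flank, span)` genomic nt
#' after `start` (acceptor side); minus-strand scaffolds are
#' reverse-complemented so they read 5'->3' in transcript orientation.
#' Flanks are genomic, not spliced, so they can include intronic sequence
#' when terminal exons are short; circles narrower than `2 * flank` get
#' internally overlapping flanks and are flagged `short_overlap`.
#'
#' @param circs Annotation tibble ([merge_annotations()]).
#' @param bundle A `genome_bundle`.
#' @param flank Flank length on each side of the junction (default 100 nt,
#'   sized so standard 125 nt reads can only place end-to-end by crossing
#'   the junction).
#' @return Tibble `circ_id`, `chrom`, `start`, `end`, `strand`, `source`,
#'   `seq`, `offset` (donor-side flank length = position of the first
#'   acceptor-side base), `short_overlap`.
#' @export
build_scaffolds <- function(circs, bundle, flank = 100L) {
  if (any(circs$end - circs$start < 1)) {
    abort("circle with span < 1 nt in annotation")
  }
  circs %>%
    mutate(
      f2 = pmin(as.integer(flank), .data$end - .data$start),
      seq = purrr::pmap_chr(
        list(.data$chrom, .data$start, .data$end, .data$strand, .data$f2),
        function(chrom, start, end, strand, f2) {
          g <- bundle$seqs[[chrom]]
          s <- paste0(subseq0(g, end - f2, end),
                      subseq0(g, start, start + f2))
          if (strand == "-") revcomp(s) else s
        }),
      offset = .data$f2,
      short_overlap = (.data$end - .data$start) < 2L * as.integer(flank)) %>%
    select(-"f2")
}

#' Align mates end-to-end to junction scaffolds
#'
#' Substitution-only end-to-end alignment of each mate against every
#' scaffold in both orientations, scored at `-mismatch_penalty` per
#' mismatch and kept when the score meets `score_threshold` *and* the
#' placement covers the junction with at least `min_overhang` nt on each
#' side. A mate with equal best score on more than one scaffold is
#' discarded as ambiguous; equal placements within one scaffold keep the
#' smallest start.
#'
#' @param mates Tibble `read_id`, `seq` (one row per mate).
#' @param scaffolds From [build_scaffolds()].
#' @param score_threshold Minimum alignment score (default -15).
#' @param mismatch_penalty Penalty per substitution (default 6).
#' @param min_overhang Minimum junction overhang per side (default 10 nt;
#'   with 125 nt reads on 200 nt scaffolds the geometric minimum is 25 nt,
#'   so the default never binds there).
#' @return Alignment tibble `read_id`, `circ_id`, `start` (0-based on the
#'   scaffold), `strand`, `mm`, `score`.
#' @export
align_to_scaffolds <- function(mates, scaffolds, score_threshold = -15,
                               mismatch_penalty = 6, min_overhang = 10L) {
  max_mm <- floor(-score_threshold / mismatch_penalty)
  out0 <- tibble(read_id = character(0), circ_id = character(0),
                 start = integer(0), strand = character(0), mm = integer(0),
                 score = double(0))
  if (nrow(mates) == 0 || nrow(scaffolds) == 0) return(out0)
  k <- min(20L, min(stringr::str_length(scaffolds$seq)))
  idx <- kmer_index_build(setNames(scaffolds$seq, scaffolds$circ_id), k)
  res <- kmer_match_reads(idx, mates$seq, as.integer(max_mm), TRUE, 64L)
  hits <- as_tibble(res$hits)
  if (nrow(hits) == 0) return(out0)
  L <- stringr::str_length(mates$seq)
  hits <- hits %>%
    mutate(read_id = mates$read_id[.data$read],
           circ_id = scaffolds$circ_id[.data$seq],
           offset = scaffolds$offset[.data$seq],
           len = L[.data$read]) %>%
    filter(.data$pos + as.integer(min_overhang) <= .data$offset,
           .data$pos + .data$len >= .data$offset + as.integer(min_overhang))
  if (nrow(hits) == 0) return(out0)
  hits %>%
    group_by(.data$read) %>%
    filter(.data$mm == min(.data$mm)) %>%
    filter(n_distinct(.data$circ_id) == 1) %>%  # ambiguous mates dropped
    arrange(.data$pos, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    transmute(read_id = .data$read_id, circ_id = .data$circ_id,
              start = .data$pos,
              strand = ifelse(.data$strand == 0, "+", "-"),
              mm = .data$mm, score = -mismatch_penalty * .data$mm)
}

#' Remove likely PCR duplicates among junction alignments
#'
#' Within one library, alignments sharing (circ_id, scaffold start, strand)
#' collapse to a single representative: highest score, ties broken by
#' lexicographically smallest read id. Idempotent.
#'
#' @param alignments Tibble from [align_to_scaffolds()], with a
#'   `library_id` column when several libraries are stacked.
#' @return The deduplicated tibble (same columns).
#' @export
dedupe <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  grp <- intersect(c("library_id", "circ_id", "start", "strand"),
                   names(alignments))
  alignments %>%
    arrange(across(all_of(grp)), desc(.data$score), .data$read_id) %>%
    distinct(across(all_of(grp)), .keep_all = TRUE)
}

#' Count deduplicated junction reads per circRNA and library
#'
#' Fragments whose two mates align to different scaffolds are excluded
#' entirely (no-chimera rule). The per-library total `N` is recorded as
#' linearly aligned mates + retained junction mates, the denominator later
#' used for TPM.
#'
#' @param alignments Deduplicated alignment tibble with `library_id`
#'   (see [dedupe()]). Mate ids must end in `/1` or `/2` with a shared
#'   fragment prefix.
#' @param scaffolds From [build_scaffolds()].
#' @param design Library design tibble (`library_id`, `tissue`, `age`,
#'   `replicate`).
#' @param n_linear Named vector or tibble (`library_id`, `n_linear`) of
#'   linearly aligned mate counts per library.
#' @return A `junction_count_matrix`: list with `counts` (long tibble
#'   `circ_id`, `library_id`, `count`, complete grid), `lib_totals`
#'   (`library_id`, `n_linear`, `n_junction`, `N`) and `design`.
#' @export
count_junctions <- function(alignments, scaffolds, design, n_linear) {
  if (is.data.frame(n_linear)) {
    n_linear <- setNames(n_linear$n_linear, n_linear$library_id)
  }
  zero_libs <- setdiff(design$library_id, unique(alignments$library_id))
  if (length(zero_libs)) {
    warn(paste("libraries with zero junction alignments:",
               paste(zero_libs, collapse = ", ")))
  }
  retained <- alignments %>%
    mutate(fragment = sub("/[12]$", "", .data$read_id)) %>%
    group_by(.data$library_id, .data$fragment) %>%
    filter(n_distinct(.data$circ_id) == 1) %>%   # -C: drop chimeric pairs
    ungroup()
  counts <- tidyr::crossing(circ_id = scaffolds$circ_id,
                            library_id = design$library_id) %>%
    left_join(retained %>% count(.data$circ_id, .data$library_id),
              by = c("circ_id", "library_id")) %>%
    mutate(count = as.integer(tidyr::replace_na(.data$n, 0L))) %>%
    select("circ_id", "library_id", "count")
  lib_totals <- counts %>%
    group_by(.data$library_id) %>%
    summarise(n_junction = sum(.data$count), .groups = "drop") %>%
    mutate(n_linear = as.integer(n_linear[.data$library_id]),
           N = .data$n_linear + .data$n_junction) %>%
    select("library_id", "n_linear", "n_junction", "N")
  structure(list(counts = counts, lib_totals = lib_totals, design = design),
            class = "junction_count_matrix")
}

#' @export
print.junction_count_matrix <- function(x, ...) {
  cat(sprintf("<junction_count_matrix> %d circRNAs x %d libraries\n",
              n_distinct(x$counts$circ_id), nrow(x$lib_totals)))
  invisible(x)
}

#' Quantify junction reads for a set of libraries
#'
#' Runs [align_to_scaffolds()], [dedupe()] and [count_junctions()] per
#' library.
#'
#' @param reads_by_lib Named list of read tibbles (`name`, `seq1`, `seq2`).
#' @param scaffolds From [build_scaffolds()].
#' @param design Design tibble covering `names(reads_by_lib)`.
#' @param n_linear Per-library linearly aligned mate counts (named vector
#'   or tibble).
#' @param ... Passed to [align_to_scaffolds()].
#' @return List: `matrix` (a `junction_count_matrix`), `alignments`
#'   (deduplicated, all libraries).
#' @export
quantify_junctions <- function(reads_by_lib, scaffolds, design, n_linear,
                               ...) {
  aln <- purrr::imap(reads_by_lib, function(reads, lib) {
    align_to_scaffolds(reads_long(reads), scaffolds, ...) %>%
      mutate(library_id = lib)
  }) %>% list_rbind() %>% dedupe()
  list(matrix = count_junctions(aln, scaffolds, design, n_linear),
       alignments = aln)
}
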