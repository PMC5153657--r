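rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", vapply(strsplit(x, NULL), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}

to_rna <- function(x) chartr("Tt", "Uu", str_to_upper(x))

#' Read a microRNA family seed table
#'
#' @param path TSV with columns `family`, `seed` (bases 2-8 of the mature
#'   microRNA, 5'->3', RNA alphabet; length 7). The package ships a small
#'   representative set of broadly conserved mouse families at
#'   `system.file("extdata", "mir_seeds.tsv", package = "circaging")`;
#'   it is an editable stand-in for a full family list.
#' @return Tibble `family`, `seed`.
#' @export
read_mir_families <- function(path = system.file("extdata", "mir_seeds.tsv",
                                                 package = "circaging")) {
  fam <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  bad <- stringr::str_length(fam$seed) != 7 |
    str_detect(fam$seed, "[^ACGU]")
  if (any(bad)) {
    abort(paste("invalid seed(s):", paste(fam$family[bad], collapse = ", ")))
  }
  fam
}

#' Find canonical microRNA seed-match sites
#'
#' Scans a target sequence (transcript orientation) for the three canonical
#' site types of one family with seed `s` = microRNA bases 2-8:
#' `7mer-m8` = exact match to `rc(s)`; `7mer-A1` = match to `rc(s[1:6])`
#' (microRNA bases 2-7) followed by an A in the target; `8mer` = both (an A
#' opposite microRNA position 1 after the full `rc(s)`). 8mer sites subsume
#' their component 7mers, which are not double-counted; all remaining
#' (including overlapping) sites are reported.
#'
#' @param target Target sequence (DNA or RNA; converted to RNA internally).
#' @param family One-row tibble or list with `family`, `seed`.
#' @return Tibble `family`, `site_type`, `position` (1-based start of the
#'   site in the target), `length` (7 or 8).
#' @export
find_seed_sites <- function(target, family) {
  t_rna <- to_rna(target)
  bad <- stringr::str_locate(t_rna, "[^ACGUN]")
  if (!is.na(bad[1, 1])) {
    abort(sprintf("non-ACGUN character at position %d", bad[1, 1]))
  }
  out0 <- tibble(family = character(0), site_type = character(0),
                 position = integer(0), length = integer(0))
  if (stringr::str_length(t_rna) < 7) return(out0)
  seed <- family$seed
  m8_site <- rna_revcomp(seed)            # 7 nt
  a1_core <- rna_revcomp(str_sub(seed, 1, 6))  # 6 nt, microRNA bases 2-7
  locate_all <- function(pat) {
    # overlapping fixed matches
    hits <- integer(0)
    from <- 1
    repeat {
      p <- stringr::str_locate(str_sub(t_rna, from), fixed(pat))[1, 1]
      if (is.na(p)) break
      hits <- c(hits, from + p - 1)
      from <- from + p
    }
    hits
  }
  p_m8 <- locate_all(m8_site)
  p_a1core <- locate_all(a1_core)
  tlen <- stringr::str_length(t_rna)
  is_a <- function(pos) pos <= tlen & str_sub(t_rna, pos, pos) == "A"
  p_8mer <- p_m8[is_a(p_m8 + 7)]
  p_7m8 <- setdiff(p_m8, p_8mer)
  p_a1 <- p_a1core[is_a(p_a1core + 6)]
  # a position is reported at its best type only: not as the A1 component
  # of an 8mer one base upstream, nor as A1 where the full m8 heptamer
  # already matches
  p_a1 <- setdiff(p_a1, c(p_8mer + 1, p_m8, p_8mer))
  bind_rows(
    tibble(site_type = "8mer", position = p_8mer, length = 8L),
    tibble(site_type = "7mer-m8", position = p_7m8, length = 7L),
    tibble(site_type = "7mer-A1", position = p_a1, length = 7L)) %>%
    mutate(family = family$family, .before = 1) %>%
    mutate(position = as.integer(.data$position)) %>%
    arrange(.data$position, .data$site_type)
}

#' Scan several sequences against several families
#'
#' @param targets Named character vector of target sequences.
#' @param families Tibble from [read_mir_families()].
#' @return Tibble with `target_id` plus [find_seed_sites()] columns.
#' @export
scan_seed_sites <- function(targets, families) {
  purrr::imap(targets, function(seq, id) {
    purrr::map(seq_len(nrow(families)),
               ~find_seed_sites(seq, families[.x, ])) %>%
      list_rbind() %>%
      mutate(target_id = id, .before = 1)
  }) %>% list_rbind()
}

#' Conservation filter over aligned orthologous sequences
#'
#' A reference-species hit is conserved when the aligned columns spanned by
#' its site contain a valid site of the same family in every other species
#' of the alignment (any canonical type by default; `strict_type = TRUE`
#' demands the identical type). Gap columns are removed per species before
#' re-scanning, so a site shifted by an alignment gap but intact still
#' counts. Hits whose site interval has no ortholog coverage (species
#' sequence all gaps) are marked unevaluable and excluded.
#'
#' @param hits Tibble from [find_seed_sites()] / [scan_seed_sites()] with
#'   `position`, `length`, `family` in *ungapped reference* coordinates.
#' @param alignment Named character vector of gapped sequences, reference
#'   species first; all equal length.
#' @param families Family table (for seed lookup).
#' @param strict_type Require the same site type in every species.
#' @return `hits` with added `conserved` and `unevaluable` logicals.
#' @export
conservation_filter <- function(hits, alignment, families,
                                strict_type = FALSE) {
  if (length(alignment) < 2) {
    return(hits %>% mutate(conserved = TRUE, unevaluable = FALSE))
  }
  gl <- unique(stringr::str_length(alignment))
  if (length(gl) != 1) abort("alignment sequences differ in length")
  ref <- to_rna(alignment[[1]])
  ref_chars <- strsplit(ref, NULL)[[1]]
  ungapped_col <- which(ref_chars != "-")   # ref position i -> column
  others <- purrr::map(alignment[-1], to_rna)
  check_one <- function(pos, len, fam_row, type) {
    cols <- ungapped_col[pos:(pos + len - 1)]
    span <- range(cols)
    ok_all <- TRUE; uneval <- FALSE
    for (sp in others) {
      seg <- str_sub(sp, span[1], span[2])
      seg <- gsub("-", "", seg, fixed = TRUE)
      if (!nchar(seg)) { uneval <- TRUE; break }
      sp_hits <- find_seed_sites(seg, fam_row)
      if (strict_type) sp_hits <- sp_hits %>%
          filter(.data$site_type == type)
      if (nrow(sp_hits) == 0) { ok_all <- FALSE; break }
    }
    c(conserved = ok_all && !uneval, unevaluable = uneval)
  }
  res <- purrr::map(seq_len(nrow(hits)), function(i) {
    fam_row <- families %>% filter(.data$family == hits$family[i])
    check_one(hits$position[i], hits$length[i], fam_row[1, ],
              hits$site_type[i])
  })
  hits %>%
    mutate(conserved = purrr::map_lgl(res, "conserved"),
           unevaluable = purrr::map_lgl(res, "unevaluable"))
}

#' Restrict hits to annotated exons of a circRNA locus
#'
#' Keeps only hits whose full site interval lies within one annotated
#' member exon; intronic sites and sites straddling an exon boundary are
#' dropped (mirroring exon-level filtering of intron-spliced circles).
#'
#' @param hits Tibble with genomic coordinates `gstart`, `gend` (0-based
#'   half-open).
#' @param circ One-row annotation tibble (`chrom`, `start`, `end`,
#'   `host_gene`).
#' @param bundle A `genome_bundle`.
#' @return Filtered `hits`.
#' @export
exon_restrict <- function(hits, circ, bundle) {
  if (nrow(hits) == 0) return(hits)
  ex <- bundle$exons %>%
    filter(.data$chrom == circ$chrom, .data$start < circ$end,
           .data$end > circ$start)
  keep <- purrr::map_lgl(seq_len(nrow(hits)), function(i) {
    any(ex$start <= hits$gstart[i] & ex$end >= hits$gend[i])
  })
  hits[keep, , drop = FALSE]
}

#' Scan a circRNA locus for conserved exonic seed sites
#'
#' Extracts the locus genomic sequence (strand-oriented), scans all
#' families, converts hit positions to genomic intervals, and applies
#' [exon_restrict()].
#'
#' @param circ One-row annotation tibble.
#' @param bundle A `genome_bundle`.
#' @param families Family table.
#' @return Hit tibble with `gstart`, `gend` genomic columns.
#' @export
scan_circ_sites <- function(circ, bundle, families) {
  g <- bundle$seqs[[circ$chrom]]
  locus <- subseq0(g, circ$start, circ$end)
  if (circ$strand == "-") locus <- revcomp(locus)
  hits <- scan_seed_sites(setNames(locus, circ$circ_id), families) %>%
    rename(circ_id = "target_id")
  span <- circ$end - circ$start
  hits <- hits %>%
    mutate(
      gstart = if (circ$strand == "+") circ$start + .data$position - 1L
               else circ$start + span - (.data$position - 1L) - .data$length,
      gend = .data$gstart + .data$length)
  exon_restrict(hits, circ, bundle)
}

#' Top microRNA families per circRNA locus
#'
#' @param hits Conserved, exon-restricted hit tibble with `circ_id`,
#'   `family`.
#' @param k Families to report per locus (default 5); ties broken by
#'   family name ascending.
#' @return Tibble `circ_id`, `family`, `n_sites`, `rank`.
#' @export
top_families <- function(hits, k = 5L) {
  hits %>%
    count(.data$circ_id, .data$family, name = "n_sites") %>%
    group_by(.data$circ_id) %>%
    arrange(desc(.data$n_sites), .data$family, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    filter(.data$rank <= k) %>%
    ungroup()
}
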