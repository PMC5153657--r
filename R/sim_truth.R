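#' Create an empty truth set for a simulated study
#'
#' The truth set records, per library, every read mate that crosses a
#' back-spliced junction (with donor- and acceptor-side overhangs and the
#' strand it would take on a junction scaffold), the injected PCR
#' duplicates, and per-library totals. Counts at any overhang threshold are
#' derived views ([truth_counts()]), so the same record serves both the
#' detection oracle (anchor-length overhang) and the quantification oracle
#' (end-to-end scaffold overhang).
#'
#' @param circs True circRNA tibble ([assign_circrnas()]).
#' @param design Library design tibble ([sim_design()]).
#' @return A list with class `truth_set`.
#' @export
new_truth_set <- function(circs, design) {
  structure(list(
    circs = circs,
    design = design,
    junction_reads = tibble(
      library_id = character(0), circ_id = character(0),
      name = character(0), mate = integer(0),
      donor_overhang = integer(0), acceptor_overhang = integer(0),
      scaffold_strand = character(0), is_dup = logical(0)),
    duplicates = tibble(library_id = character(0), name = character(0)),
    libraries = tibble(
      library_id = character(0), tissue = character(0), age = character(0),
      replicate = integer(0), n_fragments = integer(0),
      n_duplicates = integer(0), n_pairs_emitted = integer(0),
      n_circ_fragments = integer(0))),
    class = "truth_set")
}

#' True junction counts at a chosen overhang threshold
#'
#' @param truth A `truth_set`.
#' @param overhang Minimum overhang (nt) required on *both* sides of the
#'   junction for a mate to qualify.
#' @param unit Counting unit: `"fragments"` counts distinct non-duplicate
#'   fragments with at least one qualifying mate; `"mates"` counts
#'   qualifying non-duplicate mates; `"dedup_starts"` counts distinct
#'   (circ, scaffold start, strand) keys among qualifying mates -- the
#'   number a start-coordinate deduplicated junction counter should report.
#' @param flank Scaffold flank length (needed for `"dedup_starts"`).
#' @return Tibble `circ_id`, `library_id`, `true_count` (complete over the
#'   circ x library grid, zeros included).
#' @export
truth_counts <- function(truth, overhang = 20L,
                         unit = c("fragments", "mates", "dedup_starts"),
                         flank = 100L) {
  unit <- match.arg(unit)
  jr <- truth$junction_reads %>%
    filter(.data$donor_overhang >= overhang,
           .data$acceptor_overhang >= overhang)
  counted <- switch(unit,
    fragments = jr %>%
      filter(!.data$is_dup) %>%
      distinct(.data$library_id, .data$circ_id, .data$name) %>%
      count(.data$library_id, .data$circ_id, name = "true_count"),
    mates = jr %>%
      filter(!.data$is_dup) %>%
      count(.data$library_id, .data$circ_id, name = "true_count"),
    dedup_starts = jr %>%
      mutate(start = flank - .data$donor_overhang) %>%
      distinct(.data$library_id, .data$circ_id, .data$start,
               .data$scaffold_strand) %>%
      count(.data$library_id, .data$circ_id, name = "true_count"))
  tidyr::crossing(circ_id = truth$circs$circ_id,
                  library_id = truth$design$library_id) %>%
    left_join(counted, by = c("library_id", "circ_id")) %>%
    mutate(true_count = as.integer(tidyr::replace_na(.data$true_count,
                                                     0L))) %>%
    arrange(.data$circ_id, .data$library_id)
}

#' Write / read a truth set as plain TSV tables
#'
#' Writes `circs.tsv` (catalog with effect designations), a BED-like
#' `circs.bed` (0-based half-open), `junction_reads.tsv`, `duplicates.tsv`
#' and `libraries.tsv` into `dir`. The TSV round trip is lossless.
#'
#' @param truth A `truth_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly; `read_truth()` returns the `truth_set`.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(truth$circs, file.path(dir, "circs.tsv"))
  readr::write_tsv(truth$circs %>%
                     transmute(.data$chrom, .data$start, .data$end,
                               name = .data$circ_id, score = 0L,
                               .data$strand),
                   file.path(dir, "circs.bed"), col_names = FALSE)
  readr::write_tsv(truth$design, file.path(dir, "design.tsv"))
  readr::write_tsv(truth$junction_reads,
                   file.path(dir, "junction_reads.tsv"))
  readr::write_tsv(truth$duplicates, file.path(dir, "duplicates.tsv"))
  readr::write_tsv(truth$libraries, file.path(dir, "libraries.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  rd <- function(f, types) {
    readr::read_tsv(file.path(dir, f), col_types = types,
                    progress = FALSE)
  }
  structure(list(
    circs = rd("circs.tsv", readr::cols(
      circ_id = "c", gene_id = "c", transcript_id = "c", chrom = "c",
      strand = "c", start = "i", end = "i", acceptor_rank = "i",
      donor_rank = "i", n_exons_circ = "i", rel_abundance = "d",
      direction = "c", fold = "d")),
    design = rd("design.tsv", readr::cols(
      library_id = "c", tissue = "c", age = "c", replicate = "i")),
    junction_reads = rd("junction_reads.tsv", readr::cols(
      library_id = "c", circ_id = "c", name = "c", mate = "i",
      donor_overhang = "i", acceptor_overhang = "i",
      scaffold_strand = "c", is_dup = "l")),
    duplicates = rd("duplicates.tsv",
                    readr::cols(library_id = "c", name = "c")),
    libraries = rd("libraries.tsv", readr::cols(
      library_id = "c", tissue = "c", age = "c", replicate = "i",
      n_fragments = "i", n_duplicates = "i", n_pairs_emitted = "i",
      n_circ_fragments = "i"))),
    class = "truth_set")
}
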