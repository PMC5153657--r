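#' Simulate a gapped orthologous alignment for conservation filtering
#'
#' Emits an n-species gapped alignment of a reference sequence in which
#' designated intervals (e.g. seed sites) are either preserved in all
#' species or disrupted in one, and neutral positions accumulate random
#' substitutions; random gaps are inserted in non-reference species so that
#' column mapping across indels is exercised.
#'
#' @param ref Reference (e.g. mouse) sequence, DNA or RNA alphabet.
#' @param n_species Total species including the reference (default 3).
#' @param protect Tibble/list with `start`, `end` (1-based inclusive on
#'   `ref`) of intervals kept identical in every species.
#' @param disrupt Same shape; intervals whose central base is substituted
#'   in the *last* species (breaking conservation there).
#' @param mutation_rate Per-base substitution probability outside protected
#'   intervals in non-reference species.
#' @param gap_rate Per-position probability of opening a 1-3 nt gap in a
#'   non-reference species (as extra reference-skipping is not modelled,
#'   gaps are insertions in the reference track: columns where the species
#'   has '-').
#' @param seed Integer seed.
#' @param species Species names (defaults `sp1..spN`, reference first).
#' @return Named character vector of equal-length gapped sequences,
#'   reference first.
#' @export
simulate_ortholog_alignment <- function(ref, n_species = 3,
                                        protect = NULL, disrupt = NULL,
                                        mutation_rate = 0.05,
                                        gap_rate = 0.01, seed = 1,
                                        species = NULL) {
  ref <- str_to_upper(ref)
  alpha <- if (str_detect(ref, "U")) c("A", "C", "G", "U")
           else c("A", "C", "G", "T")
  n <- stringr::str_length(ref)
  prot <- rep(FALSE, n)
  mark <- function(iv, v) {
    if (is.null(iv)) return(v)
    for (i in seq_len(nrow(iv))) v[iv$start[i]:iv$end[i]] <- TRUE
    v
  }
  prot <- mark(protect, prot)
  species <- species %||% paste0("sp", seq_len(n_species))
  with_substream(seed, "ortholog-alignment", {
    rows <- list()
    rows[[species[1]]] <- strsplit(ref, NULL)[[1]]
    for (s in 2:n_species) {
      ch <- rows[[species[1]]]
      mut <- runif(n) < mutation_rate & !prot
      ch[mut] <- vapply(ch[mut], function(b) sample(setdiff(alpha, b), 1),
                        character(1))
      if (s == n_species && !is.null(disrupt)) {
        for (i in seq_len(nrow(disrupt))) {
          mid <- floor((disrupt$start[i] + disrupt$end[i]) / 2)
          ch[mid] <- sample(setdiff(alpha, ch[mid]), 1)
        }
      }
      rows[[species[s]]] <- ch
    }
    # insert gap columns: each gap deletes 1-3 bases from one non-reference
    # species, realized as '-' in that species' row (columns stay shared)
    for (s in 2:n_species) {
      ch <- rows[[species[s]]]
      open <- which(runif(n) < gap_rate & !prot)
      for (g in open) {
        w <- sample(1:3, 1)
        ivl <- g:min(n, g + w - 1)
        ch[ivl[!prot[ivl]]] <- "-"
      }
      rows[[species[s]]] <- ch
    }
    vapply(rows, paste, character(1), collapse = "")
  })
}

#' Write / read gapped multi-FASTA alignments
#'
#' @param alignment Named character vector of gapped sequences.
#' @param path FASTA path.
#' @return `write_alignment()` returns `path` invisibly; `read_alignment()`
#'   the named character vector.
#' @export
write_alignment <- function(alignment, path) {
  writeLines(as.vector(rbind(paste0(">", names(alignment)), alignment)),
             path)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
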