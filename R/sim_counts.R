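#' Simulate a count-level circRNA study for one tissue
#'
#' Draws deduplicated junction counts directly as Poisson variates --
#' young-group mean `mean_count`, old-group mean `mean_count * fold` for
#' circles designated as affected -- bypassing read-level simulation. This
#' is the natural scale for calibration studies of the differential tests
#' (type-I error, power, fold-change recovery, global shift), where
#' thousands of circles are needed and per-read detail adds nothing.
#'
#' @param n_circ Number of circRNAs.
#' @param mean_count Young-group mean deduplicated junction count.
#' @param fold True old/young fold change of affected circles.
#' @param frac_affected Fraction of circles affected (default 0: pure null).
#' @param n_rep Replicates per age (default 3).
#' @param lib_size Per-library total read count `N` (TPM denominator).
#' @param tissue Tissue label.
#' @param seed Integer seed.
#' @return List: `matrix` (a `junction_count_matrix`), `truth` (tibble
#'   `circ_id`, `true_fold`).
#' @export
simulate_count_study <- function(n_circ, mean_count, fold = 1,
                                 frac_affected = 0, n_rep = 3,
                                 lib_size = 1e6, tissue = "cortex",
                                 seed = 1) {
  design <- tidyr::crossing(age = c("young", "old"),
                            replicate = seq_len(n_rep)) %>%
    mutate(tissue = tissue,
           library_id = fmt_lib(tissue, .data$age, .data$replicate)) %>%
    select("library_id", "tissue", "age", "replicate") %>%
    arrange(desc(.data$age), .data$replicate)   # young first
  circ_id <- sprintf("circ%05d", seq_len(n_circ))
  with_substream(seed, "count-study", {
    n_aff <- round(frac_affected * n_circ)
    affected <- c(rep(TRUE, n_aff), rep(FALSE, n_circ - n_aff))
    affected <- sample(affected)
    true_fold <- ifelse(affected, fold, 1)
    counts <- tidyr::crossing(circ_id = circ_id,
                              library_id = design$library_id) %>%
      left_join(design %>% select("library_id", "age"), by = "library_id") %>%
      left_join(tibble(circ_id = circ_id, true_fold = true_fold),
                by = "circ_id") %>%
      mutate(mu = ifelse(.data$age == "old",
                         mean_count * .data$true_fold, mean_count),
             count = rpois(n(), .data$mu)) %>%
      select("circ_id", "library_id", "count")
    lib_totals <- tibble(library_id = design$library_id,
                         n_linear = as.integer(lib_size),
                         n_junction = 0L) %>%
      mutate(N = .data$n_linear + .data$n_junction)
    list(matrix = structure(list(counts = counts, lib_totals = lib_totals,
                                 design = design),
                            class = "junction_count_matrix"),
         truth = tibble(circ_id = circ_id, true_fold = true_fold))
  })
}
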