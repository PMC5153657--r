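#' Simulation configuration for a synthetic circRNA aging study
#'
#' Builds the configuration object consumed by the synthetic-data generator.
#' The defaults emulate the study design the package targets: ribo-depleted
#' total RNA-seq of three tissues (cortex, hippocampus, heart) at two ages
#' (young, old) in biological triplicate, paired-end 125 nt reads, a small
#' fraction (< 0.1 %) of reads spanning back-spliced junctions, PCR
#' duplicates, and a multiplicative age-upregulation effect applied to a
#' subset of circRNAs in the brain tissues only.
#'
#' @param seed Integer seed; every random draw in the simulator flows from it
#'   via named substreams.
#' @param n_chromosomes,chrom_length Toy genome shape (nt per chromosome).
#' @param n_genes Number of protein-coding genes placed on the genome.
#' @param exons_per_gene,exon_length,intron_length Integer ranges
#'   (length-2 vectors) sampled uniformly per gene/exon/intron.
#' @param intergenic_length Range of intergenic gap lengths between genes.
#' @param n_circ_genes Number of genes hosting at least one circRNA.
#' @param n_multi_circ_genes How many of those receive a second circle.
#' @param acceptor_index_probs Categorical distribution over the 1-based
#'   index of the splice-accepting (first) circularised exon; the default
#'   puts the mode on exon 2, matching the empirical preference of
#'   back-splice acceptors for 5'-proximal exons. Exon 1 gets probability 0
#'   by default because a first exon has no upstream acceptor splice site,
#'   so no back-splice can land on it.
#' @param read_length Read length in nt (125 by default).
#' @param fragment_mean,fragment_sd Gaussian fragment-length model (nt),
#'   truncated to `[read_length, 2*read_length + 200]`.
#' @param frags_per_library Number of sequenced fragments per library before
#'   duplicate injection.
#' @param n_replicates Biological replicates per (tissue, age) group.
#' @param tissues,ages Group labels; their crossing defines the design.
#' @param base_abundance Named list `list(meanlog=, sdlog=)` of the
#'   log-normal relative-abundance model shared by linear transcripts and
#'   circles.
#' @param circ_fraction_of_reads Target fraction of all reads that span a
#'   back-spliced junction; circle sampling weights are calibrated to it.
#' @param age_effect Named list `list(fraction_up=, fold_up=, fraction_down=,
#'   fold_down=)` applied multiplicatively to designated circRNAs in
#'   `affected_tissues` at the old age. Host linear abundances are untouched,
#'   so circular and linear regulation are independent by construction.
#' @param affected_tissues Tissues in which the age effect acts.
#' @param duplicate_rate Probability that a fragment is re-emitted once as an
#'   exact PCR duplicate.
#' @param error_rate Per-base substitution probability.
#' @param truth_overhang Minimum junction overhang (nt) a mate must have for
#'   the truth tables to call it junction-spanning at detector resolution
#'   (equals the detector's anchor length by default).
#' @param stranded Emit strand-specific pairs (`TRUE`) or unstranded-
#'   equivalent pairs where the sense mate is randomised (`FALSE`, default).
#'
#' @return A list with class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 10, n_circ_genes = 4,
#'                   chrom_length = 2e5, n_chromosomes = 1)
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length = 1000000L,
                       n_genes = 150L,
                       exons_per_gene = c(3L, 8L),
                       exon_length = c(120L, 400L),
                       intron_length = c(200L, 800L),
                       intergenic_length = c(300L, 1500L),
                       n_circ_genes = 40L,
                       n_multi_circ_genes = 5L,
                       acceptor_index_probs = c(0, 0.50, 0.22, 0.15,
                                                0.08, 0.05),
                       read_length = 125L,
                       fragment_mean = 300,
                       fragment_sd = 50,
                       frags_per_library = 11000L,
                       n_replicates = 3L,
                       tissues = c("cortex", "hippocampus", "heart"),
                       ages = c("young", "old"),
                       base_abundance = list(meanlog = 0, sdlog = 1),
                       circ_fraction_of_reads = 5e-04,
                       age_effect = list(fraction_up = 0.2, fold_up = 2,
                                         fraction_down = 0.05, fold_down = 2),
                       affected_tissues = c("cortex", "hippocampus"),
                       duplicate_rate = 0.05,
                       error_rate = 0.001,
                       truth_overhang = 20L,
                       stranded = FALSE) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    intergenic_length = as.integer(intergenic_length),
    n_circ_genes = as.integer(n_circ_genes),
    n_multi_circ_genes = as.integer(n_multi_circ_genes),
    acceptor_index_probs = acceptor_index_probs,
    read_length = as.integer(read_length),
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    frags_per_library = as.integer(frags_per_library),
    n_replicates = as.integer(n_replicates),
    tissues = tissues, ages = ages,
    base_abundance = base_abundance,
    circ_fraction_of_reads = circ_fraction_of_reads,
    age_effect = age_effect, affected_tissues = affected_tissues,
    duplicate_rate = duplicate_rate, error_rate = error_rate,
    truth_overhang = as.integer(truth_overhang),
    stranded = isTRUE(stranded))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$exons_per_gene) == 2, length(cfg$exon_length) == 2,
            length(cfg$intron_length) == 2)
  if (cfg$exon_length[1] < 1) abort("exon_length minimum must be >= 1")
  rates <- c(cfg$circ_fraction_of_reads, cfg$duplicate_rate, cfg$error_rate,
             cfg$age_effect$fraction_up, cfg$age_effect$fraction_down)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (cfg$age_effect$fold_up < 1 || cfg$age_effect$fold_down < 1)
    abort("age_effect folds must be >= 1")
  if (cfg$read_length < 2 * 20)
    abort("read_length must be >= twice the detector anchor length (20)")
  if (!all(cfg$acceptor_index_probs >= 0) ||
      sum(cfg$acceptor_index_probs) <= 0)
    abort("acceptor_index_probs must be non-negative and sum > 0")
  invisible(cfg)
}

#' Library design table implied by a simulation configuration
#'
#' @param cfg A [sim_config()] object.
#' @return A tibble with `library_id`, `tissue`, `age`, `replicate`.
#' @export
sim_design <- function(cfg) {
  tidyr::crossing(tissue = cfg$tissues, age = cfg$ages,
                  replicate = seq_len(cfg$n_replicates)) %>%
    mutate(age = factor(.data$age, levels = cfg$ages)) %>%
    arrange(.data$tissue, .data$age, .data$replicate) %>%
    mutate(age = as.character(.data$age),
           library_id = fmt_lib(.data$tissue, .data$age, .data$replicate)) %>%
    select("library_id", "tissue", "age", "replicate")
}

#' Read or write a simulation configuration as YAML-like key/value text
#'
#' The on-disk format is JSON (one structured config file); `seed` can be
#' overridden at load time.
#'
#' @param path File path.
#' @param cfg A [sim_config()] object (for writing).
#' @param seed Optional seed override (for reading).
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(sim_config, raw)
}
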