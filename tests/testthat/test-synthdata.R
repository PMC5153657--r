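test_that("genome generation is deterministic and satisfies gene-model invariants", {
  cfg <- small_cfg()
  b1 <- generate_genome(cfg)
  b2 <- generate_genome(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))

  # gene spans pairwise non-overlapping (interval sweep over emitted models)
  g <- b1$genes %>% arrange(chrom, start)
  by_chrom <- split(g, g$chrom)
  for (gc in by_chrom) {
    if (nrow(gc) > 1) expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }

  # every intron carries canonical splice dinucleotides, strand-aware
  introns <- b1$exons %>%
    group_by(transcript_id, chrom, strand) %>%
    arrange(start, .by_group = TRUE) %>%
    summarise(istart = list(end[-dplyr::n()]), iend = list(start[-1]),
              .groups = "drop") %>%
    tidyr::unnest(c(istart, iend))
  for (i in seq_len(nrow(introns))) {
    s <- b1$seqs[[introns$chrom[i]]]
    first2 <- substr(s, introns$istart[i] + 1, introns$istart[i] + 2)
    last2 <- substr(s, introns$iend[i] - 1, introns$iend[i])
    if (introns$strand[i] == "+") {
      expect_identical(c(first2, last2), c("GT", "AG"))
    } else {
      expect_identical(c(first2, last2), c("CT", "AC"))
    }
  }
})

test_that("a one-gene config yields the forced exon/intron structure", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chrom_length = 20000L,
                    n_genes = 1L, exons_per_gene = c(3L, 3L))
  b <- generate_genome(cfg)
  expect_equal(nrow(b$exons), 3)
  expect_equal(b$transcripts$n_exons, 3L)
})

test_that("genome generation errors when genes cannot be placed", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 4000L,
                    n_genes = 10L)
  expect_error(generate_genome(cfg), "cannot place gene")
})

test_that("circle assignment respects structure and acceptor-index bias", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length = 1500000L,
                    n_genes = 100L, n_circ_genes = 90L,
                    n_multi_circ_genes = 0L)
  b <- generate_genome(cfg)
  ranks <- unlist(lapply(1:12, function(s) {
    cfg_s <- cfg; cfg_s$seed <- 1000L + s
    assign_circrnas(b, cfg_s)$acceptor_rank
  }))
  expect_gt(length(ranks), 1000)
  mode_rank <- as.integer(names(which.max(table(ranks))))
  expect_identical(mode_rank, 2L)

  # start/end equal the member-exon block bounds
  circs <- assign_circrnas(b, cfg)
  for (i in sample(nrow(circs), 10)) {
    ex <- b$exons %>%
      filter(transcript_id == circs$transcript_id[i],
             exon_rank >= circs$acceptor_rank[i],
             exon_rank <= circs$donor_rank[i])
    expect_equal(circs$start[i], min(ex$start))
    expect_equal(circs$end[i], max(ex$end))
  }
})

test_that("single-exon circle configs force start/end to one exon's bounds", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_length = 300000L,
                    n_genes = 20L, exons_per_gene = c(3L, 3L),
                    n_circ_genes = 10L, n_multi_circ_genes = 0L,
                    acceptor_index_probs = c(0, 1))
  b <- generate_genome(cfg)
  circs <- assign_circrnas(b, cfg)
  expect_true(all(circs$acceptor_rank == 2 & circs$donor_rank == 2))
  expect_true(all(circs$n_exons_circ == 1))
})

test_that("two circles on one host gene have distinct coordinates", {
  study <- small_study()
  dups <- study$circs %>%
    group_by(gene_id) %>% filter(dplyr::n() > 1)
  expect_gt(nrow(dups), 0)
  expect_equal(nrow(dups), nrow(distinct(dups, gene_id, start, end)))
})

test_that("circle assignment errors when too few eligible genes exist", {
  cfg <- sim_config(seed = 2, n_chromosomes = 1, chrom_length = 200000L,
                    n_genes = 5L, n_circ_genes = 10L)
  b <- generate_genome(cfg)
  expect_error(assign_circrnas(b, cfg), "only .* genes")
})

test_that("library simulation is deterministic and conserves fragments", {
  cfg <- small_cfg()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$junction_reads, s2$truth$junction_reads)

  libs <- s1$truth$libraries
  expect_true(all(libs$n_pairs_emitted == libs$n_fragments +
                    libs$n_duplicates))
  for (lib in libs$library_id) {
    expect_equal(nrow(s1$reads[[lib]]),
                 libs$n_pairs_emitted[libs$library_id == lib])
  }
})

test_that("FASTQ round trip preserves reads byte-for-byte", {
  study <- small_study()
  lib <- names(study$reads)[1]
  tmp <- withr::local_tempdir()
  p <- write_fastq_pairs(study$reads[[lib]], file.path(tmp, lib))
  back <- read_fastq_pairs(p[1], p[2])
  expect_identical(back$seq1, study$reads[[lib]]$seq1)
  expect_identical(back$seq2, study$reads[[lib]]$seq2)
  expect_identical(back$name, study$reads[[lib]]$name)
})

test_that("per-base substitution errors occur at the configured rate", {
  set.seed(123)
  n <- 1200; L <- 125; rate <- 0.01
  seqs <- vapply(seq_len(n), function(i) random_dna_str(L), character(1))
  mutated <- circaging:::apply_sequencing_errors(seqs, rate)
  mm <- sum(vapply(seq_len(n), function(i) {
    sum(strsplit(seqs[i], NULL)[[1]] != strsplit(mutated[i], NULL)[[1]])
  }, numeric(1)))
  total <- n * L
  expect_gt(total, 1e5)
  se <- sqrt(rate * (1 - rate) / total)
  expect_lt(abs(mm / total - rate), 3 * se)
})

test_that("error-free junction reads contain the exact junction context", {
  study <- small_study()
  jr <- study$truth$junction_reads %>%
    filter(!is_dup, donor_overhang >= 2, acceptor_overhang >= 2) %>%
    head(25)
  expect_gt(nrow(jr), 0)
  for (i in seq_len(nrow(jr))) {
    circ <- study$circs %>% filter(circ_id == jr$circ_id[i])
    cs <- circaging:::circle_seq(study$bundle, circ)
    ctx <- paste0(substr(cs, nchar(cs) - 1, nchar(cs)), substr(cs, 1, 2))
    reads <- study$reads[[jr$library_id[i]]]
    mate_seq <- reads[[paste0("seq", jr$mate[i])]][reads$name == jr$name[i]]
    oriented <- if (jr$scaffold_strand[i] == "-") revcomp(mate_seq)
                else mate_seq
    expect_identical(substr(oriented, jr$donor_overhang[i] - 1,
                            jr$donor_overhang[i] + 2), ctx)
  }
})

test_that("doubling circle abundance doubles expected junction output", {
  ratios <- vapply(1:3, function(s) {
    cfg <- sim_config(seed = 500L + s, n_chromosomes = 1,
                      chrom_length = 500000L, n_genes = 30L,
                      n_circ_genes = 12L, n_multi_circ_genes = 0L,
                      tissues = "cortex", affected_tissues = "cortex",
                      frags_per_library = 4000L,
                      circ_fraction_of_reads = 0.02,
                      age_effect = list(fraction_up = 1, fold_up = 2,
                                        fraction_down = 0, fold_down = 1),
                      error_rate = 0, duplicate_rate = 0)
    study <- simulate_study(cfg)
    jr <- study$truth$junction_reads %>%
      filter(!is_dup) %>%
      distinct(library_id, name) %>%
      left_join(study$design, by = "library_id") %>%
      count(age)
    jr$n[jr$age == "old"] / jr$n[jr$age == "young"]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2) / 2, 0.1)
})

test_that("junction-spanning reads stay a small fraction at the default target", {
  study <- small_study()  # target fraction 0.01 in this fixture
  n_junction <- study$truth$junction_reads %>% filter(!is_dup) %>% nrow()
  n_reads <- 2 * sum(study$truth$libraries$n_pairs_emitted)
  expect_lt(n_junction / n_reads, 0.05)

  cfg <- small_cfg(seed = 77)
  cfg$circ_fraction_of_reads <- 0.001
  study_low <- suppressWarnings(simulate_study(cfg))
  frac <- nrow(filter(study_low$truth$junction_reads, !is_dup)) /
    (2 * sum(study_low$truth$libraries$n_pairs_emitted))
  expect_lt(frac, 0.01)
})

test_that("truth set TSV round trip is lossless", {
  study <- small_study()
  tmp <- withr::local_tempdir()
  write_truth(study$truth, tmp)
  back <- read_truth(tmp)
  for (tab in c("circs", "design", "junction_reads", "duplicates",
                "libraries")) {
    expect_equal(as.data.frame(back[[tab]]),
                 as.data.frame(study$truth[[tab]]))
  }

  # empty catalog still writes a header-only table
  empty <- new_truth_set(study$circs[0, ], study$design)
  d2 <- withr::local_tempdir()
  write_truth(empty, d2)
  expect_equal(nrow(readr::read_tsv(file.path(d2, "circs.tsv"),
                                    show_col_types = FALSE)), 0)
})

test_that("simulation config validates rates and survives file round trip", {
  expect_error(sim_config(error_rate = 1.5), "rates")
  expect_error(sim_config(age_effect = list(fraction_up = 0.1, fold_up = 0.5,
                                            fraction_down = 0,
                                            fold_down = 1)), "folds")
  cfg <- small_cfg()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, tmp)
  back <- read_sim_config(tmp)
  expect_equal(unclass(back), unclass(cfg))
  back2 <- read_sim_config(tmp, seed = 7)
  expect_equal(back2$seed, 7L)
})
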