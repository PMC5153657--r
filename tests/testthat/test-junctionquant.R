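test_that("scaffolds concatenate genomic flanks around the junction", {
  study <- small_study()
  bundle <- study$bundle
  g <- bundle$seqs[["chr1"]]
  circs <- tibble(circ_id = c("wide", "short"), chrom = "chr1",
                  start = c(1000L, 5000L), end = c(2000L, 5150L),
                  strand = "+", source = "known")
  scaf <- build_scaffolds(circs, bundle, flank = 100)
  expect_identical(scaf$seq[1], paste0(substr(g, 1901, 2000),
                                       substr(g, 1001, 1100)))
  expect_equal(scaf$offset[1], 100L)
  expect_equal(nchar(scaf$seq[1]), 200)
  expect_false(scaf$short_overlap[1])
  # span 150 < 2*flank: still 200 nt with overlapping content, flagged
  expect_equal(nchar(scaf$seq[2]), 200)
  expect_true(scaf$short_overlap[2])

  # minus-strand scaffold is the reverse complement of the plus layout
  circm <- tibble(circ_id = "m", chrom = "chr1", start = 1000L,
                  end = 2000L, strand = "-", source = "known")
  scafm <- build_scaffolds(circm, bundle, flank = 100)
  expect_identical(scafm$seq, revcomp(scaf$seq[1]))

  expect_error(build_scaffolds(mutate(circs, end = start), bundle),
               "span")
})

test_that("identical known and de novo junctions merge to one scaffold", {
  known <- tibble(chrom = "chr1", start = 100L, end = 900L, strand = "+",
                  name = "known_1")
  denovo <- tibble(chrom = c("chr1", "chr1"), start = c(100L, 2000L),
                   end = c(900L, 2800L), strand = "+",
                   name = c("novel_1", "novel_2"))
  merged <- merge_annotations(known, denovo)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$source[merged$start == 100], "both")
  expect_equal(merged$circ_id[merged$start == 100], "known_1")
  expect_equal(merged$source[merged$start == 2000], "de novo")
})

test_that("scaffold alignment enforces score threshold, junction overhang and ambiguity rules", {
  set.seed(11)
  scaffolds <- tibble(circ_id = c("cA", "cB"),
                      seq = vapply(1:2, function(i) random_dna_str(200),
                                   character(1)),
                      offset = 100L)
  mate <- substr(scaffolds$seq[1], 31, 155)   # 125 nt copy, start 30
  aln <- align_to_scaffolds(tibble(read_id = "m/1", seq = mate), scaffolds)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 30L)
  expect_equal(aln$mm, 0L)
  expect_equal(aln$score, 0)

  # reverse-complement mate aligns with strand "-" at the same start
  aln_rc <- align_to_scaffolds(tibble(read_id = "m/2", seq = revcomp(mate)),
                               scaffolds)
  expect_equal(aln_rc$start, 30L)
  expect_equal(aln_rc$strand, "-")

  # 3 substitutions: penalty 18 exceeds the -15 threshold
  m3 <- mate
  for (p in c(10, 60, 110)) {
    substr(m3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(m3, p, p))[1]
  }
  expect_equal(nrow(align_to_scaffolds(tibble(read_id = "x", seq = m3),
                                       scaffolds)), 0)
  # 2 substitutions: penalty 12, kept
  m2 <- mate
  for (p in c(10, 60)) {
    substr(m2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(m2, p, p))[1]
  }
  aln2 <- align_to_scaffolds(tibble(read_id = "y", seq = m2), scaffolds)
  expect_equal(aln2$mm, 2L)

  # placement not covering the junction offset is rejected
  edge <- substr(scaffolds$seq[1], 1, 125)    # overhang 25/100: kept
  expect_equal(nrow(align_to_scaffolds(tibble(read_id = "e", seq = edge),
                                       scaffolds, min_overhang = 10L)), 1)
  expect_equal(nrow(align_to_scaffolds(tibble(read_id = "e", seq = edge),
                                       scaffolds, min_overhang = 30L)), 0)

  # a mate matching two scaffolds equally is discarded as ambiguous
  twin <- scaffolds
  twin$seq[2] <- twin$seq[1]
  expect_equal(nrow(align_to_scaffolds(tibble(read_id = "a", seq = mate),
                                       twin)), 0)
})

test_that("dedupe collapses identical-start alignments and is idempotent", {
  aln <- tibble(library_id = "L1",
                read_id = c("f1/1", "f1dup/1", "f2/1", "f3/1"),
                circ_id = "cA", start = c(30L, 30L, 30L, 31L),
                strand = c("+", "+", "-", "+"),
                mm = 0L, score = c(0, 0, 0, 0))
  d1 <- dedupe(aln)
  expect_equal(nrow(d1), 3)              # (30,+), (30,-), (31,+)
  expect_true("f1/1" %in% d1$read_id)    # lexicographically smallest kept
  expect_false("f1dup/1" %in% d1$read_id)
  expect_identical(dedupe(d1), d1)
})

test_that("counting excludes chimeric fragments and records library totals", {
  scaffolds <- tibble(circ_id = c("cA", "cB"), seq = "", offset = 100L)
  design <- tibble(library_id = "L1", tissue = "cortex", age = "young",
                   replicate = 1L)
  aln <- tibble(library_id = "L1",
                read_id = c(paste0("f", 1:6, "/1"), "g1/1", "g1/2"),
                circ_id = c(rep("cA", 6), "cA", "cB"),
                start = c(1:6, 7L, 8L) + 20L, strand = "+", mm = 0L,
                score = 0)
  mat <- suppressWarnings(
    count_junctions(aln, scaffolds, design, c(L1 = 1000L)))
  counts <- tidyr::pivot_wider(mat$counts, names_from = circ_id,
                               values_from = count)
  expect_equal(counts$cA, 6L)   # chimeric fragment g1 contributes nothing
  expect_equal(counts$cB, 0L)
  expect_equal(mat$lib_totals$N, 1006L)
  expect_true(mat$lib_totals$N >= sum(mat$counts$count))
})

test_that("quantification equals truth counts exactly on error-free data", {
  study <- small_study()
  scaf <- build_scaffolds(study$circs %>% mutate(source = "known"),
                          study$bundle)
  quant <- quantify_junctions(
    study$reads, scaf, study$design,
    setNames(rep(3000L, nrow(study$design)), study$design$library_id))
  tc <- truth_counts(study$truth, overhang = 25L, unit = "dedup_starts")
  cmp <- quant$matrix$counts %>%
    inner_join(tc, by = c("circ_id", "library_id"))
  expect_equal(nrow(cmp), nrow(quant$matrix$counts))
  expect_identical(cmp$count, cmp$true_count)
})

test_that("stricter score thresholds never increase counts", {
  study <- fixture("noisy_study", function() {
    simulate_study(small_cfg(seed = 55, error_rate = 0.01))
  })
  scaf <- build_scaffolds(study$circs %>% mutate(source = "known"),
                          study$bundle)
  n_lin <- setNames(rep(3000L, nrow(study$design)),
                    study$design$library_id)
  loose <- quantify_junctions(study$reads, scaf, study$design, n_lin,
                              score_threshold = -15)
  strict <- quantify_junctions(study$reads, scaf, study$design, n_lin,
                               score_threshold = -6)
  joined <- loose$matrix$counts %>%
    inner_join(strict$matrix$counts, by = c("circ_id", "library_id"),
               suffix = c("_loose", "_strict"))
  expect_true(all(joined$count_strict <= joined$count_loose))
})

test_that("expression filter applies the tissue-sum rule at the boundary", {
  design <- tidyr::crossing(tissue = c("cortex", "heart"),
                            age = c("young", "old"),
                            replicate = 1:3) %>%
    mutate(library_id = paste(tissue, age, replicate, sep = "_"))
  mk <- function(cortex_counts) {
    counts <- tidyr::crossing(circ_id = "c1",
                              library_id = design$library_id) %>%
      left_join(tibble(library_id =
                         design$library_id[design$tissue == "cortex"],
                       count = cortex_counts),
                by = "library_id") %>%
      mutate(count = as.integer(tidyr::replace_na(count, 0L)))
    structure(list(counts = counts,
                   lib_totals = tibble(library_id = design$library_id,
                                       n_linear = 1000L, n_junction = 0L,
                                       N = 1000L),
                   design = design),
              class = "junction_count_matrix")
  }
  m_of <- function(cc) {
    expression_filter(mk(cc))$membership %>%
      filter(tissue == "cortex") %>% pull(retained)
  }
  expect_true(m_of(c(1, 1, 1, 1, 1, 1)))     # sum 6: retained
  expect_false(m_of(c(5, 0, 0, 0, 0, 0)))    # sum 5: dropped
  expect_true(m_of(c(0, 0, 0, 6, 0, 0)))     # sum 6 in one library: retained
  expect_true(m_of(c(7, 0, 0, 0, 0, 0)))

  # strict mode rejects tissues without exactly 6 libraries
  bad <- mk(rep(1, 6))
  bad$design <- bad$design[-1, ]
  bad$counts <- bad$counts %>%
    filter(library_id %in% bad$design$library_id)
  expect_error(expression_filter(bad), "exactly 6")
  prop <- expression_filter(bad, strict = FALSE)
  expect_equal(nrow(prop$membership), 2)
})

test_that("multigene filter flags duplicated-gene junctions and keeps the rest", {
  study <- small_study()
  bundle <- add_duplicated_gene(study$bundle, gene_id = "gene001")
  gA <- bundle$exons %>% filter(gene_id == "gene001") %>%
    arrange(start)
  gB <- bundle$exons %>% filter(gene_id == "gene001_dup") %>%
    arrange(start)
  circs <- tibble(
    circ_id = c("multi", "single", "inter"),
    chrom = gA$chrom[1],
    start = c(gA$start[1], gA$start[1], 10L),
    end = c(gB$end[1], gA$end[nrow(gA)], 60L),
    strand = "+", source = "known")
  res <- multigene_filter(circs, bundle)
  expect_equal(res$removed$circ_id, "multi")
  expect_setequal(res$kept$circ_id, c("single", "inter"))
  expect_equal(res$kept$host_gene[res$kept$circ_id == "single"], "gene001")
  expect_equal(res$kept$host_gene[res$kept$circ_id == "inter"],
               "intergenic")
})
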