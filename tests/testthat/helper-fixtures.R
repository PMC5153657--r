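suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
  library(purrr)
})

# fixtures are generated once per test run and shared across files
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, create) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, create(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_cfg <- function(seed = 42, error_rate = 0, ...) {
  sim_config(seed = seed, n_chromosomes = 1, chrom_length = 400000L,
             n_genes = 25L, n_circ_genes = 8L, n_multi_circ_genes = 2L,
             frags_per_library = 1500L, circ_fraction_of_reads = 0.01,
             error_rate = error_rate, duplicate_rate = 0.05, ...)
}

small_study <- function() {
  fixture("small_study", function() simulate_study(small_cfg()))
}

# error-free synthetic study at the scale used for the detection /
# quantification oracles (~200k read pairs over 18 libraries, 3 Mb genome,
# 150 genes, 40+ circles), shared by the acceptance tests
oracle_cfg <- function() sim_config(seed = 2024, error_rate = 0)

oracle_study <- function() {
  fixture("oracle_study", function() simulate_study(oracle_cfg()))
}

oracle_detection <- function() {
  fixture("oracle_detection", function() {
    study <- oracle_study()
    detect_circrnas(study$reads, study$bundle, min_reads = 1L)
  })
}

oracle_quant <- function() {
  fixture("oracle_quant", function() {
    study <- oracle_study()
    det <- oracle_detection()
    known <- study$circs %>%
      transmute(chrom, start, end, strand, name = circ_id)
    ann <- multigene_filter(merge_annotations(known, det$junctions),
                            study$bundle)$kept
    scaf <- build_scaffolds(ann, study$bundle)
    quantify_junctions(
      study$reads, scaf, study$design,
      setNames(det$lib_stats$n_linear, det$lib_stats$library_id))
  })
}

# Deeper single-tissue study with a uniform 2-fold circRNA age effect and
# untouched linear hosts: the regime for the expression-level oracles
# (filter retention, independence), where per-circle junction counts reach
# the tens per library.
indep_cfg <- function() {
  sim_config(
    seed = 606, n_chromosomes = 1, chrom_length = 600000L, n_genes = 30L,
    n_circ_genes = 20L, n_multi_circ_genes = 0L, tissues = "cortex",
    affected_tissues = "cortex", frags_per_library = 12000L,
    circ_fraction_of_reads = 0.06,
    base_abundance = list(meanlog = 0, sdlog = 0.3),
    age_effect = list(fraction_up = 1, fold_up = 2, fraction_down = 0,
                      fold_down = 1),
    error_rate = 0, duplicate_rate = 0.05)
}

indep_study <- function() {
  fixture("indep_study", function() simulate_study(indep_cfg()))
}

# Hand-built single-gene genome: exon A = [200, 300), exon B = [400, 500),
# splice signals planted for the requested strand, back-splice junction
# context therefore known exactly.
toy_junction_genome <- function(strand = "+") {
  set.seed(99)
  g <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
             collapse = "")
  set_sub <- function(g, start0, value) {  # 0-based half-open patch
    substr(g, start0 + 1, start0 + nchar(value)) <- value
    g
  }
  if (strand == "+") {
    g <- set_sub(g, 300, "GT");  g <- set_sub(g, 398, "AG")  # intron A..B
    g <- set_sub(g, 500, "GT");  g <- set_sub(g, 198, "AG")  # circle flanks
  } else {
    g <- set_sub(g, 300, "CT");  g <- set_sub(g, 398, "AC")
    g <- set_sub(g, 500, "CT");  g <- set_sub(g, 198, "AC")
  }
  rank <- if (strand == "+") 1:2 else 2:1
  structure(list(
    seqs = c(chr1 = g),
    genes = tibble(gene_id = "geneA", chrom = "chr1", strand = strand,
                   start = 200L, end = 500L),
    transcripts = tibble(transcript_id = "txA", gene_id = "geneA",
                         chrom = "chr1", strand = strand, n_exons = 2L,
                         tx_len = 200L, cds_tstart = 30L, cds_tend = 170L),
    exons = tibble(gene_id = "geneA", transcript_id = "txA", chrom = "chr1",
                   strand = strand, exon_rank = rank,
                   start = c(200L, 400L), end = c(300L, 500L))),
    class = "genome_bundle")
}

subseq0_chr <- function(g, start, end) substr(g, start + 1, end)

# junction read crossing the back-splice of the toy genome: last `d` nt of
# exon B followed by first `a` nt of exon A (plus-strand transcript
# orientation)
toy_junction_read <- function(bundle, d = 60, a = 60) {
  g <- bundle$seqs[["chr1"]]
  paste0(subseq0_chr(g, 500 - d, 500), subseq0_chr(g, 200, 200 + a))
}

# Brute-force breakpoint oracle for error-free reads: for every split
# position, enumerate exact genomic matches of prefix and suffix and check
# out-of-order placement plus splice signals. Independent of the package's
# anchor/extension machinery.
brute_breakpoint <- function(read, g, k = 20) {
  fw <- brute_breakpoint_oriented(read, g, k)
  rc <- brute_breakpoint_oriented(revcomp(read), g, k)
  both <- bind_rows(fw, rc)
  if (nrow(both) == 0) return(NULL)
  distinct(both, start, end, strand)
}

brute_breakpoint_oriented <- function(read, g, k = 20) {
  L <- nchar(read)
  find_all <- function(pat) {
    hits <- integer(0); from <- 1
    repeat {
      p <- regexpr(pat, substr(g, from, nchar(g)), fixed = TRUE)
      if (p < 0) break
      hits <- c(hits, from + p - 1); from <- from + p
    }
    hits - 1  # 0-based
  }
  out <- list()
  for (s in k:(L - k)) {
    pre <- substr(read, 1, s); suf <- substr(read, s + 1, L)
    for (p1 in find_all(pre)) {
      e <- p1 + s
      for (p2 in find_all(suf)) {
        a <- p2
        if (a >= e) next   # must be out-of-order
        don <- substr(g, e + 1, e + 2); acc <- substr(g, a - 1, a)
        strand <- if (don == "GT" && acc == "AG") "+"
                  else if (don == "CT" && acc == "AC") "-" else NA
        if (is.na(strand)) next
        out[[length(out) + 1]] <- tibble(start = a, end = e,
                                         strand = strand, split = s)
      }
    }
  }
  if (!length(out)) return(NULL)
  distinct(list_rbind(out), start, end, strand)
}

# Brute-force seed-site oracle: check every substring against the three
# canonical site definitions directly.
brute_seed_sites <- function(target, seed) {
  t_rna <- chartr("Tt", "Uu", toupper(target))
  rc <- function(x) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(x, NULL)[[1]]), collapse = ""))
  }
  m8 <- rc(seed)                       # 7 nt
  a1core <- rc(substr(seed, 1, 6))     # 6 nt
  n <- nchar(t_rna)
  if (n < 7) {
    return(tibble(site_type = character(0), position = integer(0),
                  length = integer(0)))
  }
  p <- seq_len(n - 6)
  w7 <- substring(t_rna, p, p + 6)
  a8 <- substring(t_rna, p + 7, p + 7)
  a7 <- substring(t_rna, p + 6, p + 6)
  prev7 <- substring(t_rna, p - 1, p + 5)    # empty string when p == 1
  is8 <- w7 == m8 & a8 == "A"
  is7m8 <- w7 == m8 & !is8
  isA1 <- substring(w7, 1, 6) == a1core & a7 == "A" & w7 != m8 & prev7 != m8
  out <- bind_rows(
    tibble(site_type = "8mer", position = p[is8], length = 8L),
    tibble(site_type = "7mer-m8", position = p[is7m8], length = 7L),
    tibble(site_type = "7mer-A1", position = p[isA1], length = 7L))
  out %>% arrange(position, site_type)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
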