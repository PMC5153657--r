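mk_matrix <- function(counts_by_lib, N = 1e6, tissue = "cortex") {
  design <- tibble(library_id = names(counts_by_lib), tissue = tissue,
                   age = rep(c("young", "old"),
                             each = length(counts_by_lib) / 2),
                   replicate = rep(seq_len(length(counts_by_lib) / 2), 2))
  counts <- purrr::imap(counts_by_lib, function(v, lib) {
    tibble(circ_id = sprintf("c%03d", seq_along(v)), library_id = lib,
           count = as.integer(v))
  }) %>% list_rbind()
  structure(list(counts = counts,
                 lib_totals = tibble(library_id = names(counts_by_lib),
                                     n_linear = as.integer(N),
                                     n_junction = 0L, N = N),
                 design = design),
            class = "junction_count_matrix")
}

test_that("TPM scaling is linear, depth-invariant and errors on empty libraries", {
  m <- mk_matrix(list(L1 = c(5, 10), L2 = c(5, 10), L3 = c(5, 10),
                      L4 = c(5, 10), L5 = c(5, 10), L6 = c(5, 10)))
  tpm <- circ_tpm(m)
  expect_equal(tpm$values$value[tpm$values$feature_id == "c001" &
                                  tpm$values$library_id == "L1"], 5)
  v <- tpm$values %>% filter(library_id == "L1") %>% arrange(feature_id)
  expect_equal(v$value[2] / v$value[1], 2)   # ratios equal count ratios

  m2 <- m
  m2$counts$count <- m2$counts$count * 2L
  m2$lib_totals$N <- m2$lib_totals$N * 2
  expect_equal(circ_tpm(m2)$values$value, tpm$values$value)

  m$lib_totals$N[1] <- 0
  expect_error(circ_tpm(m), "zero total")
})

test_that("FPKM follows the exon-union formula and assigns pairs uniquely", {
  study <- small_study()
  bundle <- study$bundle
  union <- circaging:::gene_exon_union(bundle)
  g1 <- union$gene_id[1]; len1 <- union$union_len[1]
  tx1 <- bundle$transcripts$transcript_id[bundle$transcripts$gene_id == g1]
  tx2g <- bundle$transcripts %>%
    filter(gene_id != g1) %>% slice(1)
  hits <- bind_rows(
    purrr::map(1:10, ~tibble(
      read_id = c(sprintf("f%02d/1", .x), sprintf("f%02d/2", .x)),
      target = paste0("tx|", tx1), pos = 0L, strand = "+", mm = 0L)),
    # unpaired mate: not assigned
    list(tibble(read_id = "half/1", target = paste0("tx|", tx1),
                pos = 0L, strand = "+", mm = 0L)),
    # discordant pair across genes: not assigned
    list(tibble(read_id = c("x/1", "x/2"),
                target = paste0("tx|", c(tx1, tx2g$transcript_id)),
                pos = 0L, strand = "+", mm = 0L)))
  design <- tibble(library_id = "L1", tissue = "cortex", age = "young",
                   replicate = 1L)
  fpkm <- gene_fpkm(list(L1 = hits), bundle, design)
  v1 <- fpkm$values$value[fpkm$values$feature_id == g1]
  expect_equal(v1, 10 * 1e9 / (len1 * 10))
  expect_equal(sum(fpkm$values$value > 0), 1)   # all other genes zero
})

test_that("differential testing reproduces fold changes, flags and corrections", {
  m <- mk_matrix(list(L1 = c(2, 4, 1), L2 = c(2, 4, 1), L3 = c(2, 4, 1),
                      L4 = c(3, 4, 5), L5 = c(3, 4, 5), L6 = c(3, 4, 5)))
  tpm <- circ_tpm(m)
  de <- differential(tpm, "cortex", pseudocount = 0)
  de1 <- de %>% filter(feature_id == "c001")
  expect_equal(de1$fold_change, 1.5)
  expect_true(de1$zero_var_flag)
  expect_equal(de1$p_value, 0)            # constant groups, unequal means
  de2 <- de %>% filter(feature_id == "c002")
  expect_equal(de2$fold_change, 1)
  expect_equal(de2$p_value, 1)            # identical constant groups
  expect_equal(de2$status, "unchanged")
  de3 <- de %>% filter(feature_id == "c003")
  expect_equal(de3$fold_change, 5)
  expect_equal(de3$status, "up")          # FC 5, p = 0 (flagged constant)

  # noisy case: Welch p matches stats::t.test on the same values
  set.seed(4)
  vals <- list(L1 = rpois(50, 20), L2 = rpois(50, 20), L3 = rpois(50, 20),
               L4 = rpois(50, 28), L5 = rpois(50, 28), L6 = rpois(50, 28))
  tpm2 <- circ_tpm(mk_matrix(vals))
  de_n <- differential(tpm2, "cortex")
  i <- which(!de_n$zero_var_flag)[1]
  young <- sapply(vals[1:3], `[`, i); old <- sapply(vals[4:6], `[`, i)
  expect_equal(de_n$p_value[i], t.test(old, young)$p.value)

  expect_error(differential(tpm, "liver"), "no libraries")
  glance_tbl <- glance(de)
  expect_equal(glance_tbl$n_features, 3L)
  expect_s3_class(tidy(de), "tbl_df")
})

test_that("status boundaries use the inclusive 1.5-fold cutoff", {
  set.seed(7)
  # strong significance, fold exactly 1.5 vs just below
  m <- mk_matrix(list(L1 = c(100, 100), L2 = c(100, 100), L3 = c(100, 100),
                      L4 = c(150, 149), L5 = c(150, 149), L6 = c(150, 149)))
  de <- differential(circ_tpm(m), "cortex", pseudocount = 0)
  expect_equal(de$status[de$feature_id == "c001"], "up")
  expect_equal(de$status[de$feature_id == "c002"], "unchanged")
})

test_that("global shift matches brute-force enumeration and wilcox.test", {
  enumerate_p <- function(x, y) {
    # exact two-sided p by full enumeration of group assignments
    n1 <- length(x); vals <- c(x, y)
    U_obs <- sum(rank(vals)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- combn(length(vals), n1)
    Us <- apply(combos, 2, function(idx) {
      sum(rank(vals)[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * (length(vals) - n1) / 2
    mean(abs(Us - mu) >= abs(U_obs - mu))
  }
  mk_expr <- function(x, y) {
    circaging:::new_expression_table(
      tibble(feature_id = "f",
             library_id = paste0("l", seq_len(length(x) + length(y))),
             value = c(x, y)),
      tibble(library_id = paste0("l", seq_len(length(x) + length(y))),
             tissue = "t", age = rep(c("old", "young"),
                                     c(length(x), length(y))),
             replicate = 1L), "TPM")
  }
  set.seed(21)
  for (rep in 1:60) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    gs <- global_shift(mk_expr(x, y), "t")
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(gs$U, unname(w$statistic))
    expect_equal(gs$p_value, w$p.value, tolerance = 1e-12)
    expect_equal(gs$p_value, enumerate_p(x, y), tolerance = 1e-12)
  }

  # complete separation at 5 vs 5: maximal U, exact p = 2 / choose(10, 5)
  gs_sep <- global_shift(mk_expr(6:10, 1:5), "t")
  expect_equal(gs_sep$U, 25)
  expect_equal(gs_sep$p_value, 2 / choose(10, 5))

  # large tied samples take the continuity-corrected normal path and agree
  # with stats::wilcox.test
  set.seed(22)
  x <- rpois(400, 12); y <- rpois(400, 11)
  gs_big <- global_shift(mk_expr(x, y), "t")
  expect_false(gs_big$exact)
  w_big <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(gs_big$p_value, w_big$p.value, tolerance = 1e-10)
  expect_error(global_shift(mk_expr(numeric(0), y), "t"), "empty")
})

test_that("independence analysis reports log2 FC pairs and ratio invariance", {
  mk_de <- function(ids, fc, status) {
    structure(tibble(feature_id = ids, mean_young = 1, mean_old = fc,
                     fold_change = fc, log2_fc = log2(fc), p_value = 0.01,
                     p_adj = 0.01, status = status, zero_var_flag = FALSE),
              class = c("circ_de", "tbl_df", "tbl", "data.frame"),
              tissue = "cortex")
  }
  circ_de <- mk_de(c("c1", "c2"), c(2, 1), c("up", "unchanged"))
  lin_de <- mk_de(c("g1", "g2"), c(1, 1), c("unchanged", "unchanged"))
  host <- tibble(circ_id = c("c1", "c2"), gene_id = c("g1", "intergenic"))
  ind <- circ_linear_independence(circ_de, lin_de, host)
  expect_equal(ind$n_intergenic, 1)
  expect_equal(nrow(ind$density), 1)
  expect_equal(ind$density$log2_fc_linear, 0)   # circ FC 2, host FC 1
  expect_equal(ind$density$log2_fc_circ, 1)
  expect_equal(ind$overlap_fraction, 0)

  # ratio r is invariant when circ and host double together
  libs <- paste0("l", 1:6)
  design <- tibble(library_id = libs, tissue = "cortex",
                   age = rep(c("young", "old"), each = 3),
                   replicate = rep(1:3, 2))
  ce <- circaging:::new_expression_table(
    tibble(feature_id = "c1", library_id = libs,
           value = c(10, 10, 10, 20, 20, 20)), design, "TPM")
  le <- circaging:::new_expression_table(
    tibble(feature_id = "g1", library_id = libs,
           value = c(5, 5, 5, 10, 10, 10)), design, "FPKM")
  ind2 <- circ_linear_independence(mk_de("c1", 2, "up"),
                                   mk_de("g1", 2, "up"),
                                   tibble(circ_id = "c1", gene_id = "g1"),
                                   circ_expr = ce, linear_expr = le,
                                   tissue = "cortex", eps = 0)
  expect_equal(ind2$ratio_tests$p_value, 1)
})

test_that("PCA separates duplicated groups and preserves variance identities", {
  libs <- paste0("l", 1:6)
  design <- tibble(library_id = libs, tissue = rep(c("A", "B"), each = 3),
                   age = "young", replicate = rep(1:3, 2))
  base_a <- rpois(40, 20); base_b <- rpois(40, 5)
  vals <- purrr::imap(setNames(libs, libs), function(lib, nm) {
    v <- if (substr(nm, 2, 2) %in% c("1", "2", "3")) base_a else base_b
    tibble(feature_id = sprintf("f%02d", seq_along(v)), library_id = lib,
           value = v)
  }) %>% list_rbind()
  expr <- circaging:::new_expression_table(vals, design, "TPM")
  pca <- pca_expression(expr)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-9)
  s <- pca$scores
  expect_true(all(sign(s$PC1[s$tissue == "A"]) !=
                    sign(s$PC1[s$tissue == "B"])))
  expect_equal(pca$variance_fraction[2], 0, tolerance = 1e-9)

  # full reconstruction: scores %*% t(loadings) + center == log10(x + 1)
  wide <- tidyr::pivot_wider(vals, names_from = library_id,
                             values_from = value)
  m <- log10(t(as.matrix(wide[, -1])) + 1)
  rec <- as.matrix(s[, grep("^PC", names(s))]) %*% t(pca$loadings)
  rec <- sweep(rec, 2, pca$center, "+")
  expect_equal(unname(rec), unname(m), tolerance = 1e-9)

  # constant matrix: defined output with zero scores and zero fractions
  const <- circaging:::new_expression_table(
    vals %>% mutate(value = 3), design, "TPM")
  pc0 <- pca_expression(const)
  expect_true(all(abs(pc0$scores$PC1) < 1e-12))
  expect_true(all(pc0$variance_fraction == 0))
})
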