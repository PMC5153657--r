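new_expression_table <- function(values, design, kind, lib_totals = NULL) {
  structure(list(values = values, design = design, kind = kind,
                 lib_totals = lib_totals),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table:%s> %d features x %d libraries\n", x$kind,
              n_distinct(x$values$feature_id),
              n_distinct(x$values$library_id)))
  invisible(x)
}

#' circRNA TPM normalization
#'
#' Scales deduplicated junction counts by circRNA transcripts-per-million of
#' library reads: `TPM(i, lib) = count * 1e6 / N(lib)`, with `N` the
#' per-library total of linearly aligned plus junction reads after
#' duplicate removal (a depth-invariant denominator).
#'
#' @param mat A `junction_count_matrix`.
#' @return An `expression_table` (kind `"TPM"`).
#' @export
circ_tpm <- function(mat) {
  if (any(mat$lib_totals$N <= 0)) {
    abort("circ_tpm: library with zero total reads")
  }
  values <- mat$counts %>%
    left_join(mat$lib_totals %>% select("library_id", "N"),
              by = "library_id") %>%
    transmute(feature_id = .data$circ_id, library_id = .data$library_id,
              value = .data$count * 1e6 / .data$N)
  new_expression_table(values, mat$design, "TPM", mat$lib_totals)
}

#' Simplified linear gene FPKM
#'
#' Exon-union FPKM from unique fragment assignment: a fragment is assigned
#' to a gene when both mates align end-to-end within the gene's spliced
#' transcripts; `FPKM = assigned * 1e9 / (union_len * total_assigned)`.
#' This is a deliberately simple exon-union quantifier, not an isoform
#' deconvolution engine.
#'
#' @param linear_hits Named list (library id -> best-placement tibble from
#'   [linear_filter()]/[detect_circrnas()]).
#' @param bundle A `genome_bundle`.
#' @param design Design tibble.
#' @return An `expression_table` (kind `"FPKM"`).
#' @export
gene_fpkm <- function(linear_hits, bundle, design) {
  union_len <- gene_exon_union(bundle)
  if (any(union_len$union_len <= 0)) abort("gene with zero exon length")
  tx2gene <- bundle$transcripts %>% select("transcript_id", "gene_id")
  assigned <- purrr::imap(linear_hits, function(hits, lib) {
    tx_hits <- hits %>%
      filter(stringr::str_detect(.data$target, "^tx\\|")) %>%
      mutate(transcript_id = sub("^tx\\|", "", .data$target),
             fragment = sub("/[12]$", "", .data$read_id),
             mate = sub("^.*/", "", .data$read_id)) %>%
      left_join(tx2gene, by = "transcript_id")
    tx_hits %>%
      distinct(.data$fragment, .data$mate, .data$gene_id) %>%
      group_by(.data$fragment) %>%
      filter(n_distinct(.data$mate) == 2,
             n_distinct(.data$gene_id) == 1) %>%
      ungroup() %>%
      distinct(.data$fragment, .data$gene_id) %>%
      count(.data$gene_id, name = "n_frags") %>%
      mutate(library_id = lib)
  }) %>% list_rbind()
  totals <- assigned %>%
    group_by(.data$library_id) %>%
    summarise(total = sum(.data$n_frags), .groups = "drop")
  values <- tidyr::crossing(gene_id = bundle$genes$gene_id,
                            library_id = design$library_id) %>%
    left_join(assigned, by = c("gene_id", "library_id")) %>%
    mutate(n_frags = tidyr::replace_na(.data$n_frags, 0L)) %>%
    left_join(totals, by = "library_id") %>%
    left_join(union_len, by = "gene_id") %>%
    transmute(feature_id = .data$gene_id, library_id = .data$library_id,
              value = .data$n_frags * 1e9 /
                (.data$union_len * pmax(.data$total, 1)))
  new_expression_table(values, design, "FPKM",
                       totals %>% rename(N = "total"))
}

welch_p <- function(young, old) {
  if (var(young) == 0 && var(old) == 0) {
    return(list(p = if (mean(young) == mean(old)) 1 else 0, flag = TRUE))
  }
  list(p = tryCatch(t.test(old, young)$p.value,
                    error = function(e) NA_real_), flag = FALSE)
}

#' Old-versus-young differential expression within a tissue
#'
#' Per feature: fold change `(mean(old) + eps) / (mean(young) + eps)` with a
#' pseudocount `eps` equivalent to half a read at the mean library depth,
#' and a two-sided Welch t-test on the normalized values. `correct = "none"`
#' reproduces the uncorrected circRNA analysis; `correct = "BH"` applies
#' Benjamini-Hochberg and uses adjusted p for status calls (the linear-RNA
#' convention). A feature is `up` when `fold_change >= fc_cutoff` and
#' significant, `down` when `1 / fold_change >= fc_cutoff` and significant.
#'
#' @param expr An `expression_table`.
#' @param tissue Tissue to test.
#' @param fc_cutoff Fold-change cutoff (default 1.5, boundary inclusive).
#' @param alpha Significance level (default 0.05).
#' @param correct `"none"` or `"BH"`.
#' @param ages Length-2 character vector `c(young, old)`.
#' @param pseudocount Pseudocount on group means; default is the
#'   normalized-value equivalent of 0.5 reads when library totals are
#'   known, else 0.5.
#' @param log_values Test `log2(value + 1)` instead of raw values.
#' @return A `circ_de` tibble: `feature_id`, `mean_young`, `mean_old`,
#'   `fold_change`, `log2_fc`, `p_value`, `p_adj`, `status`,
#'   `zero_var_flag`; parameters in attributes.
#' @export
differential <- function(expr, tissue, fc_cutoff = 1.5, alpha = 0.05,
                         correct = c("none", "BH"),
                         ages = c("young", "old"), pseudocount = NULL,
                         log_values = FALSE) {
  correct <- match.arg(correct)
  des <- expr$design %>% filter(.data$tissue == !!tissue)
  if (nrow(des) == 0) abort(sprintf("no libraries for tissue '%s'", tissue))
  young_libs <- des$library_id[des$age == ages[1]]
  old_libs <- des$library_id[des$age == ages[2]]
  if (length(young_libs) < 2 || length(old_libs) < 2) {
    abort("differential: need >= 2 replicates per age group")
  }
  if (is.null(pseudocount)) {
    pseudocount <- if (!is.null(expr$lib_totals)) {
      0.5 * 1e6 / mean(expr$lib_totals$N)
    } else 0.5
  }
  wide <- expr$values %>%
    filter(.data$library_id %in% c(young_libs, old_libs)) %>%
    tidyr::pivot_wider(names_from = "library_id", values_from = "value")
  ym <- as.matrix(wide[, young_libs, drop = FALSE])
  om <- as.matrix(wide[, old_libs, drop = FALSE])
  if (log_values) { ym_t <- log2(ym + 1); om_t <- log2(om + 1) }
  else { ym_t <- ym; om_t <- om }
  tests <- purrr::map(seq_len(nrow(wide)),
                      ~welch_p(ym_t[.x, ], om_t[.x, ]))
  res <- tibble(
    feature_id = wide$feature_id,
    mean_young = rowMeans(ym), mean_old = rowMeans(om),
    fold_change = (rowMeans(om) + pseudocount) /
      (rowMeans(ym) + pseudocount),
    p_value = purrr::map_dbl(tests, "p"),
    zero_var_flag = purrr::map_lgl(tests, "flag")) %>%
    mutate(log2_fc = log2(.data$fold_change),
           p_adj = if (correct == "BH") p.adjust(.data$p_value, "BH")
                   else .data$p_value,
           sig = !is.na(.data$p_adj) & .data$p_adj < alpha,
           status = case_when(
             .data$sig & .data$fold_change >= fc_cutoff ~ "up",
             .data$sig & 1 / .data$fold_change >= fc_cutoff ~ "down",
             TRUE ~ "unchanged")) %>%
    select("feature_id", "mean_young", "mean_old", "fold_change",
           "log2_fc", "p_value", "p_adj", "status", "zero_var_flag")
  structure(res, class = c("circ_de", class(res)),
            tissue = tissue, fc_cutoff = fc_cutoff, alpha = alpha,
            correct = correct, pseudocount = pseudocount,
            log_values = log_values)
}

#' Global old-versus-young distribution shift test
#'
#' Mann-Whitney / Wilcoxon rank-sum test with normal approximation and
#' continuity correction, comparing all pooled old-library values against
#' all pooled young-library values of a tissue. Reports the U statistic,
#' the tie-corrected z, and the two-sided P.
#'
#' For small untied groups (both sizes <= 50, no ties) the exact U
#' distribution is used instead, as is conventional; the pooled
#' whole-transcriptome comparison always falls in the approximation regime.
#'
#' @param expr An `expression_table` (typically TPM restricted to the
#'   tissue's expression-filtered circRNAs).
#' @param tissue Tissue to test.
#' @param ages `c(young, old)` labels.
#' @param exact `"auto"` (default), `TRUE` or `FALSE`.
#' @return A `circ_shift_test` list: `tissue`, `U`, `z`, `p_value`,
#'   `n_old`, `n_young`, `exact`.
#' @export
global_shift <- function(expr, tissue, ages = c("young", "old"),
                         exact = "auto") {
  des <- expr$design %>% filter(.data$tissue == !!tissue)
  vals <- expr$values %>%
    left_join(des %>% select("library_id", "age"), by = "library_id") %>%
    filter(!is.na(.data$age))
  old <- vals$value[vals$age == ages[2]]
  young <- vals$value[vals$age == ages[1]]
  if (!length(old) || !length(young)) {
    abort("global_shift: empty age group")
  }
  n1 <- length(old); n2 <- length(young); n <- n1 + n2
  r <- rank(c(old, young))
  has_ties <- anyDuplicated(c(old, young)) > 0
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  cc <- sign(U - mu) * 0.5
  z <- if (sigma == 0) 0 else (U - mu - cc) / sigma
  use_exact <- if (identical(exact, "auto")) {
    n1 <= 50 && n2 <= 50 && !has_ties
  } else isTRUE(exact)
  p <- if (use_exact) {
    if (U > mu) {
      min(1, 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    } else {
      min(1, 2 * stats::pwilcox(U, n1, n2))
    }
  } else {
    min(1, 2 * pnorm(-abs(z)))
  }
  structure(list(tissue = tissue, U = U, z = z, p_value = p,
                 n_old = n1, n_young = n2, exact = use_exact),
            class = "circ_shift_test")
}

#' @export
print.circ_shift_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum shift test (%s): U = %.0f, z = %.3f, P = %.3g\n",
    x$tissue, x$U, x$z, x$p_value))
  invisible(x)
}

#' Circular-versus-linear host-gene independence analysis
#'
#' Cross-references circRNA and host linear-gene differential results:
#' (a) co-regulation overlap counts (how many age-upregulated circRNAs have
#' concomitantly upregulated host mRNA, etc.); (b) optional per-circle
#' ratio test, Welch t on `circTPM / (hostFPKM + eps)` old vs young; (c) a
#' density-plot table of (log2 linear FC, log2 circ FC) pairs. Intergenic
#' circRNAs are excluded from (b) and (c) and counted separately.
#'
#' @param circ_de `circ_de` for circRNAs (uncorrected).
#' @param linear_de `circ_de` for linear genes (BH-corrected).
#' @param host_map Tibble `circ_id`, `gene_id` (`"intergenic"` allowed).
#' @param circ_expr,linear_expr Optional `expression_table`s; both needed
#'   for the ratio test.
#' @param tissue,ages Group selection for the ratio test.
#' @param eps Pseudocount on the FPKM denominator (default 0.5).
#' @return A `circ_independence` list: `overlap` (tibble of joint
#'   circ/linear status counts), `overlap_fraction` (share of up circRNAs
#'   with up host), `density` (per-circle log2 FC pairs), `ratio_tests`
#'   (or `NULL`), `n_intergenic`.
#' @export
circ_linear_independence <- function(circ_de, linear_de, host_map,
                                     circ_expr = NULL, linear_expr = NULL,
                                     tissue = NULL,
                                     ages = c("young", "old"), eps = 0.5) {
  joined <- circ_de %>%
    as_tibble() %>%
    select(circ_id = "feature_id", circ_status = "status",
           circ_log2_fc = "log2_fc") %>%
    left_join(host_map, by = "circ_id")
  n_intergenic <- sum(joined$gene_id == "intergenic" | is.na(joined$gene_id))
  genic <- joined %>%
    filter(!is.na(.data$gene_id), .data$gene_id != "intergenic") %>%
    left_join(linear_de %>% as_tibble() %>%
                select(gene_id = "feature_id", linear_status = "status",
                       linear_log2_fc = "log2_fc"),
              by = "gene_id")
  overlap <- genic %>%
    count(.data$circ_status, .data$linear_status, name = "n")
  n_up <- sum(genic$circ_status == "up")
  n_coup <- sum(genic$circ_status == "up" &
                  genic$linear_status == "up", na.rm = TRUE)
  density <- genic %>%
    transmute(.data$circ_id, .data$gene_id,
              log2_fc_linear = .data$linear_log2_fc,
              log2_fc_circ = .data$circ_log2_fc)
  ratio_tests <- NULL
  if (!is.null(circ_expr) && !is.null(linear_expr) && !is.null(tissue)) {
    des <- circ_expr$design %>% filter(.data$tissue == !!tissue)
    cvals <- circ_expr$values %>%
      filter(.data$library_id %in% des$library_id) %>%
      rename(circ_id = "feature_id", tpm = "value")
    lvals <- linear_expr$values %>%
      filter(.data$library_id %in% des$library_id) %>%
      rename(gene_id = "feature_id", fpkm = "value")
    ratios <- genic %>%
      select("circ_id", "gene_id") %>%
      inner_join(cvals, by = "circ_id",
                 relationship = "many-to-many") %>%
      inner_join(lvals, by = c("gene_id", "library_id")) %>%
      left_join(des %>% select("library_id", "age"), by = "library_id") %>%
      mutate(r = .data$tpm / (.data$fpkm + eps))
    ratio_tests <- ratios %>%
      group_by(.data$circ_id, .data$gene_id) %>%
      summarise(p_value = welch_p(.data$r[.data$age == ages[1]],
                                  .data$r[.data$age == ages[2]])$p,
                .groups = "drop")
  }
  structure(list(overlap = overlap,
                 overlap_fraction = if (n_up > 0) n_coup / n_up else NA_real_,
                 n_circ_up = n_up, n_co_up = n_coup,
                 density = density, ratio_tests = ratio_tests,
                 n_intergenic = n_intergenic),
            class = "circ_independence")
}

#' @export
print.circ_independence <- function(x, ...) {
  cat(sprintf(
    "<circ_independence> %d up circRNAs, %d with host mRNA co-up (%.1f%%)\n",
    x$n_circ_up, x$n_co_up, 100 * (x$overlap_fraction %||% NA)))
  invisible(x)
}

#' PCA of expression profiles
#'
#' Transforms values to `log10(x + pseudocount)`, centers each feature, and
#' decomposes by SVD (no scaling). Scores are per library.
#'
#' @param expr An `expression_table`.
#' @param pseudocount Added before the log (default 1, avoiding nulls).
#' @return A `circ_pca` list: `scores` (tibble, libraries x PCs joined to
#'   the design), `loadings` (matrix), `variance_fraction` (numeric; sums
#'   to 1 unless the matrix is constant, in which case all fractions and
#'   scores are zero).
#' @export
pca_expression <- function(expr, pseudocount = 1) {
  wide <- expr$values %>%
    tidyr::pivot_wider(names_from = "library_id", values_from = "value")
  m <- log10(as.matrix(wide[, -1]) + pseudocount)
  if (ncol(m) < 2) abort("pca_expression: need >= 2 libraries")
  x <- t(m)                                   # libraries x features
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  vf <- if (tot == 0) rep(0, length(pc$sdev)) else pc$sdev^2 / tot
  scores <- as_tibble(pc$x, .name_repair = "minimal") %>%
    mutate(library_id = rownames(pc$x), .before = 1) %>%
    left_join(expr$design, by = "library_id")
  structure(list(scores = scores, loadings = pc$rotation,
                 variance_fraction = vf, center = pc$center,
                 feature_id = wide$feature_id),
            class = "circ_pca")
}

#' @export
print.circ_pca <- function(x, ...) {
  cat(sprintf("<circ_pca> %d libraries; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), 100 * x$variance_fraction[1],
              100 * (x$variance_fraction[2] %||% 0)))
  invisible(x)
}
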