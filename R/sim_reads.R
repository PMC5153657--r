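# Precomputed per-study sampling state shared by all libraries: mature
# linear transcript sequences, spliced circle sequences, base abundances
# (deterministic substream of the study seed) and the circle weight scale
# calibrated so the expected junction-read fraction matches
# cfg$circ_fraction_of_reads.
sim_state <- function(bundle, circs, cfg) {
  txs <- transcript_seqs(bundle)
  tx_len <- stringr::str_length(txs)
  circ_seqs <- vapply(seq_len(nrow(circs)), function(i) {
    circle_seq(bundle, circs[i, ])
  }, character(1))
  names(circ_seqs) <- circs$circ_id
  circ_len <- stringr::str_length(circ_seqs)

  lin_ab <- with_substream(cfg$seed, "abundance", {
    rlnorm(length(txs), cfg$base_abundance$meanlog, cfg$base_abundance$sdlog)
  })
  names(lin_ab) <- names(txs)

  usable_lin <- tx_len >= cfg$read_length
  usable_circ <- circ_len >= cfg$read_length
  if (any(!usable_circ)) {
    warn(sprintf("skipping %d circle(s) shorter than read_length (%s)",
                 sum(!usable_circ),
                 paste(circs$circ_id[!usable_circ], collapse = ", ")))
  }
  fbar <- mean(trunc_frag_lengths(10000, cfg, Inf, preview_seed = cfg$seed))

  state <- list(txs = txs, tx_len = tx_len, lin_ab = lin_ab,
                usable_lin = usable_lin, circ_seqs = circ_seqs,
                circ_len = circ_len, usable_circ = usable_circ, fbar = fbar)
  # calibrated once at baseline multipliers and shared by all libraries, so
  # age effects show up as extra junction reads instead of being absorbed
  # into a per-library rescaling
  state$alpha <- calibrate_circ_scale(state, circs,
                                      rep(1, nrow(circs)), cfg)
  state
}

# Truncated-Gaussian fragment lengths on [read_length, 2*read_length + 200],
# additionally capped at `cap` (the transcript or circle length).
trunc_frag_lengths <- function(n, cfg, cap, preview_seed = NULL) {
  draw <- function(n) {
    f <- round(rnorm(n, cfg$fragment_mean, cfg$fragment_sd))
    pmin(pmax(f, cfg$read_length), min(2 * cfg$read_length + 200, cap))
  }
  if (!is.null(preview_seed)) {
    with_substream(preview_seed, "fraglen-preview", draw(n))
  } else draw(n)
}

# Circle sampling-weight scale alpha for one library such that the expected
# fraction of junction-crossing fragments among all fragments equals the
# configured target. Solves target = alpha*J / (W_lin + alpha*S) for alpha.
calibrate_circ_scale <- function(state, circs, mult, cfg) {
  w_lin <- sum(state$lin_ab[state$usable_lin] *
                 state$tx_len[state$usable_lin])
  w_c <- circs$rel_abundance * mult * state$circ_len
  w_c[!state$usable_circ] <- 0
  p_c <- pmin(state$fbar, state$circ_len) / state$circ_len
  target <- cfg$circ_fraction_of_reads
  if (target <= 0 || sum(w_c) == 0) return(0)
  J <- sum(w_c * p_c); S <- sum(w_c)
  denom <- J - target * S
  if (denom <= 0) abort("circ_fraction_of_reads target unattainable")
  target * w_lin / denom
}

apply_sequencing_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- stringr::str_length(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      old <- stringr::str_sub(seqs[i], p, p)
      stringr::str_sub(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

#' Simulate one sequencing library
#'
#' Samples `cfg$frags_per_library` fragments from mature linear transcripts
#' and circularly permuted circle sequences, emits inner-facing (FR) mate
#' pairs of `cfg$read_length` nt, applies per-base substitution errors,
#' injects exact PCR duplicates, and records in the truth set every mate
#' that crosses the back-spliced junction together with its donor- and
#' acceptor-side overhangs. Fragments longer than a circle are never drawn
#' (no rolling-circle reads).
#'
#' @param bundle A `genome_bundle`.
#' @param circs True circRNA tibble from [assign_circrnas()].
#' @param truth A `truth_set` (from [new_truth_set()]), updated and returned.
#' @param tissue,age,replicate Group labels for this library.
#' @param cfg A [sim_config()].
#' @param state Optional precomputed state (shared across libraries by
#'   [simulate_study()]).
#' @return `list(reads = tibble(name, seq1, seq2, is_dup), truth = truth)`.
#' @export
simulate_library <- function(bundle, circs, truth, tissue, age, replicate,
                             cfg, state = NULL) {
  if (!tissue %in% cfg$tissues || !age %in% cfg$ages) {
    abort(sprintf("unknown group label: %s/%s", tissue, age))
  }
  if (is.null(state)) state <- sim_state(bundle, circs, cfg)
  lib <- fmt_lib(tissue, age, replicate)
  L <- cfg$read_length
  old_age <- cfg$ages[length(cfg$ages)]
  mult <- ifelse(circs$direction != "none" & tissue %in% cfg$affected_tissues &
                   age == old_age, circs$fold, 1)
  alpha <- state$alpha

  with_substream(cfg$seed, paste0("lib:", lib), {
    w_lin <- state$lin_ab * state$tx_len
    w_lin[!state$usable_lin] <- 0
    w_circ <- alpha * circs$rel_abundance * mult * state$circ_len
    w_circ[!state$usable_circ] <- 0
    w <- c(w_lin, w_circ)
    n_feat_lin <- length(w_lin)
    counts <- as.integer(rmultinom(1, cfg$frags_per_library, w))

    frag_src <- character(0); frag_seq <- character(0); frag_jf <- integer(0)
    # linear fragments
    for (t in which(counts[seq_len(n_feat_lin)] > 0)) {
      k <- counts[t]
      tl <- state$tx_len[t]
      fl <- trunc_frag_lengths(k, cfg, tl)
      st <- floor(runif(k, 0, tl - fl + 1))
      frag_seq <- c(frag_seq, stringr::str_sub(state$txs[t], st + 1, st + fl))
      frag_src <- c(frag_src, rep(names(state$txs)[t], k))
      frag_jf <- c(frag_jf, rep(NA_integer_, k))
    }
    # circular fragments (uniform start on the circular permutation)
    for (ci in which(counts[n_feat_lin + seq_len(nrow(circs))] > 0)) {
      k <- counts[n_feat_lin + ci]
      C <- state$circ_len[ci]
      fl <- trunc_frag_lengths(k, cfg, C)
      st <- floor(runif(k, 0, C))
      doubled <- paste0(state$circ_seqs[ci], state$circ_seqs[ci])
      frag_seq <- c(frag_seq, stringr::str_sub(doubled, st + 1, st + fl))
      jf <- ifelse(st > 0 & st + fl > C, C - st, NA_integer_)
      frag_jf <- c(frag_jf, as.integer(jf))
      frag_src <- c(frag_src, rep(circs$circ_id[ci], k))
    }

    n_frag <- length(frag_seq)
    ord <- sample.int(n_frag)   # shuffle so file order carries no signal
    frag_seq <- frag_seq[ord]; frag_src <- frag_src[ord]
    frag_jf <- frag_jf[ord]
    frag_len <- stringr::str_length(frag_seq)
    name <- sprintf("%s:f%06d", lib, seq_len(n_frag))

    mateA <- stringr::str_sub(frag_seq, 1, L)                 # sense
    mateB <- revcomp(stringr::str_sub(frag_seq, frag_len - L + 1, frag_len))
    mateA <- apply_sequencing_errors(mateA, cfg$error_rate)
    mateB <- apply_sequencing_errors(mateB, cfg$error_rate)
    swap <- if (cfg$stranded) rep(FALSE, n_frag) else runif(n_frag) < 0.5
    seq1 <- ifelse(swap, mateB, mateA)
    seq2 <- ifelse(swap, mateA, mateB)

    # junction-spanning mates (sense mate covers fragment [0, L); antisense
    # mate covers [len-L, len)); overhangs measured on the fragment
    is_circ <- !is.na(frag_jf)
    jr <- list()
    if (any(is_circ)) {
      idx <- which(is_circ)
      jf <- frag_jf[idx]; fl <- frag_len[idx]
      a_span <- jf > 0 & jf < L
      b_d <- jf - (fl - L)
      b_span <- b_d > 0 & b_d < L
      slotA <- ifelse(swap[idx], 2L, 1L)
      slotB <- ifelse(swap[idx], 1L, 2L)
      jr$A <- tibble(library_id = lib, circ_id = frag_src[idx],
                     name = name[idx], mate = slotA,
                     donor_overhang = as.integer(jf),
                     acceptor_overhang = as.integer(L - jf),
                     scaffold_strand = "+")[a_span, ]
      jr$B <- tibble(library_id = lib, circ_id = frag_src[idx],
                     name = name[idx], mate = slotB,
                     donor_overhang = as.integer(b_d),
                     acceptor_overhang = as.integer(L - b_d),
                     scaffold_strand = "-")[b_span, ]
    }
    junction_reads <- if (length(jr)) list_rbind(jr) else
      tibble(library_id = character(0), circ_id = character(0),
             name = character(0), mate = integer(0),
             donor_overhang = integer(0), acceptor_overhang = integer(0),
             scaffold_strand = character(0))

    # PCR duplicates: exact re-emission of both mates under a new name
    dup <- runif(n_frag) < cfg$duplicate_rate
    dup_idx <- which(dup)
    dup_name <- sprintf("%s:dup", name[dup_idx])
    reads <- tibble(name = c(name, dup_name),
                    seq1 = c(seq1, seq1[dup_idx]),
                    seq2 = c(seq2, seq2[dup_idx]),
                    source = c(frag_src, frag_src[dup_idx]),
                    is_dup = c(rep(FALSE, n_frag), rep(TRUE, length(dup_idx))))
    if (length(dup_idx)) {
      dup_parents <- name[dup_idx]
      dup_jr <- junction_reads %>%
        filter(.data$name %in% dup_parents) %>%
        mutate(name = sprintf("%s:dup", .data$name))
      truth$duplicates <- bind_rows(
        truth$duplicates, tibble(library_id = lib, name = dup_name))
    } else dup_jr <- NULL

    truth$junction_reads <- bind_rows(
      truth$junction_reads,
      junction_reads %>% mutate(is_dup = FALSE),
      if (!is.null(dup_jr)) dup_jr %>% mutate(is_dup = TRUE))
    truth$libraries <- bind_rows(
      truth$libraries,
      tibble(library_id = lib, tissue = tissue, age = age,
             replicate = as.integer(replicate),
             n_fragments = n_frag, n_duplicates = length(dup_idx),
             n_pairs_emitted = n_frag + length(dup_idx),
             n_circ_fragments = sum(is_circ)))
    list(reads = reads, truth = truth)
  })
}

#' Simulate a complete multi-tissue aging study
#'
#' Generates the toy genome, assigns circRNAs, and simulates every library
#' in the design (tissues x ages x replicates) with shared abundances, so
#' the only systematic old-vs-young difference is the configured circRNA age
#' effect.
#'
#' @param cfg A [sim_config()].
#' @return A list with class `sim_study`: `bundle`, `circs`, `truth`,
#'   `reads` (named list of per-library read tibbles), `design` and `config`.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(seed = 7, n_genes = 12,
#'   n_circ_genes = 4, n_chromosomes = 1, chrom_length = 2e5L,
#'   frags_per_library = 300L))
#' }
#' @export
simulate_study <- function(cfg) {
  bundle <- generate_genome(cfg)
  circs <- assign_circrnas(bundle, cfg)
  design <- sim_design(cfg)
  truth <- new_truth_set(circs, design)
  state <- sim_state(bundle, circs, cfg)
  reads <- list()
  for (i in seq_len(nrow(design))) {
    res <- simulate_library(bundle, circs, truth, design$tissue[i],
                            design$age[i], design$replicate[i], cfg, state)
    reads[[design$library_id[i]]] <- res$reads
    truth <- res$truth
  }
  structure(list(bundle = bundle, circs = circs, truth = truth,
                 reads = reads, design = design, config = cfg),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d libraries, %d true circRNAs, %s read pairs\n",
    length(x$reads), nrow(x$circs),
    format(sum(x$truth$libraries$n_pairs_emitted), big.mark = ",")))
  invisible(x)
}

# Long per-mate view of a library's reads, the shape the detector consumes.
reads_long <- function(reads) {
  bind_rows(
    tibble(read_id = paste0(reads$name, "/1"), seq = reads$seq1),
    tibble(read_id = paste0(reads$name, "/2"), seq = reads$seq2))
}

#' Write / read paired FASTQ
#'
#' Constant high base qualities are written; qualities are never used
#' downstream.
#'
#' @param reads Tibble with `name`, `seq1`, `seq2`.
#' @param prefix Output prefix; `<prefix>_1.fastq` and `<prefix>_2.fastq`
#'   are written.
#' @return `write_fastq_pairs()` the two paths, invisibly;
#'   `read_fastq_pairs()` a tibble with `name`, `seq1`, `seq2`.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("seq", m)]])
    names(seqs) <- paste0(reads$name, "/", m)
    quals <- Biostrings::BStringSet(
      strrep("I", stringr::str_length(reads[[paste0("seq", m)]])))
    Biostrings::writeXStringSet(seqs, paths[m], format = "fastq",
                                qualities = quals)
  }
  invisible(paths)
}

#' @rdname write_fastq_pairs
#' @param path1,path2 Mate FASTQ paths.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  tibble(name = sub("/1$", "", sub("\\s.*$", "", names(r1))),
         seq1 = unname(as.character(r1)), seq2 = unname(as.character(r2)))
}
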