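#' Simulation configuration
#'
#' Parameters of the synthetic TE benchmark: a toy genome of TE subfamilies
#' whose copies share high sequence identity (forcing multi-mapping), a
#' sparse ground-truth expression profile, paired-end short-read fragments,
#' and a matched long-read TPM table derived from the truth.
#'
#' @param n_subfamilies number of TE subfamilies (default 2).
#' @param copies_per_subfamily genomic copies per subfamily (default 5).
#' @param consensus_length consensus length in bases (default 1000).
#' @param divergence per-base substitution fraction of each copy from its
#'   subfamily consensus, in \[0, 0.5); scalar or one value per subfamily
#'   (default 0.02: young copies that differ only at scattered positions).
#'   A per-subfamily vector such as `c(0, 0.02)` adds a subfamily of fully
#'   identical copies, the regime in which multi-mapping is unresolvable
#'   from sequence alone and residual EM ambiguity appears (see
#'   [tied_best_fraction()]).
#' @param silent_fraction fraction of loci with zero true expression
#'   (default 0.2).
#' @param n_fragments total paired-end fragments to simulate (default 5000).
#' @param read_length read length in bases (default 76).
#' @param fragment_size fragment (insert) size in bases (default 200).
#' @param spacer bases of random sequence between adjacent copies on the
#'   synthetic chromosome (default 200).
#' @param longread_thin optional probability in (0, 1\]; when set, the
#'   truth-derived long-read counts are binomially thinned with it,
#'   emulating a low-depth or unmatched long-read sample.
#' @param seed integer RNG seed (default 42).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subfamilies = 2, copies_per_subfamily = 5,
                       consensus_length = 1000, divergence = 0.02,
                       silent_fraction = 0.2, n_fragments = 5000,
                       read_length = 76, fragment_size = 200,
                       spacer = 200, longread_thin = NULL, seed = 42) {
  if (any(divergence < 0) || any(divergence >= 0.5)) {
    stop("divergence must be in [0, 0.5)")
  }
  if (!(read_length <= fragment_size && fragment_size <= consensus_length)) {
    stop("need read_length <= fragment_size <= consensus_length")
  }
  stopifnot(n_subfamilies >= 1, copies_per_subfamily >= 1,
            silent_fraction >= 0, silent_fraction < 1, n_fragments >= 1)
  if (!is.null(longread_thin)) {
    stopifnot(longread_thin > 0, longread_thin <= 1)
  }
  structure(
    list(n_subfamilies = n_subfamilies,
         copies_per_subfamily = copies_per_subfamily,
         consensus_length = consensus_length,
         divergence = rep_len(divergence, n_subfamilies),
         silent_fraction = silent_fraction,
         n_fragments = n_fragments,
         read_length = read_length,
         fragment_size = fragment_size,
         spacer = spacer,
         longread_thin = longread_thin,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

DNA <- c("A", "C", "G", "T")

# substitute each base independently with probability `rate`
mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(DNA, b), 1L), "")
  }
  chars
}

#' Build a synthetic TE genome with ground-truth expression
#'
#' Draws a random consensus per subfamily, emits copies independently
#' mutated at the subfamily's divergence rate (substitutions only, so copy
#' coordinates stay aligned), lays the copies on one synthetic chromosome
#' separated by random spacer sequence, and assigns a sparse ground-truth
#' expression profile: a `silent_fraction` of loci get TPM 0 and the rest
#' draw log-normal abundances normalized to one million.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_truth`: list with `genome`
#'   (\linkS4class{DNAStringSet}, one chromosome `chrS`), `copy_seq`
#'   (character, per-locus sequence), `annotation` ([te_annotation()]),
#'   `truth_tpm` (named, sums to 1e6 over expressed loci), `config`.
#' @export
make_te_genome <- function(config) {
  stopifnot(is(config, "sim_config"))
  with_seed(config$seed, {
    K <- config$n_subfamilies * config$copies_per_subfamily
    copy_seq <- character(K)
    locus_id <- character(K)
    subfam <- character(K)
    consensus_seq <- character(config$n_subfamilies)
    names(consensus_seq) <- sprintf("SF%d", seq_len(config$n_subfamilies))
    k <- 0L
    for (s in seq_len(config$n_subfamilies)) {
      consensus <- sample(DNA, config$consensus_length, replace = TRUE)
      consensus_seq[s] <- paste(consensus, collapse = "")
      for (cp in seq_len(config$copies_per_subfamily)) {
        k <- k + 1L
        copy_seq[k] <- paste(mutate_seq(consensus, config$divergence[s]),
                             collapse = "")
        locus_id[k] <- sprintf("SF%d_copy%d", s, cp)
        subfam[k] <- sprintf("SF%d", s)
      }
    }
    lens <- nchar(copy_seq)
    gap <- config$spacer
    starts <- cumsum(c(gap + 1, head(lens + gap, -1)))
    ends <- starts + lens - 1
    pieces <- character(2 * K + 1)
    pieces[1] <- paste(sample(DNA, gap, replace = TRUE), collapse = "")
    for (i in seq_len(K)) {
      pieces[2 * i] <- copy_seq[i]
      pieces[2 * i + 1] <- paste(sample(DNA, gap, replace = TRUE),
                                 collapse = "")
    }
    chrom <- paste(pieces, collapse = "")
    genome <- Biostrings::DNAStringSet(chrom)
    names(genome) <- "chrS"
    annotation <- te_annotation(
      locus_id = locus_id, chrom = "chrS", start = starts, end = ends,
      strand = "+", subfamily = subfam, te_class = "synthetic"
    )
    n_silent <- round(config$silent_fraction * K)
    silent <- if (n_silent > 0) sample.int(K, n_silent) else integer()
    raw <- exp(stats::rnorm(K, 0, 1))
    raw[silent] <- 0
    truth_tpm <- setNames(1e6 * raw / sum(raw), locus_id)
    structure(
      list(genome = genome, copy_seq = setNames(copy_seq, locus_id),
           consensus = consensus_seq, annotation = annotation,
           truth_tpm = truth_tpm, config = config),
      class = "synthetic_truth"
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$annotation), "TE loci,",
      sum(x$truth_tpm > 0), "expressed; chromosome of",
      Biostrings::width(x$genome), "bases\n")
  invisible(x)
}

#' Simulate paired-end fragments and the matched long-read table
#'
#' Per-locus fragment counts are multinomial with probability proportional
#' to truth TPM times locus length (length-weighted abundance, as for
#' uniform fragment coverage); fragment starts are uniform within the
#' locus; each fragment yields a forward read from its 5' end and a
#' reverse-complement read from its 3' end. The matched "long-read" count
#' table is derived from the truth (counts proportional to TPM times
#' length, so converting it back through [counts_to_tpm()] recovers the
#' truth), optionally binomially thinned.
#'
#' @param truth a [make_te_genome()] result.
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @return list with `fragments` (data.frame: `fragment_id`, `locus_id`
#'   (origin), `start` (offset within the locus), `r1`, `r2` read
#'   sequences) and `longread` (data.frame: `locus_id`, `count`).
#' @export
simulate_fragments <- function(truth, config = truth$config) {
  stopifnot(is(truth, "synthetic_truth"))
  rl <- config$read_length
  fs <- config$fragment_size
  lens <- locus_lengths(truth$annotation)
  tpm <- truth$truth_tpm[names(lens)]
  ok <- lens >= fs
  if (any(!ok & tpm > 0)) {
    warning("skipping ", sum(!ok & tpm > 0),
            " expressed locus/loci shorter than the fragment size")
  }
  prob <- tpm * lens * ok
  if (sum(prob) == 0) stop("no expressed locus can carry a fragment")
  with_seed(config$seed + 1L, {
    counts <- as.integer(stats::rmultinom(1, config$n_fragments,
                                          prob / sum(prob)))
    origin <- rep(names(lens), counts)
    n <- length(origin)
    start <- vapply(origin, function(l) {
      sample.int(lens[[l]] - fs + 1L, 1L)
    }, integer(1))
    r1 <- substr(truth$copy_seq[origin], start, start + rl - 1L)
    tail_seq <- substr(truth$copy_seq[origin], start + fs - rl, start + fs - 1L)
    r2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tail_seq)))
    frags <- data.frame(
      fragment_id = sprintf("frag%06d", seq_len(n)),
      locus_id = origin,
      start = as.integer(start),
      r1 = unname(r1), r2 = unname(r2),
      stringsAsFactors = FALSE
    )
    lr_count <- tpm * lens / 1000
    if (!is.null(config$longread_thin)) {
      lr_count <- rbinom(length(lr_count), round(lr_count),
                         config$longread_thin)
    }
    list(fragments = frags,
         longread = data.frame(locus_id = names(lens),
                               count = as.numeric(lr_count),
                               stringsAsFactors = FALSE))
  })
}

#' String-matching alignment of simulated fragments
#'
#' Stands in for an external aligner inside the synthetic benchmark: each
#' fragment's genomic window is compared base-by-base against every TE copy
#' (copies are coordinate-aligned because the mutation model is
#' substitution-only), and every copy within `max_mismatch` mismatches over
#' the two reads becomes an alignment candidate. Per-mate scores follow the
#' end-to-end alignment-score convention of common short-read aligners
#' (0 for a perfect alignment, -6 per mismatch), so the default score
#' rescale of [ingest_alignments()] applies unchanged. The true origin
#' always matches exactly, so it is guaranteed to be among the candidates.
#'
#' @param sim result of [simulate_fragments()].
#' @param truth the matching [make_te_genome()] result.
#' @param max_mismatch maximum pair mismatches for a candidate; defaults to
#'   10% of the sequenced pair bases.
#' @return data.frame with one row per (fragment, candidate locus):
#'   `fragment_id`, `locus_id`, `score` (pair score), `mm1`, `mm2`
#'   (per-mate mismatches), `start` (offset within the locus). Feed it to
#'   [fragment_matrix()] or write it with [write_sam()].
#' @export
synthetic_align <- function(sim, truth, max_mismatch = NULL) {
  stopifnot(is(truth, "synthetic_truth"))
  config <- truth$config
  rl <- config$read_length
  fs <- config$fragment_size
  if (is.null(max_mismatch)) max_mismatch <- floor(0.1 * 2 * rl)
  frags <- sim$fragments
  chars <- lapply(truth$copy_seq, function(s) strsplit(s, "")[[1]])
  lens <- vapply(chars, length, integer(1))
  ids <- names(truth$copy_seq)
  out <- vector("list", nrow(frags))
  for (fi in seq_len(nrow(frags))) {
    s <- frags$start[fi]
    i1 <- s:(s + rl - 1L)
    i2 <- (s + fs - rl):(s + fs - 1L)
    x1 <- chars[[frags$locus_id[fi]]][i1]
    x2 <- chars[[frags$locus_id[fi]]][i2]
    feasible <- which(lens >= s + fs - 1L)
    mm1 <- vapply(feasible, function(k) sum(x1 != chars[[k]][i1]), integer(1))
    mm2 <- vapply(feasible, function(k) sum(x2 != chars[[k]][i2]), integer(1))
    keep <- which(mm1 + mm2 <= max_mismatch)
    out[[fi]] <- data.frame(
      fragment_id = frags$fragment_id[fi],
      locus_id = ids[feasible[keep]],
      score = -6L * (mm1[keep] + mm2[keep]),
      mm1 = mm1[keep], mm2 = mm2[keep],
      start = s,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res[order(res$fragment_id, res$locus_id), , drop = FALSE]
}

#' Write synthetic alignments as SAM
#'
#' Emits one properly paired record pair per (fragment, candidate locus) in
#' the dialect [ingest_alignments()] consumes: coordinates on the synthetic
#' chromosome, `AS` (per-mate match score) and `NM` (per-mate mismatch)
#' tags, and secondary flags on all but the best-scoring candidate of each
#' fragment.
#'
#' @param alignments result of [synthetic_align()].
#' @param truth the matching [make_te_genome()] result.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, truth, path) {
  stopifnot(is(truth, "synthetic_truth"))
  config <- truth$config
  rl <- config$read_length
  fs <- config$fragment_size
  loci <- te_loci(truth$annotation)
  lstart <- setNames(loci$start, loci$locus_id)
  lchrom <- setNames(loci$chrom, loci$locus_id)
  aln <- alignments[order(alignments$fragment_id, -alignments$score,
                          alignments$locus_id), ]
  primary <- !duplicated(aln$fragment_id)
  qual <- strrep("I", rl)
  # window sequence on the candidate locus (forward strand)
  cand_seq <- truth$copy_seq[aln$locus_id]
  seq1 <- substr(cand_seq, aln$start, aln$start + rl - 1L)
  seq2 <- substr(cand_seq, aln$start + fs - rl, aln$start + fs - 1L)
  pos1 <- lstart[aln$locus_id] + aln$start - 1L
  pos2 <- lstart[aln$locus_id] + aln$start + fs - rl - 1L
  flag1 <- 99L + ifelse(primary, 0L, 256L)
  flag2 <- 147L + ifelse(primary, 0L, 256L)
  as1 <- -6L * aln$mm1
  as2 <- -6L * aln$mm2
  rec <- function(flag, pos, mpos, tlen, seq, as, nm) {
    paste(aln$fragment_id, flag, lchrom[aln$locus_id], pos,
          ifelse(primary, 255L, 0L), paste0(rl, "M"), "=", mpos, tlen,
          seq, qual, paste0("AS:i:", as), paste0("NM:i:", nm), sep = "\t")
  }
  lines1 <- rec(flag1, pos1, pos2, fs, seq1, as1, aln$mm1)
  lines2 <- rec(flag2, pos2, pos1, -fs, seq2, as2, aln$mm2)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(truth$genome),
                     "\tLN:", Biostrings::width(truth$genome)))
  body <- as.vector(rbind(lines1, lines2))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write simulated reads as paired FASTQ
#'
#' @param sim result of [simulate_fragments()].
#' @param prefix output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(sim, prefix) {
  frags <- sim$fragments
  qual <- strrep("I", nchar(frags$r1[1]))
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  writeLines(as.vector(rbind(paste0("@", frags$fragment_id, "/1"),
                             frags$r1, "+", qual)), p1)
  writeLines(as.vector(rbind(paste0("@", frags$fragment_id, "/2"),
                             frags$r2, "+", qual)), p2)
  invisible(c(p1, p2))
}

#' Long-read/short-read coverage scaling ratio
#'
#' Integer multiplier applied to long-read TPM coverage before re-simulating
#' short reads, so that the simulated library matches the long-read library
#' in mapped bases: `floor(bases_long / bases_short)`.
#'
#' @param bases_long mapped bases in the long-read library.
#' @param bases_short mapped bases in the trial simulated short-read
#'   library; must be positive.
#' @return integer multiplier.
#' @export
coverage_scale_ratio <- function(bases_long, bases_short) {
  stopifnot(bases_long >= 0)
  if (bases_short <= 0) stop("bases_short must be positive")
  as.integer(floor(bases_long / bases_short))
}

#' Confusion-matrix evaluation of expressed-locus detection
#'
#' Calls a locus expressed when its value exceeds the threshold on each
#' side, tallies TP/TN/FP/FN over loci, and derives precision, recall and
#' F1. An inclusion mask restricts scoring to loci captured by at least one
#' approach, when such filtering is wanted.
#'
#' @param estimated named numeric vector (estimated TPM or counts).
#' @param truth named numeric vector over the same loci.
#' @param threshold detection threshold (default 0: expressed means
#'   value > 0).
#' @param mask optional logical vector or character vector of locus ids to
#'   score.
#' @return object of class `te_confusion`: list with `TP`, `TN`, `FP`,
#'   `FN`, `precision`, `recall`, `F1`, `n`, and `degenerate` (TRUE when
#'   precision had an empty denominator and was reported as 0).
#' @export
evaluate_confusion <- function(estimated, truth, threshold = 0,
                               mask = NULL) {
  if (is.null(names(estimated)) || is.null(names(truth))) {
    stop("estimated and truth must be named by locus id")
  }
  missing_est <- setdiff(names(truth), names(estimated))
  missing_tru <- setdiff(names(estimated), names(truth))
  if (length(missing_est) || length(missing_tru)) {
    stop("locus universe mismatch; offending ids: ",
         paste(head(c(missing_est, missing_tru), 10), collapse = ", "))
  }
  ids <- names(truth)
  if (!is.null(mask)) {
    ids <- if (is.character(mask)) intersect(ids, mask) else ids[mask]
  }
  est <- estimated[ids] > threshold
  tru <- truth[ids] > threshold
  TP <- sum(est & tru); TN <- sum(!est & !tru)
  FP <- sum(est & !tru); FN <- sum(!est & tru)
  degenerate <- (TP + FP) == 0
  precision <- if (degenerate) 0 else TP / (TP + FP)
  recall <- if ((TP + FN) == 0) 0 else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(TP = TP, TN = TN, FP = FP, FN = FN, precision = precision,
         recall = recall, F1 = f1, n = length(ids), degenerate = degenerate),
    class = "te_confusion"
  )
}

#' @export
print.te_confusion <- function(x, ...) {
  cat(sprintf(
    "te_confusion (n = %d): TP %d TN %d FP %d FN %d | precision %.3f recall %.3f F1 %.3f\n",
    x$n, x$TP, x$TN, x$FP, x$FN, x$precision, x$recall, x$F1))
  invisible(x)
}

#' Write a complete synthetic fixture bundle
#'
#' Builds the toy genome, fragments, alignments and tables for one seeded
#' configuration and writes them under one directory: `genome.fasta`,
#' `te_annotation.gtf`, `reads_R1/R2.fastq`, `alignments.sam`,
#' `longread.tsv` (locus_id, count), `truth.tsv` (locus_id, subfamily,
#' length, tpm), `origins.tsv` (per-fragment true origin). Byte-identical
#' across runs with the same configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with element `paths` (named file paths) plus the in-memory
#'   `truth`, `sim` and `alignments` objects, invisibly.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(is(config, "sim_config"))
  if (config$copies_per_subfamily == 1) {
    message("single copy per subfamily: no multi-mapping is possible")
  }
  truth <- make_te_genome(config)
  sim <- simulate_fragments(truth, config)
  aln <- synthetic_align(sim, truth)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    gtf = file.path(dir, "te_annotation.gtf"),
    r1 = file.path(dir, "reads_R1.fastq"),
    r2 = file.path(dir, "reads_R2.fastq"),
    sam = file.path(dir, "alignments.sam"),
    longread = file.path(dir, "longread.tsv"),
    truth = file.path(dir, "truth.tsv"),
    origins = file.path(dir, "origins.tsv")
  )
  Biostrings::writeXStringSet(truth$genome, paths[["genome"]])
  write_te_gtf(truth$annotation, paths[["gtf"]])
  write_fastq(sim, file.path(dir, "reads"))
  write_sam(aln, truth, paths[["sam"]])
  write.table(sim$longread, paths[["longread"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_df <- te_loci(truth$annotation)[, c("locus_id", "subfamily", "length")]
  truth_df$tpm <- truth$truth_tpm[truth_df$locus_id]
  write.table(truth_df, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$fragments[, c("fragment_id", "locus_id", "start")],
              paths[["origins"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(paths = paths, truth = truth, sim = sim, alignments = aln))
}
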