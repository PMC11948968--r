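#' Alignment-score likelihood weights
#'
#' Maps per-candidate alignment scores to relative likelihood weights
#' `q_i = exp(lambda * (score_i - max(score)))`: the best-scoring candidate
#' of a fragment gets weight 1 and worse candidates decay exponentially.
#' `lambda` rescales the aligner's score units; it is exposed because score
#' scales differ between aligners.
#'
#' @param scores numeric vector of alignment scores (higher is better) for
#'   one fragment's candidates.
#' @param lambda positive rescale factor (default 0.1 per score unit).
#' @return weights in (0, 1], same order as `scores`, max exactly 1.
#' @export
score_to_weight <- function(scores, lambda = 0.1) {
  if (length(scores) == 0) stop("empty score list")
  stopifnot(lambda > 0)
  exp(lambda * (scores - max(scores)))
}

#' Build the sparse fragment-by-locus evidence matrix
#'
#' Core container for the mixture model: one row per sequenced fragment,
#' one column per annotated TE locus, entries `q` in (0, 1] giving the
#' alignment-evidence weight of each candidate locus. Rows are assembled in
#' a canonical (fragment id, annotation) order so the matrix is independent
#' of input record order. A fragment with two or more candidate loci is
#' multi-mapped (`y = 1`); with exactly one, uniquely mapped (`y = 0`).
#'
#' @param candidates data.frame with columns `fragment_id`, `locus_id`,
#'   `score` (one row per alignment candidate; duplicated
#'   fragment/locus pairs keep the best score).
#' @param annotation a [te_annotation()]; all candidate loci must exist in
#'   it.
#' @param lambda score rescale factor passed to [score_to_weight()].
#' @return object of class `fragment_matrix`: list with sparse `q`
#'   (\linkS4class{dgCMatrix}, N x K), integer `y` (length N), `fragment_id`,
#'   `locus_id`, `N`, `K`.
#' @export
fragment_matrix <- function(candidates, annotation, lambda = 0.1) {
  stopifnot(is(annotation, "te_annotation"),
            all(c("fragment_id", "locus_id", "score") %in% names(candidates)))
  if (nrow(candidates) == 0) stop("no alignment candidates supplied")
  unknown <- setdiff(unique(candidates$locus_id), annotation$locus_id)
  if (length(unknown)) {
    stop("candidate loci absent from annotation: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  # best score per (fragment, locus), then canonical order
  key <- paste(candidates$fragment_id, candidates$locus_id, sep = "\r")
  best <- tapply(candidates$score, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  df <- data.frame(
    fragment_id = vapply(parts, `[`, "", 1L),
    locus_id = vapply(parts, `[`, "", 2L),
    score = as.numeric(best),
    stringsAsFactors = FALSE
  )
  frag_ids <- sort(unique(df$fragment_id))
  row <- match(df$fragment_id, frag_ids)
  col <- match(df$locus_id, annotation$locus_id)
  ord <- order(row, col)
  df <- df[ord, ]; row <- row[ord]; col <- col[ord]
  # per-fragment weights: best candidate gets q = 1
  smax <- tapply(df$score, row, max)
  q <- exp(lambda * (df$score - as.numeric(smax[as.character(row)])))
  n_cand <- tabulate(row, nbins = length(frag_ids))
  fm <- list(
    q = Matrix::sparseMatrix(i = row, j = col, x = q,
                             dims = c(length(frag_ids), length(annotation)),
                             dimnames = list(frag_ids, annotation$locus_id)),
    y = as.integer(n_cand >= 2L),
    fragment_id = frag_ids,
    locus_id = annotation$locus_id,
    N = length(frag_ids),
    K = length(annotation),
    lambda = lambda
  )
  class(fm) <- "fragment_matrix"
  fm
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat("fragment_matrix:", x$N, "fragments x", x$K, "loci;",
      sum(x$y), "multi-mapped,", sum(x$y == 0L), "unique\n")
  invisible(x)
}

#' Ingest short-read alignments into a fragment matrix
#'
#' Reads a BAM (or plain SAM, converted internally) file, groups records
#' into fragments by query name, attaches each alignment to the TE loci it
#' overlaps, and builds the [fragment_matrix()]. Mates of a pair hitting
#' the same locus form a single candidate with the summed pair score;
#' secondary/supplementary alignments contribute candidates too. Fragments
#' overlapping no TE locus are dropped.
#'
#' Alignment scores are taken from the `AS` tag; when absent, the negated
#' edit distance (`NM`) is used, and failing that a constant 0 (uniform
#' weights) with a warning.
#'
#' @param path BAM or SAM file.
#' @param annotation a [te_annotation()].
#' @param min_overlap minimum fraction of an alignment's reference span that
#'   must overlap a locus for it to count as a candidate; the default 0
#'   requires any overlap (>= 1 base), mirroring permissive
#'   overlapping-feature counting.
#' @param lambda score rescale factor, see [score_to_weight()].
#' @return a `fragment_matrix`.
#' @export
ingest_alignments <- function(path, annotation, min_overlap = 0,
                              lambda = 0.1) {
  stopifnot(is(annotation, "te_annotation"))
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    tag = c("AS", "NM"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(aln) == 0) stop("no mapped records in ", path)
  mc <- S4Vectors::mcols(aln)
  score <- mc$AS
  if (is.null(score) || all(is.na(score))) {
    nm <- mc$NM
    if (!is.null(nm) && !all(is.na(nm))) {
      warning("no AS score tag; falling back to -NM edit distance")
      score <- -nm
    } else {
      warning("no AS/NM tags; using uniform alignment weights")
      score <- rep(0, length(aln))
    }
  }
  score[is.na(score)] <- 0
  hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(aln),
                                      annotation$granges,
                                      ignore.strand = TRUE)
  if (min_overlap > 0) {
    ov <- GenomicRanges::pintersect(
      GenomicRanges::granges(aln)[S4Vectors::queryHits(hits)],
      annotation$granges[S4Vectors::subjectHits(hits)])
    frac <- GenomicRanges::width(ov) /
      GenomicRanges::width(GenomicRanges::granges(aln))[S4Vectors::queryHits(hits)]
    hits <- hits[frac >= min_overlap]
  }
  if (length(hits) == 0) stop("no alignments overlap the TE annotation")
  qh <- S4Vectors::queryHits(hits)
  flag <- mc$flag[qh]
  mate <- ifelse(bitwAnd(flag, 0x80L) > 0L, 2L, 1L)
  cand <- data.frame(
    fragment_id = mc$qname[qh],
    locus_id = annotation$locus_id[S4Vectors::subjectHits(hits)],
    mate = mate,
    score = score[qh],
    stringsAsFactors = FALSE
  )
  # best per (fragment, locus, mate), summed over mates -> pair score
  key <- paste(cand$fragment_id, cand$locus_id, cand$mate, sep = "\r")
  best <- tapply(cand$score, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  pair <- data.frame(
    fragment_id = vapply(parts, `[`, "", 1L),
    locus_id = vapply(parts, `[`, "", 2L),
    score = as.numeric(best),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(score ~ fragment_id + locus_id, data = pair,
                          FUN = sum)
  fragment_matrix(agg, annotation, lambda = lambda)
}

#' Dump a fragment matrix to TSV (debugging aid)
#'
#' @param fm a `fragment_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_tsv <- function(fm, path) {
  stopifnot(is(fm, "fragment_matrix"))
  tri <- Matrix::summary(fm$q)
  df <- data.frame(
    fragment_id = fm$fragment_id[tri$i],
    locus_id = fm$locus_id[tri$j],
    q = tri$x,
    y = fm$y[tri$i]
  )
  df <- df[order(df$fragment_id, df$locus_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
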