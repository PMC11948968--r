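#' Final per-locus counts from converged posteriors
#'
#' Converts the fitted posterior assignment weights into a per-locus count
#' table under one of four reassignment modes:
#' \describe{
#'   \item{`best`}{each fragment contributes 1 to its highest-posterior
#'     locus; ties are broken by a seeded uniform draw.}
#'   \item{`long_read`}{like `best`, but a fragment whose best posterior is
#'     tied across several loci splits its count over the tied set in
#'     proportion to the loci's raw long-read TPM values (weighted-mean
#'     redistribution). If every tied locus has zero long-read TPM the
#'     fragment falls back to a seeded uniform split, with a warning.}
#'   \item{`average`}{fractional posteriors are summed per locus.}
#'   \item{`unique`}{only uniquely mapped fragments (y = 0) are counted.}
#' }
#' `average` and `long_read` conserve total mass (counts sum to the number
#' of fragments); `unique` sums to the number of uniquely mapped fragments.
#'
#' @param state a converged `em_state` from [run_em()].
#' @param fm the matching [fragment_matrix()].
#' @param prior a `te_prior` (or named TPM vector) supplying the raw
#'   long-read TPM used by `long_read` tie redistribution; may be `NULL`
#'   for other modes.
#' @param mode reassignment mode, default `"long_read"`.
#' @param annotation optional [te_annotation()] used to attach subfamily
#'   labels to the output.
#' @param seed integer seed for tie-breaking draws.
#' @param tie_tol relative tolerance for calling posteriors tied
#'   (default 1e-9; exact float equality is too brittle).
#' @return object of class `te_counts`: data.frame with columns `locus_id`,
#'   `subfamily` (NA without an annotation), `final_count`, `unique_count`,
#'   `em_count`; attributes `mode` and `n_fragments`.
#' @export
final_counts <- function(state, fm, prior = NULL,
                         mode = c("long_read", "best", "average", "unique"),
                         annotation = NULL, seed = 1L, tie_tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(is(state, "em_state"), is(fm, "fragment_matrix"))
  ex <- Matrix::summary(state$E)
  ord <- order(ex$i, ex$j)
  ri <- ex$i[ord]; cj <- ex$j[ord]; px <- ex$x[ord]
  K <- fm$K
  em_count <- sum_by(px, cj, K)
  # unique counts: sole candidate of each y = 0 fragment
  uq <- fm$y[ri] == 0L
  unique_count <- sum_by(rep(1, sum(uq)), cj[uq], K)
  final <- switch(mode,
    average = em_count,
    unique = unique_count,
    best = ,
    long_read = {
      tpm <- if (mode == "long_read") {
        if (is.null(prior)) stop("mode 'long_read' needs the long-read prior")
        align_prior(prior, fm$locus_id, what = "tpm")
      } else NULL
      best_assign(ri, cj, px, fm$N, K, mode, tpm, seed, tie_tol)
    }
  )
  out <- data.frame(
    locus_id = fm$locus_id,
    subfamily = if (is.null(annotation)) NA_character_ else
      annotation$subfamily[match(fm$locus_id, annotation$locus_id)],
    final_count = as.numeric(final),
    unique_count = as.numeric(unique_count),
    em_count = as.numeric(em_count),
    stringsAsFactors = FALSE
  )
  attr(out, "mode") <- mode
  attr(out, "n_fragments") <- fm$N
  class(out) <- c("te_counts", "data.frame")
  out
}

# argmax assignment with tie handling (seeded choice or long-read-weighted
# redistribution over the tied set)
best_assign <- function(ri, cj, px, N, K, mode, tpm, seed, tie_tol) {
  groups <- split(seq_along(ri), ri)
  counts <- numeric(K)
  warned <- FALSE
  with_seed(seed, {
    for (g in groups) {
      v <- px[g]
      best <- max(v)
      tied <- g[v >= best * (1 - tie_tol)]
      if (length(tied) == 1L) {
        counts[cj[tied]] <- counts[cj[tied]] + 1
      } else if (mode == "long_read") {
        tv <- tpm[cj[tied]]
        if (sum(tv) > 0) {
          counts[cj[tied]] <- counts[cj[tied]] + tv / sum(tv)
        } else {
          if (!warned) {
            warning("tie among loci with zero long-read TPM; ",
                    "splitting uniformly")
            warned <- TRUE
          }
          counts[cj[tied]] <- counts[cj[tied]] + 1 / length(tied)
        }
      } else {
        pick <- tied[sample.int(length(tied), 1L)]
        counts[cj[pick]] <- counts[cj[pick]] + 1
      }
    }
  })
  counts
}

#' Count report with TPM
#'
#' Attaches TPM values to a count table. The library-size denominator is
#' either the TE counts themselves (`te_total`, ordinary TPM over the
#' reported loci) or the length-normalized rate sum of a coding-gene count
#' table (`coding_gene_total`), which expresses TE abundance per million
#' coding-gene transcripts and is robust to how many TE loci are annotated.
#'
#' @param counts a `te_counts` from [final_counts()].
#' @param lengths named numeric vector of locus lengths in bases (e.g.
#'   [locus_lengths()]).
#' @param library_size denominator rule: `"te_total"` (default) or
#'   `"coding_gene_total"`.
#' @param coding_counts data.frame with columns `count` and `length` (one
#'   row per coding gene); required for `coding_gene_total`.
#' @return the count table, sorted by `locus_id`, with a `tpm` column.
#' @export
counts_to_report <- function(counts, lengths,
                             library_size = c("te_total",
                                              "coding_gene_total"),
                             coding_counts = NULL) {
  library_size <- match.arg(library_size)
  stopifnot(is(counts, "te_counts"))
  lens <- lengths[counts$locus_id]
  if (anyNA(lens)) {
    stop("missing lengths for loci: ",
         paste(head(counts$locus_id[is.na(lens)], 5), collapse = ", "))
  }
  rate <- counts$final_count / lens
  denom <- if (library_size == "te_total") {
    sum(rate)
  } else {
    if (is.null(coding_counts) ||
        !all(c("count", "length") %in% names(coding_counts))) {
      stop("library_size = 'coding_gene_total' needs a coding_counts table ",
           "with 'count' and 'length' columns")
    }
    sum(coding_counts$count / coding_counts$length)
  }
  counts$tpm <- if (denom > 0) 1e6 * rate / denom else rate * 0
  out <- counts[order(counts$locus_id), ]
  rownames(out) <- NULL
  attr(out, "library_size") <- library_size
  out
}
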