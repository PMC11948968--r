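#' Quantify locus-level TE expression with the long-read prior
#'
#' End-to-end pipeline: parse the TE annotation, build the
#' subfamily-normalized long-read prior, ingest the short-read alignments
#' into the fragment matrix, fit the prior-weighted EM, reassign fragments
#' under the chosen mode, and report per-locus counts with TPM.
#'
#' @param bam short-read alignments: a BAM/SAM path, a candidate data.frame
#'   (`fragment_id`, `locus_id`, `score`), or a ready [fragment_matrix()].
#' @param gtf TE annotation: a GTF path or a [te_annotation()].
#' @param longread long-read per-locus table: TSV path or data.frame with
#'   `locus_id` and `count` or `tpm` columns (see [long_read_prior()]), or
#'   a ready `te_prior`. May be `NULL` only for a prior-free run
#'   (`long_read_weight = 0` or `prior_change = "none"`).
#' @param out_dir optional output directory; when given, writes
#'   `te_counts.tsv`, `prior.tsv`, `em_trace.tsv` and `manifest.json`.
#' @param long_read_weight,prior_change,epsilon,max_iter see [em_params()].
#'   Weights outside \[0.5, 1\] proceed with a logged caution.
#' @param rescue_short rescue constant replacing zero long-read TPM
#'   (default 0; e.g. 1e-50 to keep short-read-only loci reachable).
#' @param reassign_mode see [final_counts()] (default `"long_read"`).
#' @param library_size,coding_counts see [counts_to_report()].
#' @param min_overlap,lambda see [ingest_alignments()].
#' @param locus_key,subfamily_key GTF attribute keys, see [parse_te_gtf()].
#' @param seed integer seed for tie-breaking.
#' @param verbose print one summary line per pipeline stage.
#' @return list with `report` (count table with TPM), `state` (`em_state`),
#'   `fm`, `prior`, `annotation`, and `manifest` (parameter record).
#' @export
quantify_te <- function(bam, gtf, longread, out_dir = NULL,
                        long_read_weight = 1, prior_change = "both",
                        rescue_short = 0, reassign_mode = "long_read",
                        epsilon = 0.001, max_iter = 100,
                        library_size = "te_total", coding_counts = NULL,
                        min_overlap = 0, lambda = 0.1,
                        locus_key = "gene_id", subfamily_key = "family_id",
                        seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  params <- em_params(long_read_weight = long_read_weight,
                      prior_change = prior_change, epsilon = epsilon,
                      max_iter = max_iter, seed = seed)
  if (long_read_weight > 0 && prior_change != "none" &&
      (long_read_weight < 0.5 || long_read_weight > 1)) {
    message("caution: long_read_weight ", long_read_weight,
            " is outside [0.5, 1], a range observed to reduce accuracy")
  }
  annotation <- if (is(gtf, "te_annotation")) gtf else
    parse_te_gtf(gtf, locus_key = locus_key, subfamily_key = subfamily_key)
  say("annotation: ", length(annotation), " loci, ",
      length(subfamily_members(annotation)), " subfamilies")
  prior_free <- long_read_weight == 0 || prior_change == "none"
  if (is.null(longread)) {
    if (!prior_free) {
      stop("no long-read table supplied; either provide one or request a ",
           "prior-free run explicitly (long_read_weight = 0 or ",
           "prior_change = 'none')")
    }
    prior <- subfamily_fractions(
      setNames(numeric(length(annotation)), annotation$locus_id),
      annotation, rescue = 0)
  } else if (is(longread, "te_prior")) {
    prior <- longread
  } else {
    prior <- long_read_prior(longread, annotation, rescue = rescue_short)
  }
  say("prior: ", sum(prior$tpm > 0), " loci with long-read support")
  fm <- if (is(bam, "fragment_matrix")) bam
        else if (is.data.frame(bam)) fragment_matrix(bam, annotation,
                                                     lambda = lambda)
        else ingest_alignments(bam, annotation, min_overlap = min_overlap,
                               lambda = lambda)
  say("fragments: ", fm$N, " (", sum(fm$y), " multi-mapped)")
  state <- run_em(fm, prior, params)
  say("EM: ", state$iterations, " iterations, ",
      if (state$converged) "converged" else "NOT converged",
      sprintf(" (max delta %.2g)", state$max_delta))
  counts <- final_counts(state, fm, prior = prior, mode = reassign_mode,
                         annotation = annotation, seed = seed)
  report <- counts_to_report(counts, locus_lengths(annotation),
                             library_size = library_size,
                             coding_counts = coding_counts)
  say("report: ", sum(report$final_count > 0), " loci with nonzero counts")
  manifest <- list(
    package = "loquaTE",
    version = as.character(utils::packageVersion("loquaTE")),
    parameters = list(
      long_read_weight = long_read_weight, prior_change = prior_change,
      rescue_short = rescue_short, reassign_mode = reassign_mode,
      epsilon = epsilon, max_iter = max_iter, library_size = library_size,
      min_overlap = min_overlap, lambda = lambda,
      locus_key = locus_key, subfamily_key = subfamily_key, seed = seed
    ),
    inputs = list(
      bam = input_fingerprint(bam),
      gtf = input_fingerprint(gtf),
      longread = input_fingerprint(longread)
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(as.data.frame(report), file.path(out_dir, "te_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_prior_tsv(prior, file.path(out_dir, "prior.tsv"))
    write.table(state$trace, file.path(out_dir, "em_trace.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(report = report, state = state, fm = fm, prior = prior,
                 annotation = annotation, manifest = manifest))
}

# checksum for file inputs, class tag for in-memory ones
input_fingerprint <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    list(path = x, md5 = unname(tools::md5sum(x)))
  } else if (is.null(x)) {
    NULL
  } else {
    list(class = class(x)[1])
  }
}
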