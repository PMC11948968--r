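#' Convert per-locus counts to TPM
#'
#' Standard transcripts-per-million: length-normalized count rates scaled so
#' they sum to one million. Used to turn a featureCounts-style long-read
#' count table into the TPM values the prior is built from.
#'
#' @param counts non-negative numeric vector of per-locus counts.
#' @param lengths positive numeric vector of locus lengths in bases; names,
#'   if present, must align with `counts`.
#' @return numeric vector of TPM values; all-zero input yields all zeros.
#' @export
counts_to_tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    bad <- which(!is.finite(lengths) | lengths <= 0)
    nm <- if (!is.null(names(lengths))) names(lengths)[bad] else bad
    stop("non-positive length for locus: ", paste(nm, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative counts supplied")
  rate <- counts / lengths
  total <- sum(rate)
  if (total == 0) return(counts * 0)
  1e6 * rate / total
}

#' Rescue loci with zero long-read TPM
#'
#' A locus with zero long-read TPM gets zero prior mass and is driven to a
#' zero posterior no matter how much short-read evidence supports it. The
#' rescue constant replaces exact zeros in the long-read TPM vector with a
#' small value (e.g. 1e-50) so that short-read-only loci remain reachable.
#' The default constant is 0, i.e. no rescue.
#'
#' @param tpm non-negative numeric vector of long-read TPM values.
#' @param constant rescue constant `c >= 0`; zeros in `tpm` become `c`.
#' @return `tpm` with zeros replaced by `constant`.
#' @export
apply_rescue <- function(tpm, constant = 0) {
  if (length(constant) != 1 || !is.finite(constant) || constant < 0) {
    stop("rescue constant must be a single non-negative number")
  }
  if (any(tpm < 0)) stop("negative TPM supplied")
  tpm[tpm == 0] <- constant
  tpm
}

#' Subfamily-normalized long-read prior fractions
#'
#' Computes, for each TE copy i, the fraction of its subfamily's long-read
#' TPM mass it carries: `f_i = tpm_i / sum(tpm over the copy's subfamily)`.
#' These fractions are the prior injected into the EM M-step. A subfamily
#' whose TPM is all zero (after rescue) gets fractions of 0 — the prior then
#' contributes nothing for those loci.
#'
#' @param tpm named numeric vector of (rescued) long-read TPM values, one
#'   per locus; names must be locus ids. Loci in the annotation that are
#'   missing from `tpm` are treated as 0.
#' @param annotation a [te_annotation()] providing subfamily membership.
#' @param rescue rescue constant applied (via [apply_rescue()]) before
#'   normalization.
#' @return object of class `te_prior`: data.frame with columns `locus_id`,
#'   `subfamily`, `tpm`, `fraction`, in annotation order, plus attribute
#'   `rescue`.
#' @export
subfamily_fractions <- function(tpm, annotation, rescue = 0) {
  stopifnot(is(annotation, "te_annotation"))
  ids <- annotation$locus_id
  if (is.null(names(tpm))) {
    if (length(tpm) != length(ids)) {
      stop("unnamed tpm vector must have one entry per annotation locus")
    }
    names(tpm) <- ids
  } else {
    extra <- setdiff(names(tpm), ids)
    if (length(extra)) {
      warning(length(extra), " long-read table id(s) absent from the ",
              "annotation are ignored: ",
              paste(head(extra, 5), collapse = ", "),
              if (length(extra) > 5) ", ..." else "")
    }
    tpm <- tpm[ids]
    tpm[is.na(tpm)] <- 0
    names(tpm) <- ids
  }
  tpm <- apply_rescue(tpm, rescue)
  sub_tot <- tapply(tpm, annotation$subfamily, sum)
  denom <- as.numeric(sub_tot[annotation$subfamily])
  fraction <- ifelse(denom > 0, tpm / denom, 0)
  out <- data.frame(
    locus_id = ids,
    subfamily = annotation$subfamily,
    tpm = as.numeric(tpm),
    fraction = as.numeric(fraction),
    stringsAsFactors = FALSE
  )
  attr(out, "rescue") <- rescue
  class(out) <- c("te_prior", "data.frame")
  out
}

#' Build the long-read prior from a TSV table
#'
#' Reads a tab-separated table with a header containing `locus_id` and
#' either a `count` or a `tpm` column (a `count` column is converted to TPM
#' with [counts_to_tpm()] using annotation locus lengths; a supplied `tpm`
#' column is used as-is), applies the rescue constant, and normalizes within
#' subfamilies.
#'
#' @param path TSV file path, or a data.frame of the same shape.
#' @param annotation a [te_annotation()].
#' @param rescue rescue constant (default 0; 1e-50 is a typical non-zero
#'   choice).
#' @return a `te_prior` (see [subfamily_fractions()]).
#' @export
long_read_prior <- function(path, annotation, rescue = 0) {
  tab <- if (is.data.frame(path)) path else
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"locus_id" %in% names(tab)) {
    stop("long-read table needs a 'locus_id' column")
  }
  if ("tpm" %in% names(tab)) {
    tpm <- setNames(as.numeric(tab$tpm), tab$locus_id)
  } else if ("count" %in% names(tab)) {
    counts <- setNames(as.numeric(tab$count), tab$locus_id)
    lens <- locus_lengths(annotation)
    known <- intersect(names(counts), names(lens))
    full <- setNames(numeric(length(lens)), names(lens))
    full[known] <- counts[known]
    extra <- setdiff(names(counts), names(lens))
    if (length(extra)) {
      warning(length(extra), " long-read table id(s) absent from the ",
              "annotation are ignored: ",
              paste(head(extra, 5), collapse = ", "),
              if (length(extra) > 5) ", ..." else "")
    }
    tpm <- counts_to_tpm(full, lens)
    names(tpm) <- names(lens)
  } else {
    stop("long-read table needs a 'count' or 'tpm' column")
  }
  subfamily_fractions(tpm, annotation, rescue = rescue)
}

#' Write a prior table to TSV (provenance record)
#'
#' @param prior a `te_prior`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_prior_tsv <- function(prior, path) {
  stopifnot(is(prior, "te_prior"))
  write.table(as.data.frame(prior), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
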