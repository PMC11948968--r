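#' Locus-level TE annotation index
#'
#' A `te_annotation` holds one record per genomic transposable-element copy
#' (a "locus"), its subfamily membership, and an interval index used to
#' assign alignments to copies. Coordinates are 1-based closed throughout
#' (the GTF and [GenomicRanges::GRanges] convention), so no conversion
#' happens between file and memory.
#'
#' @param locus_id character, unique identifier per TE copy.
#' @param chrom character, chromosome/sequence name.
#' @param start,end integer, 1-based closed interval with `start <= end`.
#' @param strand one of `"+"`, `"-"`, `"*"` per locus (`"."` in GTF maps to
#'   `"*"`). Recycled if length 1.
#' @param subfamily character, TE subfamily of each copy. Copies of one
#'   subfamily share a consensus sequence and therefore cause most of the
#'   multi-mapping the EM model resolves.
#' @param family,te_class optional character vectors (coarser groupings);
#'   kept for reporting only.
#'
#' @return An object of class `te_annotation` with accessors [te_loci()],
#'   [locus_lengths()], [subfamily_members()] and `length()` (number of
#'   loci, K).
#' @seealso [parse_te_gtf()], [overlapping_loci()]
#' @export
te_annotation <- function(locus_id, chrom, start, end, strand = "*",
                          subfamily, family = NA_character_,
                          te_class = NA_character_) {
  locus_id <- as.character(locus_id)
  subfamily <- as.character(subfamily)
  n <- length(locus_id)
  chrom <- rep_len(chrom, n)
  subfamily <- rep_len(subfamily, n)
  stopifnot(length(start) == n, length(end) == n)
  if (anyDuplicated(locus_id)) {
    stop("duplicated locus_id: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  }
  if (any(end < start)) {
    bad <- which(end < start)
    stop("locus with end < start: ", paste(locus_id[bad], collapse = ", "))
  }
  strand <- rep_len(ifelse(strand == ".", "*", strand), n)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)),
    strand = strand
  )
  S4Vectors::mcols(gr)$locus_id <- locus_id
  S4Vectors::mcols(gr)$subfamily <- subfamily
  S4Vectors::mcols(gr)$family <- rep_len(as.character(family), n)
  S4Vectors::mcols(gr)$te_class <- rep_len(as.character(te_class), n)
  obj <- list(
    granges = gr,
    locus_id = locus_id,
    subfamily = subfamily,
    members = split(locus_id, subfamily)
  )
  class(obj) <- "te_annotation"
  obj
}

#' @export
length.te_annotation <- function(x) length(x$locus_id)

#' @export
print.te_annotation <- function(x, ...) {
  cat("te_annotation:", length(x), "TE loci in",
      length(x$members), "subfamilies\n")
  invisible(x)
}

#' Loci of an annotation as a data frame
#'
#' @param annotation a [te_annotation()].
#' @return data.frame with columns locus_id, chrom, start, end, strand,
#'   subfamily, family, te_class, length (bases, `end - start + 1`).
#' @export
te_loci <- function(annotation) {
  stopifnot(is(annotation, "te_annotation"))
  gr <- annotation$granges
  data.frame(
    locus_id = annotation$locus_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    subfamily = annotation$subfamily,
    family = S4Vectors::mcols(gr)$family,
    te_class = S4Vectors::mcols(gr)$te_class,
    length = GenomicRanges::width(gr),
    stringsAsFactors = FALSE
  )
}

#' Locus lengths in bases
#'
#' @inheritParams te_loci
#' @return named numeric vector of locus lengths, in annotation order.
#' @export
locus_lengths <- function(annotation) {
  stopifnot(is(annotation, "te_annotation"))
  setNames(as.numeric(GenomicRanges::width(annotation$granges)),
           annotation$locus_id)
}

#' Subfamily membership map
#'
#' @inheritParams te_loci
#' @return named list, one character vector of locus ids per subfamily
#'   (the set subT used for prior normalization).
#' @export
subfamily_members <- function(annotation) {
  stopifnot(is(annotation, "te_annotation"))
  annotation$members
}

#' Parse a locus-level TE GTF into an annotation index
#'
#' Reads a RepeatMasker-derived GTF in which each record is one genomic TE
#' copy, carrying a locus identifier and a subfamily in its attribute
#' column. Attribute key names differ between GTF dialects and are
#' configurable.
#'
#' @param path GTF file path.
#' @param locus_key attribute key holding the unique locus id
#'   (default `"gene_id"`).
#' @param subfamily_key attribute key holding the subfamily
#'   (default `"family_id"`).
#' @param family_key,class_key optional attribute keys for family and class;
#'   missing keys simply yield NA columns.
#' @return a [te_annotation()] with one locus per GTF record.
#' @export
parse_te_gtf <- function(path, locus_key = "gene_id",
                         subfamily_key = "family_id",
                         family_key = "class_id", class_key = "class_id") {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) stop("GTF file contains no records: ", path)
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(key) {
    if (key %in% colnames(mc)) as.character(mc[[key]]) else
      rep(NA_character_, length(gr))
  }
  locus_id <- get_attr(locus_key)
  subfamily <- get_attr(subfamily_key)
  bad_locus <- which(is.na(locus_id) | locus_id == "")
  bad_sub <- which(is.na(subfamily) | subfamily == "")
  if (length(bad_locus) || length(bad_sub)) {
    lines <- gtf_feature_lines(path)
    if (length(bad_locus)) {
      stop("GTF record(s) missing the '", locus_key, "' attribute at line(s) ",
           paste(lines[bad_locus], collapse = ", "), " of ", path)
    }
    stop("GTF record(s) missing the '", subfamily_key,
         "' attribute at line(s) ",
         paste(lines[bad_sub], collapse = ", "), " of ", path)
  }
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr))) {
    lines <- gtf_feature_lines(path)
    bad <- which(GenomicRanges::end(gr) < GenomicRanges::start(gr))
    stop("GTF record with end < start at line(s) ",
         paste(lines[bad], collapse = ", "), " of ", path)
  }
  te_annotation(
    locus_id = locus_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    subfamily = subfamily,
    family = get_attr(family_key),
    te_class = get_attr(class_key)
  )
}

# File line number of each GTF feature row (skipping comments/blank lines),
# for error messages that point at the offending record.
gtf_feature_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  which(!grepl("^\\s*(#|$)", raw))
}

#' Write an annotation back to GTF
#'
#' Inverse of [parse_te_gtf()]: emits one feature row per locus with the
#' same attribute keys, so that re-parsing reproduces the annotation.
#'
#' @inheritParams te_loci
#' @param path output file path.
#' @inheritParams parse_te_gtf
#' @return `path`, invisibly.
#' @export
write_te_gtf <- function(annotation, path, locus_key = "gene_id",
                         subfamily_key = "family_id",
                         class_key = "class_id") {
  stopifnot(is(annotation, "te_annotation"))
  df <- te_loci(annotation)
  attr_str <- paste0(
    locus_key, " \"", df$locus_id, "\"; ",
    subfamily_key, " \"", df$subfamily, "\";",
    ifelse(is.na(df$te_class), "",
           paste0(" ", class_key, " \"", df$te_class, "\";"))
  )
  rows <- paste(df$chrom, "loquaTE", "exon", df$start, df$end, ".",
                ifelse(df$strand == "*", ".", df$strand), ".", attr_str,
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Loci overlapping a genomic interval
#'
#' Interval query against the annotation index; used to attach alignments to
#' TE copies. Overlapping or nested copies are all returned — choosing among
#' them is the mixture model's job, not the annotation's.
#'
#' @inheritParams te_loci
#' @param chrom chromosome name; an unknown chromosome yields an empty
#'   result, not an error.
#' @param start,end query interval, 1-based closed, `start <= end`.
#' @param strand optional; if `"+"` or `"-"`, only loci on that strand (or
#'   unstranded loci) are returned. Default is strand-agnostic.
#' @return character vector of locus ids in genomic (start, end) order.
#' @export
overlapping_loci <- function(annotation, chrom, start, end, strand = NULL) {
  stopifnot(is(annotation, "te_annotation"), start <= end)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    q, annotation$granges, ignore.strand = TRUE))
  idx <- S4Vectors::subjectHits(hits)
  if (!is.null(strand) && strand %in% c("+", "-")) {
    locus_strand <- as.character(GenomicRanges::strand(annotation$granges))[idx]
    idx <- idx[locus_strand == strand | locus_strand == "*"]
  }
  idx <- idx[order(GenomicRanges::start(annotation$granges)[idx],
                   GenomicRanges::end(annotation$granges)[idx])]
  annotation$locus_id[idx]
}
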