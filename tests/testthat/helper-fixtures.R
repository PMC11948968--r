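# Shared fixtures: tiny annotations, GTF writers, random fragment matrices.

# three loci, two subfamilies, on one chromosome
toy_annotation <- function() {
  te_annotation(
    locus_id = c("AluY_1", "AluY_2", "L1_1"),
    chrom = "chr1",
    start = c(101, 301, 1001),
    end = c(200, 420, 1800),
    strand = c("+", "-", "+"),
    subfamily = c("AluY", "AluY", "L1HS")
  )
}

write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(c(
    'chr1\trmsk\texon\t101\t200\t.\t+\t.\tgene_id "AluY_1"; family_id "AluY";',
    'chr1\trmsk\texon\t301\t420\t.\t-\t.\tgene_id "AluY_2"; family_id "AluY";',
    'chr1\trmsk\texon\t1001\t1800\t.\t+\t.\tgene_id "L1_1"; family_id "L1HS";'
  ), path)
  path
}

# annotation with K loci in one subfamily (for mixture tests)
flat_annotation <- function(K, width = 1000) {
  starts <- seq(1, by = width + 100, length.out = K)
  te_annotation(
    locus_id = sprintf("T%d", seq_len(K)),
    chrom = "chrT", start = starts, end = starts + width - 1,
    strand = "+", subfamily = "SF"
  )
}

# random small annotation + candidate set + matching prior, for fuzz tests
random_instance <- function(seed) {
  set.seed(seed)
  K <- sample(2:6, 1)
  ann <- flat_annotation(K)
  N <- sample(5:30, 1)
  cand <- do.call(rbind, lapply(seq_len(N), function(a) {
    k <- sample(seq_len(K), sample(seq_len(K), 1))
    data.frame(fragment_id = sprintf("f%03d", a),
               locus_id = sprintf("T%d", k),
               score = sample(-30:0, length(k), replace = TRUE))
  }))
  tpm <- runif(K) * 100
  names(tpm) <- ann$locus_id
  list(ann = ann,
       fm = fragment_matrix(cand, ann),
       prior = subfamily_fractions(tpm, ann),
       tpm = tpm)
}

# fragment set for a K-locus mixture: origins drawn from `truth`; a fragment
# is fully ambiguous (equal scores on all loci) with probability `ambig`,
# otherwise uniquely mapped to its origin
mixture_candidates <- function(truth, N, ambig, seed, ann) {
  set.seed(seed)
  K <- length(truth)
  origin <- sample.int(K, N, replace = TRUE, prob = truth)
  is_ambig <- runif(N) < ambig
  ids <- sprintf("m%05d", seq_len(N))
  data.frame(
    fragment_id = c(rep(ids[is_ambig], each = K), ids[!is_ambig]),
    locus_id = c(rep(ann$locus_id, sum(is_ambig)),
                 ann$locus_id[origin[!is_ambig]]),
    score = 0,
    stringsAsFactors = FALSE
  )
}
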