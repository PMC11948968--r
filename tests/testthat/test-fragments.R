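test_that("score weights are exponential in the score gap with max 1", {
  expect_equal(score_to_weight(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(score_to_weight(c(0, -2), lambda = 0.5), c(1, exp(-1)))
  expect_equal(score_to_weight(3), 1)
  w <- score_to_weight(c(-4, -1, -9))
  expect_true(all(diff(order(w)) == diff(order(c(-4, -1, -9)))))
  expect_error(score_to_weight(numeric(0)), "empty")
})

test_that("fragment matrix sets multi-mapping indicators and best-score dedup", {
  ann <- toy_annotation()
  cand <- data.frame(
    fragment_id = c("f1", "f2", "f2", "f2", "f3", "f3"),
    locus_id = c("AluY_1", "AluY_1", "AluY_2", "L1_1", "L1_1", "L1_1"),
    score = c(0, 0, -6, -12, -5, -2)
  )
  fm <- fragment_matrix(cand, ann)
  expect_equal(fm$N, 3L)
  expect_equal(fm$y, c(0L, 1L, 0L))
  # duplicate (f3, L1_1) keeps the best score -> q = 1
  expect_equal(fm$q["f3", "L1_1"], 1)
  # weights decay from the per-fragment best
  expect_equal(fm$q["f2", "AluY_2"], exp(0.1 * -6))
  expect_equal(unname(Matrix::rowSums(fm$q > 0)), c(1, 3, 1))
})

test_that("matrix construction is independent of candidate row order", {
  ann <- toy_annotation()
  set.seed(3)
  cand <- data.frame(
    fragment_id = rep(sprintf("f%02d", 1:12), each = 2),
    locus_id = sample(ann$locus_id, 24, replace = TRUE),
    score = sample(-20:0, 24, replace = TRUE)
  )
  fm1 <- fragment_matrix(cand, ann)
  fm2 <- fragment_matrix(cand[sample.int(nrow(cand)), ], ann)
  expect_identical(fm1$q, fm2$q)
  expect_identical(fm1$y, fm2$y)
})

test_that("unknown candidate loci are rejected", {
  ann <- toy_annotation()
  expect_error(
    fragment_matrix(data.frame(fragment_id = "f1", locus_id = "nope",
                               score = 0), ann),
    "absent from annotation"
  )
})

test_that("SAM ingestion pairs mates, sums pair scores and drops non-TE fragments", {
  ann <- toy_annotation()
  sam <- tempfile(fileext = ".sam")
  q30 <- strrep("I", 10)
  seq10 <- strrep("A", 10)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:5000",
    # pair inside AluY_1 (unique)
    paste("u1", 99, "chr1", 110, 255, "10M", "=", 150, 50, seq10, q30,
          "AS:i:0", sep = "\t"),
    paste("u1", 147, "chr1", 150, 255, "10M", "=", 110, -50, seq10, q30,
          "AS:i:-6", sep = "\t"),
    # pair hitting both AluY copies (multi): primary + secondary
    paste("m1", 99, "chr1", 120, 255, "10M", "=", 160, 50, seq10, q30,
          "AS:i:0", sep = "\t"),
    paste("m1", 147, "chr1", 160, 255, "10M", "=", 120, -50, seq10, q30,
          "AS:i:0", sep = "\t"),
    paste("m1", 355, "chr1", 320, 0, "10M", "=", 360, 50, seq10, q30,
          "AS:i:-6", sep = "\t"),
    paste("m1", 403, "chr1", 360, 0, "10M", "=", 320, -50, seq10, q30,
          "AS:i:-12", sep = "\t"),
    # pair outside any TE locus: dropped
    paste("x1", 99, "chr1", 2500, 255, "10M", "=", 2540, 50, seq10, q30,
          "AS:i:0", sep = "\t"),
    paste("x1", 147, "chr1", 2540, 255, "10M", "=", 2500, -50, seq10, q30,
          "AS:i:0", sep = "\t")
  ), sam)
  fm <- ingest_alignments(sam, ann)
  expect_equal(fm$N, 2L)
  expect_setequal(fm$fragment_id, c("u1", "m1"))
  expect_equal(fm$y[fm$fragment_id == "u1"], 0L)
  expect_equal(fm$y[fm$fragment_id == "m1"], 1L)
  # pair scores: m1 on AluY_1 = 0 + 0; on AluY_2 = -6 + -12 = -18
  expect_equal(fm$q["m1", "AluY_1"], 1)
  expect_equal(fm$q["m1", "AluY_2"], exp(0.1 * -18))
  expect_equal(fm$q["m1", "L1_1"], 0)
})

test_that("file-based ingestion reproduces the in-memory candidate path", {
  cfg <- sim_config(n_subfamilies = 2, copies_per_subfamily = 3,
                    consensus_length = 400, n_fragments = 300, seed = 5)
  truth <- make_te_genome(cfg)
  sim <- simulate_fragments(truth, cfg)
  aln <- synthetic_align(sim, truth)
  fm_mem <- fragment_matrix(aln[, c("fragment_id", "locus_id", "score")],
                            truth$annotation)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, truth, sam)
  fm_sam <- ingest_alignments(sam, truth$annotation)
  expect_identical(fm_mem$fragment_id, fm_sam$fragment_id)
  expect_identical(fm_mem$y, fm_sam$y)
  expect_equal(fm_mem$q, fm_sam$q, tolerance = 1e-12)
})

test_that("fragment matrix TSV dump lists every candidate with its weight", {
  ann <- toy_annotation()
  cand <- data.frame(fragment_id = c("f1", "f1", "f2"),
                     locus_id = c("AluY_1", "AluY_2", "L1_1"),
                     score = c(0, -6, 0))
  fm <- fragment_matrix(cand, ann)
  path <- tempfile(fileext = ".tsv")
  write_fragment_tsv(fm, path)
  dump <- read.delim(path)
  expect_equal(nrow(dump), 3L)
  expect_equal(dump$y[dump$fragment_id == "f1"], c(1L, 1L))
})
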