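test_that("zero divergence yields identical copies; positive divergence matches its rate", {
  cfg0 <- sim_config(n_subfamilies = 1, copies_per_subfamily = 4,
                     consensus_length = 600, divergence = 0, seed = 2)
  t0 <- make_te_genome(cfg0)
  expect_length(unique(unname(t0$copy_seq)), 1L)
  cfg1 <- sim_config(n_subfamilies = 1, copies_per_subfamily = 20,
                     consensus_length = 1000, divergence = 0.1, seed = 2)
  t1 <- make_te_genome(cfg1)
  cons <- strsplit(t1$consensus[["SF1"]], "")[[1]]
  mismatch <- vapply(t1$copy_seq, function(s) {
    mean(strsplit(s, "")[[1]] != cons)
  }, numeric(1))
  expect_equal(mean(mismatch), 0.10, tolerance = 0.02)
})

test_that("the generator is deterministic per seed", {
  cfg <- sim_config(n_fragments = 200, consensus_length = 400, seed = 12)
  a <- make_te_genome(cfg)
  b <- make_te_genome(cfg)
  expect_identical(a$copy_seq, b$copy_seq)
  expect_identical(a$truth_tpm, b$truth_tpm)
  d1 <- file.path(tempdir(), "bndl1"); d2 <- file.path(tempdir(), "bndl2")
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("fragments follow the truth profile with correct read geometry", {
  cfg <- sim_config(n_subfamilies = 1, copies_per_subfamily = 2,
                    consensus_length = 1000, divergence = 0.05,
                    n_fragments = 10000, silent_fraction = 0, seed = 8)
  truth <- make_te_genome(cfg)
  # impose a controlled 2:1 expression ratio on equal-length loci
  truth$truth_tpm <- setNames(c(2e6, 1e6) / 3, names(truth$truth_tpm))
  sim <- simulate_fragments(truth, cfg)
  expect_true(all(nchar(sim$fragments$r1) == 76))
  expect_true(all(nchar(sim$fragments$r2) == 76))
  counts <- table(factor(sim$fragments$locus_id,
                         levels = names(truth$truth_tpm)))
  share <- counts[[1]] / sum(counts)
  expect_equal(share, 2 / 3, tolerance = 4 * sqrt(2 / 9 / 10000))
  # silent loci emit nothing
  cfg2 <- sim_config(n_fragments = 500, seed = 3)
  t2 <- make_te_genome(cfg2)
  s2 <- simulate_fragments(t2, cfg2)
  silent <- names(t2$truth_tpm)[t2$truth_tpm == 0]
  expect_false(any(s2$fragments$locus_id %in% silent))
  # the long-read table converts back to the truth TPM exactly
  lr_tpm <- counts_to_tpm(s2$longread$count,
                          locus_lengths(t2$annotation)[s2$longread$locus_id])
  expect_equal(unname(lr_tpm), unname(t2$truth_tpm[s2$longread$locus_id]),
               tolerance = 1e-9)
})

test_that("string-matching alignment always contains the origin and tracks divergence", {
  cfg <- sim_config(n_subfamilies = 1, copies_per_subfamily = 4,
                    consensus_length = 500, divergence = 0,
                    n_fragments = 200, silent_fraction = 0, seed = 4)
  truth <- make_te_genome(cfg)
  sim <- simulate_fragments(truth, cfg)
  aln <- synthetic_align(sim, truth)
  # identical copies: every fragment hits all four with equal (zero) scores
  expect_true(all(table(aln$fragment_id) == 4))
  expect_true(all(aln$score == 0))
  # origin among candidates, always
  hit <- merge(sim$fragments[, c("fragment_id", "locus_id")], aln,
               by = c("fragment_id", "locus_id"))
  expect_equal(nrow(hit), nrow(sim$fragments))
  # high divergence: most fragments are uniquely mapped
  cfgd <- sim_config(n_subfamilies = 1, copies_per_subfamily = 4,
                     consensus_length = 500, divergence = 0.2,
                     n_fragments = 200, silent_fraction = 0, seed = 4)
  td <- make_te_genome(cfgd)
  sd <- simulate_fragments(td, cfgd)
  ad <- synthetic_align(sd, td)
  expect_gt(mean(table(ad$fragment_id) == 1), 0.5)
})

test_that("coverage scaling ratio is the floor of the base-count quotient", {
  expect_identical(coverage_scale_ratio(2277300856, 95915952), 23L)
  expect_identical(coverage_scale_ratio(1000, 1000), 1L)
  expect_identical(coverage_scale_ratio(0, 5), 0L)
  expect_error(coverage_scale_ratio(10, 0), "positive")
})

test_that("confusion matrices tally detection against the truth", {
  truth <- c(a = 5, b = 2, c = 0, d = 0, e = 1)
  perfect <- evaluate_confusion(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$F1, 1)
  est <- c(a = 1, b = 0, c = 3, d = 0, e = 2)
  cf <- evaluate_confusion(est, truth)
  expect_equal(cf$TP, 2); expect_equal(cf$FP, 1)
  expect_equal(cf$FN, 1); expect_equal(cf$TN, 1)
  expect_equal(cf$precision, 2 / 3, tolerance = 1e-9)
  expect_equal(cf$TP + cf$TN + cf$FP + cf$FN, cf$n)
  # degenerate: nothing detected
  zero <- evaluate_confusion(setNames(numeric(5), names(truth)), truth)
  expect_equal(zero$recall, 0)
  expect_equal(zero$precision, 0)
  expect_true(zero$degenerate)
  # inclusion mask restricts the universe
  masked <- evaluate_confusion(est, truth, mask = c("a", "b", "c"))
  expect_equal(masked$n, 3)
  expect_error(evaluate_confusion(est[1:4], truth), "mismatch")
})

test_that("invalid simulation configurations are rejected up front", {
  expect_error(sim_config(divergence = 0.5), "0.5")
  expect_error(sim_config(read_length = 300, fragment_size = 200),
               "read_length")
  expect_error(sim_config(fragment_size = 2000), "consensus_length")
})

test_that("the written bundle is parseable by the ingestion modules", {
  cfg <- sim_config(n_subfamilies = 2, copies_per_subfamily = 3,
                    consensus_length = 400, n_fragments = 250, seed = 6)
  dir <- file.path(tempdir(), "bundle_parse")
  b <- simulate_bundle(cfg, dir)
  ann <- parse_te_gtf(b$paths[["gtf"]])
  expect_equal(length(ann), 6L)
  expect_equal(te_loci(ann)$length,
               unname(nchar(b$truth$copy_seq)))
  genome <- Biostrings::readDNAStringSet(b$paths[["genome"]])
  df <- te_loci(ann)
  seqs <- substring(as.character(genome[["chrS"]]), df$start, df$end)
  expect_identical(unname(seqs), unname(b$truth$copy_seq[df$locus_id]))
  fm <- ingest_alignments(b$paths[["sam"]], ann)
  expect_equal(fm$N, nrow(b$sim$fragments))
  pr <- long_read_prior(b$paths[["longread"]], ann)
  expect_equal(sum(pr$tpm), 1e6, tolerance = 1e-6)
})
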