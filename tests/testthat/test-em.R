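ann3 <- flat_annotation(3)

test_that("initialization assigns equal weights to each fragment's candidates", {
  cand <- data.frame(
    fragment_id = c("f1", "f1", "f1", "f2"),
    locus_id = c("T1", "T2", "T3", "T2"),
    score = 0
  )
  fm <- fragment_matrix(cand, ann3)
  st <- em_initialize(fm)
  expect_equal(unname(as.vector(st$E["f1", ])), rep(1 / 3, 3))
  expect_equal(unname(as.vector(st$E["f2", ])), c(0, 1, 0))
  expect_equal(unname(st$pi), rep(1 / 3, 3))
  expect_equal(unname(st$theta), rep(1 / 3, 3))
  ann4 <- flat_annotation(4)
  fm4 <- fragment_matrix(data.frame(fragment_id = "f1", locus_id = "T1",
                                    score = 0), ann4)
  expect_equal(unname(em_initialize(fm4)$pi), rep(0.25, 4))
})

test_that("E-step posterior is proportional to q * pi * theta^y", {
  ann2 <- flat_annotation(2)
  fm <- fragment_matrix(data.frame(
    fragment_id = c("f1", "f1", "f2"),
    locus_id = c("T1", "T2", "T1"),
    score = 0
  ), ann2)
  st <- em_initialize(fm)
  # uniform parameters, equal q -> uniform posterior
  st1 <- em_e_step(st, fm)
  expect_equal(unname(as.vector(st1$E["f1", ])), c(0.5, 0.5))
  # skewed pi with uniform theta and equal q -> posterior follows pi
  st$pi <- setNames(c(0.9, 0.1), fm$locus_id)
  st2 <- em_e_step(st, fm)
  expect_equal(unname(as.vector(st2$E["f1", ])), c(0.9, 0.1))
  # unique fragments are pinned regardless of pi
  expect_equal(unname(as.vector(st2$E["f2", ])), c(1, 0))
})

test_that("MAP M-step reproduces the hand-derived two-locus case exactly", {
  ann2 <- flat_annotation(2)
  fm <- fragment_matrix(data.frame(
    fragment_id = c("f1", "f1"), locus_id = c("T1", "T2"), score = 0
  ), ann2)
  st <- em_initialize(fm)          # E = (0.5, 0.5), y = 1
  prior <- subfamily_fractions(c(T1 = 8, T2 = 0), ann2)  # t^Lf = (1, 0)
  st2 <- em_m_step(st, fm, prior, em_params(long_read_weight = 1))
  # rational-arithmetic oracle: (1/2 + 1*1*1)/(1 + 1*1*1) and (1/2 + 0)/2
  oracle <- map_update_rational(E_num = c(1, 1), E_den = c(2, 2), w = 1,
                                f_num = c(1, 0), f_den = c(1, 1))
  expect_equal(oracle, c(0.75, 0.25))
  expect_equal(unname(st2$pi), oracle)
  expect_equal(unname(st2$theta), oracle)
})

test_that("weight 0 reduces the M-step to the data-only estimate", {
  inst <- random_instance(21)
  st <- em_initialize(inst$fm)
  st <- em_e_step(st, inst$fm)
  st0 <- em_m_step(st, inst$fm, inst$prior, em_params(long_read_weight = 0))
  expect_equal(unname(st0$pi),
               unname(Matrix::colSums(st$E)) / inst$fm$N, tolerance = 1e-12)
})

test_that("prior_change routes the prior to the chosen parameter only", {
  inst <- random_instance(22)
  st <- em_e_step(em_initialize(inst$fm), inst$fm)
  w0 <- em_m_step(st, inst$fm, inst$prior, em_params(long_read_weight = 0))
  pi_only <- em_m_step(st, inst$fm, inst$prior,
                       em_params(long_read_weight = 1, prior_change = "pi"))
  both <- em_m_step(st, inst$fm, inst$prior,
                    em_params(long_read_weight = 1, prior_change = "both"))
  expect_equal(pi_only$theta, w0$theta)
  expect_false(isTRUE(all.equal(pi_only$pi, w0$pi)))
  expect_equal(pi_only$pi, both$pi)
  none <- em_m_step(st, inst$fm, inst$prior,
                    em_params(long_read_weight = 1, prior_change = "none"))
  expect_equal(none$pi, w0$pi)
})

test_that("symmetric data converge to the symmetric fixed point", {
  ann2 <- flat_annotation(2)
  cand <- data.frame(
    fragment_id = rep(sprintf("f%d", 1:10), each = 2),
    locus_id = rep(c("T1", "T2"), 10),
    score = 0
  )
  fm <- fragment_matrix(cand, ann2)
  prior <- subfamily_fractions(c(T1 = 5, T2 = 5), ann2)
  st <- run_em(fm, prior, em_params())
  expect_true(st$converged)
  expect_equal(unname(st$pi), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("the prior-free fit matches an independently coded dense EM", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 100)
    params <- em_params(long_read_weight = 0, epsilon = 1e-10,
                       max_iter = 200)
    st <- run_em(inst$fm, inst$prior, params)
    oracle <- dense_em_oracle(as.matrix(inst$fm$q), inst$fm$y,
                              epsilon = 1e-10, max_iter = 200)
    expect_equal(unname(st$pi), oracle$pi, tolerance = 1e-8)
    expect_equal(unname(st$theta), oracle$theta, tolerance = 1e-8)
  }
})

test_that("an overwhelming weight drives pi to the normalized prior", {
  inst <- random_instance(33)
  f <- inst$prior$fraction
  st <- run_em(inst$fm, inst$prior,
               em_params(long_read_weight = 1e9, max_iter = 1))
  expect_equal(unname(st$pi), f / sum(f), tolerance = 1e-4)
})

test_that("increasing weight pulls pi monotonically toward the prior", {
  inst <- random_instance(44)
  st <- em_e_step(em_initialize(inst$fm), inst$fm)
  f <- inst$prior$fraction
  target <- f / sum(f)
  tv <- vapply(c(0, 0.25, 0.5, 1, 2, 8, 64), function(w) {
    up <- em_m_step(st, inst$fm, inst$prior, em_params(long_read_weight = w))
    sum(abs(unname(up$pi) - target)) / 2
  }, numeric(1))
  expect_true(all(diff(tv) <= 1e-12))
})

test_that("identical inputs give bitwise-identical trajectories", {
  inst <- random_instance(55)
  a <- run_em(inst$fm, inst$prior, em_params())
  b <- run_em(inst$fm, inst$prior, em_params())
  expect_identical(a$pi, b$pi)
  expect_identical(a$trace, b$trace)
  expect_identical(as.vector(a$E), as.vector(b$E))
})

test_that("non-convergence within max_iter is flagged, not an error", {
  inst <- random_instance(66)
  st <- run_em(inst$fm, inst$prior, em_params(epsilon = 1e-15, max_iter = 3))
  expect_false(st$converged)
  expect_equal(st$iterations, 3L)
})
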