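#' EM parameter set
#'
#' Tuning parameters for the prior-weighted EM fit.
#'
#' @param long_read_weight weight `w >= 0` of the long-read prior term in
#'   the MAP updates. 1 (default) weights the prior as strongly as the
#'   data; 0 removes it (prior-free EM). Weights below 0.5 or above 1.0
#'   have been observed to reduce accuracy with mismatched long-read
#'   samples and trigger a caution in [quantify_te()].
#' @param prior_change which parameter receives the prior term: `"both"`
#'   (default), `"pi"`, `"theta"`, or `"none"` (equivalent to `w = 0`,
#'   provided for A/B comparisons).
#' @param epsilon convergence tolerance: iteration stops when the largest
#'   absolute change over the concatenation of pi and theta falls below
#'   `epsilon` (default 0.001).
#' @param max_iter maximum EM iterations (default 100).
#' @param seed optional integer seed recorded for provenance (the EM itself
#'   is deterministic; the seed is consumed by tie-breaking in
#'   [final_counts()]).
#' @return object of class `em_params`.
#' @export
em_params <- function(long_read_weight = 1, prior_change = "both",
                      epsilon = 0.001, max_iter = 100, seed = NULL) {
  prior_change <- match.arg(prior_change, c("both", "pi", "theta", "none"))
  stopifnot(long_read_weight >= 0, epsilon > 0, max_iter >= 1)
  structure(
    list(long_read_weight = long_read_weight, prior_change = prior_change,
         epsilon = epsilon, max_iter = max_iter, seed = seed),
    class = "em_params"
  )
}

# ---- internal vectorized machinery over the sparse triplet view ----------

# triplets of fm$q ordered canonically by (fragment row, locus column)
fm_triplets <- function(fm) {
  tri <- Matrix::summary(fm$q)
  ord <- order(tri$i, tri$j)
  list(i = tri$i[ord], j = tri$j[ord], q = tri$x[ord],
       groups = split(seq_along(ord), tri$i[ord]))
}

# group-wise sum of x by index idx into a length-n vector
sum_by <- function(x, idx, n) {
  out <- numeric(n)
  t <- rowsum(x, idx)
  out[as.integer(rownames(t))] <- t
  out
}

# E-step on triplets: posterior ∝ q * pi * theta^y, normalized per fragment.
# Division by the per-fragment max guards against underflow; a fragment whose
# weights all underflow to zero falls back to uniform with a warning.
e_step_vec <- function(tr, y, pi, theta, N) {
  w <- tr$q * pi[tr$j]
  multi <- y[tr$i] == 1L
  w[multi] <- w[multi] * theta[tr$j][multi]
  mx <- vapply(tr$groups, function(ix) max(w[ix]), numeric(1))
  bad <- which(!(mx > 0))
  if (length(bad)) {
    warning(length(bad), " fragment(s) with all-zero posterior weight; ",
            "falling back to uniform assignment")
    for (b in bad) w[tr$groups[[b]]] <- 1
    mx[bad] <- 1
  }
  w <- w / mx[tr$i]
  s <- sum_by(w, tr$i, N)
  w / s[tr$i]
}

# MAP M-step: prior-weighted updates for pi and theta.
# S = sum of prior fractions over all loci is taken literally from the
# update formulas (it equals the number of subfamilies with prior mass).
m_step_vec <- function(ex, tr, y, K, f, w_pi, w_theta) {
  total <- sum(ex)                      # equals N: rows are normalized
  S <- sum(f)
  cs <- sum_by(ex, tr$j, K)
  pi <- (cs + w_pi * total * f) / (total + w_pi * total * S)
  M <- sum(y)
  if (M == 0L) {
    theta <- rep(1 / K, K)
  } else {
    csy <- sum_by(ex * (y[tr$i] == 1L), tr$j, K)
    theta <- (csy + w_theta * M * f) / (M + w_theta * M * S)
  }
  list(pi = pi, theta = theta, M = M)
}

# effective prior weights per prior_change mode
effective_weights <- function(params) {
  w <- params$long_read_weight
  switch(params$prior_change,
         both = c(w, w),
         pi = c(w, 0),
         theta = c(0, w),
         none = c(0, 0))
}

# align a prior (te_prior, named or plain vector) to the matrix locus order
align_prior <- function(prior, locus_id, what = "fraction") {
  if (is(prior, "te_prior")) {
    v <- setNames(prior[[what]], prior$locus_id)[locus_id]
    if (anyNA(v)) stop("prior is missing loci present in the matrix")
    return(as.numeric(v))
  }
  if (is.numeric(prior)) {
    if (!is.null(names(prior))) {
      v <- prior[locus_id]
      if (anyNA(v)) stop("prior vector is missing loci: unnamed entries")
      return(as.numeric(v))
    }
    if (length(prior) != length(locus_id)) {
      stop("unnamed prior vector must have one entry per locus")
    }
    return(as.numeric(prior))
  }
  stop("prior must be a te_prior or a numeric vector")
}

# rebuild a sparse E matrix over the q pattern
e_matrix <- function(fm, tr, ex) {
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = ex,
                       dims = c(fm$N, fm$K),
                       dimnames = list(fm$fragment_id, fm$locus_id))
}

# ---- exported module surface ---------------------------------------------

#' Initialize the EM state
#'
#' Equal-weight initialization: each fragment's posterior is uniform over
#' its candidate loci (e.g. 1/3 each for a fragment hitting three copies),
#' and pi and theta start uniform over the K loci.
#'
#' @param fm a [fragment_matrix()].
#' @return object of class `em_state` with elements `pi`, `theta`, `E`
#'   (sparse posterior matrix), `iterations`, `converged`, `trace`.
#' @export
em_initialize <- function(fm) {
  stopifnot(is(fm, "fragment_matrix"))
  if (fm$K == 0) stop("annotation has no loci (K = 0)")
  if (fm$N == 0) stop("fragment matrix is empty")
  tr <- fm_triplets(fm)
  n_cand <- tabulate(tr$i, fm$N)
  ex <- 1 / n_cand[tr$i]
  structure(
    list(pi = setNames(rep(1 / fm$K, fm$K), fm$locus_id),
         theta = setNames(rep(1 / fm$K, fm$K), fm$locus_id),
         E = e_matrix(fm, tr, ex),
         iterations = 0L, converged = NA, max_delta = NA_real_,
         trace = data.frame(iteration = integer(), max_delta = numeric())),
    class = "em_state"
  )
}

#' @export
print.em_state <- function(x, ...) {
  cat("em_state:", length(x$pi), "loci;", x$iterations, "iterations;",
      if (isTRUE(x$converged)) "converged" else "not converged",
      sprintf("(last max delta %.3g)\n", x$max_delta))
  invisible(x)
}

#' E-step: posterior fragment-assignment weights
#'
#' For each fragment a and candidate locus i, the posterior assignment
#' weight is proportional to `q_{a,i} * pi_i * theta_i^{y_a}` and is
#' normalized over the fragment's candidates; a uniquely mapped fragment
#' keeps weight 1 on its sole candidate.
#'
#' @param state an `em_state`.
#' @param fm the [fragment_matrix()] the state was built from.
#' @return the state with `E` updated.
#' @export
em_e_step <- function(state, fm) {
  stopifnot(is(state, "em_state"), is(fm, "fragment_matrix"))
  tr <- fm_triplets(fm)
  ex <- e_step_vec(tr, fm$y, state$pi, state$theta, fm$N)
  state$E <- e_matrix(fm, tr, ex)
  state
}

#' M-step: MAP updates for pi and theta with the long-read prior
#'
#' Computes the maximum a posteriori updates
#' \deqn{\hat\pi_i = \frac{\sum_a E_{a,i} + (w T)\, f_i}{T + (w T) \sum_i f_i},
#'   \qquad
#'   \hat\theta_i = \frac{\sum_a E_{a,i} y_a + (w M)\, f_i}{M + (w M) \sum_i f_i}}
#' where `f_i` is the subfamily-normalized long-read TPM fraction of locus
#' i, `T` the total posterior mass (= number of fragments), `M` the number
#' of multi-mapped fragments, and `w` the long-read weight. `prior_change`
#' selects which of the two updates receives the prior term (the other uses
#' `w = 0`). With no multi-mapped fragments theta is uniform.
#'
#' @inheritParams em_e_step
#' @param prior a `te_prior` from [subfamily_fractions()] /
#'   [long_read_prior()], or a numeric fraction vector.
#' @param params an [em_params()].
#' @return the state with `pi` and `theta` updated.
#' @export
em_m_step <- function(state, fm, prior, params = em_params()) {
  stopifnot(is(state, "em_state"), is(fm, "fragment_matrix"))
  tr <- fm_triplets(fm)
  # posterior values on the q pattern, robust to dropped explicit zeros
  ex <- as.numeric(state$E[cbind(tr$i, tr$j)])
  f <- align_prior(prior, fm$locus_id)
  ww <- effective_weights(params)
  res <- m_step_vec(ex, tr, fm$y, fm$K, f, ww[1], ww[2])
  if (res$M == 0L) message("no multi-mapped fragments: theta set uniform")
  state$pi <- setNames(res$pi, fm$locus_id)
  state$theta <- setNames(res$theta, fm$locus_id)
  state
}

#' Fit the prior-weighted EM
#'
#' Alternates M-steps ([em_m_step()]) and E-steps ([em_e_step()]) from the
#' equal-weight initialization until the largest absolute change across pi
#' and theta drops below `params$epsilon`, or `params$max_iter` is reached
#' (the state is then flagged non-converged, not an error).
#'
#' @inheritParams em_m_step
#' @param fm a [fragment_matrix()].
#' @return a converged (or flagged) `em_state`; `trace` holds the
#'   per-iteration maximum parameter change.
#' @export
run_em <- function(fm, prior, params = em_params()) {
  stopifnot(is(fm, "fragment_matrix"))
  tr <- fm_triplets(fm)
  f <- align_prior(prior, fm$locus_id)
  ww <- effective_weights(params)
  n_cand <- tabulate(tr$i, fm$N)
  ex <- 1 / n_cand[tr$i]
  pi <- rep(1 / fm$K, fm$K)
  theta <- rep(1 / fm$K, fm$K)
  trace <- data.frame(iteration = integer(), max_delta = numeric())
  converged <- FALSE
  delta <- NA_real_
  iter <- 0L
  m_logged <- FALSE
  while (iter < params$max_iter) {
    iter <- iter + 1L
    res <- m_step_vec(ex, tr, fm$y, fm$K, f, ww[1], ww[2])
    if (res$M == 0L && !m_logged) {
      message("no multi-mapped fragments: theta set uniform")
      m_logged <- TRUE
    }
    delta <- max(abs(res$pi - pi), abs(res$theta - theta))
    pi <- res$pi
    theta <- res$theta
    ex <- e_step_vec(tr, fm$y, pi, theta, fm$N)
    trace <- rbind(trace, data.frame(iteration = iter, max_delta = delta))
    if (delta < params$epsilon) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(pi = setNames(pi, fm$locus_id),
         theta = setNames(theta, fm$locus_id),
         E = e_matrix(fm, tr, ex),
         iterations = iter, converged = converged, max_delta = delta,
         trace = trace, params = params),
    class = "em_state"
  )
}

#' Fraction of multi-mapped fragments with tied best posteriors
#'
#' Diagnostic for residual assignment ambiguity: among multi-mapped
#' fragments, the share whose posterior has two or more best candidates
#' within a relative tolerance — cases where the EM cannot name a single
#' genomic origin. An informative long-read prior reduces this share.
#'
#' @param state an `em_state`.
#' @param fm the matching [fragment_matrix()].
#' @param tol relative tolerance for calling two posteriors tied
#'   (default 1e-6).
#' @return fraction in \[0, 1\] (0 when there are no multi-mapped
#'   fragments).
#' @export
tied_best_fraction <- function(state, fm, tol = 1e-6) {
  stopifnot(is(state, "em_state"), is(fm, "fragment_matrix"))
  if (sum(fm$y) == 0L) return(0)
  ex <- Matrix::summary(state$E)
  multi <- fm$y[ex$i] == 1L
  vals <- split(ex$x[multi], ex$i[multi])
  tied <- vapply(vals, function(v) {
    v <- sort(v, decreasing = TRUE)
    length(v) >= 2 && v[2] >= v[1] * (1 - tol)
  }, logical(1))
  mean(tied)
}
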