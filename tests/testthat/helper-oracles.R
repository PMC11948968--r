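# Independent oracles the implementation is checked against.

# O(K) brute-force interval intersection over all loci (1-based closed)
brute_overlaps <- function(annotation, chrom, qs, qe) {
  df <- te_loci(annotation)
  hit <- df$chrom == chrom & df$start <= qe & df$end >= qs
  df <- df[hit, ]
  df$locus_id[order(df$start, df$end)]
}

# Dense, prior-free EM coded independently of the package internals:
# plain matrices, explicit loops, same update equations with w = 0.
dense_em_oracle <- function(q, y, epsilon = 1e-10, max_iter = 200) {
  N <- nrow(q); K <- ncol(q)
  E <- matrix(0, N, K)
  for (a in seq_len(N)) {
    cand <- which(q[a, ] > 0)
    E[a, cand] <- 1 / length(cand)
  }
  pi <- rep(1 / K, K)
  theta <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    cs <- colSums(E)
    pi_new <- cs / sum(E)
    M <- sum(y)
    theta_new <- if (M == 0) rep(1 / K, K) else colSums(E[y == 1, , drop = FALSE]) / M
    delta <- max(abs(pi_new - pi), abs(theta_new - theta))
    pi <- pi_new; theta <- theta_new
    for (a in seq_len(N)) {
      w <- q[a, ] * pi * if (y[a] == 1) theta else 1
      w[q[a, ] == 0] <- 0
      E[a, ] <- w / sum(w)
    }
    if (delta < epsilon) break
  }
  list(pi = pi, theta = theta, E = E, iterations = it)
}

# Exact rational arithmetic (integer num/den pairs) for hand-derivable
# M-step cases; independent of any floating-point path.
frac <- function(num, den = 1) {
  num <- unname(num); den <- unname(den)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  s <- if (den < 0) -1 else 1
  d <- g(abs(num), abs(den))
  if (d == 0) d <- 1
  c(num = s * num / d, den = s * den / d)
}
frac_add <- function(x, y) frac(x["num"] * y["den"] + y["num"] * x["den"],
                                x["den"] * y["den"])
frac_div <- function(x, y) frac(x["num"] * y["den"], x["den"] * y["num"])
frac_mul <- function(x, y) frac(x["num"] * y["num"], x["den"] * y["den"])
frac_val <- function(x) unname(x["num"] / x["den"])

# pi-hat_i for one multi-mapped fragment, all quantities rational:
# (E_i + w*T*f_i) / (T + w*T*S), with T and the prior terms as fractions
map_update_rational <- function(E_num, E_den, w, f_num, f_den) {
  K <- length(E_num)
  Tm <- Reduce(frac_add, lapply(seq_len(K),
                                function(i) frac(E_num[i], E_den[i])))
  S <- Reduce(frac_add, lapply(seq_len(K),
                               function(i) frac(f_num[i], f_den[i])))
  den <- frac_add(Tm, frac_mul(frac_mul(frac(w), Tm), S))
  vapply(seq_len(K), function(i) {
    num <- frac_add(frac(E_num[i], E_den[i]),
                    frac_mul(frac_mul(frac(w), Tm), frac(f_num[i], f_den[i])))
    frac_val(frac_div(num, den))
  }, numeric(1))
}
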