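# Independent oracles and small fixture builders used across the suite.

# observed-data log-likelihood of the two-component equal-variance mixture
mix_loglik <- function(x, pi, mu_low, mu_high, sigma) {
  sum(log(pi * dnorm(x, mu_low, sigma) + (1 - pi) * dnorm(x, mu_high, sigma)))
}

# dense grid search over (pi, mu_low, mu_high, sigma); returns the best
# log-likelihood found. Brute force, independent of the EM path.
grid_search_loglik <- function(x, n_mu = 24, n_sigma = 18,
                               pis = seq(0.05, 0.95, by = 0.05)) {
  mus <- seq(min(x), max(x), length.out = n_mu)
  sds <- seq(sd(x) / 12, sd(x) * 1.3, length.out = n_sigma)
  best <- -Inf
  for (p in pis) for (i in seq_len(n_mu)) for (j in i:n_mu) for (s in sds) {
    ll <- mix_loglik(x, p, mus[i], mus[j], s)
    if (ll > best) best <- ll
  }
  best
}

# textbook step-up construction of Benjamini-Hochberg q-values
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# exhaustive upper-tail hypergeometric probability via choose()
hyper_tail_oracle <- function(a, K, N, n) {
  ks <- max(a, 0):min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# numeric root of pi*N(x; mu_l, s^2) = (1-pi)*N(x; mu_h, s^2) by bisection
boundary_bisect_oracle <- function(pi, mu_l, mu_h, s) {
  g <- function(x) log(pi) - (x - mu_l)^2 / (2 * s^2) -
    log(1 - pi) + (x - mu_h)^2 / (2 * s^2)
  lo <- mu_l - 50 * s - abs(mu_l); hi <- mu_h + 50 * s + abs(mu_h)
  uniroot(g, c(lo, hi), extendInt = "yes", tol = 1e-12)$root
}

# write a genes x samples matrix as the expression TSV dialect
write_expr_tsv <- function(values, path) {
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_sheet_tsv <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# paired cohort straight from two matrices (same dimnames discipline as the
# generator): genes x pairs, tumour and normal
toy_cohort <- function(tumour, normal, units = "LOG2TPM1") {
  n <- ncol(tumour)
  patients <- sprintf("P%03d", seq_len(n))
  colnames(tumour) <- paste0(patients, "_T")
  colnames(normal) <- paste0(patients, "_N")
  structure(list(tumour = expr_matrix(tumour, units),
                 normal = expr_matrix(normal, units),
                 patient_ids = patients, dropped_patients = character(0)),
            class = "paired_cohort")
}
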