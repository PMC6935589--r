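# Independent oracle implementations used across tests. These deliberately
# re-derive each quantity by a different route than the package code.

# Weir-Cockerham (1984) two-deme variance components, written loop-wise from
# the published formulas for samples of allele copies.
oracle_wc84_fst <- function(a1, n1, a2, n2) {
  num <- 0; den <- 0
  for (l in seq_along(a1)) {
    if (n1[l] == 0 || n2[l] == 0) next
    p <- c(a1[l] / n1[l], a2[l] / n2[l])
    n <- c(n1[l], n2[l])
    r <- 2
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2)
    num <- num + a
    den <- den + a + b
  }
  num / den
}

# Numerical-integration oracle for the Zellner g-prior Bayes factor: the
# intercept is marginalized analytically under its flat prior; the slope
# (g-prior) and sigma (Jeffreys on sigma^2) are integrated numerically.
oracle_bf_quadrature <- function(y, x0, x1, g) {
  n <- length(y)
  q0 <- qr(cbind(x0))
  z <- qr.resid(q0, y)
  xt1 <- qr.resid(q0, x1)
  s11 <- sum(xt1^2)
  bhat <- sum(xt1 * z) / s11
  rssf <- sum((z - bhat * xt1)^2)
  rss0 <- sum(z^2)
  sig <- sqrt(rssf / (n - 2))
  C <- -(n - 1) * log(sig) - rssf / (2 * sig^2)
  f1 <- function(b, s) exp(-(n - 1) * log(s) -
                             sum((z - b * xt1)^2) / (2 * s^2) - C) *
    stats::dnorm(b, 0, sqrt(g) * s / sqrt(s11)) * 2 / s
  f0 <- function(s) exp(-(n - 1) * log(s) - rss0 / (2 * s^2) - C) * 2 / s
  bs <- 25 * sig / sqrt(s11)
  m1 <- stats::integrate(Vectorize(function(s)
    stats::integrate(Vectorize(function(b) f1(b, s)), bhat - bs, bhat + bs,
                     rel.tol = 1e-11)$value),
    sig / 10, sig * 12, rel.tol = 1e-10)$value
  m0 <- stats::integrate(Vectorize(f0), sig / 10, sig * 12,
                         rel.tol = 1e-10)$value
  m1 / m0
}

# tiny genotype_counts builder for toy cases
toy_counts <- function(alt, n) {
  alt <- as.matrix(alt); n <- as.matrix(n)
  rownames(alt) <- rownames(n) <- sprintf("P%d", seq_len(nrow(alt)))
  colnames(alt) <- colnames(n) <- sprintf("L%d", seq_len(ncol(alt)))
  genotype_counts(alt, n)
}

# run the GEA -> BLUP stages on a simulated dataset, mirroring the study
# pipeline (used by recovery experiments)
fit_sim_pipeline <- function(sim, min_loci = 6) {
  freqs <- compute_frequencies(sim$counts)
  env <- standardize_env(sim$env_raw, sim$scenario_raw)
  om0 <- estimate_omega(freqs)
  screen <- flk_outlier_screen(freqs, om0)
  omega <- estimate_omega(freqs, screen$flagged)
  gea <- call_candidates(gea_scan(freqs, env, omega))
  asn <- assign_loci(gea)
  vars <- names(asn$counts)[asn$counts >= min_loci]
  fits <- stats::setNames(lapply(vars, function(v) {
    loci <- asn$assignment$locus[asn$assignment$variable == v]
    fit_blup(freqs$f[, loci, drop = FALSE],
             stats::setNames(env$E[, v], env$pops), variable = v)
  }), vars)
  list(freqs = freqs, env = env, omega = omega, screen = screen,
       gea = gea, assignment = asn, fits = fits)
}

# predictor/response generator for BLUP tests: drifted allele
# frequencies as predictors, linear signal plus noise as the response
make_fit_data <- function(P = 26, L = 17, noise = 0.3, seed = 1, F_drift = 0.2) {
  set.seed(seed)
  pi <- runif(L, 0.1, 0.9)
  Fm <- sapply(pi, function(p)
    rbeta(P, p * (1 - F_drift) / F_drift, (1 - p) * (1 - F_drift) / F_drift))
  rownames(Fm) <- sprintf("P%02d", seq_len(P))
  colnames(Fm) <- sprintf("L%02d", seq_len(L))
  beta <- rnorm(L)
  E <- drop(Fm %*% beta) + rnorm(P, 0, noise)
  names(E) <- rownames(Fm)
  list(F = Fm, E = E, beta = beta)
}
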