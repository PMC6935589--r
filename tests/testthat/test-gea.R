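# Whitening, g-prior Bayes factors, Spearman statistic, candidate calling
# and assignment

make_omega <- function(W, pops = sprintf("P%d", seq_len(nrow(W)))) {
  dimnames(W) <- list(pops, pops)
  structure(list(W = W, pops = pops, epsilon = 0, n_loci = NA),
            class = "omega_matrix")
}

test_that("whitening reduces Omega-correlated draws to white noise", {
  x <- c(1, 2, 3, 4)
  expect_equal(whiten(x, make_omega(diag(4))), x)
  expect_equal(whiten(x, make_omega(4 * diag(4))), x / 2)
  # random SPD covariance: whitened draws have identity covariance
  set.seed(12)
  A <- matrix(rnorm(25), 5)
  W <- crossprod(A) + diag(5)
  om <- make_omega(W)
  L <- t(chol(W))
  draws <- matrix(rnorm(5 * 20000), 5)
  y <- L %*% draws
  wy <- apply(y, 2, whiten, omega = om)
  emp <- tcrossprod(wy) / ncol(wy)
  expect_lt(max(abs(emp - diag(5))), 0.06)
  # whiten(L e_i) = e_i
  expect_equal(whiten(L[, 2], om), c(0, 1, 0, 0, 0), tolerance = 1e-12)
  expect_error(whiten(1:3, om), "dimension")
})

test_that("g-prior BF has the closed-form null limit and is monotone in R2", {
  P <- 12; g <- P
  # R2 = 0 null limit: BF = (1+g)^(-1/2) < 1, via a locus orthogonal to the
  # environment in whitened space
  om <- make_omega(diag(P))
  E <- seq(-1.5, 1.5, length.out = P)
  set.seed(5)
  fperp <- qr.resid(qr(cbind(1, E)), rnorm(P))
  resperp <- gea_bayes_factor(fperp - min(fperp), E, om)
  expect_equal(resperp$R2, 0, tolerance = 1e-12)
  expect_equal(resperp$bayes_factor, (1 + P)^(-1 / 2), tolerance = 1e-10)
  expect_lt(resperp$bayes_factor, 1)
  # monotone increasing in R2 on a grid at fixed P, g
  grid <- seq(0, 0.99, by = 0.01)
  bfs <- (1 + g)^((P - 2) / 2) * (1 + g * (1 - grid))^(-(P - 1) / 2)
  expect_true(all(diff(bfs) > 0))
})

test_that("BF equals the numerical-quadrature oracle of the g-prior marginal
           likelihood ratio", {
  set.seed(42)
  P <- 10; g <- 10
  E <- rnorm(P)
  f <- 0.5 + 0.15 * E + rnorm(P, 0, 0.12)   # R2 around 0.5
  om <- make_omega(diag(P))
  res <- gea_bayes_factor(f, E, om, g = g)
  bf_or <- oracle_bf_quadrature(f, rep(1, P), E, g)
  expect_equal(res$bayes_factor, bf_or, tolerance = 1e-6)
  # with a non-trivial covariance: whitened columns feed the same oracle
  A <- matrix(rnorm(P * P, 0, 0.2), P); W <- crossprod(A) + diag(P) * 0.5
  om2 <- make_omega(W)
  res2 <- gea_bayes_factor(f, E, om2, g = g)
  L <- t(chol(W))
  bf_or2 <- oracle_bf_quadrature(drop(forwardsolve(L, f)),
                                 drop(forwardsolve(L, rep(1, P))),
                                 drop(forwardsolve(L, E)), g)
  expect_equal(res2$bayes_factor, bf_or2, tolerance = 1e-6)
})

test_that("BF is invariant to affine env rescaling and joint relabelling", {
  set.seed(3)
  P <- 16
  W <- crossprod(matrix(rnorm(P * P, 0, 0.2), P)) + diag(P) * 0.3
  om <- make_omega(W)
  E <- rnorm(P)
  f <- plogis(0.4 * E + rnorm(P, 0, 0.3))
  b1 <- gea_bayes_factor(f, E, om)
  b2 <- gea_bayes_factor(f, 2 * E + 3, om)
  expect_equal(b1$bayes_factor, b2$bayes_factor, tolerance = 1e-10)
  perm <- sample(P)
  omp <- make_omega(W[perm, perm], pops = om$pops[perm])
  b3 <- gea_bayes_factor(f[perm], E[perm], omp)
  expect_equal(b1$bayes_factor, b3$bayes_factor, tolerance = 1e-8)
})

test_that("Spearman statistic uses average ranks for ties", {
  expect_equal(spearman_assoc(1:6 / 10, 1:6), 1)
  expect_equal(spearman_assoc(exp(-(1:6)), 1:6), -1)
  # hand-computed tied-rank oracle for (1,2,2,3) vs (10,20,30,40):
  # ranks x = (1, 2.5, 2.5, 4), ranks y = (1,2,3,4)
  rx <- c(1, 2.5, 2.5, 4); ry <- 1:4
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_assoc(c(1, 2, 2, 3), c(10, 20, 30, 40)), hand)
  expect_true(is.na(spearman_assoc(rep(0.5, 5), 1:5)))
  expect_error(spearman_assoc(c(0.1, 0.2, NA, NA, 0.5), 1:5), "4")
})

test_that("candidate calling enforces the BF and top-decile conjunction", {
  res <- data.frame(
    locus = rep(sprintf("L%02d", 1:20), 1),
    variable = "V1",
    bf = 10^c(1.5, rep(0, 19)),
    log10_bf = c(1.5, rep(0, 19)),
    rho = c(0.1, seq(0.15, 0.9, length.out = 19)))
  attr(res, "variable_order") <- "V1"
  called <- call_candidates(res)
  # locus 1: strong BF but bottom-rank |rho| -> not a candidate
  expect_false(called$candidate[1])
  # quantile arithmetic: at most 10% of loci can pass the rho filter
  expect_lte(sum(abs(res$rho) >= attr(called, "rho_threshold")["V1"]),
             ceiling(0.1 * nrow(res)) + 1)
  # conjunction: subset of each individual filter
  expect_true(all(called$log10_bf[called$candidate] > 1))
  expect_true(all(abs(called$rho[called$candidate]) >=
                    attr(called, "rho_threshold")["V1"]))
})

test_that("locus assignment takes the argmax BF with deterministic ties", {
  res <- data.frame(
    locus = c("a", "a", "b", "b", "c"),
    variable = c("AMTemp", "MDR", "AMTemp", "MDR", "MDR"),
    bf = c(10^1.5, 10^1.2, 5, 5, 30),
    log10_bf = log10(c(10^1.5, 10^1.2, 5, 5, 30)),
    rho = c(0.9, 0.8, 0.7, 0.7, 0.9),
    candidate = TRUE)
  attr(res, "variable_order") <- c("AMTemp", "MDR")
  expect_message(asn <- assign_loci(res), "tied")
  expect_equal(asn$assignment$variable[asn$assignment$locus == "a"], "AMTemp")
  expect_equal(asn$assignment$variable[asn$assignment$locus == "b"], "AMTemp")
  expect_equal(sum(asn$counts), length(unique(res$locus)))
  # conservation on simulated data: counts sum to unique candidate loci
  sim <- simulate_dataset(sim_config(n_pops = 14, n_neutral = 300,
                                     n_adaptive = 8, seed = 23))
  pl <- fit_sim_pipeline(sim, min_loci = 1)
  expect_equal(sum(pl$assignment$counts),
               length(unique(pl$gea$locus[pl$gea$candidate])))
})

test_that("null simulations rarely reach strong support (calibration)", {
  frac <- sapply(1:10, function(seed) {
    cfg <- sim_config(n_pops = 26, n_neutral = 400, n_adaptive = 2,
                      b_range = c(0, 0), variables = c("AMTemp", "MDR"),
                      seed = seed)
    sim <- simulate_dataset(cfg)
    freqs <- compute_frequencies(sim$counts)
    env <- standardize_env(sim$env_raw, sim$scenario_raw)
    om <- estimate_omega(freqs)
    g <- gea_scan(freqs, env, om)
    mean(g$log10_bf > 1, na.rm = TRUE)
  })
  expect_lte(median(frac), 0.05)
})
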