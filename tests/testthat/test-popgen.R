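# FST estimation, Omega, and the FLK outlier screen

test_that("pairwise FST matches the independently coded WC84 oracle", {
  # single-locus case from counts (4 of 20) vs (16 of 20)
  cc <- toy_counts(rbind(4, 16), rbind(20, 20))
  expect_equal(pairwise_fst(cc, "P1", "P2"),
               oracle_wc84_fst(4, 20, 16, 20), tolerance = 1e-12)
  # multi-locus random case, ratio-of-sums combination
  set.seed(21)
  L <- 50
  n1 <- sample(10:30, L, TRUE); n2 <- sample(10:30, L, TRUE)
  a1 <- rbinom(L, n1, 0.3); a2 <- rbinom(L, n2, 0.6)
  cc2 <- toy_counts(rbind(a1, a2), rbind(n1, n2))
  expect_equal(pairwise_fst(cc2, "P1", "P2"),
               oracle_wc84_fst(a1, n1, a2, n2), tolerance = 1e-12)
  # identical frequencies, large equal samples -> ~0
  cc3 <- toy_counts(rbind(rep(40, 20), rep(40, 20)),
                    rbind(rep(100, 20), rep(100, 20)))
  expect_lt(abs(pairwise_fst(cc3, "P1", "P2")), 0.02)
  # fixed difference at every locus -> 1
  cc4 <- toy_counts(rbind(rep(0, 10), rep(50, 10)),
                    rbind(rep(50, 10), rep(50, 10)))
  expect_equal(pairwise_fst(cc4, "P1", "P2"), 1, tolerance = 1e-12)
})

test_that("FST permutation p-values follow the add-one rule and a brute-force
           oracle with a shared RNG stream", {
  set.seed(31)
  P <- 3; L <- 12
  n <- matrix(20L, P, L)
  alt <- matrix(rbinom(P * L, 20, c(0.2, 0.5, 0.8)), P, L)
  cc <- toy_counts(alt, n)
  fm <- fst_matrix(cc, n_perm = 99, seed = 42)
  expect_equal(fm$fst, t(fm$fst))
  expect_equal(diag(fm$fst), setNames(rep(0, P), cc$pops))
  expect_true(all(fm$p[upper.tri(fm$p)] >= 1 / 100 &
                    fm$p[upper.tri(fm$p)] <= 1))
  # brute-force oracle: replay the same RNG stream and recount exceedances
  set.seed(42)
  for (i in 1:(P - 1)) for (j in (i + 1):P) {
    obs <- oracle_wc84_fst(alt[i, ], n[i, ], alt[j, ], n[j, ])
    exceed <- 0
    for (b in 1:99) {
      a1p <- rhyper(L, alt[i, ] + alt[j, ], n[i, ] + n[j, ] - alt[i, ] - alt[j, ],
                    n[i, ])
      if (oracle_wc84_fst(a1p, n[i, ], alt[i, ] + alt[j, ] - a1p, n[j, ]) >= obs)
        exceed <- exceed + 1
    }
    expect_equal(fm$p[i, j], (exceed + 1) / 100)
  }
  # identical populations: observed FST near the permutation null median
  cc_same <- toy_counts(rbind(rep(10, 40), rep(10, 40)),
                        matrix(20L, 2, 40))
  fm_same <- fst_matrix(cc_same, n_perm = 199, seed = 1)
  expect_gt(fm_same$p[1, 2], 0.2)
})

test_that("Omega has the analytic structure on engineered inputs", {
  # identical populations at all loci -> off-diagonals zero (ridge only)
  f <- matrix(rep(c(0.2, 0.5, 0.8, 0.4), each = 4), nrow = 4)
  cc <- toy_counts(round(f * 50), matrix(50L, 4, 4))
  fm <- compute_frequencies(cc, min_pops = 2, maf = 0.01)
  om <- estimate_omega(fm)
  off <- om$W[upper.tri(om$W)]
  expect_true(all(abs(off) < 1e-12))
  # duplicated population rows -> off-diagonal equals diagonal (up to ridge)
  set.seed(8)
  f2 <- rbind(a = runif(30, 0.2, 0.8), b = runif(30, 0.2, 0.8))
  f2 <- rbind(f2, f2[1, ])
  cc2 <- toy_counts(round(f2 * 100), matrix(100L, 3, 30))
  fm2 <- compute_frequencies(cc2, min_pops = 2, maf = 0.01)
  om2 <- estimate_omega(fm2)
  expect_equal(om2$W[1, 3], om2$W[1, 1] - om2$epsilon, tolerance = 1e-10)
  # symmetry and Cholesky feasibility
  expect_lt(max(abs(om2$W - t(om2$W))), 1e-12)
  expect_silent(chol(om2$W))
})

test_that("Omega recovers the Balding-Nichols moments on simulation", {
  cfg <- sim_config(n_pops = 12, n_small = 0, fst_drift = 0.1,
                    n_neutral = 5000, n_adaptive = 2, n_chrom = 5000, seed = 13)
  sim <- simulate_dataset(cfg)
  fm <- compute_frequencies(sim$counts)
  om <- estimate_omega(fm)
  # diagonal ~ F * (P-1)/P (centering on the across-pop mean removes one
  # degree of freedom); off-diagonal ~ 0 for independent populations
  P <- length(fm$pops)
  expect_equal(mean(diag(om$W)), 0.1 * (P - 1) / P, tolerance = 0.03)
  expect_lt(max(abs(om$W[upper.tri(om$W)])), 0.02)
})

test_that("FLK screen is calibrated under the null and powered for a step", {
  # null statistic: locus exactly at the GLS mean is not flagged
  set.seed(77)
  P <- 10
  f <- matrix(runif(P * 50, 0.3, 0.7), P, 50)
  f[, 1] <- 0.5                               # flat locus
  cc <- toy_counts(round(f * 200), matrix(200L, P, 50))
  fm <- compute_frequencies(cc, min_pops = 2, maf = 0.01)
  om <- estimate_omega(fm)
  sc <- flk_outlier_screen(fm, om)
  expect_equal(sc$stats$T[1], 0, tolerance = 1e-8)
  expect_false(sc$stats$flagged[1])
  # null calibration: matched Balding-Nichols simulation flags few loci
  frac <- sapply(1:10, function(seed) {
    cfg <- sim_config(n_pops = 26, n_neutral = 500, n_adaptive = 2,
                      variables = c("AMTemp", "MDR"), seed = seed)
    sim <- simulate_dataset(cfg)
    fm <- compute_frequencies(sim$counts)
    om <- estimate_omega(fm)
    sc <- flk_outlier_screen(fm, om, fdr = 0.2)
    length(sc$flagged) / length(fm$loci)
  })
  expect_lte(median(frac), 0.25)
  # power: engineered +0.4 step confined to half the populations
  hits <- sapply(1:10, function(seed) {
    set.seed(seed)
    P <- 26
    f <- matrix(rbeta(P * 400, 0.3 * 19, 0.7 * 19), P, 400)  # F ~ 0.05
    f[1:13, 1] <- pmin(f[1:13, 1] + 0.4, 0.99)
    cc <- toy_counts(round(f * 1000), matrix(1000L, P, 400))
    fmx <- compute_frequencies(cc, min_pops = 2, maf = 0.01)
    scx <- flk_outlier_screen(fmx, estimate_omega(fmx), fdr = 0.2)
    "L1" %in% scx$flagged
  })
  expect_gte(mean(hits), 0.95)
})

test_that("FLK flags are equivariant under population relabelling", {
  cfg <- sim_config(n_pops = 12, n_small = 2, n_neutral = 300,
                    n_adaptive = 5, seed = 17)
  sim <- simulate_dataset(cfg)
  fm <- compute_frequencies(sim$counts)
  om <- estimate_omega(fm)
  sc1 <- flk_outlier_screen(fm, om)
  perm <- sample(length(fm$pops))
  fmp <- fm
  fmp$f <- fm$f[perm, ]; fmp$n <- fm$n[perm, ]; fmp$mask <- fm$mask[perm, ]
  fmp$pops <- fm$pops[perm]
  omp <- estimate_omega(fmp)
  sc2 <- flk_outlier_screen(fmp, omp)
  expect_setequal(sc1$flagged, sc2$flagged)
  expect_equal(sc1$stats$T, sc2$stats$T, tolerance = 1e-8)
})
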