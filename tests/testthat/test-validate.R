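# Collinearity filter, validation statistics, summary arithmetic

test_that("collinearity filter follows the greedy preference scan", {
  vars <- c("A", "B")
  cm <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(vars, vars))
  res <- collinearity_filter(cm, c("A", "B"))
  expect_equal(res$retained, "A")
  expect_equal(res$dropped, c(B = "A"))
  # nothing above threshold: keep all
  cm2 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(vars, vars))
  expect_equal(collinearity_filter(cm2, vars)$retained, vars)
  # 19-variable random matrix vs brute-force greedy oracle
  set.seed(61)
  V <- 19
  A <- matrix(rnorm(40 * V), 40)
  A[, 5] <- A[, 1] + rnorm(40, 0, 0.3)     # engineered collinearity
  A[, 12] <- -A[, 3] + rnorm(40, 0, 0.2)
  cm3 <- cor(A)
  dimnames(cm3) <- list(paste0("v", 1:V), paste0("v", 1:V))
  pref <- sample(colnames(cm3))
  res3 <- collinearity_filter(cm3, pref, threshold = 0.7)
  kept <- character(0)
  for (v in pref) if (all(abs(cm3[v, kept]) <= 0.7)) kept <- c(kept, v)
  expect_equal(res3$retained, kept)
  expect_error(collinearity_filter(matrix(c(1, 0.2, 0.4, 1), 2,
                                          dimnames = list(vars, vars)), vars),
               "symmetric")
})

test_that("count-importance correlation reproduces the textbook formula", {
  set.seed(71)
  x <- rpois(10, 20); y <- x * 2 + rnorm(10, 0, 5)
  res <- correlate_counts_importance(x, y)
  r <- res$statistic
  tstat <- r * sqrt((10 - 2) / (1 - r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-10)
  expect_equal(r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
  # proportional counts: r = 1
  expect_equal(correlate_counts_importance(1:5, 2 * (1:5))$statistic, 1)
  # anti-ordered: negative
  expect_lt(correlate_counts_importance(1:6, 6:1)$statistic, 0)
  expect_error(correlate_counts_importance(rep(2, 5), 1:5), "constant")
})

test_that("per-variable association counts correlate with gradient-importance
           weights on synthetic data", {
  # variables coupled to many loci should also dominate a niche-model-style
  # importance vector; here importance is proxied by the true locus counts
  # with noise, exercising the reporting path end to end
  cfg <- sim_config(seed = 81)
  sim <- simulate_dataset(cfg)
  pl <- fit_sim_pipeline(sim, min_loci = 1)
  counts <- pl$assignment$counts
  set.seed(81)
  importance <- 100 * (counts + rpois(length(counts), 3)) /
    sum(counts + rpois(length(counts), 3))
  res <- correlate_counts_importance(as.numeric(counts), importance)
  expect_true(res$statistic > 0)
})

test_that("fitness validation detects designed effects and stays calibrated
           under the null", {
  # power: strong injected effect gives a negative detected slope
  hit <- sapply(1:25, function(seed) {
    cfg <- sim_config(n_neutral = 5, n_adaptive = 2, seed = seed)
    sim <- simulate_dataset(cfg)
    sim$truth$delta[sample(cfg$n_pops, 6)] <- 1
    tab <- simulate_phenotypes(sim, gamma = 1.5)
    # ideal-measurement c-RONA stand-in: rona table proportional to truth
    rona <- data.frame(pop = tab$pop_id, variable = "AMTemp",
                       residual = abs(sim$truth$delta) +
                         rnorm(cfg$n_pops, 0, 0.05),
                       c_rona = NA)
    rona$c_rona <- abs(rona$residual) / 5
    out <- fitness_validation(rona, tab, variables = "AMTemp")
    out$p[1] < 0.05 && out$direction[1] == "negative"
  })
  expect_gte(mean(hit), 0.8)
  # null: gamma = 0 rejects at about the nominal rate
  pnull <- sapply(1:200, function(seed) {
    set.seed(seed + 4000)
    P <- 26
    tab <- data.frame(pop_id = sprintf("P%02d", 1:P),
                      latitude = runif(P, 55, 58),
                      longitude = runif(P, -5, -3),
                      catkin_mean = rnbinom(P, mu = 20, size = 5) + 0.01)
    rona <- data.frame(pop = tab$pop_id, variable = "AMTemp",
                       residual = rnorm(P, 0, 0.2), c_rona = NA)
    rona$c_rona <- abs(rona$residual) / 5
    fitness_validation(rona, tab, variables = "AMTemp")$p[1]
  })
  rate <- mean(pnull < 0.05)
  expect_lt(rate, 0.10)
  expect_gt(rate, 0.005)
  # constant phenotype: slope and F are zero
  tab0 <- data.frame(pop_id = sprintf("P%02d", 1:10),
                     latitude = runif(10, 55, 58),
                     longitude = runif(10, -5, -3), catkin_mean = 9)
  rona0 <- data.frame(pop = tab0$pop_id, variable = "AMTemp",
                      residual = rnorm(10), c_rona = abs(rnorm(10)))
  out0 <- fitness_validation(rona0, tab0, variables = "AMTemp")
  expect_equal(out0$statistic[1], 0)
  expect_equal(out0$p[1], 1)
})

test_that("germination model picks up the designed interaction structure", {
  cfg <- sim_config(n_neutral = 5, n_adaptive = 2, seed = 91)
  sim <- simulate_dataset(cfg)
  sim$truth$delta[sample(cfg$n_pops, 8)] <- 1.2
  tab <- simulate_phenotypes(sim, gamma = 1.5)
  rona <- do.call(rbind, lapply(c("AMTemp", "MDR"), function(v)
    data.frame(pop = tab$pop_id, variable = v,
               residual = abs(sim$truth$delta) + rnorm(cfg$n_pops, 0, 0.05),
               c_rona = NA)))
  rona$c_rona <- abs(rona$residual) / 5
  out <- fitness_validation(rona, tab, variables = c("AMTemp", "MDR"))
  germ <- out[grepl("germination", out$test), ]
  expect_equal(nrow(germ), 1)
  expect_lt(germ$p, 0.05)
})

test_that("annotation and survival summary arithmetic is exact", {
  flags <- data.frame(expressed_flower = c(rep(TRUE, 35), rep(FALSE, 150)),
                      expressed_leaf = c(rep(TRUE, 13), rep(FALSE, 22),
                                         rep(TRUE, 2), rep(FALSE, 148)))
  out <- annotation_summary(185, flags)
  expect_equal(out$pct[out$tissue == "flower"], 100 * 35 / 185)
  expect_equal(out$pct_display, c(19, 8, 7))
  expect_equal(annotation_summary(185, flags[0, , drop = FALSE])$pct_display, c(0, 0, 0))
  expect_error(annotation_summary(10, flags), "exceeds")

  gs <- germination_summary(7.6, 6.1)
  expect_equal(gs$pct, 100 * 6.1 / 7.6)
  expect_equal(gs$pct_display, 80L)
  expect_equal(germination_summary(10, 10)$pct_display, 100L)
  expect_equal(germination_summary(10, 5)$pct_display, 50L)
  expect_error(germination_summary(5, 6), "survival")
})
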