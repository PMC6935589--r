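# Synthetic-data generator: Balding-Nichols drift for neutral loci,
# logistic environmental coupling for adaptive loci, correlated
# environmental gradients over a simulated landscape, and fitness proxies
# that degrade with injected maladaptation. Every dataset carries its
# ground truth so the whole pipeline is testable without field data.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a fragmented montane shrub survey: 26 populations of
#' which a handful are tiny drift-dominated relicts, ~2000 neutral RAD loci,
#' and a minority of loci whose frequencies track correlated climatic
#' gradients.
#'
#' @param n_pops number of populations.
#' @param n_chrom allele copies genotyped per ordinary population.
#' @param n_small number of "small" relict populations.
#' @param n_chrom_small allele copies genotyped in small populations.
#' @param fst_drift Balding-Nichols drift parameter F for ordinary pops.
#' @param fst_small drift parameter for small populations.
#' @param n_neutral number of neutral loci.
#' @param variables names of environmental variables.
#' @param env_cor target pairwise correlation between variables.
#' @param env_noise_sd SD of the non-spatial component of each variable
#'   (the spatial gradient has SD `sqrt(1 - env_noise_sd^2)`).
#' @param n_adaptive number of adaptive loci coupled to each variable.
#' @param b_range magnitude range of the logistic coupling slope b (per
#'   standardized environment unit); the sign is random per locus.
#' @param logit_noise_sd SD of locus-level Gaussian noise added on the
#'   logit scale before drift.
#' @param scenarios named list of future scenarios, each a named numeric
#'   vector of uniform shifts (in current-period SD units) per variable.
#' @param phenotype list of fitness-proxy parameters: `alpha_catkin`
#'   (log mean catkins when perfectly adapted), `gamma` (log-scale decline
#'   per unit maladaptation), `nb_size` (negative-binomial dispersion),
#'   `n_plants`, `germ_logit` (baseline germination on the logit scale),
#'   `gamma_germ`, `n_seeds`.
#' @param seed integer RNG seed; the dataset is byte-reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 26,
                       n_chrom = 12,
                       n_small = 5,
                       n_chrom_small = 2,
                       fst_drift = 0.05,
                       fst_small = 0.3,
                       n_neutral = 2000,
                       variables = c("AMTemp", "MDR", "ISO", "APrec"),
                       env_cor = 0.3,
                       env_noise_sd = 0.5,
                       n_adaptive = 20,
                       b_range = c(0.75, 1.5),
                       logit_noise_sd = 0.2,
                       scenarios = list(rcp45 = c(AMTemp = 0.5),
                                        rcp85 = c(AMTemp = 1.0)),
                       phenotype = list(alpha_catkin = log(20), gamma = 0.8,
                                        nb_size = 5, n_plants = 25,
                                        germ_logit = stats::qlogis(0.076),
                                        gamma_germ = 0.8, n_seeds = 100),
                       seed = 1) {
  stopifnot(n_pops >= 4, n_small < n_pops, n_neutral > 0, n_adaptive > 0,
            fst_drift > 0, fst_drift < 1, fst_small > 0, fst_small < 1,
            env_cor > -1, env_cor < 1, length(variables) >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Balding-Nichols draw: population frequency around ancestral pi at drift F
rbn <- function(n, pi, F) {
  stats::rbeta(n, pi * (1 - F) / F, (1 - pi) * (1 - F) / F)
}

#' Simulate a population-genomic dataset with ground truth
#'
#' Populations are placed on a latitude/longitude landscape; environmental
#' variables are linear spatial gradients plus noise, linearly mixed to hit
#' the target pairwise correlation. Neutral locus frequencies follow the
#' Balding-Nichols beta model around a uniform ancestral frequency; adaptive
#' loci follow `inv-logit(a + b * E)` with beta drift at the same per-pop F,
#' clamped to \[0.01, 0.99\]. Observed counts are binomial in the genotyped
#' allele copies.
#'
#' @param cfg a [sim_config].
#' @return List of class `sim_dataset`: `counts` ([genotype_counts]),
#'   `env_raw` (current-period data.frame), `scenario_raw` (named list of
#'   data.frames), `pop_table` (data.frame), `truth` (ground truth: adaptive
#'   loci per variable, coupling coefficients a/b, per-pop drift F, injected
#'   maladaptation delta), and the `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  P <- cfg$n_pops; V <- length(cfg$variables)

  # landscape: Scottish-Highlands-like extent
  lat <- sort(stats::runif(P, 54.6, 58.4), decreasing = TRUE)
  lon <- stats::runif(P, -5.0, -2.3)
  elev <- stats::runif(P, 150, 700)
  pop_id <- sprintf("P%02d", seq_len(P))
  small <- rep(FALSE, P)
  if (cfg$n_small > 0) small[sample.int(P, cfg$n_small)] <- TRUE
  Fp <- ifelse(small, cfg$fst_small, cfg$fst_drift)
  n_chrom <- ifelse(small, cfg$n_chrom_small, cfg$n_chrom)

  # environmental fields: spatial gradient + noise, then mixed for collinearity
  lat_s <- as.numeric(scale(lat)); lon_s <- as.numeric(scale(lon))
  Z <- sapply(seq_len(V), function(v) {
    th <- stats::runif(1, 0, 2 * pi)
    g <- cos(th) * lat_s + sin(th) * lon_s
    g <- g / stats::sd(g)
    sqrt(max(0, 1 - cfg$env_noise_sd^2)) * g +
      cfg$env_noise_sd * stats::rnorm(P)
  })
  C <- matrix(cfg$env_cor, V, V); diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stopf("env correlation target is not positive definite")
  Emix <- Z %*% chol(C)
  Emix <- scale(Emix)  # standardized truth used for the coupling
  colnames(Emix) <- cfg$variables
  rownames(Emix) <- pop_id

  # raw-unit tables (the pipeline re-standardizes; units are arbitrary)
  env_units <- list(center = 6 + 2 * seq_len(V), scale = rep(2, V))
  raw_from_std <- function(M) {
    X <- sweep(sweep(M, 2, env_units$scale, "*"), 2, env_units$center, "+")
    data.frame(pop_id = pop_id, X, check.names = FALSE)
  }
  env_raw <- raw_from_std(Emix)
  scenario_raw <- lapply(cfg$scenarios, function(shift) {
    S <- Emix
    for (v in names(shift)) {
      if (!v %in% colnames(S)) stopf("scenario shift names unknown variable '%s'", v)
      S[, v] <- S[, v] + shift[[v]]
    }
    raw_from_std(S)
  })

  # neutral loci: Balding-Nichols around uniform ancestral frequencies
  pi_neutral <- stats::runif(cfg$n_neutral, 0.05, 0.95)
  # per-pop F differs, so draw row-wise
  fq_neutral <- matrix(NA_real_, P, cfg$n_neutral)
  for (p in seq_len(P)) fq_neutral[p, ] <- rbn(cfg$n_neutral, pi_neutral, Fp[p])

  # adaptive loci: logistic coupling to one variable each + drift
  La <- cfg$n_adaptive * V
  adaptive_var <- rep(cfg$variables, each = cfg$n_adaptive)
  pi_adapt <- stats::runif(La, 0.2, 0.8)
  a_coef <- stats::qlogis(pi_adapt)
  b_coef <- sample(c(-1, 1), La, replace = TRUE) *
    stats::runif(La, cfg$b_range[1], cfg$b_range[2])
  fq_adapt <- adaptive_frequencies(Emix[, adaptive_var, drop = FALSE],
                                   a_coef, b_coef, Fp, cfg$logit_noise_sd)

  freq <- cbind(fq_neutral, fq_adapt)
  loci <- c(sprintf("N%05d", seq_len(cfg$n_neutral)),
            sprintf("A_%s_%03d", adaptive_var, sequence(rep(cfg$n_adaptive, V))))
  colnames(freq) <- loci
  rownames(freq) <- pop_id

  nmat <- matrix(n_chrom, P, length(loci),
                 dimnames = list(pop_id, loci))
  alt <- matrix(stats::rbinom(length(freq), as.vector(nmat), as.vector(freq)),
                P, length(loci), dimnames = dimnames(nmat))

  pop_table <- data.frame(
    pop_id = pop_id, latitude = lat, longitude = lon, elevation = elev,
    n_genotyped = n_chrom / 2, small = small, stringsAsFactors = FALSE)

  truth <- list(
    adaptive_loci = split(loci[(cfg$n_neutral + 1):length(loci)], adaptive_var),
    locus_variable = stats::setNames(adaptive_var,
                                     loci[(cfg$n_neutral + 1):length(loci)]),
    a = stats::setNames(a_coef, loci[(cfg$n_neutral + 1):length(loci)]),
    b = stats::setNames(b_coef, loci[(cfg$n_neutral + 1):length(loci)]),
    pi_neutral = pi_neutral,
    Fp = stats::setNames(Fp, pop_id),
    E_std = Emix,
    delta = stats::setNames(rep(0, P), pop_id),
    delta_variables = character(0))

  structure(list(counts = genotype_counts(alt, nmat), env_raw = env_raw,
                 scenario_raw = scenario_raw, pop_table = pop_table,
                 truth = truth, cfg = cfg),
            class = "sim_dataset")
}

# inv-logit coupling + beta drift around it, clamped away from fixation
adaptive_frequencies <- function(Emat, a, b, Fp, logit_noise_sd) {
  P <- nrow(Emat); L <- length(a)
  mu <- stats::plogis(matrix(a, P, L, byrow = TRUE) +
                      matrix(b, P, L, byrow = TRUE) * Emat +
                      matrix(stats::rnorm(P * L, 0, logit_noise_sd), P, L))
  f <- matrix(NA_real_, P, L)
  for (p in seq_len(P)) f[p, ] <- rbn(L, mu[p, ], Fp[p])
  pmin(pmax(f, 0.01), 0.99)
}

#' Inject maladaptation into a simulated dataset
#'
#' Regenerates adaptive-locus frequencies (and counts) for the listed
#' populations using `E + delta` in the environmental coupling, so their
#' genotypes fit an environment offset by `delta` standardized units from
#' the one they live in. Neutral loci are untouched; the offset is recorded
#' in the ground truth.
#'
#' @param sim a `sim_dataset`.
#' @param pops character vector of population ids to perturb.
#' @param variables variables whose adaptive loci are regenerated
#'   (default: all).
#' @param delta environmental offset in standardized units.
#' @return The modified `sim_dataset`.
#' @export
inject_maladaptation <- function(sim, pops, variables = NULL, delta) {
  stopifnot(inherits(sim, "sim_dataset"))
  variables <- variables %||% sim$cfg$variables
  if (!all(pops %in% sim$pop_table$pop_id)) stopf("unknown population id(s)")
  if (!all(variables %in% sim$cfg$variables)) stopf("unknown variable name(s)")
  if (delta == 0) {
    warnf("delta = 0: dataset unchanged")
    return(sim)
  }
  set.seed(sim$cfg$seed + 77003L)
  tr <- sim$truth
  loci <- names(tr$locus_variable)[tr$locus_variable %in% variables]
  rows <- match(pops, sim$pop_table$pop_id)
  E <- tr$E_std[rows, tr$locus_variable[loci], drop = FALSE] + delta
  f_new <- adaptive_frequencies(E, tr$a[loci], tr$b[loci],
                                tr$Fp[rows], sim$cfg$logit_noise_sd)
  n_sub <- sim$counts$n[rows, loci, drop = FALSE]
  alt_new <- matrix(stats::rbinom(length(f_new), as.vector(n_sub),
                                  as.vector(f_new)),
                    nrow = length(rows))
  sim$counts$alt[rows, loci] <- alt_new
  sim$truth$delta[pops] <- delta
  sim$truth$delta_variables <- variables
  sim
}

#' Simulate fitness proxies tied to maladaptation
#'
#' Catkin counts are negative-binomial with log-mean declining in the
#' true maladaptation magnitude; germination is binomial with logit-mean
#' declining likewise. With `gamma = 0` the proxies are pure noise.
#'
#' @param sim a `sim_dataset` (after any [inject_maladaptation]).
#' @param gamma log-scale decline in catkin mean per unit of true
#'   maladaptation (must be >= 0; a negative value would invert the
#'   designed association and is rejected).
#' @param gamma_germ logit-scale decline for germination (default `gamma`).
#' @return The `pop_table` with `catkin_mean` and `germination_rate` filled.
#' @export
simulate_phenotypes <- function(sim, gamma = sim$cfg$phenotype$gamma,
                                gamma_germ = gamma) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (gamma < 0 || gamma_germ < 0) stopf("gamma must be >= 0")
  ph <- sim$cfg$phenotype
  set.seed(sim$cfg$seed + 88007L)
  m <- abs(sim$truth$delta)
  mu_cat <- exp(ph$alpha_catkin - gamma * m)
  catkin_mean <- vapply(mu_cat, function(mu) {
    mean(stats::rnbinom(ph$n_plants, mu = mu, size = ph$nb_size))
  }, numeric(1))
  p_germ <- stats::plogis(ph$germ_logit - gamma_germ * m)
  germ <- stats::rbinom(length(m), ph$n_seeds, p_germ) / ph$n_seeds
  tab <- sim$pop_table
  tab$catkin_mean <- catkin_mean
  tab$germination_rate <- germ
  tab$n_seeds <- ph$n_seeds
  validate_pop_table(tab)
  tab
}

#' Write a simulated dataset as VCF plus population map
#'
#' Allele copies within each population are partitioned at random into
#' diploid individuals, so the per-population counts in the VCF equal the
#' simulator's internal table exactly.
#'
#' @param sim a `sim_dataset`.
#' @param path output VCF path; a `<path>.popmap.tsv` sample-to-population
#'   map is written beside it.
#' @param loci optional subset of locus ids to write.
#' @return data.frame pop map, invisibly.
#' @export
write_sim_vcf <- function(sim, path, loci = NULL) {
  stopifnot(inherits(sim, "sim_dataset"))
  set.seed(sim$cfg$seed + 99001L)
  loci <- loci %||% sim$counts$loci
  alt <- sim$counts$alt[, loci, drop = FALSE]
  nmat <- sim$counts$n[, loci, drop = FALSE]
  pops <- sim$counts$pops
  n_ind <- nmat[, 1] / 2
  if (any(nmat != matrix(nmat[, 1], nrow(nmat), ncol(nmat))))
    stopf("VCF writing assumes constant allele copies per population")
  sample_id <- unlist(lapply(seq_along(pops), function(i)
    sprintf("%s_i%d", pops[i], seq_len(n_ind[i]))))
  gt_cols <- lapply(seq_along(pops), function(i) {
    k <- alt[i, ]; n <- nmat[i, 1]
    sapply(seq_along(loci), function(l) {
      copies <- integer(n)
      if (k[l] > 0) copies[sample.int(n, k[l])] <- 1L
      g <- matrix(copies, nrow = 2)
      paste(g[1, ], g[2, ], sep = "/")
    })  # n_ind x loci? sapply gives (n/2)? build carefully below
  })
  # assemble genotype body: one column per individual
  body <- matrix("", length(loci), sum(n_ind))
  col0 <- 0
  for (i in seq_along(pops)) {
    gt <- gt_cols[[i]]                      # (n_ind) x loci or vector
    gt <- matrix(gt, nrow = n_ind[i])
    body[, col0 + seq_len(n_ind[i])] <- t(gt)
    col0 <- col0 + n_ind[i]
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=adaptrona-simulator",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_id), collapse = "\t"))
  recs <- paste("chr1", seq_along(loci), loci, "A", "T", ".", "PASS", ".",
                "GT", apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, recs), path)
  pop_map <- data.frame(sample_id = sample_id,
                        pop_id = rep(pops, n_ind), stringsAsFactors = FALSE)
  utils::write.table(pop_map, paste0(path, ".popmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(pop_map)
}
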