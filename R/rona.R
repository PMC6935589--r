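# Multi-locus BLUP of environmental optima and the risk of nonadaptedness:
# ridge-regression effect sizes with REML variance components, genotype-
# predicted environments, and c-RONA / f-RONA per population.

#' Fit a ridge-BLUP of an environmental variable on allele frequencies
#'
#' Model: `E = mu 1 + F beta + e` with `beta ~ N(0, sigma_b^2 I)` and
#' `e ~ N(0, sigma_e^2 I)`. The variance ratio `delta = sigma_e^2 / sigma_b^2`
#' is estimated by REML, profiled on `log10(delta)` over \[-5, 5\] by
#' golden-section search (tolerance 1e-6) using the eigendecomposition of
#' `F F'`. The intercept is the GLS estimate and
#' `beta = F' (F F' + delta I)^-1 (E - mu 1)`.
#'
#' Populations with a masked frequency at any assigned locus are dropped
#' from the fit (recorded in `dropped_pops`); all-constant locus columns are
#' dropped with a warning.
#'
#' @param F_v numeric matrix populations x assigned loci of allele
#'   frequencies.
#' @param E_v standardized environmental vector (same populations).
#' @param variable variable name carried on the fit.
#' @return Object of class `blup_fit`: `variable`, `loci`, `beta`, `mu`,
#'   `delta_ridge`, `fitted` (named per population), `residual_sd`
#'   (denominator P - 1), `boundary` (logical: REML optimum at a search
#'   bound), `dropped_pops`, `pops`.
#' @export
fit_blup <- function(F_v, E_v, variable = "env") {
  F_v <- as.matrix(F_v)
  if (is.null(rownames(F_v))) rownames(F_v) <- names(E_v) %||%
      sprintf("P%02d", seq_len(nrow(F_v)))
  keep_pop <- rowSums(is.na(F_v)) == 0 & !is.na(E_v)
  dropped <- rownames(F_v)[!keep_pop]
  if (length(dropped))
    warnf("dropping %d population(s) with missing data: %s",
          length(dropped), paste(dropped, collapse = ", "))
  Fm <- F_v[keep_pop, , drop = FALSE]
  E <- E_v[keep_pop]
  P <- nrow(Fm)
  if (P < 4) stopf("need at least 4 populations with complete data")
  const <- apply(Fm, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warnf("dropping %d constant locus column(s): %s", sum(const),
          paste(colnames(Fm)[const], collapse = ", "))
    Fm <- Fm[, !const, drop = FALSE]
  }
  if (!ncol(Fm)) stopf("no non-constant loci to fit")

  K <- tcrossprod(Fm)
  eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  Et <- crossprod(U, E)          # rotated response
  ones <- crossprod(U, rep(1, P))

  reml_ll <- function(log10d) {
    delta <- 10^log10d
    w <- 1 / (d + delta)
    sw1 <- sum(w * ones^2)
    mu <- sum(w * ones * Et) / sw1
    r <- Et - mu * ones
    q <- sum(w * r^2)
    -0.5 * ((P - 1) * log(q / (P - 1)) + sum(log(d + delta)) + log(sw1) +
              (P - 1))
  }
  opt <- stats::optimize(reml_ll, interval = c(-5, 5), maximum = TRUE,
                         tol = 1e-6)
  log10d <- opt$maximum
  delta <- 10^log10d
  boundary <- log10d < -5 + 1e-3 || log10d > 5 - 1e-3

  w <- 1 / (d + delta)
  sw1 <- sum(w * ones^2)
  mu <- sum(w * ones * Et) / sw1
  Hinv_r <- U %*% (w * (Et - mu * ones))
  beta <- drop(crossprod(Fm, Hinv_r))
  fitted <- drop(mu + Fm %*% beta)
  names(fitted) <- rownames(Fm)
  structure(list(variable = variable, loci = colnames(Fm),
                 beta = stats::setNames(beta, colnames(Fm)), mu = mu,
                 delta_ridge = delta,
                 reml_loglik = opt$objective,
                 fitted = fitted,
                 residual_sd = stats::sd(E - fitted),
                 boundary = boundary,
                 dropped_pops = dropped, pops = rownames(Fm)),
            class = "blup_fit")
}

#' @exportS3Method base::print
print.blup_fit <- function(x, ...) {
  cat(sprintf(
    "<blup_fit> %s: %d loci, %d pops; delta = %.4g%s, residual SD = %.4f\n",
    x$variable, length(x$loci), length(x$pops), x$delta_ridge,
    if (x$boundary) " (boundary)" else "", x$residual_sd))
  invisible(x)
}

#' Predict the environmental optimum from allele frequencies
#'
#' `Ehat = mu + f . beta`, row-wise for a matrix of frequency rows.
#'
#' @param fit a `blup_fit`.
#' @param freqs numeric vector named by locus, or matrix (rows =
#'   populations, columns covering the fit's loci).
#' @return Predicted environment value(s).
#' @export
predict_env <- function(fit, freqs) {
  stopifnot(inherits(fit, "blup_fit"))
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1,
                                           dimnames = list(NULL, names(freqs)))
  miss <- setdiff(fit$loci, colnames(freqs))
  if (length(miss)) stopf("input lacks fitted loci: %s", paste(miss, collapse = ", "))
  drop(fit$mu + freqs[, fit$loci, drop = FALSE] %*% fit$beta)
}

#' Current risk of nonadaptedness (c-RONA)
#'
#' The residual `r_p = E_p - Ehat_p` measures each population's deviation
#' from its genotype-predicted environmental optimum; c-RONA expresses it in
#' allele-frequency units as `|r_p| / sum(|beta|)` — the uniform per-locus
#' frequency shift that would close the gap.
#'
#' @param fit a `blup_fit`.
#' @param E_v standardized environmental vector named by population (the
#'   current period).
#' @return data.frame: pop, variable, residual, c_rona.
#' @export
c_rona <- function(fit, E_v) {
  stopifnot(inherits(fit, "blup_fit"))
  sb <- sum(abs(fit$beta))
  if (sb == 0)
    stopf("all effects shrunk to zero; cannot express RONA in allele-frequency units")
  pops <- fit$pops
  if (!all(pops %in% names(E_v))) stopf("E_v must be named by population")
  r <- E_v[pops] - fit$fitted[pops]
  data.frame(pop = pops, variable = fit$variable,
             residual = as.numeric(r),
             c_rona = abs(as.numeric(r)) / sb,
             stringsAsFactors = FALSE)
}

#' Future risk of nonadaptedness (f-RONA) under a scenario
#'
#' Same scale as [c_rona] but against the projected environment:
#' `|E'_p - Ehat_p| / sum(|beta|)`. With the current table as the scenario
#' this is identical to c-RONA.
#'
#' @param fit a `blup_fit`.
#' @param E_scenario projected environmental vector named by population,
#'   standardized with the current-period transform.
#' @param scenario scenario label for the output.
#' @return data.frame: pop, variable, scenario, f_rona.
#' @export
f_rona <- function(fit, E_scenario, scenario = "scenario") {
  stopifnot(inherits(fit, "blup_fit"))
  sb <- sum(abs(fit$beta))
  if (sb == 0)
    stopf("all effects shrunk to zero; cannot express RONA in allele-frequency units")
  pops <- fit$pops
  if (!all(pops %in% names(E_scenario)))
    stopf("E_scenario must be named by population")
  r <- E_scenario[pops] - fit$fitted[pops]
  data.frame(pop = pops, variable = fit$variable, scenario = scenario,
             f_rona = abs(as.numeric(r)) / sb, stringsAsFactors = FALSE)
}

#' Build the full per-population RONA table
#'
#' Runs [c_rona] for every fitted variable and [f_rona] for every scenario,
#' and returns a wide table with one row per population x variable.
#'
#' @param fits named list of `blup_fit` objects (one per variable).
#' @param env a `std_env` (current period plus scenarios).
#' @return data.frame of class `rona_table`: pop, variable, residual,
#'   c_rona, and one `f_rona_<scenario>` column per scenario.
#' @export
rona_table <- function(fits, env) {
  stopifnot(inherits(env, "std_env"))
  rows <- lapply(fits, function(fit) {
    Ev <- stats::setNames(env$E[, fit$variable], env$pops)
    tab <- c_rona(fit, Ev)
    for (sc in names(env$scenarios)) {
      Es <- stats::setNames(env$scenarios[[sc]][, fit$variable], env$pops)
      fr <- f_rona(fit, Es, sc)
      tab[[paste0("f_rona_", sc)]] <- fr$f_rona[match(tab$pop, fr$pop)]
    }
    tab
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rona_table", "data.frame")
  out
}

#' Combine RONA across variables per population
#'
#' Reports both the mean of absolute residuals (standardized environment
#' units) and the mean c-RONA (allele-frequency units), plus per-scenario
#' mean f-RONA.
#'
#' @param rona a `rona_table`.
#' @return data.frame: pop, mean_abs_residual, mean_c_rona, and
#'   `mean_f_rona_<scenario>` columns.
#' @export
combine_rona <- function(rona) {
  if (!nrow(rona)) stopf("empty RONA table")
  pops <- unique(rona$pop)
  agg <- function(col) tapply(rona[[col]], rona$pop, mean)[pops]
  out <- data.frame(pop = pops,
                    mean_abs_residual = as.numeric(tapply(abs(rona$residual),
                                                          rona$pop, mean)[pops]),
                    mean_c_rona = as.numeric(agg("c_rona")),
                    stringsAsFactors = FALSE)
  for (col in grep("^f_rona_", names(rona), value = TRUE))
    out[[paste0("mean_", col)]] <- as.numeric(agg(col))
  out
}
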