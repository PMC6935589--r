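# Genotype-environment association: covariance-whitened regression with a
# Zellner g-prior Bayes factor, Spearman backup statistic, candidate
# calling and unique locus-to-variable assignment.

#' Whiten a population vector by the drift covariance
#'
#' Returns `L^-1 x` where `Omega = L L'` (lower Cholesky), reducing the
#' Omega-correlated model to ordinary regression.
#'
#' @param x numeric vector (or matrix with one column per series) over
#'   populations.
#' @param omega an `omega_matrix`.
#' @return Whitened vector/matrix.
#' @export
whiten <- function(x, omega) {
  stopifnot(inherits(omega, "omega_matrix"))
  x <- as.matrix(x)
  if (nrow(x) != nrow(omega$W)) stopf("dimension mismatch: %d rows vs %d pops",
                                      nrow(x), nrow(omega$W))
  L <- chol_lower(omega$W)
  out <- forwardsolve(L, x)
  dimnames(out) <- dimnames(x)
  if (ncol(out) == 1) drop(out) else out
}

# closed-form g-prior BF for one added covariate given whitened R^2
gprior_bf <- function(R2, P, g) {
  exp(((P - 2) / 2) * log1p(g) - ((P - 1) / 2) * log1p(g * (1 - R2)))
}

#' g-prior Bayes factor for a locus-environment association
#'
#' In whitened space the locus frequency vector is regressed on the whitened
#' intercept and environmental columns; the Bayes factor of the environment
#' model against the intercept-only null is the Zellner g-prior closed form
#' `BF10 = (1+g)^((P-2)/2) * (1 + g (1 - R^2))^(-(P-1)/2)` with
#' unit-information `g = P` by default. Populations with a masked frequency
#' are dropped and the Omega submatrix used.
#'
#' @param f_l frequency vector over populations (NA = masked).
#' @param E_v standardized environmental vector.
#' @param omega an `omega_matrix`.
#' @param g g-prior scale (default: number of populations used).
#' @return List with `bayes_factor`, `log10_bf`, `R2`, `n_pops`.
#' @export
gea_bayes_factor <- function(f_l, E_v, omega, g = NULL) {
  stopifnot(inherits(omega, "omega_matrix"))
  ok <- !is.na(f_l)
  P <- sum(ok)
  if (P < 4) stopf("need at least 4 populations with data")
  if (stats::sd(E_v[ok]) == 0) stopf("environmental vector is constant")
  W <- omega$W[ok, ok, drop = FALSE]
  L <- chol_lower(W)
  y <- forwardsolve(L, f_l[ok])
  X <- forwardsolve(L, cbind(1, E_v[ok]))
  r2 <- whitened_r2(y, X)
  g <- g %||% P
  bf <- gprior_bf(r2, P, g)
  list(bayes_factor = bf, log10_bf = log10(bf), R2 = r2, n_pops = P)
}

# R^2 of the whitened full fit relative to the whitened intercept-only fit
whitened_r2 <- function(y, X) {
  rss0 <- sum(stats::lsfit(X[, 1], y, intercept = FALSE)$residuals^2)
  rssf <- sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
  max(0, 1 - rssf / rss0)
}

#' Spearman correlation between a locus and an environmental variable
#'
#' Rank correlation with average ranks for ties; returns NA when either
#' vector is constant on the paired complete observations.
#'
#' @param f_l frequency vector (NA allowed).
#' @param E_v environmental vector.
#' @return rho in \[-1, 1\], or NA.
#' @export
spearman_assoc <- function(f_l, E_v) {
  ok <- !is.na(f_l) & !is.na(E_v)
  if (sum(ok) < 4) stopf("need at least 4 paired observations")
  if (stats::sd(f_l[ok]) == 0 || stats::sd(E_v[ok]) == 0) return(NA_real_)
  stats::cor(f_l[ok], E_v[ok], method = "spearman")
}

#' Scan all loci against all environmental variables
#'
#' Computes the g-prior Bayes factor and Spearman rho for every locus x
#' variable combination. Loci genotyped in every population share one
#' Cholesky factorization; loci with masked cells are handled through the
#' per-pattern submatrix route.
#'
#' @param freqs a `freq_matrix`.
#' @param env a `std_env` covering the same populations.
#' @param omega an `omega_matrix`.
#' @param g g-prior scale (default: populations used per locus).
#' @return Long-format data.frame: locus, variable, bf, log10_bf, rho.
#' @export
gea_scan <- function(freqs, env, omega, g = NULL) {
  stopifnot(inherits(freqs, "freq_matrix"), inherits(env, "std_env"))
  if (!identical(freqs$pops, env$pops)) stopf("population sets differ")
  f <- freqs$f
  E <- env$E
  P <- nrow(f)
  complete <- colSums(is.na(f)) == 0
  out <- vector("list", length(env$variables))
  L <- chol_lower(omega$W)
  for (vi in seq_along(env$variables)) {
    v <- env$variables[vi]
    bf <- rep(NA_real_, ncol(f))
    if (any(complete)) {
      gP <- g %||% P
      Y <- forwardsolve(L, f[, complete, drop = FALSE])
      X <- forwardsolve(L, cbind(1, E[, v]))
      qrX <- qr(X)
      qr0 <- qr(X[, 1, drop = FALSE])
      rssf <- colSums(qr.resid(qrX, Y)^2)
      rss0 <- colSums(qr.resid(qr0, Y)^2)
      r2 <- pmax(0, 1 - rssf / rss0)
      bf[complete] <- gprior_bf(r2, P, gP)
    }
    for (l in which(!complete)) {
      res <- gea_bayes_factor(f[, l], E[, v], omega, g)
      bf[l] <- res$bayes_factor
    }
    rho <- suppressWarnings(
      apply(f, 2, function(col) {
        ok <- !is.na(col)
        if (sum(ok) < 4 || stats::sd(col[ok]) == 0) NA_real_
        else stats::cor(col[ok], E[ok, v], method = "spearman")
      }))
    out[[vi]] <- data.frame(locus = freqs$loci, variable = v, bf = bf,
                            log10_bf = log10(bf), rho = rho,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "variable_order") <- env$variables
  res
}

#' Call candidate locus-environment associations
#'
#' A locus is a candidate for a variable iff its log10 Bayes factor exceeds
#' `log10bf_min` (strong support) *and* its absolute Spearman rho reaches
#' the `rho_quantile` empirical quantile of |rho| across all loci tested for
#' that variable.
#'
#' @param results data.frame from [gea_scan].
#' @param log10bf_min log10 Bayes-factor threshold (exclusive).
#' @param rho_quantile per-variable quantile of |rho| (inclusive).
#' @return `results` with a logical `candidate` column and, per variable,
#'   the rho threshold used in `attr(, "rho_threshold")`.
#' @export
call_candidates <- function(results, log10bf_min = 1.0, rho_quantile = 0.90) {
  if (!nrow(results)) stopf("empty results")
  thr <- tapply(abs(results$rho), results$variable,
                stats::quantile, probs = rho_quantile, na.rm = TRUE)
  results$candidate <- !is.na(results$log10_bf) &
    results$log10_bf > log10bf_min &
    !is.na(results$rho) &
    abs(results$rho) >= thr[results$variable]
  attr(results, "rho_threshold") <- thr
  results
}

#' Assign each candidate locus to a single variable
#'
#' Among the variables for which a locus is a candidate, the one with the
#' largest Bayes factor wins (no double counting); exact ties are broken by
#' the environment-table variable order, with a message.
#'
#' @param results candidate-annotated data.frame from [call_candidates].
#' @return List: `assignment` (data.frame locus, variable, bf),
#'   `counts` (named integer vector of per-variable assigned loci).
#' @export
assign_loci <- function(results) {
  if (is.null(results$candidate)) stopf("run call_candidates() first")
  var_order <- attr(results, "variable_order") %||% unique(results$variable)
  cand <- results[results$candidate, , drop = FALSE]
  if (!nrow(cand)) {
    return(list(assignment = data.frame(locus = character(0),
                                        variable = character(0),
                                        bf = numeric(0)),
                counts = stats::setNames(integer(length(var_order)), var_order)))
  }
  cand$variable <- factor(cand$variable, levels = var_order)
  cand <- cand[order(cand$locus, -cand$bf, cand$variable), , drop = FALSE]
  dup <- duplicated(cand$locus)
  ties <- tapply(cand$bf, cand$locus, function(b) sum(b == max(b)) > 1)
  if (any(ties)) message(sprintf(
    "%d locus/loci with tied Bayes factors assigned by variable order",
    sum(ties)))
  top <- cand[!dup, , drop = FALSE]
  counts <- table(factor(top$variable, levels = var_order))
  list(assignment = data.frame(locus = top$locus,
                               variable = as.character(top$variable),
                               bf = top$bf, stringsAsFactors = FALSE),
       counts = stats::setNames(as.integer(counts), var_order))
}
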