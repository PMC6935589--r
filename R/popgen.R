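# Population structure: Weir-Cockerham FST from allele counts, the
# population covariance matrix Omega (shared drift null), and the
# FLK-style chi-square outlier prescreen.

# WC84 variance components for two demes from allele-copy counts
# (haploid-sample form: counts are treated as samples of allele copies,
# so the within-individual component is absorbed into b).
wc84_components <- function(a1, n1, a2, n2) {
  ok <- n1 > 0 & n2 > 0
  a1 <- a1[ok]; n1 <- n1[ok]; a2 <- a2[ok]; n2 <- n2[ok]
  if (!length(a1)) stopf("no shared loci between the two populations")
  p1 <- a1 / n1; p2 <- a2 / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) * s2 / r)
  list(a = a, b = b)
}

#' Pairwise FST between two populations (Weir-Cockerham 1984)
#'
#' Multi-locus ratio-of-sums estimator over the loci shared (genotyped in
#' both populations). Negative ratios are reported as computed.
#'
#' @param counts a [genotype_counts] object.
#' @param popA,popB population ids.
#' @param loci optional locus id subset.
#' @return Scalar FST estimate.
#' @export
pairwise_fst <- function(counts, popA, popB, loci = NULL) {
  stopifnot(inherits(counts, "genotype_counts"))
  loci <- loci %||% counts$loci
  i <- match(popA, counts$pops); j <- match(popB, counts$pops)
  if (is.na(i) || is.na(j)) stopf("unknown population id")
  cmp <- wc84_components(counts$alt[i, loci], counts$n[i, loci],
                         counts$alt[j, loci], counts$n[j, loci])
  sum(cmp$a) / sum(cmp$a + cmp$b)
}

#' All-pairs FST matrix with optional permutation significance
#'
#' For each pair the multi-locus WC84 estimate is computed; when
#' `n_perm > 0`, allele copies are reshuffled between the two populations at
#' each locus (hypergeometric resampling of the pooled counts) and the
#' p-value is the add-one proportion `(x + 1) / (n_perm + 1)` of permuted
#' estimates at least as large as the observed one.
#'
#' @param counts a [genotype_counts] object.
#' @param loci optional locus id subset.
#' @param n_perm number of permutations per pair (0 skips p-values).
#' @param subset_label label recorded on the result ("neutral", "adaptive",
#'   "all", ...).
#' @param seed optional RNG seed for the permutations.
#' @return Object of class `fst_matrix`: `fst` (symmetric, diagonal 0),
#'   `p` (or NULL), `pops`, `subset_label`.
#' @export
fst_matrix <- function(counts, loci = NULL, n_perm = 1000,
                       subset_label = "all", seed = NULL) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (n_perm < 0) stopf("n_perm must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  loci <- loci %||% counts$loci
  P <- length(counts$pops)
  if (P < 2) stopf("need at least 2 populations")
  fst <- matrix(0, P, P, dimnames = list(counts$pops, counts$pops))
  pmat <- if (n_perm > 0) matrix(NA_real_, P, P, dimnames = dimnames(fst)) else NULL
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    a1 <- counts$alt[i, loci]; n1 <- counts$n[i, loci]
    a2 <- counts$alt[j, loci]; n2 <- counts$n[j, loci]
    cmp <- wc84_components(a1, n1, a2, n2)
    obs <- sum(cmp$a) / sum(cmp$a + cmp$b)
    fst[i, j] <- fst[j, i] <- obs
    if (n_perm > 0) {
      ok <- n1 > 0 & n2 > 0
      k <- (a1 + a2)[ok]; m1 <- n1[ok]; m2 <- n2[ok]
      L <- length(k)
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        a1p <- stats::rhyper(L, k, m1 + m2 - k, m1)
        cp <- wc84_components(a1p, m1, k - a1p, m2)
        if (sum(cp$a) / sum(cp$a + cp$b) >= obs) exceed <- exceed + 1L
      }
      pmat[i, j] <- pmat[j, i] <- (exceed + 1) / (n_perm + 1)
    }
  }
  if (!is.null(pmat)) diag(pmat) <- NA_real_
  structure(list(fst = fst, p = pmat, pops = counts$pops,
                 subset_label = subset_label),
            class = "fst_matrix")
}

#' @exportS3Method base::print
print.fst_matrix <- function(x, ...) {
  off <- x$fst[upper.tri(x$fst)]
  cat(sprintf("<fst_matrix> %d pops, subset '%s', mean pairwise FST %.3f\n",
              length(x$pops), x$subset_label, mean(off)))
  invisible(x)
}

#' Write an FST matrix as TSV (square grid plus long-format pairs)
#' @param fm an `fst_matrix`.
#' @param path output path for the square grid; pairs go to `<path>.pairs.tsv`.
#' @return `path`, invisibly.
#' @export
write_fst_tsv <- function(fm, path) {
  df <- data.frame(pop = fm$pops, signif(fm$fst, 8), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(upper.tri(fm$fst), arr.ind = TRUE)
  pairs <- data.frame(popA = fm$pops[idx[, 1]], popB = fm$pops[idx[, 2]],
                      fst = signif(fm$fst[idx], 8),
                      p = if (is.null(fm$p)) NA else signif(fm$p[idx], 6))
  utils::write.table(pairs, paste0(path, ".pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate the population covariance matrix Omega
#'
#' For each retained locus the frequency vector is centred on its across-pop
#' mean and scaled by `sqrt(fbar * (1 - fbar))`; Omega is the average outer
#' product over loci plus a trace-scaled ridge that guarantees positive
#' definiteness. Masked cells are handled by pairwise-complete averaging.
#' Loci whose across-pop mean frequency is 0 or 1 carry no information and
#' are excluded with a warning.
#'
#' @param freqs a `freq_matrix`.
#' @param excluded_loci locus ids to leave out (e.g. outlier-flagged loci).
#' @return Object of class `omega_matrix`: `W` (P x P), `pops`, `epsilon`
#'   (ridge added to the diagonal), `n_loci`.
#' @export
estimate_omega <- function(freqs, excluded_loci = character(0)) {
  stopifnot(inherits(freqs, "freq_matrix"))
  P <- length(freqs$pops)
  if (P < 3) stopf("need at least 3 populations")
  keep <- setdiff(freqs$loci, excluded_loci)
  if (length(keep) < 2) stopf("need at least 2 non-excluded loci")
  f <- freqs$f[, keep, drop = FALSE]
  fbar <- colMeans(f, na.rm = TRUE)
  degenerate <- fbar <= 0 | fbar >= 1 | !is.finite(fbar)
  if (any(degenerate)) {
    warnf("excluding %d locus/loci with across-pop mean frequency 0 or 1",
          sum(degenerate))
    f <- f[, !degenerate, drop = FALSE]
    fbar <- fbar[!degenerate]
  }
  if (!ncol(f)) stopf("no informative loci left for Omega")
  U <- sweep(sweep(f, 2, fbar), 2, sqrt(fbar * (1 - fbar)), "/")
  U0 <- U; U0[is.na(U0)] <- 0
  M <- (!is.na(U)) * 1
  S <- tcrossprod(U0)          # sum over loci of u_i u_j where both present
  Npair <- tcrossprod(M)       # number of loci contributing per pair
  if (any(Npair == 0)) stopf("some population pairs share no loci")
  W <- S / Npair
  eps <- 1e-6 * sum(diag(W)) / P
  W <- W + diag(eps, P)
  dimnames(W) <- list(freqs$pops, freqs$pops)
  structure(list(W = W, pops = freqs$pops, epsilon = eps, n_loci = ncol(f)),
            class = "omega_matrix")
}

#' @exportS3Method base::print
print.omega_matrix <- function(x, ...) {
  cat(sprintf("<omega_matrix> %d pops from %d loci (ridge %.2e); mean diag %.3f\n",
              length(x$pops), x$n_loci, x$epsilon, mean(diag(x$W))))
  invisible(x)
}

#' FLK-style chi-square outlier screen
#'
#' For each locus a GLS mean frequency under the drift null is computed and
#' the quadratic form `T = (f - fhat)' Omega^-1 (f - fhat) / (fhat (1 - fhat))`
#' is referred to a chi-square with P - 1 degrees of freedom;
#' Benjamini-Hochberg control at the stated FDR flags outliers.
#' Loci with masked cells are tested on the populations present, against the
#' corresponding Omega submatrix (degrees of freedom reduced accordingly).
#'
#' @param freqs a `freq_matrix`.
#' @param omega an `omega_matrix` for the same populations.
#' @param fdr Benjamini-Hochberg false discovery rate.
#' @return List: `flagged` (locus ids), `stats` (data.frame locus, T, df, p,
#'   flagged).
#' @export
flk_outlier_screen <- function(freqs, omega, fdr = 0.2) {
  stopifnot(inherits(freqs, "freq_matrix"), inherits(omega, "omega_matrix"))
  if (!identical(freqs$pops, omega$pops)) stopf("population sets differ")
  W <- omega$W
  Winv <- solve(W)
  one <- rep(1, nrow(W))
  f <- freqs$f
  complete <- colSums(is.na(f)) == 0
  Tstat <- rep(NA_real_, ncol(f)); df <- rep(NA_real_, ncol(f))
  if (any(complete)) {
    Fc <- f[, complete, drop = FALSE]
    w1 <- Winv %*% one
    fhat <- as.vector(crossprod(w1, Fc)) / sum(w1)
    R <- Fc - outer(one, fhat)
    quad <- colSums(R * (Winv %*% R))
    Tstat[complete] <- quad / (fhat * (1 - fhat))
    df[complete] <- nrow(W) - 1
  }
  for (l in which(!complete)) {
    ok <- !is.na(f[, l])
    if (sum(ok) < 3) next
    Wi <- solve(W[ok, ok])
    fl <- f[ok, l]
    fh <- sum(Wi %*% fl) / sum(Wi)
    r <- fl - fh
    Tstat[l] <- as.numeric(crossprod(r, Wi %*% r)) / (fh * (1 - fh))
    df[l] <- sum(ok) - 1
  }
  bad <- is.finite(Tstat) & Tstat < 0
  Tstat[bad] <- 0
  p <- stats::pchisq(Tstat, df, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  flagged <- freqs$loci[!is.na(padj) & padj <= fdr]
  list(flagged = flagged,
       stats = data.frame(locus = freqs$loci, T = Tstat, df = df, p = p,
                          p_bh = padj,
                          flagged = freqs$loci %in% flagged,
                          stringsAsFactors = FALSE))
}
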