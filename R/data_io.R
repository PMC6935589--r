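# Domain containers and file input/output: population tables, per-population
# allele counts, frequency matrices and standardized environment tables.

#' Construct a genotype-counts object
#'
#' Per-population alternate-allele copy counts at biallelic loci, the
#' post-variant-calling product everything downstream consumes. Rows are
#' populations, columns are loci. `n` holds the number of allele copies
#' actually genotyped in each cell (0 means the locus was not observed in
#' that population).
#'
#' @param alt integer matrix (populations x loci) of alternate-allele copies.
#' @param n integer matrix of the same shape: total genotyped allele copies.
#' @return An object of class `genotype_counts` with elements `alt`, `n`,
#'   `pops`, `loci`.
#' @export
genotype_counts <- function(alt, n) {
  alt <- as.matrix(alt); n <- as.matrix(n)
  if (!all(dim(alt) == dim(n))) stopf("alt and n must have identical dimensions")
  if (is.null(rownames(alt))) stopf("alt must have population rownames")
  if (is.null(colnames(alt))) stopf("alt must have locus colnames")
  if (anyNA(alt) || anyNA(n)) stopf("counts must not contain NA; use n = 0 for missing cells")
  if (any(alt < 0) || any(n < 0) || any(alt > n))
    stopf("counts must satisfy 0 <= alt_count <= n_chrom")
  structure(list(alt = alt, n = n,
                 pops = rownames(alt), loci = colnames(alt)),
            class = "genotype_counts")
}

#' @exportS3Method base::print
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %d populations x %d loci\n",
              length(x$pops), length(x$loci)))
  invisible(x)
}

#' Validate a population metadata table
#'
#' Checks the invariants of the population table: unique ids, coordinates in
#' WGS84 range, and any rate columns in \[0, 1\].
#'
#' @param pop_table data.frame with at least `pop_id`, `latitude`,
#'   `longitude`; optionally `elevation`, `n_genotyped`, `catkin_mean`,
#'   `germination_rate`, `survival_rate`.
#' @return The table, invisibly, after validation.
#' @export
validate_pop_table <- function(pop_table) {
  req <- c("pop_id", "latitude", "longitude")
  miss <- setdiff(req, names(pop_table))
  if (length(miss)) stopf("pop table missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(pop_table$pop_id)) stopf("pop_id values must be unique")
  if (any(pop_table$latitude < -90 | pop_table$latitude > 90))
    stopf("latitude out of [-90, 90]")
  if (any(pop_table$longitude < -180 | pop_table$longitude > 180))
    stopf("longitude out of [-180, 180]")
  for (rc in c("germination_rate", "survival_rate")) {
    if (rc %in% names(pop_table)) {
      v <- pop_table[[rc]]
      if (any(v < 0 | v > 1, na.rm = TRUE)) stopf("%s must lie in [0, 1]", rc)
    }
  }
  invisible(pop_table)
}

#' Read population allele counts from a VCF
#'
#' Aggregates per-sample genotypes into per-population alternate-allele copy
#' counts. Multi-allelic records are skipped with a warning; missing
#' genotype calls reduce the genotyped copy number `n` for that cell.
#'
#' @param path path to a VCF 4.x file with biallelic SNP records.
#' @param pop_map data.frame with columns `sample_id`, `pop_id` mapping every
#'   sample in the VCF to a population.
#' @return A [genotype_counts] object.
#' @export
read_genotype_vcf <- function(path, pop_map) {
  if (!file.exists(path)) stopf("cannot read VCF: %s", path)
  if (!all(c("sample_id", "pop_id") %in% names(pop_map)))
    stopf("pop_map needs columns sample_id, pop_id")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  unknown <- setdiff(samples, pop_map$sample_id)
  if (length(unknown))
    stopf("samples in VCF absent from pop_map: %s", paste(unknown, collapse = ", "))
  bial <- vcfR::is.biallelic(vcf)
  if (any(!bial)) {
    warnf("skipping %d multi-allelic record(s)", sum(!bial))
    gt <- gt[bial, , drop = FALSE]
  }
  if (nrow(gt) == 0) stopf("no biallelic records in %s", path)
  loci <- rownames(gt)
  # after restriction to biallelic records, allele codes are 0, 1 or '.'
  cells <- ifelse(is.na(gt), "", gt)
  alt_per <- nchar(gsub("[^1]", "", cells))
  tot_per <- nchar(gsub("[^01]", "", cells))
  dim(alt_per) <- dim(tot_per) <- dim(gt)
  pop_of <- pop_map$pop_id[match(samples, pop_map$sample_id)]
  pops <- unique(pop_of)
  ind <- outer(pop_of, pops, `==`) * 1  # samples x pops indicator
  alt <- t(alt_per %*% ind)             # pops x loci
  n   <- t(tot_per %*% ind)
  rownames(alt) <- rownames(n) <- pops
  colnames(alt) <- colnames(n) <- loci
  genotype_counts(alt, n)
}

#' Compute a filtered population x locus frequency matrix
#'
#' Applies the locus retention rules: a locus is kept iff it is present
#' (at least one genotyped allele copy) in at least `min_pops` populations
#' and its global minor-allele frequency, computed on counts pooled across
#' populations, exceeds `maf`. Frequencies are then computed per population;
#' cells with no data are masked (NA).
#'
#' @param counts a [genotype_counts] object.
#' @param min_pops minimum number of populations a locus must be present in.
#' @param maf global pooled minor-allele frequency threshold (exclusive).
#' @return An object of class `freq_matrix`: list with `f` (frequencies,
#'   NA where masked), `n` (allele copies), `mask` (presence), `pops`, `loci`.
#' @export
compute_frequencies <- function(counts, min_pops = 8, maf = 0.05) {
  stopifnot(inherits(counts, "genotype_counts"))
  present <- counts$n > 0
  n_pops_with <- colSums(present)
  pooled_alt <- colSums(counts$alt)
  pooled_n <- colSums(counts$n)
  pooled_f <- ifelse(pooled_n > 0, pooled_alt / pooled_n, NA_real_)
  global_maf <- pmin(pooled_f, 1 - pooled_f)
  keep <- n_pops_with >= min_pops & !is.na(global_maf) & global_maf > maf
  if (!any(keep))
    stopf("all %d loci removed by the presence/MAF filter", length(keep))
  alt <- counts$alt[, keep, drop = FALSE]
  n <- counts$n[, keep, drop = FALSE]
  f <- ifelse(n > 0, alt / n, NA_real_)
  dimnames(f) <- dimnames(n)
  structure(list(f = f, n = n, mask = n > 0,
                 pops = rownames(f), loci = colnames(f)),
            class = "freq_matrix")
}

#' @exportS3Method base::print
print.freq_matrix <- function(x, ...) {
  cat(sprintf("<freq_matrix> %d populations x %d loci (%.1f%% cells masked)\n",
              length(x$pops), length(x$loci), 100 * mean(!x$mask)))
  invisible(x)
}

#' Convert a frequency matrix back to genotype counts
#'
#' Inverse of the frequency computation (alt = f * n rounded), used when a
#' downstream step needs counts for a retained locus subset.
#' @param freqs a `freq_matrix`.
#' @return A [genotype_counts] object.
#' @export
freq_to_counts <- function(freqs) {
  f0 <- freqs$f; f0[!freqs$mask] <- 0
  genotype_counts(round(f0 * freqs$n), freqs$n)
}

#' Standardize environmental tables
#'
#' Z-scores every current-period variable (sample SD, denominator n-1) and
#' transforms each scenario table with the *same* per-variable mean/SD so
#' that projected shifts are expressed relative to the current climate.
#'
#' @param raw_env data.frame with a `pop_id` column plus numeric variables
#'   (current period).
#' @param scenario_tables named list of data.frames with the same layout and
#'   variable set (future scenarios).
#' @return Object of class `std_env`: `E` (pops x variables, mean 0 / SD 1),
#'   `scenarios` (named list of matrices on the current-period scale),
#'   `center`, `scale`, `pops`, `variables`.
#' @export
standardize_env <- function(raw_env, scenario_tables = list()) {
  if (!"pop_id" %in% names(raw_env)) stopf("raw_env needs a pop_id column")
  pops <- as.character(raw_env$pop_id)
  if (length(pops) < 2) stopf("need at least 2 populations")
  X <- as.matrix(raw_env[, setdiff(names(raw_env), "pop_id"), drop = FALSE])
  rownames(X) <- pops
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  bad <- names(scl)[scl == 0 | !is.finite(scl)]
  if (length(bad)) stopf("constant environmental variable(s): %s", paste(bad, collapse = ", "))
  E <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  scen <- lapply(scenario_tables, function(tab) {
    if (!"pop_id" %in% names(tab)) stopf("scenario table needs a pop_id column")
    S <- as.matrix(tab[, colnames(X), drop = FALSE])
    rownames(S) <- as.character(tab$pop_id)
    S <- S[pops, , drop = FALSE]
    sweep(sweep(S, 2, ctr), 2, scl, "/")
  })
  structure(list(E = E, scenarios = scen, center = ctr, scale = scl,
                 pops = pops, variables = colnames(X)),
            class = "std_env")
}

#' Recover raw environmental values from a standardized table
#'
#' @param env a `std_env` object.
#' @param scenario scenario name, or NULL for the current period.
#' @return Matrix of raw (de-standardized) values.
#' @export
destandardize_env <- function(env, scenario = NULL) {
  M <- env_matrix(env, scenario)
  sweep(sweep(M, 2, env$scale, "*"), 2, env$center, "+")
}

# pick the current-period or a named scenario matrix
env_matrix <- function(env, scenario = NULL) {
  stopifnot(inherits(env, "std_env"))
  if (is.null(scenario) || identical(scenario, "current")) return(env$E)
  if (!scenario %in% names(env$scenarios))
    stopf("unknown scenario '%s' (have: %s)", scenario,
          paste(c("current", names(env$scenarios)), collapse = ", "))
  env$scenarios[[scenario]]
}

#' Write / read a frequency matrix as TSV
#'
#' The grid is written with loci as rows and populations as columns, "NA"
#' for masked cells, at 10 significant digits; a companion `.n.tsv` file
#' carries the allele-copy numbers.
#'
#' @param freqs a `freq_matrix`.
#' @param path output path for the frequency grid; the sample-size grid is
#'   written next to it with suffix `.n.tsv`.
#' @return `path`, invisibly.
#' @export
write_freq_tsv <- function(freqs, path) {
  fm <- t(freqs$f)
  df <- data.frame(locus = rownames(fm), signif(fm, 10), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nm <- t(freqs$n)
  dn <- data.frame(locus = rownames(nm), nm, check.names = FALSE)
  utils::write.table(dn, paste0(path, ".n.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_tsv
#' @export
read_freq_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  dn <- utils::read.table(paste0(path, ".n.tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE)
  f <- t(as.matrix(df[, -1, drop = FALSE])); colnames(f) <- df$locus
  n <- t(as.matrix(dn[, -1, drop = FALSE])); colnames(n) <- dn$locus
  structure(list(f = f, n = n, mask = n > 0,
                 pops = rownames(f), loci = colnames(f)),
            class = "freq_matrix")
}
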