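# Validation computations: the collinearity pre-filter for environmental
# variables, the GEA-count vs niche-model-importance correlation, fitness
# proxy regressions against c-RONA, and the annotation / germination
# summary arithmetic.

#' Greedy collinearity filter for environmental variables
#'
#' Scans variables in preference order (less derived first) and keeps a
#' variable iff its absolute correlation with every already-kept variable is
#' at most `threshold`. Dropped variables are mapped to the kept variable
#' they exceeded the threshold with.
#'
#' @param cor_mat symmetric correlation matrix with variable dimnames.
#' @param preference character vector ordering all variables.
#' @param threshold absolute-correlation cutoff (exclusive: keep iff
#'   `|cor| <= threshold`).
#' @return List: `retained` (character), `dropped` (named character:
#'   dropped variable -> retained variable it correlated with).
#' @export
collinearity_filter <- function(cor_mat, preference, threshold = 0.7) {
  cor_mat <- as.matrix(cor_mat)
  if (max(abs(cor_mat - t(cor_mat))) > 1e-12)
    stopf("correlation matrix must be symmetric")
  if (!setequal(preference, colnames(cor_mat)))
    stopf("preference must cover exactly the variables in cor_mat")
  retained <- character(0)
  dropped <- character(0)
  for (v in preference) {
    conflict <- retained[abs(cor_mat[v, retained]) > threshold]
    if (length(conflict)) {
      dropped[v] <- conflict[1]
    } else {
      retained <- c(retained, v)
    }
  }
  list(retained = retained, dropped = dropped)
}

#' Correlate per-variable GEA counts with niche-model importance
#'
#' Pearson correlation with the textbook t test:
#' `t = r sqrt((n - 2) / (1 - r^2))`, two-sided p on n - 2 df.
#'
#' @param counts numeric vector of association counts per variable.
#' @param importance numeric vector of percentage contributions (same order).
#' @return data.frame: test, statistic, df1, df2, p, direction.
#' @export
correlate_counts_importance <- function(counts, importance) {
  if (length(counts) != length(importance)) stopf("length mismatch")
  n <- length(counts)
  if (n < 3) stopf("need at least 3 variables")
  if (stats::sd(counts) == 0 || stats::sd(importance) == 0)
    stopf("constant input")
  ct <- stats::cor.test(counts, importance, method = "pearson")
  data.frame(test = "gea_count_vs_enm_importance",
             statistic = unname(ct$estimate),
             df1 = 1, df2 = n - 2, p = ct$p.value,
             direction = ifelse(ct$estimate > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Fitness-proxy validation of c-RONA
#'
#' (a) Ordinary linear regression of square-root catkin counts on c-RONA
#' for each requested variable, with the F test of the slope. (b) An
#' overdispersed logit-link (quasibinomial) fit of germination rate on the
#' c-RONA terms and their pairwise interaction, with an F test against the
#' intercept-only model. Negative slopes support c-RONA as a maladaptation
#' measure.
#'
#' @param rona a `rona_table`.
#' @param pop_table population table with `catkin_mean` and, optionally,
#'   `germination_rate` (+ `n_seeds` weights).
#' @param variables variables to test (default: first two fitted).
#' @return data.frame of tests: test, statistic (F), df1, df2, p, direction.
#' @export
fitness_validation <- function(rona, pop_table, variables = NULL) {
  variables <- variables %||% utils::head(unique(rona$variable), 2)
  wide <- stats::reshape(rona[rona$variable %in% variables,
                              c("pop", "variable", "c_rona")],
                         idvar = "pop", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^c_rona\\.", "", names(wide))
  dat <- merge(wide, pop_table, by.x = "pop", by.y = "pop_id")
  if (nrow(dat) < 4) stopf("fewer than 4 populations with phenotypes")
  out <- list()
  for (v in variables) {
    y <- sqrt(dat$catkin_mean)
    if (stats::var(y) < 1e-12) {   # constant response: slope 0, F defined as 0
      out[[length(out) + 1]] <- data.frame(
        test = paste0("sqrt_catkin_vs_crona_", v),
        statistic = 0, df1 = 1L, df2 = nrow(dat) - 2L, p = 1,
        direction = "positive", stringsAsFactors = FALSE)
      next
    }
    fit <- stats::lm(y ~ x, data = data.frame(y = y, x = dat[[v]]))
    an <- stats::anova(fit)
    out[[length(out) + 1]] <- data.frame(
      test = paste0("sqrt_catkin_vs_crona_", v),
      statistic = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
      p = an$`Pr(>F)`[1],
      direction = ifelse(stats::coef(fit)[2] < 0, "negative", "positive"),
      stringsAsFactors = FALSE)
  }
  if ("germination_rate" %in% names(dat) &&
      !all(is.na(dat$germination_rate)) && length(variables) >= 2) {
    w <- if ("n_seeds" %in% names(dat)) dat$n_seeds else rep(100, nrow(dat))
    v1 <- dat[[variables[1]]]; v2 <- dat[[variables[2]]]
    full <- stats::glm(germination_rate ~ v1 * v2, data = dat,
                       family = stats::quasibinomial(), weights = w)
    null <- stats::glm(germination_rate ~ 1, data = dat,
                       family = stats::quasibinomial(), weights = w)
    an <- stats::anova(null, full, test = "F")
    out[[length(out) + 1]] <- data.frame(
      test = paste0("germination_vs_crona_interaction_",
                    paste(variables[1:2], collapse = "x")),
      statistic = an$F[2], df1 = an$Df[2], df2 = full$df.residual,
      p = an$`Pr(>F)`[2],
      direction = ifelse(sum(stats::coef(full)[2:3]) < 0, "negative",
                         "positive"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotation proportion summary for candidate regions
#'
#' Percentages of candidate scaffolds with expression evidence, as
#' unrounded values plus integer display rounding (half-up).
#'
#' @param n_scaffolds number of unique candidate scaffolds.
#' @param flags data.frame with logical columns `expressed_flower`,
#'   `expressed_leaf` (one row per flagged scaffold or per scaffold).
#' @return data.frame: tissue, count, pct, pct_display.
#' @export
annotation_summary <- function(n_scaffolds, flags) {
  stopifnot(n_scaffolds >= 1)
  counts <- c(flower = sum(flags$expressed_flower),
              leaf = sum(flags$expressed_leaf),
              both = sum(flags$expressed_flower & flags$expressed_leaf))
  if (any(counts > n_scaffolds)) stopf("count exceeds number of scaffolds")
  pct <- 100 * counts / n_scaffolds
  data.frame(tissue = names(counts), count = as.integer(counts),
             pct = as.numeric(pct),
             pct_display = as.integer(round_half_up(pct)),
             stringsAsFactors = FALSE)
}

#' Conditional seedling survival from germination and survival percentages
#'
#' Survival among germinated seeds: `100 * survival_pct / germination_pct`,
#' with integer display rounding.
#'
#' @param germination_pct percentage of seeds that germinated (0, 100\].
#' @param survival_pct percentage of seeds surviving (<= germination_pct).
#' @return List: `pct` (unrounded), `pct_display` (integer).
#' @export
germination_summary <- function(germination_pct, survival_pct) {
  if (germination_pct <= 0 || germination_pct > 100)
    stopf("germination_pct must be in (0, 100]")
  if (survival_pct < 0 || survival_pct > germination_pct)
    stopf("survival_pct must be in [0, germination_pct]")
  pct <- 100 * survival_pct / germination_pct
  list(pct = pct, pct_display = as.integer(round_half_up(pct)))
}
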