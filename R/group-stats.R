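#' One-way ANOVA across groups
#'
#' Classical one-way analysis of variance of a numeric response across group
#' labels. Degenerate inputs follow the documented contracts: zero
#' within-group variance with equal means gives F = 0, p = 1; zero
#' within-group variance with differing means gives F = Inf, p = 0.
#'
#' @param data A data frame.
#' @param value Column name (string) of the response.
#' @param group Column name (string) of the group labels (>= 2 groups, each
#'   with >= 2 observations).
#' @return A one-row tibble: `F`, `p_raw`, `df_between`, `df_within`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5), g = rep(c("a", "b", "c"), each = 3))
#' anova_oneway(d, "y", "g") # F = 3
#' @export
anova_oneway <- function(data, value, group) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("ANOVA needs at least two groups")
  if (any(table(g) < 2)) abort("Every group needs at least two observations")
  df_b <- nlevels(g) - 1
  df_w <- length(y) - nlevels(g)
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  if (ssw == 0) {
    if (ssb == 0) {
      return(tibble::tibble(F = 0, p_raw = 1, df_between = df_b, df_within = df_w))
    }
    return(tibble::tibble(F = Inf, p_raw = 0, df_between = df_b, df_within = df_w))
  }
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1]]
  tibble::tibble(
    F = tab$`F value`[1], p_raw = tab$`Pr(>F)`[1],
    df_between = tab$Df[1], df_within = tab$Df[2]
  )
}

#' Bonferroni adjustment
#'
#' `p_adjusted = min(1, m * p_raw)`, vectorized over `p_raw`.
#'
#' @param p_raw Raw p-value(s).
#' @param m Number of tests in the family.
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni <- function(p_raw, m) pmin(1, m * p_raw)

#' Bonferroni family size for the band-wise analyses
#'
#' The family size is the product of the number of subject groups, frequency
#' bands and network parameters compared: 3 groups x 7 bands = 21 tests for
#' the functional-connectivity analysis, and 3 x 7 x 4 = 84 for the
#' graph-theory analysis.
#'
#' @param n_groups,n_bands,n_parameters Factors of the family size.
#' @return The test count.
#' @examples
#' correction_count(3, 7) # 21
#' correction_count(3, 7, 4) # 84
#' @export
correction_count <- function(n_groups, n_bands, n_parameters = 1) {
  n_groups * n_bands * n_parameters
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of a numeric sample against a normal distribution
#' (location/scale estimated from the sample unless given). Used as a
#' pipeline gate: departures produce warnings downstream, not hard stops.
#'
#' @param x Numeric sample (n >= 3, non-constant).
#' @param mean,sd Reference normal parameters (default: sample estimates).
#' @return A one-row tibble: `D`, `p`.
#' @export
normality_ks <- function(x, mean = base::mean(x), sd = stats::sd(x)) {
  if (length(x) < 3) abort("Need at least 3 observations")
  if (stats::sd(x) == 0) abort("Constant sample: normality test is degenerate")
  res <- suppressWarnings(ks.test(x, "pnorm", mean = mean, sd = sd))
  tibble::tibble(D = unname(res$statistic), p = res$p.value)
}

#' Levene homogeneity-of-variance check
#'
#' Levene's test (centre = median, i.e. the Brown-Forsythe form) of equal
#' variances across groups.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and group.
#' @return A one-row tibble: `W`, `p`.
#' @export
homogeneity_levene <- function(data, value, group) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (any(table(g) < 3)) abort("Every group needs at least 3 observations")
  res <- car::leveneTest(y, g)
  tibble::tibble(W = res$`F value`[1], p = res$`Pr(>F)`[1])
}

#' Correlation between a network metric and a clinical variable
#'
#' Pearson or Spearman correlation with a two-sided p-value.
#'
#' @param metric,clinical Paired numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `r`, `p`, `n`, `method`.
#' @export
clinical_correlation <- function(metric, clinical, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(metric) != length(clinical)) abort("Vectors must be paired")
  if (length(metric) < 3) abort("Need at least 3 pairs")
  if (sd(metric) == 0 || sd(clinical) == 0) {
    abort("Constant vector: correlation is undefined")
  }
  res <- suppressWarnings(cor.test(metric, clinical, method = method))
  tibble::tibble(
    r = unname(res$estimate), p = res$p.value,
    n = length(metric), method = method
  )
}

#' Band-wise group comparison with Bonferroni correction
#'
#' For each frequency band, runs a one-way ANOVA of one parameter across the
#' groups, Bonferroni-corrects the raw p by the family size `m`, and adds
#' post-hoc pairwise two-sample t-tests (Bonferroni-corrected within the
#' three-comparison family). Group levels are compared in the order given by
#' `group_order` (A vs B, B vs C, A vs C).
#'
#' @param data Data frame with one row per subject x band.
#' @param value Column name (string) of the parameter.
#' @param m Bonferroni family size (see [correction_count()]).
#' @param group,band Column names of the group and band labels.
#' @param group_order Optional character vector fixing the A/B/C order.
#' @return A tibble with one row per band: `band`, `parameter`, `F`,
#'   `p_raw`, `p_bonferroni`, `p_AB`, `p_BC`, `p_AC`.
#' @export
compare_bands <- function(data, value, m,
                          group = "group", band = "band",
                          group_order = NULL) {
  g <- factor(data[[group]])
  if (!is.null(group_order)) g <- factor(as.character(g), levels = group_order)
  lv <- levels(g)
  data$.group <- g
  data |>
    dplyr::group_by(band = .data[[band]]) |>
    dplyr::group_modify(function(d, key) {
      a <- anova_oneway(d, value, ".group")
      pw <- function(l1, l2) {
        if (!all(c(l1, l2) %in% as.character(d$.group))) {
          return(NA_real_)
        }
        x <- d[[value]][d$.group == l1]
        y <- d[[value]][d$.group == l2]
        if (sd(c(x, y)) == 0) {
          return(1)
        }
        min(1, 3 * t.test(x, y, var.equal = TRUE)$p.value)
      }
      tibble::tibble(
        parameter = value, F = a$F, p_raw = a$p_raw,
        p_bonferroni = bonferroni(a$p_raw, m),
        p_AB = pw(lv[1], lv[2]),
        p_BC = if (length(lv) > 2) pw(lv[2], lv[3]) else NA_real_,
        p_AC = if (length(lv) > 2) pw(lv[1], lv[3]) else NA_real_
      )
    }) |>
    dplyr::ungroup()
}
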