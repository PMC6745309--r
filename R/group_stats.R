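#' @title Group statistics
#' @description
#' The statistical layer applied to subject-level features: one-way ANOVA
#' with Tukey HSD post hoc, Student's unpaired t-test (pooled variance by
#' default, Welch optional), Pearson test-retest reliability, and the
#' conventional significance-star labelling.
#' @name group_stats
NULL

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Standard one-way ANOVA omnibus F/p (via [stats::aov()]) with Tukey
#' honest-significant-difference pairwise comparisons (studentized-range
#' distribution, via [stats::TukeyHSD()]). Groups with fewer than 2 values
#' are dropped with a flag.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @return a `group_comparison` list: `groups` (per-group n/mean/sd/sem),
#'   `f_statistic`, `p_value`, `pairwise` data.frame (`contrast`,
#'   `estimate`, `p_adj`), `method`, `flags`.
#' @export
anova_tukey <- function(values_by_group) {
  flags <- character(0)
  sizes <- vapply(values_by_group, length, 1L)
  if (any(sizes < 2)) {
    flags <- c(flags, sprintf("group(s) dropped (n < 2): %s",
                              paste(names(values_by_group)[sizes < 2],
                                    collapse = ", ")))
    values_by_group <- values_by_group[sizes >= 2]
  }
  if (length(values_by_group) < 2)
    stop("at least two groups with n >= 2 are required")
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group),
                       vapply(values_by_group, length, 1L))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  tk <- as.data.frame(stats::TukeyHSD(fit)$group)
  pairwise <- data.frame(contrast = rownames(tk), estimate = tk$diff,
                         lwr = tk$lwr, upr = tk$upr, p_adj = tk$`p adj`,
                         row.names = NULL)
  groups <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = stats::sd(v), sem = stats::sd(v) / sqrt(length(v)))
  }))
  structure(list(groups = groups, f_statistic = fstat, p_value = pval,
                 pairwise = pairwise, method = "one-way ANOVA + Tukey HSD",
                 flags = flags),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F = %.4g, p = %.4g (%s)\n",
              x$method, x$f_statistic, x$p_value,
              significance_stars(x$p_value)))
  invisible(x)
}

#' Student's unpaired t-test
#'
#' Pooled-variance Student t by default; Welch when `pooled = FALSE`.
#' Two-sided. When both groups have zero variance and equal means the test
#' is undefined and `t = 0, p = 1` is returned by convention, flagged.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @param pooled use the pooled-variance Student t (default `TRUE`).
#' @return list with `statistic`, `df`, `p_value`, `flags`.
#' @export
unpaired_t <- function(x, y, pooled = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1, flags = "zero variance in both groups"))
    return(list(statistic = ifelse(mean(x) > mean(y), Inf, -Inf),
                df = length(x) + length(y) - 2, p_value = 0,
                flags = "zero variance in both groups"))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, flags = character(0))
}

#' Pearson test-retest reliability
#'
#' Pearson correlation across subjects between two sessions, with the
#' two-sided p-value.
#'
#' @param x_session1,y_session2 paired numeric vectors (n >= 3).
#' @return list with `r`, `p_value`, `n`, `method`, `flags`.
#' @export
reliability <- function(x_session1, y_session2) {
  stopifnot(length(x_session1) == length(y_session2),
            length(x_session1) >= 3)
  if (stats::sd(x_session1) == 0 || stats::sd(y_session2) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x_session1),
                method = "pearson", flags = "zero variance"))
  ct <- stats::cor.test(x_session1, y_session2)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(x_session1), method = "pearson", flags = character(0))
}

#' Significance star labels
#'
#' `p < 0.05` one star through `p < 0.0001` four stars (strict
#' inequalities), otherwise `"ns"`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  cut_labels <- function(pp) {
    if (pp < 0.0001) "****"
    else if (pp < 0.001) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }
  vapply(p, cut_labels, "")
}
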