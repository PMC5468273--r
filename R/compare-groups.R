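#' Group comparison following the two-branch assay convention
#'
#' Compares per-unit measurements (permeability coefficients, endpoint
#' percentages, counts) between experimental groups with the convention
#' used throughout the assays: a two-sided two-sample t-test (Welch, not
#' assuming equal variances) for exactly two groups, otherwise a one-way
#' ANOVA followed by Tukey HSD adjusted pairwise comparisons.
#'
#' @param values Named list of numeric vectors, one per group; at least two
#'   groups, each with at least two values.
#' @param conf_level Confidence level for the two-group difference interval.
#'
#' @return An object of class `"group_comparison"`: `method`, `statistic`
#'   (t or F), `p_value`, and for the two-group branch `estimate`
#'   (difference of means, group1 - group2) with `conf_int`; for the ANOVA
#'   branch `pairwise`, a data frame of Tukey-adjusted pairwise results.
#' @examples
#' compare_groups(list(ctrl = c(1.0, 1.1, 0.9), trt = c(2.1, 1.9, 2.0)))
#' @export
compare_groups <- function(values, conf_level = 0.95) {
  if (!is.list(values) || length(values) < 2L)
    stop("`values` must be a named list of at least 2 groups", call. = FALSE)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("all groups must be named", call. = FALSE)
  sizes <- vapply(values, length, integer(1))
  if (any(sizes < 2L))
    stop("every group needs at least 2 values; singleton group(s): ",
         paste(names(values)[sizes < 2L], collapse = ", "), call. = FALSE)
  for (v in values)
    if (!is.numeric(v) || anyNA(v))
      stop("group values must be numeric without NAs", call. = FALSE)

  if (length(values) == 2L) {
    ht <- t.test(values[[1L]], values[[2L]], conf.level = conf_level)
    out <- list(method = "welch_t", statistic = unname(ht$statistic),
                p_value = ht$p.value,
                estimate = unname(diff(rev(ht$estimate))),
                conf_int = unname(ht$conf.int), conf_level = conf_level,
                pairwise = NULL)
  } else {
    df <- data.frame(
      y = unlist(values, use.names = FALSE),
      g = factor(rep(names(values), sizes), levels = names(values)))
    fit <- aov(y ~ g, data = df)
    tab <- summary(fit)[[1L]]
    tk <- TukeyHSD(fit, conf.level = conf_level)$g
    out <- list(method = "anova_tukey", statistic = tab[["F value"]][1L],
                p_value = tab[["Pr(>F)"]][1L],
                estimate = NULL, conf_int = NULL, conf_level = conf_level,
                pairwise = data.frame(pair = rownames(tk),
                                      diff = tk[, "diff"],
                                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                                      p_adj = tk[, "p adj"],
                                      row.names = NULL))
  }
  out$group_means <- vapply(values, mean, numeric(1))
  out$group_n <- sizes
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  if (x$method == "welch_t") {
    cat("Welch two-sample t-test: t =", format(x$statistic, digits = digits),
        ", p =", format(x$p_value, digits = digits), "\n")
    cat("  difference of means:", format(x$estimate, digits = digits),
        sprintf(" (%d%% CI %s to %s)\n", round(100 * x$conf_level),
                format(x$conf_int[1], digits = digits),
                format(x$conf_int[2], digits = digits)))
  } else {
    cat("One-way ANOVA: F =", format(x$statistic, digits = digits),
        ", p =", format(x$p_value, digits = digits), "\n")
    cat("Tukey HSD pairwise comparisons:\n")
    print(x$pairwise, digits = digits)
  }
  invisible(x)
}
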