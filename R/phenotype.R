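#' Percent of the blood meal excreted over time
#'
#' Excretion is read out as weight loss relative to the gained meal weight.
#' For each post-feeding time point the value reported is the positive
#' magnitude \eqn{100 (W_{t0} - W_{tn}) / W_{gained}} with
#' \eqn{W_{gained} = W_{t0} - W_{t-1}} (fed minus pre-fed weight). The
#' series is expected to be monotone non-decreasing; a weight *increase*
#' between consecutive time points (e.g. measurement jitter) is retained
#' but flagged, never truncated to monotone.
#'
#' @param bugs Data frame in the wide per-bug format: columns `bug_id`,
#'   `group` (optional), `w_prefeed`, `w_fed` (mg) and weight columns
#'   `wt_<hour>` (mg) for the post-feeding hours (canonically 1, 2, 3, 4,
#'   6, 8, 12, 24).
#'
#' @return Long data frame `bug_id`, `group`, `hour`, `pct_excreted`,
#'   `flagged` (TRUE where weight rose relative to the previous time
#'   point).
#' @examples
#' b <- data.frame(bug_id = "b1", w_prefeed = 4, w_fed = 16, wt_24 = 10)
#' percent_excreted(b)  # 50% of the meal excreted by 24 h
#' @export
percent_excreted <- function(bugs) {
  bugs <- validate_bug_table(bugs)
  hours <- bug_hours(bugs)
  if (length(hours) == 0L)
    stop("no `wt_<hour>` weight columns found", call. = FALSE)
  gained <- bugs$w_fed - bugs$w_prefeed
  bad <- which(gained <= 0)
  if (length(bad))
    stop("non-positive meal weight for bug(s): ",
         paste(bugs$bug_id[bad], collapse = ", "), call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(bugs))) {
    w <- as.numeric(bugs[i, paste0("wt_", hours)])
    pct <- 100 * (bugs$w_fed[i] - w) / gained[i]
    prev <- c(bugs$w_fed[i], w[-length(w)])
    out[[i]] <- data.frame(
      bug_id = bugs$bug_id[i], group = bugs$group[i], hour = hours,
      pct_excreted = pct,
      flagged = w > prev + sqrt(.Machine$double.eps),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Engorgement as percent weight gain over pre-fed weight
#'
#' @inheritParams percent_excreted
#' @return Named numeric vector, `100 * (w_fed - w_prefeed) / w_prefeed`
#'   per bug.
#' @examples
#' engorgement_percent(data.frame(bug_id = "b1", w_prefeed = 4,
#'                                w_fed = 16.72))  # 318%
#' @export
engorgement_percent <- function(bugs) {
  bugs <- validate_bug_table(bugs, need_hours = FALSE)
  if (any(bugs$w_prefeed <= 0))
    stop("pre-feed weights must be positive", call. = FALSE)
  setNames(100 * (bugs$w_fed - bugs$w_prefeed) / bugs$w_prefeed, bugs$bug_id)
}

validate_bug_table <- function(bugs, need_hours = TRUE) {
  need <- c("bug_id", "w_prefeed", "w_fed")
  if (!is.data.frame(bugs) || !all(need %in% names(bugs)))
    stop("bug table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"group" %in% names(bugs)) bugs$group <- "all"
  bugs
}

bug_hours <- function(bugs) {
  cols <- grep("^wt_[0-9]+$", names(bugs), value = TRUE)
  sort(as.numeric(sub("^wt_", "", cols)))
}

#' Fit a urea colorimetric standard curve
#'
#' Ordinary least-squares line through the standard wells: absorbance =
#' slope * nmol + intercept. At least two distinct standard levels are
#' required and the fitted slope must be positive (a flat or inverted
#' response is rejected as a failed plate).
#'
#' @param levels Standard amounts per well, nmol.
#' @param absorbances Measured absorbances, one per standard well.
#'
#' @return An object of class `"urea_curve"`: `slope` (absorbance/nmol),
#'   `intercept`, `r_squared`, and the calibrated absorbance range used to
#'   flag extrapolation in [urea_per_bug()].
#' @examples
#' fit_urea_curve(c(0, 10), c(0.05, 0.25))  # slope 0.02, intercept 0.05
#' @export
fit_urea_curve <- function(levels, absorbances) {
  if (length(levels) != length(absorbances))
    stop("`levels` and `absorbances` must have equal length", call. = FALSE)
  if (length(unique(levels)) < 2L)
    stop("need at least 2 distinct standard levels", call. = FALSE)
  if (any(!is.finite(levels) | levels < 0) || any(!is.finite(absorbances)))
    stop("standard levels and absorbances must be finite (levels >= 0)",
         call. = FALSE)
  fit <- lm(absorbances ~ levels)
  slope <- unname(coef(fit)[["levels"]])
  if (slope <= 0)
    stop("standard curve slope must be positive (got ",
         format(slope, digits = 3), "); plate rejected", call. = FALSE)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot <= .Machine$double.eps) 1
        else 1 - sum(residuals(fit)^2) / ss_tot
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 r_squared = r2, levels = levels,
                 absorbances = absorbances,
                 abs_range = range(absorbances)),
            class = "urea_curve")
}

#' @export
print.urea_curve <- function(x, ...) {
  cat(sprintf("Urea standard curve: A = %.4g * nmol + %.4g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Back-calculate urea content per bug from well absorbance
#'
#' Inverts the standard curve for each sample well, then scales from the
#' reaction to the whole excreta sample: with `sample_volume_ul` of excreta
#' solution assayed out of `well_volume_ul` of total resuspension (defaults
#' 20 uL out of 100 uL, factor 5), nmol per bug = nmol in reaction *
#' well_volume / sample_volume. Absorbances below the curve intercept are
#' floored at 0 nmol with a warning; absorbances outside the calibrated
#' range are returned with an extrapolation flag.
#'
#' @param absorbance Numeric vector of sample-well absorbances.
#' @param curve A [fit_urea_curve()] result.
#' @param sample_volume_ul Excreta solution volume per reaction, uL.
#' @param well_volume_ul Total resuspension volume per bug, uL.
#'
#' @return Data frame `absorbance`, `nmol_reaction`, `nmol_per_bug`,
#'   `extrapolated`.
#' @examples
#' cv <- fit_urea_curve(c(0, 10), c(0.05, 0.25))
#' urea_per_bug(0.25, cv)  # 10 nmol in reaction, 50 nmol per bug
#' @export
urea_per_bug <- function(absorbance, curve, sample_volume_ul = 20,
                         well_volume_ul = 100) {
  stopifnot(inherits(curve, "urea_curve"))
  check_scalar(sample_volume_ul, "sample_volume_ul", 0, strict = TRUE)
  check_scalar(well_volume_ul, "well_volume_ul", 0, strict = TRUE)
  if (!is.numeric(absorbance) || any(!is.finite(absorbance)))
    stop("`absorbance` must be finite numeric", call. = FALSE)
  nmol <- (absorbance - curve$intercept) / curve$slope
  below <- nmol < 0
  if (any(below)) {
    warning(sum(below), " absorbance value(s) below the curve intercept; ",
            "floored at 0 nmol", call. = FALSE)
    nmol[below] <- 0
  }
  extrap <- absorbance < curve$abs_range[1L] | absorbance > curve$abs_range[2L]
  data.frame(absorbance = absorbance, nmol_reaction = nmol,
             nmol_per_bug = nmol * well_volume_ul / sample_volume_ul,
             extrapolated = extrap)
}

#' Two-group comparison of an in vivo endpoint
#'
#' Two-sided Welch t-test on a per-bug endpoint between exactly two dsRNA
#' treatment groups, with the difference of means and its confidence
#' interval reported alongside the p-value. Endpoints: percent of the meal
#' excreted by 24 h (`"excretion_24h"`, computed via [percent_excreted()]),
#' excreted urea per bug (`"urea"`, column `urea_nmol`), or total eggs
#' oviposited (`"eggs"`, column `eggs_total`). Bugs with a missing endpoint
#' value are excluded with a message naming them.
#'
#' @param bugs Wide per-bug data frame (see [percent_excreted()]) with a
#'   `group` column of exactly two levels.
#' @param endpoint One of `"excretion_24h"`, `"urea"`, `"eggs"`.
#' @param conf_level Confidence level for the difference interval.
#'
#' @return A [compare_groups()] `"group_comparison"` object with the
#'   endpoint name and per-group means attached.
#' @examples
#' bugs <- sim_bug_cohort(phenotype_sim_params(effect_multiplier = 0.5,
#'                                             seed = 3))
#' endpoint_comparison(bugs, "excretion_24h")
#' @export
endpoint_comparison <- function(bugs,
                                endpoint = c("excretion_24h", "urea", "eggs"),
                                conf_level = 0.95) {
  endpoint <- match.arg(endpoint)
  bugs <- validate_bug_table(bugs, need_hours = endpoint == "excretion_24h")
  groups <- unique(bugs$group)
  if (length(groups) != 2L)
    stop("endpoint comparison requires exactly 2 groups, got ",
         length(groups), call. = FALSE)
  vals <- switch(endpoint,
    excretion_24h = {
      pe <- percent_excreted(bugs)
      pe24 <- pe[pe$hour == 24, ]
      if (nrow(pe24) == 0L)
        stop("no 24-hour weight column (`wt_24`)", call. = FALSE)
      setNames(pe24$pct_excreted, pe24$bug_id)
    },
    urea = {
      if (!"urea_nmol" %in% names(bugs))
        stop("endpoint 'urea' needs a `urea_nmol` column", call. = FALSE)
      setNames(bugs$urea_nmol, bugs$bug_id)
    },
    eggs = {
      if (!"eggs_total" %in% names(bugs))
        stop("endpoint 'eggs' needs an `eggs_total` column", call. = FALSE)
      setNames(bugs$eggs_total, bugs$bug_id)
    })
  grp <- setNames(bugs$group, bugs$bug_id)[names(vals)]
  drop <- is.na(vals)
  if (any(drop)) {
    message("excluding bug(s) with missing ", endpoint, ": ",
            paste(names(vals)[drop], collapse = ", "))
    vals <- vals[!drop]; grp <- grp[!drop]
  }
  cmp <- compare_groups(split(unname(vals), factor(grp, levels = groups)),
                        conf_level = conf_level)
  cmp$endpoint <- endpoint
  cmp
}
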