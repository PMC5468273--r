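#' Fit permeability coefficients to oocyte swelling time courses
#'
#' The central estimator: converts per-oocyte cross-sectional area time
#' courses to relative volumes (\eqn{V/V_0 = (A_t/A_0)^{3/2}}, each oocyte
#' normalized to its own first frame), fits the initial slope of V/V0
#' against time by ordinary least squares inside an early window, and
#' inverts the slope to the osmotic water permeability Pf (`mode =
#' "water"`) or the solute permeability Ps (`mode = "solute"`). Fits with
#' R-squared below `r2_flag` are flagged, never dropped. Slopes are fitted
#' per oocyte and group statistics are computed on the per-oocyte
#' coefficients (see [summary.swelling_fit()]).
#'
#' The default window is 20 s for water assays: short enough that internal
#' dilution biases the slope only a few percent, long enough to average
#' measurement noise over a 60 s record. Solute assays default to a 2 s
#' window because the early volume response lags solute entry; see the
#' package vignette for the window sensitivity of both modes.
#'
#' @param data Data frame of the tidy swelling format: columns `oocyte_id`,
#'   `time` (s, starting at 0, strictly increasing per oocyte, at least 3
#'   samples), `area` (cross-sectional, any consistent unit) and optionally
#'   `group`.
#' @param mode `"water"` (Pf from an osmotic challenge) or `"solute"` (Ps
#'   from an isosmotic solute challenge).
#' @param window Fit window in seconds; `NULL` selects the mode default
#'   (20 s water, 2 s solute).
#' @param geometry An [oocyte_geometry()].
#' @param osm_in,osm_out Internal and bath osmolarity, mOsm (water mode).
#' @param sol_in,sol_out Internal and bath test-solute concentration, mM
#'   (solute mode).
#' @param r2_flag R-squared threshold below which a fit is flagged.
#'
#' @return An object of class `"swelling_fit"` with methods `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `plot` and `simulate`. Its
#'   `$estimates` component is a per-oocyte data frame with the slope, its
#'   standard error, R-squared, the permeability coefficient (cm/s) and the
#'   quality flag.
#' @examples
#' cohort <- sim_swelling_cohort(swelling_sim_params(n_oocytes = 5, seed = 1))
#' fit <- fit_swelling(cohort)
#' summary(fit)
#' @seealso [initial_slope()], [estimate_pf()], [estimate_ps()],
#'   [sim_swelling_cohort()]
#' @export
fit_swelling <- function(data, mode = c("water", "solute"), window = NULL,
                         geometry = oocyte_geometry(),
                         osm_in = 200, osm_out = 70,
                         sol_in = 0, sol_out = 100, r2_flag = 0.8) {
  mode <- match.arg(mode)
  if (is.null(window)) window <- if (mode == "water") 20 else 2
  check_scalar(window, "window", 0, strict = TRUE)
  need <- c("oocyte_id", "time", "area")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("`data` must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"group" %in% names(data)) data$group <- "all"

  ids <- unique(data$oocyte_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- data[data$oocyte_id == ids[i], , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    if (nrow(d) < 3L)
      stop("oocyte ", ids[i], ": need at least 3 samples", call. = FALSE)
    if (d$time[1L] != 0 || any(diff(d$time) <= 0))
      stop("oocyte ", ids[i],
           ": times must start at 0 and be strictly increasing", call. = FALSE)
    vv0 <- relative_volume(d$area)
    sl <- initial_slope(d$time, vv0, window)
    est <- if (mode == "water")
      estimate_pf(sl, geometry, osm_in, osm_out, r2_flag)
    else
      estimate_ps(sl, geometry, sol_in, sol_out, r2_flag)
    rows[[i]] <- data.frame(
      oocyte_id = ids[i], group = d$group[1L],
      slope = est$slope, slope_stderr = est$slope_stderr,
      intercept = sl$intercept, r_squared = est$r_squared,
      coefficient = est$coefficient, coef_stderr = est$coef_stderr,
      flagged = est$flagged, n_fit = sl$n,
      stringsAsFactors = FALSE)
  }
  estimates <- do.call(rbind, rows)
  structure(list(estimates = estimates, data = data, mode = mode,
                 window = window, geometry = geometry,
                 osm_in = osm_in, osm_out = osm_out,
                 sol_in = sol_in, sol_out = sol_out,
                 r2_flag = r2_flag, call = match.call()),
            class = "swelling_fit")
}

#' @export
print.swelling_fit <- function(x, ...) {
  lab <- if (x$mode == "water") "Pf" else "Ps"
  cat("Swelling assay fit (", x$mode, " mode, window ", x$window, " s)\n",
      sep = "")
  cat(" ", nrow(x$estimates), "oocytes in",
      length(unique(x$estimates$group)), "group(s)\n")
  m <- tapply(x$estimates$coefficient, x$estimates$group, mean)
  for (g in names(m))
    cat(sprintf("  %s: mean %s = %s cm/s (n = %d)\n", g, lab,
                format(m[[g]], digits = 4),
                sum(x$estimates$group == g)))
  nf <- sum(x$estimates$flagged)
  if (nf > 0) cat(" ", nf, "fit(s) flagged for R^2 <", x$r2_flag, "\n")
  invisible(x)
}

#' Per-oocyte permeability coefficients
#'
#' @param object A [fit_swelling()] result.
#' @param ... Unused.
#' @return Named numeric vector of Pf or Ps (cm/s), one per oocyte.
#' @export
coef.swelling_fit <- function(object, ...) {
  setNames(object$estimates$coefficient, object$estimates$oocyte_id)
}

#' Summarize a swelling fit with group statistics
#'
#' Group means, SD and SEM of the per-oocyte coefficients, plus the
#' standard group comparison ([compare_groups()]: Welch t-test for two
#' groups, one-way ANOVA with Tukey HSD otherwise) when every group has at
#' least two oocytes.
#'
#' @param object A [fit_swelling()] result.
#' @param ... Unused.
#' @return A `"summary.swelling_fit"` object with `$groups` (per-group
#'   table) and `$comparison` (a [compare_groups()] result or `NULL`).
#' @export
summary.swelling_fit <- function(object, ...) {
  est <- object$estimates
  groups <- split(est$coefficient, est$group)
  tab <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, sd, numeric(1)),
    row.names = NULL)
  tab$sem <- tab$sd / sqrt(tab$n)
  cmp <- if (length(groups) >= 2L && all(tab$n >= 2L))
    compare_groups(groups) else NULL
  structure(list(groups = tab, comparison = cmp, mode = object$mode,
                 window = object$window, n_flagged = sum(est$flagged)),
            class = "summary.swelling_fit")
}

#' @export
print.summary.swelling_fit <- function(x, ...) {
  lab <- if (x$mode == "water") "Pf" else "Ps"
  cat("Group", lab, "estimates (cm/s), window", x$window, "s:\n")
  print(x$groups, digits = 4)
  if (x$n_flagged > 0) cat(x$n_flagged, "low-R^2 fit(s) flagged\n")
  if (!is.null(x$comparison)) {
    cat("\n")
    print(x$comparison)
  }
  invisible(x)
}

#' Fitted V/V0 values from the per-oocyte initial-slope lines
#'
#' @param object A [fit_swelling()] result.
#' @param newdata Optional data frame with `oocyte_id` and `time`; defaults
#'   to the fitted points (observed times inside the fit window).
#' @param ... Unused.
#' @return Data frame `oocyte_id`, `time`, `fitted` (V/V0 on the fitted
#'   line).
#' @export
predict.swelling_fit <- function(object, newdata = NULL, ...) {
  est <- object$estimates
  if (is.null(newdata)) {
    d <- object$data
    newdata <- d[d$time <= object$window + sqrt(.Machine$double.eps),
                 c("oocyte_id", "time")]
  }
  i <- match(newdata$oocyte_id, est$oocyte_id)
  if (anyNA(i))
    stop("unknown oocyte_id in `newdata`", call. = FALSE)
  data.frame(oocyte_id = newdata$oocyte_id, time = newdata$time,
             fitted = est$intercept[i] + est$slope[i] * newdata$time)
}

#' Residuals of the initial-slope fits
#'
#' Observed minus fitted V/V0 at the points inside the fit window.
#'
#' @param object A [fit_swelling()] result.
#' @param ... Unused.
#' @return Data frame `oocyte_id`, `time`, `residual`.
#' @export
residuals.swelling_fit <- function(object, ...) {
  d <- object$data
  out <- vector("list", nrow(object$estimates))
  for (i in seq_len(nrow(object$estimates))) {
    id <- object$estimates$oocyte_id[i]
    di <- d[d$oocyte_id == id, , drop = FALSE]
    di <- di[order(di$time), , drop = FALSE]
    vv0 <- relative_volume(di$area)
    keep <- di$time <= object$window + sqrt(.Machine$double.eps)
    fitted <- object$estimates$intercept[i] +
      object$estimates$slope[i] * di$time[keep]
    out[[i]] <- data.frame(oocyte_id = id, time = di$time[keep],
                           residual = vv0[keep] - fitted)
  }
  do.call(rbind, out)
}

#' Plot swelling time courses with their initial-slope fits
#'
#' Relative volume against time for every oocyte, colored by group, with
#' the fitted initial-slope segment overlaid across the fit window.
#'
#' @param x A [fit_swelling()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.swelling_fit <- function(x, ...) {
  d <- x$data
  groups <- unique(x$estimates$group)
  cols <- setNames(seq_along(groups), groups)
  vv_all <- unlist(lapply(split(d$area, d$oocyte_id), relative_volume))
  graphics::plot(NA, xlim = range(d$time), ylim = range(vv_all),
                 xlab = "time (s)", ylab = "V / V0", ...)
  for (i in seq_len(nrow(x$estimates))) {
    id <- x$estimates$oocyte_id[i]
    di <- d[d$oocyte_id == id, ]
    di <- di[order(di$time), ]
    col <- cols[[x$estimates$group[i]]]
    graphics::lines(di$time, relative_volume(di$area), col = col)
    graphics::segments(0, x$estimates$intercept[i], x$window,
                       x$estimates$intercept[i] + x$estimates$slope[i] * x$window,
                       col = col, lty = 2)
  }
  graphics::legend("topleft", legend = groups, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Simulate new cohorts from a fitted swelling assay
#'
#' Parametric simulation: for each group, draws a fresh synthetic cohort
#' (via [sim_swelling_cohort()]) of the same size and time grid, using the
#' group's mean fitted coefficient as the true permeability and the
#' between-oocyte coefficient of variation estimated from the per-oocyte
#' fits (measurement noise is not re-added).
#'
#' @param object A [fit_swelling()] result.
#' @param nsim Number of cohorts to simulate.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames in the tidy swelling format.
#' @export
simulate.swelling_fit <- function(object, nsim = 1, seed = 1, ...) {
  est <- object$estimates
  d <- object$data
  dt <- min(diff(sort(unique(d$time))))
  duration <- max(d$time)
  groups <- split(est$coefficient, est$group)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    parts <- lapply(seq_along(groups), function(j) {
      co <- groups[[j]]
      cv <- if (length(co) > 1L && mean(co) > 0) sd(co) / mean(co) else 0
      p <- swelling_sim_params(
        pf_true = if (object$mode == "water") max(mean(co), 1e-12) else 2e-2,
        ps_true = if (object$mode == "solute") max(mean(co), 1e-12) else 0,
        osm_in0 = object$osm_in,
        osm_out = if (object$mode == "water") object$osm_out
                  else object$osm_in - object$sol_out,
        sol_out = if (object$mode == "solute") object$sol_out else 0,
        duration = duration, dt = dt, n_oocytes = length(co),
        pf_cv = cv, area_noise_cv = 0,
        seed = seed + (k - 1L) * length(groups) + j)
      cohort <- sim_swelling_cohort(p)
      cohort$group <- names(groups)[j]
      cohort$oocyte_id <- paste(names(groups)[j], cohort$oocyte_id, sep = "_")
      cohort
    })
    out[[k]] <- do.call(rbind, parts)
  }
  out
}
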