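#' Relative volume from cross-sectional areas
#'
#' Converts a series of measured cross-sectional areas to relative volumes
#' assuming a spherical cell: \eqn{V/V_0 = (A_t/A_0)^{3/2}}, where A0 is the
#' first (t = 0) area of the same oocyte — never a cohort average. The first
#' element is exactly 1 by construction, and the series is invariant to
#' rescaling all areas by a constant.
#'
#' @param areas Numeric vector of cross-sectional areas (any consistent
#'   unit); the first element is taken as A0.
#'
#' @return Numeric vector of V/V0, same length as `areas`.
#' @examples
#' relative_volume(c(1, 1.21, 4))  # 1, 1.331, 8
#' @export
relative_volume <- function(areas) {
  if (!is.numeric(areas) || length(areas) < 1L)
    stop("`areas` must be a non-empty numeric vector", call. = FALSE)
  bad <- which(!is.finite(areas) | areas <= 0)
  if (length(bad))
    stop("non-positive or non-finite area at index ", bad[1L], call. = FALSE)
  (areas / areas[1L])^(3 / 2)
}

#' Initial slope of a relative-volume time course
#'
#' Ordinary least-squares fit of V/V0 against time, restricted to the early
#' window `t <= window`, with a free intercept. The slope d(V/V0)/dt is the
#' quantity the Pf and Ps formulas invert. Because the osmotic gradient
#' shrinks as the cell swells (internal dilution), the fitted slope
#' decreases as the window grows; short windows track the true initial
#' slope more closely but average less noise.
#'
#' @param times Sampling times, s, starting at 0 and strictly increasing.
#' @param vv0 Relative volumes V/V0 at `times`.
#' @param window Fit window, s: only points with `t <= window` enter the fit.
#'
#' @return A list with components `slope` (s^-1), `stderr`, `r_squared`,
#'   `n` (points used) and `window`. `r_squared` is defined as 1 for an
#'   exactly constant series (zero residual).
#' @examples
#' t <- 0:20
#' initial_slope(t, 1 + 1e-3 * t, window = 20)$slope  # 1e-3
#' @export
initial_slope <- function(times, vv0, window = 20) {
  if (length(times) != length(vv0))
    stop("`times` and `vv0` must have equal length", call. = FALSE)
  check_scalar(window, "window", 0, strict = TRUE)
  keep <- times <= window + sqrt(.Machine$double.eps)
  if (sum(keep) < 2L)
    stop("need at least 2 points with t <= window (got ", sum(keep), ")",
         call. = FALSE)
  t_w <- times[keep]; y_w <- vv0[keep]
  fit <- lm(y_w ~ t_w)
  res <- residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y_w - mean(y_w))^2)
  r2 <- if (ss_tot <= .Machine$double.eps) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  n_w <- length(t_w)
  se <- if (n_w > 2L)
    sqrt(ss_res / (n_w - 2L)) / sqrt(sum((t_w - mean(t_w))^2))
  else NA_real_
  list(slope = unname(coef(fit)[["t_w"]]),
       intercept = unname(coef(fit)[["(Intercept)"]]),
       stderr = se, r_squared = r2, n = length(t_w), window = window)
}

#' Osmotic water permeability from an initial slope
#'
#' Applies the slope-based water permeability formula
#' \deqn{P_f = \frac{V_0 \; d(V/V_0)/dt}{S \, V_w \, (\mathrm{osm}_{in} -
#'   \mathrm{osm}_{out})}}
#' with the osmotic gradient converted to osmol/cm^3. The magnitude of the
#' gradient is used, so swelling under an outward-to-inward water gradient
#' yields a positive Pf regardless of how the two osmolarities are ordered.
#'
#' @param slope Either the fitted slope d(V/V0)/dt in s^-1, or the list
#'   returned by [initial_slope()] (its diagnostics are then carried over).
#' @param geometry An [oocyte_geometry()].
#' @param osm_in Internal osmolarity, mOsm (default 200, the incubation
#'   medium the oocytes equilibrated in).
#' @param osm_out Bath osmolarity, mOsm.
#' @param r2_flag Estimates with fit R-squared below this are flagged (not
#'   dropped).
#'
#' @return An object of class `"permeability_estimate"` with fields
#'   `coefficient` (cm/s), `kind`, `slope`, `slope_stderr`, `coef_stderr`,
#'   `fit_window`, `r_squared`, `flagged`.
#' @examples
#' estimate_pf(1e-3, osm_in = 200, osm_out = 70)  # Pf = 8.55e-3 cm/s
#' @export
estimate_pf <- function(slope, geometry = oocyte_geometry(),
                        osm_in = 200, osm_out = 70, r2_flag = 0.8) {
  check_scalar(osm_in, "osm_in", 0)
  check_scalar(osm_out, "osm_out", 0)
  if (osm_in == osm_out)
    stop("zero osmotic gradient: osm_in == osm_out", call. = FALSE)
  grad <- mosm_to_osm_cm3(abs(osm_in - osm_out))
  new_permeability(slope, geometry, grad, kind = "water", r2_flag = r2_flag)
}

#' Solute permeability from an initial slope
#'
#' Applies the slope-based solute permeability formula
#' \deqn{P_s = \frac{V_0 \; d(V/V_0)/dt}{S \, V_w \, |\mathrm{sol}_{in} -
#'   \mathrm{sol}_{out}|}}
#' with the solute gradient converted to mol/cm^3. Note the convention: this
#' formula carries the molar volume of water Vw (the swelling readout is
#' water following the solute), whereas part of the oocyte literature
#' defines Ps without it; values are only comparable within one convention.
#' The gradient magnitude is used so that influx-driven swelling gives a
#' positive coefficient.
#'
#' @inheritParams estimate_pf
#' @param sol_in Internal test-solute concentration, mM (0 at the start of
#'   the assay).
#' @param sol_out Bath test-solute concentration, mM.
#'
#' @return A `"permeability_estimate"` with `kind = "solute"`.
#' @examples
#' estimate_ps(5e-4, sol_in = 0, sol_out = 100)  # Ps = 5.56e-3 cm/s
#' @export
estimate_ps <- function(slope, geometry = oocyte_geometry(),
                        sol_in = 0, sol_out = 100, r2_flag = 0.8) {
  check_scalar(sol_in, "sol_in", 0)
  check_scalar(sol_out, "sol_out", 0)
  if (sol_in == sol_out)
    stop("zero solute gradient: sol_in == sol_out", call. = FALSE)
  grad <- mm_to_mol_cm3(abs(sol_in - sol_out))
  new_permeability(slope, geometry, grad, kind = "solute", r2_flag = r2_flag)
}

new_permeability <- function(slope, geometry, grad, kind, r2_flag) {
  stopifnot(inherits(geometry, "oocyte_geometry"))
  fit <- NULL
  if (is.list(slope)) {
    fit <- slope
    slope <- fit$slope
  }
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope))
    stop("`slope` must be a single finite number or an initial_slope() fit",
         call. = FALSE)
  scale <- geometry$v0 / (geometry$s * geometry$vw * grad)
  r2 <- if (is.null(fit)) NA_real_ else fit$r_squared
  structure(list(
    coefficient = slope * scale,
    kind = kind,
    slope = slope,
    slope_stderr = if (is.null(fit)) NA_real_ else fit$stderr,
    coef_stderr = if (is.null(fit) || is.na(fit$stderr)) NA_real_
                  else fit$stderr * scale,
    fit_window = if (is.null(fit)) NA_real_ else fit$window,
    r_squared = r2,
    flagged = !is.na(r2) && r2 < r2_flag
  ), class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  lab <- if (x$kind == "water") "Pf" else "Ps"
  cat(lab, "=", format(x$coefficient, digits = 4), "cm/s",
      "(slope", format(x$slope, digits = 4), "s^-1")
  if (!is.na(x$r_squared)) cat(", R^2", format(x$r_squared, digits = 3))
  cat(")")
  if (isTRUE(x$flagged)) cat("  [flagged: low R^2]")
  cat("\n")
  invisible(x)
}

#' Percent inhibition of a permeability coefficient
#'
#' Quantifies channel block (e.g. by Hg2+) as the percent reduction of the
#' treated coefficient relative to untreated:
#' `100 * (1 - treated/untreated)`. A treated coefficient above untreated
#' gives a negative value (stimulation) and is reported as-is unless
#' `clip_negative = TRUE`.
#'
#' @param coef_treated,coef_untreated Permeability coefficients, cm/s;
#'   `coef_untreated` must be positive.
#' @param clip_negative Clip negative inhibition (stimulation) at 0.
#'
#' @return Percent inhibition.
#' @examples
#' inhibition_percent(0.2, 1.0)  # 80
#' @export
inhibition_percent <- function(coef_treated, coef_untreated,
                               clip_negative = FALSE) {
  check_scalar(coef_untreated, "coef_untreated", 0, strict = TRUE)
  check_scalar(coef_treated, "coef_treated")
  pct <- 100 * (1 - coef_treated / coef_untreated)
  if (clip_negative) pct <- max(0, pct)
  pct
}
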