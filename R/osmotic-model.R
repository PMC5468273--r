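#' Forward simulation of osmotic water swelling
#'
#' Integrates the single-compartment osmotic flux model for an oocyte moved
#' into a hypo-osmotic bath. Water flux is proportional to the osmotic
#' gradient,
#' \deqn{dV/dt = P_f \, S \, V_w \, (\mathrm{osm}_{in}(t) - \mathrm{osm}_{out}),}
#' and the internal osmolyte amount is conserved, so the internal osmolarity
#' is diluted as the cell swells: \eqn{\mathrm{osm}_{in}(t) =
#' \mathrm{osm}_{in,0} V_0 / V(t)}. Because the conserved amount appears in
#' the state equation analytically, osmolyte conservation holds to machine
#' precision in the output. Volume relaxes monotonically (no overshoot, the
#' system is first order) toward the equilibrium ratio
#' [equilibrium_relative_volume()].
#'
#' Concentrations are accepted in mOsm at the interface and converted once
#' to osmol/cm^3 internally.
#'
#' @param geometry An [oocyte_geometry()].
#' @param pf Osmotic water permeability coefficient, cm/s.
#' @param osm_in0 Initial internal osmolarity, mOsm (the incubation medium
#'   the oocyte equilibrated in, ~200 mOsm).
#' @param bath A [bath_condition()]; for a water-only run, `sol_out` must be 0.
#' @param duration Simulated time, s.
#' @param dt Output sampling interval, s.
#'
#' @return An object of class `"swelling_trajectory"`: a data frame with
#'   columns `time` (s), `rel_volume` (V/V0), `osm_in` (mOsm) and `sol_in`
#'   (mM), with the model inputs stored as attributes.
#' @examples
#' tr <- simulate_water_swelling(pf = 2e-2, osm_in0 = 200,
#'                               bath = bath_condition(osm_out = 70))
#' head(tr)
#' @seealso [simulate_solute_swelling()], [fit_swelling()]
#' @export
simulate_water_swelling <- function(geometry = oocyte_geometry(), pf,
                                    osm_in0 = 200, bath = bath_condition(),
                                    duration = 60, dt = 1) {
  stopifnot(inherits(geometry, "oocyte_geometry"),
            inherits(bath, "bath_condition"))
  check_scalar(pf, "pf", 0)
  check_scalar(osm_in0, "osm_in0", 0)
  check_scalar(duration, "duration", 0, strict = TRUE)
  check_scalar(dt, "dt", 0, strict = TRUE)
  if (bath$sol_out != 0)
    stop("water-only simulation requires a bath with sol_out = 0", call. = FALSE)

  v0 <- geometry$v0
  n0 <- mosm_to_osm_cm3(osm_in0) * v0          # conserved osmolyte amount, osmol
  c_out <- mosm_to_osm_cm3(bath$osm_out)
  times <- seq(0, duration, by = dt)

  deriv <- function(t, y, p) {
    list(pf * geometry$s * geometry$vw * (n0 / y[[1]] - c_out))
  }
  v <- integrate_traj(c(V = v0), times, deriv)

  new_trajectory(times, rel_volume = v / v0,
                 osm_in = (n0 / v) / 1e-6, sol_in = rep(0, length(v)),
                 geometry = geometry, bath = bath, pf = pf, ps = 0,
                 osm_in0 = osm_in0)
}

#' Forward simulation of solute-driven swelling
#'
#' Integrates the coupled water/solute flux model for an oocyte in a bath
#' isosmotic overall but containing a permeant test solute (glycerol or
#' urea). Solute enters down its chemical gradient,
#' \deqn{ds/dt = P_s \, S \, (\mathrm{sol}_{out} - \mathrm{sol}_{in}(t)),
#'   \quad \mathrm{sol}_{in} = s/V,}
#' raising the total internal osmolarity (conserved impermeant osmolytes
#' diluted by volume, plus accumulated solute), and water follows
#' osmotically as in [simulate_water_swelling()]. With `ps = 0` in an
#' isosmotic bath there is no swelling; with `pf = 0` solute entry produces
#' no volume change because water cannot follow.
#'
#' @inheritParams simulate_water_swelling
#' @param ps Solute permeability coefficient, cm/s.
#' @param bath A [bath_condition()] with `sol_out > 0`; in the reference
#'   assay `osm_out + sol_out` equals `osm_in0` (isosmotic challenge).
#'
#' @return A `"swelling_trajectory"`; `sol_in` is the internal test-solute
#'   concentration in mM.
#' @examples
#' tr <- simulate_solute_swelling(pf = 2e-2, ps = 5e-3,
#'   bath = bath_condition(100, 100, "glycerol"), duration = 10, dt = 0.1)
#' @export
simulate_solute_swelling <- function(geometry = oocyte_geometry(), pf, ps,
                                     osm_in0 = 200,
                                     bath = bath_condition(100, 100, "glycerol"),
                                     duration = 60, dt = 1) {
  stopifnot(inherits(geometry, "oocyte_geometry"),
            inherits(bath, "bath_condition"))
  check_scalar(pf, "pf", 0)
  check_scalar(ps, "ps", 0)
  check_scalar(osm_in0, "osm_in0", 0)
  check_scalar(duration, "duration", 0, strict = TRUE)
  check_scalar(dt, "dt", 0, strict = TRUE)
  if (bath$sol_out <= 0)
    stop("solute simulation requires a bath with sol_out > 0", call. = FALSE)

  v0 <- geometry$v0
  n0 <- mosm_to_osm_cm3(osm_in0) * v0
  c_out_total <- mosm_to_osm_cm3(bath$osm_out) + mm_to_mol_cm3(bath$sol_out)
  sol_out_c <- mm_to_mol_cm3(bath$sol_out)

  deriv <- function(t, y, p) {
    v <- y[[1]]; s_amt <- y[[2]]
    osm_in_total <- (n0 + s_amt) / v
    dv <- pf * geometry$s * geometry$vw * (osm_in_total - c_out_total)
    ds <- ps * geometry$s * (sol_out_c - s_amt / v)
    list(c(dv, ds))
  }
  times <- seq(0, duration, by = dt)
  out <- integrate_traj(c(V = v0, s = 0), times, deriv, n_state = 2L)
  v <- out[, 1L]; s_amt <- out[, 2L]

  new_trajectory(times, rel_volume = v / v0,
                 osm_in = ((n0 + s_amt) / v) / 1e-6,
                 sol_in = (s_amt / v) / 1e-6,
                 geometry = geometry, bath = bath, pf = pf, ps = ps,
                 osm_in0 = osm_in0)
}

# lsoda wrapper with a hard failure check: an integrator problem is an error,
# never a silently truncated trajectory.
integrate_traj <- function(y0, times, deriv, n_state = 1L) {
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12 * abs(y0[[1]]) + 1e-18)
  if (nrow(out) != length(times) || anyNA(out))
    stop("ODE integration failed before reaching `duration`", call. = FALSE)
  if (n_state == 1L) out[, 2L] else out[, 2:(1L + n_state), drop = FALSE]
}

new_trajectory <- function(times, rel_volume, osm_in, sol_in,
                           geometry, bath, pf, ps, osm_in0) {
  df <- data.frame(time = times, rel_volume = rel_volume,
                   osm_in = osm_in, sol_in = sol_in)
  structure(df, class = c("swelling_trajectory", "data.frame"),
            geometry = geometry, bath = bath, pf = pf, ps = ps,
            osm_in0 = osm_in0)
}

#' Equilibrium relative volume of the conserved-osmolyte model
#'
#' With a fixed bath and conserved internal osmolytes, swelling stops when
#' the diluted internal osmolarity matches the bath, i.e. at
#' \eqn{V/V_0 = \mathrm{osm}_{in,0} / \mathrm{osm}_{out}}. Long-horizon
#' simulations converge monotonically to this ratio. A zero internal
#' osmolarity would predict complete collapse, which is outside the model's
#' physical range (real oocytes have an osmotically inactive fraction); the
#' value 0 is returned with a warning in that degenerate case.
#'
#' @param osm_in0 Initial internal osmolarity, mOsm.
#' @param osm_out Bath osmolarity, mOsm; must be positive (a zero-osmolarity
#'   bath implies unbounded swelling).
#'
#' @return The dimensionless equilibrium V/V0.
#' @examples
#' equilibrium_relative_volume(200, 70) # 2.857
#' @export
equilibrium_relative_volume <- function(osm_in0, osm_out) {
  check_scalar(osm_in0, "osm_in0", 0)
  check_scalar(osm_out, "osm_out", 0, strict = TRUE)
  if (osm_in0 == 0) {
    warning("osm_in0 = 0 predicts complete collapse; outside the model's ",
            "physical range", call. = FALSE)
    return(0)
  }
  osm_in0 / osm_out
}

#' Analytic initial swelling slope
#'
#' The instantaneous rate of relative volume change at t = 0, the quantity
#' the slope-based permeability formulas invert:
#' \eqn{d(V/V_0)/dt|_{t=0} = P_f S V_w \Delta\mathrm{osm} / V_0}.
#'
#' @inheritParams simulate_water_swelling
#' @param osm_out Bath osmolarity, mOsm.
#' @return Initial slope of V/V0, per second.
#' @examples
#' analytic_initial_slope(pf = 2e-2, osm_in0 = 200, osm_out = 70) # 2.34e-3
#' @export
analytic_initial_slope <- function(pf, geometry = oocyte_geometry(),
                                   osm_in0 = 200, osm_out = 70) {
  check_scalar(pf, "pf", 0)
  pf * geometry$s * geometry$vw *
    mosm_to_osm_cm3(osm_in0 - osm_out) / geometry$v0
}

#' @export
print.swelling_trajectory <- function(x, ...) {
  b <- attr(x, "bath")
  cat("Swelling trajectory:", nrow(x), "samples over",
      format(max(x$time)), "s\n")
  cat("  Pf =", format(attr(x, "pf")), "cm/s")
  if (attr(x, "ps") > 0) cat(", Ps =", format(attr(x, "ps")), "cm/s")
  cat("; internal", attr(x, "osm_in0"), "mOsm -> bath", b$osm_out, "mOsm")
  if (b$sol_out > 0) cat(" +", b$sol_out, "mM", b$solute)
  cat("\n  final V/V0 =", format(x$rel_volume[nrow(x)], digits = 4), "\n")
  invisible(x)
}

#' @export
plot.swelling_trajectory <- function(x, ...) {
  graphics::plot(x$time, x$rel_volume, type = "l", xlab = "time (s)",
                 ylab = "V / V0", ...)
  invisible(x)
}
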