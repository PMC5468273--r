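#' Oocyte geometry constants
#'
#' Physical constants used by the permeability formulas and the forward
#' swelling model: the average initial oocyte volume `v0`, the average
#' initial oocyte surface area `s`, and the molar volume of water `vw`.
#' Defaults are the standard values for stage V-VI *Xenopus laevis* oocytes
#' of roughly 1.2 mm diameter.
#'
#' The surface area is treated as constant during swelling, matching the
#' fixed-`S` convention of the slope-based permeability formulas. At large
#' relative volumes this understates the true (growing, microvillus-folded)
#' membrane area, biasing permeabilities upward; initial-slope fits over
#' short windows are insensitive to this.
#'
#' @param v0 Initial oocyte volume, cm^3.
#' @param s Oocyte surface area, cm^2.
#' @param vw Molar volume of water, cm^3/mol.
#'
#' @return An object of class `"oocyte_geometry"`.
#' @examples
#' oocyte_geometry()
#' @export
oocyte_geometry <- function(v0 = 9e-4, s = 0.045, vw = 18) {
  check_scalar(v0, "v0", 0, strict = TRUE)
  check_scalar(s, "s", 0, strict = TRUE)
  check_scalar(vw, "vw", 0, strict = TRUE)
  structure(list(v0 = v0, s = s, vw = vw), class = "oocyte_geometry")
}

#' @export
print.oocyte_geometry <- function(x, ...) {
  cat("Oocyte geometry: V0 =", format(x$v0), "cm^3, S =", format(x$s),
      "cm^2, Vw =", format(x$vw), "cm^3/mol\n")
  invisible(x)
}

# Initial cross-sectional (equatorial) area consistent with v0 under the
# sphere relation: V = 4/3 pi r^3, A = pi r^2.
sphere_area_from_volume <- function(v0) {
  pi * (3 * v0 / (4 * pi))^(2 / 3)
}

#' Bath condition for a swelling assay
#'
#' Describes the bath an oocyte is transferred into for a swelling assay:
#' its osmolarity exclusive of any test solute (`osm_out`), the test-solute
#' concentration (`sol_out`, zero for a water-only hypo-osmotic challenge),
#' and the mercury-treatment flags. In the standard designs the bath is
#' either dilute medium (70 mOsm, no solute) for water permeability, or
#' medium mixed 1:1 with isosmotic solute solution (100 mOsm salts + 100 mM
#' glycerol or urea) for solute permeability.
#'
#' @param osm_out Bath osmolarity excluding the test solute, mOsm.
#' @param sol_out Bath test-solute concentration, mM.
#' @param solute One of `"water-only"`, `"glycerol"`, `"urea"`.
#' @param hg_treated Logical; oocyte pre-incubated in HgCl2.
#' @param reversal Logical; Hg treatment followed by 2-mercaptoethanol.
#'
#' @return An object of class `"bath_condition"`.
#' @examples
#' bath_condition()                                        # 70 mOsm dilute bath
#' bath_condition(100, 100, "glycerol")                    # isosmotic solute bath
#' @export
bath_condition <- function(osm_out = 70, sol_out = 0,
                           solute = c("water-only", "glycerol", "urea"),
                           hg_treated = FALSE, reversal = FALSE) {
  solute <- match.arg(solute)
  check_scalar(osm_out, "osm_out", 0)
  check_scalar(sol_out, "sol_out", 0)
  if (solute == "water-only" && sol_out != 0)
    stop("a water-only bath must have sol_out = 0", call. = FALSE)
  if (solute != "water-only" && sol_out == 0)
    stop("a solute bath needs sol_out > 0", call. = FALSE)
  if (!is.logical(hg_treated) || !is.logical(reversal))
    stop("`hg_treated` and `reversal` must be logical", call. = FALSE)
  structure(list(osm_out = osm_out, sol_out = sol_out, solute = solute,
                 hg_treated = hg_treated, reversal = reversal),
            class = "bath_condition")
}

#' @export
print.bath_condition <- function(x, ...) {
  cat("Bath:", x$osm_out, "mOsm")
  if (x$sol_out > 0) cat(" +", x$sol_out, "mM", x$solute)
  if (x$hg_treated) cat(if (x$reversal) " [Hg2+, reversed]" else " [Hg2+]")
  cat("\n")
  invisible(x)
}

#' Effective Pf under mercury treatment
#'
#' Mercury blocks water-selective aquaporins; 2-mercaptoethanol reverses the
#' block. The treatment is modeled as a multiplicative reduction of Pf (not
#' a binding kinetic): an Hg-treated oocyte keeps fraction `hg_factor` of its
#' permeability, and reversal restores it to fraction `reversal_factor`.
#'
#' @param pf Untreated water permeability, cm/s.
#' @param bath A [bath_condition()] carrying the treatment flags.
#' @param hg_factor Fraction of Pf remaining after Hg treatment.
#' @param reversal_factor Fraction of Pf restored after 2-mercaptoethanol.
#'
#' @return Effective Pf, cm/s.
#' @export
effective_pf <- function(pf, bath, hg_factor = 0.2, reversal_factor = 0.9) {
  check_scalar(pf, "pf", 0)
  check_scalar(hg_factor, "hg_factor", 0)
  check_scalar(reversal_factor, "reversal_factor", 0)
  if (!bath$hg_treated) return(pf)
  if (bath$reversal) pf * reversal_factor else pf * hg_factor
}
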