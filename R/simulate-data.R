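#' Parameters for a synthetic swelling cohort
#'
#' Bundles the design of an oocyte swelling assay for
#' [sim_swelling_cohort()]. Defaults reproduce the reference assay: oocytes
#' equilibrated in ~200 mOsm medium and transferred to a 70 mOsm bath,
#' recorded for 60 s at 1 s intervals, at least five oocytes per group,
#' with a high-efficiency water channel (Pf = 2e-2 cm/s). Between-oocyte
#' permeability variation is lognormal (permeabilities are positive and
#' right-skewed) with coefficient of variation `pf_cv`; area measurement
#' error is multiplicative lognormal per frame with CV `area_noise_cv`.
#'
#' @param pf_true True mean water permeability, cm/s.
#' @param ps_true True mean solute permeability, cm/s; 0 for a water-only
#'   assay.
#' @param osm_in0 Initial internal osmolarity, mOsm.
#' @param osm_out Bath osmolarity excluding test solute, mOsm.
#' @param sol_out Bath test-solute concentration, mM; 0 selects the
#'   water-only model.
#' @param solute Test-solute label for the bath when `sol_out > 0`.
#' @param duration Recording length, s.
#' @param dt Sampling interval, s.
#' @param n_oocytes Number of oocytes.
#' @param pf_cv Between-oocyte coefficient of variation of Pf (and of Ps
#'   when `ps_true > 0`).
#' @param area_noise_cv Multiplicative per-frame area measurement noise CV.
#' @param seed Integer seed; generation is bit-identical given the seed.
#'
#' @return An object of class `"swelling_sim_params"`.
#' @export
swelling_sim_params <- function(pf_true = 2e-2, ps_true = 0,
                                osm_in0 = 200, osm_out = 70, sol_out = 0,
                                solute = "glycerol",
                                duration = 60, dt = 1, n_oocytes = 5,
                                pf_cv = 0.1, area_noise_cv = 0.02,
                                seed = 1) {
  check_scalar(pf_true, "pf_true", 0)
  check_scalar(ps_true, "ps_true", 0)
  check_scalar(osm_in0, "osm_in0", 0)
  check_scalar(osm_out, "osm_out", 0)
  check_scalar(sol_out, "sol_out", 0)
  check_scalar(duration, "duration", 0, strict = TRUE)
  check_scalar(dt, "dt", 0, strict = TRUE)
  check_scalar(n_oocytes, "n_oocytes", 1)
  check_scalar(pf_cv, "pf_cv", 0)
  check_scalar(area_noise_cv, "area_noise_cv", 0)
  structure(list(pf_true = pf_true, ps_true = ps_true, osm_in0 = osm_in0,
                 osm_out = osm_out, sol_out = sol_out, solute = solute,
                 duration = duration, dt = dt,
                 n_oocytes = as.integer(n_oocytes),
                 pf_cv = pf_cv, area_noise_cv = area_noise_cv,
                 seed = as.integer(seed)),
            class = "swelling_sim_params")
}

#' Simulate a cohort of oocyte swelling time courses
#'
#' Draws each oocyte's permeability from a lognormal with mean `pf_true`
#' (and `ps_true` for solute assays) and CV `pf_cv`, runs the forward
#' osmotic model ([simulate_water_swelling()] or
#' [simulate_solute_swelling()] depending on `sol_out`), converts relative
#' volumes back to cross-sectional areas under the sphere relation (the
#' t = 0 area is consistent with the geometry's V0), and applies
#' mean-one multiplicative lognormal measurement noise to every frame
#' including the first. Same seed, same output, bit for bit.
#'
#' @param params A [swelling_sim_params()].
#' @param geometry An [oocyte_geometry()].
#'
#' @return Tidy data frame `oocyte_id`, `time` (s), `area` (cm^2), with the
#'   drawn per-oocyte permeabilities in attribute `"pf"` (and `"ps"`).
#' @examples
#' cohort <- sim_swelling_cohort(swelling_sim_params(n_oocytes = 2, seed = 1))
#' @export
sim_swelling_cohort <- function(params, geometry = oocyte_geometry()) {
  stopifnot(inherits(params, "swelling_sim_params"))
  n <- params$n_oocytes
  times <- seq(0, params$duration, by = params$dt)
  a0 <- sphere_area_from_volume(geometry$v0)
  solute_mode <- params$sol_out > 0

  draws <- with_seed(params$seed, {
    pf_i <- rlnorm_cv(n, params$pf_true, params$pf_cv)
    ps_i <- if (solute_mode) rlnorm_cv(n, params$ps_true, params$pf_cv)
            else rep(0, n)
    noise <- if (params$area_noise_cv == 0)
      matrix(1, n, length(times))
    else {
      sdlog <- sqrt(log(1 + params$area_noise_cv^2))
      matrix(rlnorm(n * length(times), -sdlog^2 / 2, sdlog), n,
             length(times))
    }
    list(pf = pf_i, ps = ps_i, noise = noise)
  })

  bath <- if (solute_mode)
    bath_condition(params$osm_out, params$sol_out, params$solute)
  else
    bath_condition(params$osm_out)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- if (solute_mode)
      simulate_solute_swelling(geometry, pf = draws$pf[i], ps = draws$ps[i],
                               osm_in0 = params$osm_in0, bath = bath,
                               duration = params$duration, dt = params$dt)
    else
      simulate_water_swelling(geometry, pf = draws$pf[i],
                              osm_in0 = params$osm_in0, bath = bath,
                              duration = params$duration, dt = params$dt)
    areas <- a0 * tr$rel_volume^(2 / 3) * draws$noise[i, ]
    out[[i]] <- data.frame(oocyte_id = sprintf("oo%02d", i),
                           time = times, area = areas,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "pf") <- draws$pf
  attr(res, "ps") <- draws$ps
  attr(res, "params") <- params
  res
}

#' Simulate a qPCR Ct table under a fold-change model
#'
#' Generates a long-form Ct table in which the target-gene Ct of each group
#' is shifted by -log2(fold) from a common baseline (one cycle earlier per
#' doubling of template) and the reference (housekeeping) gene is
#' independent of group, both with additive Gaussian cycle noise. A
#' noise-free table round-trips exactly through
#' [relative_expression()]: the recovered RQ equals the generating fold.
#'
#' @param true_fold_changes Named positive numeric vector of fold changes
#'   per group; at least one group (the calibrator) must have fold 1.
#' @param n_replicates Replicates per group (the knockdown assessments use
#'   3 whole insects per time point per treatment).
#' @param ct_noise_sd Additive Ct noise SD, cycles.
#' @param seed Integer seed.
#' @param gene,reference_gene Labels for the target and reference gene.
#' @param target_baseline_ct Target-gene Ct at fold 1, cycles.
#' @param reference_ct Reference-gene Ct, cycles.
#'
#' @return Data frame `sample_id`, `group`, `gene`, `is_reference`, `ct`,
#'   `replicate`.
#' @examples
#' sim_ct_table(c(ctrl = 1, trt = 8), n_replicates = 3, ct_noise_sd = 0,
#'              seed = 1)
#' @export
sim_ct_table <- function(true_fold_changes, n_replicates = 3,
                         ct_noise_sd = 0.2, seed = 1,
                         gene = "target", reference_gene = "rpl18",
                         target_baseline_ct = 25, reference_ct = 20) {
  if (is.null(names(true_fold_changes)) ||
      any(!nzchar(names(true_fold_changes))))
    stop("`true_fold_changes` must be a named vector", call. = FALSE)
  if (any(!is.finite(true_fold_changes) | true_fold_changes <= 0))
    stop("fold changes must be positive", call. = FALSE)
  if (!any(true_fold_changes == 1))
    stop("a reference group with fold 1 must be present", call. = FALSE)
  check_scalar(n_replicates, "n_replicates", 1)
  check_scalar(ct_noise_sd, "ct_noise_sd", 0)

  groups <- names(true_fold_changes)
  n <- length(groups) * n_replicates
  with_seed(seed, {
    tgt_noise <- rnorm(n, 0, ct_noise_sd)
    ref_noise <- rnorm(n, 0, ct_noise_sd)
    grp <- rep(groups, each = n_replicates)
    repl <- rep(seq_len(n_replicates), times = length(groups))
    folds <- rep(unname(true_fold_changes), each = n_replicates)
    rbind(
      data.frame(sample_id = paste(grp, repl, sep = "_"), group = grp,
                 gene = gene, is_reference = FALSE,
                 ct = target_baseline_ct - log2(folds) + tgt_noise,
                 replicate = repl, stringsAsFactors = FALSE),
      data.frame(sample_id = paste(grp, repl, sep = "_"), group = grp,
                 gene = reference_gene, is_reference = TRUE,
                 ct = reference_ct + ref_noise,
                 replicate = repl, stringsAsFactors = FALSE))
  })
}

#' Parameters for a synthetic blood-fed bug cohort
#'
#' Design of an in vivo excretion / urea / fecundity experiment for
#' [sim_bug_cohort()]. Defaults emulate the reference phenotype assays:
#' adult females of ~4 mg unfed weight engorging to 318 +/- 72% (mean +/-
#' SD) of pre-fed weight, then excreting along an exponential approach to a
#' plateau fraction of the meal, with weights recorded at 1, 2, 3, 4, 6, 8,
#' 12 and 24 h post blood meal. The treatment group's excretion rate is
#' scaled by `effect_multiplier` (1 = null). Per-bug biological variation:
#' lognormal unfed weight (`unfed_weight_cv`) and lognormal excretion rate
#' (`excretion_rate_cv`). Egg totals are negative binomial (over-dispersed
#' counts), with the treatment mean scaled by `fecundity_multiplier`.
#'
#' @param n_bugs_per_group Bugs per group.
#' @param unfed_weight_mean Mean unfed weight, mg.
#' @param unfed_weight_cv Between-bug CV of unfed weight.
#' @param meal_gain_pct_mean,meal_gain_pct_sd Engorgement as percent of
#'   unfed weight, Gaussian mean and SD.
#' @param excretion_half_time Characteristic excretion half-time, hr.
#' @param excretion_rate_cv Between-bug CV of the excretion rate.
#' @param plateau_frac Fraction of the meal weight ultimately excreted.
#' @param effect_multiplier Factor on the treatment group's excretion rate.
#' @param urea_per_mg_excreted Excreta urea per mg of excreted meal,
#'   nmol/mg.
#' @param ct_noise_sd Ct noise for companion knockdown tables, cycles.
#' @param egg_mean Mean total eggs per control bug.
#' @param egg_dispersion Negative binomial size (dispersion) parameter.
#' @param fecundity_multiplier Factor on the treatment group's egg mean.
#' @param seed Integer seed.
#'
#' @return An object of class `"phenotype_sim_params"`.
#' @export
phenotype_sim_params <- function(n_bugs_per_group = 10,
                                 unfed_weight_mean = 4,
                                 unfed_weight_cv = 0.1,
                                 meal_gain_pct_mean = 318,
                                 meal_gain_pct_sd = 72,
                                 excretion_half_time = 4,
                                 excretion_rate_cv = 0.2,
                                 plateau_frac = 0.5,
                                 effect_multiplier = 1,
                                 urea_per_mg_excreted = 20,
                                 ct_noise_sd = 0.2,
                                 egg_mean = 6, egg_dispersion = 8,
                                 fecundity_multiplier = 1,
                                 seed = 1) {
  check_scalar(n_bugs_per_group, "n_bugs_per_group", 2)
  check_scalar(unfed_weight_mean, "unfed_weight_mean", 0, strict = TRUE)
  check_scalar(unfed_weight_cv, "unfed_weight_cv", 0)
  check_scalar(meal_gain_pct_mean, "meal_gain_pct_mean", 0, strict = TRUE)
  check_scalar(meal_gain_pct_sd, "meal_gain_pct_sd", 0)
  check_scalar(excretion_half_time, "excretion_half_time", 0, strict = TRUE)
  check_scalar(excretion_rate_cv, "excretion_rate_cv", 0)
  check_scalar(plateau_frac, "plateau_frac", 0, strict = TRUE)
  if (plateau_frac > 1)
    stop("`plateau_frac` cannot exceed 1", call. = FALSE)
  check_scalar(effect_multiplier, "effect_multiplier", 0)
  check_scalar(urea_per_mg_excreted, "urea_per_mg_excreted", 0, strict = TRUE)
  check_scalar(ct_noise_sd, "ct_noise_sd", 0)
  check_scalar(egg_mean, "egg_mean", 0, strict = TRUE)
  check_scalar(egg_dispersion, "egg_dispersion", 0, strict = TRUE)
  check_scalar(fecundity_multiplier, "fecundity_multiplier", 0, strict = TRUE)
  structure(list(n_bugs_per_group = as.integer(n_bugs_per_group),
                 unfed_weight_mean = unfed_weight_mean,
                 unfed_weight_cv = unfed_weight_cv,
                 meal_gain_pct_mean = meal_gain_pct_mean,
                 meal_gain_pct_sd = meal_gain_pct_sd,
                 excretion_half_time = excretion_half_time,
                 excretion_rate_cv = excretion_rate_cv,
                 plateau_frac = plateau_frac,
                 effect_multiplier = effect_multiplier,
                 urea_per_mg_excreted = urea_per_mg_excreted,
                 ct_noise_sd = ct_noise_sd,
                 egg_mean = egg_mean, egg_dispersion = egg_dispersion,
                 fecundity_multiplier = fecundity_multiplier,
                 seed = as.integer(seed)),
            class = "phenotype_sim_params")
}

# Canonical post-feeding weighing grid, hours.
EXCRETION_HOURS <- c(1, 2, 3, 4, 6, 8, 12, 24)

#' Simulate a blood-fed bug cohort
#'
#' Generates a control and a treatment group of per-bug records: unfed
#' weight, fed weight (engorgement drawn around `meal_gain_pct_mean`),
#' post-feeding weights on the canonical 1-24 h grid following a monotone
#' exponential excretion curve \eqn{F(t) = p (1 - e^{-\lambda t})} (with
#' per-bug lognormal rate, and the treatment rate scaled by
#' `effect_multiplier`), excreta urea proportional to the mass excreted by
#' 24 h, and negative-binomial egg totals with a thinning daily series.
#' With `effect_multiplier = 1` and `fecundity_multiplier = 1` the two
#' groups are exchangeable (null scenario). An `effect_multiplier` of 0
#' gives a bug that never loses weight after feeding (0% excreted at every
#' time point).
#'
#' @param params A [phenotype_sim_params()].
#'
#' @return Wide data frame with one row per bug: `bug_id`, `group`
#'   (`"control"`/`"treatment"`), `w_prefeed`, `w_fed`, `wt_1` ... `wt_24`
#'   (mg), `urea_nmol`, `eggs_total`; daily egg counts in attribute
#'   `"eggs_daily"`.
#' @examples
#' bugs <- sim_bug_cohort(phenotype_sim_params(seed = 2))
#' head(percent_excreted(bugs))
#' @export
sim_bug_cohort <- function(params) {
  stopifnot(inherits(params, "phenotype_sim_params"))
  n <- params$n_bugs_per_group
  groups <- c("control", "treatment")
  ntot <- 2L * n
  hours <- EXCRETION_HOURS

  with_seed(params$seed, {
    grp <- rep(groups, each = n)
    unfed <- rlnorm_cv(ntot, params$unfed_weight_mean, params$unfed_weight_cv)
    gain_pct <- pmax(rnorm(ntot, params$meal_gain_pct_mean,
                           params$meal_gain_pct_sd),
                     0.05 * params$meal_gain_pct_mean)
    fed <- unfed * (1 + gain_pct / 100)
    gained <- fed - unfed

    lambda0 <- log(2) / params$excretion_half_time
    mult <- ifelse(grp == "treatment", params$effect_multiplier, 1)
    lambda <- lambda0 * mult * rlnorm_cv(ntot, 1, params$excretion_rate_cv)
    frac <- params$plateau_frac * (1 - exp(-outer(lambda, hours)))
    wt <- fed - gained * frac
    colnames(wt) <- paste0("wt_", hours)

    urea <- params$urea_per_mg_excreted * gained *
      frac[, length(hours)]

    egg_mu <- ifelse(grp == "treatment",
                     params$egg_mean * params$fecundity_multiplier,
                     params$egg_mean)
    eggs <- rnbinom(ntot, size = params$egg_dispersion, mu = egg_mu)

    bug_id <- sprintf("%s%02d", ifelse(grp == "treatment", "t", "c"),
                      rep(seq_len(n), 2))
    # daily laying series: each egg assigned a lay day with geometric decay
    eggs_daily <- do.call(rbind, lapply(seq_len(ntot), function(i) {
      if (eggs[i] == 0L)
        return(data.frame(bug_id = character(0), day = integer(0),
                          eggs = integer(0)))
      days <- 1L + rgeom(eggs[i], 0.3)
      tab <- table(days)
      data.frame(bug_id = bug_id[i], day = as.integer(names(tab)),
                 eggs = as.integer(tab), stringsAsFactors = FALSE)
    }))

    res <- data.frame(bug_id = bug_id, group = grp, w_prefeed = unfed,
                      w_fed = fed, stringsAsFactors = FALSE)
    res <- cbind(res, as.data.frame(wt))
    res$urea_nmol <- urea
    res$eggs_total <- eggs
    attr(res, "eggs_daily") <- eggs_daily
    attr(res, "params") <- params
    res
  })
}

#' Simulate a urea colorimetric plate
#'
#' Linear plate model: absorbance = `curve_slope` * nmol + `curve_intercept`
#' + Gaussian read noise, for a set of standard wells and (optionally
#' empty) sample wells. A noise-free plate round-trips exactly:
#' back-calculation through [fit_urea_curve()] and [urea_per_bug()]
#' recovers the input nmol.
#'
#' @param curve_slope Absorbance per nmol; must be positive.
#' @param curve_intercept Blank absorbance.
#' @param standards Standard amounts, nmol; at least 2 distinct levels.
#' @param samples Sample amounts in the reaction, nmol; may be empty.
#' @param read_noise_sd Absorbance read noise SD.
#' @param seed Integer seed.
#'
#' @return Long data frame `well_type` (`"standard"`/`"sample"`), `id`,
#'   `nmol` (true), `absorbance`.
#' @examples
#' sim_urea_plate(0.02, 0.05, standards = c(0, 2, 5, 10), samples = 10,
#'                read_noise_sd = 0, seed = 1)
#' @export
sim_urea_plate <- function(curve_slope = 0.02, curve_intercept = 0.05,
                           standards = c(0, 1, 2, 4, 6, 8, 10),
                           samples = numeric(0), read_noise_sd = 0,
                           seed = 1) {
  check_scalar(curve_slope, "curve_slope", 0, strict = TRUE)
  check_scalar(read_noise_sd, "read_noise_sd", 0)
  if (length(unique(standards)) < 2L)
    stop("need at least 2 distinct standard levels", call. = FALSE)
  if (any(!is.finite(c(standards, samples))))
    stop("standards and samples must be finite", call. = FALSE)
  nmol <- c(standards, samples)
  type <- rep(c("standard", "sample"), c(length(standards), length(samples)))
  id <- c(paste0("std", seq_along(standards)),
          if (length(samples)) paste0("smp", seq_along(samples)))
  with_seed(seed, {
    data.frame(well_type = type, id = id, nmol = nmol,
               absorbance = curve_slope * nmol + curve_intercept +
                 rnorm(length(nmol), 0, read_noise_sd),
               stringsAsFactors = FALSE)
  })
}
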