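#' Amplification efficiency from a qPCR dilution series
#'
#' Fits Ct against log10 template dilution by ordinary least squares and
#' converts the slope to the amplification efficiency
#' \eqn{E = 10^{-1/\mathrm{slope}} - 1} (E = 1 means perfect doubling per
#' cycle, slope -3.3219). Primer sets are gated, not corrected: the fit
#' carries a `passes_gate` flag for the conventional 0.9 <= E <= 1.1
#' acceptance band, and gated-out genes should be excluded from
#' relative-expression analysis rather than efficiency-adjusted.
#'
#' @param gene Gene label.
#' @param dilutions Relative template quantities (e.g. `10^-(0:4)`); at
#'   least 3 distinct positive levels.
#' @param cts Observed Ct values (cycles), one per dilution.
#' @param gate Length-2 numeric, the E acceptance band.
#'
#' @return An object of class `"efficiency_fit"`: `gene`, `slope` (cycles
#'   per log10 dilution), `efficiency`, `r_squared`, `passes_gate`.
#' @examples
#' d <- 10^-(0:4)
#' efficiency_from_dilution_series("aqp1", d, 20 - 3.3219 * log10(d))
#' @export
efficiency_from_dilution_series <- function(gene, dilutions, cts,
                                            gate = c(0.9, 1.1)) {
  if (length(dilutions) != length(cts))
    stop("`dilutions` and `cts` must have equal length", call. = FALSE)
  if (length(dilutions) < 3L)
    stop("need at least 3 dilution points", call. = FALSE)
  if (any(!is.finite(dilutions) | dilutions <= 0))
    stop("dilutions must be positive", call. = FALSE)
  if (any(!is.finite(cts) | cts <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  x <- log10(dilutions)
  fit <- lm(cts ~ x)
  slope <- unname(coef(fit)[["x"]])
  if (slope >= 0)
    stop("non-physical dilution series: Ct must increase as template is ",
         "diluted (fitted slope ", format(slope, digits = 3), ")",
         call. = FALSE)
  eff <- 10^(-1 / slope) - 1
  ss_tot <- sum((cts - mean(cts))^2)
  r2 <- if (ss_tot <= .Machine$double.eps) 1
        else 1 - sum(residuals(fit)^2) / ss_tot
  structure(list(gene = gene, slope = slope, efficiency = eff,
                 r_squared = r2,
                 passes_gate = eff >= gate[1L] && eff <= gate[2L],
                 gate = gate),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("Gene %s: slope %.4f cycles/log10, E = %.3f  [%s]\n",
              x$gene, x$slope, x$efficiency,
              if (x$passes_gate) "passes gate" else
                sprintf("FAILS gate %.1f-%.1f", x$gate[1], x$gate[2])))
  invisible(x)
}

validate_ct_table <- function(ct_table) {
  need <- c("group", "gene", "is_reference", "ct")
  if (!is.data.frame(ct_table) || !all(need %in% names(ct_table)))
    stop("Ct table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct_table$ct) | ct_table$ct <= 0))
    stop("all Ct values must be finite and positive", call. = FALSE)
  invisible(ct_table)
}

#' Relative expression by the ddCt method
#'
#' Computes relative quantities RQ = 2^(-ddCt) from a long-form Ct table,
#' normalizing each target gene to the reference (housekeeping) gene within
#' each group and to a calibrator group across groups. Replicate Cts are
#' averaged before differencing (mean Ct per group and gene), so per group
#' \eqn{\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{ref}}, then
#' \eqn{\Delta\Delta Ct = \Delta Ct_{group} - \Delta Ct_{calibrator}} and
#' RQ = \eqn{2^{-\Delta\Delta Ct}}. Replicate SD is propagated to a fold
#' range \eqn{2^{-(\Delta\Delta Ct \pm s)}} with
#' \eqn{s = \sqrt{s_{target}^2 + s_{ref}^2}}. The calibrator group has
#' RQ = 1 by construction, and results are invariant to adding a constant
#' to every Ct of one sample (reference normalization).
#'
#' @param ct_table Data frame with columns `group`, `gene`, `is_reference`
#'   (logical), `ct` (cycles) and optionally `sample_id`, `replicate`.
#'   Every group must contain reference-gene rows.
#' @param calibrator Group label used as calibrator.
#'
#' @return Data frame with one row per (group, target gene): `group`,
#'   `gene`, `delta_ct`, `delta_delta_ct`, `rq`, `rq_lo`, `rq_hi`.
#' @examples
#' tab <- sim_ct_table(c(ctrl = 1, trt = 8), n_replicates = 3,
#'                     ct_noise_sd = 0, seed = 1)
#' relative_expression(tab, calibrator = "ctrl")
#' @export
relative_expression <- function(ct_table, calibrator) {
  validate_ct_table(ct_table)
  groups <- unique(ct_table$group)
  if (!calibrator %in% groups)
    stop("calibrator group '", calibrator, "' not present", call. = FALSE)
  ref_by_group <- tapply(ct_table$is_reference, ct_table$group, any)
  missing_ref <- names(ref_by_group)[!ref_by_group]
  if (length(missing_ref))
    stop("reference gene missing in group(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)

  targets <- unique(ct_table$gene[!ct_table$is_reference])
  ref <- ct_table[ct_table$is_reference, ]
  ref_mean <- tapply(ref$ct, ref$group, mean)
  ref_sd <- tapply(ref$ct, ref$group, function(x)
    if (length(x) > 1L) sd(x) else 0)

  out <- list()
  for (gn in targets) {
    tg <- ct_table[!ct_table$is_reference & ct_table$gene == gn, ]
    g_present <- unique(tg$group)
    if (!calibrator %in% g_present)
      stop("target gene '", gn, "' has no rows in the calibrator group",
           call. = FALSE)
    t_mean <- tapply(tg$ct, tg$group, mean)
    t_sd <- tapply(tg$ct, tg$group, function(x)
      if (length(x) > 1L) sd(x) else 0)
    dct <- t_mean - ref_mean[names(t_mean)]
    ddct <- dct - dct[[calibrator]]
    s <- sqrt(t_sd^2 + ref_sd[names(t_sd)]^2)
    out[[gn]] <- data.frame(
      group = names(dct), gene = gn,
      delta_ct = as.numeric(dct), delta_delta_ct = as.numeric(ddct),
      rq = 2^(-as.numeric(ddct)),
      rq_lo = 2^(-(as.numeric(ddct) + as.numeric(s))),
      rq_hi = 2^(-(as.numeric(ddct) - as.numeric(s))),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' RNAi knockdown time course of relative expression
#'
#' Per-day relative expression of a treatment group against the matched-day
#' control: for each day post injection, RQ of `treatment` with `control`
#' as calibrator, computed per target gene. Passing a table containing
#' non-target genes fills the off-target check slots: unaffected genes
#' should stay near RQ = 1 at every day.
#'
#' @param tables Named list of Ct tables (see [relative_expression()]);
#'   names are days post injection and must be coercible to numbers.
#' @param treatment,control Group labels expected in every table.
#'
#' @return Data frame `dpi`, `gene`, `rq`, `rq_lo`, `rq_hi`. Days missing
#'   either group are skipped with a warning; an empty `tables` list gives
#'   an empty result with a warning.
#' @examples
#' tabs <- lapply(c(`2` = 1, `4` = 0.1), function(f)
#'   sim_ct_table(c(gfp = 1, ds_aqp1 = f), 3, 0, seed = 7))
#' knockdown_timecourse(tabs, treatment = "ds_aqp1", control = "gfp")
#' @export
knockdown_timecourse <- function(tables, treatment, control) {
  empty <- data.frame(dpi = numeric(0), gene = character(0),
                      rq = numeric(0), rq_lo = numeric(0),
                      rq_hi = numeric(0))
  if (length(tables) == 0L) {
    warning("empty day map: no Ct tables supplied", call. = FALSE)
    return(empty)
  }
  if (is.null(names(tables)) || anyNA(suppressWarnings(as.numeric(names(tables)))))
    stop("`tables` must be named by numeric days post injection",
         call. = FALSE)
  out <- list()
  for (day in names(tables)) {
    tab <- tables[[day]]
    have <- unique(tab$group)
    if (!all(c(treatment, control) %in% have)) {
      warning("day ", day, " skipped: missing group(s) ",
              paste(setdiff(c(treatment, control), have), collapse = ", "),
              call. = FALSE)
      next
    }
    re <- relative_expression(tab, calibrator = control)
    re <- re[re$group == treatment, , drop = FALSE]
    out[[day]] <- data.frame(dpi = as.numeric(day), gene = re$gene,
                             rq = re$rq, rq_lo = re$rq_lo, rq_hi = re$rq_hi,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$dpi, res$gene), , drop = FALSE]
}
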