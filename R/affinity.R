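# Radioligand competition assay arithmetic: IC50 curve fitting, the
# Cheng-Prusoff conversion, mutant fold shifts and binding free energy
# from Ki.

#' Fit an IC50 from percent-inhibition dose-response data
#'
#' Least-squares fit of `inhibition = 100 / (1 + (ic50 / c)^hill)` via
#' Levenberg-Marquardt on `log10(ic50)`, started at the concentration whose
#' reading is nearest 50 percent (Hill slope started at 1 and fitted).
#' A fit is flagged when the optimizer fails, the data show no transition,
#' or the fitted IC50 falls outside the tested concentration range scaled
#' by `[0.01, 100]`.
#'
#' @param concentrations competitor concentrations, M (>= 4 points).
#' @param inhibition percent inhibition readings.
#' @return list with `ic50`, `hill`, `flagged`, `flag_reason`, `residual_sd`
#'   and the `fit` object (or `NULL`).
#' @export
fit_ic50 <- function(concentrations, inhibition) {
  stopifnot(length(concentrations) == length(inhibition),
            length(concentrations) >= 4, all(concentrations > 0))
  if (max(inhibition) - min(inhibition) < 5) {
    return(list(ic50 = NA_real_, hill = NA_real_, flagged = TRUE,
                flag_reason = "no transition in the data",
                residual_sd = NA_real_, fit = NULL))
  }
  start_ic50 <- concentrations[which.min(abs(inhibition - 50))]
  df <- data.frame(conc = concentrations, inh = inhibition)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      inh ~ 100 / (1 + (10^lic50 / conc)^hill),
      data = df,
      start = list(lic50 = log10(start_ic50), hill = 1),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(ic50 = NA_real_, hill = NA_real_, flagged = TRUE,
                flag_reason = "fit did not converge",
                residual_sd = NA_real_, fit = NULL))
  }
  co <- stats::coef(fit)
  ic50 <- 10^co[["lic50"]]
  rng <- range(concentrations)
  flagged <- ic50 < 0.01 * rng[1] || ic50 > 100 * rng[2]
  list(ic50 = ic50, hill = co[["hill"]], flagged = flagged,
       flag_reason = if (flagged) "IC50 outside tested range" else NA_character_,
       residual_sd = stats::sd(stats::residuals(fit)), fit = fit)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / Kd)` where `L` is the radioligand concentration
#' and `Kd` its dissociation constant at the receptor form assayed.
#'
#' @param ic50,l_conc,kd concentrations in M (`l_conc >= 0`).
#' @return Ki in M.
#' @export
cheng_prusoff <- function(ic50, l_conc, kd) {
  stopifnot(ic50 > 0, l_conc >= 0, kd > 0)
  ic50 / (1 + l_conc / kd)
}

#' Mutant fold shift
#'
#' `Ki_mutant / Ki_wt`; values above 1 indicate the mutation weakens
#' binding.
#'
#' @param ki_mut,ki_wt inhibition constants, M (> 0).
#' @return dimensionless ratio.
#' @export
fold_shift <- function(ki_mut, ki_wt) {
  stopifnot(ki_mut > 0, ki_wt > 0)
  ki_mut / ki_wt
}

#' Binding free energy from an inhibition constant
#'
#' `dG = RT log(Ki / 1 M)` with `R = 1.98720e-3 kcal/(mol K)`.
#'
#' @param ki M (> 0).
#' @param temperature Kelvin (default 298).
#' @return kcal/mol (negative for sub-molar Ki).
#' @export
delta_g_from_ki <- function(ki, temperature = 298) {
  stopifnot(ki > 0, temperature > 0)
  GAS_CONSTANT_KCAL * temperature * log(ki)
}

#' Process an assay table
#'
#' Takes a data.frame with columns `compound`, `receptor_form`, `ic50_nM`,
#' `l_nM`, `kd_nM` and returns it augmented with `ki_nM`,
#' `delta_g_kcal_mol` and, for mutant rows, `fold_shift` relative to the
#' matching wild-type (`receptor_form == "wt"`) row of the same compound.
#'
#' @param assays input data.frame.
#' @param temperature Kelvin.
#' @return augmented data.frame.
#' @export
process_assay_table <- function(assays, temperature = 298) {
  required <- c("compound", "receptor_form", "ic50_nM", "l_nM", "kd_nM")
  stopifnot(all(required %in% names(assays)))
  assays$ki_nM <- mapply(function(i, l, k) cheng_prusoff(i * 1e-9, l * 1e-9,
                                                         k * 1e-9) * 1e9,
                         assays$ic50_nM, assays$l_nM, assays$kd_nM)
  assays$delta_g_kcal_mol <- vapply(assays$ki_nM * 1e-9, delta_g_from_ki,
                                    numeric(1), temperature = temperature)
  assays$fold_shift <- NA_real_
  for (r in seq_len(nrow(assays))) {
    if (assays$receptor_form[r] == "wt") next
    wt <- which(assays$compound == assays$compound[r] &
                  assays$receptor_form == "wt")
    if (length(wt) == 1) {
      assays$fold_shift[r] <- fold_shift(assays$ki_nM[r] * 1e-9,
                                         assays$ki_nM[wt] * 1e-9)
    }
  }
  assays
}
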