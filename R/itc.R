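# Single-site (1:1) isothermal titration calorimetry: forward Wiseman
# isotherm with perfusion dilution tracking, nonlinear least-squares
# fitting, and affinity summaries.
#
# Working units: volumes in uL, concentrations in uM, enthalpy in
# kcal/mol, heats in ucal.

#' Define an ITC titration schedule
#'
#' @param cell_volume_uL Active cell volume (uL).
#' @param cell_uM Initial macromolecule concentration in the cell (uM).
#' @param syringe_uM Titrant concentration in the syringe (uM).
#' @param injection_volumes_uL Vector of injection volumes (uL).
#' @param temperature_C Experiment temperature (deg C).
#' @return A `titration_schedule` list.
#' @export
titration_schedule <- function(cell_volume_uL = 200, cell_uM = 20,
                               syringe_uM = 200,
                               injection_volumes_uL = rep(2, 20),
                               temperature_C = 25) {
  if (cell_volume_uL <= 0 || cell_uM <= 0 || syringe_uM <= 0 ||
      any(injection_volumes_uL <= 0))
    stop("volumes and concentrations must be positive")
  if (temperature_C <= -273.15) stop("temperature below absolute zero")
  structure(list(cell_volume_uL = cell_volume_uL, cell_uM = cell_uM,
                 syringe_uM = syringe_uM,
                 injection_volumes_uL = injection_volumes_uL,
                 temperature_C = temperature_C),
            class = "titration_schedule")
}

# Perfusion (displaced-volume) concentration tracking: after cumulative
# injected volume v into a cell of volume V0,
#   M_t = M0 (1 - v/2V0) / (1 + v/2V0)     (macromolecule, diluted out)
#   X_t = X0 (v/V0) / (1 + v/2V0)          (titrant, displaced as added)
.itc_concentrations <- function(schedule) {
  V0 <- schedule$cell_volume_uL
  v <- cumsum(schedule$injection_volumes_uL)
  list(M = schedule$cell_uM * (1 - v / (2 * V0)) / (1 + v / (2 * V0)),
       X = schedule$syringe_uM * (v / V0) / (1 + v / (2 * V0)))
}

#' Predict per-injection heats for a 1:1 binding isotherm
#'
#' Computes the cumulative bound heat `Q_i = n * M_t,i * dH * V0 * Theta_i`
#' where `Theta` is the bound fraction from the single-site quadratic
#' root, and differences with the displaced-volume correction
#' `dq_i = Q_i - Q_{i-1} + (dV_i/V0) * (Q_i + Q_{i-1}) / 2 + offset`.
#'
#' @param n Binding stoichiometry.
#' @param Kd_uM Dissociation constant (uM), > 0.
#' @param dH_kcal Binding enthalpy (kcal/mol).
#' @param offset Constant heat per injection (ucal), e.g. dilution heat.
#' @param schedule A `titration_schedule`.
#' @return Numeric vector of per-injection heats (ucal).
#' @export
predict_heats <- function(n, Kd_uM, dH_kcal, offset, schedule) {
  if (Kd_uM <= 0) stop("Kd must be positive")
  conc <- .itc_concentrations(schedule)
  nM <- n * conc$M
  x <- conc$X / nM
  r <- Kd_uM / nM
  disc <- (1 + x + r)^2 - 4 * x
  theta <- (1 + x + r - sqrt(pmax(disc, 0))) / 2
  V0 <- schedule$cell_volume_uL
  # uM * uL * kcal/mol = 1e-3 ucal
  Q <- n * theta * conc$M * dH_kcal * V0 * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  dV <- schedule$injection_volumes_uL
  Q - Qprev + (dV / V0) * (Q + Qprev) / 2 + offset
}

#' Fit the 1:1 binding model to ITC heats
#'
#' Nonlinear least squares over `(n, Kd, dH, offset)` with three
#' log-spaced `Kd` starting values; the best-chi-squared solution wins.
#' Standard errors come from the Gauss-Newton covariance at the optimum.
#' Fits with a Wiseman c-value (`n * cell_uM / Kd`) outside `[0.1, 1e4]`
#' or failed convergence are flagged low-confidence, mirroring the
#' practical rule that stoichiometry is not well determined for weak
#' binders.
#'
#' @param heats Per-injection heats (ucal), one per scheduled injection.
#' @param schedule A `titration_schedule`.
#' @param fix_n Optional fixed stoichiometry (e.g. 1 for weak binders).
#' @return A `binding_fit` list: `n`, `Kd_uM`, `dH_kcal`, `offset`,
#'   `se` (named vector), `chi2`, `c_value`, `flags`.
#' @export
fit_binding <- function(heats, schedule, fix_n = NULL) {
  if (length(heats) != length(schedule$injection_volumes_uL))
    stop("one heat per scheduled injection required")
  if (length(heats) < 6)
    stop("need at least 6 injections spanning the transition")
  M0 <- schedule$cell_uM
  span <- diff(range(heats))
  dH0 <- (heats[1] - heats[length(heats)]) /
    (schedule$syringe_uM * schedule$injection_volumes_uL[1] * 1e-3)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -5
  off0 <- mean(utils::tail(heats, 3))
  resid_fn <- function(par) {
    n <- if (is.null(fix_n)) exp(par[["log_n"]]) else fix_n
    pred <- predict_heats(n, exp(par[["log_kd"]]), par[["dH"]],
                          par[["offset"]], schedule)
    heats - pred
  }
  obj <- function(par) sum(resid_fn(par)^2)
  starts <- lapply(M0 * c(0.05, 1, 20), function(kd0) {
    p <- c(log_kd = log(kd0), dH = dH0, offset = off0)
    if (is.null(fix_n)) p <- c(log_n = 0, p)
    p
  })
  best <- NULL
  for (p0 in starts) {
    fit <- try(stats::optim(p0, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000,
                                           reltol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    fit <- try(stats::optim(fit$par, obj, method = "BFGS",
                            control = list(maxit = 500,
                                           reltol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("ITC fit failed to converge from all starts")
  par <- best$par
  n_hat <- if (is.null(fix_n)) exp(par[["log_n"]]) else fix_n
  kd_hat <- exp(par[["log_kd"]])
  npar <- length(par)
  dof <- max(length(heats) - npar, 1)
  sigma2 <- best$value / dof
  # Jacobian of residuals by central differences on the working scale
  J <- vapply(seq_along(par), function(j) {
    h <- pmax(abs(par[j]) * 1e-5, 1e-7)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }, numeric(length(heats)))
  JtJ <- crossprod(J)
  cov <- try(solve(JtJ) * sigma2, silent = TRUE)
  flags <- character(0)
  se <- rep(NA_real_, npar)
  if (!inherits(cov, "try-error")) {
    se <- sqrt(pmax(diag(cov), 0))
  } else {
    flags <- c(flags, "singular_covariance")
  }
  names(se) <- names(par)
  # delta method back to natural scale
  se_out <- c(n = if (is.null(fix_n)) n_hat * se[["log_n"]] else 0,
              Kd_uM = kd_hat * se[["log_kd"]],
              dH_kcal = se[["dH"]], offset = se[["offset"]])
  c_value <- n_hat * M0 / kd_hat
  if (c_value < 0.1 || c_value > 1e4)
    flags <- c(flags, "low_confidence_c_value")
  rel_kd_se <- se[["log_kd"]]
  if (is.na(rel_kd_se) || rel_kd_se > 1)
    flags <- c(flags, "wide_kd_interval")
  structure(list(n = n_hat, Kd_uM = kd_hat, dH_kcal = par[["dH"]],
                 offset = par[["offset"]], se = se_out,
                 chi2 = best$value, c_value = c_value, flags = flags),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "binding_fit: n = %.3f, Kd = %.3g uM, dH = %.3g kcal/mol (chi2 %.3g)\n",
    x$n, x$Kd_uM, x$dH_kcal, x$chi2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Mean and standard error of a set of dissociation constants
#'
#' @param values Numeric vector of Kd values (>= 2).
#' @return List with `mean` and `sem` (sample SD / sqrt(N)).
#' @export
summarize_kd <- function(values) {
  if (length(values) < 2) stop("need at least 2 values for a SEM")
  list(mean = mean(values),
       sem = stats::sd(values) / sqrt(length(values)))
}

#' Relative affinity against a reference interaction
#'
#' @param Kd,reference_Kd Positive dissociation constants (same units).
#' @return The ratio `Kd / reference_Kd` (1 = equal affinity; > 1 =
#'   weaker than the reference).
#' @export
relative_affinity <- function(Kd, reference_Kd) {
  if (any(Kd <= 0) || reference_Kd <= 0) stop("Kd values must be positive")
  Kd / reference_Kd
}
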