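# Two-state analysis of chemical denaturation (urea) and helix-induction
# (TFE) transitions monitored by CD at 222 nm, with linear baselines on
# both sides, single and global shared-m fits, and linear-extrapolation
# free energies.

#' Gas constant in kcal mol^-1 K^-1
#' @export
R_KCAL <- 1.987e-3

.rt_for <- function(mode, temperature_K) {
  if (mode == "urea") R_KCAL * temperature_K else 1
}

#' Two-state transition curve with linear baselines
#'
#' The population of the denatured (urea) or helical (TFE) end state is
#' `f_D(x) = 1 / (1 + exp(m * (midpoint - x) / RT))` with `RT` in
#' kcal/mol for urea (`m` in kcal mol^-1 M^-1) and `RT = 1` for TFE
#' (`m` dimensionless per %). The observed signal interpolates two
#' linear baselines: `y = (a_N + b_N x)(1 - f_D) + (a_D + b_D x) f_D`.
#'
#' @param params List/vector with `midpoint`, `m`, `a_N`, `b_N`, `a_D`,
#'   `b_D`.
#' @param x Denaturant concentrations (M for urea, % v/v for TFE).
#' @param mode `"urea"` or `"tfe"`.
#' @param temperature_K Temperature (default 283.15 K for urea,
#'   298.15 K for TFE).
#' @return Predicted signal at each `x`.
#' @export
two_state_curve <- function(params, x, mode = c("urea", "tfe"),
                            temperature_K = NULL) {
  mode <- match.arg(mode)
  if (is.null(temperature_K))
    temperature_K <- if (mode == "urea") 283.15 else 298.15
  p <- as.list(params)
  rt <- .rt_for(mode, temperature_K)
  fD <- stats::plogis(p$m * (x - p$midpoint) / rt)
  (p$a_N + p$b_N * x) * (1 - fD) + (p$a_D + p$b_D * x) * fD
}

.check_denat_data <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8) stop("need at least 8 titration points")
  if (any(x < 0)) stop("denaturant concentrations must be nonnegative")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
}

.denat_se_and_flags <- function(par, resid_fn, nobs, x, fD) {
  npar <- length(par)
  dof <- max(nobs - npar, 1)
  ssr <- sum(resid_fn(par)^2)
  sigma2 <- ssr / dof
  J <- vapply(seq_along(par), function(j) {
    h <- pmax(abs(par[j]) * 1e-6, 1e-8)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }, numeric(nobs))
  cov <- try(solve(crossprod(J)) * sigma2, silent = TRUE)
  if (inherits(cov, "try-error"))
    return(list(se = stats::setNames(rep(NA_real_, npar), names(par)),
                flags = "singular_covariance", chi2 = ssr))
  list(se = stats::setNames(sqrt(pmax(diag(cov), 0)), names(par)),
       flags = character(0), chi2 = ssr)
}

#' Fit a single two-state denaturation curve
#'
#' Least squares over midpoint, m-value and the four baseline
#' parameters; standard errors from the covariance at the optimum. The
#' fit is flagged when the midpoint lands outside twice the scanned
#' range or when fewer than 3 points support either baseline (end-state
#' population > 0.9).
#'
#' @param x,y Denaturant concentrations and CD signal (same length,
#'   >= 8 points).
#' @inheritParams two_state_curve
#' @return A `two_state_fit` list: `params`, `se`, `chi2`, `flags`,
#'   `mode`, `temperature_K`, and for urea `delta_g` (from
#'   [delta_g()]).
#' @export
fit_single <- function(x, y, mode = c("urea", "tfe"),
                       temperature_K = NULL) {
  mode <- match.arg(mode)
  if (is.null(temperature_K))
    temperature_K <- if (mode == "urea") 283.15 else 298.15
  .check_denat_data(x, y)
  rt <- .rt_for(mode, temperature_K)
  # starts: midpoint at half-signal crossing, baselines from curve ends
  mid0 <- x[which.min(abs(y - mean(range(y))))]
  m0 <- if (mode == "urea") 4 * rt / diff(range(x)) else
    4 / diff(range(x))
  k <- max(3, length(x) %/% 4)
  fitN <- stats::lm(y[seq_len(k)] ~ x[seq_len(k)])
  tail_i <- seq(length(x) - k + 1, length(x))
  fitD <- stats::lm(y[tail_i] ~ x[tail_i])
  p0 <- c(midpoint = mid0, m = m0,
          a_N = unname(stats::coef(fitN)[1]),
          b_N = unname(stats::coef(fitN)[2]),
          a_D = unname(stats::coef(fitD)[1]),
          b_D = unname(stats::coef(fitD)[2]))
  resid_fn <- function(par)
    y - two_state_curve(par, x, mode, temperature_K)
  obj <- function(par) sum(resid_fn(par)^2)
  # multi-start over midpoint quantiles and m scalings guards against
  # local optima on broad, short-baseline transitions
  fit <- NULL
  for (mid_try in unique(c(mid0, stats::quantile(x, c(0.3, 0.5, 0.7))))) {
    for (m_try in c(m0, 3 * m0)) {
      p_try <- p0
      p_try[["midpoint"]] <- mid_try
      p_try[["m"]] <- m_try
      f <- stats::optim(p_try, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
      f <- stats::optim(f$par, obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
      if (is.null(fit) || f$value < fit$value) fit <- f
    }
  }
  if (fit$convergence != 0)
    stop("two-state fit did not converge (code ", fit$convergence, ")")
  par <- fit$par
  if (par[["m"]] < 0) {  # canonical orientation: m > 0, baselines swap
    par[["m"]] <- -par[["m"]]
    tmp <- par[c("a_N", "b_N")]
    par[c("a_N", "b_N")] <- par[c("a_D", "b_D")]
    par[c("a_D", "b_D")] <- tmp
  }
  fD <- stats::plogis(par[["m"]] * (x - par[["midpoint"]]) / rt)
  sf <- .denat_se_and_flags(par, resid_fn, length(x), x, fD)
  flags <- sf$flags
  rng <- range(x)
  span <- diff(rng)
  if (par[["midpoint"]] < rng[1] - span || par[["midpoint"]] > rng[2] + span)
    flags <- c(flags, "midpoint_outside_scan")
  if (sum(fD < 0.1) < 3) flags <- c(flags, "short_native_baseline")
  if (sum(fD > 0.9) < 3) flags <- c(flags, "short_denatured_baseline")
  out <- structure(list(params = par, se = sf$se, chi2 = sf$chi2,
                        flags = flags, mode = mode,
                        temperature_K = temperature_K),
                   class = "two_state_fit")
  if (mode == "urea")
    out$delta_g <- delta_g(par[["midpoint"]], par[["m"]],
                           sf$se[["midpoint"]], sf$se[["m"]])
  out
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("two_state_fit (%s): midpoint = %.3g, m = %.3g\n",
              x$mode, x$params[["midpoint"]], x$params[["m"]]))
  if (!is.null(x$delta_g))
    cat(sprintf("  dG_D-N = %.3g +/- %.2g kcal/mol\n",
                x$delta_g$value, x$delta_g$se))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Global two-state fit with a shared m-value
#'
#' Jointly fits several denaturation curves of the same mode with one
#' common m-value and independent midpoints and baselines, pooling the
#' cooperativity information across variants.
#'
#' @param datasets List of lists with elements `x` and `y`.
#' @inheritParams two_state_curve
#' @return List with `m` (+`m_se`), `fits` (per-dataset parameter
#'   vectors with SEs and, for urea, `delta_g`), `chi2`, `flags`.
#' @export
fit_global_shared_m <- function(datasets, mode = c("urea", "tfe"),
                                temperature_K = NULL) {
  mode <- match.arg(mode)
  if (is.null(temperature_K))
    temperature_K <- if (mode == "urea") 283.15 else 298.15
  nd <- length(datasets)
  if (nd < 1) stop("no datasets supplied")
  singles <- lapply(datasets, function(d)
    fit_single(d$x, d$y, mode, temperature_K))
  if (nd == 1) {
    s <- singles[[1]]
    return(list(m = s$params[["m"]], m_se = s$se[["m"]],
                fits = list(s), chi2 = s$chi2, flags = s$flags))
  }
  m0 <- mean(vapply(singles, function(s) s$params[["m"]], 0))
  p0 <- c(m = m0)
  for (i in seq_len(nd)) {
    pi_ <- singles[[i]]$params[c("midpoint", "a_N", "b_N", "a_D", "b_D")]
    names(pi_) <- paste0(names(pi_), "_", i)
    p0 <- c(p0, pi_)
  }
  all_y <- unlist(lapply(datasets, `[[`, "y"))
  resid_fn <- function(par) {
    pred <- unlist(lapply(seq_len(nd), function(i) {
      p <- c(midpoint = par[[paste0("midpoint_", i)]], m = par[["m"]],
             a_N = par[[paste0("a_N_", i)]], b_N = par[[paste0("b_N_", i)]],
             a_D = par[[paste0("a_D_", i)]], b_D = par[[paste0("b_D_", i)]])
      two_state_curve(p, datasets[[i]]$x, mode, temperature_K)
    }))
    all_y - pred
  }
  obj <- function(par) sum(resid_fn(par)^2)
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-13))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  par <- fit$par
  sf <- .denat_se_and_flags(par, resid_fn, length(all_y), NULL, NULL)
  fits <- lapply(seq_len(nd), function(i) {
    keys <- paste0(c("midpoint", "a_N", "b_N", "a_D", "b_D"), "_", i)
    p <- stats::setNames(par[keys],
                         c("midpoint", "a_N", "b_N", "a_D", "b_D"))
    se <- stats::setNames(sf$se[keys],
                          c("midpoint", "a_N", "b_N", "a_D", "b_D"))
    out <- list(params = c(p, m = unname(par[["m"]])), se = se)
    if (mode == "urea")
      out$delta_g <- delta_g(p[["midpoint"]], par[["m"]],
                             se[["midpoint"]], sf$se[["m"]])
    out
  })
  list(m = unname(par[["m"]]), m_se = unname(sf$se[["m"]]),
       fits = fits, chi2 = fit$value, flags = sf$flags)
}

#' Linear-extrapolation unfolding free energy
#'
#' `dG_D-N = m * midpoint` (kcal/mol for urea), with the standard error
#' propagated in quadrature from the two factors.
#'
#' @param midpoint Transition midpoint (M).
#' @param m m-value (kcal mol^-1 M^-1).
#' @param se_midpoint,se_m Optional standard errors.
#' @return List with `value` and `se` (NA if no errors supplied).
#' @export
delta_g <- function(midpoint, m, se_midpoint = NA, se_m = NA) {
  value <- m * midpoint
  se <- if (is.na(se_midpoint) || is.na(se_m)) NA_real_ else
    sqrt((midpoint * se_m)^2 + (m * se_midpoint)^2)
  list(value = value, se = se)
}
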