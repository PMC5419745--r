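# Analytic toy systems standing in for the molecular force field:
# low-dimensional potentials with collective variables, forward models
# and quadrature reference free energies, so every element of the
# ensemble-determination machinery can be exercised at desk scale.

#' Construct or look up an analytic toy system
#'
#' Registry of named systems (energies in kJ/mol):
#' \describe{
#'   \item{`double_well_1d`}{`E(x) = a (x^2 - 1)^2`, default `a = 8`;
#'     CV = x.}
#'   \item{`asym_double_well`}{`E(x) = a (x^2 - 1)^2 + b x`, defaults
#'     `a = 8`, `b = 2`; CV = x.}
#'   \item{`harmonic_2d`}{`E(x, y) = k (x^2 + y^2) / 2`, default
#'     `k = 10`; CVs = x and y.}
#' }
#'
#' @param name System name.
#' @param ... Overrides for the system's parameters (`a`, `b`, `k`).
#' @return A `toy_system`: list with `name`, `dim`, `energy(x)`,
#'   `cvs` (list of functions of the configuration), `forward`
#'   (observable forward model, configuration -> numeric vector) and
#'   `domain` (sampling box, matrix dim x 2).
#' @export
make_toy_system <- function(name, ...) {
  pars <- list(...)
  get_par <- function(key, default)
    if (!is.null(pars[[key]])) pars[[key]] else default
  sys <- switch(
    name,
    double_well_1d = {
      a <- get_par("a", 8)
      list(dim = 1L,
           energy = function(x) a * (x[1]^2 - 1)^2,
           cvs = list(function(x) x[1]),
           forward = function(x) x[1],
           domain = matrix(c(-2.5, 2.5), 1))
    },
    asym_double_well = {
      a <- get_par("a", 8); b <- get_par("b", 2)
      list(dim = 1L,
           energy = function(x) a * (x[1]^2 - 1)^2 + b * x[1],
           cvs = list(function(x) x[1]),
           forward = function(x) x[1],
           domain = matrix(c(-2.5, 2.5), 1))
    },
    harmonic_2d = {
      k <- get_par("k", 10)
      list(dim = 2L,
           energy = function(x) k * sum(x^2) / 2,
           cvs = list(function(x) x[1], function(x) x[2]),
           forward = function(x) x,
           domain = matrix(c(-3, 3, -3, 3), 2, byrow = TRUE))
    },
    stop("unknown toy system: ", name))
  structure(c(list(name = name), sys), class = "toy_system")
}

#' Reference free energy along the first collective variable
#'
#' Computes `F(s) = -kT ln integral delta(s - cv(x)) exp(-E(x)/kT) dx`
#' by quadrature on a fine grid (for the packaged 1-D systems the CV is
#' the configuration itself, so `F(s) = E(s)` up to a constant; the 2-D
#' harmonic system is marginalized numerically). Returned values are
#' shifted so the minimum is 0.
#'
#' @param system A `toy_system`.
#' @param s Grid of CV values at which to evaluate.
#' @param kT Thermal energy (kJ/mol).
#' @return Numeric vector `F(s)` (kJ/mol), min 0.
#' @export
analytic_free_energy <- function(system, s, kT = 2.48) {
  if (system$dim == 1L) {
    F_ <- vapply(s, function(v) system$energy(v), 0)
  } else {
    # marginalize the remaining coordinates by quadrature
    grid <- seq(system$domain[2, 1], system$domain[2, 2], length.out = 401)
    F_ <- vapply(s, function(v) {
      e <- vapply(grid, function(y) system$energy(c(v, y)), 0)
      -kT * log(sum(exp(-e / kT)))
    }, 0)
  }
  F_ - min(F_)
}

#' Boltzmann partition function / averages by quadrature (1-D systems)
#'
#' @param system A 1-D `toy_system`.
#' @param kT Thermal energy (kJ/mol).
#' @param observable Function of x; default identity.
#' @param n Grid size.
#' @return List with `Z` (unnormalized, grid-spacing scaled) and `mean`
#'   (Boltzmann average of the observable).
#' @export
boltzmann_quadrature <- function(system, kT = 2.48,
                                 observable = function(x) x, n = 4001) {
  if (system$dim != 1L) stop("quadrature helper is for 1-D systems")
  g <- seq(system$domain[1, 1], system$domain[1, 2], length.out = n)
  e <- vapply(g, function(x) system$energy(x), 0)
  w <- exp(-(e - min(e)) / kT)
  obs <- vapply(g, observable, 0)
  dx <- g[2] - g[1]
  list(Z = sum(w) * dx * exp(-min(e) / kT),
       mean = sum(w * obs) / sum(w),
       grid = g, density = w / (sum(w) * dx))
}
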