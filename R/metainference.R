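# Desk-scale Gaussian metainference with well-tempered parallel-bias
# metadynamics. The replica-averaged forward model is restrained toward
# reference observables with per-replica, per-datum errors sampled on
# the fly; sampling is Metropolis Monte Carlo on analytic toy systems.

#' Construct a replica state for metainference
#'
#' @param X List (length N) of replica configurations (numeric vectors).
#' @param sigma Matrix N x N_d of per-replica, per-datum error
#'   parameters (> 0), or a scalar recycled.
#' @param kT Thermal energy (kJ/mol).
#' @param n_data Number of data points (needed when `sigma` is scalar).
#' @return A `replica_state` list.
#' @export
replica_state <- function(X, sigma = 1, kT = 2.48, n_data = NULL) {
  if (!is.list(X)) X <- list(X)
  N <- length(X)
  if (!is.matrix(sigma)) {
    if (is.null(n_data)) n_data <- 1L
    sigma <- matrix(sigma, N, n_data)
  }
  if (nrow(sigma) != N) stop("one sigma row per replica required")
  if (any(sigma <= 0)) stop("sigma must be positive")
  structure(list(X = X, sigma = sigma, kT = kT), class = "replica_state")
}

# replica-averaged forward model: mean over replicas, per datum
.replica_avg_forward <- function(state, system) {
  f <- vapply(state$X, function(x) as.numeric(system$forward(x)),
              numeric(ncol(state$sigma)))
  if (is.matrix(f)) rowMeans(f) else mean(f)
}

#' Gaussian metainference energy
#'
#' Implements
#' `E = sum_r { E_ff(X_r) + kT sum_i [ (f_i(X) - d_i)^2 / (2 sigma_r,i^2)
#' + 0.5 log(2 pi sigma_r,i) + 0.5 log sigma_r,i ] }`
#' where `f_i(X)` is the forward model averaged over the replicas. With
#' no data the energy reduces to the summed force-field energies.
#'
#' @param state A `replica_state`.
#' @param data Numeric vector of reference observables `d_i` (may be
#'   length 0).
#' @param system A `toy_system` providing `energy` and `forward`.
#' @return Total energy (kJ/mol).
#' @export
metainference_energy <- function(state, data, system) {
  if (any(state$sigma <= 0)) stop("sigma must be positive")
  E <- sum(vapply(state$X, function(x) system$energy(x), 0))
  nd <- length(data)
  if (nd == 0) return(E)
  if (ncol(state$sigma) != nd) stop("sigma needs one column per datum")
  favg <- .replica_avg_forward(state, system)
  res2 <- (favg - data)^2
  for (r in seq_along(state$X)) {
    s <- state$sigma[r, ]
    E <- E + state$kT * sum(res2 / (2 * s^2) +
                              0.5 * log(2 * pi * s) + 0.5 * log(s))
  }
  E
}

#' Metropolis update of the metainference error parameters
#'
#' Each `sigma_r,i` receives a multiplicative log-normal proposal
#' (`sigma' = sigma * exp(w * z)`, `z ~ N(0,1)`) accepted with the
#' Hastings factor `sigma'/sigma` times `exp(-dE/kT)`, which preserves
#' detailed balance with respect to `exp(-E/kT) d sigma`. Proposals
#' outside `bounds` are rejected.
#'
#' @param state A `replica_state`.
#' @param data Reference observables.
#' @param system A `toy_system`.
#' @param bounds Numeric length-2 vector `[sigma_min, sigma_max]`.
#' @param width Log-scale proposal width (default 0.1).
#' @return The updated `replica_state` (with an `accept` attribute:
#'   acceptance fraction).
#' @export
sample_sigma <- function(state, data, system, bounds = c(0.01, 10),
                         width = 0.1) {
  nd <- length(data)
  if (nd == 0) return(state)
  favg <- .replica_avg_forward(state, system)
  res2 <- (favg - data)^2
  acc <- 0L
  ntry <- 0L
  for (r in seq_len(nrow(state$sigma))) {
    for (i in seq_len(nd)) {
      s <- state$sigma[r, i]
      s_new <- s * exp(width * stats::rnorm(1))
      ntry <- ntry + 1L
      if (s_new < bounds[1] || s_new > bounds[2]) next
      # energy terms containing sigma_{r,i}, divided by kT:
      eterm <- function(sg) res2[i] / (2 * sg^2) + 1.5 * log(sg)
      log_alpha <- -(eterm(s_new) - eterm(s)) + log(s_new / s)
      if (log(stats::runif(1)) < log_alpha) {
        state$sigma[r, i] <- s_new
        acc <- acc + 1L
      }
    }
  }
  attr(state, "accept") <- acc / max(ntry, 1L)
  state
}

#' Initialize a parallel-bias well-tempered metadynamics bias
#'
#' One 1-D bias grid per collective variable. The bias is kept constant
#' outside the stated interval (boundary clamping), matching the usual
#' treatment of CV borders.
#'
#' @param cv_grids List of numeric length-2 range vectors (grid extent
#'   per CV).
#' @param sigmas Gaussian width per CV.
#' @param intervals List of length-2 vectors; bias is constant outside.
#'   Defaults to the grid ranges.
#' @param h0 Initial Gaussian height (kJ/mol).
#' @param gamma Well-tempered bias factor (default 16).
#' @param kT Thermal energy (kJ/mol).
#' @param n_grid Grid points per CV (default 512).
#' @return A `pbmetad_bias` object.
#' @export
pbmetad_bias <- function(cv_grids, sigmas, intervals = NULL, h0 = 0.5,
                         gamma = 16, kT = 2.48, n_grid = 512L) {
  ncv <- length(cv_grids)
  if (length(sigmas) != ncv) stop("one Gaussian width per CV required")
  if (is.null(intervals)) intervals <- cv_grids
  if (gamma <= 1) stop("bias factor gamma must exceed 1")
  grids <- lapply(seq_len(ncv), function(j) {
    s <- seq(cv_grids[[j]][1], cv_grids[[j]][2], length.out = n_grid)
    list(s = s, V = numeric(n_grid), sigma = sigmas[j],
         lo = intervals[[j]][1], hi = intervals[[j]][2])
  })
  structure(list(grids = grids, h0 = h0, gamma = gamma, kT = kT,
                 n_deposited = 0L),
            class = "pbmetad_bias")
}

# linear interpolation of one bias grid with constant extension
.bias_value <- function(g, s) {
  s <- pmin(pmax(s, g$s[1]), g$s[length(g$s)])
  idx <- findInterval(s, g$s, rightmost.closed = TRUE)
  idx <- pmin(idx, length(g$s) - 1L)
  f <- (s - g$s[idx]) / (g$s[idx + 1L] - g$s[idx])
  g$V[idx] * (1 - f) + g$V[idx + 1L] * f
}

# PB bias potential at a CV vector: -kT ln sum_j exp(-V_j(s_j)/kT)
.pb_potential <- function(bias, cv_values) {
  v <- vapply(seq_along(bias$grids), function(j)
    .bias_value(bias$grids[[j]], cv_values[j]), 0)
  m <- min(v)
  -bias$kT * log(sum(exp(-(v - m) / bias$kT))) + m
}

#' Deposit one parallel-bias Gaussian
#'
#' Per CV `j`, adds a Gaussian of width `sigma_j` at the current CV
#' value with height
#' `h0 * exp(-V_j(s_j) / ((gamma - 1) kT)) * w_j`, where the
#' parallel-bias weight is
#' `w_j = exp(-V_j(s_j)/kT) / sum_k exp(-V_k(s_k)/kT)`. After the
#' update the bias is clamped constant outside each CV's interval. CV
#' values outside the grid deposit at the nearest edge with a warning.
#'
#' @param bias A `pbmetad_bias`.
#' @param cv_values Numeric vector, one current value per CV.
#' @return The updated `pbmetad_bias`.
#' @export
deposit_gaussian <- function(bias, cv_values) {
  ncv <- length(bias$grids)
  if (length(cv_values) != ncv) stop("one CV value per bias grid")
  v_here <- numeric(ncv)
  for (j in seq_len(ncv)) {
    g <- bias$grids[[j]]
    if (cv_values[j] < g$s[1] || cv_values[j] > g$s[length(g$s)]) {
      warning("CV ", j, " outside grid; depositing at nearest edge")
      cv_values[j] <- pmin(pmax(cv_values[j], g$s[1]), g$s[length(g$s)])
    }
    v_here[j] <- .bias_value(g, cv_values[j])
  }
  m <- min(v_here)
  pbw <- exp(-(v_here - m) / bias$kT)
  pbw <- pbw / sum(pbw)
  for (j in seq_len(ncv)) {
    g <- bias$grids[[j]]
    h <- bias$h0 * exp(-v_here[j] / ((bias$gamma - 1) * bias$kT)) * pbw[j]
    g$V <- g$V + h * exp(-(g$s - cv_values[j])^2 / (2 * g$sigma^2))
    # constant outside the interval: clamp to boundary values
    lo_i <- which(g$s < g$lo)
    hi_i <- which(g$s > g$hi)
    if (length(lo_i)) g$V[lo_i] <- g$V[max(lo_i) + 1L]
    if (length(hi_i)) g$V[hi_i] <- g$V[min(hi_i) - 1L]
    bias$grids[[j]] <- g
  }
  bias$n_deposited <- bias$n_deposited + 1L
  bias
}

#' Run the metainference / PBMetaD sampler
#'
#' Metropolis Monte Carlo on all replica configurations under the total
#' energy (metainference energy plus each replica's parallel-bias
#' potential evaluated on its CVs), with error parameters resampled
#' every sweep and Gaussians deposited every `stride` sweeps.
#' Deterministic under a fixed seed.
#'
#' @param system A `toy_system`.
#' @param data Reference observables (numeric, possibly length 0).
#' @param config List of settings: `steps` (MC sweeps), `n_replicas`,
#'   `kT`, `seed`, `step_size` (proposal SD), `stride` (sweeps between
#'   depositions; 0 disables biasing), `h0`, `gamma`, `sigma_cv`
#'   (Gaussian width per CV), `cv_grids`, `intervals`, `sigma_bounds`,
#'   `sigma0`, `n_checkpoints` (bias snapshots over the second half).
#' @return List with `trajectory` (data frame: step, replica, coords,
#'   cv1...), `bias` (final `pbmetad_bias` or NULL), `checkpoints`
#'   (list of bias-grid snapshots with their step numbers), `sigma`
#'   (final error matrix), `acceptance`.
#' @export
run_sampler <- function(system, data = numeric(0), config = list()) {
  cfg <- utils::modifyList(list(
    steps = 10000L, n_replicas = 1L, kT = 2.48, seed = 1L,
    step_size = 0.25, stride = 0L, h0 = 0.5, gamma = 16,
    sigma_cv = rep(0.1, length(system$cvs)),
    cv_grids = lapply(seq_len(nrow(system$domain)), function(i)
      system$domain[i, ]),
    intervals = NULL, sigma_bounds = c(0.01, 10), sigma0 = 1,
    n_checkpoints = 10L, record_stride = 10L), config)
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  ncv <- length(system$cvs)
  nd <- length(data)
  N <- cfg$n_replicas
  # replicas start staggered across the domain
  X <- lapply(seq_len(N), function(r) {
    lo <- system$domain[, 1]; hi <- system$domain[, 2]
    lo + (hi - lo) * stats::runif(system$dim)
  })
  state <- replica_state(X, sigma = cfg$sigma0, kT = cfg$kT, n_data = nd)
  bias <- NULL
  if (cfg$stride > 0)
    bias <- pbmetad_bias(cfg$cv_grids[seq_len(ncv)], cfg$sigma_cv,
                         intervals = cfg$intervals, h0 = cfg$h0,
                         gamma = cfg$gamma, kT = cfg$kT)
  cvs_of <- function(x) vapply(system$cvs, function(f) f(x), 0)
  eff <- vapply(state$X, function(x) system$energy(x), 0)
  cvv <- lapply(state$X, cvs_of)
  bias_e <- rep(0, N)
  if (!is.null(bias))
    bias_e <- vapply(cvv, function(s) .pb_potential(bias, s), 0)
  favg <- if (nd) .replica_avg_forward(state, system) else numeric(0)
  data_term <- function(favg, sigma) {
    if (nd == 0) return(0)
    res2 <- (favg - data)^2
    tot <- 0
    for (r in seq_len(N)) {
      s <- sigma[r, ]
      tot <- tot + cfg$kT * sum(res2 / (2 * s^2) +
                                  0.5 * log(2 * pi * s) + 0.5 * log(s))
    }
    tot
  }
  e_data <- data_term(favg, state$sigma)
  n_acc <- 0L; n_try <- 0L
  checkpoint_steps <- if (cfg$stride > 0 && cfg$n_checkpoints > 0)
    unique(round(seq(cfg$steps / 2, cfg$steps,
                     length.out = cfg$n_checkpoints))) else integer(0)
  checkpoints <- list()
  rec_steps <- seq(cfg$record_stride, cfg$steps, by = cfg$record_stride)
  traj <- vector("list", length(rec_steps))
  ri <- 0L
  for (step in seq_len(cfg$steps)) {
    for (r in seq_len(N)) {
      x_old <- state$X[[r]]
      x_new <- x_old + cfg$step_size * stats::rnorm(system$dim)
      e_old <- eff[r]
      e_new <- system$energy(x_new)
      if (!is.finite(e_new))
        stop("divergent energy at step ", step, " replica ", r)
      cv_new <- cvs_of(x_new)
      be_new <- if (is.null(bias)) 0 else .pb_potential(bias, cv_new)
      dE <- (e_new - e_old) + (be_new - bias_e[r])
      e_data_new <- e_data
      if (nd) {
        f_new <- favg + (as.numeric(system$forward(x_new)) -
                           as.numeric(system$forward(x_old))) / N
        e_data_new <- data_term(f_new, state$sigma)
        dE <- dE + (e_data_new - e_data)
      }
      n_try <- n_try + 1L
      if (log(stats::runif(1)) < -dE / cfg$kT) {
        state$X[[r]] <- x_new
        eff[r] <- e_new
        cvv[[r]] <- cv_new
        bias_e[r] <- be_new
        if (nd) {
          favg <- f_new
          e_data <- e_data_new
        }
        n_acc <- n_acc + 1L
      }
    }
    if (nd) {
      state <- sample_sigma(state, data, system,
                            bounds = cfg$sigma_bounds)
      e_data <- data_term(favg, state$sigma)
    }
    if (!is.null(bias) && step %% cfg$stride == 0L) {
      for (r in seq_len(N)) bias <- deposit_gaussian(bias, cvv[[r]])
      bias_e <- vapply(cvv, function(s) .pb_potential(bias, s), 0)
    }
    if (step %in% checkpoint_steps) {
      checkpoints[[length(checkpoints) + 1L]] <- list(
        step = step, V = lapply(bias$grids, `[[`, "V"))
    }
    if (step %% cfg$record_stride == 0L) {
      ri <- ri + 1L
      traj[[ri]] <- data.frame(
        step = step, replica = seq_len(N),
        t(vapply(state$X, identity, numeric(system$dim))),
        cv1 = vapply(cvv, `[`, 0, 1))
    }
  }
  trajectory <- do.call(rbind, traj[seq_len(ri)])
  names(trajectory)[3:(2 + system$dim)] <-
    paste0("x", seq_len(system$dim))
  list(trajectory = trajectory, bias = bias, checkpoints = checkpoints,
       sigma = state$sigma, acceptance = n_acc / max(n_try, 1L),
       config = cfg)
}

#' Final-bias frame weights
#'
#' `w proportional to exp(+B(X)/kT)` where `B(X)` is the final
#' parallel-bias potential evaluated at each frame's CV values; zero
#' bias gives uniform weights.
#'
#' @param bias A `pbmetad_bias` (or NULL for uniform weights).
#' @param cv_values Matrix (frames x n_cv) or vector of CV values.
#' @param kT Thermal energy (kJ/mol).
#' @return Normalized weight vector.
#' @export
final_weights <- function(bias, cv_values, kT = 2.48) {
  if (!is.matrix(cv_values)) cv_values <- matrix(cv_values, ncol = 1)
  if (is.null(bias)) return(rep(1 / nrow(cv_values), nrow(cv_values)))
  B <- apply(cv_values, 1, function(s) .pb_potential(bias, s))
  reweight(B, kT)
}

#' Free-energy estimate from a bias grid
#'
#' Inverts the well-tempered relation: `F(s) = -gamma/(gamma-1) V(s)`,
#' shifted to zero mean over the requested window.
#'
#' @param V Bias values on the grid (kJ/mol).
#' @param gamma Bias factor.
#' @param sel Optional logical/integer selection of grid points (the
#'   biased interval).
#' @return Free-energy estimate, mean-shifted over `sel`.
#' @export
bias_to_free_energy <- function(V, gamma, sel = NULL) {
  F_ <- -gamma / (gamma - 1) * V
  if (is.null(sel)) sel <- seq_along(V)
  F_ - mean(F_[sel])
}

#' Convergence drift of free-energy estimates
#'
#' Given bias snapshots (checkpoints over the second half of a run),
#' converts each to a free-energy estimate, aligns them to zero mean
#' over the biased interval, and reports the maximum absolute deviation
#' of any instantaneous estimate from the checkpoint average.
#'
#' @param checkpoints List of checkpoints as produced by
#'   [run_sampler()] (`$V` holds per-CV grid vectors).
#' @param grid The CV grid (numeric vector) matching the snapshots.
#' @param gamma Bias factor used in the run.
#' @param interval Length-2 vector restricting the comparison to the
#'   biased interval.
#' @param cv Which CV's bias to analyze (default 1).
#' @return List with `max_drift` (kJ/mol), `mean_F` and `estimates`
#'   (matrix, one row per checkpoint).
#' @export
convergence_check <- function(checkpoints, grid, gamma,
                              interval = range(grid), cv = 1L) {
  if (length(checkpoints) < 2) stop("need at least 2 checkpoints")
  sel <- grid >= interval[1] & grid <= interval[2]
  est <- t(vapply(checkpoints, function(cp)
    bias_to_free_energy(cp$V[[cv]], gamma, sel), numeric(length(grid))))
  mean_F <- colMeans(est)
  max_drift <- max(abs(sweep(est[, sel, drop = FALSE], 2, mean_F[sel])))
  list(max_drift = max_drift, mean_F = mean_F, estimates = est,
       grid = grid, sel = sel)
}
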