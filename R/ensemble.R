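# Observables over weighted structural ensembles: bias reweighting,
# heavy-atom contact maps and interface summaries, RMSF after weighted
# superposition, dihedral-based helix populations, radius of gyration
# and 2-D free-energy surfaces.

#' Bias-based ensemble weights
#'
#' Converts final metadynamics bias values into normalized model
#' weights, `w_i proportional to exp(+B_i / kT)`, computed with a
#' max-shift for overflow safety. Adding a constant to all biases leaves
#' the weights unchanged.
#'
#' @param bias_values Per-model bias (kJ/mol), finite.
#' @param kT Thermal energy (kJ/mol), default 2.48 (298 K).
#' @return Normalized weight vector.
#' @export
reweight <- function(bias_values, kT = 2.48) {
  if (any(!is.finite(bias_values))) stop("bias values must be finite")
  if (kT <= 0) stop("kT must be positive")
  w <- exp((bias_values - max(bias_values)) / kT)
  w / sum(w)
}

# residue keys (chain:resid) in order of first appearance
.residue_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, sep = ":")
  match(key, unique(key))
}

#' Weighted residue-residue contact map
#'
#' Two residues are in contact in a model iff any pair of their heavy
#' atoms lies strictly within `cutoff`; the map entry is the weighted
#' fraction of models with the contact. Self-contacts are excluded.
#'
#' @param ens A `structural_ensemble`.
#' @param cutoff Heavy-atom distance cutoff in nm (default 0.5).
#' @return A `contact_map`: list with `population` (symmetric matrix),
#'   `residues` (data frame chain/resid/domain) and `inter_domain`
#'   (logical mask matrix).
#' @export
contact_map <- function(ens, cutoff = 0.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  heavy <- ens$atoms$element != "H"
  if (!any(heavy)) stop("no heavy atoms in ensemble")
  at <- ens$atoms[heavy, ]
  ridx_all <- .residue_index(ens$atoms)
  ridx <- ridx_all[heavy]
  nres <- max(ridx_all)
  if (any(tabulate(ridx, nres) == 0))
    stop("some residues contain only hydrogen atoms")
  first_atom <- match(seq_len(nres), ridx_all)
  res_tab <- data.frame(chain = ens$atoms$chain[first_atom],
                        resid = ens$atoms$resid[first_atom])
  res_tab$domain <- unname(ens$domains[res_tab$chain])
  pop <- matrix(0, nres, nres)
  for (m in seq_len(n_models(ens))) {
    xyz <- ens$coords[heavy, , m]
    D <- as.matrix(stats::dist(xyz))
    hit <- which(D < cutoff & upper.tri(D), arr.ind = TRUE)
    if (nrow(hit)) {
      rp <- cbind(ridx[hit[, 1]], ridx[hit[, 2]])
      rp <- rp[rp[, 1] != rp[, 2], , drop = FALSE]
      if (nrow(rp)) {
        rp <- unique(t(apply(rp, 1, sort)))
        pop[rp] <- pop[rp] + ens$weights[m]
      }
    }
  }
  pop <- pop + t(pop)
  diag(pop) <- 0
  inter <- outer(res_tab$domain, res_tab$domain, `!=`)
  structure(list(population = pop, residues = res_tab,
                 inter_domain = inter),
            class = "contact_map")
}

#' Summarize inter-domain interface contacts
#'
#' Counts inter-domain contacts whose population is strictly above
#' `threshold`, averages their populations, and reports per-residue
#' interface contact counts normalized by the maximum across residues.
#'
#' @param map A `contact_map`.
#' @param threshold Population threshold (default 0.05).
#' @param mode `"pairs"` counts qualifying residue pairs (primary);
#'   `"residues"` counts residues participating in at least one
#'   qualifying contact.
#' @return List with `count`, `average_population` (NULL when no
#'   contact qualifies) and `per_residue` data frame (chain, resid,
#'   domain, contacts, normalized).
#' @export
interface_summary <- function(map, threshold = 0.05,
                              mode = c("pairs", "residues")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "contact_map"))
  pop <- map$population
  qual <- map$inter_domain & pop > threshold & upper.tri(pop)
  pops <- pop[qual]
  per_res <- rowSums(map$inter_domain & pop > threshold)
  count <- if (mode == "pairs") sum(qual) else sum(per_res > 0)
  maxc <- max(per_res)
  per_residue <- cbind(map$residues,
                       contacts = per_res,
                       normalized = if (maxc > 0) per_res / maxc else
                         rep(0, length(per_res)))
  list(count = as.integer(count),
       average_population = if (length(pops)) mean(pops) else NULL,
       per_residue = per_residue)
}

# weighted mean structure after aligning every model onto `ref`
.weighted_mean_structure <- function(coords, w, ref) {
  n <- dim(coords)[1]
  acc <- matrix(0, n, 3)
  for (m in seq_len(dim(coords)[3]))
    acc <- acc + w[m] * .kabsch_align(coords[, , m], ref)
  acc
}

#' Per-residue root-mean-square fluctuation
#'
#' Iteratively superposes all models (optimal weighted rotation and
#' translation on C-alpha atoms) onto the weighted mean structure until
#' the mean moves less than `tol` nm, then reports
#' `RMSF_i = sqrt(weighted mean squared deviation of CA_i)`.
#'
#' @param ens A `structural_ensemble` with >= 2 models and CA atoms.
#' @param tol Convergence tolerance on the mean structure (nm).
#' @param max_iter Iteration cap.
#' @return Data frame with `chain`, `resid` and `rmsf` (nm).
#' @export
rmsf <- function(ens, tol = 1e-6, max_iter = 50) {
  if (n_models(ens) < 2) stop("RMSF requires at least 2 models")
  ca <- which(ens$atoms$name == "CA")
  if (!length(ca)) stop("no CA atoms found")
  coords <- ens$coords[ca, , , drop = FALSE]
  w <- ens$weights
  ref <- coords[, , which.max(w)]
  for (it in seq_len(max_iter)) {
    mean_s <- .weighted_mean_structure(coords, w, ref)
    shift <- sqrt(mean(rowSums((mean_s - ref)^2)))
    ref <- mean_s
    if (shift < tol) break
  }
  msd <- rep(0, length(ca))
  for (m in seq_len(dim(coords)[3])) {
    al <- .kabsch_align(coords[, , m], ref)
    msd <- msd + w[m] * rowSums((al - ref)^2)
  }
  data.frame(chain = ens$atoms$chain[ca], resid = ens$atoms$resid[ca],
             rmsf = sqrt(msd))
}

# phi/psi per residue for one model; NA at chain termini
.backbone_dihedrals <- function(atoms, xyz) {
  key <- paste(atoms$chain, atoms$resid, sep = ":")
  ridx <- match(key, unique(key))
  nres <- max(ridx)
  idx_of <- function(nm) {
    out <- rep(NA_integer_, nres)
    sel <- which(atoms$name == nm)
    out[ridx[sel]] <- sel
    out
  }
  iN <- idx_of("N"); iCA <- idx_of("CA"); iC <- idx_of("C")
  first <- match(seq_len(nres), ridx)
  chain <- atoms$chain[first]
  phi <- psi <- rep(NA_real_, nres)
  for (r in seq_len(nres)) {
    same_prev <- r > 1 && chain[r - 1] == chain[r]
    same_next <- r < nres && chain[r + 1] == chain[r]
    if (same_prev && !anyNA(c(iC[r - 1], iN[r], iCA[r], iC[r])))
      phi[r] <- .dihedral(xyz[iC[r - 1], ], xyz[iN[r], ],
                          xyz[iCA[r], ], xyz[iC[r], ])
    if (same_next && !anyNA(c(iN[r], iCA[r], iC[r], iN[r + 1])))
      psi[r] <- .dihedral(xyz[iN[r], ], xyz[iCA[r], ],
                          xyz[iC[r], ], xyz[iN[r + 1], ])
  }
  data.frame(chain = chain, resid = atoms$resid[first],
             phi = phi, psi = psi)
}

#' Per-residue helix population and average helical fraction
#'
#' A residue is helical in a model iff its backbone dihedrals fall in
#' the alpha region (`phi` in (-100, -30) and `psi` in (-80, -5)
#' degrees) and it belongs to a run of at least `min_run` consecutive
#' such residues in the same chain. Populations are weighted over
#' models; the average fraction is the mean over residues.
#'
#' @param ens A `structural_ensemble` with backbone N, CA, C atoms.
#' @param min_run Minimum helical run length (default 4).
#' @return List with `profile` (data frame chain/resid/helix
#'   population) and `average_fraction`.
#' @export
helix_profile <- function(ens, min_run = 4L) {
  nm <- n_models(ens)
  base <- .backbone_dihedrals(ens$atoms, ens$coords[, , 1])
  nres <- nrow(base)
  pop <- rep(0, nres)
  for (m in seq_len(nm)) {
    dh <- .backbone_dihedrals(ens$atoms, ens$coords[, , m])
    hel <- !is.na(dh$phi) & !is.na(dh$psi) &
      dh$phi > -100 & dh$phi < -30 & dh$psi > -80 & dh$psi < -5
    # run-length gate within chains
    for (ch in unique(dh$chain)) {
      sel <- which(dh$chain == ch)
      r <- rle(hel[sel])
      ok <- rep(r$values & r$lengths >= min_run, r$lengths)
      hel[sel] <- ok
    }
    pop <- pop + ens$weights[m] * hel
  }
  list(profile = data.frame(chain = base$chain, resid = base$resid,
                            helix = pop),
       average_fraction = mean(pop))
}

#' Mass-weighted radius of gyration of one model
#'
#' @param ens A `structural_ensemble`.
#' @param model Model index.
#' @return Rg in nm (heavy atoms, mass-weighted).
#' @export
radius_of_gyration <- function(ens, model = 1L) {
  heavy <- ens$atoms$element != "H"
  xyz <- ens$coords[heavy, , model, drop = FALSE][, , 1]
  mass <- .ATOM_MASSES[ens$atoms$element[heavy]]
  mass[is.na(mass)] <- 12.011
  com <- colSums(xyz * mass) / sum(mass)
  sq <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(mass * sq) / sum(mass))
}

#' Two-dimensional free-energy surface over collective variables
#'
#' Bins the weighted ensemble over two per-model collective-variable
#' vectors and reports `F = -kT ln(sum of weights in bin)`, shifted so
#' the minimum is 0; empty bins are `Inf` (unreachable).
#'
#' @param cv_x,cv_y Numeric vectors, one value per model (e.g. helix
#'   fraction and Rg).
#' @param weights Model weights (normalized internally).
#' @param bins Number of bins per axis (>= 4).
#' @param kT Thermal energy (kJ/mol).
#' @param limits Optional list with `x` and `y` range vectors.
#' @return A `free_energy_surface`: list with `F` (matrix, x rows), `x`,
#'   `y` bin centers, `kT`, `minimum` (bin-center coordinates of the
#'   lowest bin) and `flags`.
#' @export
fes_2d <- function(cv_x, cv_y, weights = NULL, bins = 32L, kT = 2.48,
                   limits = NULL) {
  if (bins < 4) stop("need at least 4 bins per axis")
  n <- length(cv_x)
  stopifnot(length(cv_y) == n)
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- weights / sum(weights)
  lim_x <- if (is.null(limits)) range(cv_x) else limits$x
  lim_y <- if (is.null(limits)) range(cv_y) else limits$y
  bx <- seq(lim_x[1], lim_x[2], length.out = bins + 1)
  by <- seq(lim_y[1], lim_y[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(cv_x, bx, rightmost.closed = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(cv_y, by, rightmost.closed = TRUE), 1), bins)
  W <- matrix(0, bins, bins)
  for (i in seq_len(n)) W[ix[i], iy[i]] <- W[ix[i], iy[i]] + weights[i]
  F_ <- -kT * log(W)
  F_ <- F_ - min(F_)
  flags <- character(0)
  if (sum(W > 0) <= 1) flags <- "degenerate_single_bin"
  xc <- (bx[-1] + bx[-length(bx)]) / 2
  yc <- (by[-1] + by[-length(by)]) / 2
  mn <- which(F_ == 0, arr.ind = TRUE)[1, ]
  structure(list(F = F_, x = xc, y = yc, kT = kT,
                 minimum = c(x = xc[mn[1]], y = yc[mn[2]]),
                 flags = flags),
            class = "free_energy_surface")
}
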