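# Synthetic-data generators. Each generator seeds R's Mersenne-Twister
# stream explicitly (documented RNG, inversion normals) so identical
# recipes and seeds give bit-identical output, and each produces data in
# the exact shape its consumer module reads.

.seed_rng <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
}

#' Simulate an alignment (and true ancestral sequences) on a tree
#'
#' Draws the root sequence from the model's equilibrium frequencies,
#' assigns each site a rate class (discrete gamma plus the invariant
#' class), evolves residues down every branch with the corresponding
#' transition matrices, and optionally applies a deletion-only indel
#' process (Poisson events per branch, geometric run lengths with mean
#' 2) whose gaps propagate to all descendants.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param model A `substitution_model`.
#' @param length Number of sites.
#' @param indel_rate Expected deletion events per site per unit branch
#'   length (0 disables).
#' @param seed Integer seed.
#' @return List with `alignment` (an `aa_alignment` of the tips),
#'   `node_sequences` (named character vector for every node, gaps
#'   applied) and `rates` (per-site rate-class index).
#' @export
simulate_msa <- function(tree, model, length = 200L, indel_rate = 0,
                         seed = 1L) {
  .check_tree(tree)
  .seed_rng(seed)
  S <- as.integer(length)
  rc <- .rate_classes(model)
  eig <- .model_eigen(model)
  classes <- sample.int(length(rc$rates), S, replace = TRUE,
                        prob = rc$probs)
  tre <- stats::reorder(tree, "postorder")
  ntip <- length(tre$tip.label)
  nnode <- ntip + tre$Nnode
  root <- ntip + 1L
  seqs <- matrix(NA_integer_, nnode, S)
  present <- matrix(TRUE, nnode, S)
  seqs[root, ] <- sample.int(20, S, replace = TRUE, prob = model$freqs)
  edge <- tre$edge
  for (e in rev(seq_len(nrow(edge)))) {  # preorder
    par <- edge[e, 1]; chi <- edge[e, 2]; t <- tre$edge.length[e]
    Ps <- lapply(rc$rates, function(r) transition_matrix(model, t * r, eig))
    child <- integer(S)
    for (c_i in seq_along(rc$rates)) {
      sel <- which(classes == c_i)
      if (!length(sel)) next
      P <- Ps[[c_i]]
      child[sel] <- vapply(seqs[par, sel], function(a)
        sample.int(20, 1, prob = P[a, ]), 0L)
    }
    seqs[chi, ] <- child
    present[chi, ] <- present[par, ]
    if (indel_rate > 0) {
      n_ev <- stats::rpois(1, indel_rate * t * S)
      if (n_ev > 0) {
        starts <- sample.int(S, n_ev, replace = TRUE)
        lens <- stats::rgeom(n_ev, 0.5) + 1L  # mean 2
        for (k in seq_len(n_ev)) {
          cols <- starts[k]:min(S, starts[k] + lens[k] - 1L)
          present[chi, cols] <- FALSE
        }
      }
    }
  }
  labs <- c(tre$tip.label, if (!is.null(tre$node.label)) tre$node.label
            else as.character((ntip + 1L):nnode))
  to_string <- function(i) {
    ch <- AA_ALPHABET[seqs[i, ]]
    ch[!present[i, ]] <- "-"
    paste(ch, collapse = "")
  }
  node_sequences <- stats::setNames(
    vapply(seq_len(nnode), to_string, ""), labs)
  aln <- aa_alignment(node_sequences[seq_len(ntip)])
  list(alignment = aln, node_sequences = node_sequences,
       rates = classes)
}

#' Simulate an ITC titration
#'
#' [predict_heats()] plus i.i.d. Gaussian heat noise.
#'
#' @inheritParams predict_heats
#' @param noise_sd Heat noise SD (ucal); `noise_frac` instead scales it
#'   to the predicted heat range (e.g. 0.02 for 2% peak-scale noise).
#' @param noise_frac Optional fractional noise overriding `noise_sd`.
#' @param seed Integer seed.
#' @return List with `heats` (ucal) and `schedule`.
#' @export
simulate_itc <- function(n, Kd_uM, dH_kcal, schedule = titration_schedule(),
                         offset = 0, noise_sd = 0, noise_frac = NULL,
                         seed = 1L) {
  .seed_rng(seed)
  mu <- predict_heats(n, Kd_uM, dH_kcal, offset, schedule)
  if (!is.null(noise_frac)) noise_sd <- noise_frac * diff(range(mu))
  heats <- mu + stats::rnorm(length(mu), 0, noise_sd)
  list(heats = heats, schedule = schedule)
}

#' Simulate a two-state denaturation curve
#'
#' [two_state_curve()] plus i.i.d. Gaussian signal noise.
#'
#' @inheritParams two_state_curve
#' @param noise_sd Signal noise SD; `noise_frac` scales to the signal
#'   range instead.
#' @param noise_frac Optional fractional noise overriding `noise_sd`.
#' @param seed Integer seed.
#' @return List with `x`, `y`, `mode`, `temperature_K`.
#' @export
simulate_denaturation <- function(params, x, mode = c("urea", "tfe"),
                                  temperature_K = NULL, noise_sd = 0,
                                  noise_frac = NULL, seed = 1L) {
  mode <- match.arg(mode)
  .seed_rng(seed)
  mu <- two_state_curve(params, x, mode, temperature_K)
  if (!is.null(noise_frac)) noise_sd <- noise_frac * diff(range(mu))
  list(x = x, y = mu + stats::rnorm(length(mu), 0, noise_sd),
       mode = mode,
       temperature_K = if (is.null(temperature_K)) {
         if (mode == "urea") 283.15 else 298.15
       } else temperature_K)
}

# ideal backbone geometry (Engh-Huber style), lengths in nm
.BB_GEOM <- list(n_ca = 0.1458, ca_c = 0.1525, c_n = 0.1329,
                 c_o = 0.1231,
                 ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                 ang_c_n_ca = 121.7, ang_ca_c_o = 120.8)

# build one chain's backbone (N, CA, C, O per residue) from phi/psi
.build_backbone <- function(phi, psi) {
  g <- .BB_GEOM
  nres <- length(phi)
  coords <- matrix(NA_real_, nres * 4L, 3)
  # seed atoms for residue 1
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- .place_atom(c(0, 1, 0), N1, CA1, g$ca_c, g$ang_n_ca_c, psi[1] - 180)
  # (the pre-N direction is arbitrary; psi of residue 1 sets C placement)
  coords[1, ] <- N1; coords[2, ] <- CA1; coords[3, ] <- C1
  prev <- list(N = N1, CA = CA1, C = C1)
  for (r in 2:nres) {
    Ni <- .place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n,
                      psi[r - 1])
    CAi <- .place_atom(prev$CA, prev$C, Ni, g$n_ca, g$ang_c_n_ca, 180)
    Ci <- .place_atom(prev$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[r])
    base <- (r - 1L) * 4L
    coords[base + 1L, ] <- Ni
    coords[base + 2L, ] <- CAi
    coords[base + 3L, ] <- Ci
    prev <- list(N = Ni, CA = CAi, C = Ci)
  }
  # carbonyl oxygens: in the peptide plane, trans to the next N
  for (r in seq_len(nres)) {
    base <- (r - 1L) * 4L
    if (r < nres) {
      Nn <- coords[r * 4L + 1L, ]
      O <- .place_atom(Nn, coords[base + 2L, ], coords[base + 3L, ],
                       g$c_o, g$ang_ca_c_o, 180)
    } else {
      O <- .place_atom(coords[base + 1L, ], coords[base + 2L, ],
                       coords[base + 3L, ], g$c_o, g$ang_ca_c_o,
                       psi[r] + 180)
    }
    coords[base + 4L, ] <- O
  }
  coords
}

#' Simulate a two-chain helical-bundle structural ensemble
#'
#' Builds each model residue-by-residue from backbone dihedrals: with
#' probability `helix_prob[r]` a residue takes ideal alpha-helical
#' dihedrals (`phi = -57`, `psi = -47`), otherwise coil dihedrals drawn
#' from the extended region (`phi ~ U(-180, -60)`,
#' `psi ~ U(120, 180)`). Helicity is sampled cooperatively: each
#' maximal window of constant `helix_prob` folds or unfolds as a unit
#' per model (two-state helix-coil), so the realized per-residue helix
#' population equals the nominal probability for windows of length
#' >= 4. The second chain is rigidly placed so a chosen
#' residue pair sits at a controllable distance (known interface
#' contact), and isotropic Gaussian jitter of SD `noise_nm` is applied
#' to every atom.
#'
#' @param n_models Number of models.
#' @param chain_lengths Named integer vector of residues per chain,
#'   e.g. `c(A = 30, B = 25)`.
#' @param helix_prob Per-residue helix probability: a single number, or
#'   a list of per-chain vectors.
#' @param noise_nm Coordinate jitter SD (nm).
#' @param contact_pair Optional list `list(chain_a=, res_a=, chain_b=,
#'   res_b=, distance_nm=)` pinning a CA-CA inter-chain distance.
#' @param separation_nm Inter-chain CA-CA offset used when
#'   `contact_pair` is NULL (default 1.2).
#' @param domains Chain-to-domain map (default chains themselves).
#' @param seed Integer seed.
#' @return A `structural_ensemble`.
#' @export
simulate_ensemble <- function(n_models = 100L,
                              chain_lengths = c(A = 30L, B = 25L),
                              helix_prob = 0.6, noise_nm = 0.02,
                              contact_pair = NULL, separation_nm = 1.2,
                              domains = NULL, seed = 1L) {
  .seed_rng(seed)
  chains <- names(chain_lengths)
  if (is.null(chains)) {
    chains <- LETTERS[seq_along(chain_lengths)]
    names(chain_lengths) <- chains
  }
  if (!is.list(helix_prob))
    helix_prob <- lapply(chain_lengths, function(n) rep(helix_prob, n))
  atoms <- do.call(rbind, lapply(chains, function(ch) {
    n <- chain_lengths[[ch]]
    data.frame(name = rep(c("N", "CA", "C", "O"), n),
               element = rep(c("N", "C", "C", "O"), n),
               resid = rep(seq_len(n), each = 4L),
               resname = "ALA", chain = ch,
               stringsAsFactors = FALSE)
  }))
  natom <- nrow(atoms)
  coords <- array(NA_real_, c(natom, 3, n_models))
  for (m in seq_len(n_models)) {
    offset_row <- 0L
    chain_xyz <- list()
    for (ch in chains) {
      n <- chain_lengths[[ch]]
      # cooperative (all-or-none) helicity per constant-probability
      # window: each maximal run of equal helix_prob folds as a unit,
      # so the realized population matches the nominal probability
      # despite the run-length >= 4 assignment rule
      pr <- helix_prob[[ch]]
      r <- rle(pr)
      hel <- rep(stats::runif(length(r$lengths)) < r$values, r$lengths)
      phi <- ifelse(hel, -57, stats::runif(n, -180, -60))
      psi <- ifelse(hel, -47, stats::runif(n, 120, 180))
      chain_xyz[[ch]] <- .build_backbone(phi, psi)
    }
    if (length(chains) >= 2) {
      # rigidly place chain 2: align a target CA pair along +x
      a <- chain_xyz[[1]]
      b <- chain_xyz[[2]]
      if (!is.null(contact_pair)) {
        ia <- (contact_pair$res_a - 1L) * 4L + 2L
        ib <- (contact_pair$res_b - 1L) * 4L + 2L
        d <- contact_pair$distance_nm
      } else {
        ia <- (chain_lengths[[1]] %/% 2) * 4L + 2L
        ib <- (chain_lengths[[2]] %/% 2) * 4L + 2L
        d <- separation_nm
      }
      target <- a[ia, ] + c(d, 0, 0)
      b <- sweep(b, 2, target - b[ib, ], "+")
      chain_xyz[[2]] <- b
    }
    xyz <- do.call(rbind, chain_xyz)
    xyz <- xyz + stats::rnorm(length(xyz), 0, noise_nm)
    coords[, , m] <- xyz
  }
  structural_ensemble(atoms, coords, domains = domains)
}
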