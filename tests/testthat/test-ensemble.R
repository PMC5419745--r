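make_two_atom_ens <- function(d_nm, n = 2, w = NULL) {
  at <- data.frame(name = c("CA", "CA"), element = c("C", "C"),
                   resid = c(1L, 1L), resname = "ALA",
                   chain = c("A", "B"), stringsAsFactors = FALSE)
  co <- array(rep(c(0, 0, 0, d_nm, 0, 0), n), c(2, 3, n))
  structural_ensemble(at, co, weights = w,
                      domains = c(A = "CID", B = "NCBD"))
}

test_that("reweighting follows exp(+B/kT) with shift invariance", {
  expect_equal(reweight(c(5, 5, 5)), rep(1 / 3, 3))
  kt <- 2.48
  expect_equal(reweight(c(0, kt * log(2)), kt), c(1 / 3, 2 / 3))
  w <- reweight(c(1, 4, 2), kt)
  expect_equal(reweight(c(1, 4, 2) + 100, kt), w)
  # huge biases do not overflow
  expect_false(anyNA(reweight(c(1e5, 1e5 + 1), kt)))
  expect_error(reweight(c(1, Inf)), "finite")
})

test_that("contact populations follow the strict cutoff and weights", {
  expect_equal(contact_map(make_two_atom_ens(0.45))$population[1, 2], 1)
  # exactly at the cutoff: no contact
  expect_equal(contact_map(make_two_atom_ens(0.5))$population[1, 2], 0)
  # weighted: contact only in model 2 with weight 0.75
  at <- data.frame(name = c("CA", "CA"), element = c("C", "C"),
                   resid = c(1L, 1L), resname = "ALA",
                   chain = c("A", "B"), stringsAsFactors = FALSE)
  co <- array(c(0, 0, 0, 2, 0, 0,   0, 0, 0, 0.3, 0, 0), c(2, 3, 2))
  ens <- structural_ensemble(at, co, weights = c(0.25, 0.75),
                             domains = c(A = "CID", B = "NCBD"))
  expect_equal(contact_map(ens)$population[1, 2], 0.75)
  # contact/helix populations are convex combinations over models
  expect_true(all(contact_map(ens)$population >= 0 &
                    contact_map(ens)$population <= 1))
})

test_that("interface summaries count, average and normalize", {
  cmap <- structure(list(
    population = matrix(c(0, 0.04, 0.06, 0.5,
                          0.04, 0, 0, 0,
                          0.06, 0, 0, 0,
                          0.5, 0, 0, 0), 4, 4),
    residues = data.frame(chain = c("A", "B", "B", "B"),
                          resid = c(1L, 1L, 2L, 3L),
                          domain = c("CID", "NCBD", "NCBD", "NCBD")),
    inter_domain = outer(c("CID", "NCBD", "NCBD", "NCBD"),
                         c("CID", "NCBD", "NCBD", "NCBD"), `!=`)),
    class = "contact_map")
  s <- interface_summary(cmap, 0.05)
  expect_equal(s$count, 2L)
  expect_equal(s$average_population, mean(c(0.06, 0.5)))
  # residue A1 participates in both contacts -> normalized 1
  expect_equal(s$per_residue$normalized[1], 1)
  expect_equal(s$per_residue$normalized[2], 0)
  sres <- interface_summary(cmap, 0.05, mode = "residues")
  expect_equal(sres$count, 3L)  # A1, B2, B3
  none <- interface_summary(cmap, 0.9)
  expect_equal(none$count, 0L)
  expect_null(none$average_population)
})

test_that("RMSF vanishes for duplicated or rigidly rotated models", {
  ens <- simulate_ensemble(n_models = 2, chain_lengths = c(A = 10L),
                           helix_prob = 1, noise_nm = 0, seed = 1)
  expect_equal(max(rmsf(ens)$rmsf), 0, tolerance = 1e-9)
  # rigid rotation + translation of model 2: still zero after fitting
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ens$coords[, , 2] <- sweep(ens$coords[, , 2] %*% Rz, 2, c(1, -2, 3), "+")
  expect_equal(max(rmsf(ens)$rmsf), 0, tolerance = 1e-9)
  expect_error(rmsf(simulate_ensemble(n_models = 1, seed = 1)), "2 models")
})

test_that("RMSF matches the sqrt(3) sigma closed form for isotropic jitter", {
  # a long chain keeps the variance absorbed by the 6 fitted
  # superposition degrees of freedom negligible (factor ~ 1 - 6/(3n))
  sigma <- 0.05
  ens <- simulate_ensemble(n_models = 500, chain_lengths = c(A = 60L),
                           helix_prob = 1, noise_nm = sigma, seed = 7)
  r <- rmsf(ens)
  expect_equal(mean(r$rmsf), sqrt(3) * sigma, tolerance = 0.05)
})

test_that("helix assignment needs the dihedral window and a run of 4", {
  ens <- simulate_ensemble(n_models = 10, chain_lengths = c(A = 12L),
                           helix_prob = 1, noise_nm = 0, seed = 2)
  hp <- helix_profile(ens)
  expect_equal(hp$profile$helix[2:11], rep(1, 10))  # termini lack phi/psi
  coil <- simulate_ensemble(n_models = 10, chain_lengths = c(A = 12L),
                            helix_prob = 0, noise_nm = 0, seed = 3)
  expect_equal(max(helix_profile(coil)$profile$helix), 0)
  # generator recovery at 60% cooperative helicity
  win <- simulate_ensemble(n_models = 1000, chain_lengths = c(A = 30L),
                           helix_prob = 0.6, noise_nm = 0.002, seed = 6)
  hpw <- helix_profile(win)
  expect_equal(mean(hpw$profile$helix[5:26]), 0.6, tolerance = 0.05)
})

test_that("Rg matches hand formulas and observables are rigid-motion invariant", {
  expect_equal(radius_of_gyration(make_two_atom_ens(1)), 0.5)
  ens <- simulate_ensemble(n_models = 5, chain_lengths = c(A = 8L, B = 6L),
                           helix_prob = 0.7, noise_nm = 0.01, seed = 4,
                           domains = c(A = "CID", B = "NCBD"))
  rot <- ens
  th <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  for (m in 1:5)
    rot$coords[, , m] <- sweep(ens$coords[, , m] %*% Rz, 2, c(3, 1, -2), "+")
  expect_equal(contact_map(rot)$population, contact_map(ens)$population,
               tolerance = 1e-9)
  expect_equal(helix_profile(rot)$profile$helix,
               helix_profile(ens)$profile$helix)
  expect_equal(radius_of_gyration(rot, 3), radius_of_gyration(ens, 3),
               tolerance = 1e-9)
  expect_equal(rmsf(rot)$rmsf, rmsf(ens)$rmsf, tolerance = 1e-7)
})

test_that("free-energy surfaces are min-shifted and weight-consistent", {
  set.seed(5)
  cvx <- stats::runif(200)
  cvy <- stats::runif(200)
  f <- fes_2d(cvx, cvy, bins = 6, kT = 2.48)
  expect_equal(min(f$F), 0)
  # bin-to-bin differences equal -kT log weight ratios exactly
  w <- rep(1 / 200, 200)
  bx <- seq(min(cvx), max(cvx), length.out = 7)
  ix <- pmin(pmax(findInterval(cvx, bx, rightmost.closed = TRUE), 1), 6)
  by <- seq(min(cvy), max(cvy), length.out = 7)
  iy <- pmin(pmax(findInterval(cvy, by, rightmost.closed = TRUE), 1), 6)
  W <- matrix(0, 6, 6)
  for (i in 1:200) W[ix[i], iy[i]] <- W[ix[i], iy[i]] + w[i]
  filled <- which(W > 0, arr.ind = TRUE)
  a <- filled[1, ]; b <- filled[nrow(filled), ]
  expect_equal(f$F[a[1], a[2]] - f$F[b[1], b[2]],
               -2.48 * log(W[a[1], a[2]] / W[b[1], b[2]]),
               tolerance = 1e-9)
  expect_error(fes_2d(cvx, cvy, bins = 3), "4 bins")
  dg <- fes_2d(rep(0.5, 10), rep(0.5, 10), bins = 4)
  expect_equal(dg$flags, "degenerate_single_bin")
})

test_that("multi-model PDB round trip preserves the ensemble", {
  ens <- simulate_ensemble(n_models = 3, chain_lengths = c(A = 6L, B = 5L),
                           helix_prob = 0.8, noise_nm = 0.01, seed = 9,
                           domains = c(A = "CID", B = "NCBD"))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, pdb)
  back <- read_ensemble_pdb(pdb, domains = c(A = "CID", B = "NCBD"))
  expect_equal(n_models(back), 3)
  expect_equal(back$atoms$name, ens$atoms$name)
  expect_equal(back$atoms$chain, ens$atoms$chain)
  expect_equal(back$coords, ens$coords, tolerance = 1e-4)  # 0.001 A files
  # bias column converts to weights on read
  back2 <- read_ensemble_pdb(pdb, bias = c(0, 0, 2.48 * log(2)), kT = 2.48)
  expect_equal(back2$weights, c(0.25, 0.25, 0.5))
})
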