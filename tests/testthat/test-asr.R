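test_that("single-leaf and zero-branch likelihoods reduce to closed forms", {
  model <- fix_jtt(alpha = Inf, k = 1)
  tree1 <- ape::read.tree(text = "(A:0.0):0;")  # single leaf under root
  aln1 <- aa_alignment(c(A = "W"))
  ll <- site_log_likelihood(aln1, tree1, model)
  expect_equal(ll, log(model$freqs[match("W", AA_ALPHABET)]),
               ignore_attr = TRUE)
  # all branch lengths 0: identical residues -> log pi; differing -> -Inf
  tree0 <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  same <- aa_alignment(c(A = "K", B = "K", C = "K"))
  diff_ <- aa_alignment(c(A = "K", B = "R", C = "K"))
  expect_equal(site_log_likelihood(same, tree0, model),
               log(model$freqs[match("K", AA_ALPHABET)]),
               ignore_attr = TRUE)
  expect_equal(site_log_likelihood(diff_, tree0, model), -Inf)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(401)
  shapes <- c("(A:%f,B:%f);",
              "((A:%f,B:%f):%f,C:%f);",
              "(((A:%f,B:%f):%f,C:%f):%f,D:%f);",
              "((A:%f,B:%f):%f,(C:%f,D:%f):%f);")
  n_edges <- c(2, 4, 6, 6)
  for (i in 1:50) {
    si <- (i - 1) %% 4 + 1
    bl <- stats::rexp(n_edges[si], 3)
    tree <- ape::read.tree(text = do.call(sprintf,
                                          c(shapes[si], as.list(bl))))
    model <- if (i %% 3 == 0) random_model(alpha = 0.7, k = 2) else
      random_model()
    tips <- tree$tip.label
    chars <- sample(c(AA_ALPHABET, "-"), length(tips), replace = TRUE,
                    prob = c(rep(1, 20), 3))
    names(chars) <- tips
    aln <- aa_alignment(vapply(tips, function(t) chars[[t]], ""))
    mine <- site_log_likelihood(aln, tree, model)
    brute <- log(brute_site_likelihood(tree, model, chars))
    expect_equal(mine, brute, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("marginal posteriors match enumeration and normalize", {
  set.seed(402)
  tree <- fix_tree3()
  for (rep in 1:5) {
    model <- random_model(alpha = 1.2, k = 3, p_inv = 0.1)
    chars <- stats::setNames(sample(AA_ALPHABET, 3, replace = TRUE),
                             c("A", "B", "C"))
    aln <- aa_alignment(chars)
    post <- marginal_ancestral(aln, tree, model, "n1")
    expect_equal(rowSums(post$probs), rep(1, 1), tolerance = 1e-9)
    expect_equal(post$probs[1, ], brute_marginal(tree, model, chars, "n1"),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(post$ml_prob, max(post$probs[1, ]))
  }
  # long outgoing branches: posterior approaches the prior
  far <- ape::read.tree(text = "((A:50,B:50)n1:50,C:50)root;")
  model <- fix_jtt(alpha = Inf, k = 1)
  p <- marginal_ancestral(aa_alignment(c(A = "W", B = "W", C = "W")),
                          far, model, "n1")
  expect_equal(p$probs[1, ], model$freqs, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_error(marginal_ancestral(fix_aln3(), tree, model, "nope"),
               "not found")
  expect_error(marginal_ancestral(fix_aln3(), tree, model, "A"),
               "internal")
})

test_that("total likelihood agrees with an independent phylogenetics engine", {
  skip_if_not_installed("phangorn")
  tree <- fix_tree3()
  aln <- aa_alignment(c(A = "ARNDW", B = "ARKDW", C = "LRNEW"))
  model <- fix_jtt(alpha = 0.7, k = 4, p_inv = 0.2)
  mine <- sum(site_log_likelihood(aln, tree, model))
  chars <- t(vapply(aln_strings(aln), function(s) strsplit(s, "")[[1]],
                    character(5)))
  pd <- phangorn::phyDat(chars, type = "AA")
  ref <- phangorn::pml(ape::unroot(tree), pd, model = "JTT", k = 4,
                       shape = 0.7, inv = 0.2)$logLik
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("likelihood is invariant to child order and rerooting", {
  model <- fix_jtt(alpha = 0.9, k = 4)
  aln <- aa_alignment(c(A = "ARND", B = "ARKD", C = "LRND"))
  t1 <- ape::read.tree(text = "((A:0.1,B:0.2):0.07,C:0.13);")
  t_swap <- ape::read.tree(text = "(C:0.13,(B:0.2,A:0.1):0.07);")
  t_slide <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,C:0.05);")
  l1 <- site_log_likelihood(aln, t1, model)
  expect_equal(site_log_likelihood(aln, t_swap, model), l1,
               tolerance = 1e-10)
  expect_equal(site_log_likelihood(aln, t_slide, model), l1,
               tolerance = 1e-10)
})

test_that("ML sequence report flags uncertain sites with ordered, tie-broken alternatives", {
  probs <- matrix(0, 3, 20, dimnames = list(NULL, AA_ALPHABET))
  # site 1: the uncertain N-terminal position pattern
  probs[1, c("I", "V", "T", "M")] <- c(0.19, 0.16, 0.15, 0.13)
  probs[1, "A"] <- 1 - sum(probs[1, ])  # 0.37, becomes ML
  probs[2, "W"] <- 1
  probs[3, c("D", "E")] <- 0.5  # exact tie
  post <- structure(list(node = "x", probs = probs,
                         ml_residue = c("A", "W", "D"),
                         ml_prob = c(0.37, 1, 0.5)),
                    class = "ancestral_posterior")
  rep_ <- ml_sequence_with_alternatives(post, threshold = 0.7)
  expect_equal(rep_$flagged, c(1L, 3L))
  expect_equal(rep_$alternatives[["1"]]$residue[1:4],
               c("I", "V", "T", "M"))
  expect_equal(rep_$alternatives[["1"]]$prob[1:4],
               c(0.19, 0.16, 0.15, 0.13))
  # alphabetical tie-break: D wins over E at 0.5/0.5
  expect_equal(substr(rep_$sequence, 3, 3), "D")
  expect_equal(rep_$alternatives[["3"]]$residue[1], "E")
  expect_error(ml_sequence_with_alternatives(post, 0), "threshold")
})

test_that("Fitch indel reconstruction resolves ties toward presence", {
  tree <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)root;")
  aln <- aa_alignment(c(A = "-KX", B = "KK-", C = "KKX", D = "KK-"))
  st <- reconstruct_indels(aln, tree)
  # column 1: gap only in A -> all internal present
  expect_true(all(st[c("root", "ab", "cd"), 1]))
  expect_false(st["A", 1])
  # column 2: no gaps -> everyone present
  expect_true(all(st[, 2]))
  # column 3: X counts as present; gaps in B and D -> root tie -> present
  expect_true(st["root", 3])
  # all-gap column -> absent everywhere
  aln2 <- aa_alignment(c(A = "-", B = "-", C = "-", D = "-"))
  expect_true(all(!reconstruct_indels(aln2, tree)))
})

test_that("gamma shape is recovered from simulated data", {
  set.seed(403)
  tree <- random_tree(8, mean_bl = 0.2)
  gen <- fix_jtt(alpha = 0.5, k = 4)
  sim <- simulate_msa(tree, gen, length = 1000, seed = 17)
  fit <- optimize_shape(sim$alignment, tree, fix_jtt(alpha = 1, k = 4))
  expect_lt(abs(fit$alpha - 0.5) / 0.5, 0.25)
  # optimality: fitted alpha beats halving/doubling
  ll_at <- function(a) sum(site_log_likelihood(
    sim$alignment, tree, fix_jtt(alpha = a, k = 4)))
  expect_gte(attr(fit, "logLik"), ll_at(fit$alpha / 2))
  expect_gte(attr(fit, "logLik"), ll_at(fit$alpha * 2))
  expect_error(optimize_shape(sim$alignment, tree, fix_jtt(k = 1)),
               "k >= 2")
})

test_that("posterior confidence in the true ancestor grows as branches shrink", {
  set.seed(404)
  base <- ape::rtree(12, rooted = TRUE)
  model <- fix_jtt(alpha = Inf, k = 1)
  mean_p <- vapply(c(0.4, 0.1, 0.02), function(bl) {
    tr <- base
    tr$edge.length <- rep(bl, nrow(tr$edge))
    tr$node.label <- paste0("nd", seq_len(tr$Nnode))
    sim <- simulate_msa(tr, model, length = 120, seed = 71)
    post <- marginal_ancestral(sim$alignment, tr, model, "nd1")
    truth <- match(strsplit(sim$node_sequences[["nd1"]], "")[[1]],
                   AA_ALPHABET)
    mean(post$probs[cbind(seq_along(truth), truth)])
  }, 0)
  expect_true(all(diff(mean_p) > 0))
})
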