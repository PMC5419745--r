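# Shared fixtures and independent oracles for the test suite.

# A random GTR-form amino-acid model (random symmetric S, random freqs).
random_model <- function(alpha = Inf, k = 1L, p_inv = 0) {
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- stats::runif(190, 0.1, 2)
  S <- S + t(S)
  f <- stats::runif(20, 0.2, 1.5)
  substitution_model(S = S, freqs = f / sum(f), alpha = alpha, k = k,
                     p_inv = p_inv)
}

# Exhaustive-enumeration site likelihood: sums the joint probability
# over every assignment of the unobserved nodes. Independent of the
# pruning code path (only transition_matrix is shared plumbing).
brute_site_likelihood <- function(tree, model, chars) {
  tre <- stats::reorder(tree, "postorder")
  ntip <- length(tre$tip.label)
  nnode <- ntip + tre$Nnode
  rc <- idpevo:::.rate_classes(model)
  states <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    idx <- match(chars[[tre$tip.label[i]]], AA_ALPHABET)
    states[[i]] <- if (is.na(idx)) 1:20 else idx  # '-'/'X' free
  }
  for (i in (ntip + 1L):nnode) states[[i]] <- 1:20
  combos <- as.matrix(expand.grid(states))
  root <- ntip + 1L
  total <- 0
  for (c_i in seq_along(rc$rates)) {
    prob <- model$freqs[combos[, root]]
    for (e in seq_len(nrow(tre$edge))) {
      Pe <- transition_matrix(model, tre$edge.length[e] * rc$rates[c_i])
      prob <- prob * Pe[cbind(combos[, tre$edge[e, 1]],
                              combos[, tre$edge[e, 2]])]
    }
    total <- total + rc$probs[c_i] * sum(prob)
  }
  total
}

# Enumeration marginal posterior at an internal node (single site).
brute_marginal <- function(tree, model, chars, node_label) {
  tre <- stats::reorder(tree, "postorder")
  ntip <- length(tre$tip.label)
  nn <- idpevo:::.node_number(tre, node_label)
  rc <- idpevo:::.rate_classes(model)
  states <- vector("list", ntip + tre$Nnode)
  for (i in seq_len(ntip)) {
    idx <- match(chars[[tre$tip.label[i]]], AA_ALPHABET)
    states[[i]] <- if (is.na(idx)) 1:20 else idx
  }
  for (i in (ntip + 1L):(ntip + tre$Nnode)) states[[i]] <- 1:20
  combos <- as.matrix(expand.grid(states))
  root <- ntip + 1L
  post <- numeric(20)
  for (c_i in seq_along(rc$rates)) {
    prob <- model$freqs[combos[, root]]
    for (e in seq_len(nrow(tre$edge))) {
      Pe <- transition_matrix(model, tre$edge.length[e] * rc$rates[c_i])
      prob <- prob * Pe[cbind(combos[, tre$edge[e, 1]],
                              combos[, tre$edge[e, 2]])]
    }
    post <- post + rc$probs[c_i] *
      vapply(1:20, function(s) sum(prob[combos[, nn] == s]), 0)
  }
  post / sum(post)
}

# Small fixed fixtures used across files
fix_tree3 <- function() ape::read.tree(
  text = "((A:0.1,B:0.3)n1:0.2,C:0.4)root;")

fix_aln3 <- function() aa_alignment(c(A = "AR", B = "AK", C = "LR"))

fix_jtt <- function(...) substitution_model("jtt", ...)

# random rooted tree with n tips and exponential branch lengths
random_tree <- function(n, mean_bl = 0.3) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_bl)
  tr
}

# deterministic denaturation baseline set used in several tests
denat_params <- function(midpoint = 4.4, m = 0.67) {
  c(midpoint = midpoint, m = m, a_N = -20, b_N = 0.2,
    a_D = -2, b_D = 0.05)
}
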