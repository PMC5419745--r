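# Maximum-likelihood ancestral sequence reconstruction on a fixed rooted
# tree. Residue likelihoods use Felsenstein's pruning algorithm under a
# GTR-form amino-acid model with discrete-gamma (+ invariant) rate
# classes; gaps and masked residues are missing data. Indel placement is
# a separate binary Fitch-parsimony pass.

# Rate classes: k gamma categories each with probability (1-p_inv)/k,
# rescaled by 1/(1-p_inv) so the overall expected rate stays 1, plus an
# invariant class (rate 0) with probability p_inv.
.rate_classes <- function(model) {
  g <- discrete_gamma_rates(model$alpha, model$k)
  if (model$p_inv > 0) {
    list(rates = c(g / (1 - model$p_inv), 0),
         probs = c(rep((1 - model$p_inv) / model$k, model$k), model$p_inv))
  } else {
    list(rates = g, probs = rep(1 / model$k, model$k))
  }
}

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be nonnegative")
  tree
}

# Shared pre-computation: postorder edges, leaf conditionals, transition
# matrices per edge and rate class.
.asr_prep <- function(aln, tree, model) {
  .check_tree(tree)
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(aln$seqs))
  if (length(missing))
    stop("alignment lacks rows for tree leaves: ",
         paste(missing, collapse = " "))
  S <- ncol(aln$seqs)
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  tre <- stats::reorder(tree, "postorder")
  eig <- .model_eigen(model)
  rc <- .rate_classes(model)
  # leaf conditionals: 20 x S, missing data ('-'/'X') = 1
  leafL <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    chars <- aln$seqs[tips[i], ]
    L <- matrix(0, 20, S)
    idx <- match(chars, AA_ALPHABET)
    obs <- !is.na(idx)
    L[cbind(idx[obs], which(obs))] <- 1
    L[, !obs] <- 1
    leafL[[i]] <- L
  }
  Ps <- lapply(rc$rates, function(r)
    lapply(tre$edge.length, function(t) transition_matrix(model, t * r, eig)))
  list(tree = tre, ntip = ntip, nnode = nnode, S = S, leafL = leafL,
       Ps = Ps, rc = rc, pi = model$freqs)
}

# Full pruning over all rate classes. Node conditionals are rescaled by
# their per-site column maximum once all children are absorbed, with the
# accumulated log scale tracked per node (protects deep trees from
# underflow). Returns, per rate class, the conditionals L, the root's
# per-site log scale, and the full scale matrix (needed by the downward
# pass).
.prune_all <- function(prep) {
  edge <- prep$tree$edge
  out <- vector("list", length(prep$rc$rates))
  for (c_i in seq_along(prep$rc$rates)) {
    P <- prep$Ps[[c_i]]
    L <- vector("list", prep$nnode)
    L[seq_len(prep$ntip)] <- prep$leafL
    scale_mat <- matrix(0, prep$nnode, prep$S)
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1]; chi <- edge[e, 2]
      msg <- P[[e]] %*% L[[chi]]
      L[[par]] <- if (is.null(L[[par]])) msg else L[[par]] * msg
      scale_mat[par, ] <- scale_mat[par, ] + scale_mat[chi, ]
      if (e == nrow(edge) || edge[e + 1, 1] != par) {
        mx <- apply(L[[par]], 2, max)
        mx[mx <= 0] <- .Machine$double.xmin
        L[[par]] <- sweep(L[[par]], 2, mx, "/")
        scale_mat[par, ] <- scale_mat[par, ] + log(mx)
      }
    }
    root <- prep$ntip + 1L
    out[[c_i]] <- list(L = L, logscale = scale_mat[root, ],
                       scale_mat = scale_mat)
  }
  out
}

#' Per-site log-likelihood under the pruning algorithm
#'
#' Computes `log sum_c p_c sum_x pi_x L_root(x | rate_c)` per alignment
#' column, where gaps (`-`) and masked residues (`X`) contribute all-ones
#' conditional vectors (missing data) and the invariant-sites class, if
#' present, enters as an extra rate-0 category.
#'
#' @param aln An `aa_alignment`.
#' @param tree Rooted `phylo` tree whose tip labels match alignment rows.
#' @param model A `substitution_model`.
#' @return Numeric vector of per-site log-likelihoods.
#' @export
site_log_likelihood <- function(aln, tree, model) {
  prep <- .asr_prep(aln, tree, model)
  pr <- .prune_all(prep)
  root <- prep$ntip + 1L
  per_class <- vapply(seq_along(pr), function(c_i) {
    lik <- colSums(prep$pi * pr[[c_i]]$L[[root]])
    log(lik) + pr[[c_i]]$logscale
  }, numeric(prep$S))
  per_class <- matrix(per_class, nrow = prep$S)
  m <- apply(per_class, 1, max)
  w <- sweep(exp(sweep(per_class, 1, m, "-")), 2, prep$rc$probs, "*")
  ifelse(is.finite(m), m + log(rowSums(w)), -Inf)
}

# Downward (root-to-node) messages U for every node, one rate class.
# U[root] = pi; for child v of p across edge e:
#   U_v = t(P_e) %*% (U_p * prod over siblings s of P_s L_s)
.down_messages <- function(prep, pruned, class_idx) {
  edge <- prep$tree$edge
  P <- prep$Ps[[class_idx]]
  L <- pruned[[class_idx]]$L
  U <- vector("list", prep$nnode)
  Uscale <- matrix(0, prep$nnode, prep$S)
  root <- prep$ntip + 1L
  U[[root]] <- matrix(prep$pi, 20, prep$S)
  lifted <- vector("list", nrow(edge))  # P_e %*% L_child per edge
  for (e in seq_len(nrow(edge))) lifted[[e]] <- P[[e]] %*% L[[edge[e, 2]]]
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  # preorder: reverse of postorder parents
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    sib_e <- setdiff(kids[[as.character(par)]], e)
    acc <- U[[par]]
    for (s in sib_e) acc <- acc * lifted[[s]]
    U[[chi]] <- crossprod(P[[e]], acc)
    mx <- apply(U[[chi]], 2, max)
    mx[mx <= 0] <- .Machine$double.xmin
    U[[chi]] <- sweep(U[[chi]], 2, mx, "/")
    Uscale[chi, ] <- Uscale[par, ] + log(mx)
    # add scaling carried by sibling conditionals
    for (s in sib_e)
      Uscale[chi, ] <- Uscale[chi, ] +
        pruned[[class_idx]]$scale_mat[edge[s, 2], ]
  }
  list(U = U, Uscale = Uscale)
}

.node_number <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.character(node)) {
    labs <- c(tree$tip.label, tree$node.label)
    idx <- match(node, labs)
    if (is.na(idx)) stop("node '", node, "' not found in tree")
    return(idx)
  }
  node <- as.integer(node)
  if (node < 1 || node > ntip + tree$Nnode) stop("node number out of range")
  node
}

#' Marginal ancestral posterior at an internal node
#'
#' Per-site posterior probabilities `P(state at node = s | data)` from
#' combined upward (pruning) and downward conditional-likelihood passes,
#' weighted over rate classes.
#'
#' @inheritParams site_log_likelihood
#' @param node Internal node label (requires `tree$node.label`) or node
#'   number in ape convention.
#' @return An object of class `ancestral_posterior`: list with `node`,
#'   `probs` (sites x 20 matrix), `ml_residue`, `ml_prob`.
#' @export
marginal_ancestral <- function(aln, tree, model, node) {
  prep <- .asr_prep(aln, tree, model)
  nn <- .node_number(prep$tree, node)
  if (nn <= prep$ntip) stop("node must be internal")
  pr <- .prune_all(prep)
  S <- prep$S
  nclass <- length(prep$rc$rates)
  logjoint <- array(NA_real_, c(nclass, 20, S))
  for (c_i in seq_len(nclass)) {
    dm <- .down_messages(prep, pr, c_i)
    J <- dm$U[[nn]] * pr[[c_i]]$L[[nn]]
    lsc <- dm$Uscale[nn, ] + pr[[c_i]]$scale_mat[nn, ]
    logjoint[c_i, , ] <- log(pmax(J, 0)) +
      matrix(lsc, 20, S, byrow = TRUE) + log(prep$rc$probs[c_i])
  }
  post <- matrix(0, S, 20, dimnames = list(NULL, AA_ALPHABET))
  for (s in seq_len(S)) {
    v <- logjoint[, , s, drop = FALSE]
    m <- max(v[is.finite(v)], -Inf)
    w <- exp(v - m)
    w[!is.finite(w)] <- 0
    p <- colSums(matrix(w, nclass, 20))
    post[s, ] <- p / sum(p)
  }
  ml_idx <- apply(post, 1, which.max)
  structure(list(node = node,
                 probs = post,
                 ml_residue = AA_ALPHABET[ml_idx],
                 ml_prob = post[cbind(seq_len(S), ml_idx)]),
            class = "ancestral_posterior")
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  cat(sprintf("ancestral_posterior: node %s, %d sites, mean ML prob %.3f\n",
              as.character(x$node), nrow(x$probs), mean(x$ml_prob)))
  invisible(x)
}

#' ML ancestral sequence with alternative residues at uncertain sites
#'
#' Reports the maximum-probability residue per site; sites whose ML
#' probability falls strictly below `threshold` are flagged and the
#' remaining residues listed in decreasing posterior order (ties broken
#' alphabetically by one-letter code).
#'
#' @param post An `ancestral_posterior`.
#' @param threshold Flagging cutoff in `(0, 1]` (default 0.7).
#' @param min_prob Alternatives with posterior below this are omitted
#'   from the report (default 0.01).
#' @return List with `sequence` (string), `flagged` (integer sites) and
#'   `alternatives` (named list of data frames residue/prob).
#' @export
ml_sequence_with_alternatives <- function(post, threshold = 0.7,
                                          min_prob = 0.01) {
  stopifnot(inherits(post, "ancestral_posterior"))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  S <- nrow(post$probs)
  ml <- character(S)
  flagged <- integer(0)
  alts <- list()
  for (s in seq_len(S)) {
    p <- post$probs[s, ]
    ord <- order(-p, AA_ALPHABET)
    ml[s] <- AA_ALPHABET[ord[1]]
    if (p[ord[1]] < threshold) {
      flagged <- c(flagged, s)
      rest <- ord[-1]
      rest <- rest[p[rest] >= min_prob]
      alts[[as.character(s)]] <- data.frame(
        residue = AA_ALPHABET[rest], prob = unname(p[rest]))
    }
  }
  list(sequence = paste(ml, collapse = ""), flagged = flagged,
       alternatives = alts)
}

#' Fitch-parsimony indel reconstruction
#'
#' Treats each column's residue presence/absence (gap) as a binary
#' character and reconstructs ancestral states by Fitch parsimony; ties
#' at the root (and, during the top-down pass, at internal nodes) are
#' resolved toward "present". Masked residues (`X`) count as present.
#'
#' @param aln An `aa_alignment`.
#' @param tree Rooted `phylo` tree.
#' @return Logical matrix (nodes x columns), `TRUE` = residue present;
#'   rows named by tip labels then node labels/numbers.
#' @export
reconstruct_indels <- function(aln, tree) {
  .check_tree(tree)
  tre <- stats::reorder(tree, "postorder")
  tips <- tre$tip.label
  ntip <- length(tips)
  nnode <- ntip + tre$Nnode
  S <- ncol(aln$seqs)
  # Fitch state sets encoded as integers: 1 = {absent}, 2 = {present},
  # 3 = {absent, present}
  sets <- matrix(0L, nnode, S)
  for (i in seq_len(ntip))
    sets[i, ] <- ifelse(aln$seqs[tips[i], ] == "-", 1L, 2L)
  edge <- tre$edge
  kids <- split(edge[, 2], edge[, 1])
  ord <- unique(edge[, 1])  # postorder parents
  for (par in ord) {
    ch <- kids[[as.character(par)]]
    acc <- sets[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(acc, sets[c2, ])
      uni <- bitwOr(acc, sets[c2, ])
      acc <- ifelse(inter > 0L, inter, uni)
    }
    sets[par, ] <- acc
  }
  final <- matrix(NA, nnode, S)
  root <- ntip + 1L
  final[root, ] <- sets[root, ] != 1L  # tie (3) -> present
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    pstate <- final[par, ]  # TRUE = present(2), FALSE = absent(1)
    pcode <- ifelse(pstate, 2L, 1L)
    keep <- bitwAnd(sets[chi, ], pcode) > 0L
    final[chi, ] <- ifelse(keep, pstate, sets[chi, ] != 1L)
  }
  labs <- c(tips, if (!is.null(tre$node.label)) tre$node.label
            else as.character((ntip + 1L):nnode))
  rownames(final) <- labs
  final
}

#' Optimize the gamma shape (and optionally invariant fraction)
#'
#' Maximizes the total pruning log-likelihood over the discrete-gamma
#' shape `alpha` by bounded one-dimensional search (tolerance 1e-4 on
#' `alpha`), optionally profiling the invariant-sites fraction as well.
#'
#' @inheritParams site_log_likelihood
#' @param optimize_pinv Also fit `p_inv` (alternating search).
#' @param interval Search bounds for `alpha`.
#' @return The input model with fitted `alpha` (and `p_inv`), refreshed
#'   `Q`, plus a `logLik` attribute.
#' @export
optimize_shape <- function(aln, tree, model, optimize_pinv = FALSE,
                           interval = c(0.02, 50)) {
  if (model$k < 2L)
    stop("shape optimization requires k >= 2 rate categories")
  obj <- function(alpha, p_inv) {
    m <- model
    m$alpha <- alpha
    m$p_inv <- p_inv
    ll <- sum(site_log_likelihood(aln, tree, m))
    if (!is.finite(ll)) stop("non-finite likelihood at alpha=", alpha)
    ll
  }
  p_inv <- model$p_inv
  fit <- stats::optimize(function(a) obj(a, p_inv), interval,
                         maximum = TRUE, tol = 1e-4)
  alpha <- fit$maximum
  if (optimize_pinv) {
    for (it in 1:3) {
      fp <- stats::optimize(function(p) obj(alpha, p), c(0, 0.7),
                            maximum = TRUE, tol = 1e-4)
      p_inv <- fp$maximum
      fa <- stats::optimize(function(a) obj(a, p_inv), interval,
                            maximum = TRUE, tol = 1e-4)
      alpha <- fa$maximum
    }
  }
  out <- substitution_model(S = model$S, freqs = model$freqs,
                            alpha = alpha, k = model$k, p_inv = p_inv)
  attr(out, "logLik") <- obj(alpha, p_inv)
  out
}

#' Write a per-site posterior table to CSV
#'
#' @param post An `ancestral_posterior`.
#' @param path Output CSV path.
#' @param threshold Flagging threshold passed through to the report.
#' @export
write_posterior_csv <- function(post, path, threshold = 0.7) {
  df <- data.frame(node = as.character(post$node),
                   site = seq_len(nrow(post$probs)))
  df <- cbind(df, as.data.frame(post$probs))
  df$ml_residue <- post$ml_residue
  df$ml_prob <- post$ml_prob
  df$flagged <- post$ml_prob < threshold
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
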