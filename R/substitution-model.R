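# Amino-acid substitution models in GTR form: a symmetric exchangeability
# matrix S, equilibrium frequencies pi, discrete-gamma rate heterogeneity
# and an optional invariant-sites class.

#' Canonical one-letter amino-acid alphabet used throughout the package
#'
#' Residues are ordered A R N D C Q E G H I L K M F P S T W Y V, the
#' ordering in which the packaged JTT matrices are stored.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# JTT (Jones-Taylor-Thornton 1992) exchangeabilities, lower triangle in
# AA_ALPHABET order, and the accompanying equilibrium frequencies.
.JTT_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101,
  64, 126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15,
  503, 232, 8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59,
  38, 4, 46, 31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209,
  62, 323, 26, 597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26,
  12, 9, 181, 18, 5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201,
  33, 55, 8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21,
  479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24,
  180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17,
  92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112,
  71, 25, 16)

.JTT_FREQS <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

.lower_to_sym <- function(x, n = 20L) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- x
  m + t(m)
}

#' Construct an amino-acid substitution model
#'
#' Bundles a GTR-form exchangeability matrix, equilibrium frequencies,
#' a discrete-gamma shape and category count, and an invariant-sites
#' fraction into a `substitution_model` object.
#'
#' @param name Either `"jtt"` (packaged Jones-Taylor-Thornton matrix) or
#'   `"poisson"` (uniform exchangeabilities and frequencies).
#' @param alpha Gamma shape parameter (> 0). `Inf` means rate homogeneity.
#' @param k Number of discrete gamma categories (>= 1).
#' @param p_inv Proportion of invariant sites, in `[0, 1)`.
#' @param S Optional 20x20 symmetric nonnegative exchangeability matrix
#'   overriding `name`.
#' @param freqs Optional length-20 frequency vector overriding `name`;
#'   must sum to 1.
#' @return An object of class `substitution_model` with elements `S`,
#'   `freqs`, `alpha`, `k`, `p_inv` and the normalized rate matrix `Q`.
#' @examples
#' m <- substitution_model("jtt", alpha = 1, k = 4)
#' range(rowSums(m$Q))  # zero row sums
#' @export
substitution_model <- function(name = c("jtt", "poisson"), alpha = Inf,
                               k = 4L, p_inv = 0, S = NULL, freqs = NULL) {
  if (is.null(S) || is.null(freqs)) {
    name <- match.arg(name)
    if (is.null(S)) {
      S <- if (name == "jtt") .lower_to_sym(.JTT_LOWER) else
        .lower_to_sym(rep(1, 190))
    }
    if (is.null(freqs)) {
      freqs <- if (name == "jtt") .JTT_FREQS else rep(1 / 20, 20)
    }
  }
  stopifnot(is.matrix(S), nrow(S) == 20, ncol(S) == 20)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
    stop("exchangeability matrix S must be symmetric")
  if (any(S < 0)) stop("exchangeability matrix S must be nonnegative")
  freqs <- freqs / sum(freqs)
  if (any(freqs <= 0)) stop("equilibrium frequencies must be positive")
  if (!(alpha > 0)) stop("gamma shape alpha must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)")
  model <- structure(
    list(S = S, freqs = freqs, alpha = alpha, k = k, p_inv = p_inv),
    class = "substitution_model")
  model$Q <- build_rate_matrix(model)
  model
}

#' Build the normalized instantaneous rate matrix Q
#'
#' Assembles `Q[i, j] = S[i, j] * pi[j]` for `i != j`, sets the diagonal
#' for zero row sums, and rescales so the expected substitution rate at
#' equilibrium, `-sum(pi * diag(Q))`, equals 1 (branch lengths are then
#' expected substitutions per site).
#'
#' @param model A `substitution_model` (the `Q` element is ignored).
#' @return A 20x20 rate matrix with rows/columns named by [AA_ALPHABET].
#' @export
build_rate_matrix <- function(model) {
  S <- model$S
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
    stop("exchangeability matrix S must be symmetric")
  pi <- model$freqs / sum(model$freqs)
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("degenerate model: zero expected rate")
  Q <- Q / rate
  dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
  Q
}

#' Discrete-gamma category rates
#'
#' Mean rates of `k` equal-probability categories of a Gamma(alpha,
#' alpha) distribution (mean 1), computed from incomplete-gamma
#' integrals so the probability-weighted mean is exactly 1.
#'
#' @param alpha Shape parameter (> 0); `Inf` gives all-ones.
#' @param k Number of categories.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  k <- as.integer(k)
  if (k == 1L || is.infinite(alpha)) return(rep(1, k))
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  # mean of the gamma density over (a, b]: alpha/rate * (F_{a+1}(b)-F_{a+1}(a))
  upper <- stats::pgamma(c(q, Inf), shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(c(0, q), shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

# Spectral decomposition of the reversible Q for fast transition matrices.
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric; cache its eigen
# system so P(t) = diag(1/sqrt(pi)) U exp(L t) U' diag(sqrt(pi)).
.model_eigen <- function(model) {
  pi <- model$freqs
  sp <- sqrt(pi)
  B <- diag(sp) %*% model$Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       left = diag(1 / sp) %*% e$vectors,
       right = t(e$vectors) %*% diag(sp))
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A `substitution_model`.
#' @param t Branch length in expected substitutions per site (>= 0).
#' @param eig Optional cached eigen system (internal use).
#' @return 20x20 stochastic matrix.
#' @export
transition_matrix <- function(model, t, eig = NULL) {
  if (t < 0) stop("branch length must be nonnegative")
  if (t == 0) {
    P <- diag(20)
    dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
    return(P)
  }
  if (is.null(eig)) eig <- .model_eigen(model)
  P <- eig$left %*% (exp(eig$values * t) * eig$right)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P
}
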