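#' Amino-acid state order
#'
#' The fixed 20-state amino-acid alphabet used throughout the package, in the
#' PAML dat-file convention (A, R, N, D, ...). All exchangeability matrices,
#' frequency vectors and ancestral-state profiles follow this order.
#'
#' @format Character vector of length 20.
#' @export
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# symbols treated as missing data (all-ones partial vectors) in likelihoods
MISSING_SYMBOLS <- c("-", "X", "?", "*")

#' Construct a substitution model
#'
#' A time-reversible amino-acid (or reduced-alphabet) substitution model:
#' symmetric exchangeabilities `S`, stationary frequencies `pi`, and a
#' discrete-gamma model of among-site rate variation with shape `alpha` and
#' `K` equal-probability categories.
#'
#' @param S Symmetric square matrix of non-negative exchangeabilities
#'   (diagonal ignored).
#' @param pi Stationary frequencies; strictly positive, summing to 1.
#' @param alpha Gamma shape parameter (> 0) for rate heterogeneity.
#' @param K Number of discrete gamma categories (integer >= 1).
#' @param alphabet Character states, one per row of `S`. Defaults to the
#'   20 amino acids in [AA_STATES] order.
#' @return An object of class `subst_model`.
#' @seealso [poisson_model()], [lg_model()], [read_paml_dat()]
#' @export
substitution_model <- function(S, pi, alpha = 1, K = 4, alphabet = AA_STATES) {
  S <- as.matrix(S)
  m <- length(alphabet)
  if (!is.numeric(S) || nrow(S) != m || ncol(S) != m)
    stop("S must be a ", m, "x", m, " numeric matrix")
  if (max(abs(S - t(S))) > 1e-10)
    stop("S must be symmetric")
  off <- S[row(S) != col(S)]
  if (any(off < 0)) stop("off-diagonal exchangeabilities must be non-negative")
  if (length(pi) != m) stop("pi must have one frequency per state")
  if (any(pi <= 0)) stop("all stationary frequencies must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-12) stop("pi must sum to 1 (within 1e-12)")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive number")
  if (K != as.integer(K) || K < 1) stop("K must be an integer >= 1")
  diag(S) <- 0
  dimnames(S) <- list(alphabet, alphabet)
  pi <- stats::setNames(as.numeric(pi), alphabet)
  structure(list(S = S, pi = pi, alpha = alpha, K = as.integer(K),
                 alphabet = alphabet),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Substitution model:", length(x$alphabet), "states,",
      "alpha =", format(x$alpha), ", K =", x$K, "\n")
  invisible(x)
}

#' Poisson (equal-rates) model
#'
#' Uniform exchangeabilities and uniform stationary frequencies over an
#' arbitrary alphabet. Used as the neutral reference model in tests and for
#' the method-comparison diagnostic in ancestral reconstruction.
#'
#' @inheritParams substitution_model
#' @export
poisson_model <- function(alpha = 1, K = 4, alphabet = AA_STATES) {
  m <- length(alphabet)
  S <- matrix(1, m, m)
  substitution_model(S, rep(1 / m, m), alpha = alpha, K = K, alphabet = alphabet)
}

#' Read a PAML dat-style empirical model file
#'
#' Parses the standard PAML amino-acid model format: 19 rows of
#' lower-triangle exchangeabilities followed by a line of 20 stationary
#' frequencies, states in [AA_STATES] order.
#'
#' @param path Path to the dat file.
#' @inheritParams substitution_model
#' @return A `subst_model`.
#' @export
read_paml_dat <- function(path, alpha = 1, K = 4) {
  lines <- readLines(path)
  nums <- lapply(lines, function(l) {
    l <- trimws(l)
    if (!nzchar(l)) return(numeric(0))
    as.numeric(strsplit(l, "\\s+")[[1]])
  })
  nums <- Filter(length, nums)
  vals <- unlist(nums)
  if (length(vals) < 190 + 20)
    stop("dat file does not contain 190 exchangeabilities plus 20 frequencies")
  S <- matrix(0, 20, 20)
  k <- 1
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- vals[k]; S[j, i] <- vals[k]; k <- k + 1
  }
  pi <- vals[191:210]
  pi <- pi / sum(pi)
  substitution_model(S, pi, alpha = alpha, K = K)
}

#' The bundled LG empirical model
#'
#' Loads the Le & Gascuel (2008) amino-acid replacement model shipped with the
#' package, the default empirical model for likelihoods, simulation and
#' ancestral reconstruction.
#'
#' @inheritParams substitution_model
#' @export
lg_model <- function(alpha = 1, K = 4) {
  path <- system.file("extdata", "lg.dat", package = "haloasr", mustWork = TRUE)
  read_paml_dat(path, alpha = alpha, K = K)
}

#' Build the normalized instantaneous rate matrix
#'
#' Assembles Q from a reversible model as `q_ij = S_ij * pi_j` (i != j) with
#' the diagonal set so rows sum to zero, rescaled so the expected
#' substitution rate at stationarity, `-sum(pi_i q_ii)`, equals 1 (branch
#' lengths are then expected replacements per site). A symmetric
#' eigendecomposition is cached for fast transition probabilities.
#'
#' @param model A [substitution_model()].
#' @return An object of class `rate_matrix` with elements `Q`, `scale`
#'   (the normalization constant divided out), `pi` and the eigensystem.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "subst_model"))
  pi <- model$pi
  Q <- model$S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate model: zero expected rate")
  Q <- Q / scale
  dimnames(Q) <- list(model$alphabet, model$alphabet)
  # detailed balance: D^(1/2) Q D^(-1/2) is symmetric; eigen once
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  structure(list(Q = Q, scale = scale, pi = pi, alphabet = model$alphabet,
                 values = es$values,
                 right = diag(1 / sq) %*% es$vectors,   # columns: Q eigenvectors
                 left = t(es$vectors) %*% diag(sq)),
            class = "rate_matrix")
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` for a [build_rate_matrix()] object, via the cached
#' spectral decomposition. Tiny negative entries from round-off are clipped
#' and rows renormalized.
#'
#' @param rm A `rate_matrix`.
#' @param t Branch length (expected replacements per site), `>= 0`.
#' @export
transition_matrix <- function(rm, t) {
  stopifnot(inherits(rm, "rate_matrix"), t >= 0, is.finite(t))
  P <- rm$right %*% (exp(rm$values * t) * rm$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(rm$alphabet, rm$alphabet)
  P
}

#' Discrete-gamma rate categories
#'
#' K equal-probability categories of a gamma(alpha, alpha) distribution
#' (mean 1); the rate of each category is the mean of its quantile bin
#' (mean-of-bin discretization). Rates are ascending and average exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param K Number of categories (integer >= 1).
#' @return Numeric vector of K relative rates.
#' @export
discrete_gamma_rates <- function(alpha, K) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive number")
  if (length(K) != 1 || K != as.integer(K) || K < 1)
    stop("K must be an integer >= 1")
  K <- as.integer(K)
  if (K == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  # E[X | bin] * P(bin) = (alpha/rate) * diff(pgamma(., alpha+1, rate)); mean 1
  mass <- diff(stats::pgamma(b, shape = alpha + 1, rate = alpha))
  rates <- K * mass
  rates / mean(rates)
}
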