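# Felsenstein pruning engine. Partial likelihoods are kept as m x L matrices
# per node, rescaled per column with accumulated log scale factors so deep
# trees do not underflow; an impossible column yields -Inf, never an error.

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length))) stop("branch lengths must be finite")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

# one-hot tip partials; missing symbols give all-ones columns
.tip_partials <- function(aln, labels, alphabet) {
  m <- length(alphabet)
  L <- ncol(aln)
  lapply(labels, function(lb) {
    s <- aln[lb, ]
    p <- matrix(0, m, L)
    idx <- match(s, alphabet)
    known <- which(!is.na(idx))
    p[cbind(idx[known], known)] <- 1
    p[, is.na(idx)] <- 1
    p
  })
}

# single pass of the pruning recursion at one relative rate.
# Returns per-node scaled partials, per-node accumulated per-column log
# scales, and the per-column log-likelihood at the root.
.peel <- function(tree, tip_partials, rm, rate, keep_partials = FALSE) {
  m <- length(rm$alphabet)
  L <- ncol(tip_partials[[1]])
  n_tip <- length(tip_partials)
  n_node <- n_tip + tree$Nnode
  partials <- vector("list", n_node)
  logscale <- matrix(0, n_node, L)
  partials[seq_len(n_tip)] <- tip_partials
  eo <- ape::reorder.phylo(tree, "postorder")
  Ps <- vector("list", nrow(eo$edge))
  msgs <- vector("list", nrow(eo$edge))
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1]; chi <- eo$edge[e, 2]
    P <- transition_matrix(rm, eo$edge.length[e] * rate)
    Ps[[e]] <- P
    msg <- P %*% partials[[chi]]
    if (keep_partials) msgs[[e]] <- msg
    if (is.null(partials[[par]])) {
      partials[[par]] <- msg
      logscale[par, ] <- logscale[chi, ]
    } else {
      partials[[par]] <- partials[[par]] * msg
      logscale[par, ] <- logscale[par, ] + logscale[chi, ]
    }
    sc <- apply(partials[[par]], 2, max)
    pos <- sc > 0
    partials[[par]][, pos] <- partials[[par]][, pos, drop = FALSE] /
      rep(sc[pos], each = m)
    logscale[par, ] <- logscale[par, ] + ifelse(pos, log(sc), -Inf)
  }
  root <- n_tip + 1L
  col_lik <- colSums(rm$pi * partials[[root]])
  col_loglik <- ifelse(col_lik > 0 & is.finite(logscale[root, ]),
                       log(col_lik) + logscale[root, ], -Inf)
  list(partials = if (keep_partials) partials else NULL,
       logscale = if (keep_partials) logscale else NULL,
       edges = if (keep_partials) eo else NULL,
       Ps = if (keep_partials) Ps else NULL,
       msgs = if (keep_partials) msgs else NULL,
       col_loglik = col_loglik)
}

# per-category column log-likelihoods (L x K matrix)
.category_logliks <- function(tree, aln, model) {
  .check_tree(tree)
  validate_alignment(aln, model$alphabet)
  labels <- tree$tip.label
  miss <- setdiff(labels, rownames(aln))
  if (length(miss))
    stop("leaf without sequence: ", paste(miss, collapse = " "))
  rm <- build_rate_matrix(model)
  rates <- discrete_gamma_rates(model$alpha, model$K)
  tp <- .tip_partials(aln[labels, , drop = FALSE], labels, model$alphabet)
  ll <- vapply(rates, function(r) .peel(tree, tp, rm, r)$col_loglik,
               numeric(ncol(aln)))
  ll <- matrix(ll, ncol = length(rates))
  list(ll = ll, rates = rates, rm = rm, tip_partials = tp)
}

#' Per-site log-likelihood by Felsenstein pruning
#'
#' Computes the per-column log-likelihood of an alignment on a rooted tree
#' under a reversible model with discrete-gamma rate heterogeneity
#' (categories weighted equally). Gap and unknown tip states are treated as
#' missing data. An impossible column (e.g. conflicting states on zero-length
#' branches) yields `-Inf`.
#'
#' @param tree Rooted `phylo` tree with non-negative branch lengths in
#'   expected replacements per site.
#' @param alignment Character matrix alignment containing all tip labels.
#' @param model A [substitution_model()].
#' @return Numeric vector of per-column log-likelihoods, with attributes
#'   `total` (their sum) and `by_category` (L x K matrix).
#' @export
pruning_loglik <- function(tree, alignment, model) {
  cl <- .category_logliks(tree, alignment, model)
  site <- .logsumexp_rows(cl$ll) - log(length(cl$rates))
  attr(site, "total") <- sum(site)
  attr(site, "by_category") <- cl$ll
  site
}

#' Site-specific posterior rates
#'
#' For each alignment column, the posterior weight of gamma category k is
#' proportional to the column likelihood under rate r_k (equal prior
#' weights); the posterior mean rate is the weight-averaged category rate.
#' Columns with only missing data get the uniform prior and are flagged.
#'
#' @inheritParams pruning_loglik
#' @return An object of class `site_rates`: list with `mean_rate` (numeric,
#'   per column), `weights` (L x K), `rates` (the K category rates) and
#'   `all_gap` (logical per column).
#' @export
site_posterior_rates <- function(tree, alignment, model) {
  cl <- .category_logliks(tree, alignment, model)
  K <- length(cl$rates)
  mx <- apply(cl$ll, 1, max)
  w <- exp(cl$ll - ifelse(is.finite(mx), mx, 0))
  w <- w / rowSums(w)
  all_gap <- apply(alignment[tree$tip.label, , drop = FALSE], 2,
                   function(col) all(col %in% MISSING_SYMBOLS))
  structure(list(mean_rate = as.numeric(w %*% cl$rates),
                 weights = w, rates = cl$rates, all_gap = all_gap),
            class = "site_rates")
}

#' Maximum-likelihood pairwise distance
#'
#' Maximizes the two-sequence likelihood over a branch length t in
#' `[1e-6, 10]` by bracketed 1-D optimization. Columns where either sequence
#' has a gap or unknown residue are skipped. Symmetric in its arguments for
#' reversible models.
#'
#' @param a,b Sequences: character vectors of states, or single strings.
#' @param model A [substitution_model()].
#' @return Distance in expected replacements per site.
#' @export
ml_pairwise_distance <- function(a, b, model) {
  as_vec <- function(x) if (length(x) == 1 && nchar(x[1]) > 1)
    strsplit(toupper(x), "")[[1]] else toupper(x)
  a <- as_vec(a); b <- as_vec(b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- !(a %in% MISSING_SYMBOLS) & !(b %in% MISSING_SYMBOLS)
  if (!any(ok)) stop("no comparable columns")
  ia <- match(a[ok], model$alphabet); ib <- match(b[ok], model$alphabet)
  if (anyNA(ia) || anyNA(ib)) stop("sequence contains symbols outside the alphabet")
  # canonicalize pairs: for a reversible model pi_i P_ij = pi_j P_ji, so the
  # objective is literally identical in both argument orders
  cnt <- table(paste(pmin(ia, ib), pmax(ia, ib)))
  key <- do.call(rbind, lapply(strsplit(names(cnt), " "), as.integer))
  n_pair <- as.numeric(cnt)
  rm <- build_rate_matrix(model)
  rates <- discrete_gamma_rates(model$alpha, model$K)
  negll <- function(t) {
    lik <- 0
    for (r in rates) {
      P <- transition_matrix(rm, t * r)
      lik <- lik + rm$pi[key[, 1]] * P[key] / length(rates)
    }
    -sum(n_pair * log(lik))
  }
  lo <- 1e-6; hi <- 10
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-10)
  d <- opt$minimum
  if (negll(lo) <= opt$objective + 1e-10) d <- lo
  if (negll(hi) <= opt$objective + 1e-10 && negll(hi) < negll(lo)) d <- hi
  d
}
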