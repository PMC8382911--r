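# Independent brute-force oracles. These deliberately avoid the package's
# pruning/DP code paths: likelihoods and marginals are computed by exhaustive
# enumeration over internal-state assignments, gap parsimony by enumeration
# over presence assignments, and DTL reconciliation by a plain recursive
# scenario search. Only usable on tiny instances.

two_state_model <- function(alpha = 1, K = 1)
  substitution_model(matrix(1, 2, 2), c(0.5, 0.5), alpha, K,
                     alphabet = c("A", "R"))

four_state_model <- function(alpha = 1, K = 1, seed = NULL) {
  ab <- c("A", "C", "G", "T")
  if (is.null(seed)) return(poisson_model(alpha, K, alphabet = ab))
  set.seed(seed)
  S <- matrix(0, 4, 4)
  S[upper.tri(S)] <- runif(6, 0.2, 2)
  S <- S + t(S)
  pi <- runif(4, 0.5, 2); pi <- pi / sum(pi)
  substitution_model(S, pi, alpha, K, alphabet = ab)
}

# enumerate every assignment of states to all nodes; sum the probability of
# assignments compatible with the observed (possibly missing) tip states
brute_force_site_lik <- function(tree, column, model) {
  ab <- model$alphabet
  m <- length(ab)
  rm <- build_rate_matrix(model)
  rates <- discrete_gamma_rates(model$alpha, model$K)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  allowed <- lapply(seq_len(n_node), function(v) {
    if (v > n_tip) return(seq_len(m))
    s <- column[tree$tip.label[v]]
    if (s %in% ab) match(s, ab) else seq_len(m)
  })
  total <- 0
  for (r in rates) {
    Ps <- apply(tree$edge, 1, function(e) NULL)
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      transition_matrix(rm, tree$edge.length[e] * r))
    grid <- do.call(expand.grid, allowed)
    for (i in seq_len(nrow(grid))) {
      st <- as.integer(grid[i, ])
      p <- unname(rm$pi[st[root]])
      for (e in seq_len(nrow(tree$edge)))
        p <- p * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      total <- total + p / length(rates)
    }
  }
  total
}

# node-state marginals by the same enumeration
brute_force_marginals <- function(tree, column, model, node) {
  ab <- model$alphabet
  m <- length(ab)
  rm <- build_rate_matrix(model)
  rates <- discrete_gamma_rates(model$alpha, model$K)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  allowed <- lapply(seq_len(n_node), function(v) {
    if (v > n_tip) return(seq_len(m))
    s <- column[tree$tip.label[v]]
    if (s %in% ab) match(s, ab) else seq_len(m)
  })
  acc <- numeric(m)
  for (r in rates) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      transition_matrix(rm, tree$edge.length[e] * r))
    grid <- do.call(expand.grid, allowed)
    for (i in seq_len(nrow(grid))) {
      st <- as.integer(grid[i, ])
      p <- unname(rm$pi[st[root]])
      for (e in seq_len(nrow(tree$edge)))
        p <- p * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      acc[st[node]] <- acc[st[node]] + p / length(rates)
    }
  }
  acc / sum(acc)
}

# minimum number of presence-state changes over all internal assignments
brute_force_gap_score <- function(tree, present) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  st <- integer(n_tip + n_int)
  st[seq_len(n_tip)] <- ifelse(present[tree$tip.label], 1L, 0L)
  best <- Inf
  assignments <- expand.grid(rep(list(0:1), n_int))
  for (i in seq_len(nrow(assignments))) {
    st[n_tip + seq_len(n_int)] <- as.integer(assignments[i, ])
    ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# minimal-change root states (for checking the "present"-preferred tie rule)
brute_force_gap_root_states <- function(tree, present) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  st <- integer(n_tip + n_int)
  st[seq_len(n_tip)] <- ifelse(present[tree$tip.label], 1L, 0L)
  best <- Inf; roots <- integer(0)
  assignments <- expand.grid(rep(list(0:1), n_int))
  for (i in seq_len(nrow(assignments))) {
    st[n_tip + seq_len(n_int)] <- as.integer(assignments[i, ])
    ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    if (ch < best) { best <- ch; roots <- st[n_tip + 1L] }
    else if (ch == best) roots <- union(roots, st[n_tip + 1L])
  }
  list(score = best, root_states = sort(roots))
}

# independent recursive DTL scenario search (no tables). States progress:
# every recursive call either consumes a gene node, descends one slice, or
# performs at most one transfer-loss hop before a non-hop event, so the
# search terminates. A second consecutive transfer-loss can never beat a
# single direct one, so capping the chain at one preserves the minimum.
brute_force_dtl <- function(stree, gtree, costs, species_map = gene_leaf_species) {
  ages <- node_ages(stree)
  n_stip <- length(stree$tip.label)
  sroot <- n_stip + 1L
  internal_ages <- sort(ages[(n_stip + 1):length(ages)], decreasing = TRUE)
  bounds <- c(internal_ages, 0)      # lower bounds of slices 1..n
  parent_age <- rep(Inf, length(ages))
  parent_age[stree$edge[, 2]] <- ages[stree$edge[, 1]]
  in_slice <- function(b, j) {       # j in 1..length(bounds)-? slice j: (bounds[j+? ]
    up <- if (j == 1) Inf else bounds[j - 1]
    lo <- bounds[j]
    ages[b] <= lo + 1e-12 && parent_age[b] >= up - 1e-12
  }
  n_slice <- length(bounds)
  slice_branches <- lapply(seq_len(n_slice), function(j) {
    if (j == 1) return(integer(0))   # unused; the virtual slice is handled apart
    Filter(function(b) in_slice(b, j), stree$edge[, 2])
  })
  # slices here: index 1 = virtual (above root), 2..n_slice real
  skids <- function(v) stree$edge[stree$edge[, 1] == v, 2]
  n_gtip <- length(gtree$tip.label)
  gkids <- function(u) gtree$edge[gtree$edge[, 1] == u, 2]
  sp_of <- match(species_map(gtree$tip.label), stree$tip.label)
  d <- costs$dup; tau <- costs$transfer; lam <- costs$loss
  rec <- function(u, b, j, tl_allowed) {
    # u on branch b within slice j (1 = virtual)
    opts <- c()
    is_leaf <- u <= n_gtip
    last <- j == n_slice
    ends <- if (j == 1) b == sroot else
      if (last) b <= n_stip else abs(ages[b] - bounds[j]) < 1e-12
    if (last && is_leaf && b <= n_stip && sp_of[u] == b)
      opts <- c(opts, 0)
    if (!last && !ends)
      opts <- c(opts, rec(u, b, j + 1, TRUE))
    if (!last && ends) {
      nd <- if (j == 1) sroot else b
      yz <- skids(nd)
      if (!is_leaf) {
        uk <- gkids(u)
        opts <- c(opts,
                  rec(uk[1], yz[1], j + 1, TRUE) + rec(uk[2], yz[2], j + 1, TRUE),
                  rec(uk[1], yz[2], j + 1, TRUE) + rec(uk[2], yz[1], j + 1, TRUE))
      }
      opts <- c(opts, lam + rec(u, yz[1], j + 1, TRUE),
                lam + rec(u, yz[2], j + 1, TRUE))
    }
    if (!is_leaf) {
      uk <- gkids(u)
      opts <- c(opts, d + rec(uk[1], b, j, TRUE) + rec(uk[2], b, j, TRUE))
      for (y in setdiff(slice_branches[[j]], b)) {
        opts <- c(opts,
                  tau + rec(uk[1], b, j, TRUE) + rec(uk[2], y, j, TRUE),
                  tau + rec(uk[1], y, j, TRUE) + rec(uk[2], b, j, TRUE))
      }
    }
    if (tl_allowed) {
      for (y in setdiff(slice_branches[[j]], b))
        opts <- c(opts, tau + lam + rec(u, y, j, FALSE))
    }
    if (!length(opts)) Inf else min(opts)
  }
  rec(n_gtip + 1L, sroot, 1L, FALSE)
}

# small fixed rooted trees for reuse
tree4 <- function() ape::read.tree(text = "((a:0.2,b:0.3):0.1,(c:0.15,d:0.25):0.2);")
tree5 <- function() ape::read.tree(
  text = "(((a:0.1,b:0.2):0.1,c:0.3):0.1,(d:0.2,e:0.1):0.25);")

random_alignment <- function(taxa, L, alphabet, gap_prob = 0) {
  m <- matrix(sample(c(alphabet, "-"), length(taxa) * L, TRUE,
                     prob = c(rep((1 - gap_prob) / length(alphabet),
                                  length(alphabet)), gap_prob)),
              length(taxa), L, dimnames = list(taxa, NULL))
  m
}
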