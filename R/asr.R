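#' Marginal (empirical-Bayes) ancestral state profiles
#'
#' For every internal node and alignment column, the posterior distribution
#' of the node's state given all tip data, branch lengths and the model,
#' marginalized over the discrete-gamma rate categories (inside-outside
#' computation). The MAP state is the maximum-posterior state, ties broken
#' by the fixed state order (tie occurrences are counted).
#'
#' @inheritParams pruning_loglik
#' @return An object of class `ancestral_profiles`: list with `prob` (per
#'   internal node, a states x columns posterior matrix), `map` (node x
#'   column MAP-state matrix), `pp` (node x column MAP posterior
#'   probability), `nodes` (internal-node labels), `alphabet`, `tree`, and
#'   `n_map_ties`.
#' @export
marginal_profiles <- function(tree, alignment, model) {
  .check_tree(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  validate_alignment(alignment, model$alphabet)
  labels <- tree$tip.label
  miss <- setdiff(labels, rownames(alignment))
  if (length(miss)) stop("leaf without sequence: ", paste(miss, collapse = " "))
  rm <- build_rate_matrix(model)
  rates <- discrete_gamma_rates(model$alpha, model$K)
  K <- length(rates)
  m <- length(model$alphabet)
  L <- ncol(alignment)
  n_tip <- length(labels)
  root <- n_tip + 1L
  n_node <- n_tip + tree$Nnode
  tp <- .tip_partials(alignment[labels, , drop = FALSE], labels, model$alphabet)
  post <- array(0, dim = c(tree$Nnode, m, L))
  ll <- matrix(0, L, K)
  per_cat <- vector("list", K)
  for (k in seq_len(K)) {
    pe <- .peel(tree, tp, rm, rates[k], keep_partials = TRUE)
    ll[, k] <- pe$col_loglik
    eo <- pe$edges
    # outside pass: G[v] proportional to P(data outside v's subtree, state v)
    G <- vector("list", n_node)
    G[[root]] <- matrix(rm$pi, m, L)
    kids_edges <- split(seq_len(nrow(eo$edge)), eo$edge[, 1])
    for (e in rev(seq_len(nrow(eo$edge)))) {   # preorder
      par <- eo$edge[e, 1]; chi <- eo$edge[e, 2]
      H <- G[[par]]
      for (e2 in kids_edges[[as.character(par)]])
        if (e2 != e) H <- H * pe$msgs[[e2]]
      Gc <- crossprod(pe$Ps[[e]], H)
      sc <- apply(Gc, 2, max)
      sc[sc <= 0] <- 1
      G[[chi]] <- Gc / rep(sc, each = m)
    }
    per_cat[[k]] <- lapply(seq_len(tree$Nnode), function(i) {
      v <- n_tip + i
      pk <- G[[v]] * pe$partials[[v]]
      cs <- colSums(pk)
      cs[cs <= 0] <- 1
      pk / rep(cs, each = m)
    })
  }
  mx <- apply(ll, 1, max)
  w <- exp(ll - ifelse(is.finite(mx), mx, 0))
  w <- w / rowSums(w)                      # L x K category weights per column
  for (k in seq_len(K))
    for (i in seq_len(tree$Nnode))
      post[i, , ] <- post[i, , ] + per_cat[[k]][[i]] * rep(w[, k], each = m)
  node_lab <- .node_labels(tree)
  map_idx <- apply(post, c(1, 3), which.max)
  pp <- apply(post, c(1, 3), max)
  ties <- sum(apply(post, c(1, 3), function(p) sum(abs(p - max(p)) < 1e-12)) > 1)
  map <- matrix(model$alphabet[map_idx], tree$Nnode, L,
                dimnames = list(node_lab, NULL))
  dimnames(pp) <- list(node_lab, NULL)
  prob <- lapply(seq_len(tree$Nnode), function(i) {
    p <- post[i, , ]
    dim(p) <- c(m, L)
    rownames(p) <- model$alphabet
    p
  })
  names(prob) <- node_lab
  structure(list(prob = prob, map = map, pp = pp, nodes = node_lab,
                 alphabet = model$alphabet, tree = tree, n_map_ties = ties),
            class = "ancestral_profiles")
}

#' @export
print.ancestral_profiles <- function(x, ...) {
  cat("Ancestral profiles:", length(x$nodes), "internal nodes x",
      ncol(x$map), "columns;", x$n_map_ties, "MAP ties\n")
  invisible(x)
}

#' Infer ancestral presence/absence (gap) states
#'
#' Treats each column's gap pattern as a binary presence character and
#' assigns ancestral states by two-pass Fitch parsimony, resolving ambiguous
#' internal assignments as "present"; or by Dollo parsimony (a single origin
#' at the most recent common ancestor of the present leaves, losses below).
#'
#' @param alignment Character matrix alignment (leaf rows; `-` is the gap).
#' @param tree Rooted `phylo` tree whose tips are alignment rows.
#' @param mode `"fitch"` (default) or `"dollo"`.
#' @return An object of class `gap_states`: list with `presence` (logical
#'   matrix, tips then internal nodes, by column), `score` (per-column
#'   parsimony change count) and `mode`.
#' @export
infer_gap_states <- function(alignment, tree, mode = c("fitch", "dollo")) {
  mode <- match.arg(mode)
  .check_tree(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  labels <- tree$tip.label
  if (!all(labels %in% rownames(alignment)))
    stop("alignment must contain every leaf")
  L <- ncol(alignment)
  n_tip <- length(labels)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  eo <- ape::reorder.phylo(tree, "postorder")
  tip_present <- alignment[labels, , drop = FALSE] != "-"
  lab_all <- c(labels, .node_labels(tree))
  if (mode == "fitch") {
    # state sets encoded as bit masks: 1 = absent, 2 = present, 3 = either
    sets <- matrix(0L, n_node, L)
    sets[seq_len(n_tip), ] <- ifelse(tip_present, 2L, 1L)
    score <- integer(L)
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chi <- eo$edge[e, 2]
      if (all(sets[par, ] == 0L)) {
        sets[par, ] <- sets[chi, ]
      } else {
        inter <- bitwAnd(sets[par, ], sets[chi, ])
        uni <- bitwOr(sets[par, ], sets[chi, ])
        score <- score + (inter == 0L)
        sets[par, ] <- ifelse(inter > 0L, inter, uni)
      }
    }
    final <- matrix(0L, n_node, L)
    final[seq_len(n_tip), ] <- sets[seq_len(n_tip), ]
    final[root, ] <- ifelse(sets[root, ] == 3L, 2L, sets[root, ])
    for (e in rev(seq_len(nrow(eo$edge)))) {
      par <- eo$edge[e, 1]; chi <- eo$edge[e, 2]
      hit <- bitwAnd(sets[chi, ], final[par, ]) > 0L
      final[chi, ] <- ifelse(hit, final[par, ], sets[chi, ])
    }
    presence <- final == 2L
  } else {
    npres <- matrix(0L, n_node, L)
    npres[seq_len(n_tip), ] <- tip_present * 1L
    for (e in seq_len(nrow(eo$edge)))
      npres[eo$edge[e, 1], ] <- npres[eo$edge[e, 1], ] + npres[eo$edge[e, 2], ]
    total <- npres[root, ]
    child_max <- matrix(0L, n_node, L)
    for (e in seq_len(nrow(eo$edge)))
      child_max[eo$edge[e, 1], ] <- pmax(child_max[eo$edge[e, 1], ],
                                         npres[eo$edge[e, 2], ])
    is_mrca <- sweep(npres, 2, total, "==") &
      !sweep(child_max, 2, total, "==")
    presence <- npres > 0L & (sweep(npres, 2, total, "<") | is_mrca)
    presence[seq_len(n_tip), ] <- tip_present
    # losses: present parent, absent child
    score <- integer(L)
    for (e in seq_len(nrow(eo$edge)))
      score <- score + (presence[eo$edge[e, 1], ] & !presence[eo$edge[e, 2], ])
  }
  rownames(presence) <- lab_all
  structure(list(presence = presence, score = score, mode = mode),
            class = "gap_states")
}

#' Compose gapped ancestral sequences
#'
#' Substitutes inferred ancestral gaps into the MAP ancestral states: a
#' node/column whose inferred presence state is absent becomes the gap
#' symbol, otherwise the MAP state is used.
#'
#' @param profiles A [marginal_profiles()] result.
#' @param gaps A [infer_gap_states()] result on the same tree/alignment.
#' @return Character matrix of ancestral sequences (one row per internal
#'   node), each of alignment length.
#' @export
compose_ancestors <- function(profiles, gaps) {
  stopifnot(inherits(profiles, "ancestral_profiles"),
            inherits(gaps, "gap_states"))
  out <- profiles$map
  if (ncol(out) != ncol(gaps$presence))
    stop("profiles and gap states have different numbers of columns")
  if (!all(rownames(out) %in% rownames(gaps$presence)))
    stop("gap states are missing internal nodes present in the profiles")
  out[!gaps$presence[rownames(out), , drop = FALSE]] <- "-"
  out
}

#' Count amino-acid replacements between two gapped sequences
#'
#' Columns where either sequence has a gap are excluded; the count is the
#' number of remaining columns whose states differ.
#'
#' @param a,b Sequences (character vectors or single strings) of equal
#'   length.
#' @return Integer replacement count.
#' @export
count_replacements <- function(a, b) {
  as_vec <- function(x) if (length(x) == 1 && nchar(x[1]) > 1)
    strsplit(x, "")[[1]] else x
  a <- as_vec(a); b <- as_vec(b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a != "-" & b != "-"
  sum(a[ok] != b[ok])
}

#' Fraction of well-identified ancestral sites
#'
#' The fraction of (non-gap) ancestral columns whose MAP posterior
#' probability is strictly greater than `threshold` (default 0.9).
#'
#' @param profiles A [marginal_profiles()] result.
#' @param node Internal-node label.
#' @param threshold Posterior probability threshold.
#' @param gaps Optional [infer_gap_states()] result; columns inferred as
#'   gaps at the node are excluded.
#' @return Fraction in `[0, 1]` (`NA` if the node has no non-gap columns).
#' @export
well_identified_fraction <- function(profiles, node, threshold = 0.9,
                                     gaps = NULL) {
  stopifnot(inherits(profiles, "ancestral_profiles"))
  if (!node %in% rownames(profiles$pp)) stop("unknown node: ", node)
  pp <- profiles$pp[node, ]
  keep <- rep(TRUE, length(pp))
  if (!is.null(gaps)) keep <- gaps$presence[node, ]
  if (!any(keep)) return(NA_real_)
  mean(pp[keep] > threshold)
}

#' Write ancestral profiles to TSV
#'
#' One row per (node, column): the full posterior vector, the MAP state and
#' its posterior probability.
#'
#' @param profiles A [marginal_profiles()] result.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "ancestral_profiles"))
  rows <- lapply(profiles$nodes, function(nd) {
    p <- t(profiles$prob[[nd]])
    colnames(p) <- paste0("p_", profiles$alphabet)
    data.frame(node = nd, column = seq_len(nrow(p)), p,
               map = profiles$map[nd, ], pp = profiles$pp[nd, ],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
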