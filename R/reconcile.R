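#' Time-slice a dated species tree
#'
#' Cuts the tree into horizontal slices bounded by consecutive internal-node
#' ages (plus 0). A binary tree with n leaves yields n-1 slices; each
#' species branch belongs to every slice intersecting its age interval.
#' Transfers during reconciliation are constrained to branches of the same
#' slice.
#'
#' @param stree Dated species tree (rooted ultrametric `phylo`, distinct
#'   internal node ages).
#' @return An object of class `time_sliced`: list with `tree`, `ages`,
#'   `boundaries` (descending, ending at 0), `slices` (per slice, the child
#'   node ids of its branches) and `branch_labels`.
#' @export
time_slice <- function(stree) {
  ages <- .validate_dated_tree(stree)
  n_tip <- length(stree$tip.label)
  internal <- sort(ages[(n_tip + 1):length(ages)], decreasing = TRUE)
  boundaries <- c(internal, 0)
  parent_age <- rep(Inf, length(ages))
  parent_age[stree$edge[, 2]] <- ages[stree$edge[, 1]]
  branches <- stree$edge[, 2]
  slices <- lapply(seq_len(length(boundaries) - 1L), function(k) {
    up <- boundaries[k]; lo <- boundaries[k + 1]
    sort(branches[ages[branches] <= lo + 1e-12 &
                    parent_age[branches] >= up - 1e-12])
  })
  structure(list(tree = stree, ages = ages, boundaries = boundaries,
                 slices = slices, branch_labels = .branch_labels(stree)),
            class = "time_sliced")
}

#' DTL event costs
#'
#' @param dup,transfer,loss Non-negative costs for duplication, transfer and
#'   loss events; speciation costs 0. Defaults 2, 3, 1.
#' @export
dtl_costs <- function(dup = 2, transfer = 3, loss = 1) {
  if (any(c(dup, transfer, loss) < 0)) stop("costs must be non-negative")
  structure(list(dup = dup, transfer = transfer, loss = loss),
            class = "dtl_costs")
}

#' Most-parsimonious DTL reconciliation
#'
#' Reconciles a rooted gene tree against a time-sliced dated species tree by
#' a minimum-cost dynamic program over (gene node, species branch, slice).
#' Events are speciation (cost 0), duplication, transfer and loss, including
#' the compound speciation-loss and transfer-loss steps; transfers are
#' permitted only between distinct branches of the same time slice. The gene
#' lineage enters above the species root. One optimal scenario is backtracked
#' with deterministic tie-breaking (event order speciation < duplication <
#' transfer, then ascending species-branch index).
#'
#' @param sliced A [time_slice()] object.
#' @param gtree Rooted gene tree (`phylo`).
#' @param costs A [dtl_costs()] object.
#' @param species_map Function mapping gene leaf labels to species leaf
#'   labels (default strips a `_<copy>` suffix).
#' @return An object of class `dtl_scenario`: list with `cost`, `counts`
#'   (named D/T/L/S vector) and `events` (data frame: kind, gene_node,
#'   branch, recipient, slice).
#' @export
reconcile_dtl <- function(sliced, gtree, costs = dtl_costs(),
                          species_map = gene_leaf_species) {
  stopifnot(inherits(sliced, "time_sliced"), inherits(costs, "dtl_costs"))
  .check_tree(gtree)
  if (!ape::is.rooted(gtree)) stop("gene tree must be rooted")
  stree <- sliced$tree
  ages <- sliced$ages
  n_stip <- length(stree$tip.label)
  sroot <- n_stip + 1L
  blab <- sliced$branch_labels
  spp <- species_map(gtree$tip.label)
  sp_id <- match(spp, stree$tip.label)
  if (anyNA(sp_id))
    stop("unmappable gene leaf: ",
         paste(gtree$tip.label[is.na(sp_id)], collapse = " "))
  n_gtip <- length(gtree$tip.label)
  g_n <- n_gtip + gtree$Nnode
  gkids <- vector("list", g_n)
  for (e in seq_len(nrow(gtree$edge)))
    gkids[[gtree$edge[e, 1]]] <- c(gkids[[gtree$edge[e, 1]]], gtree$edge[e, 2])
  groot <- n_gtip + 1L
  g_order <- c(ape::reorder.phylo(gtree, "postorder")$edge[, 2], groot)
  g_lab <- c(gtree$tip.label, .node_labels(gtree))
  skids <- vector("list", length(ages))
  for (e in seq_len(nrow(stree$edge)))
    skids[[stree$edge[e, 1]]] <- c(skids[[stree$edge[e, 1]]], stree$edge[e, 2])
  S <- length(sliced$slices)
  # slice index shift: slice 0 (virtual, root branch only) stored at 1
  slices <- c(list(sroot), sliced$slices)
  n_sl <- S + 1L
  lower <- c(sliced$boundaries[1], sliced$boundaries[-1])  # lower bound per stored slice
  # bottom node of stored slice j: node whose age equals lower[j]; for the
  # last slice the "bottom" is the leaf level (age 0)
  bottom_node <- vapply(seq_len(n_sl), function(j) {
    if (j == n_sl) return(NA_integer_)
    nd <- which(abs(ages - lower[j]) < 1e-12)
    nd[nd > n_stip][1]
  }, integer(1))
  delta <- costs$dup; tau <- costs$transfer; lam <- costs$loss
  FIN <- array(Inf, dim = c(g_n, length(ages), n_sl))
  base_of <- function(u, b, j) {
    val <- Inf
    is_leaf_u <- u <= n_gtip
    ends <- if (j == n_sl) b <= n_stip else
      (!is.na(bottom_node[j]) && bottom_node[j] == b)
    if (j == n_sl && is_leaf_u && b <= n_stip && sp_id[u] == b)
      val <- min(val, 0)
    if (j < n_sl && !ends)
      val <- min(val, FIN[u, b, j + 1])
    if (ends && j < n_sl) {
      yz <- skids[[bottom_node[j]]]
      y <- yz[1]; z <- yz[2]
      if (!is_leaf_u) {
        u1 <- gkids[[u]][1]; u2 <- gkids[[u]][2]
        val <- min(val,
                   FIN[u1, y, j + 1] + FIN[u2, z, j + 1],
                   FIN[u1, z, j + 1] + FIN[u2, y, j + 1])
      }
      val <- min(val, lam + FIN[u, y, j + 1], lam + FIN[u, z, j + 1])
    }
    if (!is_leaf_u) {
      u1 <- gkids[[u]][1]; u2 <- gkids[[u]][2]
      val <- min(val, delta + FIN[u1, b, j] + FIN[u2, b, j])
      others <- setdiff(slices[[j]], b)
      for (y in others)
        val <- min(val,
                   tau + FIN[u1, b, j] + FIN[u2, y, j],
                   tau + FIN[u1, y, j] + FIN[u2, b, j])
    }
    val
  }
  BASE <- array(Inf, dim = c(g_n, length(ages), n_sl))
  for (u in g_order) {
    for (j in n_sl:1) {
      br <- slices[[j]]
      for (b in br) BASE[u, b, j] <- base_of(u, b, j)
      if (length(br) > 1) {
        bv <- BASE[u, br, j]
        for (i in seq_along(br)) {
          alt <- tau + lam + min(bv[-i])
          FIN[u, br[i], j] <- min(bv[i], alt)
        }
      } else FIN[u, br, j] <- BASE[u, br, j]
    }
  }
  total <- FIN[groot, sroot, 1]
  if (!is.finite(total)) stop("reconciliation infeasible")
  # --- backtrack one optimal scenario -------------------------------------
  evs <- list()
  push <- function(kind, node, branch, recipient, slice)
    evs[[length(evs) + 1L]] <<- data.frame(
      kind = kind, gene_node = node, branch = branch,
      recipient = recipient, slice = slice, stringsAsFactors = FALSE)
  eq <- function(a, b) is.finite(a) && abs(a - b) < 1e-9
  trace <- function(u, b, j, use_base) {
    target <- if (use_base) BASE[u, b, j] else FIN[u, b, j]
    if (!use_base && !eq(BASE[u, b, j], target)) {   # transfer-loss move
      others <- setdiff(slices[[j]], b)
      for (y in others) {
        if (eq(tau + lam + BASE[u, y, j], target)) {
          push("transfer", g_lab[u], blab[b], blab[y], j - 1L)
          push("loss", NA_character_, blab[b], NA_character_, j - 1L)
          return(trace(u, y, j, TRUE))
        }
      }
      stop("backtrack failure (TL)")
    }
    is_leaf_u <- u <= n_gtip
    ends <- if (j == n_sl) b <= n_stip else
      (!is.na(bottom_node[j]) && bottom_node[j] == b)
    if (j == n_sl && is_leaf_u && b <= n_stip && sp_id[u] == b && eq(0, target)) {
      push("leaf", g_lab[u], blab[b], NA_character_, j - 1L)
      return(invisible())
    }
    if (j < n_sl && !ends && eq(FIN[u, b, j + 1], target))
      return(trace(u, b, j + 1, FALSE))
    if (ends && j < n_sl) {
      yz <- skids[[bottom_node[j]]]
      y <- yz[1]; z <- yz[2]
      if (!is_leaf_u) {
        u1 <- gkids[[u]][1]; u2 <- gkids[[u]][2]
        if (eq(FIN[u1, y, j + 1] + FIN[u2, z, j + 1], target)) {
          push("speciation", g_lab[u], blab[bottom_node[j]], NA_character_, j - 1L)
          trace(u1, y, j + 1, FALSE); trace(u2, z, j + 1, FALSE)
          return(invisible())
        }
        if (eq(FIN[u1, z, j + 1] + FIN[u2, y, j + 1], target)) {
          push("speciation", g_lab[u], blab[bottom_node[j]], NA_character_, j - 1L)
          trace(u1, z, j + 1, FALSE); trace(u2, y, j + 1, FALSE)
          return(invisible())
        }
      }
      for (w in c(y, z)) {
        if (eq(lam + FIN[u, w, j + 1], target)) {
          lost <- if (w == y) z else y
          push("loss", NA_character_, blab[lost], NA_character_, j)
          return(trace(u, w, j + 1, FALSE))
        }
      }
    }
    if (!is_leaf_u) {
      u1 <- gkids[[u]][1]; u2 <- gkids[[u]][2]
      if (eq(delta + FIN[u1, b, j] + FIN[u2, b, j], target)) {
        push("duplication", g_lab[u], blab[b], NA_character_, j - 1L)
        trace(u1, b, j, FALSE); trace(u2, b, j, FALSE)
        return(invisible())
      }
      for (y in setdiff(slices[[j]], b)) {
        if (eq(tau + FIN[u1, b, j] + FIN[u2, y, j], target)) {
          push("transfer", g_lab[u], blab[b], blab[y], j - 1L)
          trace(u1, b, j, FALSE); trace(u2, y, j, FALSE)
          return(invisible())
        }
        if (eq(tau + FIN[u1, y, j] + FIN[u2, b, j], target)) {
          push("transfer", g_lab[u], blab[b], blab[y], j - 1L)
          trace(u1, y, j, FALSE); trace(u2, b, j, FALSE)
          return(invisible())
        }
      }
    }
    stop("backtrack failure")
  }
  trace(groot, sroot, 1L, FALSE)
  events <- do.call(rbind, evs)
  counts <- c(D = sum(events$kind == "duplication"),
              T = sum(events$kind == "transfer"),
              L = sum(events$kind == "loss"),
              S = sum(events$kind == "speciation"))
  stopifnot(abs(delta * counts["D"] + tau * counts["T"] + lam * counts["L"] -
                  total) < 1e-9)
  structure(list(cost = total, counts = counts, events = events,
                 costs = costs),
            class = "dtl_scenario")
}

#' @export
print.dtl_scenario <- function(x, ...) {
  cat("DTL reconciliation: cost", format(x$cost), "| events:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Event counts of a reconciliation scenario
#'
#' @param scenario A [reconcile_dtl()] result.
#' @return Named integer vector `(D, T, L, S)`, consistent with the
#'   scenario's cost identity `dup*D + transfer*T + loss*L = cost`.
#' @export
event_counts <- function(scenario) {
  stopifnot(inherits(scenario, "dtl_scenario"))
  scenario$counts
}

#' Conditional clade probabilities from a gene-tree sample
#'
#' Clade frequency is the fraction of sample trees containing the clade
#' (identified by its leaf set); the conditional probability of a split is
#' the number of trees showing the clade split that way divided by the
#' number of trees containing the clade.
#'
#' @param sample Non-empty list of rooted `phylo` trees on the same leaf set.
#' @return An object of class `ccp_table`: list with data frames `clades`
#'   (clade, freq) and `splits` (clade, split, prob), and `n_trees`.
#' @export
compute_ccp <- function(sample) {
  if (!length(sample)) stop("empty tree sample")
  ref <- sort(sample[[1]]$tip.label)
  clade_counts <- new.env(parent = emptyenv())
  split_counts <- new.env(parent = emptyenv())
  bump <- function(env, key) assign(key, (if (exists(key, env)) get(key, env) else 0L) + 1L, env)
  for (tr in sample) {
    if (!identical(sort(tr$tip.label), ref))
      stop("all sample trees must share one leaf set")
    n_tip <- length(tr$tip.label)
    keys <- character(n_tip + tr$Nnode)
    keys[seq_len(n_tip)] <- tr$tip.label
    eo <- ape::reorder.phylo(tr, "postorder")
    ckids <- split(eo$edge[, 2], eo$edge[, 1])
    # build keys bottom-up along postorder edges
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chi <- eo$edge[e, 2]
      keys[par] <- if (nzchar(keys[par]))
        paste(keys[par], keys[chi], sep = "\r") else keys[chi]
    }
    norm <- function(k) paste(sort(strsplit(k, "\r", fixed = TRUE)[[1]]),
                              collapse = "|")
    seen <- character(0)
    for (v in (n_tip + 1L):(n_tip + tr$Nnode)) {
      ck <- norm(keys[v])
      if (ck %in% seen) next       # guard against duplicate clades
      bump(clade_counts, ck)
      kids <- ckids[[as.character(v)]]
      parts <- sort(vapply(kids, function(w) norm(keys[w]), character(1)))
      bump(split_counts, paste(ck, paste(parts, collapse = " + "), sep = " -> "))
      seen <- c(seen, ck)
    }
  }
  n <- length(sample)
  cl <- ls(clade_counts)
  clades <- data.frame(clade = cl,
                       freq = vapply(cl, get, numeric(1), envir = clade_counts) / n,
                       row.names = NULL)
  sp <- ls(split_counts)
  sp_clade <- sub(" -> .*$", "", sp)
  splits <- data.frame(
    clade = sp_clade,
    split = sub("^.* -> ", "", sp),
    prob = vapply(sp, get, numeric(1), envir = split_counts) /
      vapply(sp_clade, get, numeric(1), envir = clade_counts),
    row.names = NULL)
  structure(list(clades = clades, splits = splits, n_trees = n),
            class = "ccp_table")
}
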