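# All generators are pure functions of (parameters, seed): they run inside
# with_seed() and leave the caller's RNG state untouched.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# species-branch labels indexed by the branch's child node id
.branch_labels <- function(stree) {
  c(stree$tip.label, .node_labels(stree))
}

#' Simulate a dated species tree
#'
#' Forward birth-death simulation from a single lineage, observed at the
#' first passage to `n_taxa` extant lineages (observation time drawn
#' uniformly within the next inter-event wait); extinct lineages are pruned,
#' so the returned tree is ultrametric with all leaves at age 0 and distinct
#' internal node ages. Runs that go extinct are discarded and redrawn.
#'
#' @param n_taxa Number of surviving leaves (>= 2).
#' @param birth,death Speciation and extinction rates, `birth > death >= 0`.
#' @param seed Integer seed; the same seed reproduces the tree byte for byte.
#' @return A rooted ultrametric `phylo` tree with tips `s1..s<n>`.
#' @export
simulate_species_tree <- function(n_taxa, birth, death, seed) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  with_seed(seed, {
    repeat {
      tr <- .sim_bd_once(n_taxa, birth, death)
      if (!is.null(tr)) return(tr)
    }
  })
}

.sim_bd_once <- function(n, birth, death) {
  t_birth <- 0; t_death <- NA_real_; child1 <- NA_integer_; child2 <- NA_integer_
  alive <- 1L; t <- 0
  repeat {
    k <- length(alive)
    wait <- stats::rexp(1, k * (birth + death))
    t <- t + wait
    who <- alive[sample.int(k, 1)]
    if (stats::runif(1) < birth / (birth + death)) {
      id1 <- length(t_birth) + 1L; id2 <- id1 + 1L
      t_birth[c(id1, id2)] <- t; t_death[c(id1, id2)] <- NA
      child1[c(id1, id2)] <- NA; child2[c(id1, id2)] <- NA
      t_death[who] <- t; child1[who] <- id1; child2[who] <- id2
      alive <- c(setdiff(alive, who), id1, id2)
      if (length(alive) == n) {
        present <- t + stats::rexp(1, n * (birth + death)) * stats::runif(1)
        break
      }
    } else {
      t_death[who] <- t
      alive <- setdiff(alive, who)
      if (!length(alive)) return(NULL)
    }
  }
  is_alive <- seq_along(t_birth) %in% alive
  leaf_name <- character(length(t_birth))
  leaf_name[alive] <- paste0("s", seq_len(n))
  rec <- function(i) {
    if (is.na(child1[i])) {
      if (!is_alive[i]) return(NULL)
      return(list(str = leaf_name[i], time = present))
    }
    a <- rec(child1[i]); b <- rec(child2[i])
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    tb <- t_death[i]
    list(str = paste0("(", a$str, ":", sprintf("%.12g", a$time - tb), ",",
                      b$str, ":", sprintf("%.12g", b$time - tb), ")"),
         time = tb)
  }
  r <- rec(1L)
  ape::read.tree(text = paste0(r$str, ";"))
}

#' Simulate a gene history with duplications, transfers and losses
#'
#' One gene lineage enters at the species-tree root and descends the dated
#' species tree. Along each species branch, duplication, transfer and loss
#' events fire as independent Poisson processes in time; a transfer copies
#' the lineage into a uniformly chosen other species branch alive at the
#' event time; losses terminate lineages; surviving lineages bifurcate at
#' speciations. With `replace = TRUE` a transfer also deletes the gene
#' copies resident on the recipient branch (replacement transfer).
#'
#' @param stree Dated species tree (rooted ultrametric `phylo`).
#' @param dup_rate,transfer_rate,loss_rate Event rates per lineage per unit
#'   time (>= 0).
#' @param seed Integer seed.
#' @param replace Replacement-transfer semantics (default `FALSE`).
#' @return An object of class `gene_history`: list with `tree` (a `phylo`
#'   with internal labels `g<id>`, branch lengths in time units; `NULL` if
#'   all lineages were lost), `events` (data frame: kind, gene_node, donor,
#'   recipient, age), `leaf_species` (named map leaf -> species) and
#'   `params`. Gene leaves are labeled `<species>_<copy>`.
#' @export
simulate_gene_history <- function(stree, dup_rate, transfer_rate, loss_rate,
                                  seed, replace = FALSE) {
  if (any(c(dup_rate, transfer_rate, loss_rate) < 0)) stop("rates must be >= 0")
  ages <- .validate_dated_tree(stree)
  with_seed(seed, .sim_genes(stree, ages, dup_rate, transfer_rate, loss_rate,
                             replace))
}

.sim_genes <- function(stree, ages, dr, tr, lr, replace) {
  n_tip <- length(stree$tip.label)
  blab <- .branch_labels(stree)
  root <- n_tip + 1L
  kids <- function(v) stree$edge[stree$edge[, 1] == v, 2]
  branch_top <- function(v) ages[stree$edge[stree$edge[, 2] == v, 1]]
  # branches alive strictly within (a, a) moment: child age < a < parent age
  alive_at <- function(a) {
    v <- stree$edge[, 2]
    v[ages[v] < a & ages[stree$edge[, 1]] > a]
  }
  total_rate <- dr + tr + lr
  # gene node records
  g_age <- numeric(0); g_kind <- character(0); g_branch <- integer(0)
  g_kids <- list(); g_label <- character(0)
  new_node <- function(age, kind, branch) {
    g_age[length(g_age) + 1L] <<- age
    g_kind[length(g_kind) + 1L] <<- kind
    g_branch[length(g_branch) + 1L] <<- branch
    g_kids[[length(g_kids) + 1L]] <<- integer(0)
    g_label[length(g_label) + 1L] <<- ""
    length(g_age)
  }
  ev <- list()
  add_event <- function(kind, node, donor, recipient, age)
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, gene_node = node, donor = donor,
      recipient = recipient, age = age, stringsAsFactors = FALSE)
  # active lineages: parent gene node, species branch, current age, next event age
  act_parent <- integer(0); act_branch <- integer(0)
  act_age <- numeric(0); act_ev <- numeric(0)
  spawn <- function(parent, branch, age) {
    wait <- if (total_rate > 0) stats::rexp(1, total_rate) else Inf
    i <- length(act_parent) + 1L
    act_parent[i] <<- parent; act_branch[i] <<- branch
    act_age[i] <<- age; act_ev[i] <<- age - wait
  }
  drop_lineage <- function(i) {
    keep <- setdiff(seq_along(act_parent), i)
    act_parent <<- act_parent[keep]; act_branch <<- act_branch[keep]
    act_age <<- act_age[keep]; act_ev <<- act_ev[keep]
  }
  copy_count <- stats::setNames(integer(n_tip), stree$tip.label)
  # gene root: enters at species root node and speciates immediately
  groot <- new_node(ages[root], "speciation", root)
  add_event("speciation", groot, blab[root], NA, ages[root])
  for (v in kids(root)) spawn(groot, v, ages[root])
  while (length(act_parent)) {
    bottom <- ages[act_branch]
    action <- pmax(act_ev, bottom)
    i <- which(action == max(action))[1]   # oldest first; ties by index
    par <- act_parent[i]; b <- act_branch[i]
    if (act_ev[i] > bottom[i]) {
      a <- act_ev[i]
      u <- stats::runif(1) * total_rate
      if (u < dr) {                        # duplication
        nd <- new_node(a, "duplication", b)
        g_kids[[par]] <- c(g_kids[[par]], nd)
        add_event("duplication", nd, blab[b], NA, a)
        drop_lineage(i)
        spawn(nd, b, a); spawn(nd, b, a)
      } else if (u < dr + tr) {            # transfer
        cand <- setdiff(alive_at(a), b)
        if (length(cand)) {
          rcp <- cand[sample.int(length(cand), 1)]
          nd <- new_node(a, "transfer", b)
          g_kids[[par]] <- c(g_kids[[par]], nd)
          add_event("transfer", nd, blab[b], blab[rcp], a)
          gone <- i
          if (replace) {
            res <- which(act_branch == rcp)
            for (j in res) add_event("loss", NA, blab[rcp], NA, a)
            gone <- c(i, res)
          }
          drop_lineage(gone)
          spawn(nd, b, a); spawn(nd, rcp, a)
        } else {                           # no contemporaneous recipient
          act_age[i] <- a
          wait <- stats::rexp(1, total_rate)
          act_ev[i] <- a - wait
        }
      } else {                             # loss
        add_event("loss", NA, blab[b], NA, a)
        drop_lineage(i)
      }
    } else {                               # reaches bottom node of branch
      if (b <= n_tip) {                    # gene leaf
        copy_count[b] <- copy_count[b] + 1L
        nd <- new_node(0, "leaf", b)
        g_label[nd] <- paste0(stree$tip.label[b], "_", copy_count[b])
        g_kids[[par]] <- c(g_kids[[par]], nd)
        drop_lineage(i)
      } else {                             # speciation
        nd <- new_node(ages[b], "speciation", b)
        g_kids[[par]] <- c(g_kids[[par]], nd)
        add_event("speciation", nd, blab[b], NA, ages[b])
        drop_lineage(i)
        for (v in kids(b)) spawn(nd, v, ages[b])
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(0), gene_node = integer(0),
               donor = character(0), recipient = character(0),
               age = numeric(0))
  events$gene_node <- ifelse(is.na(events$gene_node), NA_character_,
                             paste0("g", events$gene_node))
  # prune non-surviving lineages, collapse single-child chains
  survives <- function(i) {
    if (g_kind[i] == "leaf") return(TRUE)
    any(vapply(g_kids[[i]], survives, logical(1)))
  }
  rec <- function(i) {
    if (g_kind[i] == "leaf")
      return(list(str = g_label[i], age = 0))
    sub <- Filter(function(x) !is.null(x), lapply(g_kids[[i]], rec))
    if (!length(sub)) return(NULL)
    if (length(sub) == 1L) return(sub[[1]])
    parts <- vapply(sub, function(s)
      paste0(s$str, ":", sprintf("%.12g", g_age[i] - s$age)), character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")g", i),
         age = g_age[i])
  }
  r <- rec(groot)
  tree <- NULL
  n_leaves <- sum(g_kind == "leaf")
  if (!is.null(r) && n_leaves >= 2)
    tree <- ape::read.tree(text = paste0(r$str, ";"))
  leaf_species <- stats::setNames(
    stree$tip.label[g_branch[g_kind == "leaf"]], g_label[g_kind == "leaf"])
  structure(list(tree = tree, events = events, leaf_species = leaf_species,
                 n_leaves = n_leaves,
                 params = list(dup_rate = dr, transfer_rate = tr,
                               loss_rate = lr, replace = replace)),
            class = "gene_history")
}

#' Map gene-copy leaf labels to species
#'
#' Gene leaves are labeled `<species>_<copy>`; this strips the copy suffix.
#'
#' @param labels Character vector of gene leaf labels.
#' @export
gene_leaf_species <- function(labels) sub("_[0-9]+$", "", labels)

#' Halophilic stationary frequencies
#'
#' An acidic-biased ("salt-in" proteome style) frequency vector: the total
#' frequency of D+E is set to `de_total` (default 0.22) and of K+R to
#' `kr_total` (default 0.06), each split proportionally to the base model's
#' frequencies; the remaining mass is distributed over the other residues
#' proportionally to the base model.
#'
#' @param model Base [substitution_model()] (20-state).
#' @param de_total,kr_total Target total frequencies of acidic and basic
#'   residues.
#' @return Named frequency vector summing to 1.
#' @export
halophilic_frequencies <- function(model, de_total = 0.22, kr_total = 0.06) {
  stopifnot(identical(model$alphabet, AA_STATES))
  pi <- model$pi
  de <- c("D", "E"); kr <- c("K", "R")
  rest <- setdiff(AA_STATES, c(de, kr))
  out <- pi
  out[de] <- pi[de] / sum(pi[de]) * de_total
  out[kr] <- pi[kr] / sum(pi[kr]) * kr_total
  out[rest] <- pi[rest] / sum(pi[rest]) * (1 - de_total - kr_total)
  out / sum(out)
}

#' Draw random sequences from a stationary composition
#'
#' @param n Number of sequences.
#' @param length Sequence length.
#' @param freqs Frequency vector over [AA_STATES] (or another alphabet given
#'   by its names).
#' @param seed Integer seed.
#' @return Character matrix (`n` rows) of residues.
#' @export
sample_root_sequences <- function(n, length, freqs, seed) {
  if (abs(sum(freqs) - 1) > 1e-9 || any(freqs <= 0))
    stop("freqs must be a strictly positive vector summing to 1")
  states <- names(freqs)
  if (is.null(states)) states <- AA_STATES
  with_seed(seed, {
    m <- matrix(sample(states, n * length, TRUE, prob = freqs), nrow = n)
    rownames(m) <- paste0("seq", seq_len(n))
    m
  })
}

#' Simulate a protein alignment along a gene tree
#'
#' The root sequence is drawn from the model's stationary frequencies (or
#' from `halophilic_bias`, in which case a matched rate matrix with those
#' frequencies is used throughout). Each site carries a discrete-gamma rate
#' category drawn at the root and inherited along the tree; child states are
#' sampled directly from the rows of `exp(Q r t)`. Insertions and deletions
#' fire per branch at `indel_rate` per site per unit length with geometric
#' lengths; column bookkeeping maintains the true alignment exactly (indels
#' never re-insert at a previously deleted homologous position), and true
#' ancestral (gapped) sequences are recorded for every internal node.
#'
#' @param gtree Rooted `phylo` gene tree, branch lengths in expected
#'   replacements per site.
#' @param model A [substitution_model()].
#' @param root_length Root sequence length (>= 1).
#' @param indel_rate Indel events per site per unit branch length.
#' @param mean_indel_len Mean geometric indel length.
#' @param halophilic_bias Optional alternative stationary frequency vector.
#' @param seed Integer seed.
#' @return List with `alignment` (leaf rows) and `truth` (class `sim_truth`:
#'   tree with node labels, true ancestral sequences, per-column rate
#'   categories, parameters, seed).
#' @export
simulate_alignment <- function(gtree, model, root_length, indel_rate = 0,
                               mean_indel_len = 3, halophilic_bias = NULL,
                               seed = 1) {
  .check_tree(gtree)
  if (!ape::is.rooted(gtree)) stop("gene tree must be rooted")
  if (root_length < 1) stop("root_length must be >= 1")
  if (!is.null(halophilic_bias))
    model <- substitution_model(model$S, halophilic_bias, model$alpha,
                                model$K, model$alphabet)
  rm <- build_rate_matrix(model)
  rates <- discrete_gamma_rates(model$alpha, model$K)
  K <- model$K
  alpha_states <- model$alphabet
  m <- length(alpha_states)
  with_seed(seed, {
    n_tip <- length(gtree$tip.label)
    n_node <- n_tip + gtree$Nnode
    root <- n_tip + 1L
    col_counter <- root_length
    col_order <- seq_len(root_length)
    col_cat <- sample.int(K, root_length, replace = TRUE)
    seq_cols <- vector("list", n_node)
    seq_states <- vector("list", n_node)
    seq_cols[[root]] <- seq_len(root_length)
    seq_states[[root]] <- sample.int(m, root_length, TRUE, prob = rm$pi)
    eo <- ape::reorder.phylo(gtree, "cladewise")   # preorder edges
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chi <- eo$edge[e, 2]; t <- eo$edge.length[e]
      cols <- seq_cols[[par]]; sts <- seq_states[[par]]
      # substitutions, grouped by (category, parent state)
      if (t > 0 && length(cols)) {
        cats <- col_cat[cols]
        for (k in seq_len(K)) {
          sel <- which(cats == k)
          if (!length(sel)) next
          P <- transition_matrix(rm, t * rates[k])
          for (s in unique(sts[sel])) {
            ii <- sel[sts[sel] == s]
            sts[ii] <- sample.int(m, length(ii), TRUE, prob = P[s, ])
          }
        }
      }
      # indels
      if (indel_rate > 0 && t > 0) {
        n_ev <- stats::rpois(1, indel_rate * t * length(cols))
        for (j in seq_len(n_ev)) {
          len <- stats::rgeom(1, 1 / mean_indel_len) + 1L
          if (stats::runif(1) < 0.5 && length(cols)) {      # deletion
            pos <- sample.int(length(cols), 1)
            drop <- pos:min(pos + len - 1L, length(cols))
            cols <- cols[-drop]; sts <- sts[-drop]
          } else {                                          # insertion
            ids <- col_counter + seq_len(len)
            col_counter <- col_counter + len
            col_cat[ids] <- sample.int(K, len, replace = TRUE)
            pos <- sample.int(length(cols) + 1L, 1) - 1L    # insert after pos
            anchor_at <- if (pos > 0) match(cols[pos], col_order)
                         else if (length(cols)) match(cols[1], col_order) - 1L
                         else length(col_order)
            col_order <- append(col_order, ids, after = anchor_at)
            cols <- append(cols, ids, after = pos)
            sts <- append(sts, sample.int(m, len, TRUE, prob = rm$pi),
                          after = pos)
          }
        }
      }
      seq_cols[[chi]] <- cols
      seq_states[[chi]] <- sts
    }
    leaf_cols <- sort(match(unique(unlist(seq_cols[seq_len(n_tip)])), col_order))
    master <- col_order[leaf_cols]
    L <- length(master)
    row_of <- function(v) {
      out <- rep("-", L)
      hit <- match(seq_cols[[v]], master)
      keep <- which(!is.na(hit))
      out[hit[keep]] <- alpha_states[seq_states[[v]][keep]]
      out
    }
    aln <- t(vapply(seq_len(n_tip), row_of, character(L)))
    rownames(aln) <- gtree$tip.label
    gtree$node.label <- .node_labels(gtree)
    anc <- t(vapply((n_tip + 1L):n_node, row_of, character(L)))
    rownames(anc) <- gtree$node.label
    truth <- structure(list(tree = gtree, ancestors = anc,
                            site_category = col_cat[master],
                            col_ids = master,
                            params = list(root_length = root_length,
                                          indel_rate = indel_rate,
                                          mean_indel_len = mean_indel_len,
                                          alpha = model$alpha, K = K,
                                          halophilic = !is.null(halophilic_bias)),
                            seed = seed),
                       class = "sim_truth")
    list(alignment = aln, truth = truth)
  })
}

#' Simulate a salt-stability transition curve
#'
#' Folded fraction `f(c) = 1 / (1 + exp(-(c - mf_half) / width))` —
#' increasing with salt concentration, as halophilic proteins unfold at low
#' salt — plus Gaussian noise clamped to `[0, 1]`.
#'
#' @param mf_half True transition midpoint (M).
#' @param width Transition width (M, > 0).
#' @param concentrations Strictly increasing concentration grid (M).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param salt Salt name annotation.
#' @return An object of class `stability_curve`: data frame with columns
#'   `concentration` and `fraction`; attributes `salt` and `true_mf_half`.
#' @export
simulate_stability_curve <- function(mf_half, width, concentrations,
                                     noise_sd = 0, seed = 1, salt = "KCl") {
  if (width <= 0) stop("width must be > 0")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  f <- 1 / (1 + exp(-(concentrations - mf_half) / width))
  if (noise_sd > 0)
    f <- with_seed(seed, pmin(1, pmax(0, f + stats::rnorm(length(f), 0, noise_sd))))
  structure(data.frame(concentration = concentrations, fraction = f),
            salt = salt, true_mf_half = mf_half, true_width = width,
            class = c("stability_curve", "data.frame"))
}
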