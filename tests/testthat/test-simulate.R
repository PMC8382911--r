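test_that("species-tree simulation is deterministic and well formed", {
  st <- simulate_species_tree(2, 1, 0, seed = 10)
  expect_equal(length(st$tip.label), 2)
  expect_true(ape::is.ultrametric(st))
  a <- ape::write.tree(simulate_species_tree(7, 1, 0.4, seed = 99))
  b <- ape::write.tree(simulate_species_tree(7, 1, 0.4, seed = 99))
  expect_identical(a, b)
  st2 <- simulate_species_tree(10, 1, 0.5, seed = 3)
  ages <- node_ages(st2)
  internal <- ages[11:19]
  expect_equal(anyDuplicated(internal), 0L)
  expect_error(simulate_species_tree(1, 1, 0, 1), "n_taxa")
  expect_error(simulate_species_tree(4, 1, 2, 1), "birth > death")
})

test_that("Yule sojourn times match the 1/k expectation", {
  n_rep <- 1500
  soj <- matrix(NA_real_, n_rep, 4)     # sojourns with k = 2..5 lineages
  for (i in seq_len(n_rep)) {
    st <- simulate_species_tree(6, 1, 0, seed = 20000 + i)
    a <- sort(node_ages(st)[7:11], decreasing = TRUE)
    soj[i, ] <- -diff(a)                # age gap between k-th and (k+1)-th split
  }
  for (k in 2:5) {
    x <- soj[, k - 1]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 1 / k), 3 * se)
  }
})

test_that("gene histories honor degenerate rate settings", {
  st <- simulate_species_tree(6, 1, 0.3, seed = 12)
  st$node.label <- haloasr:::.node_labels(st)
  gh0 <- simulate_gene_history(st, 0, 0, 0, seed = 5)
  expect_equal(sort(gh0$tree$tip.label), sort(paste0(st$tip.label, "_1")))
  expect_true(all(gh0$events$kind == "speciation"))
  g <- gh0$tree
  g$tip.label <- gene_leaf_species(g$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(st), ape::unroot(g))), 0)
  ghL <- simulate_gene_history(st, 0, 0, 0.6, seed = 6)
  expect_true(all(gene_leaf_species(names(ghL$leaf_species)) %in% st$tip.label))
  expect_false(any(ghL$events$kind %in% c("duplication", "transfer")))
})

test_that("transfer counts match the Poisson expectation on lineage time", {
  st <- simulate_species_tree(6, 1, 0, seed = 42)
  tr_rate <- 0.15
  n_rep <- 400
  diffs <- vapply(seq_len(n_rep), function(i) {
    gh <- simulate_gene_history(st, 0, tr_rate, 0, seed = 5000 + i)
    n_t <- sum(gh$events$kind == "transfer")
    n_t - tr_rate * sum(gh$tree$edge.length)
  }, numeric(1))
  se <- sd(diffs) / sqrt(n_rep)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("event lists are structurally consistent with the gene tree", {
  st <- simulate_species_tree(8, 1, 0.4, seed = 2)
  st$node.label <- haloasr:::.node_labels(st)
  gh <- simulate_gene_history(st, 0.1, 0.1, 0.1, seed = 7)
  expect_equal(gh$n_leaves, length(gh$leaf_species))
  if (!is.null(gh$tree)) {
    expect_equal(length(gh$tree$tip.label), gh$n_leaves)
    # every bifurcating internal node is backed by exactly one S/D/T record
    internal <- gh$tree$node.label[nzchar(gh$tree$node.label)]
    recs <- gh$events$gene_node[gh$events$kind != "loss"]
    expect_true(all(internal %in% recs))
    expect_equal(anyDuplicated(stats::na.omit(recs)), 0L)
    # loss records never appear as surviving nodes
    expect_true(all(is.na(gh$events$gene_node[gh$events$kind == "loss"])))
  }
  ev1 <- simulate_gene_history(st, 0.1, 0.1, 0.1, seed = 7)$events
  expect_identical(ev1, gh$events)          # determinism
})

test_that("sequence simulation respects degenerate branch and indel settings", {
  tr <- tree4()
  m <- lg_model()
  flat <- tr; flat$edge.length[] <- 0
  sim0 <- simulate_alignment(flat, m, 40, seed = 1)
  expect_true(all(apply(sim0$alignment, 2, function(x) length(unique(x)) == 1)))
  sim1 <- simulate_alignment(tr, m, 60, indel_rate = 0, seed = 2)
  expect_equal(ncol(sim1$alignment), 60)
  expect_false(any(sim1$alignment == "-"))
  expect_equal(nrow(sim1$truth$ancestors), tr$Nnode)
  expect_equal(ncol(sim1$truth$ancestors), ncol(sim1$alignment))
  a <- simulate_alignment(tr, m, 50, indel_rate = 0.1, seed = 9)
  b <- simulate_alignment(tr, m, 50, indel_rate = 0.1, seed = 9)
  expect_identical(a$alignment, b$alignment)
  expect_identical(a$truth$ancestors, b$truth$ancestors)
})

test_that("evolved sequences match the matrix-exponential divergence", {
  m <- poisson_model(K = 1)
  t <- 0.3
  tr <- ape::read.tree(text = sprintf("(a:0,b:%f);", t))
  sim <- simulate_alignment(tr, m, 20000, seed = 13)
  p_diff <- mean(sim$alignment["a", ] != sim$alignment["b", ])
  rm <- build_rate_matrix(m)
  P <- transition_matrix(rm, t)
  expected <- 1 - sum(rm$pi * diag(P))
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(p_diff - expected), 3 * se)
})

test_that("long root draws converge to the stationary composition", {
  m <- lg_model()
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  sim <- simulate_alignment(tr, m, 1e5, seed = 77)
  obs <- table(factor(sim$alignment["a", ], levels = AA_STATES))
  p <- chisq.test(obs, p = m$pi)$p.value
  expect_gt(p, 0.01)
  # halophilic bias shifts composition as configured
  hf <- halophilic_frequencies(m)
  expect_equal(sum(hf[c("D", "E")]), 0.22, tolerance = 1e-12)
  expect_equal(sum(hf[c("K", "R")]), 0.06, tolerance = 1e-12)
  expect_equal(sum(hf), 1, tolerance = 1e-12)
  simh <- simulate_alignment(tr, m, 1e4, halophilic_bias = hf, seed = 78)
  comp <- table(factor(simh$alignment["a", ], levels = AA_STATES)) / 1e4
  expect_gt(sum(comp[c("D", "E")]), 0.19)
  expect_lt(sum(comp[c("K", "R")]), 0.09)
})

test_that("stability curves follow the logistic contract", {
  cv <- simulate_stability_curve(0.5, 0.1, seq(0, 2, 0.25))
  expect_equal(cv$fraction[which.min(abs(cv$concentration - 0.5))], 0.5)
  expect_false(is.unsorted(cv$fraction))
  cv2 <- simulate_stability_curve(0.3, 0.05, seq(0, 4, 0.2))
  expect_gt(cv2$fraction[which.min(abs(cv2$concentration - 3.8))], 0.999)
  noisy1 <- simulate_stability_curve(0.5, 0.1, seq(0, 2, 0.25),
                                     noise_sd = 0.05, seed = 4)
  noisy2 <- simulate_stability_curve(0.5, 0.1, seq(0, 2, 0.25),
                                     noise_sd = 0.05, seed = 4)
  expect_identical(noisy1, noisy2)
  expect_true(all(noisy1$fraction >= 0 & noisy1$fraction <= 1))
  expect_error(simulate_stability_curve(0.5, 0, 0:3), "width")
  expect_error(simulate_stability_curve(0.5, 0.1, c(1, 1, 2)), "increasing")
})
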