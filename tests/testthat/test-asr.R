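test_that("marginal posteriors are certain for identical tips at tiny distance", {
  tr <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  aln <- matrix("A", 2, 1, dimnames = list(c("a", "b"), NULL))
  pr <- marginal_profiles(tr, aln, lg_model())
  expect_equal(unname(pr$prob[[1]]["A", 1]), 1, tolerance = 1e-6)
  expect_equal(unname(pr$map[1, 1]), "A")
})

test_that("symmetric conflict yields a 50/50 posterior and first-state MAP", {
  m <- two_state_model()
  tr <- ape::read.tree(text = "(a:0.5,b:0.5);")
  aln <- matrix(c("A", "R"), 2, 1, dimnames = list(c("a", "b"), NULL))
  pr <- marginal_profiles(tr, aln, m)
  expect_equal(unname(pr$prob[[1]][, 1]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(pr$map[1, 1]), "A")   # tie broken by state order
  expect_gte(pr$n_map_ties, 1)
})

test_that("marginal posteriors equal brute-force enumeration on small trees", {
  set.seed(33)
  for (rep in 1:3) {
    model <- four_state_model(alpha = 1.2, K = if (rep == 1) 1 else 2,
                              seed = 50 + rep)
    tr <- tree4()
    aln <- random_alignment(tr$tip.label, 5, model$alphabet, gap_prob = 0.2)
    pr <- marginal_profiles(tr, aln, model)
    n_tip <- length(tr$tip.label)
    for (v in seq_len(tr$Nnode)) {
      for (j in seq_len(ncol(aln))) {
        bf <- brute_force_marginals(tr, aln[, j], model, n_tip + v)
        expect_equal(unname(pr$prob[[v]][, j]), bf, tolerance = 1e-10)
      }
    }
  }
})

test_that("posterior vectors sum to one at every node and column", {
  m <- lg_model(alpha = 0.8)
  tr <- tree5()
  aln <- random_alignment(tr$tip.label, 30, AA_STATES, gap_prob = 0.1)
  pr <- marginal_profiles(tr, aln, m)
  for (v in pr$nodes)
    expect_equal(unname(colSums(pr$prob[[v]])), rep(1, 30), tolerance = 1e-9)
  expect_equal(unname(pr$pp),
               unname(t(vapply(pr$nodes, function(v) apply(pr$prob[[v]], 2, max),
                               numeric(30)))), tolerance = 1e-12)
})

test_that("Fitch gap inference matches brute-force parsimony", {
  tr <- tree4()
  # all leaves present -> all ancestors present
  aln_all <- matrix("A", 4, 2, dimnames = list(tr$tip.label, NULL))
  gp <- infer_gap_states(aln_all, tr)
  expect_true(all(gp$presence))
  expect_equal(gp$score, c(0L, 0L))
  # presence in exactly one leaf of a 4-leaf tree -> root gap
  aln1 <- matrix("-", 4, 1, dimnames = list(tr$tip.label, NULL))
  aln1["a", 1] <- "K"
  gp1 <- infer_gap_states(aln1, tr)
  expect_false(gp1$presence[5, 1])           # root (node 5) inferred absent
  oracle <- brute_force_gap_root_states(tr, setNames(aln1[, 1] != "-",
                                                     rownames(aln1)))
  expect_equal(gp1$score[1], oracle$score)
  expect_equal(oracle$root_states, 0L)
  # random patterns on a 5-leaf tree: score equals enumeration minimum
  tr5 <- tree5()
  set.seed(71)
  for (i in 1:12) {
    pres <- setNames(runif(5) > 0.5, tr5$tip.label)
    alnr <- matrix(ifelse(rep(pres, 1), "A", "-"), 5, 1,
                   dimnames = list(tr5$tip.label, NULL))
    gpr <- infer_gap_states(alnr, tr5)
    expect_equal(gpr$score[1], brute_force_gap_score(tr5, pres))
    # ambiguity resolved as "present": root state must be among MP-optimal
    bf <- brute_force_gap_root_states(tr5, pres)
    root_state <- as.integer(gpr$presence[6, 1])
    if (length(bf$root_states) == 2) expect_equal(root_state, 1L)
    else expect_equal(root_state, bf$root_states)
  }
})

test_that("Dollo mode places a single origin at the MRCA of present leaves", {
  tr <- tree5()   # (((a,b),c),(d,e))
  aln <- matrix("-", 5, 1, dimnames = list(tr$tip.label, NULL))
  aln[c("a", "c"), 1] <- "A"
  gp <- infer_gap_states(aln, tr, mode = "dollo")
  pres <- gp$presence[, 1]
  expect_true(pres[["nd7"]])                 # mrca(a, c)
  expect_false(pres[["nd6"]])                # root above the origin
  expect_true(pres[["nd8"]])                 # on the path to a
  expect_false(pres[["nd9"]])                # ancestor of d,e
})

test_that("composing ancestors substitutes gaps over MAP states", {
  tr <- tree4()
  m <- lg_model()
  sim <- simulate_alignment(scale_tree_height(tr, 0.2), m, 50,
                            indel_rate = 0.1, seed = 31)
  pr <- marginal_profiles(sim$truth$tree, sim$alignment, m)
  gp <- infer_gap_states(sim$alignment, sim$truth$tree)
  anc <- compose_ancestors(pr, gp)
  expect_equal(dim(anc), dim(pr$map))
  for (nd in rownames(anc)) {
    gap_here <- !gp$presence[nd, ]
    expect_true(all(anc[nd, gap_here] == "-"))
    expect_equal(anc[nd, !gap_here], pr$map[nd, !gap_here])
  }
  # all-present node: pure MAP states
  aln_all <- matrix("A", 4, 3, dimnames = list(tr$tip.label, NULL))
  pr2 <- marginal_profiles(tr, aln_all, m)
  gp2 <- infer_gap_states(aln_all, tr)
  expect_equal(compose_ancestors(pr2, gp2), pr2$map)
})

test_that("replacement counting excludes gapped columns", {
  expect_equal(count_replacements("ACDE", "ACDE"), 0)
  expect_equal(count_replacements("ACD-", "ACE-"), 1)
  expect_equal(count_replacements("A-DE", "ACD-"), 0)
  expect_equal(count_replacements(c("A", "C"), c("C", "A")), 2)
  expect_error(count_replacements("AC", "ACD"), "equal length")
})

test_that("well-identified fraction uses a strict threshold", {
  fake <- structure(list(
    pp = matrix(c(1, 0.95, 0.9, 0.2), 1, 4, dimnames = list("n1", NULL)),
    nodes = "n1"), class = "ancestral_profiles")
  expect_equal(well_identified_fraction(fake, "n1"), 0.5)  # 0.9 not counted
  fake$pp[1, ] <- 1
  expect_equal(well_identified_fraction(fake, "n1"), 1)
  expect_error(well_identified_fraction(fake, "nope"), "unknown node")
})

test_that("empirical and Poisson models disagree at only a minority of sites", {
  st <- simulate_species_tree(8, 1, 0.3, seed = 44)
  gt <- scale_tree_height(st, 0.4)
  m <- lg_model()
  sim <- simulate_alignment(gt, m, 150, seed = 45)
  pr_lg <- marginal_profiles(sim$truth$tree, sim$alignment, m)
  pr_po <- marginal_profiles(sim$truth$tree, sim$alignment, poisson_model())
  n_diff <- sum(pr_lg$map != pr_po$map)
  frac <- n_diff / length(pr_lg$map)
  expect_gte(n_diff, 0)
  expect_lt(frac, 0.2)    # method choice moves only a small minority of sites
})
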