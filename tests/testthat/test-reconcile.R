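test_that("time slicing yields one slice per internal node", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  sl2 <- time_slice(two)
  expect_equal(length(sl2$slices), 1)
  expect_setequal(sl2$slices[[1]], 1:2)     # both child branches
  st <- simulate_species_tree(7, 1, 0.3, seed = 8)
  sl <- time_slice(st)
  expect_equal(length(sl$slices), 6)        # n - 1 slices
  # every branch's slice set equals the slices intersecting its age interval
  ages <- sl$ages
  parent_age <- rep(Inf, length(ages))
  parent_age[st$edge[, 2]] <- ages[st$edge[, 1]]
  for (b in st$edge[, 2]) {
    in_slices <- which(vapply(seq_along(sl$slices), function(k)
      b %in% sl$slices[[k]], logical(1)))
    expected <- which(vapply(seq_along(sl$slices), function(k) {
      up <- sl$boundaries[k]; lo <- sl$boundaries[k + 1]
      ages[b] <= lo + 1e-12 && parent_age[b] >= up - 1e-12
    }, logical(1)))
    expect_identical(in_slices, expected)
    expect_identical(in_slices, min(in_slices):max(in_slices))  # contiguous
  }
  tied <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_error(time_slice(tied), "jitter")
})

test_that("congruent gene trees reconcile at zero cost with only speciations", {
  st <- simulate_species_tree(5, 1, 0, seed = 3)
  st$node.label <- haloasr:::.node_labels(st)
  gh <- simulate_gene_history(st, 0, 0, 0, seed = 1)
  sc <- reconcile_dtl(time_slice(st), gh$tree)
  expect_equal(sc$cost, 0)
  expect_equal(unname(event_counts(sc)), c(0, 0, 0, 4))
})

test_that("DP minimal cost equals exhaustive scenario enumeration", {
  set.seed(17)
  n_checked <- 0
  for (rep in 1:10) {
    st <- simulate_species_tree(sample(3:4, 1), 1, 0.2, seed = 300 + rep)
    st$node.label <- haloasr:::.node_labels(st)
    gh <- simulate_gene_history(st, 0.3, 0.4, 0.3, seed = 400 + rep)
    if (is.null(gh$tree) || length(gh$tree$tip.label) > 4) next
    costs <- if (rep %% 2) dtl_costs() else dtl_costs(2, 3, 1.5)
    sc <- reconcile_dtl(time_slice(st), gh$tree, costs)
    bf <- brute_force_dtl(st, gh$tree, costs)
    expect_equal(sc$cost, bf)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
})

test_that("duplication and transfer alternatives are costed correctly", {
  st <- ape::read.tree(text = "((a:1,b:1)x:1,c:2)r;")
  sl <- time_slice(st)
  # one species with two gene copies, otherwise congruent
  g_dup <- ape::read.tree(text = "(((a_1:1,a_2:1):0.5,b_1:1):1,c_1:2);")
  sc <- reconcile_dtl(sl, g_dup)
  expect_equal(sc$cost, brute_force_dtl(st, g_dup, dtl_costs()))
  # a single conflicting clade resolvable by one transfer
  g_tr <- ape::read.tree(text = "((a_1:1,c_1:1):1,b_1:2);")
  costs <- dtl_costs(2, 3, 1)
  sc2 <- reconcile_dtl(sl, g_tr, costs)
  expect_equal(sc2$cost, brute_force_dtl(st, g_tr, costs))
  # cost identity
  cnt <- event_counts(sc2)
  expect_equal(2 * cnt[["D"]] + 3 * cnt[["T"]] + 1 * cnt[["L"]], sc2$cost)
  expect_error(reconcile_dtl(sl, ape::read.tree(text = "((a_1:1,zz_1:1):1,b_1:2);")),
               "unmappable")
})

test_that("transfer-only simulated histories reconcile with only T and S", {
  st <- simulate_species_tree(5, 1, 0, seed = 23)
  st$node.label <- haloasr:::.node_labels(st)
  sl <- time_slice(st)
  found <- 0
  for (s in 1:8) {
    gh <- simulate_gene_history(st, 0, 0.25, 0, seed = 600 + s)
    if (is.null(gh$tree)) next
    # transfers strictly cheaper than any duplication-loss alternative
    sc <- reconcile_dtl(sl, gh$tree, dtl_costs(dup = 4, transfer = 1, loss = 2))
    expect_true(all(sc$events$kind %in% c("speciation", "transfer", "leaf")))
    found <- found + sum(sc$events$kind == "transfer")
  }
  expect_gt(found, 0)
})

test_that("conditional clade probabilities are frequency ratios", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  ccp <- compute_ccp(rep(list(t1), 100))
  expect_true(all(ccp$clades$freq == 1))
  mixed <- compute_ccp(c(rep(list(t1), 25), rep(list(t2), 75)))
  cd <- mixed$clades
  expect_equal(cd$freq[cd$clade == "c|d"], 0.25)
  expect_equal(cd$freq[cd$clade == "a|b"], 1)
  expect_equal(cd$freq[cd$clade == "a|b|c|d"], 1)    # leaf-set clade always 1
  # split conditionals sum to 1 for every clade
  agg <- tapply(mixed$splits$prob, mixed$splits$clade, sum)
  expect_equal(as.numeric(agg), rep(1, length(agg)), tolerance = 1e-12)
  bad <- ape::read.tree(text = "((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(compute_ccp(list(t1, bad)), "leaf set")
})
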