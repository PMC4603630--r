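test_that("congruent duplication/loss-free trees give the species tree", {
  st <- fix_st3()
  map1 <- c(a = "A", b = "B", c = "C")
  t1 <- insert_loss_leaves(lca_reconcile("((a,b),c);", st, map1), st)
  t2raw <- lca_reconcile("((p,q),s);", st, c(p = "A", q = "B", s = "C"))
  t2 <- insert_loss_leaves(t2raw, st)
  f <- fix_forest(list(t1, t2), st, c("A:a:p", "B:b:q", "C:c:s"))
  expect_length(f, 1L)
  tr <- f[[1]]
  expect_equal(sum(tr$kind == "dup"), 0L)
  expect_equal(sum(tr$kind == "loss"), 0L)
  ## isomorphic to the species tree: same species multiset, same shape
  expect_setequal(st$name[tr$species], st$name)
  expect_equal(tr$nnode, st$nnode)
})

test_that("one duplicated gene gives a 2-child duplication node", {
  st <- fix_st3()
  trees <- fix_dup2_trees(st)
  f <- fix_forest(trees, st, c("A:a1:p1", "B:b1:q1", "C:c1:s1"))
  tr <- f[[1]]
  d <- which(tr$kind == "dup")
  expect_length(d, 1L)
  expect_length(tr$children[[d]], 2L)
  ## the two children pair each copy with the single partner gene
  kids <- tr$children[[d]]
  expect_setequal(trees[[1]]$name[tr$g1[kids]], c("a1", "a2"))
  expect_equal(unique(trees[[2]]$name[tr$g2[kids]]), "p1")
})

test_that("duplications in both genes give a 4-child duplication node", {
  st <- fix_st3()
  trees <- fix_dup4_trees(st)
  f <- fix_forest(trees, st, c("A:a1:p1", "B:b1:q1", "C:c1:s1"))
  tr <- f[[1]]
  d <- which(tr$kind == "dup")
  expect_length(d, 1L)
  kids <- tr$children[[d]]
  expect_length(kids, 4L)
  pairs <- paste(trees[[1]]$name[tr$g1[kids]], trees[[2]]$name[tr$g2[kids]])
  expect_setequal(pairs, c("a1 p1", "a1 p2", "a2 p1", "a2 p2"))
})

test_that("leaf states: observed 1, unobserved 0, lost extremity ?", {
  st <- fix_st3()
  trees <- fix_dup2_trees(st)
  f <- fix_forest(trees, st, c("A:a1:p1"))
  tr <- f[[1]]
  ext <- which(tr$kind == "extant")
  g <- paste(trees[[1]]$name[tr$g1[ext]], trees[[2]]$name[tr$g2[ext]])
  expect_equal(tr$state[ext][g == "a1 p1"], 1L)
  expect_true(all(tr$state[ext][g != "a1 p1"] == 0L))

  ## lose the partner gene in species B: the pair becomes a "?" loss leaf
  g2 <- paste0("((p1[&&NHX:S=A],*LOSS*[&&NHX:S=B])x2[&&NHX:S=X:D=N],",
               "s1[&&NHX:S=C])r2[&&NHX:S=R:D=N];")
  trees2 <- list(trees[[1]], parse_reconciled_gene_tree(g2, st))
  f2 <- fix_forest(trees2, st, c("A:a1:p1"))
  tr2 <- f2[[1]]
  lb <- which(tr2$kind == "loss" & st$name[tr2$species] == "B")
  expect_length(lb, 1L)
  expect_true(is.na(tr2$state[lb]))
})

test_that("speciation-pair count matches brute-force pair enumeration", {
  set.seed(77)
  st <- toy_species_tree(6)
  for (rep in 1:6) {
    t1 <- simulate_reconciled_family(st, 0.3, 0.3, prefix = "u")
    t2 <- simulate_reconciled_family(st, 0.3, 0.3, prefix = "v")
    sim <- simulate_adjacency_evolution(t1, t2, st, 1, 0.9)
    got <- sum(vapply(sim$forest, function(tr)
      sum(tr$kind %in% c("spec", "extant")), 1L))
    want <- 0L
    for (n1 in seq_len(t1$nnode)) for (n2 in seq_len(t2$nnode)) {
      if (t1$event[n1] %in% c("speciation", "extant") &&
          t2$event[n2] %in% c("speciation", "extant") &&
          t1$species[n1] == t2$species[n2]) want <- want + 1L
    }
    expect_equal(got, want)
  }
})

test_that("class roots in different species give a forest", {
  st <- fix_st3()
  ## family 2 exists only below X (no C representative, no stem loss):
  ## roots live in different species -> independent components
  g1 <- paste0("((a1[&&NHX:S=A],b1[&&NHX:S=B])x1[&&NHX:S=X:D=N],",
               "c1[&&NHX:S=C])r1[&&NHX:S=R:D=N];")
  g2 <- "(p1[&&NHX:S=A],q1[&&NHX:S=B])x2[&&NHX:S=X:D=N];"
  trees <- list(parse_reconciled_gene_tree(g1, st),
                parse_reconciled_gene_tree(g2, st))
  f <- fix_forest(trees, st, c("A:a1:p1", "B:b1:q1"))
  expect_length(f, 1L)  # one maximal pair, at species X
  expect_equal(st$name[f[[1]]$species[f[[1]]$root]], "X")

  ## two copies in the data tree at the root species of the shorter tree:
  ## two maximal pairs -> two components
  g3 <- paste0("(((a1[&&NHX:S=A],b1[&&NHX:S=B])x1[&&NHX:S=X:D=N],",
               "(a2[&&NHX:S=A],b2[&&NHX:S=B])x2[&&NHX:S=X:D=N])",
               "dd[&&NHX:S=X:D=Y],c1[&&NHX:S=C])r1[&&NHX:S=R:D=N];")
  trees2 <- list(parse_reconciled_gene_tree(g3, st), trees[[2]])
  f2 <- fix_forest(trees2, st, c("A:a1:p1", "B:b2:q1"))
  expect_length(f2, 2L)
  expect_true(all(vapply(f2, function(tr)
    st$name[tr$species[tr$root]], "") == "X"))
})

test_that("a second same-branch duplication raises a restriction error", {
  st <- fix_st3()
  g1 <- paste0("(((a1[&&NHX:S=A],a2[&&NHX:S=A])d2[&&NHX:S=A:D=Y],",
               "a3[&&NHX:S=A])d1[&&NHX:S=A:D=Y],b1[&&NHX:S=B])",
               "x1[&&NHX:S=X:D=N];")
  g2 <- "(p1[&&NHX:S=A],q1[&&NHX:S=B])x2[&&NHX:S=X:D=N];"
  trees <- list(parse_reconciled_gene_tree(g1, st),
                parse_reconciled_gene_tree(g2, st))
  cls <- structure(list(id = 1L, tree1 = 1L, tree2 = 2L,
                        root1 = trees[[1]]$root, root2 = trees[[2]]$root),
                   class = "adjacency_class")
  expect_error(build_adjacency_forest(cls, trees, st),
               class = "adjevol_restriction_error")
})
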