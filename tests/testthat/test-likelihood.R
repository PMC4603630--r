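test_that("a tree whose leaves are all undetermined has likelihood one", {
  st <- fix_st3()
  ## both families survive only on one side each: every leaf pair is lost
  g1 <- paste0("((a1[&&NHX:S=A],*LOSS*[&&NHX:S=B])x1[&&NHX:S=X:D=N],",
               "*LOSS*[&&NHX:S=C])r1[&&NHX:S=R:D=N];")
  g2 <- paste0("((*LOSS*[&&NHX:S=A],q1[&&NHX:S=B])x2[&&NHX:S=X:D=N],",
               "s1[&&NHX:S=C])r2[&&NHX:S=R:D=N];")
  trees <- list(parse_reconciled_gene_tree(g1, st),
                parse_reconciled_gene_tree(g2, st))
  f <- fix_forest(trees, st)
  expect_true(all(vapply(f[[1]]$kind, function(k)
    k %in% c("spec", "loss"), TRUE)))
  expect_equal(forest_loglik(f, st, model_params(1.3, 0.42)), 0)
})

test_that("pruning equals brute-force enumeration (incl. duplications)", {
  fx <- random_small_adj_trees(30, seed = 11)
  st4 <- fix_st3()
  hand <- c(
    lapply(1:5, function(i) {
      set.seed(300 + i)
      randomize_states(fix_forest(fix_dup4_trees(st4), st4)[[1]])
    }),
    lapply(1:5, function(i) {
      set.seed(400 + i)
      randomize_states(fix_forest(fix_dup2_trees(st4), st4)[[1]])
    }))
  cases <- c(lapply(fx$trees, function(tr) list(tr = tr, st = fx$species)),
             lapply(hand, function(tr) list(tr = tr, st = st4)))
  p <- model_params(0.8, 0.7)
  ndup4 <- 0
  for (cs in cases) {
    tr <- cs$tr
    en <- enum_loglik_posterior(tr, cs$st, p)
    expect_equal(forest_loglik(tr, cs$st, p), en$loglik,
                 tolerance = 1e-10)
    up <- upward_likelihood(tr, cs$st, p)
    dn <- downward_likelihood(tr, cs$st, p, up)
    pp <- posterior_presence(tr, up, dn)
    expect_lt(max(abs(pp$posterior - en$posterior[pp$node])), 1e-10)
    ndup4 <- ndup4 + sum(vapply(which(tr$kind == "dup"), function(i)
      length(tr$children[[i]]) == 4L, TRUE))
  }
  expect_gt(ndup4, 0)
})

test_that("duplication-free forests reduce to textbook pruning", {
  set.seed(21)
  st <- toy_species_tree(6)
  for (i in 1:10) {
    t1 <- simulate_reconciled_family(st, 0, 0.3, prefix = "da")
    t2 <- simulate_reconciled_family(st, 0, 0.3, prefix = "db")
    sim <- simulate_adjacency_evolution(t1, t2, st, 1.2, 0.8)
    for (tr in sim$forest) {
      p <- model_params(1.2, 0.8)
      expect_equal(forest_loglik(tr, st, p), textbook_pruning(tr, st, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("forest log-likelihood is additive and order-invariant", {
  fx <- random_small_adj_trees(6, seed = 13)
  p <- model_params(1, 0.6)
  f <- structure(fx$trees, class = "adj_forest")
  ll <- forest_loglik(f, fx$species, p)
  expect_equal(forest_loglik(structure(c(fx$trees, fx$trees),
                                       class = "adj_forest"),
                             fx$species, p), 2 * ll, tolerance = 1e-12)
  perm <- structure(fx$trees[c(4, 1, 6, 2, 5, 3)], class = "adj_forest")
  expect_equal(forest_loglik(perm, fx$species, p), ll, tolerance = 1e-12)
  ## batched evaluation equals per-tree evaluation
  singles <- sum(vapply(fx$trees, function(tr)
    upward_likelihood(tr, fx$species, p)$loglik, 1))
  expect_equal(ll, singles, tolerance = 1e-12)
  expect_error(forest_loglik(list(), fx$species, p), "empty")
})

test_that("posteriors: observed leaves, near-certain roots, symmetry", {
  st <- fix_st3()
  map1 <- c(a = "A", b = "B", c = "C")
  t1 <- insert_loss_leaves(lca_reconcile("((a,b),c);", st, map1), st)
  t2 <- insert_loss_leaves(
    lca_reconcile("((p,q),s);", st, c(p = "A", q = "B", s = "C")), st)
  ## short branches, all leaves present: root posterior near one
  st_short <- st
  st_short$length[!is.na(st_short$parent)] <- 0.02
  f <- fix_forest(list(t1, t2), st_short, c("A:a:p", "B:b:q", "C:c:s"))
  tr <- f[[1]]
  p <- model_params(1, 0.5)
  up <- upward_likelihood(tr, st_short, p)
  dn <- downward_likelihood(tr, st_short, p, up)
  pp <- posterior_presence(tr, up, dn)
  en <- enum_loglik_posterior(tr, st_short, p)
  expect_lt(max(abs(pp$posterior - en$posterior[pp$node])), 1e-10)
  expect_gt(pp$posterior[pp$node == tr$root], 0.99)
  ## observed leaves keep their observed state as posterior
  ext <- which(tr$kind == "extant")
  expect_equal(pp$posterior[match(ext, pp$node)], as.numeric(tr$state[ext]))

  ## mirror symmetry: equal-length cherry with identical data on both sides
  stm <- parse_species_tree("(A:0.2,B:0.2)R;")
  m1 <- insert_loss_leaves(
    lca_reconcile("(a,b);", stm, c(a = "A", b = "B")), stm)
  m2 <- insert_loss_leaves(
    lca_reconcile("(p,q);", stm, c(p = "A", q = "B")), stm)
  fm <- fix_forest(list(m1, m2), stm, c("A:a:p", "B:b:q"))
  trm <- fm[[1]]
  upm <- upward_likelihood(trm, stm, p)
  dnm <- downward_likelihood(trm, stm, p, upm)
  ppm <- posterior_presence(trm, upm, dnm)
  leafp <- ppm$posterior[ppm$kind == "extant"]
  expect_equal(leafp[1], leafp[2], tolerance = 1e-12)
})

test_that("impossible data (zero-length conflict) raises a clear error", {
  stz <- parse_species_tree("(A:0,B:0)R;")
  m1 <- insert_loss_leaves(
    lca_reconcile("(a,b);", stz, c(a = "A", b = "B")), stz)
  m2 <- insert_loss_leaves(
    lca_reconcile("(p,q);", stz, c(p = "A", q = "B")), stz)
  f <- fix_forest(list(m1, m2), stz, "A:a:p")  # present in A, absent in B
  tr <- f[[1]]
  p <- model_params(1, 0.5)
  up <- upward_likelihood(tr, stz, p)
  dn <- downward_likelihood(tr, stz, p, up)
  expect_error(posterior_presence(tr, up, dn), "zero total likelihood")
})
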