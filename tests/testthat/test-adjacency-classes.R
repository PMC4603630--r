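# independent pairwise homology check: explicit ancestor-species sets,
# against which the package's union-find clustering is compared
oracle_equiv <- function(adj, trees, species, gidx) {
  anc_species <- function(tree, node) {
    gt <- trees[[tree]]
    out <- integer(0)
    while (!is.na(node)) {
      out <- c(out, gt$species[node])
      node <- gt$parent[node]
    }
    unique(out)
  }
  m <- nrow(adj)
  t1 <- unname(gidx$tree[adj$gene1]); n1 <- unname(gidx$node[adj$gene1])
  t2 <- unname(gidx$tree[adj$gene2]); n2 <- unname(gidx$node[adj$gene2])
  common_sp <- function(ta, na, tb, nb) {
    if (ta != tb) return(integer(0))
    gt <- trees[[ta]]
    ## species of common gene-tree ancestors of the two leaves
    path <- function(x) {
      out <- integer(0)
      while (!is.na(x)) { out <- c(out, x); x <- gt$parent[x] }
      out
    }
    unique(gt$species[intersect(path(na), path(nb))])
  }
  M <- diag(TRUE, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    ok <- length(intersect(common_sp(t1[i], n1[i], t1[j], n1[j]),
                           common_sp(t2[i], n2[i], t2[j], n2[j]))) > 0 ||
      length(intersect(common_sp(t1[i], n1[i], t2[j], n2[j]),
                       common_sp(t2[i], n2[i], t1[j], n1[j]))) > 0
    M[i, j] <- ok
  }
  ## transitive closure
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M > 0)) break
    M <- M2
  }
  apply(M, 1, function(r) min(which(r)))
}

test_that("a single adjacency forms a singleton class rooted at tree roots", {
  st <- fix_st3()
  trees <- fix_dup2_trees(st)
  adj <- fix_adj_set("A:a1:p1")
  cls <- build_adjacency_classes(adj, trees, st)
  expect_length(cls, 1L)
  expect_equal(cls[[1]]$root1, trees[[1]]$root)
  expect_equal(cls[[1]]$root2, trees[[2]]$root)
})

test_that("adjacencies in sister species with same-species ancestors merge", {
  st <- fix_st3()
  trees <- fix_dup2_trees(st)
  adj <- fix_adj_set(c("A:a1:p1", "B:b1:q1"))
  cls <- build_adjacency_classes(adj, trees, st)
  expect_length(cls, 1L)
  expect_equal(nrow(cls[[1]]$members), 2L)
})

test_that("adjacencies between unrelated family pairs stay separate", {
  st <- fix_st3()
  trees <- c(fix_dup2_trees(st), fix_dup4_trees(st))
  ## rename genes of the second pair to keep ids unique
  for (i in 3:4) {
    trees[[i]]$name <- paste0("z", trees[[i]]$name)
  }
  adj <- fix_adj_set(c("A:a1:p1", "A:za1:zp1"))
  cls <- build_adjacency_classes(adj, trees, st)
  expect_length(cls, 2L)
})

test_that("an adjacency with a gene in no tree is rejected", {
  st <- fix_st3()
  trees <- fix_dup2_trees(st)
  adj <- fix_adj_set("A:a1:nosuch")
  expect_error(build_adjacency_classes(adj, trees, st), "absent")
})

test_that("a tandem same-family adjacency gets distinct class roots", {
  st <- fix_st3()
  gt <- parse_reconciled_gene_tree(
    "(a1[&&NHX:S=A],a2[&&NHX:S=A])d[&&NHX:S=A:D=Y];", st)
  adj <- fix_adj_set("A:a1:a2")
  cls <- build_adjacency_classes(adj, list(gt), st)
  expect_length(cls, 1L)
  expect_true(cls[[1]]$root1 != cls[[1]]$root2)
  expect_setequal(gt$name[c(cls[[1]]$root1, cls[[1]]$root2)], c("a1", "a2"))
})

test_that("union-find classes equal the brute-force transitive closure", {
  set.seed(31)
  st <- toy_species_tree(6)
  for (rep in 1:5) {
    ds <- simulate_dataset(sim_config(
      species = st, n_classes = 6, dup_rate = 0.25, loss_rate = 0.25,
      kappa = 1, root_prob = 0.9, drop_fraction = 0,
      seed = 1000 + rep))
    adj <- ds$observed
    if (nrow(adj) < 2 || nrow(adj) > 50) next
    gidx <- adjevol:::.gene_index(ds$trees)
    want <- oracle_equiv(adj, ds$trees, st, gidx)
    cls <- build_adjacency_classes(adj, ds$trees, st)
    got <- integer(nrow(adj))
    key <- adjevol:::.adj_key(adj)
    for (cl in cls) {
      mk <- adjevol:::.adj_key(cl$members)
      got[match(mk, key)] <- cl$id
    }
    ## same partition (up to label permutation)
    expect_equal(length(unique(want)), length(unique(got)))
    expect_true(all(tapply(got, want, function(v) length(unique(v))) == 1))
    ## partition property: class sizes sum to the adjacency count
    expect_equal(sum(vapply(cls, function(c) nrow(c$members), 1L)),
                 nrow(adj))
    ## every member has one extremity under each root
    for (cl in cls) {
      g1 <- ifelse(cl$members$flipped, cl$members$gene2, cl$members$gene1)
      g2 <- ifelse(cl$members$flipped, cl$members$gene1, cl$members$gene2)
      for (i in seq_along(g1)) {
        expect_true(adjevol:::.gt_is_desc(
          ds$trees[[cl$tree1]], cl$root1, unname(gidx$node[g1[i]])))
        expect_true(adjevol:::.gt_is_desc(
          ds$trees[[cl$tree2]], cl$root2, unname(gidx$node[g2[i]])))
      }
    }
  }
})
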