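# Hand-built fixtures shared across tests.

# species tree ((A,B)X,C)R with assorted branch lengths
fix_st3 <- function() parse_species_tree("((A:0.3,B:0.2)X:0.25,C:0.4)R;")

# two gene trees that both duplicate on the branch to species A, giving a
# duplication node with four children in the tree of possible adjacencies
fix_dup4_trees <- function(st = fix_st3()) {
  g1 <- paste0("(((a1[&&NHX:S=A],a2[&&NHX:S=A])d1[&&NHX:S=A:D=Y],",
               "b1[&&NHX:S=B])x1[&&NHX:S=X:D=N],c1[&&NHX:S=C])",
               "r1[&&NHX:S=R:D=N];")
  g2 <- paste0("(((p1[&&NHX:S=A],p2[&&NHX:S=A])e1[&&NHX:S=A:D=Y],",
               "q1[&&NHX:S=B])x2[&&NHX:S=X:D=N],s1[&&NHX:S=C])",
               "r2[&&NHX:S=R:D=N];")
  list(parse_reconciled_gene_tree(g1, st),
       parse_reconciled_gene_tree(g2, st))
}

# single-duplication counterpart: only the first family duplicates
fix_dup2_trees <- function(st = fix_st3()) {
  g1 <- paste0("(((a1[&&NHX:S=A],a2[&&NHX:S=A])d1[&&NHX:S=A:D=Y],",
               "b1[&&NHX:S=B])x1[&&NHX:S=X:D=N],c1[&&NHX:S=C])",
               "r1[&&NHX:S=R:D=N];")
  g2 <- paste0("((p1[&&NHX:S=A],q1[&&NHX:S=B])x2[&&NHX:S=X:D=N],",
               "s1[&&NHX:S=C])r2[&&NHX:S=R:D=N];")
  list(parse_reconciled_gene_tree(g1, st),
       parse_reconciled_gene_tree(g2, st))
}

fix_forest <- function(trees, st, present = character(0)) {
  cls <- structure(list(id = 1L, tree1 = 1L, tree2 = 2L,
                        root1 = trees[[1]]$root, root2 = trees[[2]]$root),
                   class = "adjacency_class")
  f <- build_adjacency_forest(cls, trees, st)
  adj <- fix_adj_set(present)
  assign_leaf_states(f, adj, trees, st)
}

# adjacency set from "species:gene1:gene2" strings
fix_adj_set <- function(specs) {
  if (!length(specs)) {
    out <- data.frame(species = character(0), gene1 = character(0),
                      gene2 = character(0), stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(specs, ":", fixed = TRUE))
    out <- data.frame(species = parts[, 1],
                      gene1 = pmin(parts[, 2], parts[, 3]),
                      gene2 = pmax(parts[, 2], parts[, 3]),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("adjacency_set", "data.frame")
  out
}

# random 0/1 leaf states drawn in place (loss leaves stay undetermined)
randomize_states <- function(tr, p = 0.5) {
  ext <- which(tr$kind == "extant")
  tr$state[ext] <- stats::rbinom(length(ext), 1, p)
  tr
}
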