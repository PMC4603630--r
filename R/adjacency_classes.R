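## Homology classes of extant adjacencies. Two adjacencies are equivalent
## when, for some pairing of their extremities, each pair of extremity genes
## has a common gene-tree ancestor and the two ancestors live in the same
## species. Classes are the transitive closure (union-find with orientation
## parity); the class roots are the most ancient distinct common ancestors of
## the members' extremities, which reduces the likelihood problem to a pair
## of gene subtrees.

.gt_depths <- function(gt) .node_depths(gt)

.gt_lca <- function(gt, depth, a, b) {
  while (depth[a] > depth[b]) a <- gt$parent[a]
  while (depth[b] > depth[a]) b <- gt$parent[b]
  while (a != b) { a <- gt$parent[a]; b <- gt$parent[b] }
  a
}

## interval test on the shared species ancestor chain: the species of the
## common gene-tree ancestors of (na, nb) range from S(lca) up to the tree
## root's species; two such intervals must intersect.
.side_interval <- function(gt, depth, st, na, nb) {
  lca <- .gt_lca(gt, depth, na, nb)
  c(st$depth[gt$species[gt$root]], st$depth[gt$species[lca]])
}

#' Cluster extant adjacencies into homology classes
#'
#' Partitions the adjacency set by the homology equivalence relation and
#' attaches to each class its pair of root ancestors (the most ancient
#' distinct common ancestors of all extremities), with a consistent
#' orientation for every member.
#'
#' @param adjacencies An \code{adjacency_set} (see
#'   \code{\link{load_gene_orders}}).
#' @param trees List of loss-annotated \code{recon_tree}s covering every
#'   adjacency gene exactly once.
#' @param species The \code{species_tree}.
#' @return A list of \code{adjacency_class} objects: each has \code{tree1},
#'   \code{tree2} (indices into \code{trees}), \code{root1}, \code{root2}
#'   (gene-tree node ids), and \code{members} (the adjacencies, with a
#'   \code{flipped} flag telling which extremity descends from
#'   \code{root1}).
#' @export
build_adjacency_classes <- function(adjacencies, trees, species) {
  st <- species
  m <- nrow(adjacencies)
  if (m == 0L) return(list())
  gidx <- .gene_index(trees)
  miss <- setdiff(c(adjacencies$gene1, adjacencies$gene2), names(gidx$tree))
  if (length(miss))
    stop("adjacency gene absent from all gene trees: ", miss[1])
  depths <- lapply(trees, .gt_depths)
  t1 <- unname(gidx$tree[adjacencies$gene1])
  n1 <- unname(gidx$node[adjacencies$gene1])
  t2 <- unname(gidx$tree[adjacencies$gene2])
  n2 <- unname(gidx$node[adjacencies$gene2])

  ## union-find with orientation parity relative to the set representative
  par <- seq_len(m); rnk <- integer(m); flip <- integer(m)
  find <- function(i) {
    while (par[i] != i) i <- par[i]
    i
  }
  parity <- function(i) {
    f <- 0L
    while (par[i] != i) { f <- (f + flip[i]) %% 2L; i <- par[i] }
    f
  }
  union <- function(i, j, rel) {
    ri <- find(i); rj <- find(j)
    if (ri == rj) return(invisible())
    pij <- (parity(i) + parity(j) + rel) %% 2L
    if (rnk[ri] < rnk[rj]) { tmp <- ri; ri <- rj; rj <- tmp }
    par[rj] <<- ri
    flip[rj] <<- pij
    if (rnk[ri] == rnk[rj]) rnk[ri] <<- rnk[ri] + 1L
    invisible()
  }

  cond <- function(ta, na_, tb, nb_, tc, nc_, td, nd_) {
    ## side pairing (na_, nb_) in the same tree, (nc_, nd_) in the same tree
    if (ta != tb || tc != td) return(FALSE)
    i1 <- .side_interval(trees[[ta]], depths[[ta]], st, na_, nb_)
    i2 <- .side_interval(trees[[tc]], depths[[tc]], st, nc_, nd_)
    i1[1] <= i2[2] && i2[1] <= i1[2]
  }

  ## group candidate pairs by unordered tree pair to avoid the full O(m^2)
  grp <- paste(pmin(t1, t2), pmax(t1, t2))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-1]) {
      i <- idx[a]
      for (b in seq_len(a - 1L)) {
        j <- idx[b]
        if (cond(t1[i], n1[i], t1[j], n1[j], t2[i], n2[i], t2[j], n2[j])) {
          union(i, j, 0L)
        } else if (cond(t1[i], n1[i], t2[j], n2[j], t2[i], n2[i], t1[j],
                        n1[j])) {
          union(i, j, 1L)
        }
      }
    }
  }

  reps <- vapply(seq_len(m), find, 1L)
  out <- list()
  cid <- 0L
  for (r in unique(reps)) {
    cid <- cid + 1L
    members <- which(reps == r)
    fl <- vapply(members, parity, 1L) == 1L
    s1_tree <- ifelse(fl, t2[members], t1[members])
    s1_node <- ifelse(fl, n2[members], n1[members])
    s2_tree <- ifelse(fl, t1[members], t2[members])
    s2_node <- ifelse(fl, n1[members], n2[members])
    T1 <- s1_tree[1]; T2 <- s2_tree[1]
    if (any(s1_tree != T1) || any(s2_tree != T2))
      warning("orientation parity conflict in class ", cid,
              "; keeping first-found orientation")
    if (T1 != T2) {
      root1 <- trees[[T1]]$root
      root2 <- trees[[T2]]$root
    } else {
      gt <- trees[[T1]]; dp <- depths[[T1]]
      a <- Reduce(function(x, y) .gt_lca(gt, dp, x, y), s1_node)
      b <- Reduce(function(x, y) .gt_lca(gt, dp, x, y), s2_node)
      cc <- .gt_lca(gt, dp, a, b)
      if (cc != a && cc != b) {
        k <- gt$children[[cc]]
        root1 <- k[vapply(k, function(x) .gt_is_desc(gt, x, a), TRUE)][1]
        root2 <- k[vapply(k, function(x) .gt_is_desc(gt, x, b), TRUE)][1]
      } else {
        root1 <- a; root2 <- b
      }
      if (root1 == root2)
        stop("degenerate self-class: identical root ancestors")
    }
    mem <- data.frame(
      species = adjacencies$species[members],
      gene1 = adjacencies$gene1[members],
      gene2 = adjacencies$gene2[members],
      flipped = fl, stringsAsFactors = FALSE)
    cl <- list(id = cid, tree1 = T1, tree2 = T2, root1 = root1,
               root2 = root2, members = mem)
    class(cl) <- "adjacency_class"
    out[[cid]] <- cl
  }
  out
}

## TRUE iff node a is ancestor-or-self of node b in gene tree gt
.gt_is_desc <- function(gt, a, b) {
  while (!is.na(b)) {
    if (b == a) return(TRUE)
    b <- gt$parent[b]
  }
  FALSE
}

#' @export
print.adjacency_class <- function(x, ...) {
  cat("adjacency_class", x$id, ": trees (", x$tree1, ",", x$tree2,
      "),", nrow(x$members), "member adjacencies\n")
  invisible(x)
}
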