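## Trees of possible adjacencies. Nodes are same-species pairs of gene-tree
## nodes: speciation pairs (kind "spec"), extant pairs ("extant", the
## observable leaves), duplication nodes ("dup", 2 or 4 children, attached to
## their parent by a zero-duration bookkeeping edge and spanning the full
## species branch with the date-averaged kernels), and loss leaves ("loss",
## undetermined state "?", likelihood factor 1). The incoming edge duration
## of a node is the species-tree branch length of its species.

.restriction_error <- function(msg) {
  stop(errorCondition(msg, class = c("adjevol_restriction_error", "error")))
}

#' Build the forest of possible adjacencies for a class
#'
#' Enumerates all same-species pairs of speciation/extant nodes under the
#' class roots, connects them with duplication nodes and loss leaves per the
#' model's construction rule, and returns one tree per maximal pair (a
#' forest when the class roots live in different species, treated as
#' independent components).
#'
#' @param cls An \code{adjacency_class}.
#' @param trees The list of loss-complete \code{recon_tree}s the class
#'   refers to.
#' @param species The \code{species_tree}.
#' @return A list of \code{adj_tree} objects (class \code{adj_forest}).
#'   Each \code{adj_tree} is a flat node table: \code{kind}, \code{species},
#'   \code{g1}, \code{g2} (gene-tree node ids), \code{parent},
#'   \code{children}, \code{state} (leaf states; \code{NA} until assigned,
#'   loss leaves stay \code{NA}), and a post-order traversal.
#' @export
build_adjacency_forest <- function(cls, trees, species) {
  st <- species
  G1 <- trees[[cls$tree1]]; G2 <- trees[[cls$tree2]]
  same_tree <- cls$tree1 == cls$tree2

  ## candidate nodes (speciation / extant) under each root, and the species
  ## of their speciation ancestors up to the root (inclusive)
  cand <- function(gt, root) {
    nodes <- which(vapply(seq_len(gt$nnode), function(n)
      gt$event[n] %in% c("speciation", "extant") && .gt_is_desc(gt, root, n),
      TRUE))
    anc <- lapply(nodes, function(n) {
      sps <- integer(0)
      q <- n
      repeat {
        if (gt$event[q] %in% c("speciation", "extant"))
          sps <- c(sps, gt$species[q])
        if (q == root) break
        q <- gt$parent[q]
      }
      sps
    })
    list(nodes = nodes, anc = anc)
  }
  c1 <- cand(G1, cls$root1)
  c2 <- cand(G2, cls$root2)

  ## maximal pairs: same species, and no speciation-ancestor pair shares a
  ## species other than the pair's own
  roots <- list()
  for (a in seq_along(c1$nodes)) for (b in seq_along(c2$nodes)) {
    n1 <- c1$nodes[a]; n2 <- c2$nodes[b]
    if (G1$species[n1] != G2$species[n2]) next
    s <- G1$species[n1]
    shared <- intersect(c1$anc[[a]], c2$anc[[b]])
    if (length(shared) == 1L && shared == s)
      roots[[length(roots) + 1L]] <- c(n1, n2)
  }

  build_component <- function(r1, r2) {
    n <- 0L
    kind <- character(0); sp <- integer(0); g1 <- integer(0); g2 <- integer(0)
    parent <- integer(0); children <- list()
    add <- function(k, s, a, b, p) {
      n <<- n + 1L
      kind[n] <<- k; sp[n] <<- s; g1[n] <<- a; g2[n] <<- b; parent[n] <<- p
      children[[n]] <<- integer(0)
      if (!is.na(p)) children[[p]] <<- c(children[[p]], n)
      n
    }
    copies <- function(gt, d) {
      kk <- gt$children[[d]]
      for (k in kk) if (gt$event[k] == "duplication")
        .restriction_error(paste0(
          "two duplications between speciations in gene tree (class ",
          cls$id, ")"))
      kk
    }
    pair_child <- function(p1, p2, s, parentid) {
      if (G1$event[p1] == "loss" || G2$event[p2] == "loss") {
        add("loss", s, p1, p2, parentid)
      } else {
        rec(p1, p2, parentid)
      }
    }
    rec <- function(j1, j2, parentid) {
      s <- G1$species[j1]
      if (.is_leaf(st, s)) return(add("extant", s, j1, j2, parentid))
      id <- add("spec", s, j1, j2, parentid)
      for (sc in st$children[[s]]) {
        cc1 <- G1$children[[j1]][vapply(G1$children[[j1]], function(k)
          G1$species[k] == sc, TRUE)]
        cc2 <- G2$children[[j2]][vapply(G2$children[[j2]], function(k)
          G2$species[k] == sc, TRUE)]
        d1 <- G1$event[cc1] == "duplication"
        d2 <- G2$event[cc2] == "duplication"
        if (G1$event[cc1] == "loss" || G2$event[cc2] == "loss") {
          add("loss", sc, cc1, cc2, id)
        } else if (!d1 && !d2) {
          pair_child(cc1, cc2, sc, id)
        } else {
          did <- add("dup", sc, cc1, cc2, id)
          k1 <- if (d1) copies(G1, cc1) else cc1
          k2 <- if (d2) copies(G2, cc2) else cc2
          for (p1 in k1) for (p2 in k2) pair_child(p1, p2, sc, did)
        }
      }
      id
    }
    rec(r1, r2, NA_integer_)
    tr <- list(nnode = n, kind = kind, species = sp, g1 = g1, g2 = g2,
               parent = parent, children = children,
               state = rep(NA_integer_, n), root = 1L)
    tr$order <- .postorder(tr)
    class(tr) <- "adj_tree"
    tr
  }

  forest <- lapply(roots, function(r) build_component(r[1], r[2]))
  for (i in seq_along(forest)) {
    attr(forest[[i]], "class_id") <- cls$id
    attr(forest[[i]], "component") <- i
    attr(forest[[i]], "tree1") <- cls$tree1
    attr(forest[[i]], "tree2") <- cls$tree2
  }
  class(forest) <- "adj_forest"
  forest
}

#' Attach observed presence/absence states to the forest leaves
#'
#' Extant pairs become present (1) when the gene pair is an observed
#' adjacency and absent (0) otherwise; loss leaves keep the undetermined
#' state (NA, likelihood factor one).
#'
#' @param forest An \code{adj_forest} (or a single \code{adj_tree}).
#' @param adjacencies An \code{adjacency_set} of observed extant
#'   adjacencies.
#' @param trees The gene-tree list the forest refers to.
#' @param species The \code{species_tree}.
#' @return The forest with leaf states filled in.
#' @export
assign_leaf_states <- function(forest, adjacencies, trees, species) {
  single <- inherits(forest, "adj_tree")
  if (single) forest <- list(forest)
  keys <- .adj_key(adjacencies)
  for (i in seq_along(forest)) {
    tr <- forest[[i]]
    G1 <- trees[[attr(tr, "tree1")]]
    G2 <- trees[[attr(tr, "tree2")]]
    for (nd in which(tr$kind == "extant")) {
      a <- G1$name[tr$g1[nd]]
      b <- G2$name[tr$g2[nd]]
      key <- paste(species$name[tr$species[nd]], min(a, b), max(a, b),
                   sep = "\r")
      tr$state[nd] <- as.integer(key %in% keys)
    }
    forest[[i]] <- tr
  }
  if (single) forest[[1]] else structure(forest, class = "adj_forest")
}

#' @export
print.adj_tree <- function(x, ...) {
  cat("adj_tree:", sum(x$kind == "spec"), "speciation pairs,",
      sum(x$kind == "dup"), "duplication nodes,",
      sum(x$kind == "extant"), "extant pairs,",
      sum(x$kind == "loss"), "loss leaves\n")
  invisible(x)
}

#' Dump an adjacency forest as text (for inspection and debugging)
#'
#' @param forest An \code{adj_forest}.
#' @param trees Gene-tree list.
#' @param species The \code{species_tree}.
#' @param path Optional file path.
#' @return Character vector of lines, invisibly when written.
#' @export
dump_adjacency_forest <- function(forest, trees, species, path = NULL) {
  lines <- character(0)
  for (tr in forest) {
    G1 <- trees[[attr(tr, "tree1")]]
    G2 <- trees[[attr(tr, "tree2")]]
    lines <- c(lines, sprintf("# class %s component %s",
                              attr(tr, "class_id"), attr(tr, "component")))
    for (i in seq_len(tr$nnode)) {
      lines <- c(lines, paste(
        i, ifelse(is.na(tr$parent[i]), 0L, tr$parent[i]), tr$kind[i],
        species$name[tr$species[i]],
        ifelse(is.na(tr$g1[i]), ".", G1$name[tr$g1[i]]),
        ifelse(is.na(tr$g2[i]), ".", G2$name[tr$g2[i]]),
        ifelse(is.na(tr$state[i]), "?", tr$state[i]),
        sep = "\t"))
    }
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

## structural hash used to batch identically shaped trees in the likelihood
.adj_tree_hash <- function(tr) {
  paste(paste0(tr$kind, tr$species, ".",
               ifelse(is.na(tr$parent), 0L, tr$parent)), collapse = ";")
}
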