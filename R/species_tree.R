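## Species trees are stored as flat node tables indexed by integer node id.
## Branch lengths are in expected adjacency gain/loss events per adjacency
## per branch (the generator below is normalized to one expected event per
## unit length at stationarity).

#' Parse a rooted binary species tree from a Newick string
#'
#' Reads a Newick species tree, validates that it is rooted and strictly
#' binary, and assigns deterministic post-order names \code{ANC1..ANCk} to
#' unnamed internal nodes so that repeated runs label ancestral species
#' identically.
#'
#' @param text Newick string (or a file path when \code{file = TRUE}).
#' @param file Logical; if \code{TRUE}, \code{text} is a path to read.
#' @param default_length Branch length substituted when the Newick string
#'   carries none. Lengths are expected adjacency events per adjacency.
#' @return An object of class \code{species_tree}: a list with vectors
#'   \code{name}, \code{parent}, \code{length}, \code{depth}, a list
#'   \code{children}, the \code{root} id and a post-order traversal
#'   \code{order}.
#' @examples
#' st <- parse_species_tree("(A:1.0,B:1.0)R;")
#' st$name
#' @export
parse_species_tree <- function(text, file = FALSE, default_length = NA_real_) {
  ph <- if (file) ape::read.tree(file = text) else ape::read.tree(text = text)
  if (is.null(ph)) stop("could not parse Newick species tree")
  as_species_tree(ph, default_length = default_length)
}

#' Convert an ape phylo object into a species_tree
#'
#' @param ph An \code{ape::phylo} object (rooted, binary).
#' @param default_length Length used for branches without one.
#' @return A \code{species_tree} object.
#' @export
as_species_tree <- function(ph, default_length = NA_real_) {
  if (!inherits(ph, "phylo")) stop("expected an ape 'phylo' object")
  ntip <- length(ph$tip.label)
  nnode <- ntip + ph$Nnode
  parent <- rep(NA_integer_, nnode)
  children <- vector("list", nnode)
  for (i in seq_len(nnode)) children[[i]] <- integer(0)
  len <- rep(NA_real_, nnode)
  for (e in seq_len(nrow(ph$edge))) {
    p <- ph$edge[e, 1]; c <- ph$edge[e, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
    len[c] <- if (!is.null(ph$edge.length)) ph$edge.length[e] else NA_real_
  }
  len[is.na(len) & !is.na(parent)] <- default_length
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("species tree must have a single root")
  nk <- vapply(children, length, 1L)
  if (any(!(nk %in% c(0L, 2L))))
    stop("species tree must be strictly binary (non-binary node found)")
  name <- c(ph$tip.label, rep(NA_character_, ph$Nnode))
  if (!is.null(ph$node.label)) {
    lab <- ph$node.label
    lab[lab == ""] <- NA_character_
    name[(ntip + 1):nnode] <- lab
  }
  st <- list(ntip = ntip, nnode = nnode, name = name, parent = parent,
             children = children, length = len, root = root)
  st$order <- .postorder(st)
  ## deterministic post-order auto-naming of unnamed ancestors
  k <- 0L
  for (i in st$order) {
    if (length(children[[i]]) > 0L && is.na(st$name[i])) {
      k <- k + 1L
      st$name[i] <- paste0("ANC", k)
    }
  }
  if (anyDuplicated(st$name)) stop("duplicate node names in species tree")
  if (any(!is.na(st$length) & st$length < 0)) stop("negative branch length")
  st$depth <- .node_depths(st)
  st$index <- stats::setNames(seq_len(nnode), st$name)
  class(st) <- "species_tree"
  st
}

.postorder <- function(tr) {
  out <- integer(0)
  stack <- tr$root
  seen <- integer(0)
  ## iterative post-order (children before parents), left-to-right
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    seen <- c(seen, n)
    stack <- c(stack, tr$children[[n]])
  }
  rev(seen)
}

.node_depths <- function(tr) {
  d <- rep(0L, tr$nnode)
  for (n in rev(tr$order)) {  # pre-order
    p <- tr$parent[n]
    if (!is.na(p)) d[n] <- d[p] + 1L
  }
  d
}

#' Write a species tree to Newick
#'
#' Emits branch lengths with 15 significant digits so that write/parse
#' round-trips preserve lengths to better than 1e-12.
#'
#' @param st A \code{species_tree}.
#' @param path Optional file path; if \code{NULL} the string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_species_tree <- function(st, path = NULL) {
  rec <- function(n) {
    lab <- st$name[n]
    br <- if (is.na(st$length[n])) "" else sprintf(":%.15g", st$length[n])
    if (length(st$children[[n]]) == 0L) return(paste0(lab, br))
    paste0("(", paste(vapply(st$children[[n]], rec, ""), collapse = ","),
           ")", lab, br)
  }
  s <- paste0(rec(st$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", x$ntip, "extant species,", x$nnode - x$ntip,
      "ancestral species, root =", x$name[x$root], "\n")
  invisible(x)
}

## -- small tree utilities (trees are tiny; linear walks are fine) ----------

.sp_id <- function(st, name) {
  i <- st$index[name]
  if (any(is.na(i))) stop("unknown species: ", paste(name[is.na(i)], collapse = ", "))
  unname(i)
}

.is_leaf <- function(st, n) length(st$children[[n]]) == 0L

## TRUE iff a is an ancestor of (or equal to) b
.sp_is_anc <- function(st, a, b) {
  while (!is.na(b)) {
    if (b == a) return(TRUE)
    b <- st$parent[b]
  }
  FALSE
}

.sp_lca <- function(st, a, b) {
  while (st$depth[a] > st$depth[b]) a <- st$parent[a]
  while (st$depth[b] > st$depth[a]) b <- st$parent[b]
  while (a != b) { a <- st$parent[a]; b <- st$parent[b] }
  a
}

## species on the path from a (exclusive) down to b (exclusive); a must be a
## strict ancestor of b. Returned top-down.
.sp_path_between <- function(st, a, b) {
  path <- integer(0)
  n <- st$parent[b]
  while (!is.na(n) && n != a) { path <- c(n, path); n <- st$parent[n] }
  if (is.na(n)) stop("species ", st$name[a], " is not an ancestor of ", st$name[b])
  path
}

## the child of s on the side of descendant d (d must be a strict descendant)
.sp_child_towards <- function(st, s, d) {
  for (c in st$children[[s]]) if (.sp_is_anc(st, c, d)) return(c)
  stop("no child of ", st$name[s], " leads to ", st$name[d])
}

## sibling species of child c under its parent
.sp_sibling <- function(st, c) {
  p <- st$parent[c]
  setdiff(st$children[[p]], c)
}
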