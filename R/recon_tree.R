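## Reconciled gene trees: every node carries a species assignment S(n) and an
## event label (extant leaf, speciation, duplication, loss leaf). The NHX
## dialect used for I/O is [&&NHX:S=<species>:D=<Y|N>] on internal nodes,
## [&&NHX:S=<species>] on leaves, with loss leaves named "*LOSS*".

LOSS_LEAF_NAME <- "*LOSS*"

## ---- raw Newick/NHX recursive-descent parser ------------------------------
## ape drops Newick comments, so NHX node tags are parsed here directly.

.parse_newick_raw <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  pos <- 1L
  n <- 0L
  name <- character(0); len <- numeric(0); comment <- character(0)
  parent <- integer(0); children <- list()

  peek <- function() if (pos <= length(ch)) ch[pos] else ""
  new_node <- function(p) {
    n <<- n + 1L
    name[n] <<- ""; len[n] <<- NA_real_; comment[n] <<- ""
    parent[n] <<- p; children[[n]] <<- integer(0)
    if (!is.na(p)) children[[p]] <<- c(children[[p]], n)
    n
  }
  read_while <- function(stopchars) {
    start <- pos
    while (pos <= length(ch) && !(ch[pos] %in% stopchars)) pos <<- pos + 1L
    if (pos > start) paste(ch[start:(pos - 1L)], collapse = "") else ""
  }
  parse_clade <- function(p) {
    id <- new_node(p)
    if (peek() == "(") {
      repeat {
        pos <<- pos + 1L
        parse_clade(id)
        if (peek() == ",") next
        break
      }
      if (peek() != ")") stop("malformed Newick: expected ')' at position ", pos)
      pos <<- pos + 1L
    }
    name[id] <<- read_while(c("(", ")", ",", ":", ";", "["))
    while (peek() %in% c(":", "[")) {
      if (peek() == ":") {
        pos <<- pos + 1L
        num <- read_while(c("(", ")", ",", ":", ";", "["))
        len[id] <<- as.numeric(num)
      } else {
        pos <<- pos + 1L
        cm <- read_while("]")
        if (peek() != "]") stop("malformed NHX comment (unterminated '[')")
        pos <<- pos + 1L
        comment[id] <<- cm
      }
    }
    id
  }
  root <- parse_clade(NA_integer_)
  if (peek() != ";") stop("malformed Newick: expected terminating ';'")
  list(n = n, name = name, length = len, comment = comment,
       parent = parent, children = children, root = root)
}

.nhx_tags <- function(comment) {
  if (!nzchar(comment)) return(list())
  s <- sub("^&&NHX:?", "", comment)
  if (!nzchar(s)) return(list())
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2L) out[[p[1]]] <- p[2]
  out
}

## ---- recon_tree construction ---------------------------------------------

.finalize_recon <- function(name, species, event, parent, children, length,
                            root) {
  gt <- list(nnode = base::length(name), name = name, species = species,
             event = event, parent = parent, children = children,
             length = length, root = root)
  gt$order <- .postorder(gt)
  auto <- !nzchar(gt$name) | is.na(gt$name)
  gt$name[auto] <- paste0("n", which(auto))
  class(gt) <- "recon_tree"
  gt
}

#' Parse a reconciled gene tree from an NHX string
#'
#' Every node must carry a species tag \code{S=}; internal nodes carry
#' \code{D=Y} (duplication) or \code{D=N} (speciation, the default). Loss
#' leaves are leaves named \code{*LOSS*}. Species assignments and event
#' labels are validated against the species tree.
#'
#' @param text NHX string.
#' @param species A \code{species_tree}.
#' @param strict If \code{TRUE}, require the tree to be loss-complete
#'   (every speciation node's children lie exactly in the two species
#'   children); the default accepts trees whose edges skip species, which
#'   \code{\link{insert_loss_leaves}} can complete.
#' @return A \code{recon_tree}: flat node table with \code{name},
#'   \code{species} (ids into the species tree), \code{event} in
#'   \code{extant, speciation, duplication, loss}, parent/children refs.
#' @export
parse_reconciled_gene_tree <- function(text, species, strict = FALSE) {
  raw <- .parse_newick_raw(text)
  ev <- character(raw$n)
  sp <- integer(raw$n)
  for (i in seq_len(raw$n)) {
    tags <- .nhx_tags(raw$comment[i])
    if (is.null(tags$S)) stop("node without S= species tag (node ", i, ")")
    sp[i] <- .sp_id(species, tags$S)
    if (length(raw$children[[i]]) == 0L) {
      ev[i] <- if (raw$name[i] == LOSS_LEAF_NAME) "loss" else "extant"
    } else {
      ev[i] <- if (identical(tags$D, "Y")) "duplication" else "speciation"
    }
  }
  name <- raw$name
  name[name == LOSS_LEAF_NAME] <- LOSS_LEAF_NAME  # kept verbatim (non-unique)
  gt <- .finalize_recon(name, sp, ev, raw$parent, raw$children, raw$length,
                        raw$root)
  validate_recon_tree(gt, species, strict = strict)
  gt
}

#' Validate a reconciled gene tree against a species tree
#'
#' Checks rootedness, binarity of internal nodes, that extant leaves map to
#' extant species, that species assignments are monotone along edges
#' (child species inside the parent's species subtree), and the event/species
#' consistency rules for speciation and duplication nodes.
#'
#' @param gt A \code{recon_tree}.
#' @param species A \code{species_tree}.
#' @param strict Require loss-completeness (see
#'   \code{\link{parse_reconciled_gene_tree}}).
#' @return \code{gt}, invisibly; errors describe the first violation.
#' @export
validate_recon_tree <- function(gt, species, strict = FALSE) {
  st <- species
  for (i in seq_len(gt$nnode)) {
    kids <- gt$children[[i]]
    if (length(kids) == 0L) {
      if (!(gt$event[i] %in% c("extant", "loss")))
        stop("leaf ", gt$name[i], " has internal event '", gt$event[i], "'")
      if (gt$event[i] == "extant" && !.is_leaf(st, gt$species[i]))
        stop("extant gene ", gt$name[i], " mapped to ancestral species ",
             st$name[gt$species[i]])
      next
    }
    if (length(kids) != 2L)
      stop("internal node ", gt$name[i], " is not binary")
    if (!(gt$event[i] %in% c("speciation", "duplication")))
      stop("internal node ", gt$name[i], " has event '", gt$event[i], "'")
    for (k in kids) {
      if (!.sp_is_anc(st, gt$species[i], gt$species[k]))
        stop("species assignment not monotone on edge ", gt$name[i], " -> ",
             gt$name[k])
    }
    if (gt$event[i] == "speciation") {
      sk <- st$children[[gt$species[i]]]
      if (length(sk) != 2L)
        stop("speciation node ", gt$name[i], " mapped to extant species")
      side <- vapply(kids, function(k) {
        hit <- which(vapply(sk, function(s) .sp_is_anc(st, s, gt$species[k]),
                            TRUE))
        if (length(hit) != 1L)
          stop("speciation child ", gt$name[k],
               " not inside a species child of ", st$name[gt$species[i]])
        hit
      }, 1L)
      if (side[1] == side[2])
        stop("speciation node ", gt$name[i],
             " has both children on the same species side")
      if (strict && any(vapply(kids, function(k) gt$species[k], 1L) !=
                          sk[side]))
        stop("speciation node ", gt$name[i],
             " has children skipping species (tree not loss-complete)")
    } else {
      if (any(vapply(kids, function(k)
        !.sp_is_anc(st, gt$species[i], gt$species[k]), TRUE)))
        stop("duplication node ", gt$name[i], " children outside its species")
    }
  }
  invisible(gt)
}

#' Write a reconciled gene tree as NHX
#'
#' @param gt A \code{recon_tree}.
#' @param species The \code{species_tree} it is reconciled with.
#' @param path Optional file path.
#' @return The NHX string (invisibly when written to file).
#' @export
write_gene_tree <- function(gt, species, path = NULL) {
  rec <- function(n) {
    kids <- gt$children[[n]]
    sp <- species$name[gt$species[n]]
    br <- if (is.na(gt$length[n])) "" else sprintf(":%.15g", gt$length[n])
    if (length(kids) == 0L) {
      nm <- if (gt$event[n] == "loss") LOSS_LEAF_NAME else gt$name[n]
      return(paste0(nm, br, "[&&NHX:S=", sp, "]"))
    }
    d <- if (gt$event[n] == "duplication") "Y" else "N"
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")",
           gt$name[n], br, "[&&NHX:S=", sp, ":D=", d, "]")
  }
  s <- paste0(rec(gt$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @export
print.recon_tree <- function(x, ...) {
  cat("recon_tree:", sum(x$event == "extant"), "extant genes,",
      sum(x$event == "duplication"), "duplications,",
      sum(x$event == "loss"), "losses\n")
  invisible(x)
}

#' Reconcile an unannotated gene tree by LCA mapping
#'
#' Standard last-common-ancestor reconciliation: each internal node is mapped
#' to the species LCA of its children's species; a node is a duplication iff
#' it maps to the same species as one of its children. This minimizes the
#' duplication count for the given rooted topology.
#'
#' @param tree A Newick string or \code{ape::phylo} whose tips are gene ids.
#' @param species A \code{species_tree}.
#' @param species_map Named character vector mapping gene id to extant
#'   species name. If \code{NULL}, leaf NHX \code{S=} tags are used.
#' @return A \code{recon_tree} (without loss annotation; see
#'   \code{\link{insert_loss_leaves}}).
#' @export
lca_reconcile <- function(tree, species, species_map = NULL) {
  st <- species
  if (inherits(tree, "phylo")) tree <- ape::write.tree(tree)
  raw <- .parse_newick_raw(tree)
  sp <- rep(NA_integer_, raw$n)
  ev <- character(raw$n)
  for (i in seq_len(raw$n)) {
    if (length(raw$children[[i]]) == 0L) {
      spname <- if (!is.null(species_map)) {
        if (is.na(species_map[raw$name[i]]))
          stop("no species mapping for gene ", raw$name[i])
        unname(species_map[raw$name[i]])
      } else {
        tags <- .nhx_tags(raw$comment[i])
        if (is.null(tags$S)) stop("leaf ", raw$name[i], " has no species")
        tags$S
      }
      sp[i] <- .sp_id(st, spname)
      if (!.is_leaf(st, sp[i]))
        stop("gene ", raw$name[i], " mapped to ancestral species ", spname)
      ev[i] <- "extant"
    }
  }
  order <- .postorder(raw)
  for (i in order) {
    kids <- raw$children[[i]]
    if (length(kids) == 0L) next
    if (length(kids) != 2L) stop("gene tree is not binary at node ", i)
    sp[i] <- .sp_lca(st, sp[kids[1]], sp[kids[2]])
    ev[i] <- if (sp[i] == sp[kids[1]] || sp[i] == sp[kids[2]])
      "duplication" else "speciation"
  }
  gt <- .finalize_recon(raw$name, sp, ev, raw$parent, raw$children,
                        raw$length, raw$root)
  validate_recon_tree(gt, st)
  gt
}

#' Insert loss leaves so every speciation is explicit
#'
#' For every gene-tree edge whose species path skips intermediate species,
#' speciation nodes are inserted at each intermediate species, each with a
#' loss leaf on the sibling side. A family absent from a whole clade keeps a
#' single loss leaf at the clade stem. The operation is idempotent.
#'
#' @param gt A \code{recon_tree}.
#' @param species A \code{species_tree}.
#' @return A loss-complete \code{recon_tree}.
#' @export
insert_loss_leaves <- function(gt, species) {
  st <- species
  n <- 0L
  name <- character(0); sp <- integer(0); ev <- character(0)
  parent <- integer(0); children <- list(); len <- numeric(0)
  add <- function(nm, s, e, p, l = NA_real_) {
    n <<- n + 1L
    name[n] <<- nm; sp[n] <<- s; ev[n] <<- e; parent[n] <<- p; len[n] <<- l
    children[[n]] <<- integer(0)
    if (!is.na(p)) children[[p]] <<- c(children[[p]], n)
    n
  }
  ## species at which speciation nodes must be inserted above child c
  edge_chain <- function(p_old, c_old) {
    ps <- gt$species[p_old]; cs <- gt$species[c_old]
    if (gt$event[p_old] == "duplication") {
      if (cs == ps) return(integer(0))
      c(ps, .sp_path_between(st, ps, cs))
    } else {
      ai <- .sp_child_towards(st, ps, cs)
      if (cs == ai) return(integer(0))
      c(ai, .sp_path_between(st, ai, cs))
    }
  }
  rec <- function(old, chain, newp) {
    if (length(chain) == 0L) {
      id <- add(gt$name[old], gt$species[old], gt$event[old], newp,
                gt$length[old])
      for (cc in gt$children[[old]]) rec(cc, edge_chain(old, cc), id)
      return(id)
    }
    u <- chain[1]
    cont <- if (length(chain) > 1L) chain[2] else gt$species[old]
    lost <- setdiff(st$children[[u]], .sp_child_towards(st, u, cont))
    id <- add("", u, "speciation", newp)
    rec(old, chain[-1], id)
    add(LOSS_LEAF_NAME, lost, "loss", id)
    id
  }
  rec(gt$root, integer(0), NA_integer_)
  out <- .finalize_recon(name, sp, ev, parent, children, len, 1L)
  validate_recon_tree(out, st, strict = TRUE)
  out
}

#' Check the at-most-one-duplication restriction
#'
#' The model allows at most one duplication node between two consecutive
#' speciation events on any gene lineage. Two duplications in the same
#' species on one lineage (i.e. a duplication whose parent is a duplication
#' in the same species) violate it.
#'
#' @param gt A \code{recon_tree}.
#' @return A list with \code{ok} (logical) and \code{offending} (integer ids
#'   of violating duplication nodes).
#' @export
check_single_dup_constraint <- function(gt) {
  bad <- integer(0)
  for (i in seq_len(gt$nnode)) {
    if (gt$event[i] != "duplication") next
    p <- gt$parent[i]
    if (!is.na(p) && gt$event[p] == "duplication" &&
        gt$species[p] == gt$species[i])
      bad <- c(bad, i)
  }
  list(ok = length(bad) == 0L, offending = bad)
}

## gene-name -> (tree index, node id) lookup across a list of recon trees
.gene_index <- function(trees) {
  tr <- integer(0); nd <- integer(0); nm <- character(0)
  for (ti in seq_along(trees)) {
    gt <- trees[[ti]]
    ext <- which(gt$event == "extant")
    nm <- c(nm, gt$name[ext])
    tr <- c(tr, rep.int(ti, length(ext)))
    nd <- c(nd, ext)
  }
  if (anyDuplicated(nm))
    stop("extant gene ids are not unique across gene trees: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  list(tree = stats::setNames(tr, nm), node = stats::setNames(nd, nm))
}
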