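## Felsenstein pruning on trees of possible adjacencies, extended with
## duplication nodes. A duplication node conditions on the adjacency state at
## the top of its species branch (its attachment edge has zero duration); its
## children are reached through the date-averaged kernels. The inheriting
## child uses P(t); with one duplication the other child uses the averaged
## row N1(t); with two duplications the remaining children use the N11
## kernel. Which child inherits (and, for two duplications, which gene
## duplicated first and where the first-born lineage is transmitted at the
## second duplication) is unknown, so the likelihood averages uniformly over
## all scenarios of the generative process: 2 for one duplication, 16 for
## two.

## scenario table for 4-child duplication nodes: rows are scenarios, columns
## the 4 children in copy order (g1 copy i, g2 copy j) -> 2(i-1)+j; entries
## are kernel slots 1 = inheriting (P(t) from x), 2 = first-born (N11 slot 1),
## 3/4 = second-born (N11 slots 2,3).
.dup4_scenarios <- function() {
  id <- function(i, j) 2L * (i - 1L) + j
  out <- matrix(0L, 0, 4)
  for (g in 1:2) for (i in 1:2) for (j in 1:2) for (c3 in 1:2) {
    slots <- rep(3L, 4)
    M <- id(i, j)
    L <- if (g == 1L) id(3L - i, c3) else id(c3, 3L - j)
    slots[M] <- 1L
    slots[L] <- 2L
    v <- which(slots == 3L)
    slots[v[2]] <- 4L
    out <- rbind(out, slots)
  }
  dimnames(out) <- NULL
  out
}
.DUP4_SCN <- .dup4_scenarios()

.child_contrib <- function(tr, c, Lc, len, kc) {
  if (tr$kind[c] == "dup") Lc
  else Lc %*% .kc_tP(kc, len[tr$species[c]])
}

## core bottom-up pass, vectorized over m trees sharing one structure.
## states: m x nnode matrix of leaf observations (0/1 at extant leaves).
.prune <- function(tr, states, st, kc, prior, keep = FALSE) {
  m <- nrow(states)
  L <- vector("list", tr$nnode)
  logsc <- numeric(m)
  len <- st$length
  for (i in tr$order) {
    k <- tr$kind[i]
    if (k == "extant") {
      s <- states[, i]
      if (anyNA(s)) stop("extant leaf without an assigned state")
      L[[i]] <- cbind(1 - s, s)
      next
    }
    if (k == "loss") {
      L[[i]] <- matrix(1, m, 2)
      next
    }
    if (k == "spec") {
      acc <- matrix(1, m, 2)
      for (c in tr$children[[i]])
        acc <- acc * .child_contrib(tr, c, L[[c]], len, kc)
    } else { # dup
      t <- len[tr$species[i]]
      kk <- tr$children[[i]]
      tP <- .kc_tP(kc, t)
      if (length(kk) == 2L) {
        n1 <- .kc_n1(kc, t)
        acc <- 0.5 * ((L[[kk[1]]] %*% tP) * drop(L[[kk[2]]] %*% n1) +
                        (L[[kk[2]]] %*% tP) * drop(L[[kk[1]]] %*% n1))
      } else if (length(kk) == 4L) {
        nv <- .kc_n11(kc, t)
        PM <- lapply(kk, function(c) L[[c]] %*% tP)
        acc <- matrix(0, m, 2)
        for (srow in seq_len(nrow(.DUP4_SCN))) {
          slots <- .DUP4_SCN[srow, ]
          Lc <- L[[kk[which(slots == 2L)]]]
          V1 <- L[[kk[which(slots == 3L)]]]
          V2 <- L[[kk[which(slots == 4L)]]]
          w <- numeric(m)
          for (zL in 0:1) for (z1 in 0:1) for (z2 in 0:1)
            w <- w + nv[zL + 1, z1 + 1, z2 + 1] *
              Lc[, zL + 1] * V1[, z1 + 1] * V2[, z2 + 1]
          acc <- acc + PM[[which(slots == 1L)]] * w
        }
        acc <- acc / nrow(.DUP4_SCN)
      } else stop("duplication node with ", length(kk), " children")
    }
    sc <- pmax(acc[, 1], acc[, 2])
    sc[sc <= 0 | !is.finite(sc)] <- 1
    acc <- acc / sc
    logsc <- logsc + log(sc)
    L[[i]] <- acc
  }
  root_ll <- log(drop(L[[tr$root]] %*% prior)) + logsc
  if (keep) list(root_ll = root_ll, L = L, logsc = logsc)
  else list(root_ll = root_ll)
}

## group identically shaped trees so the pruning pass runs once per shape
.forest_groups <- function(forest) {
  if (inherits(forest, "adj_tree")) forest <- list(forest)
  if (length(forest) == 0L) stop("empty adjacency forest")
  hashes <- vapply(forest, .adj_tree_hash, "")
  groups <- list()
  for (h in unique(hashes)) {
    idx <- which(hashes == h)
    tr <- forest[[idx[1]]]
    states <- do.call(rbind, lapply(forest[idx], function(x) x$state))
    groups[[length(groups) + 1L]] <- list(tree = tr, idx = idx,
                                          states = states)
  }
  groups
}

.groups_loglik <- function(groups, st, params, per_tree = FALSE) {
  kc <- .kernel_cache(params$kappa)
  prior <- c(1 - params$root_prob, params$root_prob)
  total <- 0
  per <- NULL
  if (per_tree) {
    n <- max(unlist(lapply(groups, `[[`, "idx")))
    per <- numeric(n)
  }
  for (g in groups) {
    ll <- .prune(g$tree, g$states, st, kc, prior)$root_ll
    total <- total + sum(ll)
    if (per_tree) per[g$idx] <- ll
  }
  if (per_tree) attr(total, "per_tree") <- per
  total
}

#' Log-likelihood of an adjacency forest
#'
#' Trees of possible adjacencies are independent, so the forest
#' log-likelihood is the sum of per-tree log-likelihoods, each rooted with
#' the root presence prior. Identically shaped trees are pruned in one
#' vectorized pass.
#'
#' @param forest An \code{adj_forest} (or list of \code{adj_tree}, or a
#'   single tree) with leaf states assigned.
#' @param species The \code{species_tree} (its branch lengths drive the
#'   kernels).
#' @param params A \code{model_params}.
#' @param per_tree If \code{TRUE}, attach the per-tree log-likelihood vector
#'   as an attribute.
#' @return The total log-likelihood (<= 0).
#' @export
forest_loglik <- function(forest, species, params, per_tree = FALSE) {
  .groups_loglik(.forest_groups(forest), species, params,
                 per_tree = per_tree)
}

#' Bottom-up conditional likelihoods for one tree
#'
#' @param tree An \code{adj_tree} with leaf states assigned.
#' @param species The \code{species_tree}.
#' @param params A \code{model_params}.
#' @return A list with \code{L} (per node, the conditional likelihood of the
#'   data below given state absent/present, rescaled per node),
#'   \code{logscale} (accumulated log of the rescalings) and \code{loglik}
#'   (root log-likelihood under the root prior).
#' @export
upward_likelihood <- function(tree, species, params) {
  kc <- .kernel_cache(params$kappa)
  prior <- c(1 - params$root_prob, params$root_prob)
  pr <- .prune(tree, matrix(tree$state, 1), species, kc, prior, keep = TRUE)
  list(L = lapply(pr$L, drop), logscale = pr$logsc, loglik = pr$root_ll)
}

#' Top-down outside likelihoods for one tree
#'
#' Computes, for every node, the likelihood contribution of all data outside
#' the node's subtree, folding transitions exactly as the bottom-up pass
#' does (speciation edges with P(t), duplication scenarios averaged
#' uniformly). The root outside equals the root prior.
#'
#' @param tree An \code{adj_tree} with leaf states assigned.
#' @param species The \code{species_tree}.
#' @param params A \code{model_params}.
#' @param up Result of \code{\link{upward_likelihood}} on the same tree.
#' @return List of per-node outside vectors (length 2, possibly rescaled;
#'   posteriors are invariant to the rescaling).
#' @export
downward_likelihood <- function(tree, species, params, up) {
  tr <- tree
  kc <- .kernel_cache(params$kappa)
  len <- species$length
  L <- up$L
  O <- vector("list", tr$nnode)
  O[[tr$root]] <- c(1 - params$root_prob, params$root_prob)
  for (i in rev(tr$order)) {  # pre-order: parents before children
    kk <- tr$children[[i]]
    if (length(kk) == 0L) next
    Of <- O[[i]]
    if (tr$kind[i] == "spec") {
      contrib <- lapply(kk, function(c)
        drop(.child_contrib(tr, c, matrix(L[[c]], 1), len, kc)))
      for (ci in seq_along(kk)) {
        c <- kk[ci]
        base <- Of
        for (oi in seq_along(kk)) if (oi != ci) base <- base * contrib[[oi]]
        if (tr$kind[c] == "dup") {
          O[[c]] <- base
        } else {
          P <- .kc_P(kc, len[tr$species[c]])
          O[[c]] <- colSums(base * P)
        }
      }
    } else if (tr$kind[i] == "dup") {
      t <- len[tr$species[i]]
      P <- .kc_P(kc, t)
      if (length(kk) == 2L) {
        n1 <- .kc_n1(kc, t)
        for (ci in 1:2) {
          sib <- L[[kk[3 - ci]]]
          s1 <- sum(sib * n1)
          O[[kk[ci]]] <- 0.5 * (s1 * colSums(Of * P) +
                                  n1 * sum(Of * drop(P %*% sib)))
        }
      } else {
        nv <- .kc_n11(kc, t)
        nscn <- nrow(.DUP4_SCN)
        res <- lapply(kk, function(c) c(0, 0))
        ## enumerate the 16 child-state vectors per scenario
        for (srow in seq_len(nscn)) {
          slots <- .DUP4_SCN[srow, ]
          for (y1 in 0:1) for (y2 in 0:1) for (y3 in 0:1) for (y4 in 0:1) {
            y <- c(y1, y2, y3, y4)
            zM <- y[which(slots == 1L)]
            zL <- y[which(slots == 2L)]
            zV1 <- y[which(slots == 3L)]
            zV2 <- y[which(slots == 4L)]
            base <- sum(Of * P[, zM + 1]) * nv[zL + 1, zV1 + 1, zV2 + 1]
            for (ci in seq_along(kk)) {
              others <- setdiff(seq_along(kk), ci)
              w <- base
              for (oi in others) w <- w * L[[kk[oi]]][y[oi] + 1]
              res[[ci]][y[ci] + 1] <- res[[ci]][y[ci] + 1] + w
            }
          }
        }
        for (ci in seq_along(kk)) O[[kk[ci]]] <- res[[ci]] / nscn
      }
    }
    for (c in kk) {
      s <- max(O[[c]])
      if (is.finite(s) && s > 0) O[[c]] <- O[[c]] / s
    }
  }
  O
}

#' Posterior probabilities of adjacency presence
#'
#' Combines inside and outside likelihoods into per-node posterior
#' probabilities of state present. Loss leaves and duplication nodes are
#' omitted (duplication nodes duplicate their parent's state slot).
#'
#' @param tree An \code{adj_tree}.
#' @param up Result of \code{\link{upward_likelihood}}.
#' @param down Result of \code{\link{downward_likelihood}}.
#' @return Data frame with \code{node}, \code{kind}, \code{species} (id) and
#'   \code{posterior}.
#' @export
posterior_presence <- function(tree, up, down) {
  keep <- which(tree$kind %in% c("spec", "extant"))
  post <- vapply(keep, function(i) {
    v <- up$L[[i]] * down[[i]]
    tot <- sum(v)
    if (!is.finite(tot) || tot <= 0)
      stop("zero total likelihood in adjacency tree (class ",
           attr(tree, "class_id"), ")")
    v[2] / tot
  }, 1)
  data.frame(node = keep, kind = tree$kind[keep],
             species = tree$species[keep], posterior = post)
}

#' Posterior table for a whole forest
#'
#' @param forest An \code{adj_forest} with states assigned.
#' @param trees Gene-tree list (for gene names).
#' @param species The \code{species_tree}.
#' @param params A \code{model_params}.
#' @return Data frame: class, component, node, species, gene1, gene2,
#'   ancestral flag (speciation pair at an ancestral species) and posterior.
#' @export
compute_posteriors <- function(forest, trees, species, params) {
  if (inherits(forest, "adj_tree")) forest <- list(forest)
  out <- list()
  for (tr in forest) {
    up <- upward_likelihood(tr, species, params)
    dn <- downward_likelihood(tr, species, params, up)
    pp <- posterior_presence(tr, up, dn)
    G1 <- trees[[attr(tr, "tree1")]]
    G2 <- trees[[attr(tr, "tree2")]]
    out[[length(out) + 1L]] <- data.frame(
      class = attr(tr, "class_id"), component = attr(tr, "component"),
      node = pp$node, species = species$name[pp$species],
      gene1 = G1$name[tr$g1[pp$node]], gene2 = G2$name[tr$g2[pp$node]],
      ancestral = pp$kind == "spec", posterior = pp$posterior,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-species summary of reconstructed adjacencies
#'
#' For every species: the number of genes, the number of adjacencies with
#' posterior above the threshold, and the number of genes involved in more
#' than two such adjacencies (a measure of conflict with a linear gene
#' order).
#'
#' @param post Posterior table from \code{\link{compute_posteriors}}.
#' @param trees Gene-tree list.
#' @param species The \code{species_tree}.
#' @param threshold Posterior threshold (default 0.9).
#' @return Data frame with one row per species.
#' @export
ancestral_summary <- function(post, trees, species, threshold = 0.9) {
  st <- species
  genes <- integer(st$nnode)
  for (gt in trees) {
    for (i in seq_len(gt$nnode)) {
      if (gt$event[i] == "extant" || gt$event[i] == "speciation")
        genes[gt$species[i]] <- genes[gt$species[i]] + 1L
    }
  }
  rows <- lapply(seq_len(st$nnode), function(s) {
    sub <- post[post$species == st$name[s] & post$posterior > threshold, ,
                drop = FALSE]
    deg <- table(c(sub$gene1, sub$gene2))
    data.frame(species = st$name[s],
               ancestral = !.is_leaf(st, s),
               genes = genes[s],
               adjacencies = nrow(sub),
               conflicted_genes = sum(deg > 2L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
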