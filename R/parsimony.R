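## Sankoff parsimony on trees of possible adjacencies: the baseline the
## probabilistic posteriors are compared against. Unit cost for every state
## change (gain or breakage) on an edge; undetermined ("?") leaves are free
## in both states; the zero-duration attachment edge of a duplication node
## cannot change state (the duplication node's state is by construction the
## state at the parent speciation).

#' Minimum-change ancestral states for one adjacency tree
#'
#' @param tree An \code{adj_tree} with leaf states assigned.
#' @return List with \code{state} (0/1 per node; undetermined leaves get
#'   their cost-minimizing state) and \code{cost} (the minimal number of
#'   gains plus breakages). Ties break toward absent at the root, then
#'   toward the parent's state.
#' @export
parsimony_ancestral_states <- function(tree) {
  tr <- tree
  n <- tr$nnode
  cost <- matrix(0, n, 2)
  for (i in tr$order) {
    k <- tr$kind[i]
    if (k == "extant") {
      s <- tr$state[i]
      if (is.na(s)) stop("extant leaf without state")
      cost[i, ] <- if (s == 1L) c(Inf, 0) else c(0, Inf)
      next
    }
    if (k == "loss") {
      cost[i, ] <- c(0, 0)
      next
    }
    for (x in 1:2) {
      tot <- 0
      for (c in tr$children[[i]]) {
        if (tr$kind[c] == "dup") {
          tot <- tot + cost[c, x]
        } else {
          tot <- tot + min(cost[c, x], cost[c, 3 - x] + 1)
        }
      }
      cost[i, x] <- tot
    }
  }
  state <- integer(n)
  root <- tr$root
  state[root] <- if (cost[root, 1] <= cost[root, 2]) 0L else 1L
  for (i in rev(tr$order)) {
    x <- state[i] + 1L
    for (c in tr$children[[i]]) {
      if (tr$kind[c] == "dup") {
        state[c] <- state[i]
      } else {
        same <- cost[c, x]
        diff <- cost[c, 3 - x] + 1
        state[c] <- if (same <= diff) state[i] else 1L - state[i]
      }
    }
  }
  list(state = state, cost = min(cost[root, ]))
}

#' Parsimony assignments for a whole forest
#'
#' @param forest An \code{adj_forest} with leaf states assigned.
#' @param trees Gene-tree list (for gene names).
#' @param species The \code{species_tree}.
#' @return Data frame: class, component, node, species, gene1, gene2,
#'   ancestral flag and the parsimony \code{state}.
#' @export
parsimony_forest <- function(forest, trees, species) {
  if (inherits(forest, "adj_tree")) forest <- list(forest)
  out <- list()
  for (tr in forest) {
    pa <- parsimony_ancestral_states(tr)
    keep <- which(tr$kind %in% c("spec", "extant"))
    G1 <- trees[[attr(tr, "tree1")]]
    G2 <- trees[[attr(tr, "tree2")]]
    out[[length(out) + 1L]] <- data.frame(
      class = attr(tr, "class_id"), component = attr(tr, "component"),
      node = keep, species = species$name[tr$species[keep]],
      gene1 = G1$name[tr$g1[keep]], gene2 = G2$name[tr$g2[keep]],
      ancestral = tr$kind[keep] == "spec", state = pa$state[keep],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare parsimony reconstructions with model posteriors
#'
#' For every ancestral adjacency that parsimony declares present, looks up
#' its posterior probability under the model, and summarizes the agreement:
#' the fraction of parsimony adjacencies with posterior above
#' \code{hi} and below \code{lo}, plus a histogram of posteriors over all
#' possible ancestral adjacencies and over the parsimony subset.
#'
#' @param assignments Output of \code{\link{parsimony_forest}}.
#' @param posteriors Output of \code{\link{compute_posteriors}} on the same
#'   forest and parameters.
#' @param hi,lo Support thresholds (defaults 0.9 and 0.5).
#' @param breaks Histogram breaks on [0, 1].
#' @return List: \code{fraction_hi}, \code{fraction_lo} (NA when parsimony
#'   reconstructs nothing), \code{n_parsimony}, \code{n_all},
#'   \code{histogram} (bin, count_all, count_parsimony) and the merged
#'   per-adjacency table.
#' @export
compare_parsimony_posterior <- function(assignments, posteriors,
                                        hi = 0.9, lo = 0.5,
                                        breaks = seq(0, 1, 0.05)) {
  key <- function(d) paste(d$class, d$component, d$node, sep = "\r")
  anc_post <- posteriors[posteriors$ancestral, , drop = FALSE]
  anc_pars <- assignments[assignments$ancestral, , drop = FALSE]
  if (nrow(anc_post) != nrow(anc_pars) ||
      !setequal(key(anc_post), key(anc_pars)))
    stop("parsimony assignments and posteriors cover different forests")
  merged <- anc_post
  merged$parsimony <- anc_pars$state[match(key(anc_post), key(anc_pars))]
  sel <- merged$parsimony == 1L
  np <- sum(sel)
  hist_count <- function(p) {
    h <- graphics::hist(p, breaks = breaks, plot = FALSE, right = FALSE,
                        include.lowest = TRUE)
    h$counts
  }
  ## place exact 1.0 in the last bin (right-open bins otherwise drop it)
  clamp <- function(p) pmin(p, 1 - 1e-12)
  histogram <- data.frame(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    count_all = hist_count(clamp(merged$posterior)),
    count_parsimony = hist_count(clamp(merged$posterior[sel])))
  list(fraction_hi = if (np > 0) mean(merged$posterior[sel] > hi) else NA_real_,
       fraction_lo = if (np > 0) mean(merged$posterior[sel] < lo) else NA_real_,
       n_parsimony = np, n_all = nrow(merged),
       histogram = histogram, table = merged)
}
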