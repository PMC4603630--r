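# Independent oracles used across the suite.
#
# enum_loglik_posterior(): brute-force sum over every assignment of states to
# the speciation-pair nodes of an adjacency tree (duplication nodes carry
# their parent's state across the zero-duration attachment edge; loss leaves
# are marginalized inside their parent's factor). Written independently of
# the pruning/inside-outside code paths.
#
# textbook_pruning(): a minimal Felsenstein pruning for duplication-free
# trees, with transition matrices from the eigendecomposition of the
# generator (independent of the closed forms used by the package).

# uniform scenario set of the generative duplication process, derived here
# independently: inheriting child (4) x first-duplicated gene (2) x
# transmission of the first-born lineage at the second duplication (2)
oracle_dup4_scenarios <- function() {
  id <- function(i, j) 2L * (i - 1L) + j
  out <- list()
  for (gfirst in 1:2) for (i in 1:2) for (j in 1:2) for (c3 in 1:2) {
    M <- id(i, j)
    L <- if (gfirst == 1L) id(3L - i, c3) else id(c3, 3L - j)
    V <- setdiff(1:4, c(M, L))
    out[[length(out) + 1L]] <- list(M = M, L = L, V = V)
  }
  out
}

# per-(kappa, species-tree) kernel tables for the oracle, computed once
oracle_tables <- function(tr, st, params) {
  ts <- unique(st$length[tr$species])
  ts <- ts[!is.na(ts)]
  P <- lapply(ts, function(t) transition_matrix(params$kappa, t))
  n1 <- lapply(ts, function(t) dup1_kernel(params$kappa, t))
  nv <- lapply(ts, function(t) adjevol:::.n11_vec(params$kappa, t))
  names(P) <- names(n1) <- names(nv) <- as.character(ts)
  list(P = P, n1 = n1, nv = nv)
}

# probability that a duplication node in state x yields child states `ys`
# (NA entries = loss children, marginalized)
oracle_dup_factor <- function(x, ys, t, kappa, tab = NULL) {
  P <- if (!is.null(tab)) tab$P[[as.character(t)]]
       else transition_matrix(kappa, t)
  if (length(ys) == 2L) {
    n1 <- if (!is.null(tab)) tab$n1[[as.character(t)]]
          else dup1_kernel(kappa, t)
    tot <- 0
    for (m in 1:2) {
      p <- 1
      for (ci in 1:2) {
        sts <- if (is.na(ys[ci])) 0:1 else ys[ci]
        pc <- 0
        for (s in sts) pc <- pc + if (ci == m) P[x + 1, s + 1] else n1[s + 1]
        p <- p * pc
      }
      tot <- tot + p / 2
    }
    return(tot)
  }
  nv <- if (!is.null(tab)) tab$nv[[as.character(t)]]
        else adjevol:::.n11_vec(kappa, t)
  scns <- oracle_dup4_scenarios()
  tot <- 0
  for (sc in scns) {
    statesets <- lapply(1:4, function(ci) if (is.na(ys[ci])) 0:1 else ys[ci])
    for (yM in statesets[[sc$M]])
      for (yL in statesets[[sc$L]])
        for (y1 in statesets[[sc$V[1]]])
          for (y2 in statesets[[sc$V[2]]])
            tot <- tot + P[x + 1, yM + 1] * nv[yL + 1, y1 + 1, y2 + 1]
  }
  tot / length(scns)
}

# joint probability of one full assignment `s` (states on spec/extant nodes;
# dup nodes inherit their parent's state)
oracle_assignment_prob <- function(tr, st, params, s, tab) {
  pr <- if (s[tr$root] == 1L) params$root_prob else 1 - params$root_prob
  for (i in seq_len(tr$nnode)) {
    if (tr$kind[i] == "dup") s[i] <- s[tr$parent[i]]
  }
  for (i in seq_len(tr$nnode)) {
    k <- tr$kind[i]
    if (k == "spec") {
      for (c in tr$children[[i]]) {
        if (tr$kind[c] %in% c("loss", "dup")) next
        P <- tab$P[[as.character(st$length[tr$species[c]])]]
        pr <- pr * P[s[i] + 1, s[c] + 1]
      }
    } else if (k == "dup") {
      kk <- tr$children[[i]]
      ys <- vapply(kk, function(c)
        if (tr$kind[c] == "loss") NA_integer_ else s[c], 1L)
      pr <- pr * oracle_dup_factor(s[i], ys, st$length[tr$species[i]],
                                   params$kappa, tab)
    }
    if (pr == 0) break
  }
  pr
}

enum_loglik_posterior <- function(tr, st, params) {
  tab <- oracle_tables(tr, st, params)
  free <- which(tr$kind == "spec")
  fixed <- which(tr$kind == "extant")
  nf <- length(free)
  total <- 0
  acc1 <- rep(0, tr$nnode)
  for (mask in 0:(2^nf - 1)) {
    s <- rep(NA_integer_, tr$nnode)
    s[fixed] <- tr$state[fixed]
    if (nf) s[free] <- bitwAnd(bitwShiftR(mask, seq_len(nf) - 1L), 1L)
    if (is.na(s[tr$root])) s[tr$root] <- tr$state[tr$root]
    pr <- oracle_assignment_prob(tr, st, params, s, tab)
    total <- total + pr
    on <- which(!is.na(s) & s == 1L)
    acc1[on] <- acc1[on] + pr
  }
  list(loglik = log(total), posterior = acc1 / total)
}

# independent pruning for duplication-free trees; P(t) by eigendecomposition
textbook_pruning <- function(tr, st, params) {
  stopifnot(!any(tr$kind == "dup"))
  Q <- rate_matrix(params$kappa)
  ev <- eigen(Q)
  Pmat <- function(t) {
    M <- ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors)
    pmin(pmax(Re(M), 0), 1)
  }
  L <- vector("list", tr$nnode)
  for (i in tr$order) {
    if (tr$kind[i] == "extant") {
      L[[i]] <- if (tr$state[i] == 1L) c(0, 1) else c(1, 0)
    } else if (tr$kind[i] == "loss") {
      L[[i]] <- c(1, 1)
    } else {
      acc <- c(1, 1)
      for (c in tr$children[[i]]) {
        P <- Pmat(st$length[tr$species[c]])
        acc <- acc * as.vector(P %*% L[[c]])
      }
      L[[i]] <- acc
    }
  }
  log(sum(L[[tr$root]] * c(1 - params$root_prob, params$root_prob)))
}

# random small adjacency trees via the simulator (coverage of speciation,
# 2- and 4-child duplication nodes and "?" leaves), capped at max_internal
# spec+dup nodes so enumeration stays cheap
random_small_adj_trees <- function(n, max_internal = 10L, seed = 1L,
                                   dup_rate = 0.35, loss_rate = 0.25,
                                   kappa = 1, root_prob = 0.7,
                                   taxa = 6) {
  set.seed(seed)
  st <- toy_species_tree(taxa)
  out <- list()
  guard <- 0L
  while (length(out) < n && guard < 50L * n) {
    guard <- guard + 1L
    t1 <- simulate_reconciled_family(st, dup_rate, loss_rate, prefix = "oa")
    t2 <- simulate_reconciled_family(st, dup_rate, loss_rate, prefix = "ob")
    sim <- simulate_adjacency_evolution(t1, t2, st, kappa, root_prob)
    for (tr in sim$forest) {
      if (sum(tr$kind %in% c("spec", "dup")) > max_internal) next
      if (sum(tr$kind == "spec") == 0L) next
      out[[length(out) + 1L]] <- tr
      if (length(out) >= n) break
    }
  }
  list(species = st, trees = out)
}
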