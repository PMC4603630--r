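## Synthetic data under the model's own generative process: gene families
## evolve by birth/death along the species tree, adjacencies evolve by the
## two-state Gillespie process on the resulting trees of possible
## adjacencies, duplications transmit the adjacency to one uniformly chosen
## copy at a date uniform on the species branch. The simulator doubles as
## the Monte-Carlo oracle for the duplication kernels and as ground truth
## for parameter recovery.

#' Small fixed species trees used in examples and simulations
#'
#' Hard-coded Newick constants (6 or 12 extant species) with branch lengths
#' in expected adjacency events per adjacency, spanning the range a
#' rearrangement study would see (about 0.06 to 0.4 events per branch).
#'
#' @param taxa 6 or 12.
#' @return A \code{species_tree}.
#' @export
toy_species_tree <- function(taxa = 12) {
  nwk <- if (taxa == 6) {
    "((spA:0.3,(spB:0.15,spC:0.2):0.1):0.25,(spD:0.35,(spE:0.1,spF:0.18):0.22):0.08)ROOT;"
  } else if (taxa == 12) {
    paste0("(((sp01:0.12,sp02:0.08):0.21,(sp03:0.33,(sp04:0.15,sp05:0.09)",
           ":0.11):0.07):0.18,((sp06:0.41,(sp07:0.22,sp08:0.13):0.17):0.09,",
           "(sp09:0.27,(sp10:0.19,(sp11:0.1,sp12:0.24):0.14):0.06):0.23)",
           ":0.12)ROOT;")
  } else stop("taxa must be 6 or 12")
  parse_species_tree(nwk)
}

## vectorized Gillespie for the two-state chain: n independent chains with
## initial states `state`, durations `dur`, rates from rate_matrix(kappa)
.sim2state <- function(state, dur, kappa, n = length(state)) {
  state <- rep_len(as.integer(state), n)
  rem <- rep_len(dur, n)
  gain <- (kappa + 1) / 2
  loss <- (kappa + 1) / (2 * kappa)
  active <- which(rem > 0)
  while (length(active)) {
    r <- ifelse(state[active] == 0L, gain, loss)
    w <- stats::rexp(length(active), r)
    flip <- w < rem[active]
    idx <- active[flip]
    state[idx] <- 1L - state[idx]
    rem[active] <- rem[active] - w
    active <- idx
  }
  state
}

#' Simulate a reconciled gene family along the species tree
#'
#' Gene lineages traverse species branches with exponentially distributed
#' duplication and loss events (rates per gene per unit branch length);
#' speciation nodes sit at species-tree nodes; the output is fully
#' loss-annotated. Families that go extinct or violate the
#' one-duplication-between-speciations restriction are rejected and
#' resampled (the attempt count is reported as attribute \code{tries}).
#'
#' @param species A \code{species_tree}.
#' @param dup_rate,loss_rate Non-negative event rates.
#' @param prefix Gene-name prefix (keeps ids unique across families).
#' @param seed Optional integer seed (\code{NULL}: use the current RNG
#'   state).
#' @param max_tries Rejection cap.
#' @return A \code{recon_tree}.
#' @export
simulate_reconciled_family <- function(species, dup_rate = 0.1,
                                       loss_rate = 0.2, prefix = "fam1",
                                       seed = NULL, max_tries = 1000L) {
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  st <- species
  for (try in seq_len(max_tries)) {
    n <- 0L
    name <- character(0); sp <- integer(0); ev <- character(0)
    parent <- integer(0); children <- list()
    leafcount <- new.env(parent = emptyenv())
    add <- function(nm, s, e, p) {
      n <<- n + 1L
      name[n] <<- nm; sp[n] <<- s; ev[n] <<- e; parent[n] <<- p
      children[[n]] <<- integer(0)
      if (!is.na(p)) children[[p]] <<- c(children[[p]], n)
      n
    }
    extant <- function(s, p) {
      nm0 <- st$name[s]
      k <- if (is.null(leafcount[[nm0]])) 1L else leafcount[[nm0]] + 1L
      leafcount[[nm0]] <- k
      add(paste0(prefix, "_", nm0, "_g", k), s, "extant", p)
    }
    descend <- function(s, p) {
      if (.is_leaf(st, s)) return(extant(s, p))
      id <- add("", s, "speciation", p)
      for (sc in st$children[[s]]) branch(sc, st$length[sc], id)
      id
    }
    branch <- function(s, remaining, p) {
      total <- dup_rate + loss_rate
      tau <- if (total > 0) stats::rexp(1, total) else Inf
      if (tau >= remaining) return(descend(s, p))
      if (stats::runif(1) < loss_rate / total) {
        add(LOSS_LEAF_NAME, s, "loss", p)
      } else {
        id <- add("", s, "duplication", p)
        branch(s, remaining - tau, id)
        branch(s, remaining - tau, id)
        id
      }
    }
    descend(st$root, NA_integer_)
    gt <- .finalize_recon(name, sp, ev, parent, children,
                          rep(NA_real_, n), 1L)
    if (!any(gt$event == "extant")) next
    if (!check_single_dup_constraint(gt)$ok) next
    attr(gt, "tries") <- try
    return(gt)
  }
  stop("could not simulate an admissible family in ", max_tries, " tries")
}

#' Simulate one adjacency history on a pair of gene trees
#'
#' Builds the forest of possible adjacencies rooted at the two gene-tree
#' roots and simulates the two-state process down each component: root state
#' Bernoulli(\code{root_prob}); Gillespie dynamics with rates from
#' \code{\link{rate_matrix}} scaled by branch length; at each duplication a
#' date is drawn uniformly on the branch and the current state is
#' transmitted to one uniformly chosen copy, the other copy starting absent.
#'
#' @param tree1,tree2 Loss-complete \code{recon_tree}s satisfying the
#'   duplication restriction.
#' @param trees Optionally, the list containing the two trees (with indices
#'   \code{it1}, \code{it2}); by default a two-tree list is formed.
#' @param species The \code{species_tree}.
#' @param kappa,root_prob Model parameters of the simulation.
#' @param seed Optional integer seed.
#' @param it1,it2 Indices of the trees in \code{trees}.
#' @return List: \code{forest} (an \code{adj_forest} whose \code{state}
#'   holds the true extant states and with per-node \code{true_state}
#'   vectors attached) and \code{class} (the implied
#'   \code{adjacency_class} skeleton).
#' @export
simulate_adjacency_evolution <- function(tree1, tree2, species, kappa = 1,
                                         root_prob = 0.9, seed = NULL,
                                         trees = NULL, it1 = 1L, it2 = 2L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trees)) { trees <- list(tree1, tree2); it1 <- 1L; it2 <- 2L }
  cls <- structure(list(id = 1L, tree1 = it1, tree2 = it2,
                        root1 = tree1$root, root2 = tree2$root,
                        members = NULL), class = "adjacency_class")
  forest <- build_adjacency_forest(cls, trees, species)
  st <- species
  for (fi in seq_along(forest)) {
    tr <- forest[[fi]]
    true_state <- rep(NA_integer_, tr$nnode)
    sim_children <- function(i) {
      x <- true_state[i]
      for (c in tr$children[[i]]) {
        kc <- tr$kind[c]
        if (kc == "loss") next
        if (kc == "dup") {
          sim_dup(c, x)
        } else {
          true_state[c] <<- .sim2state(x, st$length[tr$species[c]], kappa)
          if (kc == "spec") sim_children(c)
        }
      }
    }
    sim_dup <- function(d, x) {
      t <- st$length[tr$species[d]]
      true_state[d] <<- x
      kk <- tr$children[[d]]
      if (length(kk) == 2L) {
        tau <- stats::runif(1, 0, t)
        main <- .sim2state(x, t, kappa)
        born <- .sim2state(0L, t - tau, kappa)
        mpos <- sample.int(2L, 1L)
        out <- c(born, born); out[mpos] <- main
      } else {
        tauA <- stats::runif(1, 0, t)   # duplication date, gene tree 1
        tauB <- stats::runif(1, 0, t)   # duplication date, gene tree 2
        main <- .sim2state(x, t, kappa)
        firstborn <- .sim2state(0L, t - min(tauA, tauB), kappa)
        v1 <- .sim2state(0L, t - max(tauA, tauB), kappa)
        v2 <- .sim2state(0L, t - max(tauA, tauB), kappa)
        i <- sample.int(2L, 1L)   # main keeps copy i of gene 1
        j <- sample.int(2L, 1L)   # main keeps copy j of gene 2
        c3 <- sample.int(2L, 1L)  # first-born lineage's transmission
        id <- function(a, b) 2L * (a - 1L) + b
        out <- integer(4)
        out[id(i, j)] <- main
        if (tauA <= tauB) {       # gene 1 duplicated first
          out[id(3L - i, c3)] <- firstborn
          out[id(i, 3L - j)] <- v1
          out[id(3L - i, 3L - c3)] <- v2
        } else {                  # gene 2 duplicated first
          out[id(c3, 3L - j)] <- firstborn
          out[id(3L - i, j)] <- v1
          out[id(3L - c3, 3L - j)] <- v2
        }
      }
      for (ci in seq_along(kk)) {
        c <- kk[ci]
        if (tr$kind[c] == "loss") next
        true_state[c] <<- out[ci]
        if (tr$kind[c] == "spec") sim_children(c)
      }
    }
    true_state[tr$root] <- stats::rbinom(1, 1, root_prob)
    if (tr$kind[tr$root] == "spec") sim_children(tr$root)
    tr$true_state <- true_state
    tr$state[tr$kind == "extant"] <- true_state[tr$kind == "extant"]
    forest[[fi]] <- tr
  }
  list(forest = forest, class = cls)
}

#' Monte-Carlo oracle for the duplication kernels
#'
#' Simulates the generative duplication process on one species branch many
#' times with true Gillespie dynamics: useful as an independent check of
#' \code{\link{dup1_kernel}} and \code{\link{dup2_kernel}}.
#'
#' @param x Source state at the top of the branch (0 or 1).
#' @param t Branch duration.
#' @param kappa Gain/loss rate ratio.
#' @param n Number of replicates.
#' @param double If \code{TRUE}, both genes duplicate (four outcome slots);
#'   otherwise one gene duplicates (two slots).
#' @param seed Optional integer seed.
#' @return List of integer matrices: \code{slot} (columns: inheriting,
#'   first-born, and for the double case the two second-born lineages) and
#'   \code{child} (columns: the labelled children of the duplication node,
#'   copy order \code{(i-1)*2 + j}), n rows each.
#' @export
simulate_duplication_branch <- function(x, t, kappa, n = 1e5,
                                        double = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  main <- .sim2state(x, t, kappa, n)
  if (!double) {
    tau <- stats::runif(n, 0, t)
    born <- .sim2state(0L, t - tau, kappa, n)
    slot <- cbind(main, born)
    mpos <- sample.int(2L, n, replace = TRUE)
    child <- cbind(ifelse(mpos == 1L, main, born),
                   ifelse(mpos == 1L, born, main))
    colnames(slot) <- c("inherit", "born")
    colnames(child) <- c("c1", "c2")
    return(list(slot = slot, child = child))
  }
  tauA <- stats::runif(n, 0, t)
  tauB <- stats::runif(n, 0, t)
  u <- t - pmin(tauA, tauB)   # residual time of the first duplication
  v <- t - pmax(tauA, tauB)   # residual time of the second duplication
  firstborn <- .sim2state(0L, u, kappa, n)
  v1 <- .sim2state(0L, v, kappa, n)
  v2 <- .sim2state(0L, v, kappa, n)
  slot <- cbind(main, firstborn, v1, v2)
  colnames(slot) <- c("inherit", "firstborn", "second1", "second2")
  i <- sample.int(2L, n, replace = TRUE)
  j <- sample.int(2L, n, replace = TRUE)
  c3 <- sample.int(2L, n, replace = TRUE)
  g1first <- tauA <= tauB
  id <- function(a, b) 2L * (a - 1L) + b
  child <- matrix(NA_integer_, n, 4)
  put <- function(pos, val) child[cbind(seq_len(n), pos)] <<- val
  put(id(i, j), main)
  put(ifelse(g1first, id(3L - i, c3), id(c3, 3L - j)), firstborn)
  put(ifelse(g1first, id(i, 3L - j), id(3L - i, j)), v1)
  put(ifelse(g1first, id(3L - i, 3L - c3), id(3L - c3, 3L - j)), v2)
  colnames(child) <- c("c11", "c12", "c21", "c22")
  list(slot = slot, child = child)
}

#' Simulation configuration
#'
#' @param species A \code{species_tree} (default: the 12-taxon toy tree).
#' @param n_classes Number of gene-family pairs / adjacency classes.
#' @param dup_rate,loss_rate Gene duplication and loss rates per gene per
#'   unit branch length.
#' @param kappa,root_prob Adjacency model parameters of the simulation.
#' @param drop_fraction Fraction of present extant adjacencies dropped from
#'   the observations (emulating assembly fragmentation).
#' @param seed Mandatory integer seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(species = toy_species_tree(12), n_classes = 100L,
                       dup_rate = 0.1, loss_rate = 0.2, kappa = 0.5,
                       root_prob = 0.9, drop_fraction = 0.2, seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  structure(list(species = species, n_classes = as.integer(n_classes),
                 dup_rate = dup_rate, loss_rate = loss_rate, kappa = kappa,
                 root_prob = root_prob, drop_fraction = drop_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a full dataset in memory
#'
#' Simulates \code{n_classes} independent gene-family pairs and their
#' adjacency histories, applies the observation drop to present extant
#' adjacencies, and returns gene trees, the forest with observed leaf
#' states, and the ground truth.
#'
#' @param config A \code{sim_config}.
#' @return List: \code{species}, \code{trees} (2 per class),
#'   \code{forest} (observed leaf states), \code{truth} (per-node true
#'   states data frame), \code{observed} (the observed
#'   \code{adjacency_set}) and \code{counts}.
#' @export
simulate_dataset <- function(config) {
  cf <- config
  set.seed(cf$seed)
  st <- cf$species
  trees <- list()
  forest <- list()
  truth <- list()
  dropped <- 0L; true_present <- 0L
  for (k in seq_len(cf$n_classes)) {
    t1 <- simulate_reconciled_family(st, cf$dup_rate, cf$loss_rate,
                                     prefix = sprintf("f%04da", k))
    t2 <- simulate_reconciled_family(st, cf$dup_rate, cf$loss_rate,
                                     prefix = sprintf("f%04db", k))
    i1 <- length(trees) + 1L
    trees[[i1]] <- t1; trees[[i1 + 1L]] <- t2
    sim <- simulate_adjacency_evolution(t1, t2, st, cf$kappa, cf$root_prob,
                                        trees = trees, it1 = i1,
                                        it2 = i1 + 1L)
    for (tr in sim$forest) {
      attr(tr, "class_id") <- k
      ext <- which(tr$kind == "extant")
      pres <- ext[tr$state[ext] == 1L]
      true_present <- true_present + length(pres)
      if (cf$drop_fraction > 0 && length(pres)) {
        drop <- stats::runif(length(pres)) < cf$drop_fraction
        tr$state[pres[drop]] <- 0L
        dropped <- dropped + sum(drop)
      }
      forest[[length(forest) + 1L]] <- tr
      truth[[length(truth) + 1L]] <- data.frame(
        class = k, component = attr(tr, "component"),
        node = seq_len(tr$nnode), kind = tr$kind,
        species = st$name[tr$species],
        gene1 = ifelse(is.na(tr$g1), NA, trees[[i1]]$name[tr$g1]),
        gene2 = ifelse(is.na(tr$g2), NA, trees[[i1 + 1L]]$name[tr$g2]),
        true_state = tr$true_state, observed = tr$state,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  obs <- .observed_adjacencies(forest, trees, st)
  list(species = st, trees = trees,
       forest = structure(forest, class = "adj_forest"),
       truth = truth, observed = obs,
       counts = list(true_present = true_present, dropped = dropped))
}

.observed_adjacencies <- function(forest, trees, st) {
  sp <- character(0); g1 <- character(0); g2 <- character(0)
  for (tr in forest) {
    G1 <- trees[[attr(tr, "tree1")]]
    G2 <- trees[[attr(tr, "tree2")]]
    ext <- which(tr$kind == "extant" & tr$state == 1L)
    if (!length(ext)) next
    a <- G1$name[tr$g1[ext]]
    b <- G2$name[tr$g2[ext]]
    sp <- c(sp, st$name[tr$species[ext]])
    g1 <- c(g1, pmin(a, b)); g2 <- c(g2, pmax(a, b))
  }
  out <- data.frame(species = sp, gene1 = g1, gene2 = g2,
                    stringsAsFactors = FALSE)
  class(out) <- c("adjacency_set", "data.frame")
  out
}

## thread observed adjacencies of one species into linear scaffolds; genes
## with more than two partners or cycle-closing adjacencies lose the extra
## edges (reported), every remaining component is a path = one scaffold
.thread_scaffolds <- function(genes, edges) {
  genes <- sort(genes)
  deg <- stats::setNames(integer(length(genes)), genes)
  par <- stats::setNames(seq_along(genes), genes)
  find <- function(i) { while (par[i] != i) i <- par[i]; i }
  nbr <- stats::setNames(vector("list", length(genes)), genes)
  droppedE <- 0L
  if (nrow(edges)) {
    edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      a <- edges$gene1[e]; b <- edges$gene2[e]
      ra <- find(par[a]); rb <- find(par[b])
      if (deg[a] >= 2L || deg[b] >= 2L || ra == rb) {
        droppedE <- droppedE + 1L
        next
      }
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
      par[rb] <- ra
    }
  }
  comp <- stats::setNames(vapply(genes, function(g) find(par[g]), 1L), genes)
  scaffolds <- list()
  for (r in unique(comp)) {
    members <- genes[comp == r]
    if (length(members) == 1L) {
      scaffolds[[length(scaffolds) + 1L]] <- members
      next
    }
    ends <- members[deg[members] <= 1L]
    cur <- sort(ends)[1]
    path <- cur; prev <- ""
    repeat {
      nxt <- setdiff(nbr[[cur]], prev)
      if (!length(nxt)) break
      prev <- cur; cur <- nxt[1]
      path <- c(path, cur)
    }
    scaffolds[[length(scaffolds) + 1L]] <- path
  }
  ord <- order(vapply(scaffolds, `[`, "", 1))
  list(scaffolds = scaffolds[ord], dropped = droppedE)
}

#' Generate a dataset on disk
#'
#' Runs \code{\link{simulate_dataset}} and writes the species tree
#' (Newick), the reconciled gene trees (NHX, one per line), the gene orders
#' (TSV, observed present adjacencies threaded into per-species scaffolds)
#' and the ground truth (TSV). Every emitted file parses back through the
#' package's own readers.
#'
#' @param config A \code{sim_config}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the \code{simulate_dataset} result plus
#'   \code{paths} and threading counts.
#' @export
generate_dataset <- function(config, outdir) {
  ds <- simulate_dataset(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- ds$species
  paths <- list(species = file.path(outdir, "species.nwk"),
                trees = file.path(outdir, "gene_trees.nhx"),
                orders = file.path(outdir, "gene_orders.tsv"),
                truth = file.path(outdir, "truth.tsv"))
  write_species_tree(st, paths$species)
  writeLines(vapply(ds$trees, write_gene_tree, "", species = st),
             paths$trees)
  rows <- list()
  conflict_dropped <- 0L
  for (s in st$name[vapply(seq_len(st$nnode), function(i) .is_leaf(st, i),
                           TRUE)]) {
    genes <- unlist(lapply(ds$trees, function(gt)
      gt$name[gt$event == "extant" &
                st$name[gt$species] == s]), use.names = FALSE)
    if (!length(genes)) next
    edges <- ds$observed[ds$observed$species == s, , drop = FALSE]
    th <- .thread_scaffolds(genes, edges)
    conflict_dropped <- conflict_dropped + th$dropped
    for (sc in seq_along(th$scaffolds)) {
      path <- th$scaffolds[[sc]]
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, scaffold = sprintf("sc%05d", sc),
        position = seq_along(path) - 1L, gene_id = path,
        stringsAsFactors = FALSE)
    }
  }
  orders <- do.call(rbind, rows)
  utils::write.table(orders, paths$orders, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ds$paths <- paths
  ds$counts$conflict_dropped <- conflict_dropped
  invisible(ds)
}
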