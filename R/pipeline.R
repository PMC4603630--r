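## End-to-end pipeline wiring: simulate -> classes -> build -> fit ->
## ancestral -> compare, with a YAML configuration and deterministic,
## timestamp-free outputs (identical config + seed => byte-identical files).

.cfg_get <- function(cfg, key, default = NULL) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

#' Read a pipeline configuration
#'
#' @param config A YAML file path or a named list. Recognized fields:
#'   \code{species_tree}, \code{gene_trees}, \code{gene_orders} (input
#'   paths), or a \code{simulate} section (\code{n_classes},
#'   \code{dup_rate}, \code{loss_rate}, \code{kappa}, \code{root_prob},
#'   \code{drop_fraction}); \code{model} (\code{kappa}, \code{root_prob}
#'   initial values); \code{optimize} (\code{kappa}, \code{root_prob},
#'   \code{branch_lengths}, \code{maxit}, \code{dup_free_only});
#'   \code{threshold}; \code{outdir}; \code{seed}.
#' @return The configuration list, with relative input paths resolved
#'   against the YAML file's directory.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    dir <- dirname(normalizePath(config))
    cfg <- yaml::read_yaml(config)
    for (key in c("species_tree", "gene_trees", "gene_orders")) {
      if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
        cand <- file.path(dir, cfg[[key]])
        if (file.exists(cand)) cfg[[key]] <- cand
      }
    }
    cfg
  } else if (is.list(config)) config
  else stop("config must be a file path or a list")
}

.pipeline_inputs <- function(cfg, outdir) {
  pick <- function(key, file) {
    p <- .cfg_get(cfg, key)
    if (is.null(p)) p <- file.path(outdir, file)
    if (!file.exists(p)) stop("missing input: ", p)
    p
  }
  st <- parse_species_tree(pick("species_tree", "species.nwk"), file = TRUE)
  tree_lines <- readLines(pick("gene_trees", "gene_trees.nhx"))
  tree_lines <- tree_lines[nzchar(tree_lines)]
  trees <- lapply(tree_lines, parse_reconciled_gene_tree, species = st)
  adj <- load_gene_orders(pick("gene_orders", "gene_orders.tsv"))
  list(species = st, trees = trees, adjacencies = adj)
}

.pipeline_forest <- function(inp) {
  classes <- build_adjacency_classes(inp$adjacencies, inp$trees,
                                     inp$species)
  forest <- list()
  skipped <- 0L
  for (cls in classes) {
    f <- tryCatch(build_adjacency_forest(cls, inp$trees, inp$species),
                  adjevol_restriction_error = function(e) NULL)
    if (is.null(f)) { skipped <- skipped + 1L; next }
    f <- assign_leaf_states(f, inp$adjacencies, inp$trees, inp$species)
    forest <- c(forest, f)
  }
  list(classes = classes, forest = structure(forest, class = "adj_forest"),
       skipped = skipped)
}

.pipeline_params <- function(cfg, outdir) {
  fitfile <- file.path(outdir, "fit.json")
  if (file.exists(fitfile)) {
    fit <- jsonlite::read_json(fitfile, simplifyVector = TRUE)
    return(list(params = model_params(fit$kappa, fit$root_prob),
                lengths = fit$branch_lengths))
  }
  m <- .cfg_get(cfg, "model", list())
  k <- .cfg_get(m, "kappa", 1)
  list(params = model_params(k, .cfg_get(m, "root_prob", k / (k + 1))),
       lengths = NULL)
}

.apply_lengths <- function(st, lengths) {
  if (is.null(lengths)) return(st)
  ids <- .sp_id(st, names(lengths))
  st$length[ids] <- unlist(lengths)
  st
}

#' Run one pipeline command
#'
#' Commands: \code{simulate} (write a synthetic dataset),
#' \code{classes} (cluster adjacencies, write \code{classes.tsv}),
#' \code{build} (write the adjacency-forest dump),
#' \code{fit} (optimize parameters, write \code{fit.json}),
#' \code{ancestral} (posteriors + per-species summary TSVs),
#' \code{compare} (parsimony-vs-posterior table, histogram and fractions).
#' Classes violating the duplication restriction are skipped with a
#' warning, never fatal.
#'
#' @param config YAML path or list (see
#'   \code{\link{read_pipeline_config}}).
#' @param command One of the six commands above.
#' @param outdir Output directory (overrides \code{config$outdir}).
#' @param seed Overrides \code{config$seed}.
#' @return Invisibly, a list of produced paths and summary values.
#' @export
run_pipeline <- function(config, command = c("simulate", "classes", "build",
                                             "fit", "ancestral", "compare"),
                         outdir = NULL, seed = NULL) {
  command <- match.arg(command)
  cfg <- read_pipeline_config(config)
  if (is.null(outdir)) outdir <- .cfg_get(cfg, "outdir", ".")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(seed)) seed <- .cfg_get(cfg, "seed", 1L)

  if (command == "simulate") {
    sim <- .cfg_get(cfg, "simulate", list())
    species <- if (!is.null(cfg$species_tree))
      parse_species_tree(cfg$species_tree, file = TRUE)
    else toy_species_tree(12)
    cf <- sim_config(species = species,
                     n_classes = .cfg_get(sim, "n_classes", 50L),
                     dup_rate = .cfg_get(sim, "dup_rate", 0.1),
                     loss_rate = .cfg_get(sim, "loss_rate", 0.2),
                     kappa = .cfg_get(sim, "kappa", 0.5),
                     root_prob = .cfg_get(sim, "root_prob", 0.9),
                     drop_fraction = .cfg_get(sim, "drop_fraction", 0.2),
                     seed = seed)
    ds <- generate_dataset(cf, outdir)
    message("simulate: ", cf$n_classes, " classes, ",
            ds$counts$dropped, " observations dropped")
    return(invisible(list(paths = ds$paths, counts = ds$counts)))
  }

  inp <- .pipeline_inputs(cfg, outdir)
  pf <- .pipeline_forest(inp)
  if (pf$skipped > 0L)
    warning(pf$skipped,
            " class(es) skipped: duplication restriction violated")
  st <- inp$species

  if (command == "classes") {
    rows <- do.call(rbind, lapply(pf$classes, function(cl) {
      data.frame(class = cl$id,
                 root1_species =
                   st$name[inp$trees[[cl$tree1]]$species[cl$root1]],
                 root2_species =
                   st$name[inp$trees[[cl$tree2]]$species[cl$root2]],
                 species = cl$members$species, gene1 = cl$members$gene1,
                 gene2 = cl$members$gene2, stringsAsFactors = FALSE)
    }))
    p <- file.path(outdir, "classes.tsv")
    utils::write.table(rows, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message("classes: ", length(pf$classes), " classes, ",
            nrow(inp$adjacencies), " adjacencies")
    return(invisible(list(paths = list(classes = p),
                          n_classes = length(pf$classes),
                          skipped = pf$skipped)))
  }

  if (command == "build") {
    p <- file.path(outdir, "forest.txt")
    dump_adjacency_forest(pf$forest, inp$trees, st, p)
    message("build: ", length(pf$forest), " adjacency trees (",
            pf$skipped, " classes skipped)")
    return(invisible(list(paths = list(forest = p),
                          n_trees = length(pf$forest),
                          skipped = pf$skipped)))
  }

  if (command == "fit") {
    oc <- .cfg_get(cfg, "optimize", list())
    pp <- .pipeline_params(cfg, outdir)
    forest <- pf$forest
    if (isTRUE(.cfg_get(oc, "dup_free_only", FALSE))) {
      keep <- vapply(forest, function(tr) !any(tr$kind == "dup"), TRUE)
      forest <- structure(forest[keep], class = "adj_forest")
    }
    fit <- optimize_parameters(
      forest, st, init = pp$params,
      free = list(kappa = .cfg_get(oc, "kappa", TRUE),
                  root_prob = .cfg_get(oc, "root_prob", TRUE),
                  branch_lengths = .cfg_get(oc, "branch_lengths", FALSE)),
      control = list(maxit = .cfg_get(oc, "maxit", 300L)))
    ids <- which(!is.na(fit$species$parent))
    rep <- list(kappa = fit$params$kappa,
                root_prob = fit$params$root_prob,
                loglik = fit$loglik, loglik_init = fit$loglik_init,
                convergence = fit$convergence,
                iterations = fit$iterations,
                n_trees = length(forest), skipped_classes = pf$skipped,
                branch_lengths = as.list(stats::setNames(
                  fit$species$length[ids], fit$species$name[ids])))
    p <- file.path(outdir, "fit.json")
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    message("fit: logLik ", format(fit$loglik), ", kappa ",
            format(fit$params$kappa))
    return(invisible(list(paths = list(fit = p), fit = fit)))
  }

  pp <- .pipeline_params(cfg, outdir)
  st_fit <- .apply_lengths(st, pp$lengths)
  post <- compute_posteriors(pf$forest, inp$trees, st_fit, pp$params)

  if (command == "ancestral") {
    thr <- .cfg_get(cfg, "threshold", 0.9)
    p1 <- file.path(outdir, "posteriors.tsv")
    out <- post
    out$posterior <- sprintf("%.6g", out$posterior)
    utils::write.table(out, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    summ <- ancestral_summary(post, inp$trees, st_fit, threshold = thr)
    p2 <- file.path(outdir, "summary.tsv")
    utils::write.table(summ, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message("ancestral: ", sum(post$ancestral & post$posterior > thr),
            " ancestral adjacencies with posterior > ", thr)
    return(invisible(list(paths = list(posteriors = p1, summary = p2),
                          posteriors = post, summary = summ)))
  }

  ## compare
  pars <- parsimony_forest(pf$forest, inp$trees, st_fit)
  cmp <- compare_parsimony_posterior(pars, post)
  p1 <- file.path(outdir, "comparison.tsv")
  tab <- cmp$table
  tab$posterior <- sprintf("%.6g", tab$posterior)
  utils::write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(outdir, "histogram.tsv")
  utils::write.table(cmp$histogram, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p3 <- file.path(outdir, "compare.json")
  jsonlite::write_json(list(fraction_hi = cmp$fraction_hi,
                            fraction_lo = cmp$fraction_lo,
                            n_parsimony = cmp$n_parsimony,
                            n_all = cmp$n_all),
                       p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("compare: ", cmp$n_parsimony, " parsimony adjacencies; ",
          "fraction > 0.9 = ", format(cmp$fraction_hi),
          ", fraction < 0.5 = ", format(cmp$fraction_lo))
  invisible(list(paths = list(comparison = p1, histogram = p2,
                              summary = p3), compare = cmp))
}
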