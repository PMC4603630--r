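## Maximum-likelihood fitting. Free parameters (any subset of kappa, the
## root presence probability and the species-tree branch lengths) are
## optimized by bounded quasi-Newton (L-BFGS-B) on log / logit transformed
## coordinates, which keeps the search unconstrained-looking while honouring
## the bounds kappa in [1e-3, 1e3], lengths in [1e-6, 100] and
## root_prob in [1e-6, 1 - 1e-6].

.AE_BOUNDS <- list(kappa = c(1e-3, 1e3), length = c(1e-6, 100),
                   prob = c(1e-6, 1 - 1e-6))

#' Fit model parameters and branch lengths by maximum likelihood
#'
#' @param forest An \code{adj_forest} (leaf states assigned).
#' @param species The \code{species_tree} providing initial branch lengths.
#' @param init Initial \code{model_params}.
#' @param free Named list of logicals: \code{kappa}, \code{root_prob},
#'   \code{branch_lengths}.
#' @param control List: \code{maxit} (default 300) and \code{factr}
#'   (L-BFGS-B tolerance, default 1e7).
#' @return An \code{adjevol_fit}: \code{params}, \code{species} (with
#'   optimized lengths), \code{loglik}, \code{loglik_init},
#'   \code{iterations}, \code{convergence} (0 = converged) and
#'   \code{message}. The fitted log-likelihood never falls below the
#'   starting one.
#' @export
optimize_parameters <- function(forest, species,
                                init = model_params(),
                                free = list(kappa = TRUE, root_prob = TRUE,
                                            branch_lengths = FALSE),
                                control = list()) {
  maxit <- if (is.null(control$maxit)) 300L else control$maxit
  factr <- if (is.null(control$factr)) 1e7 else control$factr
  groups <- .forest_groups(forest)
  st <- species
  branch_ids <- which(!is.na(st$parent))
  fk <- isTRUE(free$kappa)
  fp <- isTRUE(free$root_prob)
  fb <- isTRUE(free$branch_lengths)

  pack <- function(params, lens) {
    th <- numeric(0)
    if (fk) th <- c(th, log(params$kappa))
    if (fp) th <- c(th, stats::qlogis(params$root_prob))
    if (fb) th <- c(th, log(lens))
    th
  }
  unpack <- function(th) {
    k <- init$kappa; p <- init$root_prob; lens <- st$length[branch_ids]
    i <- 0L
    if (fk) { i <- i + 1L; k <- exp(th[i]) }
    if (fp) { i <- i + 1L; p <- stats::plogis(th[i]) }
    if (fb) { lens <- exp(th[(i + 1L):length(th)]) }
    list(kappa = k, root_prob = p, lens = lens)
  }
  lower <- c(if (fk) log(.AE_BOUNDS$kappa[1]),
             if (fp) stats::qlogis(.AE_BOUNDS$prob[1]),
             if (fb) rep(log(.AE_BOUNDS$length[1]), length(branch_ids)))
  upper <- c(if (fk) log(.AE_BOUNDS$kappa[2]),
             if (fp) stats::qlogis(.AE_BOUNDS$prob[2]),
             if (fb) rep(log(.AE_BOUNDS$length[2]), length(branch_ids)))

  st_work <- st
  objective <- function(th) {
    u <- unpack(th)
    st_work$length[branch_ids] <- u$lens
    p <- model_params(u$kappa, u$root_prob)
    ll <- .groups_loglik(groups, st_work, p)
    if (!is.finite(ll)) return(1e300)
    -ll
  }

  th0 <- pack(init, pmin(pmax(st$length[branch_ids],
                              .AE_BOUNDS$length[1]), .AE_BOUNDS$length[2]))
  ll0 <- -objective(th0)
  if (length(th0) == 0L) {
    return(structure(list(params = init, species = st, loglik = ll0,
                          loglik_init = ll0, iterations = 0L,
                          convergence = 0L, message = "nothing free"),
                     class = "adjevol_fit"))
  }
  opt <- stats::optim(th0, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = factr))
  u <- unpack(opt$par)
  st_out <- st
  st_out$length[branch_ids] <- u$lens
  params <- model_params(u$kappa, u$root_prob)
  loglik <- -opt$value
  conv <- opt$convergence
  if (loglik < ll0) {  # defensive: never return something worse than init
    params <- init; st_out <- st; loglik <- ll0; conv <- 1L
  }
  structure(list(params = params, species = st_out, loglik = loglik,
                 loglik_init = ll0,
                 iterations = unname(opt$counts["function"]),
                 convergence = conv,
                 message = if (is.null(opt$message)) "" else opt$message),
            class = "adjevol_fit")
}

#' @export
print.adjevol_fit <- function(x, ...) {
  cat("adjevol fit: logLik", format(x$loglik), "kappa",
      format(x$params$kappa), "root_prob", format(x$params$root_prob),
      "convergence", x$convergence, "\n")
  invisible(x)
}
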