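## Transition kernels of the two-state (absent/present) adjacency birth/death
## process. kappa is the gain/loss rate ratio; the generator is normalized so
## that one event per adjacency is expected per unit branch length at
## stationarity: q01 = (kappa+1)/2, q10 = (kappa+1)/(2*kappa), and the total
## rate scale is lambda = (kappa+1)^2 / (2*kappa).
##
## Duplications inside a branch have no date, so the kernels for
## duplication-born lineages are averaged uniformly over the possible dates:
## N1(t) for a single duplication, and the (x,0,0,0) components of
## P(t) (x) N11(t) for two independent duplications (one per gene tree),
## where (x) is the Kronecker product and N11 integrates uniformly over the
## ordered dates of the two duplications.

.check_kappa <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa <= 0)
    stop("kappa must be a positive scalar")
}
.check_t <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch duration t must be a non-negative scalar")
}

#' Rate matrix of the adjacency gain/loss process
#'
#' @param kappa Positive gain/loss rate ratio.
#' @return 2x2 generator with rows summing to zero; states ordered
#'   (absent, present). The off-diagonals are \code{(kappa+1)/2} (gain) and
#'   \code{(kappa+1)/(2*kappa)} (loss), so one event per unit duration is
#'   expected at stationarity.
#' @examples
#' rate_matrix(1)
#' @export
rate_matrix <- function(kappa) {
  .check_kappa(kappa)
  gain <- (kappa + 1) / 2
  loss <- (kappa + 1) / (2 * kappa)
  matrix(c(-gain, loss, gain, -loss), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Stationary distribution of the gain/loss process
#'
#' @param kappa Positive gain/loss rate ratio.
#' @return \code{c(pi0, pi1) = c(1, kappa) / (kappa + 1)}.
#' @export
stationary_distribution <- function(kappa) {
  .check_kappa(kappa)
  c(1, kappa) / (kappa + 1)
}

#' Transition probabilities over a branch
#'
#' Closed form of \code{expm(Q t)} for the two-state process:
#' \code{P01(t) = kappa (1 - exp(-lambda t)) / (kappa + 1)} with
#' \code{lambda = (kappa+1)^2 / (2 kappa)}.
#'
#' @param kappa Positive gain/loss rate ratio.
#' @param t Non-negative branch duration.
#' @return Row-stochastic 2x2 matrix, states (absent, present).
#' @export
transition_matrix <- function(kappa, t) {
  .check_kappa(kappa); .check_t(t)
  lam <- (kappa + 1)^2 / (2 * kappa)
  e <- exp(-lam * t)
  q <- -expm1(-lam * t)  # 1 - e, accurate near t = 0
  matrix(c((1 + kappa * e) / (kappa + 1), q / (kappa + 1),
           kappa * q / (kappa + 1), (kappa + e) / (kappa + 1)),
         2, 2, dimnames = list(c("0", "1"), c("0", "1")))
}

#' Date-averaged kernel for a single duplication (row from absent)
#'
#' The duplication-born lineage starts absent at a date uniform on the
#' branch, so its transition row is the uniform average
#' \code{(1/t) integral_0^t P(tau) dtau} restricted to source state 0.
#'
#' @param kappa Positive gain/loss rate ratio.
#' @param t Branch duration; \code{t = 0} returns the limit \code{c(1, 0)}.
#' @return \code{c(N00, N01)} summing to one.
#' @export
dup1_kernel <- function(kappa, t) {
  .check_kappa(kappa); .check_t(t)
  if (t < 1e-9) return(c(1, 0))
  lam <- (kappa + 1)^2 / (2 * kappa)
  x <- lam * t
  n00 <- (kappa * (-expm1(-x)) + x) / ((kappa + 1) * x)
  c(n00, 1 - n00)
}

## Coefficients of the source-0 row of P(v): P(v)[0, z] = A[z] + B[z] e^-lam v
.p0_coef <- function(kappa) {
  list(A = c(1, kappa) / (kappa + 1), B = c(kappa, -kappa) / (kappa + 1))
}

## N11 restricted to source (0,0,0): array dim c(2,2,2) over the final states
## of (first-born lineage, second-born lineage 1, second-born lineage 2).
## Exact closed form: every integrand is a linear combination of
## {1, u, e^-lam u, u e^-lam u, e^-2 lam u, e^-3 lam u}, integrated termwise.
.n11_vec <- function(kappa, t) {
  out <- array(0, c(2, 2, 2))
  lam <- (kappa + 1)^2 / (2 * kappa)
  x <- lam * t
  if (x < 1e-5) {
    ## first-order series (the exact form cancels catastrophically here):
    ## gain rate g = (kappa+1)/2; relative error O((lam t)^2)
    g <- (kappa + 1) / 2
    out[2, 1, 1] <- 2 / 3 * g * t
    out[1, 2, 1] <- 1 / 3 * g * t
    out[1, 1, 2] <- 1 / 3 * g * t
    out[1, 1, 1] <- 1 - out[2, 1, 1] - out[1, 2, 1] - out[1, 1, 2]
    return(out)
  }
  co <- .p0_coef(kappa)
  E <- function(j) -expm1(-j * x) / (j * lam)        # int_0^t e^-j lam u du
  FF <- (-expm1(-x) - x * exp(-x)) / lam^2           # int_0^t u e^-lam u du
  for (zL in 0:1) for (z1 in 0:1) for (z2 in 0:1) {
    A1 <- co$A[z1 + 1]; B1 <- co$B[z1 + 1]
    A2 <- co$A[z2 + 1]; B2 <- co$B[z2 + 1]
    ac <- A1 * A2; m <- A1 * B2 + A2 * B1; bd <- B1 * B2
    ## inner(u) = int_0^u P0z1(v) P0z2(v) dv = k0 + k1 u + k2 e^-lu + k3 e^-2lu
    k0 <- m / lam + bd / (2 * lam)
    k1 <- ac
    k2 <- -m / lam
    k3 <- -bd / (2 * lam)
    AL <- co$A[zL + 1]; BL <- co$B[zL + 1]
    val <- AL * k0 * t + AL * k1 * t^2 / 2 +
      (AL * k2 + BL * k0) * E(1) + (AL * k3 + BL * k2) * E(2) +
      BL * k3 * E(3) + BL * k1 * FF
    out[zL + 1, z1 + 1, z2 + 1] <- 2 / t^2 * val
  }
  out
}

#' Date-averaged kernel for duplications in both gene trees
#'
#' When both genes of an adjacency duplicate on the same species branch, the
#' duplication node has four children. One child inherits the adjacency
#' state along the whole branch (factor \code{P(t)}); the lineage born at
#' the first duplication starts absent and evolves for the residual time of
#' that (uniform) date; the two lineages born at the second duplication
#' start absent and evolve for its residual time. The kernel integrates
#' uniformly over the ordered pair of dates.
#'
#' @param kappa Positive gain/loss rate ratio.
#' @param t Branch duration; \code{t = 0} gives a point mass on
#'   \code{(x, 0, 0, 0)}.
#' @return A 2 x 16 matrix: rows are the source state of the inheriting
#'   lineage, columns the 16 outcome quadruples (inheriting, first-born,
#'   second-born 1, second-born 2) in binary order
#'   \code{(y1,y2,y3,y4) -> 8 y1 + 4 y2 + 2 y3 + y4 + 1}.
#' @export
dup2_kernel <- function(kappa, t) {
  .check_kappa(kappa); .check_t(t)
  P <- transition_matrix(kappa, t)
  nv <- .n11_vec(kappa, t)
  out <- matrix(0, 2, 16)
  cn <- character(16)
  for (y1 in 0:1) for (y2 in 0:1) for (y3 in 0:1) for (y4 in 0:1) {
    j <- 8 * y1 + 4 * y2 + 2 * y3 + y4 + 1
    out[, j] <- P[, y1 + 1] * nv[y2 + 1, y3 + 1, y4 + 1]
    cn[j] <- paste0(y1, y2, y3, y4)
  }
  dimnames(out) <- list(c("0", "1"), cn)
  out
}

## memoised kernel store for one kappa
.kernel_cache <- function(kappa) {
  env <- new.env(parent = emptyenv())
  env$kappa <- kappa
  env$P <- list(); env$tP <- list(); env$n1 <- list(); env$n11 <- list()
  env
}
.kc_P <- function(kc, t) {
  k <- as.character(t)
  if (is.null(kc$P[[k]])) kc$P[[k]] <- transition_matrix(kc$kappa, t)
  kc$P[[k]]
}
.kc_tP <- function(kc, t) {
  k <- as.character(t)
  if (is.null(kc$tP[[k]])) kc$tP[[k]] <- t(.kc_P(kc, t))
  kc$tP[[k]]
}
.kc_n1 <- function(kc, t) {
  k <- as.character(t)
  if (is.null(kc$n1[[k]])) kc$n1[[k]] <- dup1_kernel(kc$kappa, t)
  kc$n1[[k]]
}
.kc_n11 <- function(kc, t) {
  k <- as.character(t)
  if (is.null(kc$n11[[k]])) kc$n11[[k]] <- .n11_vec(kc$kappa, t)
  kc$n11[[k]]
}

#' Model parameters
#'
#' @param kappa Gain/loss rate ratio (> 0).
#' @param root_prob Probability that an adjacency is present at the root of
#'   a tree of possible adjacencies. Defaults to the stationary presence
#'   probability \code{kappa / (kappa + 1)}.
#' @return A \code{model_params} list.
#' @export
model_params <- function(kappa = 1, root_prob = kappa / (kappa + 1)) {
  .check_kappa(kappa)
  if (!is.numeric(root_prob) || root_prob < 0 || root_prob > 1)
    stop("root_prob must be in [0, 1]")
  structure(list(kappa = kappa, root_prob = root_prob),
            class = "model_params")
}
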