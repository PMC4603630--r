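test_that("the generator has ratio kappa and unit stationary flux", {
  expect_equal(rate_matrix(1), matrix(c(-1, 1, 1, -1), 2, 2,
                                      dimnames = list(c("0", "1"),
                                                      c("0", "1"))))
  for (k in c(0.2, 1, 3.7)) {
    Q <- rate_matrix(k)
    expect_equal(Q[1, 2] / Q[2, 1], k)
    expect_equal(rowSums(Q), c("0" = 0, "1" = 0))
    pi <- stationary_distribution(k)
    expect_lt(max(abs(pi %*% Q)), 1e-14)
    ## one expected event per unit duration at stationarity
    expect_equal(unname(pi[1] * Q[1, 2] + pi[2] * Q[2, 1]), 1)
  }
  expect_error(rate_matrix(-1), "positive")
  expect_equal(stationary_distribution(1), c(0.5, 0.5))
  expect_equal(stationary_distribution(3), c(0.25, 0.75))
})

test_that("P(t) is the matrix exponential of Q and a semigroup", {
  set.seed(2)
  for (i in 1:20) {
    k <- exp(runif(1, log(0.1), log(10)))
    t <- exp(runif(1, log(1e-3), log(20)))
    Q <- rate_matrix(k)
    ev <- eigen(Q)
    Pe <- ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors)
    expect_lt(max(abs(transition_matrix(k, t) - Pe)), 1e-10)
    a <- runif(1, 0, 3); b <- runif(1, 0, 3)
    expect_lt(max(abs(transition_matrix(k, a) %*% transition_matrix(k, b) -
                        transition_matrix(k, a + b))), 1e-12)
  }
  expect_equal(unname(transition_matrix(1.4, 0)), diag(2))
  ## long-time limit is the stationary distribution in both rows
  P <- transition_matrix(2, 1e4)
  expect_lt(max(abs(sweep(P, 2, stationary_distribution(2)))), 1e-12)
  expect_equal(transition_matrix(1, 1)[1, 2], (1 - exp(-2)) / 2)
  expect_error(transition_matrix(1, -1), "non-negative")
})

test_that("N1 matches its integral definition and known values", {
  ## kappa = 1, t = 1: (1/t) int_0^t P00 = (2 + 1 - e^-2)/4
  expect_equal(dup1_kernel(1, 1)[1], (1 - exp(-2) + 2) / 4)
  expect_equal(dup1_kernel(2, 0), c(1, 0))
  set.seed(3)
  for (i in 1:10) {
    k <- exp(runif(1, log(0.2), log(5)))
    t <- exp(runif(1, log(0.01), log(5)))
    n1 <- dup1_kernel(k, t)
    expect_equal(sum(n1), 1, tolerance = 1e-12)
    q <- stats::integrate(function(v) vapply(v, function(vv)
      transition_matrix(k, vv)[1, 1], 1), 0, t, rel.tol = 1e-12)$value / t
    expect_lt(abs(n1[1] - q), 1e-10)
  }
})

test_that("the double-duplication kernel integrates the stated process", {
  for (k in c(0.5, 2)) for (t in c(0.3, 1.5)) {
    D <- dup2_kernel(k, t)
    expect_equal(unname(rowSums(D)), c(1, 1), tolerance = 1e-12)
    expect_true(all(D >= 0 & D <= 1))
    ## marginal of the inheriting slot is exactly P(t)
    P <- transition_matrix(k, t)
    for (x in 0:1) for (y in 0:1) {
      cols <- which(substr(colnames(D), 1, 1) == as.character(y))
      expect_equal(sum(D[x + 1, cols]), P[x + 1, y + 1], tolerance = 1e-12)
    }
    ## against nested adaptive quadrature of the definition
    nv <- adjevol:::.n11_vec(k, t)
    for (zL in 0:1) for (z1 in 0:1) {
      got <- nv[zL + 1, z1 + 1, 2]  # z2 = 1 slice
      want <- stats::integrate(function(us) vapply(us, function(u) {
        pu <- transition_matrix(k, u)[1, zL + 1]
        inner <- stats::integrate(function(vs) vapply(vs, function(v) {
          pv <- transition_matrix(k, v)
          pv[1, z1 + 1] * pv[1, 2]
        }, 1), 0, u, rel.tol = 1e-11)$value
        pu * inner
      }, 1), 0, t, rel.tol = 1e-10)$value * 2 / t^2
      expect_lt(abs(got - want), 1e-8)
    }
  }
})

test_that("kernels are continuous at the small-t switch point", {
  for (k in c(0.5, 1, 3)) {
    lam <- (k + 1)^2 / (2 * k)
    below <- dup1_kernel(k, 9.9e-10)
    above <- dup1_kernel(k, 1.01e-9)
    expect_lt(max(abs(below - above)), 1e-8)
    ## around the series/closed-form switch of the N11 kernel, both
    ## branches must agree with the quadrature reference at the same point
    tsw <- 1e-5 / lam
    ref <- function(t, zL, z1, z2) {
      stats::integrate(function(us) vapply(us, function(u) {
        pu <- transition_matrix(k, u)[1, zL + 1]
        inner <- stats::integrate(function(vs) vapply(vs, function(v) {
          pv <- transition_matrix(k, v)
          pv[1, z1 + 1] * pv[1, z2 + 1]
        }, 1), 0, u, rel.tol = 1e-13)$value
        pu * inner
      }, 1), 0, t, rel.tol = 1e-12)$value * 2 / t^2
    }
    for (t in c(tsw * 0.99, tsw * 1.01)) {
      nv <- adjevol:::.n11_vec(k, t)
      expect_lt(abs(nv[1, 1, 1] - ref(t, 0, 0, 0)), 1e-8)
      expect_lt(abs(nv[2, 1, 1] - ref(t, 1, 0, 0)), 1e-8)
    }
    ## t = 0 limits: identity / point mass
    expect_equal(dup1_kernel(k, 0), c(1, 0))
    D0 <- dup2_kernel(k, 0)
    expect_equal(unname(D0[1, ]), c(1, rep(0, 15)))
    expect_equal(unname(D0[2, "1000"]), 1)
  }
})
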