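# Primal-dual interior point solver: L1 data term, L2 (NOSER) penalty.

# high-precision independent minimiser: smoothed objective, BFGS with
# beta-continuation down to 1e-9
pdipm_oracle <- function(J, b, lambda, Rw) {
  x <- rep(0, ncol(J))
  for (bb in c(1e-2, 1e-4, 1e-6, 1e-9)) {
    o <- function(x) sum(sqrt((J %*% x - b)^2 + bb^2)) + lambda * sum(Rw * x^2)
    g <- function(x) {
      r <- as.numeric(J %*% x - b)
      as.numeric(crossprod(J, r / sqrt(r^2 + bb^2))) + 2 * lambda * Rw * x
    }
    x <- optim(x, o, g, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))$par
  }
  x
}

objective <- function(J, b, lambda, Rw, x) sum(abs(J %*% x - b)) + lambda * sum(Rw * x^2)

test_that("tiny instances reach the independent optimum", {
  set.seed(7)
  for (rep in 1:4) {
    J <- matrix(rnorm(40), 8, 5)
    b <- rnorm(8)
    Rw <- colSums(J^2)^0.5
    lambda <- 0.1
    cfg <- pdipm_config(lambda = lambda, max_iterations = 300, convergence_tol = 1e-10)
    img <- reconstruct_pdipm(J, b, cfg, prior = Rw)
    ours <- objective(J, b, lambda, Rw, img$values)
    ref <- objective(J, b, lambda, Rw, pdipm_oracle(J, b, lambda, Rw))
    expect_lt(ours - ref, 1e-4)
  }
})

test_that("zero data give the zero minimiser and the log is empty", {
  J <- matrix(rnorm(40), 8, 5)
  img <- reconstruct_pdipm(J, rep(0, 8), pdipm_config(lambda = 0.1), prior = rep(1, 5))
  expect_equal(img$values, rep(0, 5))
  expect_true(attr(img, "converged"))
})

test_that("the objective never increases along accepted iterates", {
  set.seed(8)
  J <- disk16_jacobian()$matrix[, 1:80]
  b <- rnorm(nrow(J), 0, 1e-5)
  Rw <- colSums(J^2)^0.5
  img <- suppressWarnings(
    reconstruct_pdipm(J, b, pdipm_config(lambda = 1e-10, max_iterations = 60),
                      prior = Rw))
  log <- attr(img, "iterations")$objective
  expect_gt(length(log), 2)
  expect_true(all(diff(log) <= 1e-10))
})

test_that("solutions are invariant to row permutations of (J, dv)", {
  set.seed(9)
  J <- matrix(rnorm(60), 12, 5)
  b <- rnorm(12)
  Rw <- rep(1, 5)
  cfg <- pdipm_config(lambda = 0.2, max_iterations = 200, convergence_tol = 1e-12)
  x1 <- reconstruct_pdipm(J, b, cfg, prior = Rw)$values
  perm <- sample(12)
  x2 <- reconstruct_pdipm(J[perm, ], b[perm], cfg, prior = Rw)$values
  expect_equal(x2, x1, tolerance = 1e-3)
})

test_that("heavy regularisation drives the solution to zero", {
  set.seed(10)
  J <- matrix(rnorm(40), 8, 5)
  b <- rnorm(8)
  norms <- vapply(c(1, 1e2, 1e4, 1e6), function(l) {
    sqrt(sum(reconstruct_pdipm(J, b, pdipm_config(lambda = l), prior = rep(1, 5))$values^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  # stationarity bound: |x_i| <= ||J^T y||_inf / (2 lambda), |y| <= 1
  expect_lt(norms[4], sqrt(5) * max(abs(t(J) %*% rep(1, 8))) / (2 * 1e6) + 1e-10)
})

test_that("shrinking the smoothing recovers the unsmoothed L1 optimum", {
  set.seed(11)
  J <- matrix(rnorm(30), 6, 5)
  b <- rnorm(6)
  Rw <- rep(1, 5)
  lambda <- 0.05
  ref <- objective(J, b, lambda, Rw, pdipm_oracle(J, b, lambda, Rw))
  objs <- vapply(c(1e-2, 1e-4, 1e-6), function(bb) {
    img <- reconstruct_pdipm(J, b, pdipm_config(lambda = lambda, beta = bb,
                                                max_iterations = 500,
                                                convergence_tol = 1e-12),
                             prior = Rw)
    objective(J, b, lambda, Rw, img$values)
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-8))            # tighter smoothing: closer
  expect_lt(objs[3] - ref, 1e-4)
})
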