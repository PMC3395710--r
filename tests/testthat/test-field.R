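test_that("rectification clips negatives and is idempotent", {
  V <- matrix(c(-1, 0.5, 0, -0.2), 2, 2)
  expect_equal(rectify(V), matrix(c(0, 0.5, 0, 0), 2, 2))
  expect_equal(rectify(rectify(V)), rectify(V))
})

test_that("corrective gain is 1 at the center and matches the corner closed form", {
  p <- fieldParams()
  G <- correctiveGain(p, m = 33L)           # odd m puts a unit at the center
  expect_equal(G[17, 17], 1.0)
  # corner at distance sqrt(0.5): independent scalar evaluation
  expect_equal(G[1, 1], exp(-0.5 / (2 * 2.1^2)), tolerance = 1e-12)
  # invariant under quarter-turn rotations of the lattice
  rot <- function(M) t(M[nrow(M):1, ])
  expect_equal(G, rot(G))
  expect_equal(G, rot(rot(G)))
})

test_that("feed-forward input spans [0, G] between perfect match and maximal mismatch", {
  m <- 2L; n <- 4L
  G <- matrix(1, m, m)
  s <- c(0.2, 0.8, 0.5, 1)
  W <- matrix(rep(s, each = m * m), m * m, n)
  expect_equal(feedforwardInput(W, s, G), matrix(1, m, m))
  # weights and activations differing by 1 in every component
  W1 <- matrix(0, m * m, n)
  expect_equal(feedforwardInput(W1, rep(1, n), G), matrix(0, m, m))
})

test_that("feed-forward input equals a double-loop oracle on a 2x2 field", {
  set.seed(5)
  m <- 2L; n <- 4L
  W <- matrix(runif(m * m * n), m * m, n)
  s <- runif(n)
  G <- matrix(runif(m * m), m, m)
  I <- feedforwardInput(W, s, G)
  for (u in seq_len(m * m)) {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + abs(s[i] - W[u, i])
    expect_equal(as.vector(I)[u], as.vector(G)[u] * (1 - acc / n),
                 tolerance = 1e-12)
  }
})

test_that("shape mismatches in the input computation are rejected", {
  expect_error(feedforwardInput(matrix(0, 4, 3), rep(0, 4), matrix(1, 2, 2)),
               "receptor count")
})

test_that("the rest state is a fixed point and one step has the Euler closed form", {
  p <- tinyParams()
  k <- lateralKernels(p)
  Z <- matrix(0, p$m, p$m)
  expect_equal(fieldStep(Z, Z, k, p), Z)
  I <- 0.3 * correctiveGain(p)
  expect_equal(fieldStep(Z, I, k, p), (p$dt / p$tau) * I, tolerance = 1e-12)
})

test_that("a single Euler step from rest is linear in the input", {
  p <- tinyParams()
  k <- lateralKernels(p)
  Z <- matrix(0, p$m, p$m)
  set.seed(6)
  I1 <- matrix(runif(p$m^2), p$m, p$m)
  I2 <- matrix(runif(p$m^2), p$m, p$m)
  expect_equal(fieldStep(Z, I1 + I2, k, p),
               fieldStep(Z, I1, k, p) + fieldStep(Z, I2, k, p),
               tolerance = 1e-12)
})

test_that("dead units stay silent through any integration", {
  p <- tinyParams()
  k <- lateralKernels(p)
  mask <- matrix(FALSE, p$m, p$m); mask[3:5, 2:6] <- TRUE
  I <- matrix(0.8, p$m, p$m)
  st <- settleField(matrix(0, p$m, p$m), I, k, p, mask = mask,
                    max_steps = 200)
  expect_true(all(st$V[mask] == 0))
  # a fully lesioned field stays identically zero
  full <- matrix(TRUE, p$m, p$m)
  st2 <- settleField(matrix(0, p$m, p$m), I, k, p, mask = full,
                     max_steps = 20)
  expect_true(all(st2$V == 0))
})

test_that("settling is stationary: extra steps beyond convergence change nothing", {
  p <- tinyParams()
  k <- lateralKernels(p)
  I <- 0.4 * correctiveGain(p)
  a <- settleField(matrix(0, p$m, p$m), I, k, p, max_steps = 2000, tol = 1e-9)
  expect_true(a$converged)
  b <- settleField(a$V, I, k, p, max_steps = 4000, tol = 1e-9)
  expect_lt(max(abs(b$V - a$V)), 1e-6)
  # trivial case: zero input from rest converges immediately to rest
  z <- settleField(matrix(0, p$m, p$m), matrix(0, p$m, p$m), k, p)
  expect_true(z$converged)
  expect_equal(z$V, matrix(0, p$m, p$m))
})

test_that("the settled response to a localized input is a single bump", {
  p <- fieldParams(m = 16L)
  k <- lateralKernels(p)
  G <- correctiveGain(p)
  x <- seq(0, 1, length.out = 16)
  I <- G * outer(exp(-(x - 0.4)^2 / (2 * 0.1^2)),
                 exp(-(x - 0.6)^2 / (2 * 0.1^2)))
  st <- settleField(matrix(0, 16, 16), I, k, p, max_steps = 500, tol = 1e-8)
  Fv <- rectify(st$V)
  active <- Fv > 1e-6 * max(Fv)
  expect_equal(maskTopology(!active)$components_unlesioned, 1L)
})
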