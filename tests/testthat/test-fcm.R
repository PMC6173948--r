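test_that("objective evaluates the weighted sum of squared distances", {
  # crisp fit with zero distance at the assigned cluster
  U <- diag(2); D <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(fcmObjective(U, D, 2), 0)
  # hand case: n = 2, c = 2, all U = 0.5, all D = 1, m = 2
  expect_equal(fcmObjective(matrix(0.5, 2, 2), matrix(1, 2, 2), 2), 1)
  # closed form for uniform memberships and constant distance
  n <- 12; c <- 4; m <- 1.5; d <- 0.7
  expect_equal(fcmObjective(matrix(1 / c, n, c), matrix(d, n, c), m),
               n * c^(1 - m) * d^2)
})

test_that("membership update implements the distance-ratio formula", {
  # zero-distance singularity: full membership at the coincident centroid
  U <- updateMemberships(matrix(c(0, 2, 1, 3), 2, 2), 1.5)
  expect_equal(U[1, ], c(1, 0))
  # symmetry: equal distances give 1/c
  expect_equal(updateMemberships(matrix(2, 3, 4), 2)[1, ], rep(0.25, 4))
  # hand case: D = (1, 2), m = 2 so exponent 2/(m-1) = 2
  expect_equal(updateMemberships(matrix(c(1, 2), 1), 2)[1, ], c(0.8, 0.2))
  # rows always sum to one
  set.seed(5)
  D <- matrix(rexp(30) + 0.01, 10, 3)
  expect_equal(rowSums(updateMemberships(D, 1.3)), rep(1, 10))
})

test_that("centroid update implements the weighted-mean formula", {
  X <- rbind(c(0, 0, 0), c(2, 2, 2))
  # crisp: plain means
  expect_equal(updateCentroids(X, diag(2), 1.5), X)
  # uniform memberships: every centroid at the global mean
  V <- updateCentroids(X, matrix(0.5, 2, 2), 1.5)
  expect_equal(V[1, ], colMeans(X))
  expect_equal(V[2, ], colMeans(X))
  # hand case with weights (0.5^1.5, 1)
  w <- c(0.5^1.5, 1)
  V <- updateCentroids(X, matrix(c(0.5, 1), 2, 1), 1.5)
  expect_equal(V[1, ], colSums(w * X) / sum(w))
})

test_that("one compiled update cycle matches the naive loop oracle", {
  set.seed(7)
  for (n in c(6, 12)) {
    X <- matrix(rnorm(n * 5), n, 5)
    U <- matrix(runif(n * 2), n, 2); U <- U / rowSums(U)
    m <- 1.8
    ref <- oracle_fcm_cycle(X, U, m)
    fit <- fcmvalid:::.fcm_fit_cpp(X, fcmvalid:::.standardizeRows(X), U, m,
                                   1L, 0, 2L, 1e-6, 1L)
    expect_equal(max(abs(fit$V - ref$V)), 0, tolerance = 1e-12)
    expect_equal(max(abs(fit$D - ref$D)), 0, tolerance = 1e-12)
    expect_equal(max(abs(fit$U - ref$U)), 0, tolerance = 1e-12)
    expect_equal(tail(fit$J_history, 1), ref$J, tolerance = 1e-12)
  }
})

test_that("separable data is recovered near-crisply and deterministically", {
  X <- separable_fixture()
  fit <- runFCM(X, 2, seed = 3)
  expect_true(fit@converged)
  expect_true(all(apply(memberships(fit), 1, max) > 0.99))
  # the two blocks end up in different clusters
  lab <- max.col(memberships(fit))
  expect_equal(length(unique(lab[1:20])), 1)
  expect_true(lab[1] != lab[21])
  # determinism under the seed
  fit2 <- runFCM(X, 2, seed = 3)
  expect_identical(memberships(fit), memberships(fit2))
  expect_identical(objectiveHistory(fit), objectiveHistory(fit2))
})

test_that("single-cluster data yields near-uniform memberships", {
  ds <- generateOneCluster(n = 300, p = 40, seed = 11)
  fit <- runFCM(timecourses(ds), 3, seed = 1)
  expect_true(all(abs(memberships(fit) - 1 / 3) < 0.05))
})

test_that("objective descends on low-noise data and rows stay stochastic", {
  X <- separable_fixture(seed = 4)
  for (c in 2:4) {
    fit <- runFCM(X, c, seed = c)
    J <- objectiveHistory(fit)
    expect_lte(tail(J, 1), J[1])
    # the centroid update is heuristic for the correlation metric, so exact
    # per-step descent is not guaranteed; increases stay at rounding level
    expect_true(all(diff(J) <= 1e-6 * pmax(1, J[-length(J)])))
    expect_equal(rowSums(memberships(fit)), rep(1, nrow(X)),
                 tolerance = 1e-9)
    expect_true(validObject(fit))
  }
})

test_that("memberships flatten toward 1/c as m grows", {
  ds <- generateClusterDataset(3, n = 90, p = 40, sigma = 1, seed = 21)
  X <- timecourses(ds)
  flat <- function(m) max(abs(memberships(runFCM(X, 3, m = m, seed = 2)) -
                                1 / 3))
  expect_lt(flat(4), flat(2))
  expect_lt(flat(2), flat(1.5))
})

test_that("multi-restart selection returns the minimum-objective fit", {
  X <- separable_fixture(seed = 12)
  # nInit = 1 is exactly runFCM at that seed
  expect_identical(memberships(multiInitFCM(X, 2, nInit = 1, seed = 5)),
                   memberships(runFCM(X, 2, seed = 5)))
  fit <- multiInitFCM(X, 2, nInit = 10, seed = 5)
  expect_length(fit@restartJ, 10)
  expect_equal(tail(objectiveHistory(fit), 1), min(fit@restartJ))
  # easy data: every restart reaches the same minimum
  expect_lt(diff(range(fit@restartJ)) / min(fit@restartJ), 1e-6)
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- separable_fixture()
  expect_error(runFCM(X, 1), "2 <= c <= n")
  expect_error(runFCM(X, 2, m = 1), "exceed 1")
  expect_error(runFCM(X[, 1:2], 2), "at least")
  expect_error(updateCentroids(X, matrix(0, nrow(X), 2), 1.5), "degenerate")
})
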