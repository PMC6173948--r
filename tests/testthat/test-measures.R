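# a small converged partition reused across blocks
fixture_partition <- function(cTrue = 3, n = 60, p = 24, seed = 31) {
  ds <- generateClusterDataset(cTrue, n = n, p = p, sigma = 0.5, seed = seed)
  fit <- multiInitFCM(timecourses(ds), cTrue, nInit = 3, seed = seed)
  list(fit = fit, X = timecourses(ds))
}

test_that("fuzzy cardinality and variation have their closed forms", {
  n <- 20; c <- 4; m <- 1.5; d <- 0.3
  Uu <- matrix(1 / c, n, c)
  Dd <- matrix(d, n, c)
  expect_equal(fuzzyCardinality(Uu, 1), rep(n / c, c))
  expect_equal(fuzzyCardinality(Uu, m), rep(n * c^(-m), c))
  expect_equal(fuzzyVariation(Uu, Dd * 0, 1), rep(0, c))
  expect_equal(fuzzyVariation(Uu, Dd, m), rep(n * c^(-m) * d^2, c))
  # crisp memberships: member counts and within-cluster sums
  Uc <- diag(4)[rep(1:4, each = 5), ]
  expect_equal(fuzzyCardinality(Uc, 1), rep(5, 4))
  D2 <- matrix(seq_len(80) / 80, 20, 4)
  expect_equal(fuzzyVariation(Uc, D2, 1), colSums(Uc * D2^2))
})

test_that("pure-fuzzy partitions give FC = 1/c, FS = (c-1)/2, FO = c(c-1)/2", {
  for (c in c(2, 5, 9)) {
    n <- 30; p <- 12
    set.seed(c)
    X <- matrix(rnorm(n * p), n, p)
    part <- new("FuzzyPartition", U = matrix(1 / c, n, c),
                V = matrix(rnorm(c * p, sd = 1e-3), c, p) +
                  matrix(colMeans(X), c, p, byrow = TRUE),
                D = matrix(0.5, n, c), m = 1.5, JHistory = 1,
                nIter = 1L, converged = TRUE, seed = 1L, restartJ = 1,
                distance = "modified")
    cm <- compactnessMeasures(part)
    sm <- separationMeasures(part, colMeans(X))
    expect_equal(cm$FC, 1 / c)
    expect_equal(sm$FS, (c - 1) / 2)
    expect_equal(sm$FO, c * (c - 1) / 2)
    # uniform U, constant D: pi_m1 = c^(2-m) d^2
    expect_equal(cm$piM1, c^(2 - 1.5) * 0.25)
  }
})

test_that("crisp partitions give FC = 1", {
  U <- diag(3)[rep(1:3, each = 4), ]
  part <- new("FuzzyPartition", U = U, V = matrix(rnorm(9), 3, 3),
              D = matrix(0.2, 12, 3), m = 1.5, JHistory = 1, nIter = 1L,
              converged = TRUE, seed = 1L, restartJ = 1,
              distance = "modified")
  expect_equal(compactnessMeasures(part)$FC, 1)
})

test_that("separation scalars hit their analytic special cases", {
  n <- 10; p <- 6
  set.seed(3)
  X <- matrix(rnorm(n * p), n, p)
  xbar <- colMeans(X)
  # all centroids at the grand-mean level: no separation
  gm <- rep(mean(xbar), p)
  part <- new("FuzzyPartition", U = matrix(0.5, n, 2),
              V = rbind(gm, gm), D = matrix(0.4, n, 2), m = 2,
              JHistory = 1, nIter = 1L, converged = TRUE, seed = 1L,
              restartJ = 1, distance = "modified")
  sm <- separationMeasures(part, xbar)
  expect_equal(sm$Km, 0)
  expect_equal(sm$S, 0)
  expect_true(is.na(sm$SS))   # coincident centroids: degenerate
  # two centroids at Euclidean distance d: SS = 2/d
  d <- 3.5
  V <- rbind(rep(0, p), c(d, rep(0, p - 1)))
  part2 <- new("FuzzyPartition", U = matrix(0.5, n, 2), V = V,
               D = matrix(0.4, n, 2), m = 2, JHistory = 1, nIter = 1L,
               converged = TRUE, seed = 1L, restartJ = 1,
               distance = "modified")
  expect_equal(separationMeasures(part2, rep(0, p))$SS, 2 / d)
})

test_that("centroid distance summaries enumerate pairs correctly", {
  # collinear centroids at 0, 1, 3 on the first axis
  V <- cbind(c(0, 1, 3), 0, 0)
  cd <- centroidDistances(V)
  expect_equal(cd$Vdmin, 1)
  expect_equal(cd$Vdmax, 3)
  expect_equal(cd$VdminPerCluster, c(1, 1, 2))
  # a duplicated centroid is a redundancy detector
  expect_equal(centroidDistances(rbind(V, V[2, ]))$Vdmin, 0)
  # equilateral triple
  Ve <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  cde <- centroidDistances(Ve)
  expect_equal(cde$Vdmin, 1)
  expect_equal(cde$Vdmax, 1)
})

test_that("dissimilarity coefficients match their defining ratios", {
  # perfectly symmetric partition: both coefficients equal 1
  U <- matrix(0.5, 20, 2)
  D <- matrix(0.3, 20, 2)
  id <- dissimilarityCoefficients(U, D)
  expect_equal(id$IDintra, 1)
  expect_equal(id$IDinter, 1)
  # one cluster with half the variation of the (equal) others
  U3 <- matrix(1 / 3, 18, 3)
  D3 <- cbind(rep(sqrt(0.5), 18), rep(1, 18), rep(1, 18))
  expect_equal(dissimilarityCoefficients(U3, D3)$IDinter, 0.5)
  # hand case: c = 2, n1 = (25, 75), sigma1 = (2, 6), n = 100
  U2 <- rbind(matrix(c(1, 0), 25, 2, byrow = TRUE),
              matrix(c(0, 1), 75, 2, byrow = TRUE))
  D2 <- cbind(c(rep(sqrt(2 / 25), 25), rep(0, 75)),
              c(rep(0, 25), rep(sqrt(6 / 75), 75)))
  id2 <- dissimilarityCoefficients(U2, D2)
  expect_equal(id2$IDintra, 1)
  # zero variation propagates the degenerate sentinel
  expect_true(is.na(dissimilarityCoefficients(U, D * 0)$IDintra))
})

test_that("every measure matches the naive loop oracle on random fixtures", {
  set.seed(17)
  for (rep in 1:5) {
    U <- matrix(runif(30), 10, 3); U <- U / rowSums(U)
    D <- matrix(rexp(30) + 0.05, 10, 3)
    V <- matrix(rnorm(3 * 7), 3, 7)
    X <- matrix(rnorm(10 * 7), 10, 7)
    m <- 1 + runif(1, 0.2, 1.5)
    part <- new("FuzzyPartition", U = U, V = V, D = D, m = m,
                JHistory = 1, nIter = 1L, converged = TRUE, seed = 1L,
                restartJ = 1, distance = "modified")
    ms <- computeMeasures(part, X)
    om <- oracle_measures(U, D, V, X, m)
    expect_equal(ms@n1, om$n1, tolerance = 1e-12)
    expect_equal(ms@nm, om$nm, tolerance = 1e-12)
    expect_equal(ms@sigma1, om$s1, tolerance = 1e-12)
    expect_equal(ms@sigmam, om$sm, tolerance = 1e-12)
    expect_equal(ms@piM1, om$piM1, tolerance = 1e-12)
    expect_equal(ms@piMM, om$piMM, tolerance = 1e-12)
    expect_equal(ms@FC, om$FC, tolerance = 1e-12)
    expect_equal(ms@Km, om$Km, tolerance = 1e-12)
    expect_equal(ms@K1, om$K1, tolerance = 1e-12)
    expect_equal(ms@FS, om$FS, tolerance = 1e-12)
    expect_equal(ms@S, om$S, tolerance = 1e-12)
    expect_equal(ms@SS, om$SS, tolerance = 1e-12)
    expect_equal(ms@FO, om$FO, tolerance = 1e-12)
    expect_equal(ms@Vdmin, om$Vdmin, tolerance = 1e-12)
    expect_equal(ms@Vdmax, om$Vdmax, tolerance = 1e-12)
    expect_equal(ms@VdminPerCluster, om$Vdminj, tolerance = 1e-12)
    expect_equal(ms@IDintra, om$IDintra, tolerance = 1e-12)
    expect_equal(ms@IDinter, om$IDinter, tolerance = 1e-12)
    expect_equal(ms@J1, om$J1, tolerance = 1e-12)
    expect_equal(ms@Jm, om$Jm, tolerance = 1e-12)
    # fuzzy cardinalities with exponent 1 always sum to n
    expect_equal(sum(ms@n1), nrow(U), tolerance = 1e-10)
    expect_true(validObject(ms))
  }
})

test_that("measureRow flattens a MeasureSet into the sweep table layout", {
  fp <- fixture_partition()
  ms <- computeMeasures(fp$fit, fp$X)
  row <- measureRow(ms)
  expect_equal(nrow(row), 1)
  expect_equal(row$c, 3)
  expect_equal(row$J1, sum(ms@sigma1))
  expect_true(all(c("FC", "Km", "FS", "SS", "Vdmin", "IDinter") %in%
                    names(row)))
})
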