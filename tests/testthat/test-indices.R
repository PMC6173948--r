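# measures from a real small partition, for hand-checking index formulas
toy_measures <- function(cTrue = 3, seed = 41) {
  ds <- generateClusterDataset(cTrue, n = 60, p = 20, sigma = 0.5,
                               seed = seed)
  fit <- multiInitFCM(timecourses(ds), cTrue, nInit = 3, seed = seed)
  list(ms = computeMeasures(fit, timecourses(ds)), X = timecourses(ds),
       fit = fit)
}

test_that("optimisation directions follow the published conventions", {
  dirs <- cvDirections()
  expect_equal(unname(dirs[c("cv_rlr", "cv_kp")]), c("min", "min"))
  expect_equal(unname(dirs[c("cv_zle", "cv_gv", "cv_pbm", "cv_wy",
                             "cv_bws", "cv_new")]), rep("max", 6))
})

test_that("every index matches a naive re-implementation on real fixtures", {
  for (seed in c(41, 42, 43)) {
    toy <- toy_measures(seed = seed)
    ms <- toy$ms
    alphas <- c(cv_rlr = 2.5, cv_zle = 1.8, cv_kp = 4.2, cv_pbm = ms@n)
    got <- computeIndexPanel(ms, alphas)
    om <- oracle_measures(memberships(toy$fit), distances(toy$fit),
                          centroids(toy$fit), toy$X, fuzziness(toy$fit))
    ref <- oracle_indices(om, toy$X, ms@c, ms@m, ms@n, alphas)
    for (ix in names(ref))
      expect_equal(unname(got[[ix]]), ref[[ix]], tolerance = 1e-10,
                   label = ix)
  }
})

test_that("index special cases hold", {
  toy <- toy_measures()
  ms <- toy$ms
  # RLR second term equals 1 when alpha is fixed at this partition's own value
  alpha_self <- ms@Vdmax / ms@Vdmin * ms@SS
  first_term <- sum(ms@sigma1) / (ms@c * ms@sigmaXNorm)
  expect_equal(cvRLR(ms, alpha_self), first_term + 1, tolerance = 1e-12)
  # halving all sigma_1 halves the RLR first term (linearity)
  ms2 <- ms; ms2@sigma1 <- ms@sigma1 / 2
  expect_equal(cvRLR(ms2, alpha_self) - 1, (first_term) / 2,
               tolerance = 1e-12)
  # KP normalisation: second term equals 1 at its own alpha
  alpha_kp <- ms@c / ms@Vdmin
  pi11 <- sum(ms@sigma1 / ms@n1)
  expect_equal(cvKP(ms, alpha_kp), pi11 / ms@c + 1, tolerance = 1e-12)
  # GV linearity in K1 and zero at coincident centroids
  ms3 <- ms; ms3@K1 <- 2 * ms@K1
  expect_equal(cvGV(ms3), 2 * cvGV(ms), tolerance = 1e-12)
  ms4 <- ms; ms4@K1 <- 0
  expect_equal(cvGV(ms4), 0)
  # PBM proportional to its alpha = n
  expect_equal(cvPBM(ms, 2 * ms@n), 2 * cvPBM(ms), tolerance = 1e-12)
  ms5 <- ms; ms5@Vdmax <- 0
  expect_equal(cvPBM(ms5), 0)
  # BWS is a pure scale-free ratio
  ms6 <- ms; ms6@Km <- 2 * ms@Km; ms6@piMM <- 2 * ms@piMM
  expect_equal(cvBWS(ms6), cvBWS(ms), tolerance = 1e-12)
  ms7 <- ms; ms7@Km <- 0
  expect_equal(cvBWS(ms7), 0)
  expect_equal(cvNew(ms7), 0)
  # ZLE at S = 0 reduces to minus the fuzzy overlap
  ms8 <- ms; ms8@S <- 0
  expect_equal(cvZLE(ms8, 3), -ms@FS / ms@FC, tolerance = 1e-12)
})

test_that("Wu-Yang index respects its published range and limits", {
  toy <- toy_measures()
  ms <- toy$ms
  expect_lte(cvWY(ms), ms@c)
  expect_gte(cvWY(ms), -ms@c)
  # coincident centroids with equal cardinalities: exactly 0
  msc <- ms
  msc@n1 <- rep(ms@n / ms@c, ms@c)
  msc@VdminPerCluster <- rep(0, ms@c)
  expect_equal(cvWY(msc), 0)
  # widely separated centroids approach c from below
  msf <- msc
  msf@VdminPerCluster <- rep(1e6, ms@c)
  expect_equal(cvWY(msf), ms@c, tolerance = 1e-6)
  # random fixtures stay inside [-c, c]
  set.seed(9)
  for (rep in 1:10) {
    msr <- ms
    msr@n1 <- runif(ms@c, 1, 50)
    msr@VdminPerCluster <- runif(ms@c, 0, 5)
    msr@S <- runif(1, 0.1, 5)
    expect_lte(cvWY(msr), ms@c)
    expect_gte(cvWY(msr), -ms@c)
  }
})

test_that("alpha constants are fixed from the top-of-sweep partition", {
  toy <- toy_measures()
  ms <- toy$ms
  a <- alphaAtCmax(ms)
  expect_equal(unname(a["cv_rlr"]), ms@Vdmax / ms@Vdmin * ms@SS)
  expect_equal(unname(a["cv_zle"]), ms@FO)
  expect_equal(unname(a["cv_kp"]), ms@c / ms@Vdmin)
  expect_equal(unname(a["cv_pbm"]), ms@n)
})

test_that("degenerate and redundant partitions can never win", {
  toy <- toy_measures()
  ms <- toy$ms
  alphas <- alphaAtCmax(ms)
  # coincident centroids: Vdmin at rounding level relative to the data scale
  msr <- ms; msr@Vdmin <- 1e-9 * ms@dataScale
  expect_true(is.na(cvRLR(msr, alphas[["cv_rlr"]])))
  expect_true(is.na(cvKP(msr, alphas[["cv_kp"]])))
  expect_true(all(is.na(computeIndexPanel(msr, alphas))))
  # a healthy panel is fully finite
  expect_true(all(is.finite(computeIndexPanel(ms, alphas))))
})

test_that("selection applies directions, tie-breaks and sentinel exclusion", {
  expect_equal(selectCOpt(c(0.3, 0.1, 0.2), 2:4, "cv_rlr"), 3L)
  expect_equal(selectCOpt(c(0.3, 0.5, 0.5), 2:4, "cv_new"), 3L)  # tie: small c
  expect_equal(selectCOpt(c(0.3, NA, 0.5), 2:4, "cv_new"), 4L)
  expect_equal(selectCOpt(c(0.9, NA, NA), 2:4, "cv_kp"), 2L)
  expect_error(selectCOpt(c(NA_real_, NA_real_), 2:3, "cv_new"),
               "degenerate")
})
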