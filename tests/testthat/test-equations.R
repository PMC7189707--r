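test_that("within-population single-GRM accuracy matches the closed form", {
  expect_equal(wpsgAccuracy(h2 = 0.3, n = 476, me = 280, rho2 = 0.8),
               0.5198064, tolerance = 1e-6)
  expect_equal(wpsgAccuracy(0.3, 476, 280, 0), 0)
  # asymptote: with rho2 = 1 and unbounded training the accuracy tends to 1
  expect_equal(wpsgAccuracy(0.5, 1e9, 280, 1), 1, tolerance = 1e-6)
  expect_equal(wpsgAccuracy(0.3, 0, 280, 0.8), 0)
})

test_that("equation inputs are validated", {
  expect_error(wpsgAccuracy(0.3, 476, -5, 0.8), "Me must be positive")
  expect_error(wpsgAccuracy(0.3, 476, 0, 0.8), "Me must be positive")
  expect_error(wpsgAccuracy(1.2, 476, 280, 0.8), "h2")
  expect_error(wpsgAccuracy(0.3, 476, 280, 1.3), "rho2")
  expect_error(relativeChange(0.5, 0), "positive")
  expect_error(predictionInputs(h2A = 0.3, nA = 476, rho21 = 0.7,
                                rho22 = 0.7, meA1 = 100),
               "rho21 \\+ rho22")
})

test_that("within-population two-GRM accuracy matches direct evaluation", {
  pi1 <- predictionInputs(h2A = 0.3, nA = 476, rho21 = 0.4, rho22 = 0.4,
                          meA1 = 159, meA2 = 280)
  expect_equal(wpmgAccuracy(pi1), 0.5695294, tolerance = 1e-6)
  # single informative set reduces to the single-GRM formula on that set
  pi2 <- tweakInputs(pi1, rho21 = 1, rho22 = 0)
  expect_equal(wpmgAccuracy(pi2), 0.6878670, tolerance = 1e-6)
  expect_equal(wpmgAccuracy(pi2), wpsgAccuracy(0.3, 476, 159, 1))
  expect_equal(wpmgAccuracy(tweakInputs(pi1, rho21 = 0, rho22 = 0)), 0)
})

test_that("multi-population single-GRM accuracy matches the two-source index", {
  expect_equal(mpsgAccuracy(0.3, 0.3, 476, 5553, rho2A = 0.8, rg = 1,
                            meA = 280, meAB = 33242),
               0.5359264, tolerance = 1e-6)
  # rg = 0 and nB = 0 both cut off population B entirely
  expect_equal(mpsgAccuracy(0.3, 0.3, 476, 5553, 0.8, 0, 280, 33242),
               wpsgAccuracy(0.3, 476, 280, 0.8))
  expect_equal(mpsgAccuracy(0.3, 0.3, 476, 0, 0.8, 0.9, 280, 33242),
               wpsgAccuracy(0.3, 476, 280, 0.8))
  expect_equal(mpsgAccuracy(0.3, 0.3, 476, 5553, 0.8, 0.6, 280, 1000),
               0.5963382, tolerance = 1e-6)
  expect_equal(mpsgAccuracy(0.3, 0.3, 476, 5553, 0.8, 0.6, 280, 20000),
               0.5291525, tolerance = 1e-6)
})

test_that("two-source index accuracy agrees with cofactor-expansion arithmetic", {
  set.seed(401)
  for (i in 1:200) {
    h2A <- runif(1, 0.05, 1); h2B <- runif(1, 0.05, 1)
    nA <- sample(50:2000, 1); nB <- sample(50:9000, 1)
    rho2 <- runif(1); rg <- runif(1, -1, 1)
    meA <- runif(1, 20, 2000); meAB <- runif(1, 50, 50000)
    a <- h2A / meA; b <- h2B / meAB
    g1 <- sqrt(rho2) * sqrt(a); g2 <- sqrt(rho2) * rg * sqrt(b)
    p11 <- a + 1 / nA; p22 <- b + 1 / nB; p12 <- rg * sqrt(a * b)
    det <- p11 * p22 - p12 * p12
    quad <- (g1 * g1 * p22 - 2 * g1 * g2 * p12 + g2 * g2 * p11) / det
    expect_equal(mpsgAccuracy(h2A, h2B, nA, nB, rho2, rg, meA, meAB),
                 sqrt(quad), tolerance = 1e-12)
  }
})

test_that("the four-source index has the documented structure", {
  case1 <- predictionInputs(h2A = 0.3, h2B = 0.3, nA = 476, nB = 5553,
                            rho21 = 0.4, rho22 = 0.4, rg = 1,
                            meA1 = 159, meAB1 = 463,
                            meA2 = 280, meAB2 = 32970)
  idx <- buildMpmgIndex(case1)
  expect_equal(idx@P[1, 1], 0.0039876, tolerance = 1e-4)
  expect_equal(idx@P[2, 2], 0.00082804, tolerance = 1e-4)
  # no coupling between the two SNP-set blocks
  expect_true(all(idx@P[1:2, 3:4] == 0) && all(idx@P[3:4, 1:2] == 0))
  idx0 <- buildMpmgIndex(tweakInputs(case1, rg1 = 0, rg2 = 0))
  expect_equal(idx0@P[1, 2], 0)
  expect_equal(idx0@P[3, 4], 0)
  expect_equal(selectionIndexAccuracy(idx), 0.6862204, tolerance = 1e-6)
})

test_that("index accuracy follows sqrt(g' P^-1 g) and flags degeneracies", {
  # diagonal P with g equal to the reliabilities: accuracy sqrt(r1^2 + r2^2)
  r2 <- c(0.21, 0.34)
  ix <- new("SelectionIndex", g = r2, P = diag(r2))
  expect_equal(selectionIndexAccuracy(ix), sqrt(sum(r2)))
  expect_equal(selectionIndexAccuracy(new("SelectionIndex", g = c(0, 0),
                                          P = diag(c(0.2, 0.4)))), 0)
  expect_error(selectionIndexAccuracy(
    new("SelectionIndex", g = c(0.1, 0.1),
        P = matrix(c(1, 1, 1, 1), 2))), "positive definite")
  expect_error(selectionIndexAccuracy(
    new("SelectionIndex", g = c(0.9, 0.9), P = diag(c(0.5, 0.5)))),
    "inconsistent")
})

test_that("scalar and matrix forms of the multi-population accuracy agree", {
  set.seed(402)
  for (i in 1:1000) {
    pi <- randomPredictionInputs()
    m <- mpmgAccuracy(pi, form = "matrix")
    s <- mpmgAccuracy(pi, form = "scalar")
    expect_lte(abs(s - m), 1e-10 * max(m, 1e-12))
  }
})

test_that("the multi-population equation reduces correctly at its boundaries", {
  set.seed(403)
  for (i in 1:200) {
    pi <- randomPredictionInputs()
    # rg = 0: population B carries no information, within-population value
    pi0 <- tweakInputs(pi, rg1 = 0, rg2 = 0)
    expect_equal(mpmgAccuracy(pi0), wpmgAccuracy(pi0), tolerance = 1e-12)
    # rho22 = 0: second set carries no variance, single-GRM two-population
    piA <- tweakInputs(pi, rho22 = 0)
    expect_equal(mpmgAccuracy(piA),
                 mpsgAccuracy(piA@h2A, piA@h2B, piA@nA, piA@nB,
                              rho2A = piA@rho21, rg = piA@rg1,
                              meA = piA@meA1, meAB = piA@meAB1),
                 tolerance = 1e-12)
  }
})

test_that("accuracy moves monotonically with each input", {
  set.seed(404)
  up <- list(nA = 1.2, nB = 1.2, h2A = 0.98, rho21 = 0.98, rho22 = 0.98)
  for (i in 1:50) {
    pi <- randomPredictionInputs()
    base <- mpmgAccuracy(pi)
    expect_gte(base, 0); expect_lte(base, 1)
    # more data, higher heritability, more captured variance: no worse
    for (nm in names(up)) {
      v <- if (up[[nm]] > 1) slot(pi, nm) * up[[nm]]
           else slot(pi, nm) + (1 - slot(pi, nm)) * 0.5
      if (nm %in% c("rho21", "rho22") &&
          v + slot(pi, setdiff(c("rho21", "rho22"), nm)) > 1) next
      tweaked <- do.call(tweakInputs, c(list(pi), setNames(list(v), nm)))
      expect_gte(mpmgAccuracy(tweaked) - base, -1e-12)
    }
    # stronger genetic correlation: no worse
    piUp <- tweakInputs(pi, rg1 = sign(pi@rg1 + 1e-12) * min(1, abs(pi@rg1) * 1.1 + 0.01))
    piUp <- tweakInputs(piUp, rg2 = piUp@rg1)
    pi2 <- tweakInputs(pi, rg2 = pi@rg1)
    expect_gte(mpmgAccuracy(piUp) - mpmgAccuracy(pi2), -1e-12)
    # larger Me (less information per segment): no better
    for (nm in c("meA1", "meA2", "meAB1", "meAB2")) {
      tweaked <- do.call(tweakInputs,
                         c(list(pi), setNames(list(slot(pi, nm) * 1.3), nm)))
      expect_lte(mpmgAccuracy(tweaked) - base, 1e-12)
    }
  }
})

test_that("percent changes reproduce the benchmark figures", {
  expect_equal(round(relativeChange(0.5696, 0.5198), 1), 9.6)
  expect_equal(round(relativeChange(0.5291, 0.5963), 1), -11.3)
  expect_equal(relativeChange(0.42, 0.42), 0)
})

test_that("prediction inputs can be read from a flat config file", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("h2A: 0.3", "h2B: 0.3", "nA: 476", "nB: 5553",
               "rho21: 0.4", "rho22: 0.4", "rg: 1",
               "meA1: 159", "meAB1: 463", "meA2: 280", "meAB2: 32970"), f)
  pi <- readPredictionConfig(f)
  expect_s4_class(pi, "PredictionInputs")
  expect_equal(mpmgAccuracy(pi), 0.6862204, tolerance = 1e-6)
  writeLines(c("h2A: 0.3", "bogus: 1"), f)
  expect_error(readPredictionConfig(f), "unknown configuration keys")
})
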