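# shared small two-population data set for the GBLUP tests
makeGblupData <- function(seed = 201, nA = 30, nB = 40, nSnps = 120,
                          nCausal = 40, h2 = 0.5, rg = 0.6, level = 20) {
  cfg <- simulationConfig(nA = nA, nB = nB, nSnps = nSnps, nCausal = nCausal,
                          fst = 0.05, seed = seed, replicates = 1)
  g <- simulateGenotypes(cfg)
  causal <- sort(snpIds(g)[seq_len(nCausal)])
  part <- partitionCausal(causal, snpIds(g), level, seed = seed + 1,
                          includeUnselectedCausal = TRUE)
  eff <- sampleEffects(causal, rg, seed = seed + 2)
  ph <- simulatePhenotypes(g, eff, h2, h2, seed = seed + 3,
                           selected = part@selected)
  list(g = g, part = part, ph = ph,
       grm1 = buildGRM(g, part@selected),
       grm2 = buildGRM(g, part@remaining),
       vc = truthComponents(ph, rg))
}

test_that("truth components mirror the simulated variance structure", {
  d <- makeGblupData()
  expect_s4_class(d$vc, "VarianceComponents")
  expect_equal(unname(d$vc@K1["A", "A"]),
               var(d$ph@tgv1[d$ph@population == "A"]))
  expect_equal(unname(d$vc@K1["A", "B"]),
               0.6 * sqrt(d$vc@K1["A", "A"] * d$vc@K1["B", "B"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # rg = 0: no genetic covariance between populations
  vc0 <- truthComponents(d$ph, 0)
  expect_equal(unname(vc0@K1["A", "B"]), 0)
  # h2 = 1: no residual variance
  ph1 <- simulatePhenotypes(d$g, d$ph@effects, 1, 1, seed = 9,
                            selected = d$part@selected)
  expect_equal(max(truthComponents(ph1, 0.6)@residVar), 0)
  # an even causal split puts genetic variance on both GRMs (the averaged
  # half/half property is asserted over replicates in the simulator tests)
  frac <- unname(d$vc@K1["A", "A"] / (d$vc@K1["A", "A"] + d$vc@K2["A", "A"]))
  expect_gt(frac, 0.1); expect_lt(frac, 0.9)
})

test_that("best linear prediction agrees with the mixed-model equations", {
  # single population, single GRM, <= 50 individuals, ridged to keep G
  # invertible for the MME oracle
  cfg <- simulationConfig(nA = 40, nB = 0, nSnps = 150, nCausal = 30,
                          fst = 0.05, seed = 210, replicates = 1)
  g <- simulateGenotypes(cfg)
  grm <- buildGRM(g)
  AA <- grmBlock(grm, "AA") + diag(1e-6, 40)
  grmR <- new("MultiPopGRM", AA = AA, BB = grm@BB, AB = grm@AB,
              freqA = grm@freqA, freqB = grm@freqB, snps = grm@snps)
  eff <- sampleEffects(snpIds(g)[1:30], 1, seed = 211)
  ph <- simulatePhenotypes(g, eff, 0.4, seed = 212)
  s2g <- unname(ph@sigma2g["A"])
  s2e <- unname(ph@residVar["A"])
  vc <- varianceComponents(matrix(s2g, 1, 1, dimnames = list("A", "A")),
                           matrix(0, 1, 1, dimnames = list("A", "A")),
                           c(A = s2e))
  valIds <- sampleIds(g)[1:8]
  res <- predictEgv(grmR, NULL, vc, phenotypes(ph), populations(ph), valIds)
  trainIdx <- 9:40
  mme <- mmeOracle(AA, phenotypes(ph)[trainIdx], trainIdx, s2g, s2e)
  expect_equal(unname(egvTotal(res)), unname(mme$u[1:8]), tolerance = 1e-8)
})

test_that("prediction collapses sensibly in degenerate settings", {
  d <- makeGblupData()
  valIds <- sampleIds(d$g)[populations(d$g) == "A"][1:6]
  # overwhelming residual noise: no information, EGV ~ 0
  vcNoise <- varianceComponents(d$vc@K1, d$vc@K2,
                                setNames(rep(1e8, 2), names(d$vc@residVar)))
  resN <- predictEgv(d$grm1, d$grm2, vcNoise, phenotypes(d$ph),
                     populations(d$ph), valIds)
  expect_lt(max(abs(egvTotal(resN))), 1e-3)
  # zero second component: total EGV is the first component
  vc1 <- varianceComponents(d$vc@K1, d$vc@K2 * 0, d$vc@residVar)
  res1 <- predictEgv(d$grm1, NULL, vc1, phenotypes(d$ph),
                     populations(d$ph), valIds)
  expect_equal(egvTotal(res1), res1@egv1)
  expect_true(all(res1@egv2 == 0))
  # two-GRM call with zero K2 matches the single-GRM call
  res1b <- predictEgv(d$grm1, d$grm2, vc1, phenotypes(d$ph),
                      populations(d$ph), valIds)
  expect_equal(egvTotal(res1b), egvTotal(res1))
})

test_that("cross-validation holds out every target individual exactly once", {
  d <- makeGblupData()
  res <- crossValidate(d$grm1, d$grm2, d$vc, phenotypes(d$ph),
                       populations(d$ph), k = 5, seed = 220)
  aIds <- sampleIds(d$g)[populations(d$g) == "A"]
  expect_setequal(names(egvTotal(res)), aIds)
  expect_equal(as.vector(table(res@fold)), rep(6L, 5))
  res2 <- crossValidate(d$grm1, d$grm2, d$vc, phenotypes(d$ph),
                        populations(d$ph), k = 5, seed = 220)
  expect_identical(egvTotal(res), egvTotal(res2))
  expect_error(crossValidate(d$grm1, d$grm2, d$vc, phenotypes(d$ph),
                             populations(d$ph), k = 1, seed = 1),
               "invalid parameter")
  # leave-one-out degenerates gracefully
  resLoo <- crossValidate(d$grm1, d$grm2, d$vc, phenotypes(d$ph),
                          populations(d$ph), k = 30, seed = 221)
  expect_length(egvTotal(resLoo), 30)
})

test_that("empirical accuracy is the held-out EGV/TGV correlation", {
  d <- makeGblupData()
  res <- crossValidate(d$grm1, d$grm2, d$vc, phenotypes(d$ph),
                       populations(d$ph), k = 5, seed = 222)
  acc <- empiricalAccuracy(res, trueGenomicValues(d$ph))
  expect_true(acc >= -1 && acc <= 1)
  expect_gt(acc, 0.2)  # informative model on its own data
  # perfect prediction
  fake <- new("GBLUPResult",
              egv1 = trueGenomicValues(d$ph)[1:10],
              egv2 = trueGenomicValues(d$ph)[1:10] * 0,
              egvTotal = trueGenomicValues(d$ph)[1:10],
              fold = rep(1L, 10))
  expect_equal(empiricalAccuracy(fake, trueGenomicValues(d$ph)), 1)
  flat <- new("GBLUPResult", egv1 = rep(0, 5), egv2 = rep(0, 5),
              egvTotal = setNames(rep(0, 5), names(d$ph@tgv)[1:5]),
              fold = rep(1L, 5))
  expect_error(empiricalAccuracy(flat, trueGenomicValues(d$ph)),
               "degenerate")
  expect_error(accuracySummary(0.5), "invalid parameter")
  expect_equal(unname(accuracySummary(c(0.4, 0.6))), c(0.5, sd(c(0.4, 0.6))))
})

test_that("noise-only prediction has accuracy centred at zero", {
  d <- makeGblupData(seed = 230)
  vcNoise <- varianceComponents(d$vc@K1 * 1e-8, d$vc@K2 * 1e-8,
                                setNames(rep(1, 2), names(d$vc@residVar)))
  res <- crossValidate(d$grm1, d$grm2, vcNoise, phenotypes(d$ph),
                       populations(d$ph), k = 5, seed = 231)
  acc <- empiricalAccuracy(res, trueGenomicValues(d$ph))
  expect_lt(abs(acc), 3 / sqrt(30) + 0.25)
})

test_that("the empirical rho-squared estimate follows the accuracy ratio", {
  expect_equal(as.numeric(estimateRho2Empirical(0.5, 0.5)), 1)
  r <- estimateRho2Empirical(0.33, 0.5)
  expect_equal(as.numeric(r), 0.66)
  expect_equal(attr(r, "squared"), 0.66^2)
  expect_equal(as.numeric(estimateRho2Empirical(0.33, 0.5,
                                                type = "squared")), 0.4356)
  expect_warning(capped <- estimateRho2Empirical(0.6, 0.5), "capping")
  expect_equal(as.numeric(capped), 1)
  expect_error(estimateRho2Empirical(0.5, 0), "invalid parameter")
  # the parameterisation used downstream: 0.66 x unexplained fraction
  expect_equal(0.66 * 0.5, 0.33)
})

test_that("EGV component correlations behave at their limits", {
  d <- makeGblupData(seed = 240)
  # identical GRMs with equal components: the two EGV are proportional
  vcEq <- varianceComponents(d$vc@K1, d$vc@K1, d$vc@residVar)
  valIds <- sampleIds(d$g)[populations(d$g) == "A"][1:8]
  resEq <- predictEgv(d$grm1, d$grm1, vcEq, phenotypes(d$ph),
                      populations(d$ph), valIds)
  expect_equal(egvComponentCorrelation(resEq), 1, tolerance = 1e-8)
  # zero second component: correlation undefined
  vc1 <- varianceComponents(d$vc@K1, d$vc@K2 * 0, d$vc@residVar)
  res1 <- predictEgv(d$grm1, NULL, vc1, phenotypes(d$ph),
                     populations(d$ph), valIds)
  expect_error(egvComponentCorrelation(res1), "degenerate")
  # list of replicates: mean and sd
  res <- crossValidate(d$grm1, d$grm2, d$vc, phenotypes(d$ph),
                       populations(d$ph), k = 5, seed = 241)
  cc <- egvComponentCorrelation(list(res, resEq))
  expect_named(cc, c("mean", "sd"))
})
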