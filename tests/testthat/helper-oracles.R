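# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles are written with explicit loops / textbook formulas so
# they share no code with the package implementation.

# 3 individuals x 4 SNPs, two populations, hand-enterable codes
smallGenotypeFixture <- function() {
  codes <- matrix(c(0, 1, 2, 2,
                    1, 1, 0, 2,
                    2, 0, 1, 1,
                    0, 2, 2, 0,
                    1, 2, 1, 0),
                  nrow = 5, byrow = TRUE,
                  dimnames = list(paste0("ind", 1:5),
                                  paste0("snp", 1:4)))
  genotypeMatrix(codes, c("A", "A", "A", "B", "B"))
}

# GRM oracle: explicit elementwise centered cross-products with
# population-specific frequencies, no matrix algebra
grmOracle <- function(codes, pop) {
  pops <- unique(pop)
  p <- lapply(pops, function(k) {
    apply(codes[pop == k, , drop = FALSE], 2, mean) / 2
  })
  names(p) <- pops
  S <- vapply(pops, function(k) sum(2 * p[[k]] * (1 - p[[k]])), 0)
  names(S) <- pops
  n <- nrow(codes)
  G <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ki <- pop[i]; kj <- pop[j]
      acc <- 0
      for (m in seq_len(ncol(codes))) {
        acc <- acc + (codes[i, m] - 2 * p[[ki]][m]) *
          (codes[j, m] - 2 * p[[kj]][m])
      }
      G[i, j] <- acc / sqrt(S[ki] * S[kj])
    }
  }
  G
}

# mixed-model-equations oracle for single-population, single-GRM GBLUP:
# all individuals are levels of u; validation individuals have no record
mmeOracle <- function(G, yTrain, trainIdx, sigma2g, sigma2e) {
  n <- nrow(G)
  nt <- length(trainIdx)
  Z <- matrix(0, nt, n)
  Z[cbind(seq_len(nt), trainIdx)] <- 1
  one <- rep(1, nt)
  lambda <- sigma2e / sigma2g
  lhs <- rbind(
    c(sum(one), t(one) %*% Z),
    cbind(t(Z) %*% one, crossprod(Z) + lambda * solve(G))
  )
  rhs <- c(sum(yTrain), drop(t(Z) %*% yTrain))
  sol <- solve(lhs, rhs)
  list(mu = sol[1], u = sol[-1])
}

# draw a random valid set of equation inputs (fixed-seed loops in callers)
randomPredictionInputs <- function() {
  r1 <- runif(1, 0, 0.7)
  predictionInputs(
    h2A = runif(1, 0.05, 1), h2B = runif(1, 0.05, 1),
    nA = sample(50:5000, 1), nB = sample(50:10000, 1),
    rho21 = r1, rho22 = runif(1, 0, 1 - r1),
    rg = runif(1, -1, 1),
    meA1 = runif(1, 20, 2000), meA2 = runif(1, 50, 50000),
    meAB1 = runif(1, 20, 5000), meAB2 = runif(1, 100, 50000))
}

# copy of a PredictionInputs with some slots replaced
tweakInputs <- function(inputs, ...) {
  mod <- list(...)
  for (nm in names(mod)) slot(inputs, nm) <- mod[[nm]]
  validObject(inputs)
  inputs
}
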