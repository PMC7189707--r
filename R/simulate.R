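#' Configure the two-population simulation
#'
#' Defaults reproduce the study design the accuracy equations were validated
#' on: two diverged dairy-cattle populations (a small target population A
#' and a large auxiliary population B), a genome-wide SNP panel of which 500
#' random SNPs are causal in both populations, bivariate normal causal
#' effects with correlation \code{rg}, and per-population heritabilities.
#' Population divergence is modelled with Balding-Nichols allele-frequency
#' draws; an Fst of 0.1 reflects the differentiation of distantly related
#' cattle breeds. Loci are unlinked.
#'
#' @param nA,nB individuals per population (defaults 595 and 5553).
#' @param nSnps,nCausal panel size and causal SNP count (defaults 48912, 500).
#' @param fst Balding-Nichols divergence parameter (default 0.1).
#' @param mafRange range of the ancestral allele frequency (default
#'   c(0.05, 0.5)).
#' @param rg correlation of causal effects between populations (default 0.8).
#' @param h2A,h2B heritabilities (default 0.3 in both populations).
#' @param csnpLevel number of causal SNPs pre-selected into the first GRM
#'   (default 500, i.e. all of them).
#' @param seed base seed; replicate r draws from seed + r.
#' @param replicates number of replicates (default 100).
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nA = 595, nB = 5553, nSnps = 48912,
                             nCausal = 500, fst = 0.1,
                             mafRange = c(0.05, 0.5), rg = 0.8,
                             h2A = 0.3, h2B = 0.3, csnpLevel = nCausal,
                             seed = 1, replicates = 100) {
  new("SimulationConfig", nA = nA, nB = nB, nSnps = nSnps,
      nCausal = nCausal, fst = fst, mafRange = mafRange, rg = rg,
      h2A = h2A, h2B = h2B, csnpLevel = csnpLevel, seed = seed,
      replicates = replicates)
}

#' Simulate unlinked two-population genotypes
#'
#' Ancestral allele frequencies are drawn uniformly on the configured MAF
#' range; per-population frequencies follow the Balding-Nichols model,
#' \code{Beta(p (1-Fst)/Fst, (1-p)(1-Fst)/Fst)}; genotypes are
#' \code{Binomial(2, p_k)} draws at unlinked loci. SNPs that come out
#' monomorphic across all individuals are redrawn so the panel is
#' polymorphic overall.
#'
#' @param config a [SimulationConfig-class].
#' @param seed seed for this call; defaults to the config seed.
#' @return a [GenotypeMatrix-class] with populations labelled "A" and "B"
#'   (population A rows first).
#' @export
simulateGenotypes <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(seed)
  nA <- config@nA; nB <- config@nB
  n <- nA + nB
  m <- config@nSnps
  shape <- (1 - config@fst) / config@fst
  drawLocus <- function(k) {
    p <- runif(k, config@mafRange[1L], config@mafRange[2L])
    pA <- rbeta(k, p * shape, (1 - p) * shape)
    pB <- rbeta(k, p * shape, (1 - p) * shape)
    gA <- if (nA > 0) matrix(rbinom(nA * k, 2L, rep(pA, each = nA)), nA, k)
          else matrix(0L, 0L, k)
    gB <- if (nB > 0) matrix(rbinom(nB * k, 2L, rep(pB, each = nB)), nB, k)
          else matrix(0L, 0L, k)
    rbind(gA, gB)
  }
  codes <- drawLocus(m)
  repeat {
    cs <- colSums(codes)
    fixed <- which(cs == 0L | cs == 2L * n)
    if (!length(fixed)) break
    codes[, fixed] <- drawLocus(length(fixed))
  }
  storage.mode(codes) <- "double"
  rownames(codes) <- c(if (nA > 0) paste0("A", seq_len(nA)),
                       if (nB > 0) paste0("B", seq_len(nB)))
  colnames(codes) <- paste0("snp", seq_len(m))
  genotypeMatrix(codes, rep(c("A", "B"), c(nA, nB)))
}

#' Sample correlated allele-substitution effects for two populations
#'
#' Causal effects are drawn from a bivariate normal distribution with mean
#' 0, unit variances and correlation \code{rg} between the population-A and
#' population-B effect of each causal SNP. Effects are independent of allele
#' frequency, so rarer causal alleles contribute less genetic variance.
#'
#' @param causalIds ids of the causal SNPs.
#' @param rg effect correlation in [-1, 1].
#' @param seed random seed.
#' @return a matrix (causal SNPs x 2) with columns \code{A} and \code{B}.
#' @export
sampleEffects <- function(causalIds, rg, seed) {
  if (abs(rg) > 1)
    stop("invalid parameter: rg must lie in [-1, 1]", call. = FALSE)
  set.seed(seed)
  k <- length(causalIds)
  z1 <- rnorm(k)
  z2 <- rnorm(k)
  a <- cbind(A = z1, B = rg * z1 + sqrt(1 - rg^2) * z2)
  rownames(a) <- causalIds
  a
}

#' Pre-select causal SNPs into the first SNP set
#'
#' Randomly draws \code{csnpLevel} of the causal SNPs as the pre-selected
#' set (first GRM). By default the remaining set (second GRM) contains only
#' the non-causal SNPs: causal SNPs that were not pre-selected enter neither
#' set. With \code{includeUnselectedCausal = TRUE} the non-selected causal
#' SNPs are kept in the remaining set instead.
#'
#' @param causalIds ids of all causal SNPs.
#' @param allIds ids of all genotyped SNPs.
#' @param csnpLevel number of causal SNPs to pre-select.
#' @param seed random seed.
#' @param includeUnselectedCausal keep non-selected causal SNPs in set 2.
#' @return a [SnpPartition-class].
#' @export
partitionCausal <- function(causalIds, allIds, csnpLevel, seed,
                            includeUnselectedCausal = FALSE) {
  if (csnpLevel > length(causalIds))
    stop("invalid parameter: csnpLevel exceeds the number of causal SNPs",
         call. = FALSE)
  set.seed(seed)
  selected <- sort(sample(causalIds, csnpLevel))
  remaining <- if (includeUnselectedCausal) setdiff(allIds, selected)
               else setdiff(allIds, causalIds)
  new("SnpPartition", selected = selected, remaining = remaining)
}

#' Simulate phenotypes from genotypes and causal effects
#'
#' The true genomic value of individual i is \code{sum_j x_ij a_j} over the
#' causal SNPs, using the effect column of the individual's population.
#' Residuals are drawn per population from a normal distribution with
#' variance \code{sigma2g_k * (1/h2_k - 1)}, where \code{sigma2g_k} is the
#' realized variance of the true genomic values in population k, so the
#' realized heritability targets \code{h2_k}. The genomic value is also
#' split into the contribution of a pre-selected causal subset
#' (\code{tgv1}) and the remaining causal SNPs (\code{tgv2}).
#'
#' @param g a [GenotypeMatrix-class].
#' @param effects causal SNPs x 2 effect matrix from [sampleEffects()].
#' @param h2A,h2B heritability per population.
#' @param seed random seed for the residual draw.
#' @param selected causal ids contributing to \code{tgv1}; defaults to all
#'   causal SNPs.
#' @return a [PhenotypeSet-class].
#' @export
simulatePhenotypes <- function(g, effects, h2A, h2B = h2A, seed,
                               selected = rownames(effects)) {
  stopifnot(is(g, "GenotypeMatrix"))
  causal <- rownames(effects)
  if (!all(causal %in% snpIds(g)))
    stop("effects refer to SNPs absent from the genotypes", call. = FALSE)
  if (!all(selected %in% causal))
    stop("selected must be a subset of the causal SNPs", call. = FALSE)
  set.seed(seed)
  pop <- g@population
  h2 <- c(A = h2A, B = h2B)
  n <- nrow(g@codes)
  tgv <- tgv1 <- numeric(n)
  for (k in levels(droplevels(pop))) {
    rows <- pop == k
    xk <- g@codes[rows, causal, drop = FALSE]
    tgv[rows] <- drop(xk %*% effects[, k])
    if (length(selected))
      tgv1[rows] <- drop(g@codes[rows, selected, drop = FALSE] %*%
                           effects[selected, k])
  }
  tgv2 <- tgv - tgv1
  sigma2g <- residVar <- setNames(numeric(nlevels(droplevels(pop))),
                                  levels(droplevels(pop)))
  e <- numeric(n)
  for (k in names(sigma2g)) {
    rows <- pop == k
    sigma2g[k] <- var(tgv[rows])
    if (!is.finite(sigma2g[k]) || sigma2g[k] <= 0)
      stop("degenerate data: zero realized genetic variance in population ",
           k, call. = FALSE)
    residVar[k] <- sigma2g[k] * (1 / h2[k] - 1)
    e[rows] <- rnorm(sum(rows), 0, sqrt(residVar[k]))
  }
  ids <- rownames(g@codes)
  new("PhenotypeSet", effects = effects, causal = causal,
      tgv = setNames(tgv, ids), tgv1 = setNames(tgv1, ids),
      tgv2 = setNames(tgv2, ids), residuals = setNames(e, ids),
      phenotypes = setNames(tgv + e, ids), population = pop,
      sigma2g = sigma2g, residVar = residVar)
}

#' Write simulator outputs as plain-text tables
#'
#' Emits the genotype matrix (delimited dialect of [loadGenotypes()]), a
#' phenotype table (id, population, phenotype, tgv, tgv1, tgv2), and a truth
#' file with the causal effects and the SNP partition.
#'
#' @param g a [GenotypeMatrix-class].
#' @param pheno a [PhenotypeSet-class].
#' @param partition a [SnpPartition-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(g, pheno, partition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genotypes.txt", "phenotypes.txt", "truth.txt"))
  geno <- data.frame(id = sampleIds(g), population = as.character(g@population),
                     g@codes, check.names = FALSE)
  utils::write.table(geno, paths[1L], quote = FALSE, row.names = FALSE)
  ph <- data.frame(id = names(pheno@tgv),
                   population = as.character(pheno@population),
                   phenotype = pheno@phenotypes, tgv = pheno@tgv,
                   tgv1 = pheno@tgv1, tgv2 = pheno@tgv2)
  utils::write.table(ph, paths[2L], quote = FALSE, row.names = FALSE)
  tr <- data.frame(snp = pheno@causal, effectA = pheno@effects[, "A"],
                   effectB = pheno@effects[, "B"],
                   selected = pheno@causal %in% partition@selected)
  utils::write.table(tr, paths[3L], quote = FALSE, row.names = FALSE)
  invisible(paths)
}
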