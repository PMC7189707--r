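#' @import methods
#' @importFrom stats var cor rnorm rbeta rbinom runif setNames
NULL

.isProportion <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

#' Scalar inputs of the deterministic accuracy equations
#'
#' Holds every scalar that enters the within- and multi-population accuracy
#' predictors: heritabilities in the target population A and the auxiliary
#' population B, training sizes, the proportions of genetic variance captured
#' by the two SNP sets, the genetic correlation between populations, and the
#' effective number of independent chromosome segments (Me) per SNP set,
#' within A and across A and B.
#'
#' Separate genetic correlations may be supplied for the two SNP sets
#' (\code{rg1}, \code{rg2}); by default both equal \code{rg}, as when
#' pre-selected SNPs are a random draw from the causal set, but a higher
#' correlation for the pre-selected set can be expressed when prior
#' information warrants it.
#'
#' @slot h2A,h2B heritability of the trait in populations A and B, in (0, 1].
#' @slot nA,nB number of training individuals from A (positive) and B
#'   (non-negative).
#' @slot rho21,rho22 proportion of the total genetic variance in the
#'   validation population explained by SNP set 1 (pre-selected) and set 2
#'   (remaining); their sum may not exceed 1.
#' @slot rg1,rg2 genetic correlation between A and B applied to SNP sets 1
#'   and 2, each in [-1, 1].
#' @slot meA1,meA2 Me within population A for SNP sets 1 and 2.
#' @slot meAB1,meAB2 Me across populations A and B for SNP sets 1 and 2.
#'
#' @seealso [predictionInputs()] for the user-facing constructor.
#' @export
setClass("PredictionInputs",
  representation(
    h2A = "numeric", h2B = "numeric",
    nA = "numeric", nB = "numeric",
    rho21 = "numeric", rho22 = "numeric",
    rg1 = "numeric", rg2 = "numeric",
    meA1 = "numeric", meA2 = "numeric",
    meAB1 = "numeric", meAB2 = "numeric"
  )
)

setValidity("PredictionInputs", function(object) {
  msg <- character()
  if (!(is.numeric(object@h2A) && object@h2A > 0 && object@h2A <= 1))
    msg <- c(msg, "h2A must lie in (0, 1]")
  if (!(is.numeric(object@h2B) && object@h2B > 0 && object@h2B <= 1))
    msg <- c(msg, "h2B must lie in (0, 1]")
  if (!(object@nA > 0)) msg <- c(msg, "nA must be positive")
  if (object@nB < 0) msg <- c(msg, "nB must be non-negative")
  if (!.isProportion(object@rho21)) msg <- c(msg, "rho21 must lie in [0, 1]")
  if (!.isProportion(object@rho22)) msg <- c(msg, "rho22 must lie in [0, 1]")
  if (object@rho21 + object@rho22 > 1 + 1e-12)
    msg <- c(msg, "rho21 + rho22 may not exceed 1")
  for (s in c("rg1", "rg2")) {
    v <- slot(object, s)
    if (!(is.numeric(v) && abs(v) <= 1)) msg <- c(msg, paste(s, "must lie in [-1, 1]"))
  }
  for (s in c("meA1", "meA2", "meAB1", "meAB2")) {
    v <- slot(object, s)
    if (!(is.numeric(v) && v > 0)) msg <- c(msg, paste(s, "must be positive"))
  }
  if (length(msg)) msg else TRUE
})

#' A two- or four-source selection index
#'
#' The covariance vector \code{g} between the information sources (the
#' estimated genomic values) and the true genomic value, and the symmetric
#' (co)variance matrix \code{P} of the sources. The true genomic value is
#' scaled to unit variance, so \code{sqrt(g' P^-1 g)} is the index accuracy.
#'
#' @slot g numeric vector of source-target covariances.
#' @slot P symmetric positive-definite matrix of source (co)variances.
#' @export
setClass("SelectionIndex", representation(g = "numeric", P = "matrix"))

setValidity("SelectionIndex", function(object) {
  msg <- character()
  if (nrow(object@P) != ncol(object@P)) msg <- c(msg, "P must be square")
  if (length(object@g) != nrow(object@P))
    msg <- c(msg, "length(g) must match dim(P)")
  if (nrow(object@P) > 0 && max(abs(object@P - t(object@P))) > 1e-8)
    msg <- c(msg, "P must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Additive-coded genotypes with population labels
#'
#' Individuals by SNPs matrix of additive allele counts (0/1/2, possibly NA
#' before imputation), with one population label per individual. Row names
#' are individual ids, column names SNP ids.
#'
#' @slot codes integer-valued matrix of allele counts, individuals x SNPs.
#' @slot population factor of population labels, one per individual.
#' @export
setClass("GenotypeMatrix",
  representation(codes = "matrix", population = "factor"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (length(object@population) != nrow(object@codes))
    msg <- c(msg, "one population label is required per individual")
  ok <- object@codes %in% c(0, 1, 2) | is.na(object@codes)
  if (!all(ok)) msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (is.null(rownames(object@codes)) || is.null(colnames(object@codes)))
    msg <- c(msg, "codes must carry individual (row) and SNP (column) names")
  if (length(msg)) msg else TRUE
})

#' Partition of SNPs into a pre-selected and a remaining set
#'
#' @slot selected SNP ids used to build the first GRM (pre-selected panel).
#' @slot remaining SNP ids used to build the second GRM.
#' @export
setClass("SnpPartition",
  representation(selected = "character", remaining = "character"))

setValidity("SnpPartition", function(object) {
  if (length(intersect(object@selected, object@remaining)))
    "selected and remaining SNP sets must be disjoint" else TRUE
})

#' Multi-population genomic relationship matrix
#'
#' Within-population blocks (AA, BB) and the across-population block (AB),
#' built from genotypes centered with population-specific allele frequencies
#' and scaled per population by the sum of 2p(1-p). For a single-population
#' input the BB and AB blocks are empty.
#'
#' @slot AA,BB symmetric within-population blocks.
#' @slot AB rectangular across-population block (A rows, B columns).
#' @slot freqA,freqB per-SNP allele frequencies used for each population.
#' @slot snps ids of the SNPs the matrix was built from.
#' @export
setClass("MultiPopGRM",
  representation(AA = "matrix", BB = "matrix", AB = "matrix",
                 freqA = "numeric", freqB = "numeric", snps = "character"))

setValidity("MultiPopGRM", function(object) {
  msg <- character()
  if (nrow(object@AA) != ncol(object@AA)) msg <- c(msg, "AA must be square")
  if (nrow(object@BB) != ncol(object@BB)) msg <- c(msg, "BB must be square")
  if (nrow(object@AA) > 1 && max(abs(object@AA - t(object@AA))) > 1e-8)
    msg <- c(msg, "AA must be symmetric")
  if (nrow(object@BB) > 1 && max(abs(object@BB - t(object@BB))) > 1e-8)
    msg <- c(msg, "BB must be symmetric")
  if (nrow(object@BB) > 0 &&
      (nrow(object@AB) != nrow(object@AA) || ncol(object@AB) != nrow(object@BB)))
    msg <- c(msg, "AB must be nA x nB")
  if (length(msg)) msg else TRUE
})

#' Configuration of the two-population simulation
#'
#' Describes the synthetic stand-in for the study design the equations were
#' validated on: two diverged populations genotyped on a shared SNP panel, a
#' fixed number of causal SNPs shared by both populations, bivariate normal
#' allele-substitution effects with correlation \code{rg}, and per-population
#' heritabilities. Population divergence follows the Balding-Nichols model
#' with parameter \code{fst}; loci are unlinked.
#'
#' @slot nA,nB number of individuals simulated per population.
#' @slot nSnps,nCausal total SNPs and causal SNPs (causal in both
#'   populations).
#' @slot fst Balding-Nichols divergence parameter in (0, 1).
#' @slot mafRange range of the ancestral allele frequency draw.
#' @slot rg genetic correlation between populations (correlation of causal
#'   effects).
#' @slot h2A,h2B trait heritability per population.
#' @slot csnpLevel number of causal SNPs pre-selected into the first GRM.
#' @slot seed base random seed; replicate r uses seed + r at each stage.
#' @slot replicates number of simulation replicates.
#' @export
setClass("SimulationConfig",
  representation(nA = "numeric", nB = "numeric", nSnps = "numeric",
                 nCausal = "numeric", fst = "numeric", mafRange = "numeric",
                 rg = "numeric", h2A = "numeric", h2B = "numeric",
                 csnpLevel = "numeric", seed = "numeric",
                 replicates = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nCausal > object@nSnps) msg <- c(msg, "nCausal must not exceed nSnps")
  if (object@csnpLevel > object@nCausal)
    msg <- c(msg, "csnpLevel must not exceed nCausal")
  if (!(object@fst > 0 && object@fst < 1)) msg <- c(msg, "fst must lie in (0, 1)")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must be increasing within (0, 0.5]")
  if (abs(object@rg) > 1) msg <- c(msg, "rg must lie in [-1, 1]")
  for (s in c("h2A", "h2B")) {
    v <- slot(object, s)
    if (!(v > 0 && v <= 1)) msg <- c(msg, paste(s, "must lie in (0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Simulated effects, genomic values and phenotypes
#'
#' @slot effects matrix of allele-substitution effects, causal SNPs x 2
#'   (columns A and B).
#' @slot causal ids of the causal SNPs.
#' @slot tgv,tgv1,tgv2 true genomic value per individual, total and split
#'   into the contribution of the pre-selected causal set (tgv1) and the
#'   rest (tgv2); tgv = tgv1 + tgv2 exactly.
#' @slot residuals,phenotypes per-individual residual and phenotype;
#'   phenotypes = tgv + residuals exactly.
#' @slot population factor of population labels.
#' @slot sigma2g realized variance of tgv per population.
#' @slot residVar residual variance used per population,
#'   sigma2g * (1/h2 - 1).
#' @export
setClass("PhenotypeSet",
  representation(effects = "matrix", causal = "character",
                 tgv = "numeric", tgv1 = "numeric", tgv2 = "numeric",
                 residuals = "numeric", phenotypes = "numeric",
                 population = "factor", sigma2g = "numeric",
                 residVar = "numeric"))

setValidity("PhenotypeSet", function(object) {
  msg <- character()
  n <- length(object@tgv)
  if (any(lengths(list(object@tgv1, object@tgv2, object@residuals,
                       object@phenotypes)) != n) ||
      length(object@population) != n)
    msg <- c(msg, "per-individual slots must have equal length")
  if (n && max(abs(object@tgv - object@tgv1 - object@tgv2)) > 1e-8)
    msg <- c(msg, "tgv must equal tgv1 + tgv2")
  if (n && max(abs(object@phenotypes - object@tgv - object@residuals)) > 1e-8)
    msg <- c(msg, "phenotypes must equal tgv + residuals")
  if (length(msg)) msg else TRUE
})

#' Genetic and residual (co)variance components of the two-GRM model
#'
#' \code{K1} and \code{K2} are the 2 x 2 across-population genetic
#' (co)variance matrices attached to the first and second GRM; rows and
#' columns are named by population. \code{residVar} is the per-population
#' residual variance.
#'
#' @slot K1,K2 symmetric positive semi-definite matrices with population
#'   dimnames.
#' @slot residVar named non-negative numeric vector.
#' @export
setClass("VarianceComponents",
  representation(K1 = "matrix", K2 = "matrix", residVar = "numeric"))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  for (s in c("K1", "K2")) {
    K <- slot(object, s)
    if (max(abs(K - t(K))) > 1e-8) msg <- c(msg, paste(s, "must be symmetric"))
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, paste(s, "must be positive semi-definite"))
  }
  if (any(object@residVar < 0)) msg <- c(msg, "residual variances must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Estimated genomic values of held-out individuals
#'
#' Per-GRM and total estimated genomic values (EGV) for validation
#' individuals, with the cross-validation fold each individual was held out
#' in. EGV are reported only for held-out individuals.
#'
#' @slot egv1,egv2,egvTotal named numeric vectors of per-GRM and total EGV.
#' @slot fold integer fold assignment per validation individual.
#' @export
setClass("GBLUPResult",
  representation(egv1 = "numeric", egv2 = "numeric", egvTotal = "numeric",
                 fold = "integer"))

setValidity("GBLUPResult", function(object) {
  n <- length(object@egvTotal)
  if (length(object@egv1) != n || length(object@egv2) != n ||
      length(object@fold) != n)
    "egv1, egv2, egvTotal and fold must have equal length" else TRUE
})
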