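#' Variance components from simulation truth
#'
#' Builds the genetic (co)variance matrices attached to the two GRMs from
#' the realized variances of the simulated genomic values: per population,
#' the set-s genetic variance is the realized variance of the corresponding
#' true-genomic-value component, the across-population covariance is
#' \code{rg * sqrt(var_A * var_B)}, and the residual variance is the one
#' used in the simulation. This substitutes known components for REML
#' estimation, so the prediction step is evaluated at the true variance
#' structure.
#'
#' @param pheno a [PhenotypeSet-class] from [simulatePhenotypes()].
#' @param rg genetic correlation between populations.
#' @return a [VarianceComponents-class].
#' @export
truthComponents <- function(pheno, rg) {
  stopifnot(is(pheno, "PhenotypeSet"))
  pops <- names(pheno@sigma2g)
  mkK <- function(tgvs) {
    v <- vapply(pops, function(k) var(tgvs[pheno@population == k]), 0)
    K <- diag(v, length(pops))
    dimnames(K) <- list(pops, pops)
    if (length(pops) == 2L)
      K[1L, 2L] <- K[2L, 1L] <- rg * sqrt(prod(v))
    K
  }
  new("VarianceComponents", K1 = mkK(pheno@tgv1), K2 = mkK(pheno@tgv2),
      residVar = pheno@residVar)
}

#' Construct variance components directly
#'
#' @param K1,K2 2 x 2 (or 1 x 1) genetic (co)variance matrices with
#'   population dimnames.
#' @param residVar named per-population residual variances.
#' @return a [VarianceComponents-class].
#' @export
varianceComponents <- function(K1, K2, residVar) {
  new("VarianceComponents", K1 = K1, K2 = K2, residVar = residVar)
}

# labels may be named by id or positionally aligned with y
.alignLabels <- function(population, y) {
  lab <- as.character(population)
  names(lab) <- if (is.null(names(population))) names(y)
                else names(population)
  lab
}

# per-pair genetic covariance matrix of component s over a set of ids:
# C[i, j] = K[pop_i, pop_j] * G[i, j]
.componentCov <- function(G, K, pop) {
  idx <- match(as.character(pop), rownames(K))
  n <- length(idx)
  K[matrix(c(rep(idx, times = n), rep(idx, each = n)), ncol = 2L)] *
    G
}

#' Best linear prediction of genomic values under the two-GRM model
#'
#' Computes the estimated genomic values of validation individuals from
#' training phenotypes at known variance components. The phenotype
#' covariance among training individuals is the sum of the two genetic
#' component covariances (genetic (co)variance matrix applied elementwise to
#' the corresponding GRM) plus a diagonal per-population residual; fixed
#' per-population means are estimated by generalized least squares.
#' Validation individuals keep their GRM rows (relationships are
#' genotype-based) but contribute no phenotypes.
#'
#' @param grm1 a [MultiPopGRM-class] for the pre-selected SNP set.
#' @param grm2 a [MultiPopGRM-class] for the remaining set, or \code{NULL}
#'   for a single-GRM model (the second component is then zero).
#' @param vc a [VarianceComponents-class]; with \code{grm2 = NULL},
#'   \code{K2} must be zero.
#' @param y named phenotype vector (training and validation individuals).
#' @param population population label per element of \code{y}.
#' @param validationIds ids whose phenotypes are withheld and whose genomic
#'   values are predicted.
#' @return a [GBLUPResult-class] with per-GRM and total EGV for the
#'   validation individuals.
#' @export
predictEgv <- function(grm1, grm2, vc, y, population, validationIds) {
  stopifnot(is(grm1, "MultiPopGRM"), is(vc, "VarianceComponents"))
  G1 <- grmMatrix(grm1)
  ids <- rownames(G1)
  if (is.null(names(y)) || !all(ids %in% names(y)))
    stop("y must be named and cover every individual in the GRM",
         call. = FALSE)
  y <- y[ids]
  pop <- factor(.alignLabels(population, y)[ids])
  if (is.null(grm2)) {
    if (any(vc@K2 != 0))
      stop("grm2 is NULL but K2 is non-zero", call. = FALSE)
    G2 <- NULL
  } else {
    G2 <- grmMatrix(grm2)
    if (!identical(rownames(G2), ids))
      stop("grm1 and grm2 must cover the same individuals in the same order",
           call. = FALSE)
  }
  C1 <- .componentCov(G1, vc@K1, pop)
  C2 <- if (is.null(G2) || all(vc@K2 == 0)) NULL
        else .componentCov(G2, vc@K2, pop)
  val <- match(validationIds, ids)
  if (anyNA(val)) stop("validation ids absent from the GRM", call. = FALSE)
  tr <- setdiff(seq_along(ids), val)
  V <- C1[tr, tr]
  if (!is.null(C2)) V <- V + C2[tr, tr]
  diag(V) <- diag(V) + vc@residVar[as.character(pop[tr])]
  R <- tryCatch(chol(V), error = function(e)
    stop("numerical degeneracy: phenotype covariance is not positive definite",
         call. = FALSE))
  Vinv <- function(b) backsolve(R, backsolve(R, b, transpose = TRUE))
  trPop <- droplevels(pop[tr])
  X <- vapply(levels(trPop), function(l) as.numeric(trPop == l),
              numeric(length(tr)))
  ViX <- Vinv(X)
  beta <- solve(crossprod(X, ViX), crossprod(ViX, y[tr]))
  resid <- Vinv(y[tr] - drop(X %*% beta))
  egv1 <- drop(C1[val, tr, drop = FALSE] %*% resid)
  egv2 <- if (is.null(C2)) numeric(length(val))
          else drop(C2[val, tr, drop = FALSE] %*% resid)
  new("GBLUPResult",
      egv1 = setNames(egv1, ids[val]), egv2 = setNames(egv2, ids[val]),
      egvTotal = setNames(egv1 + egv2, ids[val]),
      fold = rep(1L, length(val)))
}

#' Cross-validated genomic prediction for the target population
#'
#' Splits the population-A individuals into \code{k} folds; in turn each
#' fold is held out while all remaining A individuals and every B individual
#' stay in training. Every A individual is held out exactly once; the
#' pooled held-out estimated genomic values are returned.
#'
#' @param grm1,grm2,vc,y,population as in [predictEgv()].
#' @param k number of folds (2 to the number of A individuals).
#' @param seed seed for the random fold split.
#' @return a [GBLUPResult-class] with pooled held-out EGV and fold labels.
#' @export
crossValidate <- function(grm1, grm2, vc, y, population, k = 5, seed = 1) {
  ids <- rownames(grmMatrix(grm1))
  pop <- .alignLabels(population, y)[ids]
  aIds <- ids[pop == "A"]
  if (k < 2 || k > length(aIds))
    stop("invalid parameter: k must lie between 2 and the number of ",
         "population-A individuals", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(aIds)))
  egv1 <- egv2 <- egvT <- setNames(numeric(length(aIds)), aIds)
  foldOut <- setNames(integer(length(aIds)), aIds)
  for (f in seq_len(k)) {
    held <- aIds[fold == f]
    res <- predictEgv(grm1, grm2, vc, y, population, held)
    egv1[held] <- res@egv1[held]
    egv2[held] <- res@egv2[held]
    egvT[held] <- res@egvTotal[held]
    foldOut[held] <- f
  }
  new("GBLUPResult", egv1 = egv1, egv2 = egv2, egvTotal = egvT,
      fold = foldOut)
}

#' Empirical prediction accuracy
#'
#' Pearson correlation between the pooled held-out estimated genomic values
#' and the simulated true genomic values of the same individuals.
#'
#' @param result a [GBLUPResult-class].
#' @param tgv named vector of true genomic values covering the validation
#'   individuals.
#' @return the correlation, in [-1, 1].
#' @export
empiricalAccuracy <- function(result, tgv) {
  stopifnot(is(result, "GBLUPResult"))
  ids <- names(result@egvTotal)
  if (length(ids) < 3L)
    stop("at least 3 held-out individuals are required", call. = FALSE)
  e <- result@egvTotal
  t <- tgv[ids]
  if (var(e) == 0 || var(t) == 0)
    stop("degenerate data: zero variance in EGV or TGV", call. = FALSE)
  cor(e, t)
}

#' Summarise accuracies across replicates
#'
#' @param accs numeric vector of per-replicate accuracies.
#' @return named vector with the mean and standard deviation.
#' @export
accuracySummary <- function(accs) {
  if (length(accs) < 2L)
    stop("invalid parameter: at least 2 replicates are required", call. = FALSE)
  c(mean = mean(accs), sd = stats::sd(accs))
}

#' Proportion of genetic variance explained, estimated empirically
#'
#' Ratio of the empirical cross-validation accuracy to the accuracy
#' predicted under the assumption that the SNPs capture the total genetic
#' variance. The raw ratio is the drop-in estimate of rho-squared used when
#' parameterising the prediction equations; the squared ratio is also
#' reported. Ratios marginally above 1 are capped with a warning.
#'
#' @param empiricalAcc empirical accuracy from cross-validation.
#' @param predictedAccFull predicted accuracy assuming all genetic variance
#'   is captured (must be positive).
#' @param type return the raw \code{"ratio"} (default) or the
#'   \code{"squared"} ratio.
#' @param tol tolerance above 1 before capping.
#' @return the selected estimate, with both forms as attributes
#'   \code{"ratio"} and \code{"squared"}.
#' @export
estimateRho2Empirical <- function(empiricalAcc, predictedAccFull,
                                  type = c("ratio", "squared"), tol = 1e-8) {
  type <- match.arg(type)
  if (predictedAccFull <= 0)
    stop("invalid parameter: predicted accuracy must be positive",
         call. = FALSE)
  ratio <- empiricalAcc / predictedAccFull
  if (ratio > 1 + tol) {
    warning("inconsistent inputs: empirical accuracy exceeds the ",
            "full-variance prediction; capping the ratio at 1")
  }
  ratio <- min(ratio, 1)
  out <- if (type == "ratio") ratio else ratio^2
  attr(out, "ratio") <- ratio
  attr(out, "squared") <- ratio^2
  out
}

#' Correlation between the two EGV components
#'
#' Pearson correlation of the held-out estimated genomic values from the
#' first and second GRM. For a list of replicate results the per-replicate
#' correlations are averaged and their standard deviation reported.
#'
#' @param result a [GBLUPResult-class], or a list of them (one per
#'   replicate).
#' @return a single correlation, or for a list a named vector with the mean
#'   and standard deviation across replicates.
#' @export
egvComponentCorrelation <- function(result) {
  one <- function(r) {
    stopifnot(is(r, "GBLUPResult"))
    if (var(r@egv1) == 0 || var(r@egv2) == 0)
      stop("degenerate data: an EGV component has zero variance",
           call. = FALSE)
    cor(r@egv1, r@egv2)
  }
  if (is(result, "GBLUPResult")) return(one(result))
  accs <- vapply(result, one, 0)
  c(mean = mean(accs), sd = stats::sd(accs))
}
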