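#' Baseline parameters of the benchmark scenarios
#'
#' The fixed parameter set behind the four benchmark cases: a small target
#' population A (476 training individuals) and a large auxiliary population
#' B (5553), heritability 0.3 in both, and Me values estimated from the
#' genotype panel: within A, 159 for the 500 pre-selected SNPs and 280 for
#' the remaining (and for all) SNPs; across populations, 463 for the
#' pre-selected SNPs, 32,970 for the remaining SNPs and 33,242 for all
#' SNPs.
#'
#' @return a named list of baseline constants.
#' @export
caseBaseline <- function() {
  list(h2A = 0.3, h2B = 0.3, nA = 476, nB = 5553,
       meA1 = 159, meAB1 = 463,
       meA2 = 280, meAB2 = 32970,
       meAall = 280, meABall = 33242)
}

.caseRow <- function(sweep, value, model, acc, wpsg) {
  data.frame(sweep = sweep, value = value, model = model, accuracy = acc,
             pctVsWpsg = relativeChange(acc, wpsg),
             stringsAsFactors = FALSE)
}

#' Run one benchmark case
#'
#' Evaluates the deterministic accuracy of the WPSG, WPMG, MPSG and MPMG
#' models over the case's sweep and reports each accuracy together with its
#' percent change relative to the within-population single-GRM (WPSG)
#' reference.
#'
#' \describe{
#'   \item{Case 1}{sweep of the genetic correlation \code{rg} in [0, 1];
#'     all SNPs explain 80\% of the genetic variance, the pre-selected set
#'     40\%.}
#'   \item{Case 2}{sweep of the variance proportion of the pre-selected set
#'     \code{rho21} in [0, 1] with \code{rho22 = 1 - rho21} and
#'     \code{rg = 0.6}; all SNPs explain the full genetic variance.}
#'   \item{Case 3}{sweep of the across-population Me of the remaining SNP
#'     set from 1000 to 50,000 at \code{rg = 0.6}; this Me also drives the
#'     single-GRM multi-population model.}
#'   \item{Case 4}{sweep of the underestimation fraction \code{u} in
#'     [0, 0.9]; every within-A Me is multiplied by \code{1 - u} while the
#'     across-population Me stay at their reference values;
#'     \code{rho21 = rho22 = 0.5}, \code{rg = 0.6}.}
#' }
#'
#' @param case integer 1 to 4.
#' @param sweep optional numeric grid overriding the default sweep.
#' @param baseline list of baseline constants, by default [caseBaseline()].
#' @return a data frame with columns \code{sweep} (parameter name),
#'   \code{value}, \code{model}, \code{accuracy}, \code{pctVsWpsg}.
#' @examples
#' head(runCase(1))
#' @export
runCase <- function(case, sweep = NULL, baseline = caseBaseline()) {
  stopifnot(case %in% 1:4)
  b <- baseline
  out <- list()
  if (case == 1) {
    grid <- if (is.null(sweep)) seq(0, 1, by = 0.1) else sweep
    wpsg <- wpsgAccuracy(b$h2A, b$nA, b$meAall, 0.8)
    wpmg <- wpmgAccuracy(predictionInputs(
      h2A = b$h2A, nA = b$nA, rho21 = 0.4, rho22 = 0.4,
      meA1 = b$meA1, meA2 = b$meA2))
    for (rg in grid) {
      mpsg <- mpsgAccuracy(b$h2A, b$h2B, b$nA, b$nB, rho2A = 0.8, rg = rg,
                           meA = b$meAall, meAB = b$meABall)
      mpmg <- mpmgAccuracy(predictionInputs(
        h2A = b$h2A, h2B = b$h2B, nA = b$nA, nB = b$nB,
        rho21 = 0.4, rho22 = 0.4, rg = rg,
        meA1 = b$meA1, meAB1 = b$meAB1, meA2 = b$meA2, meAB2 = b$meAB2))
      out[[length(out) + 1L]] <- .caseRow("rg", rg,
        c("WPSG", "WPMG", "MPSG", "MPMG"), c(wpsg, wpmg, mpsg, mpmg), wpsg)
    }
  } else if (case == 2) {
    grid <- if (is.null(sweep)) seq(0, 1, by = 0.05) else sweep
    wpsg <- wpsgAccuracy(b$h2A, b$nA, b$meAall, 1)
    mpsg <- mpsgAccuracy(b$h2A, b$h2B, b$nA, b$nB, rho2A = 1, rg = 0.6,
                         meA = b$meAall, meAB = b$meABall)
    for (r1 in grid) {
      wpmg <- wpmgAccuracy(predictionInputs(
        h2A = b$h2A, nA = b$nA, rho21 = r1, rho22 = 1 - r1,
        meA1 = b$meA1, meA2 = b$meA2))
      mpmg <- mpmgAccuracy(predictionInputs(
        h2A = b$h2A, h2B = b$h2B, nA = b$nA, nB = b$nB,
        rho21 = r1, rho22 = 1 - r1, rg = 0.6,
        meA1 = b$meA1, meAB1 = b$meAB1, meA2 = b$meA2, meAB2 = b$meAB2))
      out[[length(out) + 1L]] <- .caseRow("rho21", r1,
        c("WPSG", "WPMG", "MPSG", "MPMG"), c(wpsg, wpmg, mpsg, mpmg), wpsg)
    }
  } else if (case == 3) {
    grid <- if (is.null(sweep)) seq(1000, 50000, by = 1000) else sweep
    wpsg <- wpsgAccuracy(b$h2A, b$nA, b$meAall, 0.8)
    wpmg <- wpmgAccuracy(predictionInputs(
      h2A = b$h2A, nA = b$nA, rho21 = 0.4, rho22 = 0.4,
      meA1 = b$meA1, meA2 = b$meA2))
    for (meAB in grid) {
      mpsg <- mpsgAccuracy(b$h2A, b$h2B, b$nA, b$nB, rho2A = 0.8, rg = 0.6,
                           meA = b$meAall, meAB = meAB)
      mpmg <- mpmgAccuracy(predictionInputs(
        h2A = b$h2A, h2B = b$h2B, nA = b$nA, nB = b$nB,
        rho21 = 0.4, rho22 = 0.4, rg = 0.6,
        meA1 = b$meA1, meAB1 = b$meAB1, meA2 = b$meA2, meAB2 = meAB))
      out[[length(out) + 1L]] <- .caseRow("meAB2", meAB,
        c("WPSG", "WPMG", "MPSG", "MPMG"), c(wpsg, wpmg, mpsg, mpmg), wpsg)
    }
  } else {
    grid <- if (is.null(sweep)) seq(0, 0.9, by = 0.1) else sweep
    wpsgRef <- wpsgAccuracy(b$h2A, b$nA, b$meAall, 1)
    for (u in grid) {
      sc <- 1 - u
      wpsg <- wpsgAccuracy(b$h2A, b$nA, b$meAall * sc, 1)
      wpmg <- wpmgAccuracy(predictionInputs(
        h2A = b$h2A, nA = b$nA, rho21 = 0.5, rho22 = 0.5,
        meA1 = b$meA1 * sc, meA2 = b$meA2 * sc))
      mpsg <- mpsgAccuracy(b$h2A, b$h2B, b$nA, b$nB, rho2A = 1, rg = 0.6,
                           meA = b$meAall * sc, meAB = b$meABall)
      mpmg <- mpmgAccuracy(predictionInputs(
        h2A = b$h2A, h2B = b$h2B, nA = b$nA, nB = b$nB,
        rho21 = 0.5, rho22 = 0.5, rg = 0.6,
        meA1 = b$meA1 * sc, meAB1 = b$meAB1,
        meA2 = b$meA2 * sc, meAB2 = b$meAB2))
      out[[length(out) + 1L]] <- .caseRow("underestimation", u,
        c("WPSG", "WPMG", "MPSG", "MPMG"), c(wpsg, wpmg, mpsg, mpmg),
        wpsgRef)
    }
  }
  do.call(rbind, out)
}

#' Validate the deterministic predictions against simulated data
#'
#' For every combination of genetic correlation, heritability and
#' pre-selection level, repeatedly simulates a two-population data set,
#' builds the two GRMs, runs k-fold cross-validated two-GRM GBLUP at
#' simulation-truth variance components, and compares the mean empirical
#' accuracy with the deterministic multi-population two-GRM prediction
#' parameterised with Me estimated from the synthetic GRMs and the analytic
#' variance split (a pre-selected fraction f of causal SNPs explains, on
#' average, a fraction f of the genetic variance).
#'
#' Non-selected causal SNPs are kept in the second SNP set
#' (\code{includeUnselectedCausal = TRUE}) so that, with unlinked loci, the
#' second GRM genuinely tags the remaining genetic variance and the
#' analytic split applies.
#'
#' @param config a [SimulationConfig-class] giving the population sizes,
#'   panel, Fst and replicate count.
#' @param rgValues,h2Values,csnpLevels grids of genetic correlations,
#'   heritabilities and pre-selection counts.
#' @param k number of cross-validation folds.
#' @return a data frame with one row per scenario cell: grids, replicate
#'   count, mean/SD empirical accuracy, mean predicted accuracy, and
#'   whether the prediction lies within two replicate-SD of the mean
#'   empirical accuracy.
#' @export
runValidationGrid <- function(config,
                              rgValues = c(0.4, 0.8),
                              h2Values = c(0.3, 0.8),
                              csnpLevels = c(config@nCausal / 2,
                                             config@nCausal),
                              k = 5) {
  stopifnot(is(config, "SimulationConfig"))
  reps <- config@replicates
  if (reps < 2)
    stop("invalid parameter: at least 2 replicates are required",
         call. = FALSE)
  cells <- expand.grid(rg = rgValues, h2 = h2Values, level = csnpLevels,
                       KEEP.OUT.ATTRS = FALSE)
  emp <- pred <- matrix(NA_real_, nrow(cells), reps)
  nTrainA <- round(config@nA * (k - 1) / k)
  for (r in seq_len(reps)) {
    seedR <- config@seed + r
    geno <- simulateGenotypes(config, seed = seedR)
    causal <- sort(sample(snpIds(geno), config@nCausal))  # uses seedR stream
    byLevel <- list()
    for (lev in unique(cells$level)) {
      part <- partitionCausal(causal, snpIds(geno), lev,
                              seed = seedR + 7L,
                              includeUnselectedCausal = TRUE)
      grm1 <- buildGRM(geno, part@selected)
      grm2 <- buildGRM(geno, part@remaining)
      byLevel[[as.character(lev)]] <- list(
        part = part, grm1 = grm1, grm2 = grm2,
        meA1 = meWithin(grm1, "A"), meAB1 = meAcross(grm1),
        meA2 = meWithin(grm2, "A"), meAB2 = meAcross(grm2))
    }
    effByRg <- lapply(setNames(nm = as.character(unique(cells$rg))),
      function(rg) sampleEffects(causal, as.numeric(rg), seed = seedR + 13L))
    for (i in seq_len(nrow(cells))) {
      rg <- cells$rg[i]; h2 <- cells$h2[i]
      lv <- byLevel[[as.character(cells$level[i])]]
      pheno <- simulatePhenotypes(geno, effByRg[[as.character(rg)]],
                                  h2A = h2, h2B = h2, seed = seedR + 29L,
                                  selected = lv$part@selected)
      vc <- truthComponents(pheno, rg)
      res <- crossValidate(lv$grm1,
                           if (all(vc@K2 == 0)) NULL else lv$grm2,
                           if (all(vc@K2 == 0))
                             varianceComponents(vc@K1, vc@K2 * 0,
                                                vc@residVar)
                           else vc,
                           phenotypes(pheno), populations(pheno),
                           k = k, seed = seedR + 43L)
      emp[i, r] <- empiricalAccuracy(res, trueGenomicValues(pheno))
      frac <- cells$level[i] / config@nCausal
      pred[i, r] <- mpmgAccuracy(predictionInputs(
        h2A = h2, h2B = h2, nA = nTrainA, nB = config@nB,
        rho21 = frac, rho22 = 1 - frac, rg = rg,
        meA1 = lv$meA1, meAB1 = lv$meAB1,
        meA2 = lv$meA2, meAB2 = lv$meAB2))
    }
  }
  cells$replicates <- reps
  cells$meanEmpirical <- rowMeans(emp)
  cells$sdEmpirical <- apply(emp, 1L, stats::sd)
  cells$meanPredicted <- rowMeans(pred)
  cells$withinTwoSd <-
    abs(cells$meanPredicted - cells$meanEmpirical) <= 2 * cells$sdEmpirical
  cells
}

#' Write scenario tables and a run manifest
#'
#' @param tables named list of data frames; each is written as
#'   \code{<name>.csv}.
#' @param dir output directory, created if absent.
#' @param manifest named list echoed into \code{manifest.txt} (configuration,
#'   seeds, package version).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(tables, dir, manifest = list()) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  manifest <- c(list(package = "gpacc",
                     version = as.character(utils::packageVersion("gpacc")),
                     date = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                manifest)
  mf <- file.path(dir, "manifest.txt")
  writeLines(paste(names(manifest), vapply(manifest, function(x)
    paste(format(x), collapse = " "), ""), sep = ": "), mf)
  invisible(c(paths, mf))
}
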