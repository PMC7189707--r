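#' Construct the scalar inputs of the accuracy equations
#'
#' User-facing constructor for [PredictionInputs-class]. All arguments map
#' one-to-one onto the symbols of the deterministic accuracy predictors.
#' A single genetic correlation \code{rg} is applied to both SNP sets unless
#' per-set values \code{rg1}/\code{rg2} are given.
#'
#' @param h2A,h2B heritability of the trait in population A (the target) and
#'   population B, each in (0, 1].
#' @param nA,nB training-population sizes from A and B.
#' @param rho21,rho22 proportion of the total genetic variance in the
#'   validation population explained by SNP set 1 (pre-selected) and SNP set
#'   2 (remaining); rho21 + rho22 <= 1.
#' @param rg genetic correlation between populations, applied to both SNP
#'   sets by default.
#' @param meA1,meA2 effective number of independent chromosome segments (Me)
#'   within population A, per SNP set.
#' @param meAB1,meAB2 Me across populations A and B, per SNP set.
#' @param rg1,rg2 optional per-set genetic correlations overriding \code{rg}.
#' @return a validated [PredictionInputs-class] object.
#' @examples
#' predictionInputs(h2A = 0.3, h2B = 0.3, nA = 476, nB = 5553,
#'                  rho21 = 0.4, rho22 = 0.4, rg = 1,
#'                  meA1 = 159, meAB1 = 463, meA2 = 280, meAB2 = 32970)
#' @export
predictionInputs <- function(h2A, h2B = h2A, nA, nB = 0,
                             rho21, rho22 = 0, rg = 0,
                             meA1, meA2 = meA1, meAB1 = meA1, meAB2 = meA2,
                             rg1 = rg, rg2 = rg) {
  new("PredictionInputs", h2A = h2A, h2B = h2B, nA = nA, nB = nB,
      rho21 = rho21, rho22 = rho22, rg1 = rg1, rg2 = rg2,
      meA1 = meA1, meA2 = meA2, meAB1 = meAB1, meAB2 = meAB2)
}

.checkEquationArgs <- function(h2, n, me, rho2) {
  if (!is.finite(me) || me <= 0)
    stop("invalid parameter: Me must be positive", call. = FALSE)
  if (!is.finite(h2) || h2 <= 0 || h2 > 1)
    stop("invalid parameter: h2 must lie in (0, 1]", call. = FALSE)
  if (!is.finite(rho2) || rho2 < 0 || rho2 > 1)
    stop("invalid parameter: rho2 must lie in [0, 1]", call. = FALSE)
  if (!is.finite(n) || n < 0)
    stop("invalid parameter: N must be non-negative", call. = FALSE)
  invisible(TRUE)
}

# reliability of estimated SNP effects for one population/SNP set
.rSnp2 <- function(h2, n, me) h2 * n / (h2 * n + me)

#' Within-population, single-GRM accuracy
#'
#' The classical deterministic accuracy of genomic prediction with one GRM
#' and a single training population:
#' \code{sqrt(rho2 * h2 * N / (h2 * N + Me))}, where \code{rho2} is the
#' proportion of the total genetic variance captured by the SNPs and
#' \code{Me} the effective number of independent chromosome segments.
#'
#' @param h2 trait heritability in the training/validation population.
#' @param n number of training individuals.
#' @param me effective number of independent chromosome segments.
#' @param rho2 proportion of genetic variance explained by the SNPs.
#' @return predicted accuracy in [0, 1].
#' @examples
#' wpsgAccuracy(h2 = 0.3, n = 476, me = 280, rho2 = 0.8)
#' @export
wpsgAccuracy <- function(h2, n, me, rho2) {
  .checkEquationArgs(h2, n, me, rho2)
  sqrt(rho2 * .rSnp2(h2, n, me))
}

#' Within-population, two-GRM accuracy
#'
#' Accuracy of the total estimated genomic value when two GRMs, built from a
#' pre-selected and a remaining SNP set, are fitted simultaneously within one
#' population. Because the two sets of estimated genomic values are
#' uncorrelated when jointly fitted, the index accuracy collapses to
#' \code{sqrt(rho21 * k1 + rho22 * k2)} with
#' \code{ks = h2 N / (h2 N + Me_s)}.
#'
#' @param inputs a [PredictionInputs-class]; only \code{h2A}, \code{nA},
#'   \code{rho21}, \code{rho22}, \code{meA1} and \code{meA2} are consumed.
#' @return predicted accuracy in [0, 1].
#' @examples
#' pi <- predictionInputs(h2A = 0.3, nA = 476, rho21 = 0.4, rho22 = 0.4,
#'                        meA1 = 159, meA2 = 280)
#' wpmgAccuracy(pi)
#' @export
wpmgAccuracy <- function(inputs) {
  stopifnot(is(inputs, "PredictionInputs"))
  .checkEquationArgs(inputs@h2A, inputs@nA, inputs@meA1, inputs@rho21)
  .checkEquationArgs(inputs@h2A, inputs@nA, inputs@meA2, inputs@rho22)
  sqrt(inputs@rho21 * .rSnp2(inputs@h2A, inputs@nA, inputs@meA1) +
       inputs@rho22 * .rSnp2(inputs@h2A, inputs@nA, inputs@meA2))
}

#' Multi-population, single-GRM accuracy
#'
#' Two-source selection-index accuracy of predicting population-A candidates
#' from a combined A + B training population with one GRM. The sources are
#' the estimated genomic values obtained from the A and B parts of the
#' training population; information from B is discounted by the genetic
#' correlation \code{rg} and by the (large) across-population \code{meAB}.
#'
#' @param h2A,h2B heritabilities in populations A and B.
#' @param nA,nB training sizes from A and B.
#' @param rho2A proportion of genetic variance explained by the SNPs in the
#'   validation population A.
#' @param rg genetic correlation between populations.
#' @param meA,meAB Me within A and across A and B.
#' @return predicted accuracy in [0, 1].
#' @examples
#' mpsgAccuracy(h2A = 0.3, h2B = 0.3, nA = 476, nB = 5553, rho2A = 0.8,
#'              rg = 1, meA = 280, meAB = 33242)
#' @export
mpsgAccuracy <- function(h2A, h2B, nA, nB, rho2A, rg, meA, meAB) {
  .checkEquationArgs(h2A, nA, meA, rho2A)
  .checkEquationArgs(h2B, nB, meAB, rho2A)
  if (abs(rg) > 1) stop("invalid parameter: rg must lie in [-1, 1]", call. = FALSE)
  if (nB == 0 || rg == 0) return(wpsgAccuracy(h2A, nA, meA, rho2A))
  a <- h2A / meA
  b <- h2B / meAB
  rho <- sqrt(rho2A)
  g <- c(rho * sqrt(a), rho * rg * sqrt(b))
  P <- matrix(c(a + 1 / nA, rg * sqrt(a * b),
                rg * sqrt(a * b), b + 1 / nB), 2L, 2L)
  selectionIndexAccuracy(new("SelectionIndex", g = g, P = P))
}

#' Build the four-source selection index of the multi-population two-GRM model
#'
#' Constructs the covariance vector \code{g} and 4 x 4 (co)variance matrix
#' \code{P} of the index that combines, for each of the two SNP sets, the
#' estimated genomic values obtained from the A and the B part of the
#' training population. The set-1 and set-2 blocks of \code{P} are uncoupled
#' because jointly fitted GRMs yield uncorrelated estimated genomic values.
#'
#' @param inputs a [PredictionInputs-class] with \code{nA > 0} and
#'   \code{nB > 0}.
#' @return a [SelectionIndex-class] with 4 sources, ordered (set1-A, set1-B,
#'   set2-A, set2-B).
#' @export
buildMpmgIndex <- function(inputs) {
  stopifnot(is(inputs, "PredictionInputs"))
  if (inputs@nB <= 0)
    stop("invalid parameter: the multi-population index requires nB > 0",
         call. = FALSE)
  block <- function(rho2, rg, meA, meAB) {
    a <- inputs@h2A / meA
    b <- inputs@h2B / meAB
    rho <- sqrt(rho2)
    list(g = c(rho * sqrt(a), rho * rg * sqrt(b)),
         P = matrix(c(a + 1 / inputs@nA, rg * sqrt(a * b),
                      rg * sqrt(a * b), b + 1 / inputs@nB), 2L, 2L))
  }
  b1 <- block(inputs@rho21, inputs@rg1, inputs@meA1, inputs@meAB1)
  b2 <- block(inputs@rho22, inputs@rg2, inputs@meA2, inputs@meAB2)
  P <- matrix(0, 4L, 4L)
  P[1:2, 1:2] <- b1$P
  P[3:4, 3:4] <- b2$P
  new("SelectionIndex", g = c(b1$g, b2$g), P = P)
}

#' Accuracy of a selection index
#'
#' \code{sqrt(g' P^-1 g)} for a selection index whose breeding goal (the true
#' genomic value) has unit variance. \code{P} must be positive definite; a
#' radicand marginally above 1 (floating point) is clamped, a larger excess
#' signals inconsistent inputs and raises an error.
#'
#' @param index a [SelectionIndex-class].
#' @param tol tolerance above 1 within which the radicand is clamped.
#' @return accuracy in [0, 1].
#' @export
selectionIndexAccuracy <- function(index, tol = 1e-8) {
  stopifnot(is(index, "SelectionIndex"))
  R <- tryCatch(chol(index@P), error = function(e)
    stop("numerical degeneracy: P is not positive definite", call. = FALSE))
  u <- backsolve(R, index@g, transpose = TRUE)
  r2 <- sum(u^2)
  if (r2 > 1 + tol)
    stop(sprintf(
      "inconsistent inputs: squared index accuracy %.6g exceeds 1", r2),
      call. = FALSE)
  sqrt(min(r2, 1))
}

#' Multi-population, two-GRM accuracy
#'
#' Deterministic accuracy of the total estimated genomic value of
#' population-A candidates when individuals from populations A and B are
#' combined in training and two GRMs (pre-selected and remaining SNPs) are
#' fitted simultaneously. The \code{"matrix"} form evaluates the four-source
#' selection index of [buildMpmgIndex()]; the \code{"scalar"} form evaluates
#' the algebraically equivalent closed form in which each SNP set contributes
#' an independent two-source term. Both agree to floating-point precision.
#'
#' At \code{rg = 0} the equation reduces to the within-population two-GRM
#' accuracy; at \code{rho22 = 0} it reduces to the multi-population
#' single-GRM accuracy evaluated on the set-1 quantities.
#'
#' @param inputs a [PredictionInputs-class].
#' @param form \code{"scalar"} or \code{"matrix"}.
#' @return predicted accuracy in [0, 1].
#' @examples
#' pi <- predictionInputs(h2A = 0.3, h2B = 0.3, nA = 476, nB = 5553,
#'                        rho21 = 0.4, rho22 = 0.4, rg = 1,
#'                        meA1 = 159, meAB1 = 463, meA2 = 280, meAB2 = 32970)
#' mpmgAccuracy(pi)
#' @export
mpmgAccuracy <- function(inputs, form = c("scalar", "matrix")) {
  stopifnot(is(inputs, "PredictionInputs"))
  form <- match.arg(form)
  if (inputs@nB <= 0 || (inputs@rg1 == 0 && inputs@rg2 == 0))
    return(wpmgAccuracy(inputs))
  if (form == "matrix")
    return(selectionIndexAccuracy(buildMpmgIndex(inputs)))
  term <- function(rho2, rg, meA, meAB) {
    a <- inputs@h2A / meA
    b <- inputs@h2B / meAB
    num <- a * (b + 1 / inputs@nB) + rg^2 * b * (a + 1 / inputs@nA) -
      2 * a * rg^2 * b
    den <- (a + 1 / inputs@nA) * (b + 1 / inputs@nB) - a * rg^2 * b
    rho2 * num / den
  }
  r2 <- term(inputs@rho21, inputs@rg1, inputs@meA1, inputs@meAB1) +
    term(inputs@rho22, inputs@rg2, inputs@meA2, inputs@meAB2)
  if (r2 > 1 + 1e-8)
    stop(sprintf(
      "inconsistent inputs: squared accuracy %.6g exceeds 1", r2),
      call. = FALSE)
  sqrt(min(r2, 1))
}

#' Percent change of one accuracy relative to another
#'
#' @param accNew,accRef the accuracy of interest and the reference accuracy
#'   (\code{accRef > 0}).
#' @return \code{100 * (accNew / accRef - 1)}.
#' @examples
#' relativeChange(0.5696, 0.5198)  # ~ 9.6
#' @export
relativeChange <- function(accNew, accRef) {
  if (any(accRef <= 0))
    stop("invalid parameter: reference accuracy must be positive", call. = FALSE)
  100 * (accNew / accRef - 1)
}

#' Read prediction inputs from a flat YAML or JSON configuration file
#'
#' The file must be a flat mapping whose keys are the argument names of
#' [predictionInputs()] (h2A, h2B, nA, nB, rho21, rho22, rg, meA1, meA2,
#' meAB1, meAB2, optionally rg1/rg2).
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return a [PredictionInputs-class].
#' @export
readPredictionConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(predictionInputs))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(predictionInputs, vals)
}
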