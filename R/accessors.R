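#' Accessors for package classes
#'
#' Small accessor generics: genotype codes, population labels, SNP ids, the
#' assembled GRM and its blocks, selection-index components, and EGV vectors.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genoCodes", function(x, ...) standardGeneric("genoCodes"))

#' @rdname accessors
#' @export
setMethod("genoCodes", "GenotypeMatrix", function(x, ...) x@codes)

#' @rdname accessors
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname accessors
#' @export
setMethod("populations", "GenotypeMatrix", function(x, ...)
  setNames(x@population, rownames(x@codes)))

#' @rdname accessors
#' @export
setMethod("populations", "PhenotypeSet", function(x, ...)
  setNames(x@population, names(x@tgv)))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x, ...) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x, ...) colnames(x@codes))

#' @rdname accessors
#' @export
setMethod("snpIds", "MultiPopGRM", function(x, ...) x@snps)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x, ...) rownames(x@codes))

#' Assembled multi-population GRM
#'
#' Returns the full symmetric relationship matrix, population-A individuals
#' first, assembled from the within- and across-population blocks.
#'
#' @param x a [MultiPopGRM-class].
#' @param ... unused.
#' @return a symmetric numeric matrix with individual ids as dimnames.
#' @export
setGeneric("grmMatrix", function(x, ...) standardGeneric("grmMatrix"))

#' @rdname grmMatrix
#' @export
setMethod("grmMatrix", "MultiPopGRM", function(x, ...) {
  if (nrow(x@BB) == 0L) return(x@AA)
  rbind(cbind(x@AA, x@AB), cbind(t(x@AB), x@BB))
})

#' @rdname accessors
#' @export
setGeneric("grmBlock", function(x, ...) standardGeneric("grmBlock"))

#' Extract a single GRM block
#'
#' @param x a [MultiPopGRM-class].
#' @param which one of "AA", "BB", "AB".
#' @param ... unused.
#' @rdname accessors
#' @export
setMethod("grmBlock", "MultiPopGRM", function(x, which = c("AA", "BB", "AB"), ...)
  slot(x, match.arg(which)))

#' @rdname accessors
#' @export
setGeneric("indexWeights", function(x, ...) standardGeneric("indexWeights"))

#' Selection-index weights b = P^-1 g
#' @rdname accessors
#' @export
setMethod("indexWeights", "SelectionIndex", function(x, ...)
  drop(solve(x@P, x@g)))

#' @rdname accessors
#' @export
setGeneric("egvTotal", function(x, ...) standardGeneric("egvTotal"))

#' @rdname accessors
#' @export
setMethod("egvTotal", "GBLUPResult", function(x, ...) x@egvTotal)

#' @rdname accessors
#' @export
setGeneric("trueGenomicValues", function(x, ...) standardGeneric("trueGenomicValues"))

#' @rdname accessors
#' @export
setMethod("trueGenomicValues", "PhenotypeSet", function(x, ...) x@tgv)

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x, ...) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setMethod("phenotypes", "PhenotypeSet", function(x, ...) x@phenotypes)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@codes), "individuals x",
      ncol(object@codes), "SNPs\n")
  print(table(population = object@population))
})

setMethod("show", "MultiPopGRM", function(object) {
  cat("MultiPopGRM built from", length(object@snps), "SNPs\n")
  cat("  blocks: AA", paste(dim(object@AA), collapse = "x"))
  if (nrow(object@BB)) {
    cat(", BB", paste(dim(object@BB), collapse = "x"),
        ", AB", paste(dim(object@AB), collapse = "x"))
  }
  cat("\n")
})

setMethod("show", "PredictionInputs", function(object) {
  cat("PredictionInputs\n")
  cat(sprintf("  h2: A=%.3g B=%.3g   N: A=%g B=%g   rg: %.3g/%.3g\n",
              object@h2A, object@h2B, object@nA, object@nB,
              object@rg1, object@rg2))
  cat(sprintf("  rho2: set1=%.3g set2=%.3g\n", object@rho21, object@rho22))
  cat(sprintf("  Me within A: %g / %g   Me across: %g / %g\n",
              object@meA1, object@meA2, object@meAB1, object@meAB2))
})

setMethod("show", "SelectionIndex", function(object) {
  cat("SelectionIndex with", length(object@g), "information sources\n")
  cat("g:", signif(object@g, 5), "\n")
  cat("P:\n"); print(signif(object@P, 5))
})

setMethod("show", "PhenotypeSet", function(object) {
  cat("PhenotypeSet:", length(object@tgv), "individuals,",
      length(object@causal), "causal SNPs\n")
  cat("  realized sigma2_g:", signif(object@sigma2g, 4), "\n")
})

setMethod("show", "GBLUPResult", function(object) {
  cat("GBLUPResult:", length(object@egvTotal), "validation individuals in",
      length(unique(object@fold)), "fold(s)\n")
})
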