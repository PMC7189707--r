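#' Load additive-coded genotypes
#'
#' Reads an individuals x SNPs matrix of additive allele counts (0/1/2,
#' \code{NA} allowed) together with population labels.
#'
#' Two dialects are supported. \code{"delimited"}: a whitespace- or
#' comma-delimited table with a header row of SNP ids and two leading
#' columns, \code{id} and \code{population}. \code{"plink_raw"}: the PLINK
#' additive export with header
#' \code{FID IID PAT MAT SEX PHENOTYPE snp1_A ...}; codes are read from
#' column 7 onward and population labels are taken from a sidecar sample
#' table (\code{id}, \code{population}).
#'
#' @param path path to the genotype file.
#' @param format \code{"delimited"} or \code{"plink_raw"}.
#' @param samples for \code{"plink_raw"}, path to the sidecar sample table;
#'   ignored for \code{"delimited"}.
#' @return a [GenotypeMatrix-class].
#' @export
loadGenotypes <- function(path, format = c("delimited", "plink_raw"),
                          samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  sep <- if (format == "delimited" &&
             grepl(",", readLines(path, n = 1L))) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "delimited") {
    if (!all(c("id", "population") %in% names(tab)[1:2]))
      stop("format error: delimited genotypes need leading 'id' and ",
           "'population' columns", call. = FALSE)
    ids <- as.character(tab$id)
    pop <- as.character(tab$population)
    codes <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!identical(names(tab)[1:6], fixed))
      stop("format error: not a PLINK .raw additive file", call. = FALSE)
    ids <- as.character(tab$IID)
    codes <- as.matrix(tab[, -(1:6), drop = FALSE])
    colnames(codes) <- sub("_[ACGT12]$", "", colnames(codes))
    if (is.null(samples))
      stop("a sidecar sample table is required for plink_raw input",
           call. = FALSE)
    side <- utils::read.table(samples, header = TRUE,
                              stringsAsFactors = FALSE)
    missing <- setdiff(ids, side$id)
    if (length(missing))
      stop("consistency error: individuals absent from sample table: ",
           paste(utils::head(missing), collapse = ", "), call. = FALSE)
    pop <- side$population[match(ids, side$id)]
  }
  storage.mode(codes) <- "double"
  if (any(!is.na(codes) & !(codes %in% c(0, 1, 2))))
    stop("format error: genotype codes must be 0, 1 or 2", call. = FALSE)
  rownames(codes) <- ids
  new("GenotypeMatrix", codes = codes,
      population = factor(pop))
}

#' Construct a GenotypeMatrix from a matrix in memory
#'
#' @param codes individuals x SNPs matrix of 0/1/2 codes (NA allowed), with
#'   dimnames.
#' @param population population label per individual.
#' @return a [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(codes, population) {
  new("GenotypeMatrix", codes = codes, population = factor(population))
}

#' Filter SNPs on combined minor-allele count
#'
#' Removes SNPs whose minor-allele count, summed over all populations, is
#' below \code{minMinorCopies} (default 10 copies).
#'
#' @param g a [GenotypeMatrix-class].
#' @param minMinorCopies minimum number of copies of the minor allele.
#' @return the filtered [GenotypeMatrix-class].
#' @export
qcFilter <- function(g, minMinorCopies = 10) {
  stopifnot(is(g, "GenotypeMatrix"), minMinorCopies >= 0)
  alt <- colSums(g@codes, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(g@codes))
  mac <- pmin(alt, tot - alt)
  keep <- mac >= minMinorCopies
  if (!any(keep))
    stop("degenerate data: no SNP passes the minor-allele-count filter",
         call. = FALSE)
  new("GenotypeMatrix", codes = g@codes[, keep, drop = FALSE],
      population = g@population)
}

#' Per-SNP allele frequencies
#'
#' Frequency of the counted allele, \code{mean(codes) / 2}, per SNP; with
#' \code{byPopulation = TRUE} one row per population.
#'
#' @param g a [GenotypeMatrix-class].
#' @param byPopulation compute frequencies separately per population.
#' @return a numeric vector (overall) or a populations x SNPs matrix.
#' @export
alleleFrequencies <- function(g, byPopulation = FALSE) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (!byPopulation)
    return(colMeans(g@codes, na.rm = TRUE) / 2)
  pops <- levels(g@population)
  out <- matrix(NA_real_, length(pops), ncol(g@codes),
                dimnames = list(pops, colnames(g@codes)))
  for (p in pops) {
    rows <- g@population == p
    if (!any(rows))
      stop("degenerate data: population ", p, " has no individuals",
           call. = FALSE)
    out[p, ] <- colMeans(g@codes[rows, , drop = FALSE], na.rm = TRUE) / 2
  }
  out
}

#' Build a (multi-population) genomic relationship matrix
#'
#' Genotypes are centered with population-specific allele frequencies
#' (\code{z = x - 2 p_k}, with \code{p_k} the frequency in the individual's
#' own population) and, per population, scaled by \code{sum(2 p_k (1-p_k))}.
#' The within-population blocks are \code{Z_k Z_k' / S_k}; the
#' across-population block is \code{Z_A Z_B' / sqrt(S_A S_B)}. Missing codes
#' are mean-imputed per population before centering. With a single
#' population only the AA block is produced.
#'
#' @param g a [GenotypeMatrix-class] with one or two populations.
#' @param snps SNP ids to build the matrix from; default all SNPs.
#' @return a [MultiPopGRM-class].
#' @export
buildGRM <- function(g, snps = snpIds(g)) {
  stopifnot(is(g, "GenotypeMatrix"))
  miss <- setdiff(snps, snpIds(g))
  if (length(miss))
    stop("unknown SNP ids: ", paste(utils::head(miss), collapse = ", "),
         call. = FALSE)
  x <- g@codes[, snps, drop = FALSE]
  pops <- levels(droplevels(g@population))
  if (length(pops) > 2L)
    stop("at most two populations are supported", call. = FALSE)
  Z <- vector("list", length(pops))
  S <- numeric(length(pops))
  fr <- vector("list", length(pops))
  for (k in seq_along(pops)) {
    rows <- g@population == pops[k]
    xk <- x[rows, , drop = FALSE]
    p <- colMeans(xk, na.rm = TRUE) / 2
    if (anyNA(xk)) {
      imp <- rep(2 * p, each = nrow(xk))
      xk[is.na(xk)] <- imp[is.na(xk)]
    }
    Z[[k]] <- sweep(xk, 2L, 2 * p)
    S[k] <- sum(2 * p * (1 - p))
    fr[[k]] <- p
    if (S[k] <= 0)
      stop("degenerate data: no polymorphic SNP in population ", pops[k],
           call. = FALSE)
  }
  AA <- tcrossprod(Z[[1L]]) / S[1L]
  if (length(pops) == 1L) {
    e <- matrix(numeric(0), 0L, 0L)
    return(new("MultiPopGRM", AA = AA, BB = e,
               AB = matrix(numeric(0), nrow(AA), 0L),
               freqA = fr[[1L]], freqB = numeric(0), snps = snps))
  }
  BB <- tcrossprod(Z[[2L]]) / S[2L]
  AB <- tcrossprod(Z[[1L]], Z[[2L]]) / sqrt(S[1L] * S[2L])
  new("MultiPopGRM", AA = AA, BB = BB, AB = AB,
      freqA = fr[[1L]], freqB = fr[[2L]], snps = snps)
}

#' Effective number of independent chromosome segments within a population
#'
#' Estimated as the inverse of the variance of the off-diagonal
#' (between-individual) elements of the population's within-population GRM
#' block. Diagonal elements reflect inbreeding rather than segment sharing
#' and are excluded.
#'
#' @param grm a [MultiPopGRM-class].
#' @param population \code{"A"} or \code{"B"}, selecting the block.
#' @return Me, a positive real.
#' @export
meWithin <- function(grm, population = c("A", "B")) {
  stopifnot(is(grm, "MultiPopGRM"))
  block <- switch(match.arg(population), A = grm@AA, B = grm@BB)
  if (nrow(block) < 3L)
    stop("at least 3 individuals are required to estimate Me", call. = FALSE)
  off <- block[lower.tri(block)]
  v <- var(off)
  if (!is.finite(v) || v <= 0)
    stop("degenerate data: zero variance of genomic relationships",
         call. = FALSE)
  1 / v
}

#' Effective number of independent chromosome segments across two populations
#'
#' Estimated as the inverse of the variance of the elements of the
#' across-population block of the multi-population GRM.
#'
#' @param grm a [MultiPopGRM-class] built from two populations.
#' @return Me across populations, a positive real.
#' @export
meAcross <- function(grm) {
  stopifnot(is(grm, "MultiPopGRM"))
  if (length(grm@AB) < 2L)
    stop("an across-population block with >= 2 elements is required",
         call. = FALSE)
  v <- var(as.vector(grm@AB))
  if (!is.finite(v) || v <= 0)
    stop("degenerate data: zero variance of across-population relationships",
         call. = FALSE)
  1 / v
}

#' Write a GRM and its Me summary to disk
#'
#' Writes the assembled square matrix as a delimited file with an id header,
#' and a small block summary (Me within A, Me within B, Me across) alongside.
#'
#' @param grm a [MultiPopGRM-class].
#' @param path output path for the matrix; the summary is written to
#'   \code{paste0(path, ".summary")}.
#' @return invisibly, the summary data frame.
#' @export
writeGRM <- function(grm, path) {
  m <- grmMatrix(grm)
  utils::write.table(m, path, quote = FALSE, sep = "\t", col.names = NA)
  summ <- data.frame(
    statistic = c("me_within_A", "me_within_B", "me_across"),
    value = c(meWithin(grm, "A"),
              if (nrow(grm@BB) >= 3L) meWithin(grm, "B") else NA_real_,
              if (length(grm@AB) >= 2L) meAcross(grm) else NA_real_))
  utils::write.table(summ, paste0(path, ".summary"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(summ)
}
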