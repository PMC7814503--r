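#' @include AllClasses.R
NULL

# mean-impute missing dosages per SNP (rows of the SNP x accession matrix)
.imputeDosages <- function(d) {
  mu <- rowMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 1L]]
  d
}

#' Principal component analysis of a genotype panel
#'
#' Missing calls are mean-imputed per SNP, the dosage matrix is centered
#' (and optionally scaled) per SNP, and accessions are projected onto the
#' top eigenvectors. Three components are the conventional structure
#' correction for a two-subpopulation barley panel.
#'
#' @param gm a [GenotypePanel-class] with at least 2 accessions and 2 SNPs.
#' @param nPcs number of components to retain (default 3).
#' @param scale scale each SNP to unit variance before decomposition.
#' @return a [StructureModel-class] with scores and variance fractions
#'   (kinship slot empty).
#' @export
pcaStructure <- function(gm, nPcs = 3, scale = FALSE) {
  stopifnot(is(gm, "GenotypePanel"), ncol(gm) >= 2, nrow(gm) >= 2)
  X <- t(.imputeDosages(dosages(gm)))          # accessions x SNPs
  keep <- apply(X, 2, stats::var) > 0
  if (!any(keep)) stop("constant genotype matrix: no variance to decompose")
  X <- X[, keep, drop = FALSE]
  pr <- stats::prcomp(X, center = TRUE, scale. = scale)
  nPcs <- min(nPcs, ncol(pr$x))
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  new("StructureModel",
      scores = pr$x[, seq_len(nPcs), drop = FALSE],
      varianceExplained = ve[seq_len(nPcs)],
      kinship = matrix(numeric(0), 0, 0))
}

#' VanRaden marker-based kinship matrix
#'
#' Centered cross-product of mean-imputed dosages scaled by
#' \eqn{\sum 2 p (1 - p)} over SNPs, where `p` is the alt-allele frequency.
#' The diagonal averages about 1 on an unstructured panel, and the result is
#' symmetric positive semi-definite by construction.
#'
#' @param gm a [GenotypePanel-class].
#' @return accessions x accessions numeric matrix.
#' @export
kinshipMatrix <- function(gm) {
  stopifnot(is(gm, "GenotypePanel"), ncol(gm) >= 2, nrow(gm) >= 2)
  d <- .imputeDosages(dosages(gm))
  p <- rowMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("constant genotype matrix: kinship undefined")
  d <- d[poly, , drop = FALSE]; p <- p[poly]
  W <- d - 2 * p                               # center by 2p, recycled by row
  denom <- sum(2 * p * (1 - p))
  K <- crossprod(W) / denom
  dimnames(K) <- list(colnames(d), colnames(d))
  K
}

#' Identity-by-state distance between accessions
#'
#' `1 - (proportion of alleles shared)`, i.e. the mean of `|a - b| / 2` over
#' SNPs where both calls are non-missing (pairwise-complete; no imputation).
#'
#' @param gm a [GenotypePanel-class].
#' @return symmetric accessions x accessions distance matrix, zero diagonal.
#' @export
ibsDistance <- function(gm) {
  stopifnot(is(gm, "GenotypePanel"))
  d <- dosages(gm)
  Ms <- lapply(0:2, function(v) {
    M <- (d == v); M[is.na(M)] <- FALSE; M * 1
  })
  N <- (!is.na(d)) * 1
  nPairs <- crossprod(N)
  if (any(nPairs == 0)) stop("accession pair with no shared non-missing SNPs")
  # sum |a-b| over pairs: |0-1| and |1-2| contribute 1, |0-2| contributes 2
  absDiff <- crossprod(Ms[[1]], Ms[[2]]) + crossprod(Ms[[2]], Ms[[1]]) +
    crossprod(Ms[[2]], Ms[[3]]) + crossprod(Ms[[3]], Ms[[2]]) +
    2 * (crossprod(Ms[[1]], Ms[[3]]) + crossprod(Ms[[3]], Ms[[1]]))
  D <- absDiff / (2 * nPairs)
  diag(D) <- 0
  dimnames(D) <- list(colnames(d), colnames(d))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj]) with one practical fix:
#' negative branch lengths are clamped to zero and the deficit moved to the
#' adjacent (sibling) edge, preserving path lengths between the affected
#' leaves and the rest of the tree as closely as possible. The returned
#' tree is unrooted. Any additive (four-point-condition) matrix is
#' reproduced exactly.
#'
#' @param distanceMatrix symmetric non-negative matrix with zero diagonal,
#'   at least 3 taxa.
#' @param labels optional taxon labels (defaults to matrix dimnames).
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(distanceMatrix, labels = NULL) {
  D <- as.matrix(distanceMatrix)
  if (any(is.na(D)) || any(!is.finite(D))) stop("NaN/NA distances")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < -1e-12)) stop("distances must be non-negative")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  if (is.null(rownames(D))) dimnames(D) <- list(paste0("t", seq_len(nrow(D))),
                                                paste0("t", seq_len(nrow(D))))
  tree <- ape::nj(stats::as.dist(D))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    sib <- which(tree$edge[, 1L] == parent)
    sib <- setdiff(sib, e)
    if (length(sib))
      tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
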