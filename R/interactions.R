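#' @include AllClasses.R
NULL

#' Two-locus likelihood-ratio interaction test
#'
#' Compares, by maximum likelihood under Gaussian errors, the full model
#' `y ~ 1 + PCs + m1 + m2 + m1:m2` against the reduced model `y ~ 1 + PCs`.
#' Twice the log-likelihood difference is referred to a chi-square
#' distribution with 3 degrees of freedom (the two additive terms plus one
#' additive-by-additive interaction term under dosage coding).
#'
#' @param y numeric phenotype.
#' @param dosage1,dosage2 dosage vectors of the two markers.
#' @param pcs matrix of structure covariates (or `NULL`).
#' @param id1,id2 marker labels carried into the result.
#' @return data.frame row: `snp1`, `snp2`, `lrt`, `df`, `p`, `n_used`.
#' @export
lrtInteraction <- function(y, dosage1, dosage2, pcs = NULL,
                           id1 = "m1", id2 = "m2") {
  stopifnot(length(y) == length(dosage1), length(y) == length(dosage2))
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    stopifnot(nrow(pcs) == length(y))
  }
  ok <- !is.na(y) & !is.na(dosage1) & !is.na(dosage2)
  y <- y[ok]; m1 <- dosage1[ok]; m2 <- dosage2[ok]
  if (!is.null(pcs)) pcs <- pcs[ok, , drop = FALSE]
  nCov <- 1L + if (is.null(pcs)) 0L else ncol(pcs)
  if (length(y) < nCov + 5L)
    stop("too few complete cases for the two-locus test")
  if (stats::var(m1) == 0 || stats::var(m2) == 0)
    stop(sprintf("monomorphic marker in pair (%s, %s)", id1, id2))
  if (abs(stats::cor(m1, m2)) > 1 - 1e-12)
    stop(sprintf("collinear markers in pair (%s, %s)", id1, id2))
  Xr <- cbind(rep(1, length(y)), pcs)
  Xf <- cbind(Xr, m1, m2, m1 * m2)
  lrt <- 2 * (.gaussMl(Xf, y) - .gaussMl(Xr, y))
  lrt <- max(lrt, 0)
  data.frame(snp1 = id1, snp2 = id2, lrt = lrt, df = 3L,
             p = stats::pchisq(lrt, df = 3, lower.tail = FALSE),
             n_used = length(y), stringsAsFactors = FALSE)
}

# Gaussian maximum log-likelihood of OLS fit (sigma^2 at its ML value rss/n)
.gaussMl <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

#' Candidate SNPs for the interaction screen
#'
#' Markers whose BH-adjusted p-value from a prior single-marker scan is at
#' most `qMax` (the conservative reading of a "q-value <= 0.1" preselection).
#'
#' @param scan an [AssociationScan-class].
#' @param qMax adjusted-p cutoff (default 0.1).
#' @return character vector of snp ids.
#' @export
candidateSnps <- function(scan, qMax = 0.1) {
  r <- scanResults(scan)
  valid <- is.na(r$skipped) & !is.na(r$p)
  padj <- stats::p.adjust(r$p[valid], method = "BH")
  r$snp_id[valid][padj <= qMax]
}

#' Screen all pairs of candidate SNPs for two-locus interactions
#'
#' Tests every unordered pair of candidate markers with [lrtInteraction]
#' and returns the results sorted by p-value. Pairs that fail the test's
#' preconditions (monomorphic or collinear markers, too few cases) are
#' skipped and reported in `attr(x, "skipped")`.
#'
#' @param gm a [GenotypePanel-class].
#' @param trait named (or panel-aligned) numeric phenotype vector, e.g.
#'   days to flowering.
#' @param pcs structure covariates (or `NULL`).
#' @param candidates character vector of candidate snp ids (from
#'   [candidateSnps] on a prior scan of the trait).
#' @return data.frame of interaction tests sorted by p (empty, with a
#'   warning, when fewer than 2 candidates are given).
#' @export
interactionScreen <- function(gm, trait, pcs = NULL, candidates) {
  stopifnot(is(gm, "GenotypePanel"))
  empty <- data.frame(snp1 = character(0), snp2 = character(0),
                      lrt = numeric(0), df = integer(0), p = numeric(0),
                      n_used = integer(0), stringsAsFactors = FALSE)
  if (length(candidates) < 2) {
    warning("fewer than 2 candidate SNPs: nothing to test")
    return(empty)
  }
  acc <- accessionIds(gm)
  if (!is.null(names(trait))) trait <- trait[acc]
  if (length(trait) != length(acc)) stop("trait does not align with accessions")
  miss <- setdiff(candidates, snpInfo(gm)$snp_id)
  if (length(miss)) stop("unknown candidate snp ids: ", paste(miss, collapse = ", "))
  D <- dosages(gm)[candidates, , drop = FALSE]
  prs <- utils::combn(candidates, 2)
  out <- vector("list", ncol(prs))
  skipped <- character(0)
  for (i in seq_len(ncol(prs))) {
    a <- prs[1, i]; b <- prs[2, i]
    out[[i]] <- tryCatch(
      lrtInteraction(trait, D[a, ], D[b, ], pcs = pcs, id1 = a, id2 = b),
      error = function(e) {
        skipped[[paste(a, b, sep = ":")]] <<- conditionMessage(e)
        NULL
      })
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
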