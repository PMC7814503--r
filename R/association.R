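#' @include AllClasses.R
NULL

# OLS / weighted-OLS of y on X, returning the test on the LAST column of X.
# Returns NULL when the system is singular or df <= 0.
.olsLastCoef <- function(X, y) {
  n <- length(y); p <- ncol(X)
  df <- n - p
  if (df <= 0) return(NULL)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  XtXinv <- chol2inv(R)
  beta <- XtXinv %*% crossprod(X, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * XtXinv[p, p])
  b <- beta[p, 1L]
  tstat <- if (se > 0) b / se else sign(b) * Inf
  p.value <- 2 * stats::pt(-abs(tstat), df)
  list(beta = b, se = se, stat = tstat, p = max(p.value, 1e-300), df = df)
}

.remlProfile <- function(logLambda, d, ystar, Xstar) {
  lambda <- exp(logLambda)
  w <- lambda * d + 1
  sw <- sqrt(w)
  Xw <- Xstar / sw
  yw <- ystar / sw
  p <- ncol(Xw); n <- length(yw)
  XtX <- crossprod(Xw)
  R <- chol(XtX)
  beta <- chol2inv(R) %*% crossprod(Xw, yw)
  rss <- sum((yw - Xw %*% beta)^2)
  np <- n - p
  sigma2 <- rss / np
  -0.5 * (np * log(2 * pi * sigma2) + np + sum(log(w)) +
            2 * sum(log(diag(R))))
}

#' Fit the null mixed model for P3D association scanning
#'
#' Restricted maximum-likelihood estimate of the variance ratio
#' \eqn{\lambda = \sigma^2_g / \sigma^2_e} under
#' \eqn{y = X\beta + g + e,\; g \sim N(0, \sigma^2_g K)}, obtained by 1-D
#' optimisation over \eqn{\log\lambda} on the kinship eigenbasis. The
#' eigen-rotation is retained so that every marker test reuses it
#' (P3D/EMMAX approximation: variance components estimated once on the null
#' model, not per SNP).
#'
#' @param y numeric phenotype (no missing values; non-constant).
#' @param covariates matrix of covariates including the intercept column.
#' @param kinship symmetric PSD accessions x accessions matrix.
#' @return a [NullModelFit-class].
#' @export
fitNullMlm <- function(y, covariates, kinship) {
  y <- as.numeric(y)
  X <- as.matrix(covariates)
  if (stats::var(y) == 0) stop("phenotype is constant")
  if (qr(X)$rank < ncol(X)) stop("covariates are rank deficient")
  K <- as.matrix(kinship)
  if (!isSymmetric(unname(K), tol = 1e-6)) stop("kinship must be symmetric")
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values), 1))
    stop("kinship is not positive semi-definite; consider adding jitter to its diagonal")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)
  opt <- stats::optimize(.remlProfile, interval = log(c(1e-6, 1e6)),
                         d = d, ystar = ystar, Xstar = Xstar, maximum = TRUE)
  lambda <- exp(opt$maximum)
  if (opt$maximum < log(1e-6) + 1e-3 || opt$maximum > log(1e6) - 1e-3) {
    warning("variance-ratio estimate at optimisation boundary; lambda clamped")
    lambda <- min(max(lambda, 1e-6), 1e6)
  }
  new("NullModelFit", lambda = lambda, logLik = opt$objective,
      eigenvalues = d, eigenvectors = U, rotatedY = ystar, rotatedX = Xstar)
}

#' Single-marker association scan in one environment
#'
#' For `model = "lm"`, ordinary least squares of the phenotype on
#' `[1, PCs, dosage]` with a two-sided t-test on the dosage coefficient;
#' accessions missing the phenotype are dropped, and missing dosages are
#' dropped pairwise per SNP. For `model = "mlm"`, generalised least squares
#' under the null-fit covariance (the variance ratio is estimated once and
#' reused for every SNP, P3D/EMMAX-style) with a Wald test; missing dosages
#' are mean-imputed per SNP so the one-time eigen-rotation stays valid.
#' SNPs monomorphic after dropping, or with too few usable accessions, are
#' recorded as skipped with a reason. p-values are floored at 1e-300.
#'
#' @param gm a [GenotypePanel-class].
#' @param y named numeric phenotype vector (names = accession ids) or an
#'   unnamed vector aligned with `accessionIds(gm)`.
#' @param pcs matrix of principal-component covariates (or `NULL`).
#' @param model `"lm"` or `"mlm"`.
#' @param nullFit a [NullModelFit-class] for `"mlm"`; when `NULL` it is
#'   fitted here from `kinship`.
#' @param kinship kinship matrix for `"mlm"` (default [kinshipMatrix] of the
#'   non-missing subset).
#' @param environment label stored on the result.
#' @return an [AssociationScan-class].
#' @export
scanEnvironment <- function(gm, y, pcs = NULL, model = c("lm", "mlm"),
                            nullFit = NULL, kinship = NULL,
                            environment = "env") {
  model <- match.arg(model)
  stopifnot(is(gm, "GenotypePanel"))
  acc <- accessionIds(gm)
  if (!is.null(names(y))) {
    if (!all(acc %in% names(y))) stop("phenotype names do not cover accessions")
    y <- y[acc]
  } else if (length(y) != length(acc))
    stop("phenotype length does not match accessions")
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != length(acc)) stop("PC rows must match accessions")
  }
  use <- !is.na(y)
  if (sum(use) < 3) stop("fewer than 3 non-missing phenotypes")
  yu <- as.numeric(y[use])
  if (stats::var(yu) == 0) stop("phenotype is constant")
  D <- dosages(gm)[, use, drop = FALSE]
  Xcov <- cbind(`(Intercept)` = rep(1, sum(use)),
                if (!is.null(pcs)) pcs[use, , drop = FALSE])
  info <- snpInfo(gm)
  m <- nrow(gm)
  beta <- se <- stat <- p <- rep(NA_real_, m)
  nUsed <- rep(NA_integer_, m)
  skipped <- rep(NA_character_, m)
  minN <- ncol(Xcov) + 2L
  if (model == "mlm") {
    if (is.null(nullFit)) {
      if (is.null(kinship)) kinship <- kinshipMatrix(gm[, use])
      nullFit <- fitNullMlm(yu, Xcov, kinship)
    }
    w <- nullFit@lambda * nullFit@eigenvalues + 1
    sw <- sqrt(w)
    U <- nullFit@eigenvectors
    yw <- nullFit@rotatedY / sw
    Xw <- nullFit@rotatedX / sw
    for (j in seq_len(m)) {
      g <- D[j, ]
      nUsed[j] <- sum(!is.na(g))
      if (nUsed[j] < minN) { skipped[j] <- "too few accessions"; next }
      if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
      if (stats::var(g) == 0) { skipped[j] <- "monomorphic"; next }
      gw <- drop(crossprod(U, g)) / sw
      fit <- .olsLastCoef(cbind(Xw, gw), yw)
      if (is.null(fit)) { skipped[j] <- "collinear"; next }
      beta[j] <- fit$beta; se[j] <- fit$se; stat[j] <- fit$stat; p[j] <- fit$p
    }
  } else {
    for (j in seq_len(m)) {
      g <- D[j, ]
      ok <- !is.na(g)
      nUsed[j] <- sum(ok)
      if (nUsed[j] < minN) { skipped[j] <- "too few accessions"; next }
      gg <- g[ok]
      if (stats::var(gg) == 0) { skipped[j] <- "monomorphic"; next }
      fit <- .olsLastCoef(cbind(Xcov[ok, , drop = FALSE], gg), yu[ok])
      if (is.null(fit)) { skipped[j] <- "collinear"; next }
      beta[j] <- fit$beta; se[j] <- fit$se; stat[j] <- fit$stat; p[j] <- fit$p
    }
  }
  res <- S4Vectors::DataFrame(snp_id = info$snp_id, chrom = info$chrom,
                              pos = info$pos, beta = beta, se = se,
                              stat = stat, p = p, n_used = nUsed,
                              skipped = skipped)
  new("AssociationScan", environment = environment, model = model, results = res)
}

#' Association scans for every usable environment
#'
#' Runs [scanEnvironment] once per winter-survival environment. Environments
#' with fewer than `minN` non-missing phenotypes, or with no phenotypic
#' variation (non-differential survival), are excluded and reported --
#' mirroring the exclusion of non-differential field sites before GWAS.
#'
#' @param gm a [GenotypePanel-class].
#' @param pheno a [PhenotypePanel-class] with matching accessions.
#' @param model `"lm"` or `"mlm"`.
#' @param nPcs number of principal components used as covariates (default 3).
#' @param minN minimum non-missing phenotypes per environment (default 30).
#' @return named list of [AssociationScan-class]; excluded environments and
#'   their reasons are in `attr(x, "excluded")`.
#' @export
scanAll <- function(gm, pheno, model = c("lm", "mlm"), nPcs = 3, minN = 30) {
  model <- match.arg(model)
  stopifnot(is(gm, "GenotypePanel"), is(pheno, "PhenotypePanel"))
  acc <- accessionIds(gm)
  if (!all(acc %in% accessionIds(pheno)))
    stop("phenotype table does not cover the genotyped accessions")
  ws <- wsMatrix(pheno)[acc, , drop = FALSE]
  pcs <- pcScores(pcaStructure(gm, nPcs = nPcs))
  K <- if (model == "mlm") kinshipMatrix(gm) else NULL
  scans <- list()
  excluded <- character(0)
  for (e in colnames(ws)) {
    y <- ws[, e]
    if (sum(!is.na(y)) < minN) {
      excluded[e] <- sprintf("fewer than %d non-missing phenotypes", minN)
      next
    }
    if (stats::var(y, na.rm = TRUE) == 0) {
      excluded[e] <- "no differential survival (constant WS)"
      next
    }
    ok <- !is.na(y)
    Ke <- if (!is.null(K)) K[ok, ok] else NULL
    scans[[e]] <- scanEnvironment(gm, y, pcs = pcs, model = model,
                                  kinship = Ke, environment = e)
  }
  if (!length(scans)) stop("no usable environments")
  attr(scans, "excluded") <- excluded
  scans
}
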