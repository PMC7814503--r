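# small builders shared across test files

# GenotypePanel from a plain dosage matrix; SNPs named s1..sm on chromosome
# labels recycled over `chrom`, positions `pos` (NA = unplaced)
makePanel <- function(d, chrom = "1H", pos = seq_len(nrow(d)) * 1000L,
                      accessions = NULL) {
  d <- as.matrix(d)
  if (is.null(accessions))
    accessions <- if (!is.null(colnames(d))) colnames(d)
                  else paste0("a", seq_len(ncol(d)))
  info <- data.frame(snp_id = paste0("s", seq_len(nrow(d))),
                     chrom = rep_len(chrom, nrow(d)),
                     pos = as.integer(pos))
  GenotypePanel(d, info, accessions = accessions)
}

# brute-force OLS oracle: coefficient on the last column of X, via explicit
# normal equations and the t distribution (independent of the scan path)
olsOracle <- function(X, y) {
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  p <- ncol(X)
  se <- sqrt(s2 * XtXinv[p, p])
  tstat <- beta[p] / se
  list(beta = beta[p], se = se, stat = tstat,
       p = 2 * stats::pt(-abs(tstat), df))
}

# closed-form chi-square upper tail at even df = 2k:
# exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!
chisqSurvivalEvenDf <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# exhaustive BH oracle: the largest feasible rejection set, where a set of
# the i smallest p-values is feasible iff its maximum p is <= i*q/m
bhOracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  best <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) best <- i
  if (best == 0L) list(n = 0L, crit = NA_real_)
  else list(n = sum(p <= ps[best]), crit = ps[best])
}
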