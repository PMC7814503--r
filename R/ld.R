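#' @include AllClasses.R
NULL

#' Pairwise linkage disequilibrium (r2) within a chromosome
#'
#' r2 is the squared Pearson correlation of dosage vectors over accessions
#' non-missing at both SNPs. Pairs where either SNP is monomorphic on the
#' shared accessions are skipped (correlation undefined). Only physically
#' placed SNPs are used.
#'
#' @param gm a [GenotypePanel-class].
#' @param chrom chromosome label, e.g. `"5H"`.
#' @param maxDistance optional bp cap on pair distance.
#' @return data.frame with `snp1`, `snp2`, `distance` (bp), `r2`, one row per
#'   unordered pair.
#' @export
ldR2 <- function(gm, chrom, maxDistance = NULL) {
  stopifnot(is(gm, "GenotypePanel"))
  gm <- subsetPlaced(gm)
  sel <- snpInfo(gm)$chrom == chrom
  if (sum(sel) < 2) stop("need >= 2 placed SNPs on chromosome ", chrom)
  gm <- gm[sel, ]
  d <- dosages(gm)
  pos <- snpInfo(gm)$pos
  r <- suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs"))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(snp1 = rownames(d)[ut[, 1L]], snp2 = rownames(d)[ut[, 2L]],
                    distance = abs(pos[ut[, 2L]] - pos[ut[, 1L]]),
                    r2 = r[ut]^2, stringsAsFactors = FALSE)
  out <- out[!is.na(out$r2), , drop = FALSE]       # monomorphic pairs skipped
  if (!is.null(maxDistance)) out <- out[out$distance <= maxDistance, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample r2 among unlinked (inter-chromosomal) SNP pairs
#'
#' "Unlinked markers" are proxied by pairs on different chromosomes, the
#' standard convention; a random sample of such pairs calibrates the
#' critical r2 threshold for LD decay.
#'
#' @param gm a [GenotypePanel-class].
#' @param nPairs number of pairs to sample (default 50000).
#' @param seed integer seed for the pair sample.
#' @return numeric vector of r2 values (undefined pairs dropped).
#' @export
sampleUnlinkedR2 <- function(gm, nPairs = 50000, seed = 1L) {
  stopifnot(is(gm, "GenotypePanel"))
  gm <- subsetPlaced(gm)
  ch <- snpInfo(gm)$chrom
  if (length(unique(ch)) < 2) stop("need SNPs on >= 2 chromosomes")
  set.seed(seed)
  m <- nrow(gm)
  i <- sample.int(m, nPairs, replace = TRUE)
  j <- sample.int(m, nPairs, replace = TRUE)
  keep <- ch[i] != ch[j]
  i <- i[keep]; j <- j[keep]
  d <- dosages(gm)
  r2 <- vapply(seq_along(i), function(q) {
    suppressWarnings(stats::cor(d[i[q], ], d[j[q], ],
                                use = "pairwise.complete.obs"))^2
  }, 0)
  r2[!is.na(r2)]
}

#' Linkage-disequilibrium decay against an unlinked-marker threshold
#'
#' Fits a locally weighted regression (tricube weights, degree 1) of r2 on
#' physical distance, evaluates it on an even grid, and reports the smallest
#' grid distance at which the fitted curve first falls to the critical
#' threshold -- the empirical 99th percentile of r2 among unlinked pairs.
#'
#' @param pairs data.frame with `distance` and `r2` columns (within-
#'   chromosome pairs, as from [ldR2]; >= 100 pairs).
#' @param unlinkedR2 numeric vector of r2 for unlinked pairs (>= 100).
#' @param span locally weighted regression span (default 0.3).
#' @param gridN grid resolution (default 512).
#' @return an [LDProfile-class]. When the curve never reaches the threshold
#'   the profile reports "no decay within range" (`ldDecayDistance()` = NA).
#' @export
ldDecay <- function(pairs, unlinkedR2, span = 0.3, gridN = 512) {
  stopifnot(all(c("distance", "r2") %in% colnames(pairs)),
            nrow(pairs) >= 100, length(unlinkedR2) >= 100)
  stopifnot(all(pairs$r2 >= -1e-12 & pairs$r2 <= 1 + 1e-12))
  thr <- unname(stats::quantile(unlinkedR2, 0.99))
  grid <- seq(min(pairs$distance), max(pairs$distance), length.out = gridN)
  if (stats::var(pairs$r2) == 0) {                 # degenerate: constant curve
    fit <- rep(pairs$r2[1L], gridN)
  } else {
    lo <- stats::loess(r2 ~ distance, data = pairs, span = span, degree = 1,
                       family = "gaussian",
                       control = stats::loess.control(surface = "direct"))
    fit <- stats::predict(lo, newdata = data.frame(distance = grid))
  }
  hit <- which(fit <= thr)
  decayed <- length(hit) > 0
  new("LDProfile", pairs = pairs[, c("distance", "r2")],
      curve = data.frame(distance = grid, r2 = fit),
      unlinkedThreshold = thr,
      decayDistance = if (decayed) grid[hit[1L]] else NA_real_,
      decayed = decayed)
}
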