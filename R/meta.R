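#' @include AllClasses.R
NULL

#' Fisher's combined probability test
#'
#' Combines k independent p-values as \eqn{X^2 = -2 \sum_i \ln p_i}, referred
#' to a chi-square distribution with 2k degrees of freedom:
#' \eqn{p_{Fisher} = 1 - \Pr(\chi^2_{2k} \le X^2)}. With a single study the
#' combined p equals the input. Inputs below 1e-300 are clamped to keep the
#' logarithm finite.
#'
#' @param p numeric vector of p-values in (0, 1]; drop missing entries
#'   before calling.
#' @return list with `X2`, `pFisher` and `k`.
#' @export
fisherCombine <- function(p) {
  if (length(p) < 1) stop("empty p-value list")
  if (anyNA(p)) stop("missing p-values must be dropped before combining")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0,1]; floor zeros first")
  p <- pmax(p, 1e-300)
  k <- length(p)
  X2 <- -2 * sum(log(p))
  list(X2 = X2, pFisher = stats::pchisq(X2, df = 2 * k, lower.tail = FALSE),
       k = k)
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Sorts the m p-values ascending, finds the largest i with
#' \eqn{p_{(i)} \le i q / m}, and rejects every p at or below that critical
#' value (ties rejected together).
#'
#' @param p numeric vector of p-values in (0,1].
#' @param q FDR level in (0,1) (default 0.01).
#' @return list of class `FdrVerdict`: `q`, `nRejected`, `criticalP`
#'   (largest rejected p; NA when nothing is rejected),
#'   `thresholdMinusLog10`, and `rejected`, a logical vector aligned with
#'   the input.
#' @export
bhFdr <- function(p, q = 0.01) {
  stopifnot(q > 0, q < 1)
  if (!length(p)) {
    return(structure(list(q = q, nRejected = 0L, criticalP = NA_real_,
                          thresholdMinusLog10 = NA_real_, rejected = logical(0)),
                     class = "FdrVerdict"))
  }
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0,1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= seq_len(m) * q / m)
  if (!length(pass)) {
    crit <- NA_real_
    rejected <- rep(FALSE, m)
  } else {
    crit <- ps[max(pass)]
    rejected <- p <= crit
  }
  structure(list(q = q, nRejected = sum(rejected), criticalP = crit,
                 thresholdMinusLog10 = if (is.na(crit)) NA_real_ else -log10(crit),
                 rejected = rejected),
            class = "FdrVerdict")
}

#' @export
print.FdrVerdict <- function(x, ...) {
  cat(sprintf("BH-FDR verdict at q = %g: %d rejection(s)", x$q, x$nRejected))
  if (!is.na(x$criticalP))
    cat(sprintf(", critical p = %.3g (-log10 = %.2f)", x$criticalP,
                x$thresholdMinusLog10))
  cat("\n")
  invisible(x)
}

#' Fisher meta-analysis over per-environment association scans
#'
#' For every SNP, collects the valid per-environment p-values (k may vary by
#' SNP when some environments skipped it), applies [fisherCombine], and
#' controls the FDR over all scored SNPs with [bhFdr] at level `q`.
#' `envs_significant` counts, per SNP, the individual environments in which
#' the SNP passed that scan's own BH threshold at the same `q` -- the loci
#' significant in the meta-analysis but in few or no individual environments
#' are the gene-by-environment candidates.
#'
#' @param scans list of [AssociationScan-class] (one per environment).
#' @param q FDR level (default 0.01).
#' @return list with `meta`, a data.frame (snp_id, chrom, pos, k, X2,
#'   p_fisher, minus_log10_p, significant, envs_significant), and `verdict`,
#'   the [bhFdr] result over the combined p-values.
#' @export
metaScan <- function(scans, q = 0.01) {
  stopifnot(length(scans) >= 1)
  tabs <- lapply(scans, scanResults)
  allSnps <- unique(unlist(lapply(tabs, `[[`, "snp_id")))
  pmat <- matrix(NA_real_, nrow = length(allSnps), ncol = length(tabs),
                 dimnames = list(allSnps, names(tabs)))
  sigmat <- matrix(FALSE, nrow = length(allSnps), ncol = length(tabs),
                   dimnames = list(allSnps, names(tabs)))
  for (i in seq_along(tabs)) {
    t0 <- tabs[[i]]
    valid <- is.na(t0$skipped) & !is.na(t0$p)
    pmat[t0$snp_id[valid], i] <- t0$p[valid]
    v <- bhFdr(t0$p[valid], q)
    sigmat[t0$snp_id[valid], i] <- v$rejected
  }
  k <- rowSums(!is.na(pmat))
  scored <- k >= 1
  if (any(!scored))
    message(sum(!scored), " SNP(s) with no valid scan omitted from the meta-analysis")
  comb <- lapply(which(scored), function(i) fisherCombine(pmat[i, !is.na(pmat[i, ])]))
  X2 <- vapply(comb, `[[`, 0, "X2")
  pF <- pmax(vapply(comb, `[[`, 0, "pFisher"), 1e-300)
  verdict <- bhFdr(pF, q)
  ref <- do.call(rbind, lapply(tabs, function(t0)
    data.frame(snp_id = t0$snp_id, chrom = t0$chrom, pos = t0$pos,
               stringsAsFactors = FALSE)))
  ref <- ref[!duplicated(ref$snp_id), ]
  rownames(ref) <- ref$snp_id
  ids <- allSnps[scored]
  meta <- data.frame(snp_id = ids, chrom = ref[ids, "chrom"],
                     pos = ref[ids, "pos"], k = k[scored], X2 = X2,
                     p_fisher = pF, minus_log10_p = -log10(pF),
                     significant = verdict$rejected,
                     envs_significant = rowSums(sigmat)[scored],
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  list(meta = meta, verdict = verdict)
}
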