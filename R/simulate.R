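#' @include AllClasses.R
NULL

#' Specify a simulated winter-survival QTL
#'
#' @param effect additive effect, WS percentage points per alt allele.
#' @param envMask character vector of environment labels where the effect is
#'   active (non-empty).
#' @param snp optional SNP index into the simulated panel; when `NA` the
#'   simulator picks a well-polymorphic marker itself.
#' @return a list of class `QtlSpec`.
#' @export
qtlSpec <- function(effect, envMask, snp = NA_integer_) {
  stopifnot(is.finite(effect), length(envMask) >= 1)
  structure(list(snp = snp, effect = effect, envMask = as.character(envMask)),
            class = "QtlSpec")
}

#' Specify the two-locus epistatic architecture of the censored DTF trait
#'
#' The default mean table encodes a vernalization-style interaction between a
#' proxy VRN-H1 (winter allele dosage `a`) and a proxy VRN-H2 (intact-locus
#' dosage `b`): flowering is late (140 d) only when both loci carry at least
#' one functional allele, otherwise early (60 d) — a pure interaction that an
#' additive model cannot capture.
#'
#' @param meanTable 3 x 3 numeric matrix of DTF means indexed by dosages
#'   0..2 of the two loci (rows = locus 1, cols = locus 2).
#' @param noiseSd residual s.d. of DTF in days.
#' @param censor right-censor day; observations at or beyond it are recorded
#'   as `censor` with the censored flag set.
#' @return a list of class `EpistasisSpec`.
#' @export
epistasisSpec <- function(meanTable = NULL, noiseSd = 8, censor = 154) {
  if (is.null(meanTable)) {
    meanTable <- matrix(60, 3, 3)
    meanTable[2:3, 2:3] <- 140
  }
  stopifnot(identical(dim(meanTable), c(3L, 3L)), censor >= max(meanTable),
            noiseSd >= 0)
  structure(list(meanTable = meanTable, noiseSd = noiseSd, censor = censor),
            class = "EpistasisSpec")
}

#' Configuration of the synthetic panel generator
#'
#' Defaults emulate the real study panel: 882 accessions x 5,725 biallelic
#' SNPs on 7 chromosomes, two subpopulations in 0.6/0.4 proportion (the
#' 6-row/2-row split of 529 vs 350 accessions), Balding-Nichols divergence
#' 0.15, block LD, 10 winter-survival environments around a panel mean of
#' about 38%, and a censored days-to-flowering trait driven by a two-locus
#' interaction. The default QTL set mirrors the study's architecture: two
#' major loci active in 6/10 environments (the FR-H1/FR-H2 pattern), one in
#' 2/10, two in a single environment, and two weak loci active everywhere
#' that only a meta-analysis can see.
#'
#' @param nAccessions,nSnps,nChrom panel dimensions.
#' @param chromLength chromosome length in bp (barley-scale, 6e8).
#' @param subpopProportions two proportions summing to 1.
#' @param divergence Balding-Nichols F between the two subpopulations.
#' @param mafRange range the ancestral minor allele frequency is drawn from.
#' @param blockSize markers per LD block.
#' @param flipProb per-marker probability of flipping the block template
#'   haplotype (controls within-block r2, roughly (1-2f)^2).
#' @param missingRate fraction of genotype calls masked as missing.
#' @param environments environment labels (opaque codes).
#' @param intercepts per-environment WS intercepts (percent).
#' @param residSd per-environment residual s.d. of WS (percent).
#' @param wsQtls list of [qtlSpec] objects; `NULL` = the default architecture.
#' @param epistasis an [epistasisSpec].
#' @param seed integer seed fixing the full random stream.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(nAccessions = 882, nSnps = 5725, nChrom = 7,
                      chromLength = 6e8,
                      subpopProportions = c(0.6, 0.4), divergence = 0.15,
                      mafRange = c(0.05, 0.5), blockSize = 10, flipProb = 0.05,
                      missingRate = 0.02,
                      environments = c("MN-14", "MN-15", "OH-14", "OH-15",
                                       "AB-14", "AB-15", "DE-14", "ID-15",
                                       "UK-15", "ES-15"),
                      intercepts = NULL, residSd = NULL,
                      wsQtls = NULL, epistasis = epistasisSpec(), seed = 1L) {
  k <- length(environments)
  if (is.null(intercepts)) intercepts <- rep(35, k)
  if (is.null(residSd)) residSd <- rep(15, k)
  stopifnot(abs(sum(subpopProportions) - 1) < 1e-8,
            length(subpopProportions) == 2,
            divergence >= 0, all(residSd >= 0),
            length(intercepts) == k, length(residSd) == k,
            mafRange[1] > 0, mafRange[2] <= 0.5, blockSize >= 1,
            flipProb >= 0, flipProb <= 0.5, missingRate >= 0, missingRate < 1)
  if (is.null(wsQtls)) {
    six <- environments[seq_len(min(6, k))]
    wsQtls <- list(
      qtlSpec(10, six),                               # FR-H2-like major locus
      qtlSpec(8, six),                                # FR-H1-like major locus
      qtlSpec(6, environments[seq_len(min(2, k))]),   # VRN-H2-like, 2 envs
      qtlSpec(6, environments[k]),                    # single-environment loci
      qtlSpec(6, environments[k - 1]),
      qtlSpec(3, environments),                       # weak, everywhere:
      qtlSpec(3, environments))                       # meta-analysis only
  }
  labs <- unlist(lapply(wsQtls, `[[`, "envMask"))
  if (!all(labs %in% environments)) stop("QTL envMask labels must be environments")
  structure(list(nAccessions = nAccessions, nSnps = nSnps, nChrom = nChrom,
                 chromLength = chromLength,
                 subpopProportions = subpopProportions, divergence = divergence,
                 mafRange = mafRange, blockSize = blockSize, flipProb = flipProb,
                 missingRate = missingRate, environments = environments,
                 intercepts = intercepts, residSd = residSd, wsQtls = wsQtls,
                 epistasis = epistasis, seed = as.integer(seed)),
            class = "SimConfig")
}

# Balding-Nichols draw of subpopulation frequencies around ancestral q0.
.bnFreq <- function(q0, fst) {
  if (fst <= 0) return(q0)
  a <- q0 * (1 - fst) / fst
  b <- (1 - q0) * (1 - fst) / fst
  stats::rbeta(length(q0), a, b)
}

#' Simulate a structured genotype/phenotype panel with known ground truth
#'
#' Genotypes: SNPs are laid out in LD blocks along `nChrom` chromosomes. For
#' each block an ancestral template frequency is drawn (minor allele
#' frequency uniform in `mafRange`, random orientation), diverged per
#' subpopulation by a Balding-Nichols beta draw, and each gamete copies the
#' block template with per-marker flip probability `flipProb`; accession
#' dosage is the sum of two gametes. Winter survival in environment e is
#' `intercept_e + sum over active QTLs of effect * dosage + N(0, sd_e)`,
#' clipped to \[0,100\] (the clipped fraction is reported in the truth
#' object). DTF follows the 3 x 3 epistasis mean table at the planted locus
#' pair plus noise, right-censored at the censor day.
#'
#' @param cfg a [simConfig] object.
#' @return `list(genotypes = GenotypePanel, phenotypes = PhenotypePanel,
#'   truth = SimTruth)`; fully reproducible from `cfg$seed`.
#' @export
simulatePanel <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (length(cfg$wsQtls) + 2 > cfg$nSnps)
    stop("more causal SNPs requested than nSnps")
  set.seed(cfg$seed)
  n <- cfg$nAccessions; m <- cfg$nSnps
  # map: split SNPs over chromosomes, sorted positions
  chrom <- sort(rep_len(seq_len(cfg$nChrom), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i)
    sort(sample.int(cfg$chromLength, length(i)))), use.names = FALSE)
  chromLab <- paste0(chrom, "H")
  snpId <- sprintf("SNP_%s_%07d", chromLab, seq_len(m))
  # blocks are consecutive markers within a chromosome
  block <- unlist(lapply(split(seq_len(m), chrom), function(i)
    rep(seq_len(ceiling(length(i) / cfg$blockSize)), each = cfg$blockSize)[seq_along(i)]),
    use.names = FALSE)
  blockId <- paste(chrom, block)
  ublocks <- unique(blockId)
  nb <- length(ublocks)
  maf0 <- stats::runif(nb, cfg$mafRange[1], cfg$mafRange[2])
  q0 <- ifelse(stats::runif(nb) < 0.5, maf0, 1 - maf0)
  q1 <- .bnFreq(q0, cfg$divergence)
  q2 <- .bnFreq(q0, cfg$divergence)
  n1 <- round(n * cfg$subpopProportions[1]); n2 <- n - n1
  subpop <- rep(c(1L, 2L), c(n1, n2))
  geno <- matrix(0L, nrow = m, ncol = n)
  bidx <- match(blockId, ublocks)
  qAcc <- function(b) ifelse(subpop == 1L, q1[b], q2[b])
  for (b in seq_len(nb)) {
    mk <- which(bidx == b)
    # both gametes of an accession draw from its own subpopulation frequency
    z <- stats::rbinom(2 * n, 1, rep(qAcc(b), 2))
    E <- matrix(stats::rbinom(2L * n * length(mk), 1, cfg$flipProb),
                nrow = 2L * n)
    A <- (z + E) %% 2L                       # gametes x markers in block
    geno[mk, ] <- t(A[seq_len(n), , drop = FALSE] +
                    A[n + seq_len(n), , drop = FALSE])
  }
  acc <- sprintf("acc%04d", seq_len(n))
  # pick causal SNPs among well-polymorphic markers, one per LD block
  maf <- pmin(rowMeans(geno) / 2, 1 - rowMeans(geno) / 2)
  eligible <- which(maf >= 0.2)
  if (length(eligible) < length(cfg$wsQtls) + 2)
    eligible <- order(maf, decreasing = TRUE)[seq_len(length(cfg$wsQtls) + 2)]
  pickDistinctBlocks <- function(k, used) {
    out <- integer(0)
    pool <- sample(eligible)
    for (s in pool) {
      if (bidx[s] %in% used) next
      out <- c(out, s); used <- c(used, bidx[s])
      if (length(out) == k) break
    }
    if (length(out) < k) stop("not enough polymorphic blocks for causal SNPs")
    out
  }
  needPick <- vapply(cfg$wsQtls, function(q) is.na(q$snp), TRUE)
  usedBlocks <- bidx[stats::na.omit(vapply(cfg$wsQtls, function(q)
    as.integer(q$snp), 1L))]
  picked <- pickDistinctBlocks(sum(needPick) + 2L, usedBlocks)
  qtlSnp <- vapply(cfg$wsQtls, function(q) as.integer(q$snp), 1L)
  qtlSnp[needPick] <- picked[seq_len(sum(needPick))]
  epiSnp <- utils::tail(picked, 2L)
  # winter survival
  envs <- cfg$environments; k <- length(envs)
  ws <- matrix(NA_real_, n, k, dimnames = list(acc, envs))
  gval <- matrix(0, n, k)
  for (j in seq_along(cfg$wsQtls)) {
    active <- envs %in% cfg$wsQtls[[j]]$envMask
    gval[, active] <- gval[, active] +
      cfg$wsQtls[[j]]$effect * geno[qtlSnp[j], ]
  }
  h2 <- numeric(k)
  for (e in seq_len(k)) {
    raw <- cfg$intercepts[e] + gval[, e] + stats::rnorm(n, 0, cfg$residSd[e])
    h2[e] <- if (stats::var(raw) > 0) stats::var(gval[, e]) / stats::var(raw) else 0
    ws[, e] <- raw
  }
  clipped <- mean(ws < 0 | ws > 100)
  ws <- pmin(pmax(ws, 0), 100)
  # censored DTF from the epistasis table
  epi <- cfg$epistasis
  a <- geno[epiSnp[1], ]; b <- geno[epiSnp[2], ]
  mu <- epi$meanTable[cbind(a + 1L, b + 1L)]
  dtfRaw <- mu + stats::rnorm(n, 0, epi$noiseSd)
  censored <- dtfRaw >= epi$censor
  dtf <- pmax(1, round(pmin(dtfRaw, epi$censor)))
  # mask missing genotype calls
  if (cfg$missingRate > 0) {
    mask <- stats::runif(length(geno)) < cfg$missingRate
    geno[mask] <- NA_integer_
  }
  gp <- GenotypePanel(geno,
                      S4Vectors::DataFrame(snp_id = snpId, chrom = chromLab,
                                           pos = as.integer(pos),
                                           ref = "A", alt = "G"),
                      accessions = acc)
  pheno <- PhenotypePanel(acc, ws, dtf = dtf, dtfCensored = censored,
                          rowType = ifelse(subpop == 1L, "6", "2"),
                          meta = S4Vectors::DataFrame(subpop = subpop,
                                                      row.names = acc))
  truth <- new("SimTruth",
               qtl = data.frame(snp_id = snpId[qtlSnp],
                                effect = vapply(cfg$wsQtls, `[[`, 1, "effect"),
                                env_mask = vapply(cfg$wsQtls, function(q)
                                  paste(q$envMask, collapse = ","), ""),
                                stringsAsFactors = FALSE),
               envMasks = lapply(cfg$wsQtls, `[[`, "envMask"),
               epistaticPair = snpId[epiSnp],
               heritability = stats::setNames(h2, envs),
               clippedFraction = clipped)
  list(genotypes = gp, phenotypes = pheno, truth = truth)
}

#' Simulate a null p-value matrix
#'
#' i.i.d. Uniform(0,1) entries; the calibration harness for the
#' meta-analysis false-discovery-rate checks.
#'
#' @param k number of environments (columns).
#' @param m number of SNPs (rows).
#' @param seed integer seed.
#' @return an `m x k` numeric matrix, reproducible from `seed`.
#' @export
simulateNullPvalues <- function(k, m, seed = 1L) {
  stopifnot(k >= 1, m >= 1)
  set.seed(seed)
  matrix(stats::runif(m * k), nrow = m, ncol = k)
}
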