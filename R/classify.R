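#' @include AllClasses.R
NULL

#' Classify vernalization response from days to flowering
#'
#' Unvernalized plants flowering by `insensitiveMax` days (default 73) are
#' vernalization-insensitive; those not flowering before `sensitiveMin`
#' days (default 130) are sensitive; the rest are intermediate. Plants that
#' never flowered carry the censor value (default 154) and so classify as
#' sensitive. The three classes partition every attainable DTF exactly.
#'
#' @param dtf numeric days to flowering (NA allowed -> "unclassified").
#' @param insensitiveMax upper DTF bound of the insensitive class.
#' @param sensitiveMin lower DTF bound of the sensitive class.
#' @param censor censor day (only validated: `insensitiveMax < sensitiveMin
#'   <= censor`).
#' @return character vector in \{"insensitive", "intermediate", "sensitive",
#'   "unclassified"\}.
#' @export
classifyVernalization <- function(dtf, insensitiveMax = 73, sensitiveMin = 130,
                                  censor = 154) {
  stopifnot(insensitiveMax < sensitiveMin, sensitiveMin <= censor)
  out <- rep("unclassified", length(dtf))
  out[!is.na(dtf) & dtf <= insensitiveMax] <- "insensitive"
  out[!is.na(dtf) & dtf > insensitiveMax & dtf < sensitiveMin] <- "intermediate"
  out[!is.na(dtf) & dtf >= sensitiveMin] <- "sensitive"
  out
}

#' Derive VRN-H2 locus status from the three ZCCT gene presence flags
#'
#' The VRN-H2 complex locus comprises ZCCT-Ha, ZCCT-Hb and ZCCT-Hc. All
#' three deleted is a complete deletion (the loss-of-function state required
#' for facultative growth habit); all present is intact; any other known
#' combination is a partial deletion; any missing flag gives "missing".
#'
#' @param haPresent,hbPresent,hcPresent logical presence flags (NA allowed).
#' @return character vector in \{"intact", "partial_deletion",
#'   "complete_deletion", "missing"\}.
#' @export
callVrnH2 <- function(haPresent, hbPresent, hcPresent) {
  n <- length(haPresent)
  stopifnot(length(hbPresent) == n, length(hcPresent) == n)
  flags <- cbind(haPresent, hbPresent, hcPresent)
  out <- rep("partial_deletion", n)
  nPresent <- rowSums(flags)
  out[which(nPresent == 3)] <- "intact"
  out[which(nPresent == 0)] <- "complete_deletion"
  out[which(rowSums(is.na(flags)) > 0)] <- "missing"
  out
}

#' Growth-habit classification from locus calls and vernalization class
#'
#' The facultative ideotype requires all of: complete deletion of the
#' VRN-H2 complex locus, the winter VRN-H1 allele with the intact full
#' intron 1, the truncated (short-day sensitive) HvFT3 allele at PPD-H2,
#' and no vernalization requirement (insensitive DTF class). Winter habit is
#' an intact VRN-H2 with a sensitive DTF class. Decision table for the rest:
#' insensitive accessions missing any facultative key are "spring_like";
#' all remaining combinations (intermediate sensitivity, sensitive without
#' intact VRN-H2, or any missing field) are "unclassified".
#'
#' @param ppdH2 character, \{"intact_HvFT3", "truncated_HvFT3",
#'   "novel_deletion", "missing"\}.
#' @param vrnH1 character, \{"intact_intron1", "other", "missing"\}.
#' @param vrnH2 character status from [callVrnH2].
#' @param vernClass character from [classifyVernalization].
#' @return character vector in \{"facultative", "winter", "spring_like",
#'   "unclassified"\}.
#' @export
classifyFacultative <- function(ppdH2, vrnH1, vrnH2, vernClass) {
  n <- length(ppdH2)
  stopifnot(length(vrnH1) == n, length(vrnH2) == n, length(vernClass) == n)
  isMissing <- function(x) is.na(x) | x %in% c("missing", "unclassified")
  anyMissing <- isMissing(ppdH2) | isMissing(vrnH1) | isMissing(vrnH2) |
    isMissing(vernClass)
  out <- rep("unclassified", n)
  fac <- vrnH2 == "complete_deletion" & vrnH1 == "intact_intron1" &
    ppdH2 == "truncated_HvFT3" & vernClass == "insensitive"
  win <- vrnH2 == "intact" & vernClass == "sensitive"
  spr <- vernClass == "insensitive" & !fac
  out[!anyMissing & spr] <- "spring_like"
  out[!anyMissing & win] <- "winter"
  out[!anyMissing & fac] <- "facultative"
  out
}

#' Mean winter survival across environments
#'
#' Unweighted mean of the non-missing environment values per accession;
#' accessions missing more than half of the environments are flagged.
#'
#' @param pheno a [PhenotypePanel-class].
#' @return named numeric vector with attribute `flagged` (ids with > 50%
#'   missing environments).
#' @export
meanWs <- function(pheno) {
  ws <- wsMatrix(pheno)
  mu <- rowMeans(ws, na.rm = TRUE)
  mu[rowSums(!is.na(ws)) == 0] <- NA_real_
  flagged <- accessionIds(pheno)[rowMeans(is.na(ws)) > 0.5]
  structure(stats::setNames(mu, accessionIds(pheno)), flagged = flagged)
}

#' Select the top fraction of accessions by mean winter survival
#'
#' Ranks accessions by the unweighted mean of their non-missing WS values
#' and returns the top `floor(frac * n)` (so 882 accessions at 5% give 44).
#' Ties are broken by accession id, ascending, so the selection is
#' deterministic.
#'
#' @param pheno a [PhenotypePanel-class].
#' @param frac fraction in (0, 1] (default 0.05).
#' @return data.frame `accession`, `mean_ws`, sorted by decreasing mean;
#'   empty (with a warning) when `floor(frac * n)` is zero.
#' @export
selectTopFraction <- function(pheno, frac = 0.05) {
  if (frac <= 0 || frac > 1) stop("frac must lie in (0,1]")
  mu <- meanWs(pheno)
  mu <- mu[!is.na(mu)]
  if (!length(mu)) stop("no accession with a computable mean WS")
  size <- floor(frac * length(mu))
  if (size == 0) {
    warning("top-fraction size is zero at frac = ", frac)
    return(data.frame(accession = character(0), mean_ws = numeric(0)))
  }
  o <- order(-mu, names(mu))
  sel <- o[seq_len(size)]
  data.frame(accession = names(mu)[sel], mean_ws = unname(mu[sel]),
             stringsAsFactors = FALSE)
}

# round half up to integer (2.5 -> 3), matching the printed integer means;
# base round() uses banker's rounding and would differ on .5 values
.roundHalfUp <- function(x) floor(x + 0.5)

#' Per-clade mean winter survival
#'
#' Arithmetic mean of the member values per clade, rounded half-up to the
#' integer, plus the grand mean over all members.
#'
#' @param membership named character/factor: accession -> clade.
#' @param values named numeric: accession -> mean WS.
#' @return list with `clades` (data.frame `clade`, `n`, `mean_ws`) and
#'   `grandMean` (integer-rounded mean over all members).
#' @export
cladeSummary <- function(membership, values) {
  ids <- names(membership)
  if (is.null(ids)) stop("membership must be named by accession")
  if (!all(ids %in% names(values))) stop("values missing for some members")
  v <- values[ids]
  if (anyNA(v)) stop("every member needs a mean WS")
  agg <- tapply(v, as.character(membership), mean)
  cl <- data.frame(clade = names(agg),
                   n = as.integer(table(as.character(membership))[names(agg)]),
                   mean_ws = .roundHalfUp(unname(agg)),
                   stringsAsFactors = FALSE)
  list(clades = cl, grandMean = .roundHalfUp(mean(v)))
}

#' Check-based adjustment of a modified augmented design (Type II)
#'
#' Unreplicated entries sit in blocks anchored by a replicated primary check
#' and secondary checks. `method = "primary"` subtracts each block's
#' primary-check deviation from the grand primary-check mean;
#' `method = "secondary"` regresses check deviations on block mean check
#' deviations and removes the fitted block effect (a reconstruction of the
#' regression adjustment; the original design papers give the exact
#' formulas). Relative efficiency is the variance among replicated-check
#' deviations before adjustment over that after adjustment, computed on the
#' checks not used to build the adjustment; RE <= 1 means adjustment gives
#' no advantage and unadjusted values should be used (the decision rule
#' applied to the field data).
#'
#' @param layout data.frame with columns `block`, `entry`, `value`.
#' @param checks list with `primary` (one entry id) and `secondary`
#'   (character vector, possibly empty).
#' @param method `"none"`, `"primary"` or `"secondary"`.
#' @return list: `adjusted` (the layout with an `adjusted` column),
#'   `relativeEfficiency` (1 when degenerate: no check variance either way).
#' @export
adjustAugmented <- function(layout, checks, method = c("none", "primary", "secondary")) {
  method <- match.arg(method)
  stopifnot(all(c("block", "entry", "value") %in% colnames(layout)),
            is.numeric(layout$value))
  blocks <- unique(layout$block)
  isCheck <- layout$entry %in% c(checks$primary, checks$secondary)
  hasPrimary <- vapply(blocks, function(b)
    any(layout$block == b & layout$entry == checks$primary), TRUE)
  if (!all(hasPrimary))
    stop("block missing its primary check: ", paste(blocks[!hasPrimary], collapse = ", "))
  blockAdj <- stats::setNames(rep(0, length(blocks)), blocks)
  if (method == "primary") {
    pv <- vapply(blocks, function(b)
      mean(layout$value[layout$block == b & layout$entry == checks$primary]), 0)
    blockAdj[] <- pv - mean(pv)
  } else if (method == "secondary") {
    allChecks <- c(checks$primary, checks$secondary)
    dev <- do.call(rbind, lapply(allChecks, function(ck) {
      rows <- layout$entry == ck
      data.frame(block = layout$block[rows],
                 dev = layout$value[rows] - mean(layout$value[rows]))
    }))
    blockMean <- tapply(dev$dev, dev$block, mean)
    beta <- {
      x <- blockMean[as.character(dev$block)]
      if (stats::var(x) == 0) 0 else sum(x * dev$dev) / sum(x^2)
    }
    blockAdj[names(blockMean)] <- beta * blockMean
  }
  adjusted <- layout$value - blockAdj[as.character(layout$block)]
  # RE on checks not used for the adjustment (secondaries under "primary";
  # all checks otherwise)
  evalChecks <- if (method == "primary" && length(checks$secondary))
    checks$secondary else c(checks$primary, checks$secondary)
  devVar <- function(values) {
    d <- unlist(lapply(evalChecks, function(ck) {
      v <- values[layout$entry == ck]
      v - mean(v)
    }))
    if (length(d) < 2) 0 else stats::var(d)
  }
  v0 <- devVar(layout$value)
  v1 <- devVar(adjusted)
  re <- if (v0 == 0 && v1 == 0) 1 else if (method == "none") 1 else v0 / v1
  out <- layout
  out$adjusted <- adjusted
  list(adjusted = out, relativeEfficiency = re)
}

#' Candidate genes around significant SNPs
#'
#' For each placed SNP, reports the annotated genes overlapping it or lying
#' within `windowBp`, with a distance of 0 when the SNP falls inside the
#' gene and `min(|pos - start|, |pos - end|)` otherwise, sorted by distance.
#' Unplaced SNPs are skipped with a reason.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (the significant
#'   markers, e.g. rows of a [metaScan] table).
#' @param annotations a GRanges from [readGff3], or a data.frame with
#'   `gene_id`, `chrom`, `start`, `end`.
#' @param windowBp search window in bp (>= 0).
#' @return data.frame `snp_id`, `gene_id`, `distance`, `description`;
#'   skipped SNPs in `attr(x, "skipped")`.
#' @export
candidateGenes <- function(snps, annotations, windowBp = 300000) {
  stopifnot(windowBp >= 0)
  if (is(annotations, "GRanges")) {
    ann <- data.frame(gene_id = annotations$gene_id,
                      chrom = as.character(GenomicRanges::seqnames(annotations)),
                      start = GenomicRanges::start(annotations),
                      end = GenomicRanges::end(annotations),
                      description = if (!is.null(annotations$description))
                        as.character(annotations$description) else NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    ann <- as.data.frame(annotations)
    if (is.null(ann$description)) ann$description <- NA_character_
  }
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% colnames(ann)),
            all(ann$start <= ann$end))
  out <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(snps))) {
    id <- snps$snp_id[i]; pos <- snps$pos[i]; ch <- snps$chrom[i]
    if (is.na(pos)) { skipped[[id]] <- "unplaced SNP"; next }
    g <- ann[ann$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    inside <- pos >= g$start & pos <= g$end
    dist <- ifelse(inside, 0, pmin(abs(pos - g$start), abs(pos - g$end)))
    keep <- dist <= windowBp
    if (!any(keep)) next
    g <- g[keep, , drop = FALSE]; dist <- dist[keep]
    o <- order(dist, g$gene_id)
    out[[id]] <- data.frame(snp_id = id, gene_id = g$gene_id[o],
                            distance = dist[o], description = g$description[o],
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(0), gene_id = character(0),
               distance = numeric(0), description = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
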