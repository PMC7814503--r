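#' @include AllClasses.R
NULL

#' Accessors for panel objects
#'
#' `dosages()` returns the SNP x accession dosage matrix; `snpInfo()` the
#' per-SNP metadata; `accessionIds()` the accession ids; `snpMAF()` and
#' `snpMissingRate()` per-SNP minor allele frequency and missing-call rate;
#' `wsMatrix()` the accession x environment winter-survival matrix;
#' `environments()` the environment labels; `dtfValues()` days to flowering.
#'
#' @param x a [GenotypePanel-class] or [PhenotypePanel-class].
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))
#' @rdname accessors
#' @export
setGeneric("snpMAF", function(x) standardGeneric("snpMAF"))
#' @rdname accessors
#' @export
setGeneric("snpMissingRate", function(x) standardGeneric("snpMissingRate"))
#' @rdname accessors
#' @export
setGeneric("wsMatrix", function(x) standardGeneric("wsMatrix"))
#' @rdname accessors
#' @export
setGeneric("environments", function(x) standardGeneric("environments"))
#' @rdname accessors
#' @export
setGeneric("dtfValues", function(x) standardGeneric("dtfValues"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypePanel", function(x) SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypePanel", function(x) rowData(x))

#' @rdname accessors
#' @export
setMethod("accessionIds", "GenotypePanel", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("accessionIds", "PhenotypePanel", function(x) x@accession)

#' @rdname accessors
#' @export
setMethod("snpMAF", "GenotypePanel", function(x) {
  d <- dosages(x)
  p <- rowMeans(d, na.rm = TRUE) / 2            # alt allele frequency
  maf <- pmin(p, 1 - p)
  maf[rowSums(!is.na(d)) == 0] <- NA_real_      # all-missing: MAF undefined
  stats::setNames(maf, rownames(d))
})

#' @rdname accessors
#' @export
setMethod("snpMissingRate", "GenotypePanel", function(x) {
  d <- dosages(x)
  stats::setNames(rowMeans(is.na(d)), rownames(d))
})

#' @rdname accessors
#' @export
setMethod("wsMatrix", "PhenotypePanel", function(x) x@ws)

#' @rdname accessors
#' @export
setMethod("environments", "PhenotypePanel", function(x) colnames(x@ws))

#' @rdname accessors
#' @export
setMethod("dtfValues", "PhenotypePanel", function(x)
  stats::setNames(x@dtf, x@accession))

#' @rdname accessors
#' @export
setGeneric("rowTypes", function(x) standardGeneric("rowTypes"))

#' @rdname accessors
#' @export
setMethod("rowTypes", "PhenotypePanel", function(x)
  stats::setNames(x@rowType, x@accession))

setMethod("show", "GenotypePanel", function(object) {
  placed <- sum(!is.na(rowData(object)$pos))
  cat(sprintf("GenotypePanel: %d SNPs x %d accessions (%d placed)\n",
              nrow(object), ncol(object), placed))
  cat(sprintf("  chromosomes: %s\n",
              paste(sort(unique(rowData(object)$chrom)), collapse = ", ")))
})

setMethod("show", "PhenotypePanel", function(object) {
  cat(sprintf("PhenotypePanel: %d accessions, %d WS environments\n",
              length(object@accession), ncol(object@ws)))
  if (ncol(object@ws))
    cat(sprintf("  environments: %s\n", paste(colnames(object@ws), collapse = ", ")))
  cat(sprintf("  DTF scored for %d accessions (%d censored)\n",
              sum(!is.na(object@dtf)), sum(object@dtfCensored, na.rm = TRUE)))
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel: %d accessions, %d PCs", nrow(object@scores),
              ncol(object@scores)))
  if (length(object@varianceExplained))
    cat(sprintf(" (%.1f%% variance)", 100 * sum(object@varianceExplained)))
  cat(if (length(object@kinship)) ", kinship attached\n" else "\n")
})

setMethod("show", "AssociationScan", function(object) {
  r <- object@results
  cat(sprintf("AssociationScan [%s, %s]: %d SNPs tested, %d skipped\n",
              object@environment, object@model, sum(is.na(r$skipped)),
              sum(!is.na(r$skipped))))
})

setMethod("show", "LDProfile", function(object) {
  cat(sprintf("LDProfile: %d pairs, unlinked r2 threshold %.4f\n",
              nrow(object@pairs), object@unlinkedThreshold))
  if (isTRUE(object@decayed))
    cat(sprintf("  decay distance: %.0f bp\n", object@decayDistance))
  else cat("  no decay within observed range\n")
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d WS QTLs, epistatic DTF pair (%s)\n",
              nrow(object@qtl), paste(object@epistaticPair, collapse = ", ")))
})

#' Extract scan results as a data.frame
#'
#' @param scan an [AssociationScan-class].
#' @return base data.frame of per-SNP results.
#' @export
scanResults <- function(scan) {
  stopifnot(is(scan, "AssociationScan"))
  as.data.frame(scan@results)
}

#' @rdname scanResults
#' @param profile an [LDProfile-class].
#' @export
ldPairs <- function(profile) profile@pairs

#' @rdname scanResults
#' @export
ldCurve <- function(profile) profile@curve

#' @rdname scanResults
#' @export
ldDecayDistance <- function(profile)
  if (isTRUE(profile@decayed)) profile@decayDistance else NA_real_

#' @rdname scanResults
#' @param model a [StructureModel-class].
#' @export
pcScores <- function(model) model@scores

#' @rdname scanResults
#' @export
varianceExplained <- function(model) model@varianceExplained

#' @rdname scanResults
#' @export
kinshipOf <- function(model) model@kinship

#' @rdname scanResults
#' @param truth a [SimTruth-class].
#' @export
truthQtls <- function(truth) truth@qtl

#' @rdname scanResults
#' @export
truthEpistaticPair <- function(truth) truth@epistaticPair
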