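#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GenotypePanel: biallelic SNP dosages for an association panel
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay, `"dosage"`, with SNPs as rows and accessions as columns. Dosages are
#' counts of the alternate allele in \{0, 1, 2\}; missing calls are `NA` (never
#' 0, to avoid silent allele-frequency bias). Row metadata carries `snp_id`,
#' `chrom`, `pos` (1-based bp; `NA` for unplaced markers) and the `ref`/`alt`
#' alleles.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

.validGenotypePanel <- function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    ok <- is.na(d) | d %in% c(0, 1, 2)
    if (!all(ok))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  for (f in c("snp_id", "chrom", "pos"))
    if (!f %in% colnames(rd)) msg <- c(msg, sprintf("rowData column '%s' is required", f))
  if ("snp_id" %in% colnames(rd) && anyDuplicated(rd$snp_id))
    msg <- c(msg, "snp_id values must be unique")
  if (!is.null(colnames(object)) && anyDuplicated(colnames(object)))
    msg <- c(msg, "accession ids must be unique")
  if ("pos" %in% colnames(rd)) {
    p <- rd$pos
    if (any(!is.na(p) & p < 1)) msg <- c(msg, "placed positions must be >= 1")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypePanel", .validGenotypePanel)

#' Construct a GenotypePanel
#'
#' @param dosage numeric matrix, SNPs x accessions, values in \{0,1,2,NA\}.
#' @param snpInfo data.frame/DataFrame with columns `snp_id`, `chrom`, `pos`
#'   (integer bp or `NA` for unplaced) and optionally `ref`, `alt`.
#' @param accessions character vector of accession ids (defaults to the
#'   column names of `dosage`).
#' @return A [GenotypePanel-class] object.
#' @examples
#' d <- matrix(c(0, 2, 1, 0, 2, 2), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' gp <- GenotypePanel(d, data.frame(snp_id = c("s1", "s2"),
#'                                   chrom = "1H", pos = c(100L, 2000L)))
#' snpMAF(gp)
#' @export
GenotypePanel <- function(dosage, snpInfo, accessions = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  snpInfo <- as(snpInfo, "DataFrame")
  if (is.null(snpInfo$ref)) snpInfo$ref <- NA_character_
  if (is.null(snpInfo$alt)) snpInfo$alt <- NA_character_
  snpInfo$pos <- as.integer(snpInfo$pos)
  if (nrow(dosage) != nrow(snpInfo))
    stop("dosage rows and snpInfo rows disagree")
  if (is.null(accessions))
    accessions <- paste0("acc", seq_len(ncol(dosage)))
  rownames(dosage) <- snpInfo$snp_id
  colnames(dosage) <- accessions
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowData = snpInfo)
  new("GenotypePanel", se)
}

#' PhenotypePanel: multi-environment winter survival and flowering phenotypes
#'
#' Holds per-accession winter survival (WS, percent in \[0, 100\]) scored in
#' `k` environments, days to flowering (DTF) of unvernalized plants with a
#' right-censoring flag, the spike row type, and free-form metadata.
#'
#' @slot accession character, accession ids (unique).
#' @slot ws numeric matrix, accessions x environments, values in \[0,100\] or NA.
#' @slot dtf numeric, days to flowering (NA when unscored).
#' @slot dtfCensored logical, TRUE when the plant had not flowered at the
#'   censor day and `dtf` carries the censor value.
#' @slot rowType character, "2", "6" or NA.
#' @slot meta DataFrame of additional per-accession columns.
#' @export
setClass("PhenotypePanel",
  representation(accession = "character", ws = "matrix", dtf = "numeric",
                 dtfCensored = "logical", rowType = "character",
                 meta = "DataFrame"))

setValidity("PhenotypePanel", function(object) {
  msg <- NULL
  n <- length(object@accession)
  if (anyDuplicated(object@accession)) msg <- c(msg, "accession ids must be unique")
  if (nrow(object@ws) != n) msg <- c(msg, "ws rows must match accessions")
  w <- object@ws
  if (any(!is.na(w) & (w < 0 | w > 100))) msg <- c(msg, "WS values must lie in [0,100]")
  if (length(object@dtf) != n) msg <- c(msg, "dtf length must match accessions")
  if (any(!is.na(object@dtf) & object@dtf < 1)) msg <- c(msg, "dtf must be >= 1")
  if (length(object@dtfCensored) != n) msg <- c(msg, "dtfCensored length must match accessions")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PhenotypePanel
#'
#' @param accession character accession ids.
#' @param ws numeric matrix (accessions x environments) of winter survival
#'   percentages; column names are environment labels (opaque codes such as
#'   "AB-14").
#' @param dtf numeric days to flowering (NA allowed).
#' @param dtfCensored logical censoring flags (default all FALSE).
#' @param rowType character row type per accession ("2", "6", NA).
#' @param meta data.frame of extra columns (contributor, origin, clade, ...).
#' @return A [PhenotypePanel-class] object.
#' @export
PhenotypePanel <- function(accession, ws, dtf = rep(NA_real_, length(accession)),
                           dtfCensored = rep(FALSE, length(accession)),
                           rowType = rep(NA_character_, length(accession)),
                           meta = S4Vectors::DataFrame(row.names = accession)) {
  ws <- as.matrix(ws)
  rownames(ws) <- accession
  new("PhenotypePanel", accession = as.character(accession), ws = ws,
      dtf = as.numeric(dtf), dtfCensored = as.logical(dtfCensored),
      rowType = as.character(rowType), meta = as(meta, "DataFrame"))
}

#' StructureModel: principal components and kinship of a panel
#'
#' @slot scores numeric matrix, accessions x PCs.
#' @slot varianceExplained numeric, fraction of genotypic variance per PC.
#' @slot kinship numeric matrix, accessions x accessions (may be 0 x 0 when
#'   only PCs were computed).
#' @export
setClass("StructureModel",
  representation(scores = "matrix", varianceExplained = "numeric",
                 kinship = "matrix"))

setValidity("StructureModel", function(object) {
  msg <- NULL
  v <- object@varianceExplained
  if (length(v) && (any(v < -1e-12 | v > 1 + 1e-12) || is.unsorted(rev(v), strictly = FALSE)))
    msg <- c(msg, "varianceExplained must be non-increasing fractions in [0,1]")
  k <- object@kinship
  if (length(k)) {
    if (!isSymmetric(unname(k), tol = 1e-8)) msg <- c(msg, "kinship must be symmetric")
    if (any(!is.finite(k))) msg <- c(msg, "kinship entries must be finite")
  }
  if (is.null(msg)) TRUE else msg
})

#' AssociationScan: per-environment single-marker scan results
#'
#' @slot environment character scalar, the environment label.
#' @slot model character scalar, "lm" or "mlm".
#' @slot results DataFrame with one row per filtered SNP: `snp_id`, `chrom`,
#'   `pos`, `beta`, `se`, `stat`, `p`, `n_used`, `skipped` (NA or the reason a
#'   SNP produced no test).
#' @export
setClass("AssociationScan",
  representation(environment = "character", model = "character",
                 results = "DataFrame"))

setValidity("AssociationScan", function(object) {
  msg <- NULL
  r <- object@results
  need <- c("snp_id", "chrom", "pos", "beta", "se", "stat", "p", "n_used", "skipped")
  miss <- setdiff(need, colnames(r))
  if (length(miss)) msg <- c(msg, paste("missing result columns:", paste(miss, collapse = ", ")))
  if ("p" %in% colnames(r)) {
    p <- r$p
    if (any(!is.na(p) & (p <= 0 | p > 1))) msg <- c(msg, "p-values must lie in (0,1]")
  }
  if (!object@model %in% c("lm", "mlm")) msg <- c(msg, "model must be 'lm' or 'mlm'")
  if (is.null(msg)) TRUE else msg
})

#' NullModelFit: one-time variance-component fit for the P3D mixed model
#'
#' Stores the REML estimate of the genetic-to-residual variance ratio
#' \eqn{\lambda = \sigma^2_g / \sigma^2_e} together with the kinship
#' eigen-decomposition and rotated covariates, so that every marker test can
#' reuse them (P3D/EMMAX approximation).
#'
#' @slot lambda numeric, variance ratio (clamped to \[1e-6, 1e6\]).
#' @slot logLik numeric, restricted log-likelihood at the optimum.
#' @slot eigenvalues numeric, kinship eigenvalues.
#' @slot eigenvectors matrix, kinship eigenvectors (columns).
#' @slot rotatedY numeric, eigenbasis-rotated phenotype.
#' @slot rotatedX matrix, eigenbasis-rotated covariates (incl. intercept).
#' @export
setClass("NullModelFit",
  representation(lambda = "numeric", logLik = "numeric", eigenvalues = "numeric",
                 eigenvectors = "matrix", rotatedY = "numeric", rotatedX = "matrix"))

#' LDProfile: linkage-disequilibrium decay summary
#'
#' @slot pairs data.frame with `distance` (bp) and `r2` for within-chromosome
#'   SNP pairs.
#' @slot curve data.frame with the locally weighted regression fit (`distance`,
#'   `r2`) on an even grid.
#' @slot unlinkedThreshold numeric, 99th percentile of r2 among unlinked
#'   (inter-chromosomal) pairs.
#' @slot decayDistance numeric, smallest grid distance at which the fitted
#'   curve first falls to the threshold; NA when it never does.
#' @slot decayed logical, FALSE when the curve never reaches the threshold
#'   within the observed range.
#' @export
setClass("LDProfile",
  representation(pairs = "data.frame", curve = "data.frame",
                 unlinkedThreshold = "numeric", decayDistance = "numeric",
                 decayed = "logical"))

#' SimTruth: ground truth emitted by the synthetic-panel generator
#'
#' @slot qtl data.frame: `snp_id`, `effect` (WS percent per alt allele) and a
#'   comma-separated `env_mask` of active environments.
#' @slot envMasks list of character vectors, active environments per QTL.
#' @slot epistaticPair character, the two SNP ids driving the censored DTF
#'   trait (proxy VRN-H1 / VRN-H2).
#' @slot heritability numeric, realized per-environment heritability of WS.
#' @slot clippedFraction numeric, fraction of WS values clipped into [0,100].
#' @export
setClass("SimTruth",
  representation(qtl = "data.frame", envMasks = "list", epistaticPair = "character",
                 heritability = "numeric", clippedFraction = "numeric"))
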