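#' @include AllClasses.R
NULL

# Tabular genotype dialect mirrors the supplementary-table shape: SNPs as
# rows, accessions as columns; columns 1-4 are snp_id, chrom, pos, alleles.
# pos is an integer or the literal "unplaced"; missing calls are NA.

#' Read a genotype matrix from a tabular file or a VCF
#'
#' The tabular dialect has SNPs as rows and accessions as columns, with a
#' header row of accession ids and fixed leading columns `snp_id`, `chrom`,
#' `pos` (integer bp or `"unplaced"`) and `alleles` (`"REF/ALT"`). VCF input
#' is restricted to biallelic SNP records; multi-allelic or non-SNP records
#' are skipped and the skip count stored in `metadata(x)$skipped_records`.
#' Heterozygous calls are coded 1 (alt-allele dosage).
#'
#' @param path file to read.
#' @param format `"table"` or `"vcf"`.
#' @return A [GenotypePanel-class]; SNP order is the file order.
#' @export
readGenotypes <- function(path, format = c("table", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "table") .readGenotypesTable(path) else .readGenotypesVcf(path)
}

.readGenotypesTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  need <- c("snp_id", "chrom", "pos", "alleles")
  if (!identical(colnames(tab)[seq_len(4)], need))
    stop("malformed header at line 1: expected leading columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(tab$snp_id))
    stop("duplicate snp_id: ", tab$snp_id[duplicated(tab$snp_id)][1L])
  acc <- colnames(tab)[-seq_len(4)]
  calls <- as.matrix(tab[, -seq_len(4), drop = FALSE])
  d <- suppressWarnings(matrix(as.numeric(calls), nrow = nrow(tab)))
  bad <- !is.na(d) & !d %in% c(0, 1, 2)
  if (any(bad)) stop("genotype codes must be 0/1/2/NA")
  pos <- suppressWarnings(as.integer(tab$pos))   # "unplaced" -> NA
  al <- strsplit(tab$alleles, "/", fixed = TRUE)
  info <- S4Vectors::DataFrame(
    snp_id = tab$snp_id, chrom = tab$chrom, pos = pos,
    ref = vapply(al, function(a) a[1L] %||% NA_character_, ""),
    alt = vapply(al, function(a) if (length(a) > 1) a[2L] else NA_character_, ""))
  GenotypePanel(d, info, accessions = acc)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

.readGenotypesVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altL)
  alt1 <- rep(NA_character_, length(nAlt))
  alt1[nAlt >= 1] <- as.character(unlist(altL))[cumsum(nAlt)[nAlt >= 1] - 0]
  # keep biallelic SNPs only: single one-base ALT, one-base REF
  keep <- nAlt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  nSkipped <- sum(!keep)
  if (nSkipped) message(nSkipped, " multi-allelic/non-SNP record(s) skipped")
  vcf <- vcf[keep]
  ids <- names(SummarizedExperiment::rowRanges(vcf))
  if (anyDuplicated(ids)) stop("duplicate snp_id: ", ids[duplicated(ids)][1L])
  gt <- VariantAnnotation::geno(vcf)$GT
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0")] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% c("1/1", "1")] <- 2
    out
  }
  d <- matrix(code(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  gr <- SummarizedExperiment::rowRanges(vcf)
  info <- S4Vectors::DataFrame(
    snp_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(VariantAnnotation::alt(vcf))))
  gp <- GenotypePanel(d, info, accessions = colnames(gt))
  metadata(gp)$skipped_records <- nSkipped
  gp
}

#' Write a genotype matrix in the tabular dialect
#'
#' @param gm a [GenotypePanel-class].
#' @param path output file.
#' @return `path`, invisibly. `readGenotypes(path)` recovers `gm`.
#' @export
writeGenotypes <- function(gm, path) {
  info <- snpInfo(gm)
  pos <- ifelse(is.na(info$pos), "unplaced", as.character(info$pos))
  alleles <- ifelse(is.na(info$ref) | is.na(info$alt), "N/N",
                    paste0(info$ref, "/", info$alt))
  tab <- data.frame(snp_id = info$snp_id, chrom = info$chrom, pos = pos,
                    alleles = alleles, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(dosages(gm), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a panel to physically placed SNPs
#'
#' Keeps only SNPs with an assigned chromosome position; required before any
#' distance-based analysis (LD, Manhattan output).
#'
#' @param gm a [GenotypePanel-class].
#' @return A [GenotypePanel-class] (possibly with zero SNPs).
#' @export
subsetPlaced <- function(gm) {
  stopifnot(is(gm, "GenotypePanel"))
  gm[!is.na(snpInfo(gm)$pos), ]
}

#' Quality-filter a genotype matrix
#'
#' Retains SNPs whose missing-call rate is at most `maxMissing` and whose
#' minor allele frequency, computed on non-missing calls as
#' \eqn{\min(p, 1-p)} of the alt-allele frequency, is at least `minMaf`.
#' The defaults match the standard array-data filter (drop SNPs with >20%
#' missing data or MAF < 0.05). SNPs with all calls missing are always
#' removed. Accessions are never dropped. The filter is idempotent.
#'
#' @param gm a [GenotypePanel-class].
#' @param maxMissing maximum tolerated missing-call fraction (default 0.20).
#' @param minMaf minimum minor allele frequency (default 0.05).
#' @return The filtered [GenotypePanel-class].
#' @export
filterGenotypes <- function(gm, maxMissing = 0.20, minMaf = 0.05) {
  stopifnot(is(gm, "GenotypePanel"),
            maxMissing >= 0, maxMissing <= 1, minMaf >= 0, minMaf <= 0.5)
  maf <- snpMAF(gm)
  miss <- snpMissingRate(gm)
  keep <- !is.na(maf) & miss <= maxMissing & maf >= minMaf
  gm[keep, ]
}

#' Read a multi-environment phenotype table
#'
#' One CSV row per accession. Winter-survival environment columns are
#' auto-detected by prefix: a column named `<wsPrefix><label>` (default
#' prefix `"WS_"`) becomes environment `<label>`; labels are opaque codes
#' such as `"AB-14"`. Recognised optional columns: `dtf`, `dtf_censored`
#' (logical or 0/1), `row_type`; all remaining columns are kept as metadata.
#'
#' @param path CSV file.
#' @param wsPrefix prefix marking winter-survival columns.
#' @param accessionCol name of the accession-id column.
#' @return A [PhenotypePanel-class].
#' @export
readPhenotypes <- function(path, wsPrefix = "WS_", accessionCol = "accession") {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!accessionCol %in% colnames(tab))
    stop("missing accession column '", accessionCol, "'")
  wsCols <- grep(paste0("^", wsPrefix), colnames(tab), value = TRUE)
  ws <- as.matrix(tab[, wsCols, drop = FALSE])
  storage.mode(ws) <- "double"
  colnames(ws) <- sub(paste0("^", wsPrefix), "", wsCols)
  if (any(!is.na(ws) & (ws < 0 | ws > 100)))
    stop("WS values outside [0,100]")
  dtf <- if ("dtf" %in% colnames(tab)) as.numeric(tab$dtf) else rep(NA_real_, nrow(tab))
  cens <- if ("dtf_censored" %in% colnames(tab)) as.logical(tab$dtf_censored)
          else rep(FALSE, nrow(tab))
  rt <- if ("row_type" %in% colnames(tab)) as.character(tab$row_type)
        else rep(NA_character_, nrow(tab))
  metaCols <- setdiff(colnames(tab), c(accessionCol, wsCols, "dtf", "dtf_censored", "row_type"))
  PhenotypePanel(tab[[accessionCol]], ws, dtf = dtf, dtfCensored = cens,
                 rowType = rt,
                 meta = S4Vectors::DataFrame(tab[, metaCols, drop = FALSE]))
}

#' Write a phenotype table (inverse of [readPhenotypes])
#'
#' @param pheno a [PhenotypePanel-class].
#' @param path output CSV.
#' @param wsPrefix prefix for environment columns.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(pheno, path, wsPrefix = "WS_") {
  ws <- wsMatrix(pheno)
  out <- data.frame(accession = accessionIds(pheno), check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(ws)) {
    wsd <- as.data.frame(ws, check.names = FALSE)
    colnames(wsd) <- paste0(wsPrefix, colnames(ws))
    out <- cbind(out, wsd)
  }
  out$dtf <- pheno@dtf
  out$dtf_censored <- pheno@dtfCensored
  out$row_type <- pheno@rowType
  if (ncol(pheno@meta)) out <- cbind(out, as.data.frame(pheno@meta))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Keeps records of type `gene` (all records when none is typed `gene`) with
#' 1-based inclusive coordinates, the same convention as SNP positions.
#'
#' @param path GFF3 file.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `description`.
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% colnames(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(id)) stop("GFF3 gene records need an ID or Name attribute")
  if (anyDuplicated(id))
    stop("duplicate gene_id: ", id[duplicated(id)][1L])
  S4Vectors::mcols(gr)$gene_id <- as.character(id)
  if (is.null(gr$description)) S4Vectors::mcols(gr)$description <- NA_character_
  gr
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over [ape::write.tree] and [ape::read.tree]; output carries
#' branch lengths and is terminated by `";"`.
#'
#' @param tree an [ape::phylo] tree.
#' @param path optional file; when `NULL`, the Newick string is returned.
#' @return `writeNewick`: the Newick string (invisibly when written to file);
#'   `readNewick`: a `phylo`.
#' @export
writeNewick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
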