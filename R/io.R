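#' Read and write pedigree TSV
#'
#' Tab-separated columns id, sire, dam, sex, cohort; \code{"0"} denotes an
#' unknown parent.
#'
#' @param path file path
#' @return [readPedigree()]: a [Pedigree-class]
#' @export
readPedigree <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(d)))
    stop("pedigree file needs columns id, sire, dam")
  Pedigree(id = d$id, sire = d$sire, dam = d$dam,
           sex = if ("sex" %in% names(d)) d$sex else NULL,
           cohort = if ("cohort" %in% names(d)) as.integer(d$cohort) else NULL)
}

#' @rdname readPedigree
#' @param pedigree a [Pedigree-class]
#' @export
writePedigree <- function(pedigree, path) {
  d <- data.frame(id = pedigree@id,
                  sire = ifelse(is.na(pedigree@sire), "0", pedigree@sire),
                  dam = ifelse(is.na(pedigree@dam), "0", pedigree@dam),
                  sex = pedigree@sex, cohort = pedigree@cohort)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genotype dosage TSV
#'
#' Rows are individuals (first column \code{id}), remaining columns are SNP
#' ids with entries 0/1/2/NA.
#'
#' @param path file path
#' @return [readDosage()]: a [GenotypeData-class]
#' @export
readDosage <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  stopifnot("id" %in% names(d))
  m <- as.matrix(d[setdiff(names(d), "id")])
  rownames(m) <- d$id
  GenotypeData(m)
}

#' @rdname readDosage
#' @param genotypes a [GenotypeData-class]
#' @export
writeDosage <- function(genotypes, path) {
  d <- data.frame(id = rownames(genotypes@counts),
                  genotypes@counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write relationship matrices as GRM text triplets
#'
#' The triplet format used by the common GRM tooling: one row per pair
#' (lower triangle including the diagonal) with 1-based indices i >= j, the
#' number of markers used (0 for a pedigree matrix), and the value, plus a
#' companion \code{.id} file with one individual per line (family and
#' individual id columns).
#'
#' @param path path of the triplet file; the id file is \code{paste0(path,
#'   ".id")} unless given
#' @param idPath optional explicit id-file path
#' @return [readGRM()]: a [RelationshipMatrix-class]
#' @export
readGRM <- function(path, idPath = paste0(path, ".id"),
                    kind = c("genomic_G", "pedigree_A")) {
  kind <- match.arg(kind)
  ids <- utils::read.delim(idPath, header = FALSE,
                           colClasses = "character")[[2L]]
  tr <- utils::read.delim(path, header = FALSE)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  M[cbind(tr[[1L]], tr[[2L]])] <- tr[[4L]]
  M[cbind(tr[[2L]], tr[[1L]])] <- tr[[4L]]
  new("RelationshipMatrix", values = M, kind = kind)
}

#' @rdname readGRM
#' @param K a [RelationshipMatrix-class]
#' @param nMarkers marker count recorded per pair (0 for pedigree matrices)
#' @param kind matrix kind when reading
#' @export
writeGRM <- function(K, path, idPath = paste0(path, ".id"),
                     nMarkers = 0L) {
  v <- relValues(K)
  lt <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  tr <- data.frame(i = lt[, 1L], j = lt[, 2L], n = nMarkers,
                   value = v[lt])
  utils::write.table(tr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(ids(K), ids(K)), idPath, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write relationship matrices as square TSV
#'
#' @param path file path
#' @param kind matrix kind when reading
#' @return [readRelationshipTSV()]: a [RelationshipMatrix-class]
#' @export
readRelationshipTSV <- function(path, kind = c("genomic_G", "pedigree_A")) {
  kind <- match.arg(kind)
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[setdiff(names(d), "id")])
  rownames(m) <- d$id
  new("RelationshipMatrix", values = m, kind = kind)
}

#' @rdname readRelationshipTSV
#' @param K a [RelationshipMatrix-class]
#' @export
writeRelationshipTSV <- function(K, path) {
  v <- relValues(K)
  d <- data.frame(id = rownames(v), v, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated genotypes as an (uncompressed) VCF
#'
#' Minimal VCF 4.2 with unphased GT entries; one record per SNP on a dummy
#' chromosome, REF/ALT fixed to A/B so the coded allele (counted in the
#' dosage matrix) is the ALT allele. Missing genotypes become \code{./.}.
#'
#' @param genotypes a [GenotypeData-class]
#' @param path output path (plain text)
#' @export
writeGenotypeVCF <- function(genotypes, path) {
  x <- genotypes@counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gherit-simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(x)), collapse = "\t")),
             con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(x))) {
    gt <- ifelse(is.na(x[, j]), "./.", gtmap[x[, j] + 1L])
    writeLines(paste(c("1", j, colnames(x)[j], "A", "B", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses unphased GT fields into ALT-allele counts. Records that are not
#' biallelic SNVs are skipped and counted in the returned metadata.
#'
#' @param path VCF path (plain or bgzipped)
#' @return a [GenotypeData-class]; \code{x@metadata$skippedNonBiallelic}
#'   holds the number of skipped records
#' @export
readGenotypeVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  ref <- vcfR::getREF(v)
  biallelic <- !grepl(",", alt) & nchar(alt) == 1L & nchar(ref) == 1L
  nSkipped <- sum(!biallelic)
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v[biallelic, ], element = "GT")
  counts <- matrix(NA_integer_, ncol(gt), nrow(gt),
                   dimnames = list(colnames(gt), rownames(gt)))
  clean <- gsub("\\|", "/", t(gt))
  counts[clean %in% c("0/0")] <- 0L
  counts[clean %in% c("0/1", "1/0")] <- 1L
  counts[clean %in% c("1/1")] <- 2L
  GenotypeData(counts, metadata = list(skippedNonBiallelic = nSkipped))
}

#' Write phenotype/covariate tables and posterior outputs
#'
#' Small TSV writers shared by the pipeline: phenotypes, coefficient
#' tables, residuals, posterior samples and heritability summaries.
#'
#' @param x data.frame (or object with an obvious table)
#' @param path output path
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) utils::read.delim(path, check.names = FALSE)
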