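#' Assemble an aligned case-control cohort
#'
#' Bundles the four tables every pipeline stage consumes: a fixed genotype
#' matrix (minor-allele dosages), per-SNP annotation, per-individual
#' covariates, and one or more binary trait replicates simulated or observed
#' on the same individuals. All components are checked for id agreement and
#' reordered to the genotype matrix's individual and SNP order.
#'
#' @param genotypes integer matrix, individuals x SNPs, values 0/1/2 or NA
#'   (missing); rownames are individual ids, colnames SNP ids.
#' @param annotation data.frame with columns \code{snp_id}, \code{gene},
#'   \code{nonsynonymous} (logical or 0/1), and optionally \code{chrom},
#'   \code{pos}, \code{true_maf}.
#' @param covariates data.frame with columns \code{id}, \code{age},
#'   \code{sex}, \code{smoking}.
#' @param phenotypes integer matrix, individuals x replicates, values 0/1;
#'   rownames are individual ids, colnames replicate names.
#' @return An object of class \code{cohort}: a list with elements
#'   \code{genotypes}, \code{annotation}, \code{covariates},
#'   \code{phenotypes}.
#' @export
cohort <- function(genotypes, annotation, covariates, phenotypes) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)),
            !is.null(colnames(genotypes)))
  bad <- genotypes[!is.na(genotypes)]
  if (!all(bad %in% 0:2))
    stop("genotype dosages must be 0, 1, 2 or NA")
  req <- c("snp_id", "gene", "nonsynonymous")
  if (!all(req %in% names(annotation)))
    stop("annotation needs columns: ", paste(req, collapse = ", "))
  annotation$nonsynonymous <- as.logical(annotation$nonsynonymous)

  ids <- rownames(genotypes)
  snps <- colnames(genotypes)
  .check_ids(snps, annotation$snp_id, "genotype columns", "annotation snp_id")
  .check_ids(ids, covariates$id, "genotype rows", "covariate ids")
  .check_ids(ids, rownames(phenotypes), "genotype rows", "phenotype rows")
  if (anyDuplicated(snps)) stop("duplicated SNP ids")
  if (anyDuplicated(ids)) stop("duplicated individual ids")

  annotation <- annotation[match(snps, annotation$snp_id), , drop = FALSE]
  rownames(annotation) <- NULL
  covariates <- covariates[match(ids, covariates$id), , drop = FALSE]
  rownames(covariates) <- NULL
  phenotypes <- phenotypes[match(ids, rownames(phenotypes)), , drop = FALSE]
  storage.mode(phenotypes) <- "integer"
  if (!all(phenotypes %in% 0:1)) stop("phenotypes must be 0/1")
  ok <- colSums(phenotypes) > 0 & colSums(phenotypes) < nrow(phenotypes)
  if (!all(ok))
    stop("replicates without both classes: ",
         paste(colnames(phenotypes)[!ok], collapse = ", "))

  structure(list(genotypes = genotypes, annotation = annotation,
                 covariates = covariates, phenotypes = phenotypes),
            class = "cohort")
}

.check_ids <- function(a, b, la, lb) {
  extra <- setdiff(a, b); missing <- setdiff(b, a)
  if (length(extra) || length(missing))
    stop(sprintf("id mismatch between %s and %s; only in %s: %s; only in %s: %s",
                 la, lb, la, paste(utils::head(extra, 5), collapse = ","),
                 lb, paste(utils::head(missing, 5), collapse = ",")))
  invisible(TRUE)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals, %d SNPs in %d genes, %d trait replicate(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$annotation$gene)), ncol(x$phenotypes)))
  cat(sprintf("  nonsynonymous SNPs: %d; case fraction (replicate 1): %.3f\n",
              sum(x$annotation$nonsynonymous),
              mean(x$phenotypes[, 1])))
  invisible(x)
}

#' Folded minor allele frequency per SNP
#'
#' Computes the sample MAF of every SNP over a subset of individuals:
#' \code{min(c, 2n' - c) / (2n')} where \code{c} is the summed dosage over
#' the \code{n'} subset individuals with a non-missing genotype. Folding
#' guarantees MAF in [0, 0.5]; monomorphic SNPs return 0. SNPs missing in
#' every subset individual return NA and must be excluded downstream.
#'
#' @param genotypes individuals x SNPs dosage matrix (0/1/2/NA).
#' @param subset optional individual ids or indices; default all rows.
#' @return Named numeric vector of per-SNP MAFs in [0, 0.5] (NA where
#'   undefined).
#' @export
compute_sample_maf <- function(genotypes, subset = NULL) {
  g <- if (is.null(subset)) genotypes else genotypes[subset, , drop = FALSE]
  if (nrow(g) == 0) stop("empty individual subset")
  nonmiss <- colSums(!is.na(g))
  cnt <- colSums(g, na.rm = TRUE)
  maf <- ifelse(nonmiss == 0, NA_real_,
                pmin(cnt, 2 * nonmiss - cnt) / (2 * nonmiss))
  names(maf) <- colnames(g)
  maf
}

#' Gene-to-SNP membership map
#'
#' @param annotation cohort annotation table.
#' @return Named list: gene id -> character vector of member SNP ids, in
#'   annotation order. Every SNP belongs to exactly one gene.
#' @export
gene_map <- function(annotation) {
  split(annotation$snp_id, annotation$gene)
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes \code{annotation.tsv}, \code{covariates.tsv}, \code{phenotypes.tsv}
#' (columns \code{id}, \code{rep_1..rep_R}) and either \code{genotypes.tsv}
#' (id + one 0/1/2 column per SNP) or \code{genotypes.vcf} (VCF 4.2, GT
#' field; INFO keys \code{GENE} and \code{NS}; the minor allele is written as
#' ALT so ALT dosage equals minor-allele dosage).
#'
#' @param x a \code{cohort}.
#' @param dir output directory (created if needed).
#' @param format \code{"tsv"} or \code{"vcf"} for the genotype component.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(x, dir, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- x$annotation
  if (is.null(ann$chrom)) ann$chrom <- 1L
  if (is.null(ann$pos)) ann$pos <- seq_len(nrow(ann))
  utils::write.table(ann, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(id = rownames(x$phenotypes), x$phenotypes,
                   check.names = FALSE)
  utils::write.table(ph, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (format == "tsv") {
    gt <- data.frame(id = rownames(x$genotypes), x$genotypes,
                     check.names = FALSE)
    utils::write.table(gt, file.path(dir, "genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    .write_vcf(x$genotypes, ann, file.path(dir, "genotypes.vcf"))
  }
  invisible(dir)
}

# Minimal VCF 4.2 text writer. ALT is the minor allele by construction, so
# the ALT dosage in GT equals the stored minor-allele dosage.
.write_vcf <- function(genotypes, ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Nonsynonymous flag\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    d <- genotypes[, j]
    calls <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(ann$chrom[j], ann$pos[j], ann$snp_id[j], "A", "T",
                       ".", "PASS",
                       sprintf("GENE=%s;NS=%d", ann$gene[j],
                               as.integer(ann$nonsynonymous[j])),
                       "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cohort from a directory of plain-text files
#'
#' Inverse of \code{\link{write_cohort}}. For VCF input the ALT dosage is
#' re-oriented to the minor allele on the full sample (if the ALT sample
#' frequency exceeds 0.5 the REF allele is counted instead, i.e. dosage
#' becomes \code{2 - #ALT}), so downstream coding never depends on REF/ALT
#' orientation. SNPs with more than \code{max_missing} missingness are
#' dropped with a warning; remaining missing dosages are kept as NA
#' (collapsing treats them as non-carrier; the SVM feature builder imputes
#' the training-set rounded mean dosage).
#'
#' @param dir directory written by \code{write_cohort}.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param max_missing per-SNP missingness fraction above which the SNP is
#'   dropped (default 0.05).
#' @return A \code{cohort}.
#' @export
read_cohort <- function(dir, format = c("tsv", "vcf"), max_missing = 0.05) {
  format <- match.arg(format)
  ann <- utils::read.delim(file.path(dir, "annotation.tsv"),
                           colClasses = c(snp_id = "character",
                                          gene = "character"))
  cov <- utils::read.delim(file.path(dir, "covariates.tsv"),
                           colClasses = c(id = "character"))
  ph <- utils::read.delim(file.path(dir, "phenotypes.tsv"), check.names = FALSE,
                          colClasses = c(id = "character"))
  phm <- as.matrix(ph[, -1, drop = FALSE])
  rownames(phm) <- ph$id

  if (format == "tsv") {
    gt <- utils::read.delim(file.path(dir, "genotypes.tsv"), check.names = FALSE,
                            colClasses = c(id = "character"))
    g <- as.matrix(gt[, -1, drop = FALSE])
    rownames(g) <- gt$id
    storage.mode(g) <- "integer"
  } else {
    g <- .read_vcf_dosage(file.path(dir, "genotypes.vcf"))
  }

  miss <- colMeans(is.na(g))
  if (any(miss > max_missing)) {
    drop <- colnames(g)[miss > max_missing]
    warning(sprintf("dropping %d SNP(s) with >%.0f%% missing genotypes: %s",
                    length(drop), 100 * max_missing,
                    paste(utils::head(drop, 5), collapse = ",")))
    g <- g[, !(colnames(g) %in% drop), drop = FALSE]
    ann <- ann[!(ann$snp_id %in% drop), , drop = FALSE]
  }
  cohort(g, ann, cov, phm)
}

# Parse a VCF via vcfR and return the minor-allele dosage matrix
# (individuals x SNPs). Multi-allelic records are rejected.
.read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multi-allelic VCF records are not supported; split them first")
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- as.vector(gt)
  ok <- is.na(calls) | grepl("^[01.][/|][01.]$", calls)
  if (!all(ok)) {
    bad_row <- (which(!ok)[1] - 1L) %% nrow(gt) + 1L
    stop(sprintf("malformed VCF genotype call at record %d (%s): '%s'",
                 bad_row, vcfR::getID(v)[bad_row], calls[which(!ok)[1]]))
  }
  # count ALT alleles per call; any-missing allele -> NA dosage
  cnt <- ifelse(is.na(calls) | grepl("\\.", calls), NA_integer_,
                lengths(regmatches(calls, gregexpr("1", calls))))
  d <- matrix(as.integer(cnt), nrow = nrow(gt), dimnames = dimnames(gt))
  d <- t(d)  # individuals x SNPs
  colnames(d) <- vcfR::getID(v)
  # orient to the minor allele on the full sample
  freq <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  storage.mode(d) <- "integer"
  d
}
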