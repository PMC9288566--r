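GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Joint multi-sample variant container
#'
#' One row per (site, ALT allele) after multi-allelic splitting, with a
#' per-plant genotype call re-interpreted against that allele.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qv`.
#' @param genotypes character matrix (`nrow(variants)` x `length(plants)`)
#'   with values `hom_ref`, `het`, `hom_alt` or `missing`.
#' @param plants character vector of plant (sample) identifiers.
#' @return An object of class `cohort_vcf`.
#' @export
cohort_vcf <- function(variants, genotypes, plants) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "qv") %in% names(variants)),
            nrow(genotypes) == nrow(variants),
            ncol(genotypes) == length(plants))
  if (nrow(variants)) {
    if (any(variants$pos <= 0L)) stop("variant position must be positive")
    if (any(variants$ref == variants$alt)) stop("REF equals ALT")
    if (any(!is.na(variants$qv) & variants$qv < 0)) stop("negative quality value")
    if (!all(genotypes %in% GT_LEVELS)) stop("malformed genotype call")
  }
  colnames(genotypes) <- plants
  structure(list(variants = variants, genotypes = genotypes, plants = plants),
            class = "cohort_vcf")
}

#' @export
print.cohort_vcf <- function(x, ...) {
  cat("Joint cohort VCF:", nrow(x$variants), "record(s),",
      length(x$plants), "plant(s)\n")
  invisible(x)
}

# Re-interpret one diploid GT string against ALT allele index `a`.
# "0/2" counted against allele 1 is hom_ref; any "." makes the call missing.
.gt_against_allele <- function(gt, a) {
  gt <- sub(":.*$", "", gt)
  gt[is.na(gt)] <- "./."  # vcfR reports fully missing genotypes as NA
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) != 2L || !all(grepl("^([0-9]+|\\.)$", p)))
      stop("malformed genotype field: ", paste(p, collapse = "/"))
    if (any(p == ".")) return("missing")
    n <- sum(p == as.character(a))
    c("hom_ref", "het", "hom_alt")[n + 1L]
  }, character(1))
}

#' Read a joint multi-sample VCF
#'
#' Multi-allelic sites are split into one record per ALT allele, each keeping
#' the site QUAL; genotypes are re-interpreted against the split allele.
#' `./.` genotypes become `missing`.
#'
#' @param path VCF (v4.x) file path with at least one sample column.
#' @return A [cohort_vcf()].
#' @export
read_joint_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  plants <- colnames(v@gt)[-1]
  if (length(plants) < 1L) stop("VCF has no sample columns")
  n <- nrow(fix)
  if (is.null(n) || n == 0L)
    return(cohort_vcf(data.frame(chrom = character(), pos = integer(),
                                 ref = character(), alt = character(),
                                 qv = numeric()),
                      matrix(character(), 0, length(plants)), plants))
  pos <- as.integer(fix[, "POS"])
  if (any(pos <= 0L)) stop("variant position must be positive")
  rows <- vector("list", n)
  gts <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    qv <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    sub_rows <- vector("list", length(alts))
    sub_gts <- vector("list", length(alts))
    for (a in seq_along(alts)) {
      sub_rows[[a]] <- data.frame(chrom = fix[i, "CHROM"], pos = pos[i],
                                  ref = fix[i, "REF"], alt = alts[a], qv = qv)
      sub_gts[[a]] <- .gt_against_allele(gt_raw[i, ], a)
    }
    rows[[i]] <- do.call(rbind, sub_rows)
    gts[[i]] <- do.call(rbind, sub_gts)
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  cohort_vcf(variants, do.call(rbind, gts), plants)
}

.GT_STRING <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")

#' Write a cohort to VCF
#'
#' Emits a minimal VCF v4.2 with GT-only sample columns, one bi-allelic line
#' per record. Reading the file back reproduces the records field-for-field.
#'
#' @param vcf a [cohort_vcf()].
#' @param path output path.
#' @param contigs optional named vector of contig lengths for header lines.
#' @export
write_joint_vcf <- function(vcf, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vcf$plants), collapse = "\t"), con)
  if (nrow(vcf$variants)) {
    v <- vcf$variants
    qual <- ifelse(is.na(v$qv), ".",
                   format(v$qv, trim = TRUE, scientific = FALSE, digits = 12))
    gt_cols <- lapply(seq_along(vcf$plants), function(j)
      unname(.GT_STRING[vcf$genotypes[, j]]))
    gt_txt <- do.call(paste, c(gt_cols, sep = "\t"))
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, ".", ".", "GT",
                  gt_txt, sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a TSV table with a required schema
#'
#' @param path TSV path with a header row.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_table_tsv <- function(path, required = character()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Write a TSV table
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
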