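#' Classify variant rows as SNV / insertion / deletion
#' @param ref,alt allele strings.
#' @return list with `variant_class` and signed `indel_length` (0 for SNVs).
#' @keywords internal
variant_class_of <- function(ref, alt) {
  dl <- nchar(alt) - nchar(ref)
  cls <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
                ifelse(dl > 0L, "insertion", "deletion"))
  if (any(cls != "SNV" & dl == 0L))
    stop("equal-length multi-base alleles are not supported")
  list(variant_class = cls, indel_length = ifelse(cls == "SNV", 0L, dl))
}

#' Keep cohort-unique heterozygous variants
#'
#' A record survives iff exactly one plant in the cohort is non-reference for
#' the allele and that plant's genotype is heterozygous; the variant is then
#' assigned to that plant. Homozygous-alt carriers disqualify a site, and
#' missing genotypes in other plants are ignored when counting carriers.
#'
#' @param vcf a [cohort_vcf()] with at least two plants (a single-sample VCF
#'   triggers a warning: uniqueness is undefined without a cohort).
#' @return Curated variant data.frame with columns `plant_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `qv`, `variant_class`, `indel_length`.
#' @export
filter_unique_heterozygous <- function(vcf) {
  if (length(vcf$plants) < 2L)
    warning("single-sample VCF: cohort uniqueness is undefined", call. = FALSE)
  gt <- vcf$genotypes
  carriers <- (gt == "het") + (gt == "hom_alt")
  n_carriers <- rowSums(carriers > 0)
  keep <- which(n_carriers == 1L)
  owner_idx <- max.col(carriers[keep, , drop = FALSE], ties.method = "first")
  is_het <- gt[cbind(keep, owner_idx)] == "het"
  keep <- keep[is_het]
  owner <- vcf$plants[owner_idx[is_het]]
  v <- vcf$variants[keep, , drop = FALSE]
  vc <- variant_class_of(v$ref, v$alt)
  out <- data.frame(plant_id = owner, chrom = v$chrom, pos = v$pos,
                    ref = v$ref, alt = v$alt, qv = v$qv,
                    variant_class = vc$variant_class,
                    indel_length = vc$indel_length)
  rownames(out) <- NULL
  out
}

#' Filter variants on site quality value
#'
#' Keeps variants with QV strictly greater than the threshold (a variant with
#' QV exactly at the threshold is removed). Variants with missing QV are
#' removed for any positive threshold.
#'
#' @param variants curated variant data.frame with a `qv` column.
#' @param threshold non-negative QV cutoff.
#' @return Filtered data.frame.
#' @export
apply_qv_threshold <- function(variants, threshold) {
  stopifnot(threshold >= 0)
  if (threshold == 0) return(variants)
  variants[!is.na(variants$qv) & variants$qv > threshold, , drop = FALSE]
}

#' Remove InDels inside repeat-masked regions
#'
#' Only InDel variants are tested against the mask (their POS, the leftmost
#' base); SNVs are kept regardless of masking.
#'
#' @param variants curated variant data.frame.
#' @param mask an [interval_set()].
#' @return Filtered data.frame.
#' @export
remove_masked_indels <- function(variants, mask) {
  if (!nrow(variants)) return(variants)
  is_indel <- variants$variant_class != "SNV"
  masked <- rep(FALSE, nrow(variants))
  if (any(is_indel))
    masked[is_indel] <- interval_member(mask, variants$chrom[is_indel],
                                        variants$pos[is_indel])
  variants[!masked, , drop = FALSE]
}

#' Calibrate the QV threshold against a validation table
#'
#' For each candidate threshold, counts validated variants with QV strictly
#' above it and the fraction confirmed true by independent (Sanger)
#' sequencing.
#'
#' @param validation_rows data.frame with `qv` and logical `confirmed`.
#' @param thresholds numeric vector of candidate thresholds.
#' @return data.frame with `qv_threshold`, `n_tested`, `n_true`,
#'   `true_positive_pct` and `false_positive_pct` (1 decimal; `NA` when
#'   nothing remains above a threshold).
#' @export
calibrate_qv_threshold <- function(validation_rows, thresholds) {
  conf <- validation_rows$confirmed
  if (!is.logical(conf)) conf <- tolower(as.character(conf)) %in% c("yes", "true", "1")
  out <- lapply(sort(thresholds), function(th) {
    sel <- validation_rows$qv > th
    n <- sum(sel)
    nt <- sum(conf[sel])
    data.frame(
      qv_threshold = th, n_tested = n, n_true = nt,
      true_positive_pct = if (n > 0) round_half_up(100 * nt / n, 1)
                          else NA_real_,
      false_positive_pct = if (n > 0) round_half_up(100 * (n - nt) / n, 1)
                           else NA_real_)
  })
  do.call(rbind, out)
}

#' Full curation pipeline
#'
#' Applies, in order: cohort-unique heterozygous filtering, the QV threshold,
#' and removal of repeat-masked InDels. The three filters commute; this order
#' matches the discovery protocol.
#'
#' @param vcf a [cohort_vcf()].
#' @param mask optional [interval_set()] of repeat-masked intervals.
#' @param qv_threshold site quality cutoff (strictly-greater comparison).
#' @return list with `variants` (curated data.frame) and `summary` (list:
#'   `n_snv`, `n_insertion`, `n_deletion`, `n_total`, `per_plant` named
#'   vector of SNV+InDel counts per plant).
#' @export
curate <- function(vcf, mask = NULL, qv_threshold = 80) {
  cur <- filter_unique_heterozygous(vcf)
  cur <- apply_qv_threshold(cur, qv_threshold)
  if (!is.null(mask)) cur <- remove_masked_indels(cur, mask)
  per_plant <- table(factor(cur$plant_id, levels = vcf$plants))
  list(variants = cur,
       summary = list(
         n_snv = sum(cur$variant_class == "SNV"),
         n_insertion = sum(cur$variant_class == "insertion"),
         n_deletion = sum(cur$variant_class == "deletion"),
         n_total = nrow(cur),
         per_plant = stats::setNames(as.integer(per_plant),
                                     names(per_plant))))
}
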